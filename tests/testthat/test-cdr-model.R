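# The deconvolutional model core: IRF evaluation, convolution against a
# brute-force oracle, seeded determinism, early stopping, intercept-only
# recovery, ensembles, and temporal causality.

preds3 <- c("unigram_surprisal", "gpt2_surprisal", "word_length")

test_that("zero-initialized output layer gives zero contributions", {
  sim <- simulate_dataset(small_config(seed = 2), seed = 2)
  cfg <- mlp_test_config(preds3, seed = 2)
  m0 <- unfitted_model(cfg, sim)
  out <- irf_forward(m0, c(unigram_surprisal = 1.3), delay = 0.2)
  expect_equal(unname(out[1, ]), c(0, 0, 0))
  # determinism of the forward pass
  m <- fit_cdr(mlp_test_config(preds3, max_steps = 30, seed = 5),
               sim$events, split_responses(sim$responses)$train,
               split_responses(sim$responses)$validation, seed = 5)
  a <- irf_forward(m, c(gpt2_surprisal = 0.7), delay = c(0, 0.5, 1.5))
  b <- irf_forward(m, c(gpt2_surprisal = 0.7), delay = c(0, 0.5, 1.5))
  expect_identical(a, b)
  expect_error(irf_forward(m, delay = -0.1), "negative delay")
})

test_that("linear IRF with hand-set weights equals the closed-form kernel", {
  sim <- simulate_dataset(small_config(seed = 3), seed = 3)
  cfg <- linear_test_config(preds3, seed = 3)
  m0 <- unfitted_model(cfg, sim)
  W <- m0$pars$nets[[1]]$Wout
  W[] <- 0
  fn <- colnames(prepare_cdr_data(cfg, sim$events,
                                  sim$responses[1:2, ], m0$std,
                                  m0$levels)$feats[[1]])
  # weight 5 on the rate-3 basis feature of gpt2_surprisal, onto tau
  W[which(fn == "gpt2_surprisal@3"), 3] <- 5
  m0$pars$nets[[1]]$Wout <- W
  d <- c(0, 0.25, 1)
  out <- irf_forward(m0, c(gpt2_surprisal = 2), delay = d)
  expect_equal(out[, "tau"], 5 * 2 * exp(-3 * d), tolerance = 1e-12)
  expect_equal(out[, "mu"], rep(0, 3))
})

test_that("convolution matches the brute-force double-loop oracle", {
  set.seed(4)
  worst <- 0
  for (rep in 1:100) {
    cfg <- generator_config(
      n_participants = 2, n_texts = 1,
      n_words_per_text = sample(3:10, 1),
      mean_inter_event_interval = runif(1, 0.1, 0.6),
      seed = rep)
    sim <- simulate_dataset(cfg, seed = rep)
    mcfg <- if (rep %% 2) mlp_test_config(preds3, seed = rep) else
      linear_test_config(preds3, seed = rep)
    m <- unfitted_model(mcfg, sim)
    # randomize all weights so the oracle check is nontrivial
    m$pars <- with_seed(rep, utils::relist(
      rnorm(length(flatten_pars(m$pars)), sd = 0.3), m$pars))
    m$pars$b <- c(250, softplus_inv(40), softplus_inv(150))
    idx <- sample(nrow(sim$responses), 2)
    got <- predict_params(m, sim$events, sim$responses[idx, ])
    for (j in 1:2) {
      want <- oracle_convolve(m, sim$events, sim$responses[idx[j], ])
      worst <- max(worst, max(abs(got[j, ] - want)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("duplicated event at one timestamp doubles its contribution", {
  cfg <- generator_config(n_participants = 1, n_texts = 1,
                          n_words_per_text = 3)
  sim <- simulate_dataset(cfg, seed = 6)
  m <- unfitted_model(linear_test_config(names(cfg$predictors), seed = 6),
                      sim)
  m$pars$nets[[1]]$Wout[] <- 0.5
  resp <- sim$responses[3, ]
  one <- predict_params(m, sim$events, resp)
  ev2 <- rbind(sim$events, sim$events)
  two <- predict_params(m, ev2, resp)
  base <- m$pars$b
  # pre-link contributions double exactly
  expect_equal(two[1, "mu"] - base[1], 2 * (one[1, "mu"] - base[1]),
               tolerance = 1e-10)
  # empty history: baseline-only parameters
  early <- resp
  early$time_s <- sim$events$time_s[1] - 5
  p0 <- predict_params(m, sim$events, early)
  expect_equal(unname(p0[1, ]),
               c(base[1], softplus(base[2]) + 1, softplus(base[3]) + 1),
               tolerance = 1e-12)
  expect_equal(attr(p0, "n_no_history"), 1L)
})

test_that("temporal causality: later events never affect a response", {
  cfg <- small_config(seed = 8)
  sim <- simulate_dataset(cfg, seed = 8)
  m <- unfitted_model(linear_test_config(preds3, seed = 8), sim)
  m$pars$nets[[1]]$Wout[] <- with_seed(8, rnorm(length(m$pars$nets[[1]]$Wout)))
  resp <- sim$responses[10, , drop = FALSE]
  before <- predict_params(m, sim$events, resp)
  ev <- sim$events
  later <- ev$time_s > resp$time_s + 1e-6
  ev$unigram_surprisal[later] <- ev$unigram_surprisal[later] + 100
  after <- predict_params(m, ev, resp)
  expect_equal(before[1, ], after[1, ], tolerance = 1e-12)
})

test_that("intercept-only fit recovers generator parameters within 5%", {
  cfg <- generator_config(
    n_participants = 4, n_texts = 5, n_words_per_text = 250,
    effects = list(), participant_sd = c(mu = 0, sigma = 0, tau = 0))
  sim <- simulate_dataset(cfg, seed = 12)            # 5,000 responses
  sp <- split_responses(sim$responses)
  icfg <- cdr_config(preds3, networks = list(), irf = "linear",
                     optimizer = "lbfgs", max_steps = 200,
                     ranef_participant = FALSE, ranef_gain = FALSE,
                     ranef_token = FALSE, lambda = 0, seed = 12)
  m <- fit_cdr(icfg, sim$events, sp$train, sp$validation, seed = 12)
  got <- c(m$pars$b[1], softplus(m$pars$b[2]) + 1, softplus(m$pars$b[3]) + 1)
  expect_equal(got[1], 250, tolerance = 0.05 * 250)
  expect_equal(got[2], 40, tolerance = 0.05 * 40)
  expect_equal(got[3], 150, tolerance = 0.05 * 150)
})

test_that("fits are deterministic in (config, data, seed) and early-stopped", {
  sim <- simulate_dataset(small_config(seed = 13), seed = 13)
  sp <- split_responses(sim$responses)
  cfg <- mlp_test_config(preds3, max_steps = 60, seed = 13)
  m1 <- fit_cdr(cfg, sim$events, sp$train, sp$validation, seed = 13)
  m2 <- fit_cdr(cfg, sim$events, sp$train, sp$validation, seed = 13)
  expect_identical(m1$val_loglik, m2$val_loglik)
  expect_identical(flatten_pars(m1$pars), flatten_pars(m2$pars))
  m3 <- fit_cdr(cfg, sim$events, sp$train, sp$validation, seed = 14)
  expect_false(identical(m1$val_loglik, m3$val_loglik))
  # returned checkpoint is at least as good as the final step
  expect_gte(m1$val_loglik, m1$final_val_loglik)
})

test_that("minibatch training runs and improves over the initialization", {
  sim <- simulate_dataset(small_config(seed = 19), seed = 19)
  sp <- split_responses(sim$responses)
  cfg <- mlp_test_config(preds3, batch_size = 64, max_steps = 120,
                         eval_every = 30, seed = 19)
  m <- fit_cdr(cfg, sim$events, sp$train, sp$validation, seed = 19)
  m0 <- unfitted_model(cfg, sim)
  expect_gt(m$val_loglik, m0$val_loglik - 1e-9)
})

test_that("ensembles record distinct seeds and are order-invariant", {
  sim <- simulate_dataset(small_config(seed = 15), seed = 15)
  sp <- split_responses(sim$responses)
  cfg <- linear_test_config(preds3, max_steps = 60, seed = 15)
  ens <- fit_ensemble(cfg, sim$events, sp$train, sp$validation,
                      n_members = 3, base_seed = 100)
  expect_equal(ens$seeds, c(100, 101, 102))
  expect_equal(length(ens), 3L)
  ll <- test_loglik(ens, sim$events, sp$test)
  perm <- new_ensemble(ens$members[c(3, 1, 2)])
  ll2 <- test_loglik(perm, sim$events, sp$test)
  expect_equal(as.numeric(ll), as.numeric(ll2), tolerance = 1e-12)
  expect_error(fit_ensemble(cfg, sim$events, sp$train, sp$validation,
                            n_members = 1), "at least 2")
})

test_that("ensemble log-likelihood is the log mean member density", {
  sim <- simulate_dataset(small_config(seed = 16), seed = 16)
  sp <- split_responses(sim$responses)
  cfg <- linear_test_config(preds3, max_steps = 60, seed = 16)
  m <- fit_cdr(cfg, sim$events, sp$train, sp$validation, seed = 16)
  single <- new_ensemble(list(m))
  ll1 <- test_loglik(single, sim$events, sp$test)
  p <- predict_params(m, sim$events, sp$test)
  direct <- dexgauss(sp$test$duration_ms, p[, "mu"], p[, "sigma"],
                     p[, "tau"], log = TRUE)
  expect_equal(as.numeric(ll1), direct, tolerance = 1e-12)
  # identical members: mixture equals the common density
  twin <- new_ensemble(list(m, m))
  ll2 <- test_loglik(twin, sim$events, sp$test)
  expect_equal(as.numeric(ll2), direct, tolerance = 1e-12)
  # conservation: vector sums to the total
  expect_equal(sum(ll1), sum(direct))
})

test_that("held-out likelihood of the full model beats intercept-only", {
  cfg <- generator_config(n_participants = 4, n_texts = 4,
                          n_words_per_text = 100)
  sim <- simulate_dataset(cfg, seed = 17)
  sp <- split_responses(sim$responses)
  full <- linear_test_config(preds3, seed = 17)
  m <- fit_cdr(full, sim$events, sp$train, sp$validation, seed = 17)
  icfg <- cdr_config(preds3, networks = list(), irf = "linear",
                     optimizer = "lbfgs", max_steps = 100,
                     ranef_gain = FALSE, ranef_token = FALSE, seed = 17)
  m0 <- fit_cdr(icfg, sim$events, sp$train, sp$validation, seed = 17)
  llf <- test_loglik(new_ensemble(list(m)), sim$events, sp$test)
  ll0 <- test_loglik(new_ensemble(list(m0)), sim$events, sp$test)
  expect_gt(mean(llf), mean(ll0))
})

test_that("checkpoints round-trip and reproduce the validation likelihood", {
  sim <- simulate_dataset(small_config(seed = 21), seed = 21)
  sp <- split_responses(sim$responses)
  cfg <- linear_test_config(preds3, max_steps = 60, seed = 21)
  m <- fit_cdr(cfg, sim$events, sp$train, sp$validation, seed = 21)
  path <- tempfile(fileext = ".rds")
  write_cdr_model(m, path)
  back <- read_cdr_model(path)
  expect_identical(back$val_loglik, m$val_loglik)
  d <- prepare_cdr_data(back$config, sim$events, sp$validation, back$std,
                        back$levels)
  recomputed <- mean(cdr_loss_grad(back$pars, d, back$config,
                                   want_grad = FALSE)$loglik)
  expect_equal(recomputed, m$val_loglik, tolerance = 1e-12)
  saveRDS(list(1), path)
  expect_error(read_cdr_model(path), "checkpoint")
})

test_that("unknown participants fall back to population-level effects", {
  sim <- simulate_dataset(small_config(seed = 18), seed = 18)
  sp <- split_responses(sim$responses)
  cfg <- linear_test_config(preds3, max_steps = 60, seed = 18)
  m <- fit_cdr(cfg, sim$events, sp$train, sp$validation, seed = 18)
  test <- sp$test[1:5, ]
  test$participant_id <- "p99"
  ev <- sim$events[sim$events$participant_id == sp$test$participant_id[1], ]
  ev$participant_id <- "p99"
  p <- predict_params(m, rbind(sim$events, ev), test)
  expect_equal(attr(p, "n_unknown_participant"), 5L)
  expect_true(all(is.finite(p)))
})
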