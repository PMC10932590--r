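# Shared fixtures: small simulated datasets and reduced model settings used
# across the test files. Everything is generated in code at test time.

small_config <- function(seed = 1L, ...) {
  generator_config(n_participants = 4, n_texts = 2, n_words_per_text = 50,
                   seed = seed, ...)
}

# Reduced-size model configurations: small history window and network so
# fits stay desk-scale. The linear configuration is closed-form in its
# weights and is used wherever many fits are needed.
linear_test_config <- function(preds, seed = 1L, ...) {
  args <- list(predictors = preds, irf = "linear", history_n = 6,
               history_t = 3, optimizer = "lbfgs", max_steps = 150,
               lambda = 0.01, ranef_token = FALSE, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cdr_config, args)
}

mlp_test_config <- function(preds, seed = 1L, ...) {
  args <- list(predictors = preds, irf = "mlp", hidden = 8L, history_n = 6,
               history_t = 3, optimizer = "adam", learning_rate = 0.08,
               batch_size = Inf, max_steps = 400, eval_every = 20,
               patience = 6, lambda = 0.01, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cdr_config, args)
}

# Independent brute-force oracle for the smoothed n-gram conditionals,
# computed directly from raw token sequences (no shared code with the
# package implementation beyond the definition itself).
oracle_base_prob <- function(sentences, w) {
  toks <- unlist(sentences)
  n <- length(toks)
  cnt <- sum(toks == w)
  if (cnt > 0) cnt / (n + 1) else 1 / (n + 1)
}

oracle_cond_prob <- function(sentences, context, w, order, D = 0.75) {
  if (order == 1) return(oracle_base_prob(sentences, w))
  ctx <- tail(context, order - 1)
  # enumerate all order-grams with <s> padding
  grams <- lapply(sentences, function(s) {
    padded <- c(rep("<s>", order - 1), s)
    if (length(padded) < order) return(NULL)
    t(vapply(seq_len(length(padded) - order + 1),
             function(i) padded[i:(i + order - 1)], character(order)))
  })
  grams <- do.call(rbind, grams)
  is_ctx <- rep(TRUE, nrow(grams))
  for (j in seq_along(ctx)) is_ctx <- is_ctx & grams[, j] == ctx[j]
  c_ctx <- sum(is_ctx)
  lower <- oracle_cond_prob(sentences, ctx[-1], w, order - 1, D)
  if (c_ctx == 0) return(lower)
  c_full <- sum(is_ctx & grams[, order] == w)
  n1p <- length(unique(grams[is_ctx, order]))
  max(c_full - D, 0) / c_ctx + D * n1p / c_ctx * lower
}

# Brute-force convolution oracle: naive double loop over responses and
# events, calling the exported single-event IRF evaluator.
oracle_convolve <- function(model, events, response) {
  config <- model$config
  eta <- model$pars$b
  sel <- which(events$participant_id == response$participant_id &
                 events$text_id == response$text_id &
                 events$time_s <= response$time_s + 1e-9)
  sel <- sel[order(events$time_s[sel])]
  if (length(sel) > config$history_n)
    sel <- sel[(length(sel) - config$history_n + 1):length(sel)]
  sel <- sel[events$time_s[sel] >= response$time_s - config$history_t]
  p_idx <- match(response$participant_id, model$levels$participants)
  for (m in seq_along(config$networks)) {
    gain <- 1
    if (!is.null(model$pars$gain) && !is.na(p_idx)) {
      gc <- model$pars$gain[, m] - mean(model$pars$gain[, m])
      gain <- 1 + gc[p_idx]
    }
    for (e in sel) {
      x <- vapply(used_predictors(config), function(p)
        (events[[p]][e] - model$std$mean[[p]]) / model$std$sd[[p]],
        numeric(1))
      contrib <- irf_forward(model, x, response$time_s - events$time_s[e],
                             network = m)
      eta <- eta + gain * contrib[1, ]
    }
  }
  if (!is.null(model$pars$u) && !is.na(p_idx))
    eta <- eta + model$pars$u[p_idx, ]
  if (!is.null(model$pars$wtok))
    eta[1] <- eta[1] + model$pars$wtok[
      min(max(response$token_position, 1), model$levels$n_token)]
  c(mu = eta[[1]], sigma = softplus(eta[[2]]) + 1,
    tau = softplus(eta[[3]]) + 1)
}

# A quickly fitted throwaway model (zero optimization steps) whose weights
# can be set by hand for oracle tests.
unfitted_model <- function(config, sim) {
  cfg0 <- config
  cfg0$optimizer <- "adam"
  cfg0$max_steps <- 0L
  fit_cdr(cfg0, sim$events, sim$responses, sim$responses,
          seed = config$seed)
}
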