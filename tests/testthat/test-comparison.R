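# Null-model construction and the paired permutation machinery.

preds3 <- c("unigram_surprisal", "gpt2_surprisal", "word_length")

test_that("drop_predictor removes the target from every network", {
  full <- cdr_config(preds3)
  pair <- build_null_config(full, ablation_spec("drop_predictor",
                                                "unigram_surprisal"))
  expect_false("unigram_surprisal" %in% pair$null$networks[[1]]$predictors)
  expect_identical(pair$alternative, full)
  # sequential ablation of both critical predictors leaves controls intact
  pair2 <- build_null_config(pair$null,
                             ablation_spec("drop_predictor",
                                           "gpt2_surprisal"))
  expect_equal(pair2$null$networks[[1]]$predictors, "word_length")
  expect_error(build_null_config(full, ablation_spec("drop_predictor",
                                                     "absent")), "absent")
})

test_that("interaction null splits the critical pair across two networks", {
  full <- cdr_config(preds3, irf = "linear", interactions = TRUE)
  pair <- build_null_config(
    full, ablation_spec("interaction_null",
                        c("unigram_surprisal", "gpt2_surprisal")))
  n1 <- pair$null$networks[[1]]$predictors
  n2 <- pair$null$networks[[2]]$predictors
  expect_true("unigram_surprisal" %in% n1 && !"gpt2_surprisal" %in% n1)
  expect_true("gpt2_surprisal" %in% n2 && !"unigram_surprisal" %in% n2)
  expect_true(all(c("word_length") %in% intersect(n1, n2)))
  # matched alternative: two redundant all-predictor networks
  expect_length(pair$alternative$networks, 2)
  for (net in pair$alternative$networks)
    expect_setequal(net$predictors, preds3)
})

test_that("distributional drop removes one predictor from one network", {
  full <- cdr_config(preds3)
  pair <- build_null_config(
    full, ablation_spec("distributional_drop", "unigram_surprisal",
                        param = "tau"))
  expect_length(pair$null$networks, 3)
  expect_length(pair$alternative$networks, 3)
  for (i in 1:3) {
    par <- pair$null$networks[[i]]$params
    if (par == "tau") {
      expect_false("unigram_surprisal" %in% pair$null$networks[[i]]$predictors)
    } else {
      expect_true("unigram_surprisal" %in% pair$null$networks[[i]]$predictors)
    }
    expect_setequal(pair$alternative$networks[[i]]$predictors, preds3)
  }
  expect_error(ablation_spec("distributional_drop", "unigram_surprisal"),
               "mu/sigma/tau")
  expect_error(ablation_spec("interaction_null", "one"), "two")
})

test_that("permutation test handles identical, shifted, and swapped inputs", {
  set.seed(2)
  ll <- rnorm(50, -6, 1)
  same <- paired_permutation_test(ll, ll, n_permutations = 499, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # a uniform shift is detected at (nearly) the smallest attainable p;
  # only the rare all-same-sign draws can tie the observed statistic
  shift <- paired_permutation_test(ll, ll + 0.5, n_permutations = 999,
                                   seed = 1)
  expect_gte(shift$p_value, 1 / 1000)
  expect_lt(shift$p_value, 0.02)
  expect_equal(shift$statistic, 25)

  expect_error(paired_permutation_test(1:3, 1:4), "length")
  expect_error(paired_permutation_test(1, 1), "two")
})

test_that("p-values are invariant to common shifts and to A/B swap", {
  set.seed(7)
  llA <- rnorm(80, -6, 1)
  llB <- llA + rnorm(80, 0.05, 0.3)
  r1 <- paired_permutation_test(llA, llB, n_permutations = 999, seed = 3)
  r2 <- paired_permutation_test(llA + 10, llB + 10, n_permutations = 999,
                                seed = 3)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  r3 <- paired_permutation_test(llB, llA, n_permutations = 999, seed = 3)
  expect_equal(r3$statistic, -r1$statistic, tolerance = 1e-10)
  expect_equal(r3$p_value, r1$p_value)
  # permutation p-values are deterministic given the seed
  r4 <- paired_permutation_test(llA, llB, n_permutations = 999, seed = 3)
  expect_identical(r1$p_value, r4$p_value)
})

test_that("under exchangeable noise the test is calibrated", {
  # pure datapoint-level noise: the sign-flip null is exact here
  set.seed(11)
  ps <- replicate(400, {
    d <- rnorm(40)
    paired_permutation_test(rep(0, 40), d, n_permutations = 199,
                            seed = sample.int(1e6, 1))$p_value
  })
  rate <- mean(ps <= 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("aggregate test pools datasets and reports contributions", {
  set.seed(9)
  llA1 <- rnorm(40); llB1 <- llA1 + rnorm(40, 0.1, 0.2)
  llA2 <- rnorm(60); llB2 <- llA2 + rnorm(60, 0.1, 0.2)
  single <- paired_permutation_test(llA1, llB1, n_permutations = 999,
                                    seed = 2)
  agg1 <- aggregate_test(list(d1 = list(llA = llA1, llB = llB1)),
                         n_permutations = 999, seed = 2)
  expect_equal(agg1$statistic, single$statistic)
  expect_equal(agg1$p_value, single$p_value)

  agg <- aggregate_test(list(d1 = list(llA = llA1, llB = llB1),
                             d2 = list(llA = llA2, llB = llB2)),
                        n_permutations = 999, seed = 2)
  expect_equal(agg$n, 100)
  expect_equal(agg$per_dataset$statistic,
               c(sum(llB1 - llA1), sum(llB2 - llA2)))
  # equal-and-opposite totals cancel
  opp <- aggregate_test(list(list(llA = llA1, llB = llA1 + 0.1),
                             list(llA = llA2[1:40], llB = llA2[1:40] - 0.1)),
                        n_permutations = 199, seed = 2)
  expect_equal(opp$statistic, 0, tolerance = 1e-10)
  expect_error(aggregate_test(list()), "empty")
})

test_that("consistently signed small effects gain power when pooled", {
  # three small datasets, each individually non-significant but with
  # consistently signed totals: pooling should sharpen the evidence
  set.seed(13)
  n_qualifying <- 0L
  n_better <- 0L
  for (r in 1:120) {
    sets <- lapply(1:3, function(i) {
      llA <- rnorm(25)
      list(llA = llA, llB = llA + rnorm(25, 0.12, 0.45))
    })
    stats_i <- vapply(sets, function(s) sum(s$llB - s$llA), numeric(1))
    indiv <- vapply(sets, function(s)
      paired_permutation_test(s$llA, s$llB, 499, seed = r)$p_value,
      numeric(1))
    if (!(all(stats_i > 0) && all(indiv > 0.05))) next
    n_qualifying <- n_qualifying + 1L
    agg <- aggregate_test(sets, 499, seed = r)$p_value
    if (agg < min(indiv)) n_better <- n_better + 1L
  }
  expect_gte(n_qualifying, 20L)
  expect_gte(n_better / n_qualifying, 0.9)
})
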