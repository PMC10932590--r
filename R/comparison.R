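#' Ablation specification for null-model construction
#'
#' Describes how to turn the full model configuration into a matched
#' null/alternative pair:
#' * `"drop_predictor"` -- remove the target predictor(s) from every
#'   network (tests the predictor's overall contribution).
#' * `"interaction_null"` -- the null splits the model into two networks,
#'   one convolving the first target predictor plus all controls and the
#'   other the second target plus all controls, so the two targets can
#'   interact with controls but not with each other; the matched
#'   alternative contains two redundant networks that each convolve all
#'   predictors.
#' * `"distributional_drop"` -- the alternative has three networks, one
#'   per distributional parameter, each seeing all predictors; the null
#'   removes the target predictor from exactly the network generating the
#'   named parameter.
#'
#' @param kind one of `"drop_predictor"`, `"interaction_null"`,
#'   `"distributional_drop"`.
#' @param predictors target predictor(s): any number for
#'   `drop_predictor`, exactly two for `interaction_null`, exactly one for
#'   `distributional_drop`.
#' @param param for `distributional_drop`: one of `"mu"`, `"sigma"`,
#'   `"tau"`.
#' @return object of class `ablation_spec`.
#' @export
ablation_spec <- function(kind = c("drop_predictor", "interaction_null",
                                   "distributional_drop"),
                          predictors, param = NULL) {
  kind <- match.arg(kind)
  if (kind == "interaction_null" && length(predictors) != 2L)
    stop("interaction_null needs exactly two target predictors")
  if (kind == "distributional_drop") {
    if (length(predictors) != 1L)
      stop("distributional_drop targets exactly one predictor")
    if (is.null(param) || !param %in% c("mu", "sigma", "tau"))
      stop("distributional_drop must name one of mu/sigma/tau")
  }
  structure(list(kind = kind, predictors = predictors, param = param),
            class = "ablation_spec")
}

#' Build a matched null/alternative configuration pair
#'
#' @param full the full-model [cdr_config()].
#' @param spec an [ablation_spec()].
#' @return list with elements `null` and `alternative`, both `cdr_config`s.
#'   For `drop_predictor` the alternative is the full configuration itself;
#'   for the other kinds both members are rebuilt so the architectures are
#'   matched and differ only in the ablated inputs.
#' @export
build_null_config <- function(full, spec) {
  stopifnot(inherits(full, "cdr_config"), inherits(spec, "ablation_spec"))
  missing <- setdiff(spec$predictors, full$predictors)
  if (length(missing))
    stop("ablation targets absent from the model: ",
         paste(missing, collapse = ", "))
  remake <- function(networks, predictors = full$predictors) {
    cfg <- full
    cfg$predictors <- predictors
    cfg$networks <- networks
    cfg
  }
  all_p <- full$predictors
  switch(spec$kind,
    drop_predictor = {
      keep <- setdiff(all_p, spec$predictors)
      nets <- lapply(full$networks, function(net) {
        net$predictors <- setdiff(net$predictors, spec$predictors)
        if (!length(net$predictors))
          stop("ablation empties a network: ",
               paste(spec$predictors, collapse = ", "))
        net
      })
      list(null = remake(nets, keep), alternative = full)
    },
    interaction_null = {
      a <- spec$predictors[1]; b <- spec$predictors[2]
      null_nets <- list(
        list(predictors = setdiff(all_p, b), params = c("mu", "sigma", "tau")),
        list(predictors = setdiff(all_p, a), params = c("mu", "sigma", "tau")))
      alt_nets <- list(
        list(predictors = all_p, params = c("mu", "sigma", "tau")),
        list(predictors = all_p, params = c("mu", "sigma", "tau")))
      list(null = remake(null_nets), alternative = remake(alt_nets))
    },
    distributional_drop = {
      alt_nets <- lapply(c("mu", "sigma", "tau"), function(par)
        list(predictors = all_p, params = par))
      null_nets <- lapply(c("mu", "sigma", "tau"), function(par) {
        p <- if (par == spec$param) setdiff(all_p, spec$predictors) else all_p
        if (!length(p)) stop("ablation empties a network")
        list(predictors = p, params = par)
      })
      list(null = remake(null_nets), alternative = remake(alt_nets))
    })
}

perm_stat_null <- function(diffs, n_permutations, seed, chunk = 200L) {
  n <- length(diffs)
  with_seed(seed + 11L, {
    stats_null <- numeric(n_permutations)
    done <- 0L
    while (done < n_permutations) {
      k <- min(chunk, n_permutations - done)
      signs <- matrix(sample(c(-1, 1), k * n, replace = TRUE), k, n)
      stats_null[done + seq_len(k)] <- as.numeric(signs %*% diffs)
      done <- done + k
    }
    stats_null
  })
}

#' Paired permutation test of out-of-sample log-likelihood
#'
#' Compares two ensembles scored on the same test responses. The observed
#' statistic is `sum(llB - llA)`; the null distribution is generated by
#' independently swapping the two ensembles' log-likelihoods per datapoint
#' (sign-flipping the paired differences) with probability 1/2. The
#' two-sided p-value uses the add-one correction
#' `p = (1 + #{|stat*| >= |stat|}) / (n_permutations + 1)`, so the smallest
#' attainable p is `1/(n_permutations + 1)`.
#'
#' @param llA,llB numeric vectors of per-datapoint log-likelihoods for
#'   ensembles A (null) and B (alternative), aligned on the same
#'   datapoints.
#' @param n_permutations number of sign permutations (default 10,000).
#' @param seed integer seed for the permutation draws.
#' @return object of class `comparison_result` with elements `statistic`,
#'   `p_value`, `n`, `n_permutations`, `seed`, and the two total
#'   likelihoods.
#' @export
paired_permutation_test <- function(llA, llB, n_permutations = 10000L,
                                    seed = 1L) {
  llA <- as.numeric(llA); llB <- as.numeric(llB)
  if (length(llA) != length(llB))
    stop("log-likelihood vectors differ in length")
  if (length(llA) < 2L) stop("need at least two paired datapoints")
  diffs <- llB - llA
  stat <- sum(diffs)
  null_stats <- perm_stat_null(diffs, n_permutations, seed)
  p <- (1 + sum(abs(null_stats) >= abs(stat) - 1e-12)) / (n_permutations + 1)
  structure(list(statistic = stat, p_value = p, n = length(diffs),
                 n_permutations = as.integer(n_permutations), seed = seed,
                 total_llA = sum(llA), total_llB = sum(llB),
                 per_dataset = NULL),
            class = "comparison_result")
}

#' Aggregate permutation test across datasets
#'
#' Pools the per-datapoint paired differences of several dataset-level
#' comparisons and applies the same sign-flipping permutation scheme to the
#' pooled vector, reporting each dataset's contribution to the statistic.
#'
#' @param per_dataset_pairs non-empty named or unnamed list; each element
#'   is a list with components `llA` and `llB`.
#' @inheritParams paired_permutation_test
#' @return a `comparison_result` whose `per_dataset` element is a
#'   data.frame of per-dataset statistics and sizes.
#' @export
aggregate_test <- function(per_dataset_pairs, n_permutations = 10000L,
                           seed = 1L) {
  if (!length(per_dataset_pairs)) stop("empty list of dataset pairs")
  diffs_list <- lapply(per_dataset_pairs, function(p) {
    if (length(p$llA) != length(p$llB))
      stop("log-likelihood vectors differ in length")
    p$llB - p$llA
  })
  nm <- names(per_dataset_pairs)
  if (is.null(nm)) nm <- paste0("dataset", seq_along(per_dataset_pairs))
  llA <- unlist(lapply(per_dataset_pairs, `[[`, "llA"))
  llB <- unlist(lapply(per_dataset_pairs, `[[`, "llB"))
  res <- paired_permutation_test(llA, llB, n_permutations, seed)
  res$per_dataset <- data.frame(
    dataset = nm,
    statistic = vapply(diffs_list, sum, numeric(1)),
    n = vapply(diffs_list, length, integer(1)))
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Paired permutation test of out-of-sample log-likelihood\n")
  cat(sprintf("  statistic (sum of paired differences): %.4f over %d datapoints\n",
              x$statistic, x$n))
  cat(sprintf("  p = %.4g (%d permutations, two-sided, add-one corrected)\n",
              x$p_value, x$n_permutations))
  if (!is.null(x$per_dataset)) {
    cat("  per-dataset contributions:\n")
    print(x$per_dataset, row.names = FALSE)
  }
  invisible(x)
}
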