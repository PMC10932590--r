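#' Configuration for a continuous-time deconvolutional exGaussian model
#'
#' A CDR model relates a stream of timestamped word events to the location
#' (`mu`), dispersion (`sigma`), and skewness (`tau`) parameters of an
#' exGaussian predictive distribution over reading times. Each of one or
#' more impulse-response networks maps (event predictors, delay) to additive
#' pre-link contributions to the distributional parameters it targets; a
#' response's parameters are the baseline plus random effects plus the sum
#' of contributions from all in-window past events, passed through the
#' links (identity for `mu`, softplus for `sigma` and `tau`).
#'
#' Two IRF families are available:
#' * `"mlp"` -- a small feed-forward network with tanh hidden layers whose
#'   inputs are the standardized predictors plus the delay encoded as
#'   `(d, log(1 + d))`; the output layer is zero-initialized so the model
#'   starts at the baseline-only solution.
#' * `"linear"` -- a closed-form kernel-basis configuration with no hidden
#'   layers: features are the predictors (optionally with within-network
#'   pairwise products) scaled by exponential-decay basis functions
#'   `exp(-r d)` at fixed rates. Contributions are exactly linear in the
#'   weights, which makes this configuration suitable for oracle tests and
#'   fast large-scale simulation studies.
#'
#' @param predictors character vector: predictor columns available in the
#'   event table.
#' @param networks list of network specifications, each
#'   `list(predictors = <chr>, params = <subset of c("mu","sigma","tau")>)`.
#'   Default: one network with all predictors targeting all parameters.
#'   Multi-network configurations express the null models used for
#'   interaction and distributional-parameter tests.
#' @param irf `"mlp"` or `"linear"`.
#' @param hidden integer vector of hidden-layer widths (mlp only).
#' @param basis_rates exponential decay rates (1/s) of the kernel basis
#'   (linear only). The default log-spaced triple spans decay scales from
#'   roughly 0.1 s to 1 s.
#' @param interactions logical (linear only): include pairwise products of
#'   a network's predictors among its features.
#' @param history_n,history_t history window: at most `history_n` events
#'   and at most `history_t` seconds before the response, whichever
#'   truncates first.
#' @param ranef_participant by-participant additive offsets on the three
#'   pre-link baselines.
#' @param ranef_gain by-participant multiplicative gain on each network's
#'   output (a random-slope analogue on the IRF).
#' @param ranef_token by-token-position intercepts on pre-link `mu`.
#' @param lambda L2 shrinkage strength on all random effects.
#' @param optimizer `"adam"` (stochastic gradient, early stopping on
#'   validation likelihood) or `"lbfgs"` (full-batch quasi-Newton).
#' @param learning_rate,batch_size,max_steps,eval_every,patience training
#'   controls: Adam step size; responses per minibatch (`Inf` = full
#'   batch); maximum optimization steps; validation-evaluation interval in
#'   steps; evaluations without improvement before stopping.
#' @param init_sd standard deviation of random weight initialization.
#' @param seed default fitting seed (overridden by `fit_cdr`'s `seed`).
#' @return object of class `cdr_config`.
#' @seealso [fit_cdr()], [fit_ensemble()], [build_null_config()]
#' @export
cdr_config <- function(predictors,
                       networks = NULL,
                       irf = c("mlp", "linear"),
                       hidden = c(64L, 64L),
                       basis_rates = c(1, 3, 9),
                       interactions = FALSE,
                       history_n = 32L,
                       history_t = 20,
                       ranef_participant = TRUE,
                       ranef_gain = TRUE,
                       ranef_token = TRUE,
                       lambda = 0.01,
                       optimizer = c("adam", "lbfgs"),
                       learning_rate = 0.03,
                       batch_size = 1024,
                       max_steps = 2000L,
                       eval_every = 25L,
                       patience = 10L,
                       init_sd = 0.1,
                       seed = 1L) {
  irf <- match.arg(irf)
  optimizer <- match.arg(optimizer)
  if (is.null(networks)) {
    networks <- list(list(predictors = predictors,
                          params = c("mu", "sigma", "tau")))
  }
  for (net in networks) {
    if (!all(net$predictors %in% predictors))
      stop("network names predictors absent from the predictor list: ",
           paste(setdiff(net$predictors, predictors), collapse = ", "))
    if (!all(net$params %in% c("mu", "sigma", "tau")) || !length(net$params))
      stop("network params must be a non-empty subset of mu/sigma/tau")
  }
  if (history_n < 1L || history_t <= 0)
    stop("history window must be positive")
  cfg <- list(predictors = predictors, networks = networks, irf = irf,
              hidden = as.integer(hidden), basis_rates = basis_rates,
              interactions = interactions,
              history_n = as.integer(history_n), history_t = history_t,
              ranef_participant = ranef_participant,
              ranef_gain = ranef_gain, ranef_token = ranef_token,
              lambda = lambda, optimizer = optimizer,
              learning_rate = learning_rate, batch_size = batch_size,
              max_steps = as.integer(max_steps),
              eval_every = as.integer(eval_every),
              patience = as.integer(patience),
              init_sd = init_sd, seed = as.integer(seed))
  class(cfg) <- "cdr_config"
  cfg
}

#' @export
print.cdr_config <- function(x, ...) {
  cat("Continuous-time deconvolutional exGaussian model configuration\n")
  cat(sprintf("  IRF family: %s%s\n", x$irf,
              if (x$irf == "mlp")
                sprintf(" (hidden: %s)", paste(x$hidden, collapse = "x"))
              else
                sprintf(" (basis rates: %s%s)",
                        paste(x$basis_rates, collapse = ", "),
                        if (x$interactions) "; with interactions" else "")))
  for (i in seq_along(x$networks)) {
    cat(sprintf("  network %d: [%s] -> {%s}\n", i,
                paste(x$networks[[i]]$predictors, collapse = ", "),
                paste(x$networks[[i]]$params, collapse = ", ")))
  }
  cat(sprintf("  history window: %d events / %.3g s\n",
              x$history_n, x$history_t))
  cat(sprintf("  optimizer: %s (lr %.3g, batch %s, max %d steps)\n",
              x$optimizer, x$learning_rate,
              if (is.finite(x$batch_size)) x$batch_size else "full",
              x$max_steps))
  invisible(x)
}

# Column indices (within the eta matrix) that a network targets.
net_param_idx <- function(net) {
  match(net$params, c("mu", "sigma", "tau"))
}
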