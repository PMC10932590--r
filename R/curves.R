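# Effect-curve extraction from fitted ensembles: instantaneous effects,
# interaction overlays, delay timecourses, and ensemble uncertainty bands.

# Evaluate a member model's predicted response for a batch of standardized
# predictor settings, under the reporting convention used by all curves:
# zero random effects, a single conditioning event observed `delay` seconds
# before the response, all other predictors at their (standardized) means.
member_response <- function(model, xz, delay, scale) {
  config <- model$config
  n <- nrow(xz)
  eta <- matrix(rep(model$pars$b, each = n), n, 3)
  for (m in seq_along(config$networks)) {
    net <- config$networks[[m]]
    H <- network_features(config, net, xz, rep(delay, n))
    W <- model$pars$nets[[m]]
    if (config$irf == "mlp") {
      for (l in seq_along(config$hidden))
        H <- tanh(sweep(H %*% W[[paste0("W", l)]], 2,
                        W[[paste0("b", l)]], `+`))
      out <- sweep(H %*% W$Wout, 2, W$bout, `+`)
    } else {
      out <- H %*% W$Wout
    }
    idx <- net_param_idx(net)
    eta[, idx] <- eta[, idx] + out
  }
  # same links as cdr_forward (softplus with the 1 ms floor)
  switch(scale,
         mean = eta[, 1] + softplus(eta[, 3]) + 1,
         mu = eta[, 1],
         sigma = softplus(eta[, 2]) + 1,
         tau = softplus(eta[, 3]) + 1)
}

curve_xz <- function(model, predictor, grid, conditioning) {
  preds <- used_predictors(model$config)
  xz <- matrix(0, length(grid), length(preds),
               dimnames = list(NULL, preds))
  for (nm in intersect(names(conditioning), preds))
    xz[, nm] <- conditioning[[nm]]
  if (predictor %in% preds) xz[, predictor] <- grid
  xz
}

predictor_in_model <- function(config, predictor) {
  predictor %in% unlist(lapply(config$networks, `[[`, "predictors"))
}

assemble_curve <- function(grid_col, grid, member_curves, meta) {
  est <- colMeans(member_curves)
  if (nrow(member_curves) >= 2L) {
    bands <- uncertainty_bands(member_curves)
    lo <- bands$lo; hi <- bands$hi
  } else {
    lo <- hi <- rep(NA_real_, length(grid))
  }
  out <- data.frame(grid, estimate = est, lo = lo, hi = hi)
  names(out)[1] <- grid_col
  attributes(out) <- c(attributes(out), meta,
                       list(member_curves = member_curves))
  class(out) <- c(meta$curve_class, "data.frame")
  out
}

#' Instantaneous effect curve of a predictor
#'
#' How the predicted response at zero delay deviates from its value at the
#' reference input as one predictor moves across a grid, holding all other
#' inputs at their reference values (predictor means, zero random effects,
#' a single conditioning event). The deviation at the reference input is 0
#' by construction. The ensemble point estimate is the across-member mean;
#' 95% pointwise bands come from the across-member percentile distribution.
#'
#' @param ensemble a [fit_ensemble()] / [new_ensemble()] object.
#' @param predictor predictor name. If the predictor has been ablated from
#'   the model, a flat zero curve is returned with a warning and the
#'   attribute `"ablated" = TRUE`.
#' @param grid numeric grid of standardized predictor values (default 101
#'   points over +/- 2 SD).
#' @param scale response scale: `"mean"` (expected reading time,
#'   `mu + tau`), or one of the distributional parameters `"mu"`,
#'   `"sigma"`, `"tau"`.
#' @param conditioning named numeric: standardized values at which the
#'   other predictors are held (default: all at 0, their means).
#' @param delay delay in seconds of the conditioning event (default 0:
#'   instantaneous).
#' @return data.frame of class `effect_curve` with columns `grid`,
#'   `estimate`, `lo`, `hi`; attributes record the predictor, scale,
#'   reference convention, and the member-level curves.
#' @export
instantaneous_effect <- function(ensemble, predictor,
                                 grid = seq(-2, 2, length.out = 101),
                                 scale = c("mean", "mu", "sigma", "tau"),
                                 conditioning = numeric(0),
                                 delay = 0) {
  stopifnot(inherits(ensemble, "cdr_ensemble"))
  scale <- match.arg(scale)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (delay < 0) stop("negative delay")
  meta <- list(predictor = predictor, scale = scale, delay = delay,
               conditioning = conditioning,
               reference = "predictor means, zero random effects, single conditioning event",
               curve_class = "effect_curve", ablated = FALSE)
  if (!predictor_in_model(ensemble$config, predictor)) {
    warning(sprintf("predictor '%s' is ablated from the model: flat zero curve",
                    predictor))
    meta$ablated <- TRUE
    mc <- matrix(0, length(ensemble$members), length(grid))
    return(assemble_curve("grid", grid, mc, meta))
  }
  mc <- t(vapply(ensemble$members, function(m) {
    xz <- curve_xz(m, predictor, grid, conditioning)
    ref <- curve_xz(m, predictor, 0, conditioning)
    member_response(m, xz, delay, scale) -
      member_response(m, ref, delay, scale)
  }, numeric(length(grid))))
  assemble_curve("grid", grid, mc, meta)
}

#' Interaction overlay: one predictor's effect at levels of another
#'
#' Re-computes the instantaneous effect curve of `predictor` while holding
#' `other` at its mean and +/- 1 SD. Under additive effects the three
#' curves coincide; the additivity score is the maximum spread between
#' level curves across the grid, relative to the range of the mean-level
#' curve.
#'
#' @inheritParams instantaneous_effect
#' @param other the conditioning predictor (must differ from `predictor`).
#' @param levels standardized conditioning levels (default mean and
#'   +/- 1 SD).
#' @return object of class `interaction_overlay`: list with `curves` (one
#'   `effect_curve` per level), `additivity_score`, and
#'   `additivity_spread` (the absolute spread, response units).
#' @export
interaction_overlay <- function(ensemble, predictor, other,
                                levels = c(-1, 0, 1),
                                grid = seq(-2, 2, length.out = 101),
                                scale = "mean") {
  if (identical(predictor, other))
    stop("predictor and conditioning predictor must differ")
  curves <- lapply(levels, function(lv) {
    cond <- stats::setNames(lv, other)
    instantaneous_effect(ensemble, predictor, grid, scale,
                         conditioning = cond)
  })
  names(curves) <- paste0(other, "=", levels)
  est <- vapply(curves, `[[`, numeric(length(grid)), "estimate")
  spread <- max(apply(est, 1, max) - apply(est, 1, min))
  main_range <- diff(range(est[, which.min(abs(levels))]))
  structure(list(curves = curves, levels = levels,
                 additivity_spread = spread,
                 additivity_score = spread / max(main_range, 1e-12)),
            class = "interaction_overlay")
}

#' @export
print.interaction_overlay <- function(x, ...) {
  cat(sprintf("Interaction overlay: %d level curves\n", length(x$curves)))
  cat(sprintf("  additivity score: %.3f (max level spread / main-effect range)\n",
              x$additivity_score))
  invisible(x)
}

#' Effect timecourse over delay
#'
#' The expected change in response from observing a +1 SD increase of one
#' predictor on an event `d` seconds before the response, as a function of
#' `d` -- a continuous-time analogue of spillover effects.
#'
#' @inheritParams instantaneous_effect
#' @param delays numeric vector of delays in seconds (default 41 points
#'   over 0-2 s); negative delays are rejected.
#' @param step standardized increment applied to the predictor (default
#'   +1 SD).
#' @return data.frame of class `timecourse_curve` with columns `delay`,
#'   `estimate`, `lo`, `hi`.
#' @export
timecourse <- function(ensemble, predictor,
                       delays = seq(0, 2, length.out = 41),
                       step = 1, scale = c("mean", "mu", "sigma", "tau")) {
  stopifnot(inherits(ensemble, "cdr_ensemble"))
  scale <- match.arg(scale)
  if (any(delays < 0)) stop("negative delay")
  meta <- list(predictor = predictor, scale = scale, step = step,
               reference = "predictor means, zero random effects, single conditioning event",
               curve_class = "timecourse_curve", ablated = FALSE)
  if (!predictor_in_model(ensemble$config, predictor)) {
    meta$ablated <- TRUE
    mc <- matrix(0, length(ensemble$members), length(delays))
    return(assemble_curve("delay", delays, mc, meta))
  }
  mc <- t(vapply(ensemble$members, function(m) {
    vapply(delays, function(d) {
      x1 <- curve_xz(m, predictor, step, numeric(0))
      x0 <- curve_xz(m, predictor, 0, numeric(0))
      member_response(m, x1, d, scale) - member_response(m, x0, d, scale)
    }, numeric(1))
  }, numeric(length(delays))))
  assemble_curve("delay", delays, mc, meta)
}

#' Pointwise ensemble uncertainty bands
#'
#' Percentile interval of curve evaluations across ensemble members, the
#' package's uncertainty mechanism for all curve displays. Degenerate
#' (zero-width) bands are flagged.
#'
#' @param member_curves numeric matrix, members x grid points.
#' @param level interval mass (default 0.95).
#' @return list with `lo`, `hi` (numeric vectors) and `zero_width`
#'   (logical flag, `TRUE` if every interval has zero width).
#' @export
uncertainty_bands <- function(member_curves, level = 0.95) {
  if (!is.matrix(member_curves) || nrow(member_curves) < 2L)
    stop("uncertainty bands need at least 2 ensemble members")
  a <- (1 - level) / 2
  lo <- apply(member_curves, 2, stats::quantile, probs = a, names = FALSE)
  hi <- apply(member_curves, 2, stats::quantile, probs = 1 - a,
              names = FALSE)
  list(lo = lo, hi = hi, zero_width = all(hi - lo < 1e-12))
}

#' True effect curves implied by a generator's ground truth
#'
#' The generator-side analogues of [instantaneous_effect()] and
#' [timecourse()], for parameter-recovery comparisons: deviations of the
#' true response surface under the same reference convention (single event,
#' zero random effects, other predictors at their means).
#'
#' @param truth a [ground_truth()] object.
#' @param predictor predictor name.
#' @param grid standardized predictor grid.
#' @param scale `"mean"`, `"mu"`, `"sigma"`, or `"tau"`.
#' @param delay delay of the conditioning event (s).
#' @return data.frame with `grid` (or `delay`) and `truth` columns.
#' @export
true_instantaneous_effect <- function(truth, predictor,
                                      grid = seq(-2, 2, length.out = 101),
                                      scale = "mean", delay = 0) {
  stopifnot(inherits(truth, "ground_truth"))
  k <- truth$kernel(delay)
  eta_dev <- outer(grid * k, truth$effects[predictor, ])
  b <- truth$baseline_prelink
  resp <- function(dev) {
    switch(scale,
           mean = (b[["mu"]] + dev[, 1]) + softplus(b[["tau"]] + dev[, 3]),
           mu = b[["mu"]] + dev[, 1],
           sigma = softplus(b[["sigma"]] + dev[, 2]),
           tau = softplus(b[["tau"]] + dev[, 3]))
  }
  ref <- resp(matrix(0, 1, 3))
  data.frame(grid = grid, truth = resp(eta_dev) - ref)
}

#' @rdname true_instantaneous_effect
#' @param delays delay grid (s).
#' @param step standardized predictor increment.
#' @export
true_timecourse <- function(truth, predictor,
                            delays = seq(0, 2, length.out = 41),
                            step = 1, scale = "mean") {
  stopifnot(inherits(truth, "ground_truth"))
  b <- truth$baseline_prelink
  dev <- outer(step * truth$kernel(delays), truth$effects[predictor, ])
  resp <- function(d) {
    switch(scale,
           mean = (b[["mu"]] + d[, 1]) + softplus(b[["tau"]] + d[, 3]),
           mu = b[["mu"]] + d[, 1],
           sigma = softplus(b[["sigma"]] + d[, 2]),
           tau = softplus(b[["tau"]] + d[, 3]))
  }
  ref <- resp(matrix(0, 1, 3))
  data.frame(delay = delays, truth = resp(dev) - ref)
}

#' Plot an effect or timecourse curve
#'
#' Base-graphics display: point estimate with dotted 95% ensemble bands.
#'
#' @param x an `effect_curve` or `timecourse_curve`.
#' @param ... passed to [plot()].
#' @export
plot.effect_curve <- function(x, ...) {
  plot(x[[1]], x$estimate, type = "l",
       xlab = paste0(attr(x, "predictor"), " (SD units)"),
       ylab = sprintf("deviation in %s (ms)", attr(x, "scale")), ...)
  if (!all(is.na(x$lo))) {
    graphics::lines(x[[1]], x$lo, lty = 3)
    graphics::lines(x[[1]], x$hi, lty = 3)
  }
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' @rdname plot.effect_curve
#' @export
plot.timecourse_curve <- function(x, ...) {
  plot(x[[1]], x$estimate, type = "l", xlab = "delay (s)",
       ylab = sprintf("change in %s (ms) per +1 SD", attr(x, "scale")), ...)
  if (!all(is.na(x$lo))) {
    graphics::lines(x[[1]], x$lo, lty = 3)
    graphics::lines(x[[1]], x$hi, lty = 3)
  }
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
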