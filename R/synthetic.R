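#' Configuration for the synthetic reading-data generator
#'
#' Defines a known continuous-time generative model of word-by-word reading:
#' word events arrive with exponentially distributed inter-event intervals,
#' carry correlated surprisal-scale predictors, and influence the parameters
#' of an exGaussian reading-time distribution through a decaying impulse
#' response function (IRF). Every downstream stage of the package (model
#' fitting, ablation testing, effect-curve recovery) can be exercised against
#' this generator's ground truth.
#'
#' Effects are expressed in ms per standard deviation of the predictor and
#' act on the pre-link scale of a distributional parameter: identity for
#' `mu`, softplus for `sigma` and `tau` (the same links the regression model
#' uses, so generator and model are conjugate and parameter recovery is
#' well-posed). The IRF is a gamma-density-shaped kernel normalized to peak
#' value 1, so an effect size is the peak (for the default exponential
#' kernel: instantaneous) contribution of a +1 SD event.
#'
#' @param n_participants,n_texts,n_words_per_text positive integers; the
#'   simulated design size (total events = product of the three).
#' @param mean_inter_event_interval mean of the exponential inter-event
#'   interval, seconds. Default 0.3 s (self-paced-reading-like pacing).
#' @param sentence_length words per sentence (used for sentence indices and
#'   data partitioning).
#' @param predictors named list; each element `list(mean =, sd =)` on the
#'   surprisal scale. The first two predictors are the correlated
#'   frequency-surprisal and contextual-surprisal pair; the rest are
#'   independent controls.
#' @param rho correlation in `[-1, 1]` between the first two predictors.
#' @param effects named list mapping predictor name to a named list of
#'   per-parameter effect sizes in ms per SD, e.g. `list(tau = 20)`.
#'   Parameters not named get effect 0. Default places all effects on `tau`,
#'   the skewness parameter.
#' @param interaction_coef interaction between the first two predictors
#'   (ms per SD^2), acting on `tau`. Default 0 (additive effects).
#' @param irf list with `shape` and `rate` of the gamma-shaped kernel.
#'   Default `shape = 1, rate = 3`: exponential decay with most of the mass
#'   inside 0.5-1 s.
#' @param baseline named numeric `c(mu, sigma, tau)` in ms; `sigma`, `tau`
#'   must be positive.
#' @param participant_sd named numeric `c(mu, sigma, tau)`: SDs of
#'   by-participant random offsets on the pre-link parameters.
#' @param seed integer seed stored with the configuration (used when a call
#'   does not pass its own).
#'
#' @return an object of class `generator_config`.
#' @seealso [generate_events()], [sample_responses()], [simulate_dataset()]
#' @export
generator_config <- function(n_participants = 10L,
                             n_texts = 20L,
                             n_words_per_text = 100L,
                             mean_inter_event_interval = 0.3,
                             sentence_length = 10L,
                             predictors = list(
                               unigram_surprisal = list(mean = 10, sd = 3),
                               gpt2_surprisal    = list(mean = 5,  sd = 2.5),
                               word_length       = list(mean = 4.5, sd = 2.3)
                             ),
                             rho = 0.6,
                             effects = list(
                               unigram_surprisal = list(tau = 20),
                               gpt2_surprisal    = list(tau = 30),
                               word_length       = list(tau = 8)
                             ),
                             interaction_coef = 0,
                             irf = list(shape = 1, rate = 3),
                             baseline = c(mu = 250, sigma = 40, tau = 150),
                             participant_sd = c(mu = 15, sigma = 5, tau = 15),
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_texts = as.integer(n_texts),
    n_words_per_text = as.integer(n_words_per_text),
    mean_inter_event_interval = mean_inter_event_interval,
    sentence_length = as.integer(sentence_length),
    predictors = predictors,
    rho = rho,
    effects = effects,
    interaction_coef = interaction_coef,
    irf = irf,
    baseline = baseline[c("mu", "sigma", "tau")],
    participant_sd = participant_sd[c("mu", "sigma", "tau")],
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_participants < 1L || cfg$n_texts < 1L || cfg$n_words_per_text < 1L)
    stop("configuration error: participant/text/word counts must be positive")
  if (!is.finite(cfg$mean_inter_event_interval) ||
      cfg$mean_inter_event_interval <= 0)
    stop("configuration error: mean_inter_event_interval must be > 0")
  if (cfg$sentence_length < 1L)
    stop("configuration error: sentence_length must be positive")
  if (abs(cfg$rho) > 1) stop("configuration error: rho must lie in [-1, 1]")
  sds <- vapply(cfg$predictors, function(p) p$sd, numeric(1))
  if (any(sds < 0)) stop("configuration error: predictor SDs must be >= 0")
  if (any(is.na(cfg$baseline)) || cfg$baseline[["sigma"]] <= 0 ||
      cfg$baseline[["tau"]] <= 0)
    stop("configuration error: baseline sigma and tau must be > 0")
  if (any(is.na(cfg$participant_sd)) || any(cfg$participant_sd < 0))
    stop("configuration error: participant SDs must be >= 0")
  if (cfg$irf$shape <= 0 || cfg$irf$rate <= 0)
    stop("configuration error: IRF shape and rate must be > 0")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic reading-data generator configuration\n")
  cat(sprintf("  design: %d participants x %d texts x %d words (%d events)\n",
              x$n_participants, x$n_texts, x$n_words_per_text,
              x$n_participants * x$n_texts * x$n_words_per_text))
  cat(sprintf("  inter-event interval: exponential, mean %.3g s\n",
              x$mean_inter_event_interval))
  cat(sprintf("  predictors: %s (rho = %.2f between first two)\n",
              paste(names(x$predictors), collapse = ", "), x$rho))
  cat(sprintf("  IRF: gamma kernel, shape %.3g, rate %.3g (peak-normalized)\n",
              x$irf$shape, x$irf$rate))
  cat(sprintf("  baseline exGaussian: mu %.4g, sigma %.4g, tau %.4g ms\n",
              x$baseline[["mu"]], x$baseline[["sigma"]], x$baseline[["tau"]]))
  cat(sprintf("  interaction coefficient: %.3g ms/SD^2 (on tau)\n",
              x$interaction_coef))
  invisible(x)
}

# Evaluate a (config, seed)-scoped expression with restored RNG state so the
# generator never perturbs the caller's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Peak-normalized gamma kernel: value 1 at its mode, decaying to 0.
irf_kernel <- function(irf) {
  shape <- irf$shape
  rate <- irf$rate
  mode <- if (shape >= 1) (shape - 1) / rate else 0
  peak <- if (shape >= 1 && mode > 0) {
    stats::dgamma(mode, shape, rate)
  } else {
    rate  # dgamma(0, 1, rate) = rate; shape < 1 diverges at 0, cap at rate
  }
  function(d) stats::dgamma(pmax(d, 0), shape, rate) / peak
}

# Delay beyond which the kernel is numerically negligible.
irf_support <- function(irf, tol = 1e-10) {
  k <- irf_kernel(irf)
  d <- (irf$shape - 1) / irf$rate
  d <- max(d, 0) + 1 / irf$rate
  while (k(d) > tol) d <- d * 2
  d
}

#' Ground truth of a generator configuration
#'
#' Materializes the generative model implied by a [generator_config()]: the
#' IRF kernel, per-predictor per-parameter effect coefficients, the pre-link
#' baselines, and the realized by-participant random offsets (drawn from the
#' configured SDs under `seed`).
#'
#' @param config a [generator_config()].
#' @param seed integer; defaults to `config$seed`. The participant offsets
#'   are a deterministic function of `(config, seed)`.
#' @return an object of class `ground_truth` with elements `kernel`
#'   (function of delay), `effects` (matrix predictor x parameter, ms/SD),
#'   `interaction_coef`, `baseline_prelink`, `participant_offsets`
#'   (matrix participant x parameter), and `seed`.
#' @export
ground_truth <- function(config, seed = config$seed) {
  pred_names <- names(config$predictors)
  eff <- matrix(0, nrow = length(pred_names), ncol = 3,
                dimnames = list(pred_names, c("mu", "sigma", "tau")))
  for (nm in names(config$effects)) {
    if (!nm %in% pred_names)
      stop("effect names an unknown predictor: ", nm)
    for (par in names(config$effects[[nm]]))
      eff[nm, par] <- config$effects[[nm]][[par]]
  }
  base_prelink <- c(
    mu = unname(config$baseline[["mu"]]),
    sigma = softplus_inv(config$baseline[["sigma"]]),
    tau = softplus_inv(config$baseline[["tau"]])
  )
  offsets <- with_seed(seed + 1L, {
    matrix(stats::rnorm(config$n_participants * 3), ncol = 3) %*%
      diag(config$participant_sd[c("mu", "sigma", "tau")])
  })
  dimnames(offsets) <- list(sprintf("p%02d", seq_len(config$n_participants)),
                            c("mu", "sigma", "tau"))
  out <- list(
    kernel = irf_kernel(config$irf),
    kernel_support = irf_support(config$irf),
    effects = eff,
    interaction_coef = config$interaction_coef,
    interaction_pair = pred_names[seq_len(min(2, length(pred_names)))],
    baseline = config$baseline,
    baseline_prelink = base_prelink,
    participant_offsets = offsets,
    predictor_spec = config$predictors,
    irf = config$irf,
    seed = seed
  )
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth of a synthetic reading-data generator\n")
  cat("  effect sizes (ms per SD, pre-link):\n")
  print(round(x$effects, 2))
  cat(sprintf("  interaction: %.3g ms/SD^2 on tau (%s)\n",
              x$interaction_coef, paste(x$interaction_pair, collapse = " x ")))
  cat(sprintf("  participants: %d, seed: %d\n",
              nrow(x$participant_offsets), x$seed))
  invisible(x)
}

#' True IRF contribution of a predictor at given delays
#'
#' @param truth a [ground_truth()] object.
#' @param predictor predictor name.
#' @param delays numeric vector of delays (s), all `>= 0`.
#' @param param one of `"mu"`, `"sigma"`, `"tau"`.
#' @return numeric vector: pre-link contribution (ms) of a +1 SD event at
#'   each delay.
#' @export
true_irf <- function(truth, predictor, delays, param = "tau") {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(delays < 0)) stop("delays must be non-negative")
  truth$effects[predictor, param] * truth$kernel(delays)
}

#' Generate a word-event stream from a generator configuration
#'
#' Draws a timestamped event table. Predictor values are drawn once per
#' (text, word) and shared across participants, mirroring real designs in
#' which all participants read the same texts; the first two predictors are
#' bivariate Gaussian with the configured correlation, the rest independent.
#' Event times are cumulative exponential inter-event intervals, independent
#' per participant and text.
#'
#' @param config a [generator_config()].
#' @param seed integer; defaults to `config$seed`. Identical
#'   `(config, seed)` give byte-identical output.
#' @return a data.frame with columns `participant_id`, `text_id`,
#'   `sentence_index`, `token_position`, `time_s`, and one column per
#'   predictor, time-ordered within participant. The attribute
#'   `"predictor_names"` records the predictor columns.
#' @export
generate_events <- function(config, seed = config$seed) {
  validate_generator_config(config)
  pred_names <- names(config$predictors)
  n_p <- config$n_participants
  n_t <- config$n_texts
  n_w <- config$n_words_per_text
  sents_per_text <- ceiling(n_w / config$sentence_length)

  with_seed(seed, {
    # per-text predictor matrices, shared across participants
    text_preds <- lapply(seq_len(n_t), function(t) {
      z1 <- stats::rnorm(n_w)
      z2 <- config$rho * z1 + sqrt(1 - config$rho^2) * stats::rnorm(n_w)
      x <- matrix(NA_real_, n_w, length(pred_names),
                  dimnames = list(NULL, pred_names))
      zs <- c(list(z1, z2),
              replicate(max(0, length(pred_names) - 2),
                        stats::rnorm(n_w), simplify = FALSE))
      for (j in seq_along(pred_names)) {
        spec <- config$predictors[[j]]
        x[, j] <- spec$mean + spec$sd * zs[[j]]
      }
      x
    })
    rows <- vector("list", n_p * n_t)
    k <- 0L
    for (p in seq_len(n_p)) {
      for (t in seq_len(n_t)) {
        k <- k + 1L
        iei <- stats::rexp(n_w, rate = 1 / config$mean_inter_event_interval)
        tok <- seq_len(n_w)
        df <- data.frame(
          participant_id = sprintf("p%02d", p),
          text_id = sprintf("t%02d", t),
          sentence_index = (t - 1L) * sents_per_text +
            (tok - 1L) %/% config$sentence_length,
          token_position = tok,
          time_s = cumsum(iei),
          stringsAsFactors = FALSE
        )
        df <- cbind(df, as.data.frame(text_preds[[t]]))
        rows[[k]] <- df
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "predictor_names") <- pred_names
    out
  })
}

#' Sample exGaussian reading times from events under a known ground truth
#'
#' For every event, the three distributional parameters are assembled as
#' `baseline + participant offset + sum over past events of the true IRF
#' contribution at the realized delay` (events from the same participant and
#' text, including the current event at delay 0), mapped through the model's
#' links (identity for `mu`, softplus for `sigma` and `tau`), and one
#' reading time is drawn from the resulting exGaussian. Negative draws are
#' redrawn and counted in the attribute `"n_redrawn"`.
#'
#' @param events event table from [generate_events()], time-ordered within
#'   participant and text.
#' @param truth a [ground_truth()] object.
#' @param seed integer seed for the response draws.
#' @param measure_name label stored in the `measure_name` column.
#' @return a data.frame with columns `participant_id`, `text_id`,
#'   `token_position`, `sentence_index`, `time_s`, `duration_ms`,
#'   `measure_name`. Attribute `"true_params"` holds the per-response
#'   (mu, sigma, tau) used for the draw.
#' @export
sample_responses <- function(events, truth, seed = truth$seed,
                             measure_name = "rt") {
  stopifnot(inherits(truth, "ground_truth"))
  pred_names <- rownames(truth$effects)
  if (!all(pred_names %in% names(events)))
    stop("events lack predictor columns: ",
         paste(setdiff(pred_names, names(events)), collapse = ", "))

  # standardized predictor values (effects are per SD of the marginal spec)
  zx <- vapply(pred_names, function(nm) {
    spec <- truth$predictor_spec[[nm]]
    (events[[nm]] - spec$mean) / spec$sd
  }, numeric(nrow(events)))
  zx <- matrix(zx, nrow = nrow(events),
               dimnames = list(NULL, pred_names))

  # per-event pre-link impulse weights for each parameter
  cw <- zx %*% truth$effects
  if (truth$interaction_coef != 0 && length(truth$interaction_pair) == 2) {
    cw[, "tau"] <- cw[, "tau"] + truth$interaction_coef *
      zx[, truth$interaction_pair[1]] * zx[, truth$interaction_pair[2]]
  }

  grp <- interaction(events$participant_id, events$text_id, drop = TRUE)
  ord <- order(grp, events$time_s)
  sig <- matrix(0, nrow(events), 3, dimnames = list(NULL, c("mu", "sigma", "tau")))
  for (g in split(ord, grp[ord])) {
    tms <- events$time_s[g]
    if (is.unsorted(tms)) stop("events must be time-ordered within participant")
    n <- length(g)
    acc <- matrix(0, n, 3)
    for (lag in 0:(n - 1)) {
      i <- (lag + 1L):n
      j <- seq_len(n - lag)
      d <- tms[i] - tms[j]
      if (min(d) > truth$kernel_support) break
      kv <- truth$kernel(d)
      acc[i, ] <- acc[i, ] + cw[g[j], , drop = FALSE] * kv
    }
    sig[g, ] <- acc
  }

  pid <- match(events$participant_id, rownames(truth$participant_offsets))
  if (anyNA(pid)) stop("events reference participants absent from ground truth")
  off <- truth$participant_offsets[pid, , drop = FALSE]

  eta_mu <- truth$baseline_prelink[["mu"]] + off[, "mu"] + sig[, "mu"]
  eta_sg <- truth$baseline_prelink[["sigma"]] + off[, "sigma"] + sig[, "sigma"]
  eta_ta <- truth$baseline_prelink[["tau"]] + off[, "tau"] + sig[, "tau"]
  mu <- eta_mu
  sigma <- softplus(eta_sg)
  tau <- softplus(eta_ta)
  if (any(sigma <= 0) || any(tau <= 0)) {
    bad <- which(sigma <= 0 | tau <= 0)[1]
    stop(sprintf("non-positive sigma/tau at datapoint %d (participant %s, t=%.3f)",
                 bad, events$participant_id[bad], events$time_s[bad]))
  }

  n_redrawn <- 0L
  y <- with_seed(seed + 2L, {
    y <- rexgauss(nrow(events), mu, sigma, tau)
    for (tries in 1:100) {
      neg <- which(y <= 0)
      if (!length(neg)) break
      n_redrawn <- n_redrawn + length(neg)
      y[neg] <- rexgauss(length(neg), mu[neg], sigma[neg], tau[neg])
    }
    if (any(y <= 0)) stop("responses could not be drawn positive")
    y
  })

  out <- data.frame(
    participant_id = events$participant_id,
    text_id = events$text_id,
    token_position = events$token_position,
    sentence_index = events$sentence_index,
    time_s = events$time_s,
    duration_ms = y,
    measure_name = measure_name,
    stringsAsFactors = FALSE
  )
  attr(out, "true_params") <- cbind(mu = mu, sigma = sigma, tau = tau)
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Simulate a complete synthetic reading dataset
#'
#' Convenience wrapper: ground truth, events, responses, and the partition
#' column (train/validation/test by participant and sentence index).
#'
#' @inheritParams generate_events
#' @return list with elements `events`, `responses`, `truth`, `config`.
#'   `responses` carries a `partition` column from [assign_partition()].
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  truth <- ground_truth(config, seed)
  events <- generate_events(config, seed)
  responses <- sample_responses(events, truth, seed)
  p_idx <- as.integer(factor(responses$participant_id)) - 1L
  responses$partition <- assign_partition(p_idx, responses$sentence_index)
  list(events = events, responses = responses, truth = truth, config = config)
}

#' Write / read event and response tables as TSV
#'
#' Plain-text serialization of the generator's two tables.
#'
#' @param x a data.frame.
#' @param path file path.
#' @return `read_table_tsv` returns a data.frame.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
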