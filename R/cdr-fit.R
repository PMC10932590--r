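# Fitting machinery: parameter flattening, Adam, early stopping, and the
# user-facing fit/predict functions.

flatten_pars <- function(pars) unlist(pars, use.names = FALSE)

unflatten_pars <- function(v, skeleton) utils::relist(v, skeleton)

adam_optimize <- function(par, grad_fn, eval_fn, config) {
  m <- v <- numeric(length(par))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  best_par <- par
  best_val <- eval_fn(par)
  stale <- 0L
  log <- list()
  final_val <- best_val
  for (step in seq_len(config$max_steps)) {
    gr <- grad_fn(par)
    g <- gr$grad
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^step)
    vhat <- v / (1 - beta2^step)
    par <- par - lr * mhat / (sqrt(vhat) + eps)
    if (step %% config$eval_every == 0L || step == config$max_steps) {
      val <- eval_fn(par)
      final_val <- val
      log[[length(log) + 1L]] <-
        data.frame(step = step, train_loss = gr$loss, val_loglik = val)
      if (val > best_val + 1e-10) {
        best_val <- val
        best_par <- par
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  }
  list(par = best_par, val_loglik = best_val, final_val_loglik = final_val,
       log = do.call(rbind, log))
}

#' Fit a continuous-time deconvolutional exGaussian model
#'
#' Maximizes the summed exGaussian log-likelihood of the training responses
#' by gradient optimization. With the `"adam"` optimizer, validation
#' likelihood is evaluated periodically and the returned model is the
#' checkpoint with the best validation likelihood (early stopping); with
#' `"lbfgs"`, a full-batch quasi-Newton fit is run to convergence. Event
#' (predictor) tables are used unfiltered; only responses are split.
#'
#' @param config a [cdr_config()].
#' @param events full event table (see [generate_events()] for the layout).
#' @param train,validation response tables (disjoint subsets, e.g. from
#'   [split_responses()]); columns `participant_id`, `text_id`,
#'   `token_position`, `time_s`, `duration_ms`.
#' @param seed integer; fitting is a deterministic function of
#'   `(config, data, seed)`.
#' @return object of class `cdr_model`: learned parameters,
#'   standardization statistics, training log, validation log-likelihood
#'   (mean per datapoint) of the returned checkpoint, and the seed.
#' @export
fit_cdr <- function(config, events, train, validation,
                    seed = config$seed) {
  stopifnot(inherits(config, "cdr_config"))
  if (nrow(train) < 1L) stop("no training responses")
  std <- predictor_stats(config, events)
  levels <- list(participants = sort(unique(events$participant_id)),
                 n_token = max(events$token_position))
  dtr <- prepare_cdr_data(config, events, train, std, levels)
  dva <- prepare_cdr_data(config, events, validation, std, levels)

  mom <- exgauss_moments(train$duration_ms)
  baseline_init <- c(mom[["mu"]],
                     softplus_inv(max(mom[["sigma"]] - 1, 0.5)),
                     softplus_inv(max(mom[["tau"]] - 1, 0.5)))
  pars0 <- init_cdr_params(config, vapply(dtr$feats, ncol, integer(1)),
                           levels, baseline_init, seed)
  skeleton <- pars0
  flat0 <- flatten_pars(pars0)

  val_loglik <- function(v) {
    p <- unflatten_pars(v, skeleton)
    mean(cdr_loss_grad(p, dva, config, want_grad = FALSE)$loglik)
  }

  fit <- with_seed(seed + 7L, {
    if (config$optimizer == "lbfgs") {
      # optim calls fn and gr at the same point; cache one evaluation
      memo <- new.env(parent = emptyenv())
      evaluate <- function(v) {
        if (!is.null(memo$v) && identical(v, memo$v)) return(memo$res)
        memo$v <- v
        memo$res <- cdr_loss_grad(unflatten_pars(v, skeleton), dtr, config)
        memo$res
      }
      opt <- stats::optim(
        flat0,
        fn = function(v) evaluate(v)$loss,
        gr = function(v) flatten_pars(evaluate(v)$grad),
        method = "L-BFGS-B",
        control = list(maxit = config$max_steps))
      vl <- val_loglik(opt$par)
      list(par = opt$par, val_loglik = vl, final_val_loglik = vl,
           log = data.frame(step = opt$counts[1], train_loss = opt$value,
                            val_loglik = vl))
    } else {
      full_batch <- !is.finite(config$batch_size) ||
        config$batch_size >= dtr$n
      grad_fn <- function(v) {
        p <- unflatten_pars(v, skeleton)
        d <- if (full_batch) dtr else
          subset_cdr_data(dtr, sample.int(dtr$n, config$batch_size))
        res <- cdr_loss_grad(p, d, config)
        if (!is.finite(res$loss))
          stop("non-finite training loss; offending batch recorded")
        list(loss = res$loss, grad = flatten_pars(res$grad))
      }
      adam_optimize(flat0, grad_fn, val_loglik, config)
    }
  })

  model <- list(pars = unflatten_pars(fit$par, skeleton),
                config = config,
                std = std,
                levels = levels,
                baseline_init = baseline_init,
                training_log = fit$log,
                val_loglik = fit$val_loglik,
                final_val_loglik = fit$final_val_loglik,
                n_train = dtr$n, n_validation = dva$n,
                n_no_history = sum(dtr$n_events == 0L),
                seed = seed)
  class(model) <- "cdr_model"
  model
}

#' @export
print.cdr_model <- function(x, ...) {
  cat("Fitted continuous-time deconvolutional exGaussian model\n")
  cat(sprintf("  IRF: %s; %d network(s); %d training / %d validation responses\n",
              x$config$irf, length(x$config$networks), x$n_train,
              x$n_validation))
  cat(sprintf("  validation log-likelihood (mean): %.4f\n", x$val_loglik))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Predict exGaussian parameters for responses
#'
#' Convolves each response's in-window event history through the fitted
#' impulse-response networks and returns the per-response distributional
#' parameters on their natural scale. Responses of participants unseen at
#' fit time fall back to population-level effects (random offsets zero);
#' responses with no in-window events get baseline-only parameters. Both
#' conditions are counted in attributes.
#'
#' @param model a fitted [fit_cdr()] model.
#' @param events event table.
#' @param responses response table.
#' @return numeric matrix `n x 3` with columns `mu`, `sigma`, `tau`;
#'   attributes `"n_no_history"` and `"n_unknown_participant"`.
#' @export
predict_params <- function(model, events, responses) {
  stopifnot(inherits(model, "cdr_model"))
  d <- prepare_cdr_data(model$config, events, responses, model$std,
                        model$levels)
  fw <- cdr_forward(model$pars, d, model$config)
  out <- cbind(mu = fw$mu, sigma = fw$sigma, tau = fw$tau)
  attr(out, "n_no_history") <- sum(d$n_events == 0L)
  attr(out, "n_unknown_participant") <- sum(d$part == 0L)
  out
}

#' ExGaussian parameter triple
#'
#' @param mu,sigma,tau location, dispersion, skewness (ms); `sigma` and
#'   `tau` must be strictly positive.
#' @return named numeric of class `exgauss_params`; the implied mean is
#'   `mu + tau`.
#' @export
exgauss_params <- function(mu, sigma, tau) {
  if (sigma <= 0 || tau <= 0) stop("sigma and tau must be strictly positive")
  structure(c(mu = mu, sigma = sigma, tau = tau), class = "exgauss_params")
}

#' Convolve one response's event history into exGaussian parameters
#'
#' The deconvolutional model's core operation for a single datapoint:
#' `parameter = link(baseline + random offsets + sum over in-window past
#' events of the IRF contribution at the realized delay)`.
#'
#' @param events event table (time-sorted within participant and text).
#' @param response a one-row response data.frame.
#' @param model a fitted [fit_cdr()] model.
#' @return an [exgauss_params()] triple.
#' @export
convolve_response <- function(events, response, model) {
  stopifnot(nrow(response) == 1L)
  p <- predict_params(model, events, response)
  exgauss_params(p[1, "mu"], p[1, "sigma"], p[1, "tau"])
}

#' Evaluate one impulse-response network at given inputs
#'
#' Returns the pre-link contribution vector (delta-mu, delta-sigma-tilde,
#' delta-tau-tilde) of a single event with standardized predictor values
#' `x` observed `delay` seconds before the response, excluding random
#' effects. Deterministic; defined for any real predictor values; negative
#' delays are rejected (future events never influence a response).
#'
#' @param model a fitted [fit_cdr()] model.
#' @param x named numeric of standardized predictor values; must cover the
#'   network's predictors (missing names default to 0, the predictor mean).
#' @param delay numeric vector of delays in seconds, all `>= 0`.
#' @param network network index.
#' @return matrix `length(delay) x 3` with columns `mu`, `sigma`, `tau`
#'   (zero for parameters the network does not target).
#' @export
irf_forward <- function(model, x = numeric(0), delay = 0, network = 1L) {
  stopifnot(inherits(model, "cdr_model"))
  if (any(delay < 0)) stop("negative delay: future events cannot contribute")
  config <- model$config
  net <- config$networks[[network]]
  preds <- used_predictors(config)
  xz <- matrix(0, length(delay), length(preds),
               dimnames = list(NULL, preds))
  for (nm in intersect(names(x), preds)) xz[, nm] <- x[[nm]]
  H <- network_features(config, net, xz, delay)
  W <- model$pars$nets[[network]]
  if (config$irf == "mlp") {
    for (l in seq_along(config$hidden))
      H <- tanh(sweep(H %*% W[[paste0("W", l)]], 2, W[[paste0("b", l)]], `+`))
    out <- sweep(H %*% W$Wout, 2, W$bout, `+`)
  } else {
    out <- H %*% W$Wout
  }
  full <- matrix(0, length(delay), 3,
                 dimnames = list(NULL, c("mu", "sigma", "tau")))
  full[, net_param_idx(net)] <- out
  full
}

#' Fit an ensemble of independently seeded models
#'
#' Fits `n_members` models that differ only in their seeds (default 10,
#' which averages out variability due to stochastic optimization). A member
#' whose fit fails is retried once with a shifted seed; more than two
#' failed members abort the ensemble.
#'
#' @inheritParams fit_cdr
#' @param n_members number of members (`>= 2`).
#' @param base_seed members use seeds `base_seed .. base_seed+n_members-1`.
#' @return object of class `cdr_ensemble`.
#' @export
fit_ensemble <- function(config, events, train, validation,
                         n_members = 10L, base_seed = config$seed) {
  if (n_members < 2L)
    stop("an ensemble needs at least 2 members")
  seeds <- base_seed + seq_len(n_members) - 1L
  members <- vector("list", n_members)
  n_failed <- 0L
  for (i in seq_len(n_members)) {
    members[[i]] <- tryCatch(
      fit_cdr(config, events, train, validation, seed = seeds[i]),
      error = function(e) {
        n_failed <<- n_failed + 1L
        if (n_failed > 2L)
          stop("more than two ensemble members failed: ", conditionMessage(e))
        seeds[i] <<- seeds[i] + 1000L
        fit_cdr(config, events, train, validation, seed = seeds[i])
      })
  }
  new_ensemble(members, seeds = seeds)
}

#' @rdname fit_ensemble
#' @param members list of fitted `cdr_model`s sharing a configuration.
#' @param seeds integer vector of member seeds.
#' @export
new_ensemble <- function(members, seeds = vapply(members, `[[`, numeric(1),
                                                 "seed")) {
  stopifnot(length(members) >= 1L,
            all(vapply(members, inherits, logical(1), "cdr_model")))
  structure(list(members = members, seeds = seeds,
                 config = members[[1]]$config),
            class = "cdr_ensemble")
}

#' @export
print.cdr_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d deconvolutional exGaussian models (seeds %s)\n",
              length(x$members),
              paste(range(x$seeds), collapse = "..")))
  cat(sprintf("  mean validation log-likelihood: %.4f\n",
              mean(vapply(x$members, `[[`, numeric(1), "val_loglik"))))
  invisible(x)
}

#' @export
length.cdr_ensemble <- function(x) length(x$members)

# log(mean(exp(ll))) by row, stable.
row_log_mean_exp <- function(ll) {
  mx <- apply(ll, 1, max)
  log(rowMeans(exp(ll - mx))) + mx
}

#' Out-of-sample per-datapoint log-likelihood of an ensemble
#'
#' Scores each test response under the ensemble's predictive distribution:
#' the uniform mixture of the member densities, i.e. the log of the
#' arithmetic mean of the member exGaussian densities. Member order does
#' not affect the result.
#'
#' @param ensemble a [fit_ensemble()] or [new_ensemble()] object.
#' @param events event table.
#' @param test response table (disjoint from training and validation).
#' @return numeric vector of per-datapoint log-likelihoods, in the row
#'   order of `test`; attribute `"per_member"` holds the `n x M` member
#'   log-density matrix.
#' @export
test_loglik <- function(ensemble, events, test) {
  stopifnot(inherits(ensemble, "cdr_ensemble"))
  ll <- vapply(ensemble$members, function(m) {
    p <- predict_params(m, events, test)
    dexgauss(test$duration_ms, p[, "mu"], p[, "sigma"], p[, "tau"],
             log = TRUE)
  }, numeric(nrow(test)))
  ll <- matrix(ll, nrow = nrow(test))
  out <- row_log_mean_exp(ll)
  attr(out, "per_member") <- ll
  out
}

#' Save / load a fitted model as a single-file checkpoint
#'
#' The checkpoint contains the learned weights, configuration,
#' standardization statistics, training log, and seed; a reloaded model
#' reproduces its stored validation likelihood exactly.
#'
#' @param model a fitted [fit_cdr()] model.
#' @param path file path for the checkpoint.
#' @return `read_cdr_model` returns the restored `cdr_model`.
#' @export
write_cdr_model <- function(model, path) {
  stopifnot(inherits(model, "cdr_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_cdr_model
#' @export
read_cdr_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cdr_model"))
    stop("file does not contain a fitted model checkpoint")
  model
}

#' Split a response table by its partition column
#'
#' @param responses response table with a `partition` column (see
#'   [assign_partition()]).
#' @return named list of data.frames: `train`, `validation`, `test`.
#' @export
split_responses <- function(responses) {
  stopifnot("partition" %in% names(responses))
  list(train = responses[responses$partition == "train", , drop = FALSE],
       validation = responses[responses$partition == "validation", ,
                              drop = FALSE],
       test = responses[responses$partition == "test", , drop = FALSE])
}
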