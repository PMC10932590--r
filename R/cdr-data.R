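# Internal data preparation and the forward/backward passes of the
# deconvolutional model. All heavy lifting is vectorized over
# (response, event) pairs: the pair feature matrices are precomputed once
# per dataset, so each optimization step is a handful of matrix products.

used_predictors <- function(config) {
  unique(unlist(lapply(config$networks, `[[`, "predictors")))
}

# Standardization statistics from an event table (the full predictor matrix
# is never filtered, so statistics come from all events).
predictor_stats <- function(config, events) {
  preds <- used_predictors(config)
  missing <- setdiff(preds, names(events))
  if (length(missing))
    stop("events lack predictor columns: ", paste(missing, collapse = ", "))
  m <- vapply(preds, function(p) mean(events[[p]]), numeric(1))
  s <- vapply(preds, function(p) stats::sd(events[[p]]), numeric(1))
  if (any(!is.finite(s)) || any(s == 0))
    stop("constant predictor column(s): ",
         paste(preds[!is.finite(s) | s == 0], collapse = ", "))
  list(mean = m, sd = s)
}

# Build the (response, event) pair structure: for each response, the events
# of the same participant and text with event time <= response time, limited
# to the last `history_n` events within `history_t` seconds.
build_history <- function(config, events, responses) {
  ev_grp <- paste(events$participant_id, events$text_id, sep = "\r")
  rs_grp <- paste(responses$participant_id, responses$text_id, sep = "\r")
  ev_split <- split(seq_len(nrow(events)), ev_grp)
  rs_split <- split(seq_len(nrow(responses)), rs_grp)

  pair_event <- vector("list", length(rs_split))
  pair_resp <- vector("list", length(rs_split))
  gi <- 0L
  for (key in names(rs_split)) {
    gi <- gi + 1L
    ridx <- rs_split[[key]]
    eidx <- ev_split[[key]]
    if (is.null(eidx)) next
    et <- events$time_s[eidx]
    o <- order(et)
    eidx <- eidx[o]
    et <- et[o]
    rt <- responses$time_s[ridx]
    last <- findInterval(rt + 1e-9, et)
    pe <- pr <- vector("list", length(ridx))
    for (j in seq_along(ridx)) {
      if (last[j] == 0L) next
      from <- max(1L, last[j] - config$history_n + 1L)
      sel <- from:last[j]
      sel <- sel[et[sel] >= rt[j] - config$history_t]
      pe[[j]] <- eidx[sel]
      pr[[j]] <- rep.int(ridx[j], length(sel))
    }
    pair_event[[gi]] <- unlist(pe)
    pair_resp[[gi]] <- unlist(pr)
  }
  pair_event <- unlist(pair_event)
  pair_resp <- unlist(pair_resp)
  list(event = as.integer(pair_event), resp = as.integer(pair_resp))
}

# Per-network feature matrix for a set of pairs.
#  mlp:    [standardized predictors, d, log(1 + d)]
#  linear: [1, predictors, (pairwise products)] x exp(-r d) per basis rate
network_features <- function(config, net, xz, d) {
  if (config$irf == "mlp") {
    cbind(xz[, net$predictors, drop = FALSE], d = d, logd = log1p(d))
  } else {
    base <- cbind(rep(1, length(d)), xz[, net$predictors, drop = FALSE])
    colnames(base) <- c("(basis)", net$predictors)
    if (isTRUE(config$interactions) && length(net$predictors) > 1) {
      prs <- utils::combn(net$predictors, 2, simplify = FALSE)
      inter <- vapply(prs, function(pr) xz[, pr[1]] * xz[, pr[2]],
                      numeric(length(d)))
      inter <- matrix(inter, ncol = length(prs))
      colnames(inter) <- vapply(prs, paste, character(1), collapse = ":")
      base <- cbind(base, inter)
    }
    feats <- lapply(config$basis_rates, function(r) {
      f <- base * exp(-r * d)
      colnames(f) <- paste0(colnames(base), "@", r)
      f
    })
    do.call(cbind, feats)
  }
}

# Assemble everything fitting and prediction need for one response set.
prepare_cdr_data <- function(config, events, responses, std, levels) {
  n <- nrow(responses)
  part <- match(responses$participant_id, levels$participants)
  part[is.na(part)] <- 0L  # unknown participant: population-level effects
  tok <- pmin(pmax(responses$token_position, 1L), levels$n_token)

  pairs <- build_history(config, events, responses)
  preds <- used_predictors(config)
  xz <- vapply(preds, function(p) {
    (events[[p]][pairs$event] - std$mean[[p]]) / std$sd[[p]]
  }, numeric(length(pairs$event)))
  xz <- matrix(xz, ncol = length(preds), dimnames = list(NULL, preds))
  d <- responses$time_s[pairs$resp] - events$time_s[pairs$event]

  feats <- lapply(config$networks, function(net)
    network_features(config, net, xz, d))

  n_ev <- tabulate(pairs$resp, nbins = n)
  list(n = n,
       y = responses$duration_ms,
       part = part,
       tok = as.integer(tok),
       pair_resp = pairs$resp,
       pair_part = part[pairs$resp],
       feats = feats,
       n_events = n_ev)
}

# Dimensions of the parameter set implied by a config and data levels.
init_cdr_params <- function(config, feats_ncol, levels, baseline_init,
                            seed) {
  with_seed(seed, {
    nets <- vector("list", length(config$networks))
    for (m in seq_along(config$networks)) {
      net <- config$networks[[m]]
      P <- length(net$params)
      Fm <- feats_ncol[m]
      if (config$irf == "mlp") {
        widths <- c(Fm, config$hidden)
        W <- list()
        for (l in seq_along(config$hidden)) {
          W[[paste0("W", l)]] <- matrix(
            stats::rnorm(widths[l] * widths[l + 1], sd = 1 / sqrt(widths[l])),
            widths[l], widths[l + 1])
          W[[paste0("b", l)]] <- rep(0, widths[l + 1])
        }
        W$Wout <- matrix(0, utils::tail(widths, 1), P)  # zero-init output
        W$bout <- rep(0, P)
        nets[[m]] <- W
      } else {
        nets[[m]] <- list(Wout = matrix(
          stats::rnorm(Fm * P, sd = config$init_sd * 0.1), Fm, P))
      }
    }
    pars <- list(b = baseline_init, nets = nets)
    if (config$ranef_participant)
      pars$u <- matrix(0, length(levels$participants), 3)
    if (config$ranef_gain)
      pars$gain <- matrix(0, length(levels$participants),
                          length(config$networks))
    if (config$ranef_token)
      pars$wtok <- rep(0, levels$n_token)
    pars
  })
}

# Forward pass: pre-link eta (n x 3), link-scale parameters, and (optionally)
# the per-network activation caches needed for backpropagation.
cdr_forward <- function(pars, data, config, want_cache = FALSE) {
  n <- data$n
  eta <- matrix(rep(pars$b, each = n), n, 3)
  if (!is.null(pars$u)) {
    known <- data$part > 0L
    eta[known, ] <- eta[known, ] + pars$u[data$part[known], , drop = FALSE]
  }
  if (!is.null(pars$wtok))
    eta[, 1] <- eta[, 1] + pars$wtok[data$tok]

  caches <- vector("list", length(config$networks))
  for (m in seq_along(config$networks)) {
    net <- config$networks[[m]]
    W <- pars$nets[[m]]
    H <- data$feats[[m]]
    if (!nrow(H)) next
    acts <- list(H)
    if (config$irf == "mlp") {
      for (l in seq_along(config$hidden)) {
        H <- tanh(sweep(H %*% W[[paste0("W", l)]], 2,
                        W[[paste0("b", l)]], `+`))
        acts[[l + 1L]] <- H
      }
      out <- sweep(H %*% W$Wout, 2, W$bout, `+`)
    } else {
      out <- H %*% W$Wout
    }
    gainfac <- rep(1, length(data$pair_resp))
    if (!is.null(pars$gain)) {
      # centered so the population-level IRF scale stays identified
      gain_c <- pars$gain[, m] - mean(pars$gain[, m])
      kn <- data$pair_part > 0L
      gainfac[kn] <- 1 + gain_c[data$pair_part[kn]]
    }
    contrib <- out * gainfac
    cols <- net_param_idx(net)
    for (cc in seq_along(cols)) {
      agg <- rowsum(contrib[, cc], data$pair_resp)
      eta[as.integer(rownames(agg)), cols[cc]] <-
        eta[as.integer(rownames(agg)), cols[cc]] + agg[, 1]
    }
    if (want_cache)
      caches[[m]] <- list(acts = acts, out = out, gainfac = gainfac)
  }

  mu <- eta[, 1]
  # 1 ms floor: keeps the likelihood defined and well-conditioned if the
  # optimizer drives a dispersion toward zero (durations are on the ms scale)
  sigma <- softplus(eta[, 2]) + 1
  tau <- softplus(eta[, 3]) + 1
  list(eta = eta, mu = mu, sigma = sigma, tau = tau, caches = caches)
}

# Mean negative log-likelihood plus L2 penalty on random effects, with
# analytic gradients with respect to every parameter.
cdr_loss_grad <- function(pars, data, config, want_grad = TRUE) {
  fw <- cdr_forward(pars, data, config, want_cache = want_grad)
  ll <- dexgauss(data$y, fw$mu, fw$sigma, fw$tau, log = TRUE)
  n <- data$n
  pen <- 0
  if (!is.null(pars$u)) pen <- pen + sum(pars$u^2)
  if (!is.null(pars$gain)) pen <- pen + sum(pars$gain^2)
  if (!is.null(pars$wtok)) pen <- pen + sum(pars$wtok^2)
  loss <- -mean(ll) + config$lambda * pen / n
  if (!want_grad) return(list(loss = loss, loglik = ll))

  g <- exgauss_logpdf_grad(data$y, fw$mu, fw$sigma, fw$tau)
  G <- cbind(-g$mu,
             -g$sigma * softplus_grad(fw$eta[, 2]),
             -g$tau * softplus_grad(fw$eta[, 3])) / n

  grad <- list(b = colSums(G), nets = vector("list", length(config$networks)))
  if (!is.null(pars$u)) {
    du <- matrix(0, nrow(pars$u), 3)
    known <- data$part > 0L
    if (any(known)) {
      agg <- rowsum(G[known, , drop = FALSE], data$part[known])
      du[as.integer(rownames(agg)), ] <- agg
    }
    grad$u <- du + 2 * config$lambda * pars$u / n
  }
  if (!is.null(pars$wtok)) {
    dw <- rep(0, length(pars$wtok))
    agg <- rowsum(G[, 1], data$tok)
    dw[as.integer(rownames(agg))] <- agg[, 1]
    grad$wtok <- dw + 2 * config$lambda * pars$wtok / n
  }
  if (!is.null(pars$gain))
    dgain <- matrix(0, nrow(pars$gain), ncol(pars$gain))

  for (m in seq_along(config$networks)) {
    net <- config$networks[[m]]
    W <- pars$nets[[m]]
    cache <- fw$caches[[m]]
    if (is.null(cache)) {
      # no pairs reached this network (degenerate dataset): zero grads
      grad$nets[[m]] <- rapply(W, function(x) x * 0, how = "replace")
      next
    }
    cols <- net_param_idx(net)
    dContrib <- G[data$pair_resp, cols, drop = FALSE]
    if (!is.null(pars$gain)) {
      kn <- data$pair_part > 0L
      if (any(kn)) {
        per_pair <- rowSums(cache$out * dContrib)
        agg <- rowsum(per_pair[kn], data$pair_part[kn])
        dgain[as.integer(rownames(agg)), m] <-
          dgain[as.integer(rownames(agg)), m] + agg[, 1]
      }
    }
    dOut <- dContrib * cache$gainfac
    gW <- list()
    if (config$irf == "mlp") {
      L <- length(config$hidden)
      Hlast <- cache$acts[[L + 1L]]
      gW$Wout <- crossprod(Hlast, dOut)
      gW$bout <- colSums(dOut)
      dH <- dOut %*% t(W$Wout)
      for (l in L:1) {
        dA <- dH * (1 - cache$acts[[l + 1L]]^2)
        gW[[paste0("W", l)]] <- crossprod(cache$acts[[l]], dA)
        gW[[paste0("b", l)]] <- colSums(dA)
        if (l > 1L) dH <- dA %*% t(W[[paste0("W", l)]])
      }
      gW <- gW[names(W)]
    } else {
      gW$Wout <- crossprod(cache$acts[[1]], dOut)
    }
    grad$nets[[m]] <- gW
  }
  if (!is.null(pars$gain)) {
    # chain rule through the per-network centering of the gains
    dgain <- sweep(dgain, 2, colMeans(dgain))
    grad$gain <- dgain + 2 * config$lambda * pars$gain / n
  }
  grad <- grad[names(pars)]
  list(loss = loss, grad = grad, loglik = ll)
}

# Subset the prepared data to a set of response indices (for minibatching).
subset_cdr_data <- function(data, idx) {
  sel <- data$pair_resp %in% idx
  remap <- integer(data$n)
  remap[idx] <- seq_along(idx)
  list(n = length(idx),
       y = data$y[idx],
       part = data$part[idx],
       tok = data$tok[idx],
       pair_resp = remap[data$pair_resp[sel]],
       pair_part = data$pair_part[sel],
       feats = lapply(data$feats, function(f) f[sel, , drop = FALSE]),
       n_events = data$n_events[idx])
}
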