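# Route log-likelihoods under a decoding policy, the importance-weighted
# negative log-likelihood used for training, and an exhaustive-enumeration
# oracle for tiny molecules.

#' Loss configuration
#'
#' Controls the importance-weighted likelihood: \code{alpha} sets the
#' randomness of the route-sampling distribution q_alpha (1 = deterministic
#' canonical decoding) and \code{k} the number of routes drawn per molecule.
#' The defaults follow the reference training setup: alpha 0.8 with k = 5;
#' for alpha = 1 a single route suffices.
#'
#' @param alpha canonical-action probability in [0, 1]
#' @param k routes per molecule (defaults to 1 when alpha = 1, else 5)
#' @return list of class \code{loss_config}
#' @export
loss_config <- function(alpha = 0.8, k = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (is.null(k)) k <- if (alpha == 1) 1L else 5L
  stopifnot(k >= 1L)
  structure(list(alpha = alpha, k = as.integer(k)), class = "loss_config")
}

as_policy_bundle <- function(model) {
  if (inherits(model, "molgen"))
    return(list(params = model$params, config = model$config,
                vocab = model$vocab))
  stopifnot(is.list(model), !is.null(model$params), !is.null(model$config),
            !is.null(model$vocab))
  model
}

route_key <- function(route)
  paste(vapply(route$steps, function(s) tr_key(s$transition), character(1)),
        collapse = ";")

#' Log-probability of a decoding route under the policy
#'
#' Sums the per-step log-probabilities the policy assigns to the realized
#' transitions: the initialization step is scored by the initial-atom
#' distribution, every later step by a full policy forward pass on the
#' intermediate graph (MolRNN threads its recurrent state through the
#' steps). A transition outside the policy's support yields \code{-Inf}
#' with a warning.
#'
#' @param model a fitted \code{molgen} model or a bundle with
#'   \code{params}, \code{config}, \code{vocab}
#' @param route a \code{decoding_route}
#' @param condition optional conditional code vector
#' @return scalar log-probability
#' @export
route_logp <- function(model, route, condition = NULL) {
  route_score(as_policy_bundle(model), route, condition)$logp
}

# full scoring pass; optionally keeps caches for the reverse pass
route_score <- function(bundle, route, cvec = NULL, want_cache = FALSE) {
  P <- bundle$params; cfg <- bundle$config; vocab <- bundle$vocab
  n_a <- nrow(vocab); n_b <- 4L
  steps <- route$steps
  lp <- 0
  caches <- if (want_cache) vector("list", length(steps)) else NULL
  realized <- vector("list", length(steps))
  state <- if (cfg$model == "rnn") rnn_state_new(cfg) else NULL
  for (k in seq_along(steps)) {
    tr <- steps[[k]]$transition
    if (k == 1L) {
      stopifnot(tr$tag == "init")
      lpi <- init_policy_logp(P, cvec)
      ai <- vocab_index(vocab, data.frame(symbol = tr$symbol, nh = tr$nh,
                                          charge = tr$charge))
      lp <- lp + lpi[ai]
      realized[[k]] <- list(kind = "init", ai = ai, lpi = lpi)
      next
    }
    g <- steps[[k]]$graph
    fk <- if (!is.null(route$feats)) route$feats[[k]] else NULL
    po <- policy_forward(P, cfg, vocab, g, cvec, state, feats = fk,
                         want_cache = want_cache)
    state <- po$state
    if (tr$tag == "terminate") {
      lp_step <- po$log_term
      realized[[k]] <- list(kind = "term")
    } else if (tr$tag == "append") {
      ai <- vocab_index(vocab, data.frame(symbol = tr$symbol, nh = tr$nh,
                                          charge = tr$charge))
      row <- score_row_append(n_a, ai, tr$bond)
      lp_step <- po$log_append[row, tr$anchor]
      realized[[k]] <- list(kind = "act", row = row, col = tr$anchor)
    } else if (tr$tag == "connect") {
      row <- score_row_connect(n_a, n_b, tr$bond)
      lp_step <- po$log_append[row, tr$target]
      realized[[k]] <- list(kind = "act", row = row, col = tr$target)
    } else stop("unexpected transition in route")
    if (!is.finite(lp_step)) {
      warning("transition outside policy support; log-probability is -Inf")
      lp_step <- -Inf
    }
    lp <- lp + lp_step
    if (want_cache) caches[[k]] <- po
  }
  list(logp = as.numeric(lp), caches = caches, realized = realized)
}

# Accumulate gradient of (weight * negative log-likelihood of `route`).
route_nll_grad <- function(bundle, route, cvec, gr, weight = 1) {
  P <- bundle$params; cfg <- bundle$config; vocab <- bundle$vocab
  n_a <- nrow(vocab); n_b <- 4L
  sc <- route_score(bundle, route, cvec, want_cache = TRUE)
  steps <- route$steps
  K <- length(steps)
  # init step
  r1 <- sc$realized[[1]]
  p1 <- exp(r1$lpi)
  d1 <- weight * p1
  d1[r1$ai] <- d1[r1$ai] - weight
  init_policy_backward(P, cvec, d1, gr)
  if (K == 1L) return(sc$logp)
  f2 <- cfg$fc_widths[2]
  head_parts <- vector("list", K)
  for (k in 2:K) {
    po <- sc$caches[[k]]
    probs <- exp(po$log_append)          # (A*B + B) x n
    dY <- weight * probs
    dystar <- weight * exp(po$log_term)
    rk <- sc$realized[[k]]
    if (rk$kind == "term") dystar <- dystar - weight
    else dY[rk$row, rk$col] <- dY[rk$row, rk$col] - weight
    hp <- policy_backward_step(P, cfg, po$cache, dY, dystar, gr)
    head_parts[[k]] <- list(cache = po$cache, dF2_head = hp$dF2_head,
                            dgvec = hp$dgvec)
  }
  if (cfg$model == "rnn") {
    dstate <- lapply(cfg$rnn_widths, numeric)
    for (k in K:2) {
      hp <- head_parts[[k]]
      rb <- rnn_backward(P, cfg, hp$cache$rnn$caches, hp$dgvec, dstate, gr)
      dstate <- rb$dstate
      dhv <- rb$dx[seq_len(f2)]
      dhG <- rb$dx[(f2 + 1L):(2L * f2)]
      trunk_backprop_with_g(P, cfg, hp$cache, hp$dF2_head, dhG, dhv, gr)
    }
  } else {
    for (k in 2:K) {
      hp <- head_parts[[k]]
      trunk_backprop_with_g(P, cfg, hp$cache, hp$dF2_head, hp$dgvec, NULL, gr)
    }
  }
  sc$logp
}

#' Importance-weighted negative log-likelihood
#'
#' Draws \code{k} routes from q_alpha and returns the negative of the
#' importance-sampling lower bound on log p(G): \code{-log mean_i
#' exp(log p(G, r_i) - log q_alpha(r_i | G))}. With alpha = 1 and k = 1
#' this collapses to the exact negative log-likelihood of the canonical
#' route.
#'
#' @param model fitted \code{molgen} or policy bundle
#' @param g a connected, valid \code{molgraph}
#' @param loss a \code{\link{loss_config}}
#' @param condition optional conditional code vector
#' @param memo optional environment memoizing route log-probabilities by
#'   route signature (useful for repeated estimates on tiny molecules)
#' @param cache optional decoding-state cache passed to
#'   \code{\link{sample_route}}
#' @return scalar loss (negative lower bound)
#' @export
iw_nll <- function(model, g, loss = loss_config(), condition = NULL,
                   memo = NULL, cache = NULL) {
  bundle <- as_policy_bundle(model)
  routes <- lapply(seq_len(loss$k),
                   function(i) sample_route(g, loss$alpha, cache = cache))
  lw <- vapply(routes, function(r) {
    lp <- if (!is.null(memo)) {
      key <- route_key(r)
      v <- memo[[key]]
      if (is.null(v)) {
        v <- route_score(bundle, r, condition)$logp
        memo[[key]] <- v
      }
      v
    } else route_score(bundle, r, condition)$logp
    lp - r$log_q
  }, numeric(1))
  if (all(!is.finite(lw))) {
    warning("all sampled routes have zero policy probability")
    return(1e6)
  }
  -(logsumexp(lw) - log(loss$k))
}

# loss + gradient for one molecule (used by the trainer); routes may be
# passed in (e.g. cached canonical routes when alpha = 1)
iw_nll_grad <- function(bundle, g, loss, cvec, gr, routes = NULL,
                        weight = 1) {
  if (is.null(routes))
    routes <- lapply(seq_len(loss$k), function(i) sample_route(g, loss$alpha))
  lps <- vapply(routes, function(r) route_score(bundle, r, cvec)$logp,
                numeric(1))
  lw <- lps - vapply(routes, function(r) r$log_q, numeric(1))
  if (all(!is.finite(lw))) {
    warning("all sampled routes have zero policy probability")
    return(1e6)
  }
  lse <- logsumexp(lw)
  omega <- exp(lw - lse)
  for (i in seq_along(routes)) {
    if (omega[i] > 0)
      route_nll_grad(bundle, routes[[i]], cvec, gr, weight = weight * omega[i])
  }
  as.numeric(-(lse - log(length(routes))))
}

#' Exact log-likelihood by route enumeration
#'
#' Computes log p(G) = log sum over all decoding routes of p(G, r) by
#' exhaustive enumeration. Intractable in general, so restricted to tiny
#' molecules; serves as the oracle against which the importance-weighted
#' estimate is validated.
#'
#' @param model fitted \code{molgen} or policy bundle
#' @param g a connected, valid \code{molgraph} with at most \code{max_atoms}
#'   atoms
#' @param condition optional conditional code vector
#' @param max_atoms enumeration size bound
#' @return exact scalar log-likelihood
#' @export
enumerate_logp <- function(model, g, condition = NULL, max_atoms = 5L) {
  bundle <- as_policy_bundle(model)
  routes <- enumerate_routes(g, max_atoms = max_atoms)
  lps <- vapply(routes, function(r) route_score(bundle, r, condition)$logp,
                numeric(1))
  logsumexp(lps)
}
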