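# Decoding-policy networks: atom embedding, edge-conditioned graph
# convolution with remote-neighbor terms, fully connected trunk, action
# heads with joint normalization, and the molecule-level GRU of MolRNN.
# Forward passes cache every intermediate needed by the hand-written
# reverse pass; gradients are exact.

# --- featurization --------------------------------------------------------

# adjacency indicators per bond type and per path distance 2..D
graph_features <- function(g, vocab, D) {
  n <- nrow(g$atoms)
  aidx <- vocab_index(vocab, g$atoms)
  M <- vector("list", 4L)
  for (b in 1:4) M[[b]] <- matrix(0, n, n)
  if (nrow(g$bonds) > 0) for (k in seq_len(nrow(g$bonds))) {
    b <- g$bonds$type[k]; i <- g$bonds$i[k]; j <- g$bonds$j[k]
    M[[b]][i, j] <- 1; M[[b]][j, i] <- 1
  }
  Md <- list()
  if (D >= 2L && n > 1L) {
    dist <- mg_distances(g, max_d = D)
    for (d in 2:D) Md[[as.character(d)]] <- (dist == d) * 1
  }
  list(n = n, aidx = aidx, latest = g$latest, M = M, Md = Md)
}

# --- atom-level trunk -----------------------------------------------------

trunk_forward <- function(P, cfg, feats, cvec = NULL) {
  n <- feats$n
  X0 <- P$emb_type[, feats$aidx, drop = FALSE]
  if (!is.na(feats$latest)) X0[, feats$latest] <- X0[, feats$latest] + P$emb_latest
  L <- length(cfg$conv_widths)
  X <- vector("list", L); Z <- vector("list", L); NS <- vector("list", L)
  Xprev <- X0
  for (l in seq_len(L)) {
    Zl <- if (l == 1L) Xprev else pmax(Xprev, 0)
    A <- P[[paste0("W", l)]] %*% Zl + P[[paste0("bconv", l)]]
    ns_l <- list()
    for (b in 1:4) {
      if (any(feats$M[[b]] != 0)) {
        Nb <- Zl %*% feats$M[[b]]
        ns_l[[paste0("b", b)]] <- Nb
        A <- A + P[[paste0("Th", l, "_", b)]] %*% Nb
      }
    }
    for (d in names(feats$Md)) {
      if (any(feats$Md[[d]] != 0)) {
        Nd <- Zl %*% feats$Md[[d]]
        ns_l[[paste0("d", d)]] <- Nd
        A <- A + P[[paste0("Ph", l, "_", d)]] %*% Nd
      }
    }
    if (cfg$cond_dim > 0L)
      A <- A + as.vector(P[[paste0("Psi", l)]] %*% cvec)
    X[[l]] <- A; Z[[l]] <- Zl; NS[[l]] <- ns_l
    Xprev <- A
  }
  S0 <- do.call(rbind, X)
  S <- pmax(S0, 0)
  F1a <- P$U1 %*% S + P$c1; F1 <- pmax(F1a, 0)
  F2a <- P$U2 %*% F1 + P$c2; F2 <- pmax(F2a, 0)
  hG <- rowMeans(F2)
  list(n = n, feats = feats, cvec = cvec, X0 = X0, X = X, Z = Z, NS = NS,
       S0 = S0, S = S, F1a = F1a, F1 = F1, F2a = F2a, F2 = F2, hG = hG)
}

trunk_backward <- function(P, cfg, cache, dF2, gr) {
  dF2m <- dF2 * (cache$F2a > 0)
  grad_acc(gr, "U2", dF2m %*% t(cache$F1))
  grad_acc(gr, "c2", rowSums(dF2m))
  dF1 <- crossprod(P$U2, dF2m) * (cache$F1a > 0)
  grad_acc(gr, "U1", dF1 %*% t(cache$S))
  grad_acc(gr, "c1", rowSums(dF1))
  dS <- crossprod(P$U1, dF1) * (cache$S0 > 0)
  L <- length(cfg$conv_widths)
  offs <- cumsum(c(0L, cfg$conv_widths))
  dX <- vector("list", L)
  for (l in seq_len(L))
    dX[[l]] <- dS[(offs[l] + 1L):offs[l + 1L], , drop = FALSE]
  feats <- cache$feats
  for (l in rev(seq_len(L))) {
    dA <- dX[[l]]
    Zl <- cache$Z[[l]]
    grad_acc(gr, paste0("W", l), dA %*% t(Zl))
    grad_acc(gr, paste0("bconv", l), rowSums(dA))
    dZ <- crossprod(P[[paste0("W", l)]], dA)
    for (b in 1:4) {
      Nb <- cache$NS[[l]][[paste0("b", b)]]
      if (is.null(Nb)) next
      grad_acc(gr, paste0("Th", l, "_", b), dA %*% t(Nb))
      dZ <- dZ + crossprod(P[[paste0("Th", l, "_", b)]], dA) %*% feats$M[[b]]
    }
    for (d in names(feats$Md)) {
      Nd <- cache$NS[[l]][[paste0("d", d)]]
      if (is.null(Nd)) next
      grad_acc(gr, paste0("Ph", l, "_", d), dA %*% t(Nd))
      dZ <- dZ + crossprod(P[[paste0("Ph", l, "_", d)]], dA) %*% feats$Md[[d]]
    }
    if (cfg$cond_dim > 0L)
      grad_acc(gr, paste0("Psi", l), rowSums(dA) %*% t(cache$cvec))
    if (l > 1L) {
      dX[[l - 1L]] <- dX[[l - 1L]] + dZ * (cache$X[[l - 1L]] > 0)
    } else {
      dX0 <- dZ
    }
  }
  # embedding gradients
  dEmb <- matrix(0, nrow(P$emb_type), ncol(P$emb_type))
  for (v in seq_len(cache$n))
    dEmb[, feats$aidx[v]] <- dEmb[, feats$aidx[v]] + dX0[, v]
  grad_acc(gr, "emb_type", dEmb)
  if (!is.na(feats$latest)) grad_acc(gr, "emb_latest", dX0[, feats$latest])
  invisible(NULL)
}

# --- molecule-level GRU (MolRNN) ------------------------------------------

rnn_state_new <- function(cfg) lapply(cfg$rnn_widths, numeric)

sigm <- function(x) 1 / (1 + exp(-x))

rnn_forward <- function(P, cfg, x, state) {
  J <- length(cfg$rnn_widths)
  caches <- vector("list", J)
  for (j in seq_len(J)) {
    h <- state[[j]]
    z <- sigm(as.vector(P[[paste0("gruWz", j)]] %*% x) +
                as.vector(P[[paste0("gruUz", j)]] %*% h) + P[[paste0("grubz", j)]])
    r <- sigm(as.vector(P[[paste0("gruWr", j)]] %*% x) +
                as.vector(P[[paste0("gruUr", j)]] %*% h) + P[[paste0("grubr", j)]])
    hh <- tanh(as.vector(P[[paste0("gruWh", j)]] %*% x) +
                 as.vector(P[[paste0("gruUh", j)]] %*% (r * h)) +
                 P[[paste0("grubh", j)]])
    hn <- (1 - z) * h + z * hh
    caches[[j]] <- list(x = x, h = h, z = z, r = r, hh = hh)
    state[[j]] <- hn
    x <- hn
  }
  list(state = state, caches = caches)
}

# backward through one time step of the stack.
# dtop: grad wrt the top-layer output at this step; dstate: list of grads
# wrt each layer's new hidden state flowing back from the next time step.
# Returns list(dx = grad wrt the step input vector, dstate = grads wrt the
# previous hidden states).
rnn_backward <- function(P, cfg, caches, dtop, dstate, gr) {
  J <- length(cfg$rnn_widths)
  dh_out <- dstate
  dh_out[[J]] <- dh_out[[J]] + dtop
  dx_lower <- NULL
  dstate_prev <- vector("list", J)
  for (j in rev(seq_len(J))) {
    cj <- caches[[j]]
    dhn <- dh_out[[j]]
    if (!is.null(dx_lower)) dhn <- dhn + dx_lower
    z <- cj$z; r <- cj$r; hh <- cj$hh; h <- cj$h; x <- cj$x
    dz <- dhn * (hh - h)
    dhh <- dhn * z
    dh_prev <- dhn * (1 - z)
    da_h <- dhh * (1 - hh^2)
    grad_acc(gr, paste0("gruWh", j), da_h %*% t(x))
    grad_acc(gr, paste0("gruUh", j), da_h %*% t(r * h))
    grad_acc(gr, paste0("grubh", j), da_h)
    dx <- as.vector(crossprod(P[[paste0("gruWh", j)]], da_h))
    drh <- as.vector(crossprod(P[[paste0("gruUh", j)]], da_h))
    dr <- drh * h
    dh_prev <- dh_prev + drh * r
    da_z <- dz * z * (1 - z)
    grad_acc(gr, paste0("gruWz", j), da_z %*% t(x))
    grad_acc(gr, paste0("gruUz", j), da_z %*% t(h))
    grad_acc(gr, paste0("grubz", j), da_z)
    dx <- dx + as.vector(crossprod(P[[paste0("gruWz", j)]], da_z))
    dh_prev <- dh_prev + as.vector(crossprod(P[[paste0("gruUz", j)]], da_z))
    da_r <- dr * r * (1 - r)
    grad_acc(gr, paste0("gruWr", j), da_r %*% t(x))
    grad_acc(gr, paste0("gruUr", j), da_r %*% t(h))
    grad_acc(gr, paste0("grubr", j), da_r)
    dx <- dx + as.vector(crossprod(P[[paste0("gruWr", j)]], da_r))
    dh_prev <- dh_prev + as.vector(crossprod(P[[paste0("gruUr", j)]], da_r))
    dstate_prev[[j]] <- dh_prev
    dx_lower <- dx
  }
  list(dx = dx_lower, dstate = dstate_prev)
}

# --- action heads ---------------------------------------------------------

heads_forward <- function(P, gvec, F2) {
  n <- ncol(F2)
  U <- rbind(F2, matrix(gvec, length(gvec), n))
  H1a <- P$V1 %*% U + P$d1; H1 <- pmax(H1a, 0)
  Y <- P$V2 %*% H1 + P$d2
  ystar <- as.vector(P$wstar %*% gvec) + P$dstar
  logZ <- logsumexp(c(Y, ystar))
  list(U = U, H1a = H1a, H1 = H1, Y = Y, ystar = ystar, logZ = logZ,
       gvec = gvec, f2 = nrow(F2))
}

heads_backward <- function(P, hc, dY, dystar, gr) {
  dH1 <- crossprod(P$V2, dY) * (hc$H1a > 0)
  grad_acc(gr, "V2", dY %*% t(hc$H1))
  grad_acc(gr, "d2", rowSums(dY))
  dU <- crossprod(P$V1, dH1)
  grad_acc(gr, "V1", dH1 %*% t(hc$U))
  grad_acc(gr, "d1", rowSums(dH1))
  f2 <- hc$f2
  dF2 <- dU[seq_len(f2), , drop = FALSE]
  dgvec <- rowSums(dU[(f2 + 1L):nrow(dU), , drop = FALSE]) +
    as.vector(t(P$wstar)) * dystar
  grad_acc(gr, "wstar", dystar * t(hc$gvec))
  grad_acc(gr, "dstar", dystar)
  list(dF2 = dF2, dgvec = dgvec)
}

# --- full policy forward --------------------------------------------------

# One forward pass of the decoding policy on a non-empty graph state.
# Returns the jointly normalized action log-probabilities (log-domain) and
# the caches needed for the reverse pass; for MolRNN also the updated
# molecule-level recurrent state.
policy_forward <- function(P, cfg, vocab, g, cvec = NULL, state = NULL,
                           feats = NULL, want_cache = FALSE) {
  if (nrow(g$atoms) == 0L) stop("policy_forward needs a non-empty graph")
  if (cfg$cond_dim > 0L && is.null(cvec))
    stop("conditional model requires a condition code", call. = FALSE)
  if (is.null(feats)) feats <- graph_features(g, vocab, cfg$receptive_field)
  tc <- trunk_forward(P, cfg, feats, cvec)
  if (cfg$model == "rnn") {
    if (is.null(state)) state <- rnn_state_new(cfg)
    f2 <- cfg$fc_widths[2]
    hv <- if (!is.na(feats$latest)) tc$F2[, feats$latest] else numeric(f2)
    x <- c(hv, tc$hG)
    rc <- rnn_forward(P, cfg, x, state)
    gvec <- rc$state[[length(rc$state)]]
  } else {
    rc <- NULL
    gvec <- tc$hG
  }
  hc <- heads_forward(P, gvec, tc$F2)
  out <- list(
    n = feats$n,
    log_append = hc$Y - hc$logZ,  # (|A|*|B| + |B|) x n, see score_index
    ystar = hc$ystar, logZ = hc$logZ,
    log_term = hc$ystar - hc$logZ,
    state = if (cfg$model == "rnn") rc$state else NULL)
  if (want_cache) out$cache <- list(trunk = tc, heads = hc, rnn = rc,
                                    feats = feats)
  class(out) <- "policy_output"
  out
}

# row index into the stacked per-atom score matrix for an action
score_row_append <- function(n_a, a, b) (b - 1L) * n_a + a
score_row_connect <- function(n_a, n_b, b) n_a * n_b + b

#' Policy output probabilities
#'
#' Materializes the jointly normalized probabilities of a policy forward
#' pass: the per-atom append matrix (|A| x |B| per atom), the per-atom
#' connect vector (|B|), and the termination scalar. All entries are
#' positive and sum to one.
#'
#' @param po internal policy output (from the generator loop)
#' @param n_a,n_b vocabulary and bond-type counts
#' @return list with \code{p_append} (array |A| x |B| x n),
#'   \code{p_connect} (|B| x n), \code{p_terminate}
#' @keywords internal
policy_probs <- function(po, n_a, n_b = 4L) {
  p_all <- exp(po$log_append)
  n <- po$n
  p_append <- array(p_all[seq_len(n_a * n_b), , drop = FALSE],
                    dim = c(n_a, n_b, n))
  p_connect <- matrix(p_all[(n_a * n_b + 1L):(n_a * n_b + n_b), , drop = FALSE],
                      n_b, n)
  list(p_append = p_append, p_connect = p_connect,
       p_terminate = exp(po$log_term))
}

# backward: dY/dystar on the score scale; handles trunk + heads (+ the
# per-step head-side of the RNN; BPTT is orchestrated by the caller)
policy_backward_step <- function(P, cfg, cache, dY, dystar, gr) {
  hb <- heads_backward(P, cache$heads, dY, dystar, gr)
  list(dF2_head = hb$dF2, dgvec = hb$dgvec)
}

# distribute molecule-level gradient into the trunk and run it
trunk_backprop_with_g <- function(P, cfg, cache, dF2_head, dhG, dhv, gr) {
  n <- cache$trunk$n
  dF2 <- dF2_head + matrix(dhG / n, length(dhG), n)
  latest <- cache$feats$latest
  if (!is.null(dhv) && !is.na(latest))
    dF2[, latest] <- dF2[, latest] + dhv
  trunk_backward(P, cfg, cache$trunk, dF2, gr)
}

# --- initialization policy ------------------------------------------------

# log-probabilities over atom types for the very first atom
init_policy_logp <- function(P, cvec = NULL) {
  logits <- P$ilogit
  if (!is.null(P$icond) && !is.null(cvec))
    logits <- logits + as.vector(P$icond %*% cvec)
  logits - logsumexp(logits)
}

init_policy_backward <- function(P, cvec, dlogits, gr) {
  grad_acc(gr, "ilogit", dlogits)
  if (!is.null(P$icond) && !is.null(cvec))
    grad_acc(gr, "icond", dlogits %*% t(cvec))
  invisible(NULL)
}

#' Initial-atom distribution
#'
#' The decoding scheme's initialization step needs a distribution over atom
#' types on the empty graph, which the graph network cannot produce; a
#' learned categorical (optionally shifted linearly by the conditional
#' code) fills that role.
#'
#' @param model a fitted \code{molgen} model (or a bare parameter list)
#' @param condition optional conditional code vector
#' @return named numeric vector of probabilities over the vocabulary
#' @export
init_distribution <- function(model, condition = NULL) {
  P <- if (inherits(model, "molgen")) model$params else model
  lp <- init_policy_logp(P, condition)
  p <- exp(lp)
  if (inherits(model, "molgen"))
    names(p) <- vocab_key(model$vocab$symbol, model$vocab$nh,
                          model$vocab$charge)
  p
}
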