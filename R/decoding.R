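# The decoding scheme: graph transitions, canonical depth-first routes, and
# the alpha-randomized route sampler q_alpha used for importance-weighted
# likelihood estimation.
#
# Routes are distributions over *actions* (transition tuples), not over
# target-atom choices: symmetric atoms of the target molecule collapse to
# the same action, so q_alpha is an exact probability distribution over
# distinct decoding routes. This is implemented by maintaining the set of
# live embeddings of the partial graph into the target molecule; an
# embedding stays live only while the remaining edges can still be emitted
# under the connect-from-v* restriction.

#' Graph transitions
#'
#' Constructors for the four transition types of the decoding scheme:
#' initialization (place the first atom), append (new atom + bond to an
#' existing atom; the new atom becomes the latest atom \code{v*}), connect
#' (new bond from \code{v*} to an existing atom), terminate.
#'
#' @param symbol,nh,charge atom-type triple of the new atom
#' @param anchor index of the existing atom an append bonds to
#' @param target index of the existing atom a connect bonds \code{v*} to
#' @param bond integer bond-type code (see \code{\link{bond_types}})
#' @return object of class \code{transition}
#' @export
t_init <- function(symbol, nh = 0L, charge = 0L) {
  structure(list(tag = "init", symbol = symbol, nh = as.integer(nh),
                 charge = as.integer(charge)), class = "transition")
}

#' @rdname t_init
#' @export
t_append <- function(anchor, symbol, nh = 0L, charge = 0L, bond = 1L) {
  structure(list(tag = "append", anchor = as.integer(anchor), symbol = symbol,
                 nh = as.integer(nh), charge = as.integer(charge),
                 bond = as.integer(bond)), class = "transition")
}

#' @rdname t_init
#' @export
t_connect <- function(target, bond = 1L) {
  structure(list(tag = "connect", target = as.integer(target),
                 bond = as.integer(bond)), class = "transition")
}

#' @rdname t_init
#' @export
t_terminate <- function() structure(list(tag = "terminate"), class = "transition")

#' @export
print.transition <- function(x, ...) {
  cat(switch(x$tag,
    init = sprintf("<init (%s,%d,%d)>", x$symbol, x$nh, x$charge),
    append = sprintf("<append anchor=%d (%s,%d,%d) bond=%d>", x$anchor,
                     x$symbol, x$nh, x$charge, x$bond),
    connect = sprintf("<connect target=%d bond=%d>", x$target, x$bond),
    terminate = "<terminate>"), "\n")
  invisible(x)
}

transition_error <- function(msg) mol_error(msg, "molgraphgen_transition_error")

#' Apply a transition to a graph
#'
#' Performs the structural update \code{G_{i+1} = t(G_i)}. Only structural
#' applicability is enforced; chemical validity is deliberately not checked,
#' mirroring a decoding scheme that leaves learning chemistry to the policy.
#'
#' @param g a \code{molgraph} (the intermediate state)
#' @param t a \code{transition}
#' @return the updated \code{molgraph}
#' @export
apply_transition <- function(g, t) {
  stopifnot(inherits(g, "molgraph"), inherits(t, "transition"))
  n <- nrow(g$atoms)
  switch(t$tag,
    init = {
      if (n != 0L) transition_error("init only applies to the empty graph")
      molgraph(data.frame(symbol = t$symbol, nh = t$nh, charge = t$charge),
               latest = 1L)
    },
    append = {
      if (t$anchor < 1L || t$anchor > n)
        transition_error("append anchor out of range")
      atoms <- rbind(g$atoms, data.frame(symbol = t$symbol, nh = t$nh,
                                         charge = t$charge))
      bonds <- rbind(g$bonds, data.frame(i = t$anchor, j = n + 1L,
                                         type = t$bond))
      molgraph(atoms, bonds, latest = n + 1L)
    },
    connect = {
      if (is.na(g$latest)) transition_error("connect requires v* to be set")
      if (t$target < 1L || t$target > n)
        transition_error("connect target out of range")
      if (t$target == g$latest) transition_error("connect target equals v*")
      if (nrow(g$bonds) > 0) {
        key <- paste(pmin(g$bonds$i, g$bonds$j), pmax(g$bonds$i, g$bonds$j))
        if (paste(min(g$latest, t$target), max(g$latest, t$target)) %in% key)
          transition_error("bond v*-target already exists")
      }
      bonds <- rbind(g$bonds, data.frame(i = g$latest, j = t$target,
                                         type = t$bond))
      molgraph(g$atoms, bonds, latest = g$latest)
    },
    terminate = g,
    transition_error("unknown transition tag"))
}

#' Number of decoding steps for a molecule
#'
#' Every decoding route of a connected graph \code{G = (V, E)} has exactly
#' \code{|E| + 2} steps: one initialization, one transition per edge (an
#' append carries its new atom's bond), and one termination.
#'
#' @param g a connected \code{molgraph}
#' @return integer step count
#' @export
route_length <- function(g) {
  if (!mg_connected(g)) stop("graph is disconnected", call. = FALSE)
  nrow(g$bonds) + 2L
}

# --- internal route machinery ---------------------------------------------

route_context <- function(g) {
  if (nrow(g$atoms) == 0L) stop("cannot decode the empty graph", call. = FALSE)
  if (!mg_connected(g)) stop("graph is disconnected", call. = FALSE)
  list(g = g, adj = mg_adjacency(g), rank = canonical_ranks(g),
       n = nrow(g$atoms))
}

# bond type between two target atoms (0 if none)
ctx_bond <- function(ctx, u, w) {
  k <- match(w, ctx$adj[[u]]$nbr)
  if (is.na(k)) 0L else ctx$adj[[u]]$type[k]
}

atom_key <- function(sym, nh, chg) paste0(sym, ",", nh, ",", chg)
tr_key <- function(t) switch(t$tag,
  init = paste0("i|", atom_key(t$symbol, t$nh, t$charge)),
  append = paste0("a|", t$anchor, "|", atom_key(t$symbol, t$nh, t$charge),
                  "|", t$bond),
  connect = paste0("c|", t$target, "|", t$bond),
  terminate = "t")

# For one embedding row: the unbuilt target edges among mapped atoms.
# Partial bonds map through the row, so unbuilt = mapped-pair target edges
# minus images of partial bonds. Returns NULL if the row is dead (an
# unbuilt mapped edge misses v*), else list(pending = matrix of (g_u, g_w)).
row_pending <- function(ctx, e, partial_bonds, latest_p) {
  p <- length(e)
  built <- character(0)
  if (nrow(partial_bonds) > 0) {
    gi <- e[partial_bonds$i]; gj <- e[partial_bonds$j]
    built <- paste(pmin(gi, gj), pmax(gi, gj))
  }
  latest_g <- e[latest_p]
  pend_u <- integer(0); pend_w <- integer(0)
  for (k in seq_len(p)) {
    u <- e[k]
    nb <- ctx$adj[[u]]$nbr
    for (w in nb[nb > u]) {
      if (!(w %in% e)) next
      if (paste(u, w) %in% built) next
      if (u != latest_g && w != latest_g) return(NULL)  # dead row
      pend_u <- c(pend_u, u); pend_w <- c(pend_w, w)
    }
  }
  cbind(pend_u, pend_w)
}

# Enumerate distinct valid actions at a state. Returns list(actions = named
# list of transitions, emb = live rows only).
state_actions <- function(ctx, emb, partial) {
  if (is.null(emb)) {  # empty graph: initialization
    acts <- list()
    for (w in seq_len(ctx$n)) {
      a <- ctx$g$atoms[w, ]
      tr <- t_init(a$symbol, a$nh, a$charge)
      acts[[tr_key(tr)]] <- tr
    }
    return(list(actions = acts, emb = NULL))
  }
  latest_p <- partial$latest
  acts <- list()
  live <- logical(nrow(emb))
  for (r in seq_len(nrow(emb))) {
    e <- emb[r, ]
    pend <- row_pending(ctx, e, partial$bonds, latest_p)
    if (is.null(pend)) next
    live[r] <- TRUE
    if (nrow(pend) > 0) {
      latest_g <- e[latest_p]
      for (q in seq_len(nrow(pend))) {
        t_g <- if (pend[q, 1] == latest_g) pend[q, 2] else pend[q, 1]
        tr <- t_connect(match(t_g, e), ctx_bond(ctx, latest_g, t_g))
        acts[[tr_key(tr)]] <- tr
      }
    } else if (length(e) == ctx$n) {
      acts[["t"]] <- t_terminate()
    } else {
      for (k in seq_along(e)) {
        nb <- ctx$adj[[e[k]]]
        for (q in seq_along(nb$nbr)) {
          w <- nb$nbr[q]
          if (w %in% e) next
          a <- ctx$g$atoms[w, ]
          tr <- t_append(k, a$symbol, a$nh, a$charge, nb$type[q])
          acts[[tr_key(tr)]] <- tr
        }
      }
    }
  }
  list(actions = acts, emb = emb[live, , drop = FALSE])
}

# canonical action under the lexicographically smallest live embedding
# (by canonical-rank sequence)
state_canonical_action <- function(ctx, emb, partial) {
  if (is.null(emb)) {
    w <- which(ctx$rank == 1L)
    a <- ctx$g$atoms[w, ]
    return(t_init(a$symbol, a$nh, a$charge))
  }
  # pick canonical row
  rk <- matrix(ctx$rank[emb], nrow = nrow(emb))
  best <- 1L
  if (nrow(emb) > 1L) {
    ord <- do.call(order, as.data.frame(rk))
    best <- ord[1]
  }
  e <- emb[best, ]
  latest_p <- partial$latest
  pend <- row_pending(ctx, e, partial$bonds, latest_p)
  latest_g <- e[latest_p]
  if (nrow(pend) > 0) {
    targets <- ifelse(pend[, 1] == latest_g, pend[, 2], pend[, 1])
    t_g <- targets[which.min(ctx$rank[targets])]
    return(t_connect(match(t_g, e), ctx_bond(ctx, latest_g, t_g)))
  }
  if (length(e) == ctx$n) return(t_terminate())
  # depth-first: deepest (most recently added) atom with an unmapped neighbor
  for (k in rev(seq_along(e))) {
    nb <- ctx$adj[[e[k]]]
    un <- nb$nbr[!(nb$nbr %in% e)]
    if (length(un) > 0) {
      w <- un[which.min(ctx$rank[un])]
      a <- ctx$g$atoms[w, ]
      return(t_append(k, a$symbol, a$nh, a$charge, ctx_bond(ctx, e[k], w)))
    }
  }
  stop("internal: no canonical action found")  # nocov
}

# successor embeddings after applying `tr` to (emb, partial)
state_advance_emb <- function(ctx, emb, partial, tr) {
  if (tr$tag == "init") {
    ak <- atom_key(tr$symbol, tr$nh, tr$charge)
    ws <- which(vapply(seq_len(ctx$n), function(w)
      atom_key(ctx$g$atoms$symbol[w], ctx$g$atoms$nh[w],
               ctx$g$atoms$charge[w]) == ak, logical(1)))
    return(matrix(ws, ncol = 1))
  }
  if (tr$tag == "terminate") return(emb)
  latest_p <- partial$latest
  if (tr$tag == "connect") {
    keep <- logical(nrow(emb))
    for (r in seq_len(nrow(emb))) {
      e <- emb[r, ]
      pend <- row_pending(ctx, e, partial$bonds, latest_p)
      if (is.null(pend)) next
      keep[r] <- ctx_bond(ctx, e[latest_p], e[tr$target]) == tr$bond &&
        nrow(pend) > 0
    }
    return(emb[keep, , drop = FALSE])
  }
  # append: extend pending-free rows by matching unmapped neighbors
  ak <- atom_key(tr$symbol, tr$nh, tr$charge)
  new_rows <- list()
  for (r in seq_len(nrow(emb))) {
    e <- emb[r, ]
    pend <- row_pending(ctx, e, partial$bonds, latest_p)
    if (is.null(pend) || nrow(pend) > 0) next
    nb <- ctx$adj[[e[tr$anchor]]]
    for (q in seq_along(nb$nbr)) {
      w <- nb$nbr[q]
      if (w %in% e || nb$type[q] != tr$bond) next
      a <- ctx$g$atoms[w, ]
      if (atom_key(a$symbol, a$nh, a$charge) != ak) next
      new_rows[[length(new_rows) + 1L]] <- c(e, w)
    }
  }
  do.call(rbind, new_rows)
}

new_route <- function(steps, log_q, alpha, final) {
  structure(list(steps = steps, log_q = log_q, alpha = alpha, final = final),
            class = "decoding_route")
}

#' @export
print.decoding_route <- function(x, ...) {
  cat(sprintf("<decoding_route: %d steps, alpha=%.2f, log_q=%.4f>\n",
              length(x$steps), x$alpha, x$log_q))
  invisible(x)
}

# Walk the action tree once. A state is fully determined by the action
# prefix, so an optional cache environment memoizes per-state action sets
# and successor embeddings across repeated walks on the same molecule
# (sampling q_alpha many times is then nearly free).
route_walk <- function(g, alpha, deterministic = FALSE, cache = NULL) {
  ctx <- if (!is.null(cache) && !is.null(cache$.ctx)) cache$.ctx
         else route_context(g)
  if (!is.null(cache) && is.null(cache$.ctx)) cache$.ctx <- ctx
  key <- "^"
  steps <- list()
  log_q <- 0
  prev <- NULL      # parent cache entry
  prev_akey <- NULL # action taken from the parent
  repeat {
    ent <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(ent)) {
      if (is.null(prev)) {
        partial <- molgraph(); emb <- NULL
      } else {
        emb <- state_advance_emb(ctx, prev$emb, prev$partial,
                                 prev$actions[[prev_akey]])
        partial <- apply_transition(prev$partial, prev$actions[[prev_akey]])
      }
      sa <- state_actions(ctx, emb, partial)
      can <- state_canonical_action(ctx, sa$emb, partial)
      ent <- list(partial = partial, emb = sa$emb, actions = sa$actions,
                  can_key = tr_key(can))
      stopifnot(ent$can_key %in% names(sa$actions))
      if (!is.null(cache)) cache[[key]] <- ent
    }
    m <- length(ent$actions) - 1L
    if (deterministic || m == 0L) {
      akey <- ent$can_key
    } else if (stats::runif(1) < alpha) {
      akey <- ent$can_key
      log_q <- log_q + log(alpha)
    } else {
      alt_keys <- setdiff(names(ent$actions), ent$can_key)
      akey <- alt_keys[sample.int(m, 1L)]
      log_q <- log_q + log(1 - alpha) - log(m)
    }
    tr <- ent$actions[[akey]]
    steps[[length(steps) + 1L]] <- list(graph = ent$partial, transition = tr)
    if (tr$tag == "terminate") return(new_route(steps, log_q, alpha,
                                                ent$partial))
    prev <- ent; prev_akey <- akey
    key <- paste0(key, akey, ";")
  }
}

#' Canonical decoding route
#'
#' The deterministic depth-first route: start at the atom of canonical rank
#' 1, append tree edges in ascending canonical-rank order, emit ring-closure
#' connects as soon as the closing atom is the latest one (ascending target
#' rank), terminate when the molecule is complete. Equivalent to
#' \code{\link{sample_route}} with \code{alpha = 1}.
#'
#' @param g a connected, valid \code{molgraph}
#' @return object of class \code{decoding_route}: \code{steps} (list of
#'   (graph, transition) pairs), \code{log_q} (0 here), \code{alpha},
#'   \code{final} (the replayed graph)
#' @export
canonical_route <- function(g) route_walk(g, alpha = 1, deterministic = TRUE)

#' Sample a decoding route from q_alpha
#'
#' At each step the canonical depth-first action is taken with probability
#' \code{alpha}; otherwise one of the alternative actions still consistent
#' with producing \code{g} is drawn uniformly (a "random mistake"). When no
#' alternative exists the canonical action has probability one. \code{log_q}
#' accumulates the exact log-probability of the realized route, so that
#' importance weights p(G, r)/q_alpha(r|G) are computable.
#'
#' @param g a connected, valid \code{molgraph}
#' @param alpha probability of following the canonical action at each step
#' @param cache optional environment memoizing decoding states across
#'   repeated samples of the same molecule
#' @return a \code{decoding_route}
#' @export
sample_route <- function(g, alpha = 0.8, cache = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  route_walk(g, alpha, deterministic = (alpha == 1), cache = cache)
}

#' Replay a decoding route
#'
#' Applies the route's transitions starting from the empty graph.
#'
#' @param route a \code{decoding_route}
#' @return the resulting \code{molgraph}
#' @export
replay_route <- function(route) {
  g <- molgraph()
  for (s in route$steps) {
    if (s$transition$tag == "terminate") break
    g <- apply_transition(g, s$transition)
  }
  g
}

#' Enumerate all decoding routes of a small molecule
#'
#' Exhaustively walks the action tree, yielding every distinct decoding
#' route that produces \code{g}. Used by the exact-likelihood oracle; the
#' route count grows combinatorially, so the molecule size is capped.
#'
#' @param g a connected, valid \code{molgraph}
#' @param max_atoms enumeration size bound
#' @return list of \code{decoding_route} objects (with \code{log_q = NA})
#' @export
enumerate_routes <- function(g, max_atoms = 5L) {
  if (nrow(g$atoms) > max_atoms)
    stop("molecule exceeds the enumeration bound of ", max_atoms, " atoms",
         call. = FALSE)
  ctx <- route_context(g)
  out <- list()
  rec <- function(partial, emb, steps) {
    sa <- state_actions(ctx, emb, partial)
    for (tr in sa$actions) {
      steps2 <- c(steps, list(list(graph = partial, transition = tr)))
      if (tr$tag == "terminate") {
        out[[length(out) + 1L]] <<- new_route(steps2, NA_real_, NA_real_,
                                              partial)
      } else {
        emb2 <- state_advance_emb(ctx, sa$emb, partial, tr)
        rec(apply_transition(partial, tr), emb2, steps2)
      }
    }
  }
  rec(molgraph(), NULL, list())
  out
}

#' Dump a route as JSON lines (debug aid)
#'
#' One step per line: step index, action tag, parameters, and the SMILES of
#' the cumulative structure where it is serializable.
#'
#' @param route a \code{decoding_route}
#' @param path output file
#' @return the path, invisibly
#' @export
route_dump <- function(route, path) {
  con <- file(path, "w")
  on.exit(close(con))
  g <- molgraph()
  for (k in seq_along(route$steps)) {
    tr <- route$steps[[k]]$transition
    if (tr$tag != "terminate") g <- apply_transition(g, tr)
    smi <- tryCatch(smiles_from_graph(g), error = function(e) NA_character_)
    rec <- list(step = k - 1L, action_tag = tr$tag,
                params = tr[setdiff(names(tr), "tag")],
                cumulative_smiles = smi)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}
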