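# Small internal graph helpers operating on a molgraph's bond table.

# adjacency list: for each atom, data.frame(nbr, type, bond_idx)
mg_adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- list(nbr = integer(0), type = integer(0))
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]; t <- g$bonds$type[k]
      adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$type <- c(adj[[i]]$type, t)
      adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$type <- c(adj[[j]]$type, t)
    }
  }
  adj
}

# logical vector over bonds: TRUE if the bond lies on a cycle (non-bridge).
# Classic bridge-finding DFS with discovery/low times, iterative-free since
# molecules are small.
mg_cycle_bonds <- function(n_atoms, bonds) {
  m <- nrow(bonds)
  if (m == 0L) return(logical(0))
  nbrs <- vector("list", n_atoms)
  for (k in seq_len(m)) {
    i <- bonds$i[k]; j <- bonds$j[k]
    nbrs[[i]] <- rbind(nbrs[[i]], c(j, k))
    nbrs[[j]] <- rbind(nbrs[[j]], c(i, k))
  }
  disc <- rep(0L, n_atoms); low <- rep(0L, n_atoms)
  bridge <- rep(FALSE, m)
  timer <- 0L
  dfs <- function(v, parent_edge) {
    timer <<- timer + 1L
    disc[v] <<- timer; low[v] <<- timer
    nb <- nbrs[[v]]
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      u <- nb[r, 1]; e <- nb[r, 2]
      if (e == parent_edge) next
      if (disc[u] == 0L) {
        dfs(u, e)
        low[v] <<- min(low[v], low[u])
        if (low[u] > disc[v]) bridge[e] <<- TRUE
      } else {
        low[v] <<- min(low[v], disc[u])
      }
    }
  }
  for (v in seq_len(n_atoms)) if (disc[v] == 0L) dfs(v, 0L)
  !bridge
}

# connected components over an edge subset; returns component id per atom
# (0 for atoms touching no selected edge)
mg_edge_components <- function(n_atoms, bonds, keep) {
  comp <- rep(0L, n_atoms)
  if (!any(keep)) return(comp)
  nbrs <- vector("list", n_atoms)
  for (k in which(keep)) {
    i <- bonds$i[k]; j <- bonds$j[k]
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
  }
  cid <- 0L
  for (s in seq_len(n_atoms)) {
    if (comp[s] != 0L || is.null(nbrs[[s]])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in nbrs[[v]]) if (comp[u] == 0L) { comp[u] <- cid; queue <- c(queue, u) }
    }
  }
  comp
}

# is the whole molecule connected?
mg_connected <- function(g) {
  n <- nrow(g$atoms)
  if (n <= 1L) return(TRUE)
  adj <- mg_adjacency(g)
  seen <- rep(FALSE, n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]$nbr) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  all(seen)
}

# all-pairs shortest path distances on the bond graph (unit edge weights),
# capped at `max_d`; entries beyond the cap are Inf
mg_distances <- function(g, max_d = Inf) {
  n <- nrow(g$atoms)
  adj <- mg_adjacency(g)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (D[s, v] >= max_d) next
      for (u in adj[[v]]$nbr) {
        if (is.infinite(D[s, u])) { D[s, u] <- D[s, v] + 1; queue <- c(queue, u) }
      }
    }
  }
  D
}
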