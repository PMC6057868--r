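#' Canonical atom ranking
#'
#' Deterministic total order over the atoms of a molecular graph, computed
#' by iterative Morgan-style neighborhood refinement of an initial invariant
#' (symbol, explicit H, charge, degree), with remaining ties broken by atom
#' index. Canonical decoding routes traverse atoms in this order.
#'
#' @param g a \code{molgraph}
#' @return integer vector: rank 1..n per atom (1 = root of canonical DFS)
#' @export
canonical_ranks <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L) return(integer(0))
  adj <- mg_adjacency(g)
  deg <- vapply(adj, function(a) length(a$nbr), integer(1))
  inv <- paste(g$atoms$symbol, g$atoms$nh, g$atoms$charge, deg)
  rank <- match(inv, sort(unique(inv)))
  repeat {
    sig <- vapply(seq_len(n), function(v) {
      nb <- adj[[v]]
      if (length(nb$nbr) == 0L) return(sprintf("%04d|", rank[v]))
      neigh <- sort(paste0(nb$type, ":", sprintf("%04d", rank[nb$nbr])))
      paste0(sprintf("%04d", rank[v]), "|", paste(neigh, collapse = ","))
    }, character(1))
    new_rank <- match(sig, sort(unique(sig)))
    if (identical(new_rank, rank)) break
    rank <- new_rank
  }
  # total order: refined rank, then atom index
  ord <- order(rank, seq_len(n))
  out <- integer(n)
  out[ord] <- seq_len(n)
  out
}
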