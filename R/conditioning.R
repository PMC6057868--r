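# Conditional codes: scaffold sets and scaffold fingerprints, (QED, SA)
# property codes, activity-label codes from trained classifiers, and
# sampling codes from requirement regions.

# induced subgraph on a set of atoms keeping a subset of bonds, with
# hydrogen-count repair: a removed bond is replaced by hydrogens on the
# kept endpoint (the Bemis-Murcko convention), and explicit-H counts are
# re-reduced to the SMILES reader rule.
mg_induced <- function(g, keep_atoms, keep_bond) {
  totalh <- mg_total_h(g)
  idx_map <- match(seq_len(nrow(g$atoms)), keep_atoms)
  lost <- rep(0L, length(keep_atoms))
  bi <- integer(0); bj <- integer(0); bt <- integer(0)
  if (nrow(g$bonds) > 0) for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]; ty <- g$bonds$type[k]
    ki <- idx_map[i]; kj <- idx_map[j]
    if (!is.na(ki) && !is.na(kj) && keep_bond[k]) {
      bi <- c(bi, ki); bj <- c(bj, kj); bt <- c(bt, ty)
    } else {
      o <- .bond_sigma(ty)
      if (!is.na(ki)) lost[ki] <- lost[ki] + o
      if (!is.na(kj)) lost[kj] <- lost[kj] + o
    }
  }
  sym <- g$atoms$symbol[keep_atoms]
  chg <- g$atoms$charge[keep_atoms]
  th <- totalh[keep_atoms] + lost
  bonds <- data.frame(i = bi, j = bj, type = bt)
  sigma <- rep(0L, length(keep_atoms)); has_ar <- rep(FALSE, length(keep_atoms))
  if (nrow(bonds) > 0) for (k in seq_len(nrow(bonds))) {
    s <- .bond_sigma(bonds$type[k])
    sigma[bonds$i[k]] <- sigma[bonds$i[k]] + s
    sigma[bonds$j[k]] <- sigma[bonds$j[k]] + s
    if (bonds$type[k] == 4L) {
      has_ar[bonds$i[k]] <- TRUE; has_ar[bonds$j[k]] <- TRUE
    }
  }
  nh <- th
  for (v in seq_along(keep_atoms)) {
    if (chg[v] != 0L || !(sym[v] %in% .ORGANIC_SUBSET)) next
    imp <- reader_implied_h(sym[v], sigma[v], has_ar[v])
    if (imp == th[v]) nh[v] <- 0L
  }
  molgraph(data.frame(symbol = sym, nh = nh, charge = chg), bonds)
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Removes all side-chain atoms by iteratively deleting terminal
#' (degree-one) atoms; what remains are the ring systems and the linkers
#' between them. Acyclic molecules have no scaffold.
#'
#' @param g a \code{molgraph} (or a SMILES string)
#' @return a \code{molgraph}, or \code{NULL} for acyclic molecules
#' @export
bemis_murcko <- function(g) {
  if (is.character(g)) g <- graph_from_smiles(g)
  keep <- rep(TRUE, nrow(g$atoms))
  bonds <- g$bonds
  repeat {
    deg <- rep(0L, nrow(g$atoms))
    if (nrow(bonds) > 0) for (k in seq_len(nrow(bonds))) {
      deg[bonds$i[k]] <- deg[bonds$i[k]] + 1L
      deg[bonds$j[k]] <- deg[bonds$j[k]] + 1L
    }
    drop <- which(keep & deg <= 1L)
    if (length(drop) == 0L) break
    keep[drop] <- FALSE
    if (nrow(bonds) > 0)
      bonds <- bonds[!(bonds$i %in% drop | bonds$j %in% drop), , drop = FALSE]
    if (!any(keep)) return(NULL)
  }
  keep_atoms <- which(keep)
  keep_bond <- rep(FALSE, nrow(g$bonds))
  if (nrow(g$bonds) > 0) {
    bk <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    gk <- paste(pmin(g$bonds$i, g$bonds$j), pmax(g$bonds$i, g$bonds$j))
    keep_bond <- gk %in% bk
  }
  mg_induced(g, keep_atoms, keep_bond)
}

#' Ring assemblies of a molecule
#'
#' A ring assembly is a connected component of the subgraph formed by ring
#' bonds (bonds lying on a cycle); fused systems stay together, linkers are
#' excluded.
#'
#' @param g a \code{molgraph} (or a SMILES string)
#' @return list of \code{molgraph}s (possibly empty)
#' @export
ring_assemblies <- function(g) {
  if (is.character(g)) g <- graph_from_smiles(g)
  if (nrow(g$bonds) == 0L) return(list())
  cyc <- mg_cycle_bonds(nrow(g$atoms), g$bonds)
  if (!any(cyc)) return(list())
  comp <- mg_edge_components(nrow(g$atoms), g$bonds, cyc)
  out <- list()
  for (cid in setdiff(unique(comp), 0L)) {
    atoms <- which(comp == cid)
    keep_bond <- cyc & comp[g$bonds$i] == cid & comp[g$bonds$j] == cid
    out[[length(out) + 1L]] <- mg_induced(g, atoms, keep_bond)
  }
  out
}

#' Extract a scaffold set from a corpus
#'
#' Collects the Bemis-Murcko scaffold and all ring assemblies of every
#' molecule, deduplicated by canonical SMILES and sorted. Acyclic molecules
#' contribute nothing.
#'
#' @param corpus character vector of SMILES
#' @return object of class \code{scaffold_set}: data.frame with columns
#'   \code{smiles} and \code{source} (\code{bemis_murcko} or
#'   \code{ring_assembly})
#' @export
extract_scaffold_set <- function(corpus) {
  rows <- list()
  for (smi in corpus) {
    g <- graph_from_smiles(smi)
    bm <- bemis_murcko(g)
    if (!is.null(bm))
      rows[[length(rows) + 1L]] <-
        data.frame(smiles = smiles_from_graph(bm), source = "bemis_murcko")
    for (ra in ring_assemblies(g))
      rows[[length(rows) + 1L]] <-
        data.frame(smiles = smiles_from_graph(ra), source = "ring_assembly")
  }
  if (length(rows) == 0L)
    return(structure(data.frame(smiles = character(0), source = character(0)),
                     class = c("scaffold_set", "data.frame")))
  df <- do.call(rbind, rows)
  # prefer the Bemis-Murcko tag when a structure arises both ways
  df <- df[order(df$smiles, df$source), , drop = FALSE]
  df <- df[!duplicated(df$smiles), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("scaffold_set", "data.frame"))
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("<scaffold_set: %d structures (%d Bemis-Murcko, %d ring assemblies)>\n",
              nrow(x), sum(x$source == "bemis_murcko"),
              sum(x$source == "ring_assembly")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Scaffold fingerprint of a molecule
#'
#' Binary substructure-membership vector over a scaffold set: bit i is 1
#' when scaffold i occurs as a substructure of the molecule.
#'
#' @param g a valid \code{molgraph} or a SMILES string
#' @param scaffolds a \code{\link{extract_scaffold_set}} result (or a
#'   character vector of scaffold SMILES)
#' @return numeric 0/1 vector of length \code{nrow(scaffolds)}
#' @export
scaffold_fingerprint <- function(g, scaffolds) {
  smi <- if (is.character(g)) canonical_smiles(g) else smiles_from_graph(g)
  if (is.na(smi)) stop("invalid molecule", call. = FALSE)
  pats <- if (is.data.frame(scaffolds)) scaffolds$smiles else scaffolds
  vapply(pats, function(p) as.numeric(ob_smarts_count(smi, p) > 0),
         numeric(1), USE.NAMES = FALSE)
}

#' Drug-likeness / synthetic-accessibility property code
#'
#' The two-component conditional code c = (QED, SA): quantitative estimate
#' of drug-likeness (0-1, higher = more drug-like) and the
#' synthetic-accessibility score (1-10, higher = harder to synthesize),
#' both computed with RDKit's reference implementations through the
#' bundled Python bridge.
#'
#' @param g a valid \code{molgraph}, or a character vector of SMILES
#' @return matrix with columns \code{qed} and \code{sa}
#' @export
property_code <- function(g) {
  smi <- if (inherits(g, "molgraph")) smiles_from_graph(g) else g
  sc <- rdkit_scores(smi)
  if (anyNA(sc$qed)) stop("invalid molecule in property_code", call. = FALSE)
  as.matrix(sc[, c("qed", "sa")])
}

#' Train an activity classifier on fingerprints
#'
#' Random-forest classifier on circular (ECFP6-style, radius 3) fingerprints
#' folded to \code{bits} positions; the conditional code for activity tasks
#' thresholds its predicted probability at 0.5. Class imbalance is handled
#' by class weighting.
#'
#' @param smiles training molecules
#' @param active logical (or 0/1) activity labels
#' @param bits fingerprint length
#' @param ntree forest size
#' @return object of class \code{activity_classifier}
#' @export
fit_activity_classifier <- function(smiles, active, bits = 2048L,
                                    ntree = 200L) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("the randomForest package is required", call. = FALSE)
  active <- as.logical(active)
  stopifnot(length(smiles) == length(active), length(unique(active)) == 2L)
  X <- t(vapply(smiles, function(s) as.numeric(ob_ecfp(s, bits)),
                numeric(bits)))
  y <- factor(ifelse(active, "active", "inactive"),
              levels = c("inactive", "active"))
  w <- c(inactive = sum(active), active = sum(!active)) / length(active)
  fit <- randomForest::randomForest(X, y, ntree = ntree, classwt = w)
  structure(list(fit = fit, bits = bits), class = "activity_classifier")
}

#' @export
predict.activity_classifier <- function(object, smiles, threshold = 0.5, ...) {
  X <- t(vapply(smiles, function(s) as.numeric(ob_ecfp(s, object$bits)),
                numeric(object$bits)))
  p <- stats::predict(object$fit, X, type = "prob")[, "active"]
  as.numeric(p >= threshold)
}

#' Activity conditional code
#'
#' Two-bit code (activity against target A, activity against target B) from
#' a pair of trained classifiers.
#'
#' @param smiles molecules to label
#' @param clf_a,clf_b \code{\link{fit_activity_classifier}} objects
#' @return matrix with one 0/1 row per molecule
#' @export
activity_code <- function(smiles, clf_a, clf_b) {
  cbind(a = predict(clf_a, smiles), b = predict(clf_b, smiles))
}

#' Requirement regions in code space
#'
#' Per-dimension interval constraints C used to express generation
#' requirements such as "QED above 0.84 and SA below 1.9".
#'
#' @param lo,hi numeric bounds per dimension
#' @param closed_lo,closed_hi logical, whether each bound is inclusive
#' @return object of class \code{code_region}
#' @export
code_region <- function(lo, hi, closed_lo = TRUE, closed_hi = TRUE) {
  stopifnot(length(lo) == length(hi), all(lo <= hi))
  closed_lo <- rep_len(closed_lo, length(lo))
  closed_hi <- rep_len(closed_hi, length(hi))
  structure(list(lo = lo, hi = hi, closed_lo = closed_lo,
                 closed_hi = closed_hi), class = "code_region")
}

#' @rdname code_region
#' @param codes numeric matrix of codes (rows = observations)
#' @param region a \code{code_region}
#' @return logical vector
#' @export
in_region <- function(codes, region) {
  codes <- as.matrix(codes)
  stopifnot(ncol(codes) == length(region$lo))
  ok <- rep(TRUE, nrow(codes))
  for (d in seq_along(region$lo)) {
    lo_ok <- if (region$closed_lo[d]) codes[, d] >= region$lo[d]
             else codes[, d] > region$lo[d]
    hi_ok <- if (region$closed_hi[d]) codes[, d] <= region$hi[d]
             else codes[, d] < region$hi[d]
    ok <- ok & lo_ok & hi_ok
  }
  ok
}

#' Sample conditional codes from a requirement region
#'
#' Draws codes from the empirical distribution p(c | c in C): uniform draws
#' from the subset of observed codes that satisfy the region.
#'
#' @param empirical_codes numeric matrix of observed codes
#' @param region a \code{\link{code_region}}
#' @param n number of draws
#' @return matrix of \code{n} sampled codes
#' @export
sample_code <- function(empirical_codes, region, n = 1L) {
  empirical_codes <- as.matrix(empirical_codes)
  ok <- which(in_region(empirical_codes, region))
  if (length(ok) == 0L)
    stop("no empirical code satisfies the region; widen the requirement C",
         call. = FALSE)
  empirical_codes[ok[sample.int(length(ok), n, replace = TRUE)], ,
                  drop = FALSE]
}
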