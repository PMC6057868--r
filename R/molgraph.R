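#' Molecular graphs
#'
#' A \code{molgraph} is the package's labeled-graph representation of a
#' molecule: nodes carry atom types, edges carry bond types, and the graph
#' optionally marks the latest appended atom \code{v*} used by the decoding
#' scheme. An atom type is the triple (element symbol, number of explicit
#' hydrogens, formal charge); a bond type is one of single, double, triple,
#' aromatic (see \code{\link{bond_types}}).
#'
#' @param atoms data.frame with columns \code{symbol} (character),
#'   \code{nh} (integer explicit-hydrogen count) and \code{charge} (integer).
#' @param bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{type} (integer bond code).
#' @param latest index of the latest appended atom, or \code{NA}.
#' @return Object of class \code{molgraph}.
#' @export
molgraph <- function(atoms = data.frame(symbol = character(0),
                                        nh = integer(0),
                                        charge = integer(0)),
                     bonds = data.frame(i = integer(0), j = integer(0),
                                        type = integer(0)),
                     latest = NA_integer_) {
  atoms$symbol <- as.character(atoms$symbol)
  atoms$nh <- as.integer(atoms$nh)
  atoms$charge <- as.integer(atoms$charge)
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  bonds$type <- as.integer(bonds$type)
  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    if (any(bonds$i == bonds$j)) stop("self-loop bond", call. = FALSE)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond index out of range", call. = FALSE)
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond", call. = FALSE)
    if (!all(bonds$type %in% 1:4)) stop("unknown bond type", call. = FALSE)
  }
  if (n > 0 && is.na(latest)) latest <- NA_integer_
  if (!is.na(latest) && (latest < 1L || latest > n))
    stop("latest atom index out of range", call. = FALSE)
  structure(list(atoms = atoms, bonds = bonds, latest = as.integer(latest)),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d atoms, %d bonds%s>\n", nrow(x$atoms),
              nrow(x$bonds),
              if (!is.na(x$latest)) sprintf(", v*=%d", x$latest) else ""))
  invisible(x)
}

#' Number of atoms / bonds
#' @param g a molgraph
#' @return integer count
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(g) nrow(g$bonds)

# total hydrogen count per atom under the package's SMILES conventions:
# atoms with explicit hydrogens or a formal charge are "bracket" atoms and
# carry exactly nh hydrogens; all others receive the reader-implied fill.
mg_total_h <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L) return(integer(0))
  sigma <- rep(0L, n); has_ar <- rep(FALSE, n)
  if (nrow(g$bonds) > 0) for (k in seq_len(nrow(g$bonds))) {
    b <- g$bonds[k, ]
    s <- .bond_sigma(b$type)
    sigma[b$i] <- sigma[b$i] + s; sigma[b$j] <- sigma[b$j] + s
    if (b$type == 4L) { has_ar[b$i] <- TRUE; has_ar[b$j] <- TRUE }
  }
  out <- integer(n)
  for (v in seq_len(n)) {
    a <- g$atoms[v, ]
    if (a$nh > 0L || a$charge != 0L || !(a$symbol %in% .ORGANIC_SUBSET)) {
      out[v] <- a$nh
    } else {
      out[v] <- reader_implied_h(a$symbol, sigma[v], has_ar[v])
    }
  }
  out
}

#' Chemical validity of a molecular graph
#'
#' Total function reporting whether a graph passes the package's
#' sanitization model: a per-atom valence check against an allowed-valence
#' table, and an aromaticity check requiring every aromatic bond to lie in a
#' ring and every aromatic system to admit a Kekule assignment (a perfect
#' matching over the atoms that must carry a ring double bond).
#'
#' @param g a \code{molgraph}
#' @return Logical scalar; attribute \code{failure_class} is one of
#'   \code{"valence"}, \code{"aromaticity"}, \code{"other"} when invalid.
#' @export
is_valid <- function(g) {
  cls <- validity_class(g)
  structure(is.na(cls), failure_class = cls)
}

# NA = valid; otherwise the failure class
validity_class <- function(g) {
  if (!inherits(g, "molgraph")) return("other")
  n <- nrow(g$atoms)
  if (n == 0L) return("other")
  totalh <- mg_total_h(g)
  sigma1 <- rep(0L, n)
  m <- nrow(g$bonds)
  if (m > 0) for (k in seq_len(m)) {
    b <- g$bonds[k, ]
    s <- .bond_sigma(b$type)
    sigma1[b$i] <- sigma1[b$i] + s; sigma1[b$j] <- sigma1[b$j] + s
  }
  # valence check (sigma framework + hydrogens must not exceed max valence)
  for (v in seq_len(n)) {
    av <- allowed_valences(g$atoms$symbol[v], g$atoms$charge[v])
    if (is.null(av) || length(av) == 0L) next
    load <- sigma1[v] + totalh[v]
    if (load > max(av)) return("valence")
    # aromatic atoms additionally need room for (or exemption from) the
    # pi bond, settled below by the Kekule assignment
  }
  if (any(g$bonds$type == 4L)) {
    arom <- g$bonds$type == 4L
    # every aromatic bond must lie on a cycle made of aromatic bonds
    ar_bonds <- g$bonds[arom, , drop = FALSE]
    in_cycle <- mg_cycle_bonds(n, ar_bonds)
    if (!all(in_cycle)) return("aromaticity")
    # partition aromatic systems
    comp <- mg_edge_components(n, g$bonds, arom)
    for (cid in setdiff(unique(comp), 0L)) {
      members <- which(comp == cid)
      must <- logical(n)
      for (v in members) {
        av <- allowed_valences(g$atoms$symbol[v], g$atoms$charge[v])
        load <- sigma1[v] + totalh[v]
        if (is.null(av) || length(av) == 0L) { must[v] <- TRUE; next }
        av2 <- av[av >= load]
        slack <- if (length(av2) == 0L) 0L else min(av2) - load
        must[v] <- slack >= 1L
      }
      # Kekule assignment: perfect matching over the atoms that must carry
      # a ring double bond, restricted to aromatic bonds (sanitizer rule:
      # an aromatic system is acceptable iff it kekulizes)
      if (!kekule_matching(members[must[members]], ar_bonds)) {
        return("aromaticity")
      }
    }
  }
  NA_character_
}

# backtracking perfect matching of `verts` within aromatic bonds
kekule_matching <- function(verts, ar_bonds) {
  if (length(verts) == 0L) return(TRUE)
  if (length(verts) %% 2L == 1L) return(FALSE)
  vset <- verts
  nbr <- lapply(vset, function(v) {
    u <- c(ar_bonds$j[ar_bonds$i == v], ar_bonds$i[ar_bonds$j == v])
    intersect(u, vset)
  })
  names(nbr) <- as.character(vset)
  matched <- setNames(rep(FALSE, length(vset)), as.character(vset))
  rec <- function() {
    un <- names(matched)[!matched]
    if (length(un) == 0L) return(TRUE)
    v <- un[1]
    for (u in nbr[[v]]) {
      cu <- as.character(u)
      if (!matched[[cu]]) {
        matched[[v]] <<- TRUE; matched[[cu]] <<- TRUE
        if (rec()) return(TRUE)
        matched[[v]] <<- FALSE; matched[[cu]] <<- FALSE
      }
    }
    FALSE
  }
  rec()
}

mol_error <- function(msg, class) {
  stop(structure(class = c(class, "molgraphgen_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Parse a SMILES string into a molecular graph
#'
#' Uses Open Babel's perception of the molecule: aromatic bonds are stored
#' as the aromatic type (not kekulized), hydrogen counts are reduced to the
#' explicit count of the atom-type triple, and formal charges are kept.
#'
#' @param smiles a single SMILES string
#' @return a \code{molgraph} with \code{latest} unset
#' @export
graph_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch(ob_convert("SMI", "SDF", smiles, add_h = TRUE),
                  error = function(e) mol_error(
                    paste0("cannot parse SMILES '", smiles, "': ",
                           conditionMessage(e)), "molgraphgen_parse_error"))
  mol2 <- tryCatch(ob_convert("SMI", "MOL2", smiles, add_h = TRUE),
                   error = function(e) mol_error(
                     paste0("cannot parse SMILES '", smiles, "': ",
                            conditionMessage(e)), "molgraphgen_parse_error"))
  s <- parse_sdf_block(sdf)
  m2 <- parse_mol2(mol2)
  if (length(s$elements) != length(m2$elements) ||
      !all(s$elements == m2$elements))
    mol_error("inconsistent Open Babel output (SDF vs MOL2 atom order)",
              "molgraphgen_parse_error")
  g <- assemble_graph(s, m2)
  cls <- validity_class(g)
  if (!is.na(cls))
    mol_error(paste0("SMILES '", smiles, "' fails sanitization (", cls, ")"),
              "molgraphgen_validity_error")
  g
}

# build a heavy-atom molgraph from the parallel SDF + MOL2 reads
assemble_graph <- function(s, m2) {
  el <- s$elements
  heavy <- which(el != "H")
  idx_map <- match(seq_along(el), heavy)   # full index -> heavy index
  # hydrogen counts
  nh_total <- rep(0L, length(heavy))
  for (k in seq_len(nrow(s$bonds))) {
    i <- s$bonds$i[k]; j <- s$bonds$j[k]
    if (el[i] == "H" && el[j] != "H") nh_total[idx_map[j]] <- nh_total[idx_map[j]] + 1L
    if (el[j] == "H" && el[i] != "H") nh_total[idx_map[i]] <- nh_total[idx_map[i]] + 1L
  }
  charge <- s$charge[heavy]
  # heavy-heavy bonds; aromatic flag from MOL2, order from SDF
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ar_keys <- character(0)
  if (nrow(m2$bonds) > 0) {
    ar <- m2$bonds$type_raw == "ar"
    ar_keys <- key(m2$bonds$i[ar], m2$bonds$j[ar])
  }
  bi <- integer(0); bj <- integer(0); bt <- integer(0)
  for (k in seq_len(nrow(s$bonds))) {
    i <- s$bonds$i[k]; j <- s$bonds$j[k]
    if (el[i] == "H" || el[j] == "H") next
    type <- s$bonds$order[k]
    if (type == 4L) type <- 1L  # should not occur; guard
    if (key(i, j) %in% ar_keys) type <- 4L
    bi <- c(bi, idx_map[i]); bj <- c(bj, idx_map[j]); bt <- c(bt, type)
  }
  # OB flags delocalized acyclic groups (carboxylate) "ar" in MOL2; only
  # ring bonds may be aromatic, so demote acyclic "ar" to the SDF order
  bonds <- data.frame(i = bi, j = bj, type = bt)
  if (any(bonds$type == 4L)) {
    cyc <- mg_cycle_bonds(length(heavy), bonds)
    for (k in which(bonds$type == 4L & !cyc)) {
      ksdf <- which(key(heavy[bonds$i[k]], heavy[bonds$j[k]]) ==
                      key(s$bonds$i, s$bonds$j))
      bonds$type[k] <- s$bonds$order[ksdf[1]]
    }
  }
  # explicit-H reduction: drop hydrogens a SMILES reader would re-infer
  g0 <- molgraph(data.frame(symbol = el[heavy], nh = nh_total, charge = charge),
                 bonds)
  sigma <- rep(0L, length(heavy)); has_ar <- rep(FALSE, length(heavy))
  if (nrow(bonds) > 0) for (k in seq_len(nrow(bonds))) {
    sgm <- .bond_sigma(bonds$type[k])
    sigma[bonds$i[k]] <- sigma[bonds$i[k]] + sgm
    sigma[bonds$j[k]] <- sigma[bonds$j[k]] + sgm
    if (bonds$type[k] == 4L) {
      has_ar[bonds$i[k]] <- TRUE; has_ar[bonds$j[k]] <- TRUE
    }
  }
  nh <- nh_total
  for (v in seq_along(heavy)) {
    if (charge[v] != 0L) next                    # bracket atom: all H explicit
    if (!(el[heavy[v]] %in% .ORGANIC_SUBSET)) next
    imp <- reader_implied_h(el[heavy[v]], sigma[v], has_ar[v])
    if (imp == nh_total[v]) nh[v] <- 0L
  }
  molgraph(data.frame(symbol = el[heavy], nh = nh, charge = charge), bonds)
}

#' Canonical SMILES of a molecular graph
#'
#' Validates the graph first (see \code{\link{is_valid}}); on failure a
#' condition of class \code{molgraphgen_validity_error} is signalled whose
#' \code{failure_class} field distinguishes valence violations from broken
#' aromaticity. Valid graphs are serialized through Open Babel and returned
#' as canonical SMILES.
#'
#' @param g a \code{molgraph}
#' @return canonical SMILES string
#' @export
smiles_from_graph <- function(g) {
  if (!inherits(g, "molgraph")) stop("not a molgraph", call. = FALSE)
  if (nrow(g$atoms) == 0L)
    mol_error("empty graph has no SMILES", "molgraphgen_validity_error")
  cls <- validity_class(g)
  if (!is.na(cls)) {
    cond <- structure(
      class = c("molgraphgen_validity_error", "molgraphgen_error",
                "error", "condition"),
      list(message = paste0("invalid molecule (", cls, ")"), call = NULL))
    cond$failure_class <- cls
    stop(cond)
  }
  mb <- molgraph_to_molblock(g)
  out <- tryCatch(ob_convert("MOL", "CAN", mb),
                  error = function(e) mol_error(
                    paste0("serialization failed: ", conditionMessage(e)),
                    "molgraphgen_validity_error"))
  strsplit(trimws(out), "[ \t\n]")[[1]][1]
}

#' Canonicalize a SMILES string
#' @param smiles character vector of SMILES
#' @return character vector of canonical SMILES (NA where unparseable)
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    tryCatch(ob_canonical_smiles(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}
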