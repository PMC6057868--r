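# Bundled desk-scale inputs: a fixed list of drug-like molecules and a
# seeded generator of random valence-respecting molecular graphs, so the
# whole package is exercisable with no external data.

#' Bundled molecule corpus
#'
#' A fixed list of about thirty well-known drug-like molecules (including
#' cimetidine and candesartan) covering aromatic rings, fused systems,
#' charged atoms and explicit-hydrogen heteroatoms.
#'
#' @return named character vector of SMILES
#' @export
bundled_corpus <- function() {
  c(
    cimetidine    = "CC1=C(N=CN1)CSCCNC(=NC)NC#N",
    candesartan   = "CCOC1=NC2=CC=CC(=C2N1CC3=CC=C(C=C3)C4=CC=CC=C4C5=NNN=N5)C(=O)O",
    aspirin       = "CC(=O)Oc1ccccc1C(=O)O",
    paracetamol   = "CC(=O)Nc1ccc(O)cc1",
    caffeine      = "CN1C=NC2=C1C(=O)N(C(=O)N2C)C",
    ibuprofen     = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    nicotine      = "CN1CCCC1c1cccnc1",
    metronidazole = "Cc1ncc([N+](=O)[O-])n1CCO",
    choline       = "C[N+](C)(C)CCO",
    tryptamine    = "NCCc1c[nH]c2ccccc12",
    benzamide     = "NC(=O)c1ccccc1",
    phenol        = "Oc1ccccc1",
    pyridine      = "c1ccncc1",
    imidazole     = "c1cnc[nH]1",
    furan         = "c1ccoc1",
    thiophene     = "c1ccsc1",
    toluene       = "Cc1ccccc1",
    ethanolamine  = "NCCO",
    glycine       = "NCC(=O)O",
    alanine       = "CC(N)C(=O)O",
    urea          = "NC(=O)N",
    acetamide     = "CC(=O)N",
    dimethylamine = "CNC",
    isopropanol   = "CC(C)O",
    acetonitrile  = "CC#N",
    fluorobenzene = "Fc1ccccc1",
    chloroethane  = "CCCl",
    pyrimidine    = "c1cncnc1",
    piperidine    = "C1CCNCC1",
    morpholine    = "C1COCCN1"
  )
}

#' Specification for random molecule generation
#'
#' @param n_molecules number of molecules
#' @param max_atoms heavy-atom cap per molecule (>= 1)
#' @param elements named numeric vector of element sampling weights
#' @param ring_prob probability of attempting one ring closure
#' @param seed optional integer seed
#' @return list of class \code{fixture_spec}
#' @export
fixture_spec <- function(n_molecules = 20L, max_atoms = 20L,
                         elements = c(C = 0.6, N = 0.16, O = 0.16,
                                      S = 0.04, F = 0.02, Cl = 0.02),
                         ring_prob = 0.3, seed = NULL) {
  stopifnot(n_molecules >= 1L, max_atoms >= 1L, all(elements > 0),
            ring_prob >= 0, ring_prob <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 max_atoms = as.integer(max_atoms), elements = elements,
                 ring_prob = ring_prob, seed = seed),
            class = "fixture_spec")
}

max_valence <- function(symbol) max(allowed_valences(symbol, 0L))

random_molgraph <- function(spec) {
  m <- if (spec$max_atoms == 1L) 1L else sample(2:spec$max_atoms, 1L)
  elems <- names(spec$elements)
  wts <- as.numeric(spec$elements)
  sym <- sample(elems, 1L, prob = wts)
  atoms <- data.frame(symbol = sym, nh = 0L, charge = 0L)
  bonds <- data.frame(i = integer(0), j = integer(0), type = integer(0))
  used <- 0L
  while (nrow(atoms) < m) {
    free <- vapply(seq_len(nrow(atoms)), function(v)
      max_valence(atoms$symbol[v]) -
        sum(.bond_sigma(bonds$type[bonds$i == v | bonds$j == v])), integer(1))
    anchors <- which(free >= 1L)
    if (length(anchors) == 0L) break
    anchor <- anchors[sample.int(length(anchors), 1L)]
    sym_new <- sample(elems, 1L, prob = wts)
    max_order <- min(free[anchor], max_valence(sym_new), 3L)
    order <- sample.int(max_order, 1L,
                        prob = c(0.85, 0.12, 0.03)[seq_len(max_order)])
    atoms <- rbind(atoms, data.frame(symbol = sym_new, nh = 0L, charge = 0L))
    bonds <- rbind(bonds, data.frame(i = anchor, j = nrow(atoms),
                                     type = order))
  }
  g <- molgraph(atoms, bonds)
  if (stats::runif(1) < spec$ring_prob && nrow(atoms) >= 3L) {
    free <- vapply(seq_len(nrow(atoms)), function(v)
      max_valence(atoms$symbol[v]) -
        sum(.bond_sigma(bonds$type[bonds$i == v | bonds$j == v])), integer(1))
    dist <- mg_distances(g)
    cand <- which(outer(free >= 1L, free >= 1L, "&") & dist >= 2 &
                    upper.tri(dist), arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      pick <- cand[sample.int(nrow(cand), 1L), ]
      bonds <- rbind(bonds, data.frame(i = pick[1], j = pick[2], type = 1L))
      g <- molgraph(atoms, bonds)
    }
  }
  g
}

#' Generate random valid molecules
#'
#' Grows random bond trees with valence-respecting bond orders plus
#' occasional single-bond ring closures; drafts that fail sanitization are
#' rejected and redrawn. Deterministic under the spec's seed.
#'
#' @param spec a \code{\link{fixture_spec}}
#' @return character vector of SMILES
#' @export
random_molecules <- function(spec = fixture_spec()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  out <- character(spec$n_molecules)
  for (k in seq_len(spec$n_molecules)) {
    smi <- NA_character_
    for (try in 1:25) {
      g <- random_molgraph(spec)
      if (!is_valid(g)) next
      smi <- tryCatch(smiles_from_graph(g), error = function(e) NA_character_)
      if (!is.na(smi)) break
    }
    if (is.na(smi)) stop("random molecule generation failed after 25 tries",
                         call. = FALSE)
    out[k] <- smi
  }
  out
}

# attach a benzene ring to a random atom with free valence (used to build
# two-class conditional corpora with a clear substructure signal)
attach_phenyl <- function(g) {
  n <- nrow(g$atoms)
  free <- vapply(seq_len(n), function(v)
    max_valence(g$atoms$symbol[v]) -
      sum(.bond_sigma(g$bonds$type[g$bonds$i == v | g$bonds$j == v])) -
      g$atoms$nh[v], integer(1))
  anchors <- which(free >= 1L)
  if (length(anchors) == 0L) return(NULL)
  anchor <- anchors[sample.int(length(anchors), 1L)]
  atoms <- rbind(g$atoms, data.frame(symbol = rep("C", 6), nh = 0L,
                                     charge = 0L))
  ring <- data.frame(i = n + c(1:5, 6), j = n + c(2:6, 1), type = 4L)
  link <- data.frame(i = anchor, j = n + 1L, type = 1L)
  molgraph(atoms, rbind(g$bonds, ring, link))
}

#' Synthetic conditional corpus
#'
#' Generates random molecules, attaches a benzene ring to roughly half of
#' them, and labels each molecule with \code{rule}. The default rule is the
#' one-bit "contains benzene" code, giving a two-class corpus with a clear
#' structural signal for conditional-generation tests.
#'
#' @param spec a \code{\link{fixture_spec}}
#' @param rule function(character SMILES vector) -> numeric code matrix;
#'   default is the benzene-substructure bit
#' @return list with \code{smiles}, \code{codes} (matrix) and
#'   \code{balance} (per-class counts of the first code column)
#' @export
synthetic_conditional_corpus <- function(spec = fixture_spec(),
                                         rule = NULL) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  spec2 <- spec; spec2$seed <- NULL
  smiles <- character(spec$n_molecules)
  for (k in seq_len(spec$n_molecules)) {
    smi <- NA_character_
    for (try in 1:25) {
      g <- random_molgraph(spec2)
      if (stats::runif(1) < 0.5) {
        g2 <- attach_phenyl(g)
        if (!is.null(g2)) g <- g2
      }
      if (!is_valid(g)) next
      smi <- tryCatch(smiles_from_graph(g), error = function(e) NA_character_)
      if (!is.na(smi)) break
    }
    if (is.na(smi)) stop("conditional corpus generation failed", call. = FALSE)
    smiles[k] <- smi
  }
  if (is.null(rule)) rule <- rule_substructure("c1ccccc1")
  codes <- rule(smiles)
  codes <- as.matrix(codes)
  list(smiles = smiles, codes = codes,
       balance = table(codes[, 1]))
}

#' Labeling rules for synthetic conditional corpora
#'
#' \code{rule_substructure} labels each molecule with a 0/1 bit for the
#' presence of a SMARTS pattern; \code{rule_qed_sa} labels with the
#' (QED, SA) property code.
#'
#' @param smarts SMARTS pattern
#' @return function(character) -> numeric matrix
#' @export
rule_substructure <- function(smarts) {
  force(smarts)
  function(smiles)
    matrix(vapply(smiles, function(s) as.numeric(ob_smarts_count(s, smarts) > 0),
                  numeric(1), USE.NAMES = FALSE), ncol = 1)
}

#' @rdname rule_substructure
#' @export
rule_qed_sa <- function() function(smiles) property_code(smiles)
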