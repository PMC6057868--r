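# Bond type codes used throughout: 1 single, 2 double, 3 triple, 4 aromatic.

#' Bond types
#'
#' The four bond types of the molecular-graph model, with their stable
#' integer encoding: single (1), double (2), triple (3), aromatic (4).
#'
#' @return Named integer vector of length 4.
#' @export
bond_types <- function() {
  c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
}

# sigma-framework contribution of a bond type (aromatic counts 1)
.bond_sigma <- function(type) ifelse(type == 4L, 1L, as.integer(type))

# Elements written without brackets in SMILES when uncharged with default H
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.KNOWN_ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Zn", "Ga", "Ge", "As", "Se",
  "Br", "Kr", "Sn", "Sb", "Te", "I", "Xe"
)

# Allowed total valences (bond order sum + hydrogens) for a neutral atom.
.BASE_VALENCES <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
  As = c(3L, 5L), Se = c(2L, 4L, 6L), Br = 1L, I = 1L
)

# Allowed valences adjusted for formal charge. Unknown combinations return
# NULL, which the validity checker treats as "no constraint".
allowed_valences <- function(symbol, charge = 0L) {
  base <- .BASE_VALENCES[[symbol]]
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  switch(symbol,
    C = 4L - abs(charge),
    B = if (charge < 0L) 4L else max(0L, 3L - charge),
    N = base + charge,
    O = base + charge,
    P = if (charge > 0L) 4L else c(3L, 5L) + charge,
    S = if (charge > 0L) c(3L, 5L) else pmax(0L, c(2L, 4L, 6L) + charge),
    Se = if (charge > 0L) c(3L, 5L) else pmax(0L, c(2L, 4L, 6L) + charge),
    {
      v <- base + charge
      v[v >= 0L]
    }
  )
}

# Hydrogens a SMILES reader would infer for a bracket-free aliphatic atom
# with integer bond-order sum `sigma`. Bracket atoms get none.
implied_hydrogens <- function(symbol, sigma) {
  av <- allowed_valences(symbol, 0L)
  if (is.null(av)) return(0L)
  av <- av[av >= sigma]
  if (length(av) == 0L) return(0L)
  as.integer(min(av) - sigma)
}

# Aromatic bracket-free atoms: lone-pair donors (sigma already meets the
# lowest normal valence, e.g. aromatic o/s, three-coordinate n) get no
# hydrogens; otherwise the ring pi bond claims one valence unit and the
# reader fills the rest (benzene c -> 1 H, pyridine n -> 0 H).
aromatic_implied_h <- function(symbol, sigma1) {
  av <- allowed_valences(symbol, 0L)
  if (is.null(av) || length(av) == 0L) return(0L)
  if (min(av) <= sigma1) return(0L)
  implied_hydrogens(symbol, sigma1 + 1L)
}

# dispatcher used by the graph code
reader_implied_h <- function(symbol, sigma1, aromatic) {
  if (aromatic) aromatic_implied_h(symbol, sigma1)
  else implied_hydrogens(symbol, sigma1)
}
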