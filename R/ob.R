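# Bridge to Open Babel (via ChemmineOB) for SMILES I/O, canonicalization,
# substructure search, descriptors and fingerprints. Aromatic bond flags are
# only available through the TRIPOS MOL2 output format, which no installed
# package reads, so a minimal reader for its ATOM/BOND blocks lives here.

ob_convert <- function(from, to, source, add_h = FALSE) {
  # "i": ignore stereochemistry on SMILES output (out of scope here, and
  # avoids Open Babel's no-coordinates warning on generated mol blocks)
  nms <- c(if (add_h) "h", if (to %in% c("CAN", "SMI")) "i")
  out <- tryCatch(
    suppressWarnings(if (length(nms)) {
      ChemmineOB::convertFormat(from, to, source,
                                options = data.frame(names = nms, args = ""))
    } else {
      ChemmineOB::convertFormat(from, to, source)
    }),
    error = function(e) stop("Open Babel conversion failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!nzchar(trimws(out)))
    stop("Open Babel produced no output for input: ", substr(source, 1, 60),
         call. = FALSE)
  out
}

# Canonical SMILES of a SMILES string (errors on unparseable input)
ob_canonical_smiles <- function(smiles) {
  out <- ob_convert("SMI", "CAN", smiles)
  strsplit(trimws(out), "[ \t\n]")[[1]][1]
}

# --- MOL2 reading ----------------------------------------------------------

# returns list(atoms = data.frame(element), bonds = data.frame(i, j, type_raw))
parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  b0 <- which(lines == "@<TRIPOS>BOND")
  if (length(a0) != 1L || length(b0) != 1L)
    stop("malformed MOL2 block", call. = FALSE)
  sect_end <- function(start) {
    k <- start
    while (k <= length(lines) && !startsWith(lines[k], "@<TRIPOS>")) k <- k + 1L
    k - 1L
  }
  atom_lines <- lines[(a0 + 1L):sect_end(a0 + 1L)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  el <- vapply(strsplit(trimws(atom_lines), "[ \t]+"), function(f) {
    # column 6 is the SYBYL type "C.ar" etc.; element is the part before "."
    strsplit(f[6], ".", fixed = TRUE)[[1]][1]
  }, character(1))
  bonds <- data.frame(i = integer(0), j = integer(0), type_raw = character(0))
  if (b0 + 1L <= length(lines)) {
    bl <- lines[(b0 + 1L):sect_end(b0 + 1L)]
    bl <- bl[nzchar(trimws(bl))]
    if (length(bl)) {
      f <- strsplit(trimws(bl), "[ \t]+")
      bonds <- data.frame(
        i = vapply(f, function(x) as.integer(x[2]), integer(1)),
        j = vapply(f, function(x) as.integer(x[3]), integer(1)),
        type_raw = vapply(f, function(x) x[4], character(1))
      )
    }
  }
  list(elements = el, bonds = bonds)
}

# --- SDF reading (atom elements, formal charges, integer bond orders) ------

parse_sdf_block <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atoms <- lines[5:(4 + na)]
  el <- trimws(substr(atoms, 32, 34))
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  }
  charge <- rep(0L, na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    k <- as.integer(f[3])
    if (length(f) >= 3 + 2 * k) for (t in seq_len(k)) {
      charge[as.integer(f[2 + 2 * t])] <- as.integer(f[3 + 2 * t])
    }
  }
  list(elements = el, bonds = bonds, charge = charge)
}

# --- MOL block writing -----------------------------------------------------

# Write a V2000 mol block from a molgraph; explicit hydrogens become real
# H atoms so that Open Babel preserves total hydrogen counts exactly.
molgraph_to_molblock <- function(g) {
  n <- nrow(g$atoms)
  sym <- g$atoms$symbol
  nh <- g$atoms$nh
  chg <- g$atoms$charge
  h_owner <- rep(seq_len(n), times = nh)
  na <- n + length(h_owner)
  bonds <- g$bonds
  nb <- nrow(bonds) + length(h_owner)
  hdr <- c("", "  molgraphgen", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atom_line <- function(s)
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", s)
  lines <- c(hdr, vapply(sym, atom_line, character(1)),
             rep(atom_line("H"), length(h_owner)))
  if (nrow(bonds) > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", bonds$i, bonds$j,
                              ifelse(bonds$type == 4L, 4L, bonds$type)))
  }
  if (length(h_owner)) {
    lines <- c(lines, sprintf("%3d%3d  1  0  0  0  0", h_owner,
                              n + seq_along(h_owner)))
  }
  charged <- which(chg != 0L)
  if (length(charged)) {
    for (start in seq(1, length(charged), by = 8)) {
      idx <- charged[start:min(start + 7, length(charged))]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(idx)),
                               paste0(sprintf("%4d%4d", idx, chg[idx]),
                                      collapse = "")))
    }
  }
  paste(c(lines, "M  END", ""), collapse = "\n")
}

# OBMol reference for descriptor / SMARTS / fingerprint calls
ob_molref <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

# named list of Open Babel descriptors for a vector of SMILES
ob_properties <- function(smiles) {
  res <- lapply(smiles, function(s) {
    p <- ChemmineOB::prop_OB(ob_molref(s))
    data.frame(MW = p$MW, LogP = p$logP, cansmi = p$cansmi)
  })
  do.call(rbind, res)
}

# substructure match count of a SMARTS pattern in a molecule given as SMILES
ob_smarts_count <- function(smiles, smarts) {
  as.numeric(ChemmineOB::smartsSearch_OB(ob_molref(smiles), smarts))
}

# ECFP-style circular fingerprint, folded to `bits` positions
ob_ecfp <- function(smiles, bits = 2048L, variant = "ECFP6") {
  raw <- ChemmineOB::fingerprint_OB(ob_molref(smiles), variant)
  raw <- as.numeric(raw)
  idx <- which(raw != 0) - 1L
  out <- logical(bits)
  out[(idx %% bits) + 1L] <- TRUE
  out
}
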