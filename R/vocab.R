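#' Atom-type vocabulary
#'
#' The ordered set A of atom-type triples (symbol, explicit hydrogens,
#' formal charge) occurring in a corpus. Order is fixed by sorting on
#' symbol, then hydrogen count, then charge, so a vocabulary is reproducible
#' regardless of corpus order.
#'
#' @param corpus character vector of SMILES (one molecule each)
#' @return object of class \code{atom_vocab}: data.frame with columns
#'   \code{symbol}, \code{nh}, \code{charge}
#' @export
build_vocab <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  rows <- list()
  for (k in seq_along(corpus)) {
    g <- tryCatch(graph_from_smiles(corpus[k]), error = function(e)
      stop(sprintf("line %d: %s", k, conditionMessage(e)), call. = FALSE))
    rows[[k]] <- g$atoms
  }
  all_atoms <- do.call(rbind, rows)
  key <- paste(all_atoms$symbol, all_atoms$nh, all_atoms$charge)
  uniq <- all_atoms[!duplicated(key), , drop = FALSE]
  ord <- order(uniq$symbol, uniq$nh, uniq$charge)
  uniq <- uniq[ord, , drop = FALSE]
  rownames(uniq) <- NULL
  if (nrow(uniq) == 0L) stop("empty vocabulary", call. = FALSE)
  structure(uniq, class = c("atom_vocab", "data.frame"))
}

#' @export
print.atom_vocab <- function(x, ...) {
  cat(sprintf("<atom_vocab: %d atom types>\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

vocab_key <- function(symbol, nh, charge) paste(symbol, nh, charge)

#' Index of atom types in a vocabulary
#'
#' @param vocab an \code{atom_vocab}
#' @param atoms data.frame with \code{symbol}, \code{nh}, \code{charge}
#' @return integer vector of 1-based indices; error if any atom is missing
#' @export
vocab_index <- function(vocab, atoms) {
  idx <- match(vocab_key(atoms$symbol, atoms$nh, atoms$charge),
               vocab_key(vocab$symbol, vocab$nh, vocab$charge))
  if (anyNA(idx)) {
    miss <- atoms[is.na(idx), , drop = FALSE][1, ]
    mol_error(sprintf("atom type (%s,%d,%d) not in vocabulary",
                      miss$symbol, miss$nh, miss$charge),
              "molgraphgen_vocab_error")
  }
  idx
}

#' Read / write vocabulary files
#'
#' Vocabularies are stored as a JSON list of \code{[symbol, nH, charge]}
#' triples.
#'
#' @param vocab an \code{atom_vocab}
#' @param path file path
#' @return \code{read_vocab} returns an \code{atom_vocab}
#' @export
write_vocab <- function(vocab, path) {
  triples <- lapply(seq_len(nrow(vocab)), function(i)
    list(vocab$symbol[i], vocab$nh[i], vocab$charge[i]))
  jsonlite::write_json(triples, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  triples <- jsonlite::read_json(path)
  df <- data.frame(
    symbol = vapply(triples, function(t) as.character(t[[1]]), character(1)),
    nh = vapply(triples, function(t) as.integer(t[[2]]), integer(1)),
    charge = vapply(triples, function(t) as.integer(t[[3]]), integer(1))
  )
  structure(df, class = c("atom_vocab", "data.frame"))
}
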