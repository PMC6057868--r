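# SMILES text files: one molecule per line, with an optional tab-separated
# second column holding a comma-separated conditional code.

#' Read / write SMILES files
#'
#' One record per line; an optional second tab-separated column carries a
#' comma-separated numeric conditional code.
#'
#' @param path file path
#' @return \code{read_smiles} returns a list with \code{smiles} (character)
#'   and \code{codes} (numeric matrix or NULL)
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[`, character(1), 1L)
  codes <- NULL
  if (any(lengths(parts) > 1L)) {
    if (!all(lengths(parts) > 1L))
      stop("mixed annotated and unannotated SMILES records", call. = FALSE)
    code_list <- lapply(parts, function(p)
      as.numeric(strsplit(p[2], ",", fixed = TRUE)[[1]]))
    d <- unique(lengths(code_list))
    if (length(d) != 1L) stop("ragged condition codes", call. = FALSE)
    codes <- do.call(rbind, code_list)
  }
  list(smiles = smiles, codes = codes)
}

#' Model checkpoints
#'
#' A checkpoint stores the fitted parameters, architecture configuration
#' and vocabulary (with a consistency hash) in a versioned container, so a
#' model can be reloaded for sampling or fine-tuning.
#'
#' @param model a fitted \code{\link{molgen}}
#' @param path file path
#' @return \code{read_checkpoint} returns the \code{molgen} object
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "molgen"))
  vocab_hash <- sum(utf8ToInt(paste(vocab_key(model$vocab$symbol,
                                              model$vocab$nh,
                                              model$vocab$charge),
                                    collapse = ";")))
  saveRDS(list(format = "molgraphgen-checkpoint", version = 1L,
               vocab_hash = vocab_hash, model = model), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "molgraphgen-checkpoint"))
    stop("not a molgraphgen checkpoint: ", path, call. = FALSE)
  m <- obj$model
  vocab_hash <- sum(utf8ToInt(paste(vocab_key(m$vocab$symbol, m$vocab$nh,
                                              m$vocab$charge),
                                    collapse = ";")))
  if (!identical(vocab_hash, obj$vocab_hash))
    stop("checkpoint vocabulary hash mismatch", call. = FALSE)
  m
}

#' @rdname read_smiles
#' @param smiles character vector of SMILES
#' @param codes optional numeric matrix, one row per molecule
#' @export
write_smiles <- function(smiles, path, codes = NULL) {
  if (is.null(codes)) {
    writeLines(smiles, path)
  } else {
    codes <- as.matrix(codes)
    stopifnot(nrow(codes) == length(smiles))
    ann <- apply(codes, 1, paste, collapse = ",")
    writeLines(paste(smiles, ann, sep = "\t"), path)
  }
  invisible(path)
}
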