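# Batched bridge to the Python RDKit toolkit for the two scores that have
# no R implementation: QED (quantitative estimate of drug-likeness) and
# the Ertl-Schuffenhauer synthetic-accessibility score. Also reports
# RDKit's own parse/sanitize verdict, which tests use as an independent
# validity oracle.

rdkit_python <- function() Sys.getenv("MOLGRAPHGEN_PYTHON", "python")

rdkit_script <- function() {
  p <- system.file("python", "props.py", package = "molgraphgen")
  if (nzchar(p)) return(p)
  if (file.exists("inst/python/props.py")) return("inst/python/props.py")
  stop("props.py not found; is the package installed?", call. = FALSE)
}

#' RDKit property scores for a set of molecules
#'
#' Runs the bundled Python helper once for the whole batch and returns, per
#' molecule: whether RDKit sanitizes it, its QED score and its SA score.
#'
#' @param smiles character vector of SMILES
#' @return data.frame with columns \code{valid} (logical), \code{qed},
#'   \code{sa} (NA where RDKit cannot parse)
#' @export
rdkit_scores <- function(smiles) {
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(smiles, fin)
  status <- suppressWarnings(
    system2(rdkit_python(), c(rdkit_script(), fin, fout),
            stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(fout))
    stop("the RDKit Python bridge failed (python executable: ",
         rdkit_python(), ")", call. = FALSE)
  out <- utils::read.delim(fout)
  stopifnot(nrow(out) == length(smiles))
  out$valid <- out$valid == 1
  out
}
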