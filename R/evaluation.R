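# Evaluation metrics for generative models: validity and novelty, kernel
# density KL/JS divergences of molecular-property distributions,
# conditional control matrices with enrichment over random, reproduction
# rate, and internal diversity.

#' Validity and novelty of generated samples
#'
#' Validity is the fraction of outputs that sanitize; novelty is the
#' fraction of the valid, canonicalized outputs absent from the training
#' set; valid-and-novel is their product over the full sample.
#'
#' @param samples a \code{\link{generate}} result, or a character vector of
#'   SMILES (entries that fail to parse count as invalid)
#' @param training_corpus character vector of training SMILES
#' @return list with \code{valid}, \code{novel}, \code{valid_and_novel}
#' @export
validity_novelty <- function(samples, training_corpus) {
  if (is.data.frame(samples)) {
    can <- samples$smiles[samples$status == "ok" & !is.na(samples$smiles)]
    n_total <- nrow(samples)
  } else {
    can <- canonical_smiles(samples)
    n_total <- length(samples)
    can <- can[!is.na(can)]
  }
  train_can <- unique(canonical_smiles(training_corpus))
  valid <- length(can) / n_total
  novel <- if (length(can) == 0L) 0 else mean(!(can %in% train_can))
  list(valid = valid, novel = novel,
       valid_and_novel = if (n_total == 0L) 0
                         else sum(!(can %in% train_can)) / n_total)
}

# Gaussian KDE with Scott's bandwidth, evaluated on a shared grid
kde_on_grid <- function(x, grid) {
  n <- length(x)
  h <- stats::sd(x) * n^(-1 / 5)
  if (!is.finite(h) || h <= 0)
    stop("degenerate (zero-variance) sample in density estimate",
         call. = FALSE)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = h)),
                 numeric(1))
  dens
}

#' Distribution divergences of molecular properties
#'
#' Kullback-Leibler and Jensen-Shannon divergences between the generated
#' and reference distributions of molecular weight, logP (and optionally
#' QED), each estimated by Gaussian kernel densities with Scott's-rule
#' bandwidth and integrated by quadrature on a 2048-point grid spanning
#' both samples.
#'
#' @param generated,reference character vectors of valid SMILES (at least
#'   two each)
#' @param properties subset of \code{c("MW", "LogP", "QED")}; QED requires
#'   the Python RDKit bridge
#' @return data.frame with columns \code{property}, \code{d_kl},
#'   \code{d_js}
#' @export
property_divergences <- function(generated, reference,
                                 properties = c("MW", "LogP")) {
  stopifnot(length(generated) >= 2L, length(reference) >= 2L)
  properties <- match.arg(properties, c("MW", "LogP", "QED"),
                          several.ok = TRUE)
  need_ob <- intersect(properties, c("MW", "LogP"))
  pg <- pr <- list()
  if (length(need_ob)) {
    og <- ob_properties(generated); or <- ob_properties(reference)
    for (p in need_ob) { pg[[p]] <- og[[p]]; pr[[p]] <- or[[p]] }
  }
  if ("QED" %in% properties) {
    pg[["QED"]] <- rdkit_scores(generated)$qed
    pr[["QED"]] <- rdkit_scores(reference)$qed
  }
  rows <- lapply(properties, function(p) {
    dv <- density_divergences(pg[[p]], pr[[p]])
    data.frame(property = p, d_kl = dv$d_kl, d_js = dv$d_js)
  })
  do.call(rbind, rows)
}

#' @rdname property_divergences
#' @param x,y numeric samples (generated, reference)
#' @param grid_size quadrature grid resolution
#' @export
density_divergences <- function(x, y, grid_size = 2048L) {
  hx <- stats::sd(x) * length(x)^(-1 / 5)
  hy <- stats::sd(y) * length(y)^(-1 / 5)
  lo <- min(x, y) - 3 * max(hx, hy)
  hi <- max(x, y) + 3 * max(hx, hy)
  grid <- seq(lo, hi, length.out = grid_size)
  dx <- grid[2] - grid[1]
  floor_at <- 1e-12
  p <- pmax(kde_on_grid(x, grid), floor_at)
  q <- pmax(kde_on_grid(y, grid), floor_at)
  kl <- function(a, b) sum(a * log(a / b)) * dx
  m <- (p + q) / 2
  list(d_kl = kl(p, q), d_js = 0.5 * kl(p, m) + 0.5 * kl(q, m))
}

#' Conditional control matrix, correct-generation rate and enrichment
#'
#' For sample sets M_c generated under each condition c, the matrix entry
#' K[c, c'] is the fraction of M_c satisfying condition c'. The diagonal
#' gives the rate of correctly generated outputs R_c; dividing by the
#' training-set base rate R0_c yields the enrichment over random EOR_c.
#'
#' @param sample_sets named list: condition name -> character vector of
#'   valid SMILES
#' @param checker function(smiles_vector, condition_name) -> logical vector
#' @param base_rates optional named numeric: training-set rate R0_c per
#'   condition (zero rates yield \code{NA} enrichment)
#' @return list with matrix \code{K}, vector \code{R}, vector \code{EOR}
#' @export
conditional_matrix <- function(sample_sets, checker, base_rates = NULL) {
  cn <- names(sample_sets)
  stopifnot(!is.null(cn), all(nzchar(cn)))
  K <- matrix(NA_real_, length(cn), length(cn), dimnames = list(cn, cn))
  for (c1 in cn) for (c2 in cn)
    K[c1, c2] <- mean(checker(sample_sets[[c1]], c2))
  R <- diag(K); names(R) <- cn
  EOR <- rep(NA_real_, length(cn)); names(EOR) <- cn
  if (!is.null(base_rates)) {
    for (c1 in cn) {
      r0 <- base_rates[[c1]]
      if (!is.null(r0) && !is.na(r0) && r0 > 0) EOR[c1] <- R[c1] / r0
    }
  }
  list(K = K, R = R, EOR = EOR)
}

#' Rate of reproduced active compounds
#'
#' Fraction of a known-active test set recovered by the union of two
#' conditionally generated sample sets, all compared as canonical SMILES.
#'
#' @param m_c1,m_c2 character vectors of generated SMILES
#' @param test_actives character vector of known actives (non-empty)
#' @return scalar fraction
#' @export
reproduction_rate <- function(m_c1, m_c2, test_actives) {
  if (length(test_actives) == 0L) stop("empty active test set", call. = FALSE)
  gen <- unique(c(canonical_smiles(m_c1), canonical_smiles(m_c2)))
  tst <- unique(canonical_smiles(test_actives))
  length(intersect(gen, tst)) / length(tst)
}

#' Internal diversity of a molecule set
#'
#' Mean Tanimoto distance of circular fingerprints (radius 3, folded to
#' 2048 bits) over all ordered pairs of the set. As defined, the average
#' runs over the full M x M product including self-pairs (distance zero);
#' set \code{include_self = FALSE} for the diagonal-excluded convention.
#'
#' @param smiles character vector of valid SMILES
#' @param include_self include self-pairs in the average (default TRUE)
#' @param bits fingerprint length
#' @return scalar in [0, 1]
#' @export
internal_diversity <- function(smiles, include_self = TRUE, bits = 2048L) {
  m <- length(smiles)
  stopifnot(m >= 1L)
  if (m == 1L) return(0)
  FP <- t(vapply(smiles, function(s) as.numeric(ob_ecfp(s, bits)),
                 numeric(bits)))
  inter <- FP %*% t(FP)
  cnt <- rowSums(FP)
  uni <- outer(cnt, cnt, "+") - inter
  ts <- ifelse(uni > 0, inter / uni, 1)
  td <- 1 - ts
  diag(td) <- 0
  if (include_self) sum(td) / m^2 else sum(td) / (m * (m - 1))
}
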