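#' Default p-value threshold ladder
#'
#' Seven cutoffs spanning sparse to all-SNP scores.
#' @export
default_thresholds <- c(0.001, 0.01, 0.05, 0.1, 0.2, 0.5, 1.0)

#' Compute raw polygenic scores at multiple p-value thresholds
#'
#' For threshold t the score of sample i is
#' \eqn{\sum_{j: p_j < t} w_j d_{ij}} over harmonized variants, with
#' missing dosages mean-imputed as twice the panel alt-allele frequency.
#' Threshold comparison is strict (<).
#'
#' @param panel A \code{genotype_panel}.
#' @param hw A \code{harmonized_weights} object.
#' @param thresholds Ascending p-value cutoffs in (0, 1].
#' @return A list of class \code{score_set} with \code{sample_ids},
#'   \code{thresholds}, \code{raw_scores} (samples x thresholds),
#'   \code{n_snps_used}; the PGS-PCA slots are filled by
#'   \code{\link{pgs_pca}}.
#' @export
compute_raw_scores <- function(panel, hw, thresholds = default_thresholds) {
  stopifnot(nrow(hw) > 0)
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must be strictly ascending and in (0, 1]")
  D <- panel$dosages[, hw$variant_index, drop = FALSE]
  af <- panel$variants$afreq[hw$variant_index]
  if (anyNA(D)) {
    imp <- matrix(rep(2 * af, each = nrow(D)), nrow = nrow(D))
    D[is.na(D)] <- imp[is.na(D)]
  }
  nt <- length(thresholds)
  W <- matrix(0, nrow(hw), nt)
  n_used <- integer(nt)
  for (t in seq_len(nt)) {
    pass <- hw$pvalue < thresholds[t]
    n_used[t] <- sum(pass)
    if (n_used[t] == 0)
      warning("no variants pass threshold ", thresholds[t],
              "; score column is all zero")
    W[pass, t] <- hw$aligned_weight[pass]
  }
  raw <- D %*% W
  rownames(raw) <- rownames(panel$dosages)
  colnames(raw) <- paste0("p", thresholds)
  structure(list(sample_ids = rownames(panel$dosages),
                 thresholds = thresholds, raw_scores = raw,
                 n_snps_used = setNames(n_used, colnames(raw)),
                 pgs_pca = NULL, pc1_loadings = NULL,
                 pc1_variance_fraction = NULL),
            class = "score_set")
}

#' Aggregate threshold scores into a PGS-PCA composite
#'
#' Each threshold column is standardized to mean 0 / SD 1; a principal
#' component analysis is run on the standardized columns; the first
#' component's scores are extracted, sign-flipped if the sum of its
#' loadings is negative (so the composite is positively oriented with the
#' threshold scores), and z-standardized.
#'
#' @param ss A \code{score_set} from \code{\link{compute_raw_scores}}.
#' @return The \code{score_set} with \code{pgs_pca} (standardized composite,
#'   named by sample), \code{pc1_loadings} and
#'   \code{pc1_variance_fraction} filled in. Constant columns (e.g. empty
#'   thresholds) are excluded with a warning; if all columns are constant
#'   the error is fatal.
#' @export
pgs_pca <- function(ss) {
  X <- ss$raw_scores
  if (nrow(X) < 2) stop("PGS-PCA needs at least 2 samples")
  sds <- apply(X, 2, sd)
  usable <- sds > 0
  if (!any(usable))
    stop("all threshold score columns are constant; cannot aggregate")
  if (!all(usable))
    warning(sum(!usable), " constant threshold column(s) excluded from PGS-PCA")
  Z <- scale(X[, usable, drop = FALSE])
  if (ncol(Z) == 1) {
    comp <- Z[, 1]
    loadings <- setNames(1, colnames(Z))
    varfrac <- 1
  } else {
    pc <- prcomp(Z, center = FALSE, scale. = FALSE)
    v1 <- pc$rotation[, 1]
    if (sum(v1) < 0) v1 <- -v1
    comp <- as.vector(Z %*% v1)
    loadings <- v1
    varfrac <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  comp <- as.vector(scale(comp))
  names(comp) <- ss$sample_ids
  ss$pgs_pca <- comp
  full <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  full[names(loadings)] <- loadings
  ss$pc1_loadings <- full
  ss$pc1_variance_fraction <- varfrac
  ss
}

#' @export
print.score_set <- function(x, ...) {
  cat("score_set:", length(x$sample_ids), "samples,",
      length(x$thresholds), "thresholds\n")
  cat("  n_snps_used:", paste(x$n_snps_used, collapse = ", "), "\n")
  if (!is.null(x$pc1_variance_fraction))
    cat(sprintf("  PGS-PCA: PC1 explains %.1f%% of threshold-score variance\n",
                100 * x$pc1_variance_fraction))
  invisible(x)
}

#' Write a score set to a TSV file
#' @param ss A \code{score_set}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_scores <- function(ss, path) {
  out <- data.frame(sample_id = ss$sample_ids, ss$raw_scores,
                    check.names = FALSE)
  if (!is.null(ss$pgs_pca)) out$pgs_pca <- unname(ss$pgs_pca)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ancestry principal components of the dosage matrix
#'
#' PCs of the centered, variance-standardized dosage matrix (missing
#' dosages mean-imputed, monomorphic variants excluded). Each component's
#' sign is fixed by making its largest-magnitude variant loading positive.
#'
#' @param panel A \code{genotype_panel}.
#' @param k Number of components (default 5); if k exceeds the available
#'   rank, fewer are returned with a warning. k = 0 yields a zero-column
#'   matrix.
#' @return Samples x k matrix with columns PC1..PCk.
#' @export
compute_ancestry_pcs <- function(panel, k = 5) {
  n <- nrow(panel$dosages)
  if (k == 0)
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(rownames(panel$dosages), NULL)))
  X <- panel$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  sds <- apply(X, 2, sd)
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) == 0) stop("no polymorphic variants for ancestry PCA")
  Z <- scale(X)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  kmax <- sum(pc$sdev > sqrt(.Machine$double.eps))
  if (k > kmax) {
    warning("requested ", k, " PCs but rank supports ", kmax)
    k <- kmax
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(panel$dosages)
  scores
}

#' Score a cohort end to end
#'
#' Convenience wrapper: harmonize the cohort's summary statistics against
#' its panel, compute raw scores at the thresholds, and aggregate by
#' PGS-PCA.
#' @param cohort A \code{trio_cohort} (or list with \code{panel} and
#'   \code{sumstats}).
#' @param thresholds P-value ladder.
#' @param maf_threshold Passed to \code{\link{harmonize}}.
#' @return A completed \code{score_set}.
#' @export
score_cohort <- function(cohort, thresholds = default_thresholds,
                         maf_threshold = 0.05) {
  hw <- harmonize(cohort$sumstats, cohort$panel,
                  maf_threshold = maf_threshold)
  pgs_pca(compute_raw_scores(cohort$panel, hw, thresholds))
}
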