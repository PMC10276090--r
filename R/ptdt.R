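#' Mid-parent deviations of proband polygenic scores
#'
#' Selects complete trios (child plus both genotyped, scored parents), one
#' child per family, and computes each child's deviation from the
#' mid-parent score, standardized by the SD of the mid-parent distribution
#' over the retained trios:
#' \deqn{dev_f = (PGS_{child,f} - (PGS_{father,f}+PGS_{mother,f})/2) /
#'   SD(midparent).}
#' In families with several scored children, one is chosen by a seeded
#' uniform draw (the seed is recorded in the result) so reruns retain the
#' same child.
#'
#' @param panel A \code{genotype_panel} carrying pedigree roles.
#' @param scores Either a completed \code{score_set} (its \code{pgs_pca}
#'   composite is used) or a named numeric vector of per-sample scores.
#' @param cohort_label Label stored with the deviations (used by
#'   \code{\link{combine_ptdt}}).
#' @param seed Seed for the multi-child tie-break.
#' @return Data frame of class \code{trio_deviations} with one row per
#'   retained trio: \code{family_id}, \code{child_id}, \code{child_score},
#'   \code{father_score}, \code{mother_score}, \code{midparent},
#'   \code{deviation}. Attributes: \code{cohort_label},
#'   \code{sd_midparent}, \code{tiebreak_seed}, \code{n_incomplete}
#'   (families with a scored child but not both parents).
#' @export
trio_deviations <- function(panel, scores, cohort_label = "cohort1",
                            seed = 1L) {
  sc <- if (inherits(scores, "score_set")) {
    if (is.null(scores$pgs_pca))
      stop("score_set has no PGS-PCA composite; run pgs_pca() first")
    scores$pgs_pca
  } else scores
  if (is.null(names(sc))) stop("scores must be named by sample_id")
  s <- panel$samples
  kids <- s[s$role %in% c("proband", "sibling"), , drop = FALSE]
  child_sc <- sc[kids$sample_id]
  father_sc <- sc[kids$father_id]
  mother_sc <- sc[kids$mother_id]
  complete <- !is.na(child_sc) & !is.na(father_sc) & !is.na(mother_sc)
  n_incomplete <- length(unique(kids$family_id[!complete]))
  kids <- kids[complete, , drop = FALSE]
  child_sc <- child_sc[complete]
  father_sc <- father_sc[complete]
  mother_sc <- mother_sc[complete]
  if (nrow(kids) == 0) stop("no complete trios available")

  # one child per family, seeded uniform tie-break
  pick <- integer(0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (f in unique(kids$family_id)) {
    rows <- which(kids$family_id == f)
    pick <- c(pick, if (length(rows) == 1) rows
              else rows[sample.int(length(rows), 1)])
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  kids <- kids[pick, , drop = FALSE]
  child_sc <- child_sc[pick]
  father_sc <- father_sc[pick]
  mother_sc <- mother_sc[pick]

  mid <- (father_sc + mother_sc) / 2
  sd_mid <- sd(mid)
  if (!is.finite(sd_mid) || sd_mid == 0)
    stop("mid-parent scores are degenerate (zero variance)")
  out <- data.frame(family_id = kids$family_id,
                    child_id = kids$sample_id,
                    child_score = unname(child_sc),
                    father_score = unname(father_sc),
                    mother_score = unname(mother_sc),
                    midparent = unname(mid),
                    deviation = unname((child_sc - mid) / sd_mid),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cohort_label") <- cohort_label
  attr(out, "sd_midparent") <- sd_mid
  attr(out, "tiebreak_seed") <- seed
  attr(out, "n_incomplete") <- n_incomplete
  class(out) <- c("trio_deviations", "data.frame")
  out
}

#' Polygenic transmission disequilibrium test
#'
#' One-sample two-sided t-test of the mean standardized mid-parent
#' deviation against zero: over-transmission of polygenic liability to
#' ascertained probands shifts the mean above zero.
#'
#' @param x A \code{trio_deviations} data frame or a numeric vector of
#'   deviations.
#' @param ... Unused.
#' @return Object of class \code{ptdt}: \code{n_trios},
#'   \code{mean_deviation}, \code{se_deviation}, \code{t_statistic},
#'   \code{df}, \code{pvalue}, \code{cohort_label}.
#' @export
ptdt <- function(x, ...) {
  dev <- if (inherits(x, "trio_deviations")) x$deviation else as.numeric(x)
  label <- attr(x, "cohort_label")
  n <- length(dev)
  if (n < 2) stop("pTDT needs at least 2 trios, got ", n)
  m <- mean(dev)
  s <- sd(dev)
  if (s == 0) stop("deviations have zero variance; t-test undefined")
  se <- s / sqrt(n)
  tval <- m / se
  p <- 2 * pt(-abs(tval), df = n - 1)
  structure(list(n_trios = n, mean_deviation = m, se_deviation = se,
                 t_statistic = tval, df = n - 1, pvalue = p,
                 cohort_label = if (is.null(label)) NA_character_
                                else label),
            class = "ptdt")
}

#' @export
print.ptdt <- function(x, ...) {
  cat("Polygenic transmission disequilibrium test\n")
  if (!is.na(x$cohort_label)) cat("  cohort:", x$cohort_label, "\n")
  cat(sprintf("  n_trios = %d\n", x$n_trios))
  cat(sprintf("  mean deviation = %.4f (SE %.4f)\n",
              x$mean_deviation, x$se_deviation))
  cat(sprintf("  t = %.3f on %d df, two-sided p = %.4g\n",
              x$t_statistic, x$df, x$pvalue))
  invisible(x)
}

#' @export
summary.ptdt <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Combined-cohort pTDT
#'
#' Pools the per-trio deviations of several cohorts (each computed with its
#' own mid-parent SD and composite standardization) and runs the one-sample
#' t-test on the pooled vector.
#'
#' @param devsets List of \code{trio_deviations} objects (at least 2).
#' @return A \code{ptdt} object with \code{cohort_label} "combined" and a
#'   \code{cohorts} attribute listing per-cohort sizes.
#' @export
combine_ptdt <- function(devsets) {
  if (length(devsets) < 2) stop("need at least 2 cohorts to combine")
  dev <- unlist(lapply(devsets, function(d) d$deviation))
  res <- ptdt(dev)
  res$cohort_label <- "combined"
  attr(res, "cohorts") <- vapply(devsets, function(d)
    length(d$deviation), integer(1))
  res
}

#' pTDT table over several polygenic scores
#'
#' Runs the pTDT for each named set of deviations (one per discovery
#' phenotype) and applies Benjamini-Hochberg FDR correction across them.
#' @param devlist Named list of \code{trio_deviations} (or numeric
#'   deviation vectors), one entry per PGS.
#' @return Data frame with columns \code{phenotype}, \code{n_trios},
#'   \code{mean_deviation}, \code{se}, \code{t}, \code{p}, \code{p_fdr}.
#' @export
ptdt_table <- function(devlist) {
  stopifnot(length(devlist) >= 1, !is.null(names(devlist)))
  rows <- lapply(names(devlist), function(nm) {
    r <- ptdt(devlist[[nm]])
    data.frame(phenotype = nm, n_trios = r$n_trios,
               mean_deviation = r$mean_deviation, se = r$se_deviation,
               t = r$t_statistic, p = r$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
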