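#' Harmonize summary statistics against a genotype panel
#'
#' Matches summary-statistics variants to panel variants (by ID, falling
#' back to chrom:pos where IDs are absent), orients each weight to count
#' alt-allele copies of the panel, optionally resolving strand flips, drops
#' strand-ambiguous (A/T, C/G) pairs and variants at or below the panel
#' minor-allele-frequency threshold, and returns sign-corrected weights with
#' a per-variant provenance flag plus a harmonization report.
#'
#' Orientation rules, for sumstats alleles (effect, other) against panel
#' alleles (ref, alt):
#' \itemize{
#'   \item effect = alt, other = ref: \code{direct}, weight kept;
#'   \item effect = ref, other = alt: \code{allele_swapped}, weight negated;
#'   \item matches only after complementing both sumstats alleles:
#'     \code{strand_flipped} / \code{strand_flipped_and_swapped}, same sign
#'     rule applied after complementing;
#'   \item anything else: dropped as unmatched.
#' }
#'
#' @param ss A \code{pgs_sumstats} data frame.
#' @param panel A \code{genotype_panel}.
#' @param maf_threshold Panel minor-allele-frequency cutoff; variants with
#'   MAF \eqn{\le} this are dropped (default 0.05, i.e. MAF > 5\% retained).
#' @param drop_ambiguous Drop A/T and C/G variants (default TRUE).
#' @return A data frame of class \code{harmonized_weights} with columns
#'   \code{variant_id}, \code{variant_index} (into the panel's variants),
#'   \code{aligned_weight}, \code{pvalue}, \code{flag}; the report is in
#'   \code{attr(, "report")}.
#' @export
harmonize <- function(ss, panel, maf_threshold = 0.05,
                      drop_ambiguous = TRUE) {
  if (ncol(panel$dosages) == 0) stop("panel has no variants")
  pv <- panel$variants
  n_input <- nrow(ss)

  idx <- match(ss$variant_id, pv$variant_id)
  no_id <- is.na(ss$variant_id) | ss$variant_id %in% c("", ".")
  if (any(no_id & is.na(idx))) {
    key_ss <- paste(ss$chrom, ss$pos, sep = ":")
    key_pv <- paste(pv$chrom, pv$pos, sep = ":")
    fb <- no_id & is.na(idx)
    idx[fb] <- match(key_ss[fb], key_pv)
  }
  overlap <- !is.na(idx)
  n_no_overlap <- sum(!overlap)
  if (!any(overlap)) stop("no variants overlap between sumstats and panel")

  ss2 <- ss[overlap, , drop = FALSE]
  idx <- idx[overlap]
  eff <- ss2$effect_allele
  oth <- ss2$other_allele
  ref <- toupper(pv$ref[idx])
  alt <- toupper(pv$alt[idx])

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- eff == comp[oth]          # A/T or C/G pair
  eff_c <- unname(comp[eff])
  oth_c <- unname(comp[oth])

  flag <- rep(NA_character_, nrow(ss2))
  sign <- rep(NA_real_, nrow(ss2))
  direct <- eff == alt & oth == ref
  swapped <- eff == ref & oth == alt
  flipped <- !direct & !swapped & eff_c == alt & oth_c == ref
  flip_swap <- !direct & !swapped & eff_c == ref & oth_c == alt
  flag[direct] <- "direct";            sign[direct] <- 1
  flag[swapped] <- "allele_swapped";   sign[swapped] <- -1
  flag[flipped] <- "strand_flipped";   sign[flipped] <- 1
  flag[flip_swap] <- "strand_flipped_and_swapped"; sign[flip_swap] <- -1

  keep <- !is.na(flag)
  n_unmatched <- sum(!keep)
  if (drop_ambiguous) {
    n_ambiguous <- sum(ambiguous & keep)
    keep <- keep & !ambiguous
  } else n_ambiguous <- 0L

  maf <- pv$maf[idx]
  low_maf <- !is.na(maf) & maf <= maf_threshold
  n_maf <- sum(keep & low_maf)
  keep <- keep & !low_maf

  hw <- data.frame(
    variant_id = pv$variant_id[idx[keep]],
    variant_index = idx[keep],
    aligned_weight = ss2$weight[keep] * sign[keep],
    pvalue = ss2$pvalue[keep],
    flag = flag[keep],
    stringsAsFactors = FALSE
  )
  rownames(hw) <- NULL
  report <- list(n_input = n_input,
                 n_retained = nrow(hw),
                 n_dropped_maf = n_maf,
                 n_dropped_ambiguous = n_ambiguous,
                 n_dropped_unmatched = n_unmatched,
                 n_dropped_no_overlap = n_no_overlap,
                 maf_threshold = maf_threshold,
                 drop_ambiguous = drop_ambiguous)
  attr(hw, "report") <- report
  class(hw) <- c("harmonized_weights", "data.frame")
  if (nrow(hw) == 0) stop("no variants retained after harmonization")
  hw
}

#' Write a per-variant harmonization report
#' @param hw A \code{harmonized_weights} object.
#' @param path Output TSV path; summary counts go in '#'-prefixed header
#'   lines.
#' @return Invisibly, \code{path}.
#' @export
write_harmonization_report <- function(hw, path) {
  rep <- attr(hw, "report")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("n_input", "n_retained", "n_dropped_maf",
              "n_dropped_ambiguous", "n_dropped_unmatched",
              "n_dropped_no_overlap"))
    writeLines(paste0("# ", k, "\t", rep[[k]]), con)
  write.table(as.data.frame(hw), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
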