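#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file, maps its columns onto the
#' canonical fields, converts effect sizes to the log odds-ratio scale, and
#' drops rows that violate the field invariants (invalid alleles, p-values
#' outside (0, 1], non-finite weights, duplicate variant IDs).
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Named list mapping canonical field names
#'   (\code{variant_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{weight}, \code{pvalue}, optionally
#'   \code{eaf}) to the column names in the file.
#' @param scale Scale of the effect column: \code{"logOR"} (used as is),
#'   \code{"OR"} (log-transformed), or \code{"beta"} (used as is).
#' @return A data frame of class \code{pgs_sumstats} with columns
#'   \code{variant_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#'   \code{other_allele}, \code{weight} (log OR), \code{pvalue} and, when
#'   mapped, \code{eaf}. The number of rows dropped per reason is stored in
#'   \code{attr(, "drop_log")}.
#' @export
read_sumstats <- function(path,
                          column_map = list(variant_id = "SNP", chrom = "CHR",
                                            pos = "BP", effect_allele = "A1",
                                            other_allele = "A2",
                                            weight = "BETA", pvalue = "P"),
                          scale = c("logOR", "OR", "beta")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("variant_id", "chrom", "pos", "effect_allele",
                "other_allele", "weight", "pvalue")
  for (f in required) {
    cm <- column_map[[f]]
    if (is.null(cm)) stop("column_map does not map required field '", f, "'")
    if (!cm %in% names(raw))
      stop("required column '", cm, "' (field '", f, "') missing from ", path)
  }
  ss <- data.frame(
    variant_id    = as.character(raw[[column_map$variant_id]]),
    chrom         = as.character(raw[[column_map$chrom]]),
    pos           = as.integer(raw[[column_map$pos]]),
    effect_allele = toupper(as.character(raw[[column_map$effect_allele]])),
    other_allele  = toupper(as.character(raw[[column_map$other_allele]])),
    weight        = as.numeric(raw[[column_map$weight]]),
    pvalue        = as.numeric(raw[[column_map$pvalue]]),
    stringsAsFactors = FALSE
  )
  if (!is.null(column_map$eaf) && column_map$eaf %in% names(raw))
    ss$eaf <- as.numeric(raw[[column_map$eaf]])
  if (scale == "OR") {
    bad_or <- !is.na(ss$weight) & ss$weight <= 0
    ss$weight[bad_or] <- NA_real_
    ss$weight <- log(ss$weight)
  }
  validate_sumstats(ss)
}

#' Validate a summary-statistics data frame
#'
#' Drops rows violating the invariants and records the count per reason.
#' @param ss Data frame with the canonical summary-statistics columns.
#' @return A \code{pgs_sumstats} data frame; fatal error if no rows survive.
#' @export
validate_sumstats <- function(ss) {
  bases <- c("A", "C", "G", "T")
  drop_log <- c(bad_allele = 0L, same_alleles = 0L, bad_pvalue = 0L,
                bad_weight = 0L, duplicate_id = 0L)
  keep <- rep(TRUE, nrow(ss))

  bad <- keep & (!ss$effect_allele %in% bases | !ss$other_allele %in% bases)
  drop_log["bad_allele"] <- sum(bad); keep <- keep & !bad
  bad <- keep & (ss$effect_allele == ss$other_allele)
  drop_log["same_alleles"] <- sum(bad); keep <- keep & !bad
  bad <- keep & (is.na(ss$pvalue) | ss$pvalue <= 0 | ss$pvalue > 1)
  drop_log["bad_pvalue"] <- sum(bad); keep <- keep & !bad
  bad <- keep & (is.na(ss$weight) | !is.finite(ss$weight))
  drop_log["bad_weight"] <- sum(bad); keep <- keep & !bad
  bad <- keep & duplicated(ss$variant_id)
  drop_log["duplicate_id"] <- sum(bad); keep <- keep & !bad

  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(n_dropped, " summary-statistics row(s) dropped (",
            paste(names(drop_log)[drop_log > 0], drop_log[drop_log > 0],
                  sep = "=", collapse = ", "), ")")
  ss <- ss[keep, , drop = FALSE]
  if (nrow(ss) == 0) stop("no valid summary-statistics rows remain")
  rownames(ss) <- NULL
  attr(ss, "drop_log") <- drop_log
  class(ss) <- c("pgs_sumstats", "data.frame")
  ss
}

#' Write summary statistics to a TSV file
#' @param ss A \code{pgs_sumstats} data frame.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_sumstats <- function(ss, path) {
  out <- as.data.frame(ss)
  names(out) <- sub("^variant_id$", "SNP", names(out))
  names(out) <- sub("^chrom$", "CHR", names(out))
  names(out) <- sub("^pos$", "BP", names(out))
  names(out) <- sub("^effect_allele$", "A1", names(out))
  names(out) <- sub("^other_allele$", "A2", names(out))
  names(out) <- sub("^weight$", "BETA", names(out))
  names(out) <- sub("^pvalue$", "P", names(out))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
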