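#' Construct a genotype panel
#'
#' The panel bundles a samples-by-variants dosage matrix (alt-allele copies,
#' values 0/1/2/NA) with sample metadata (pedigree roles, batch) and variant
#' metadata (alleles, alt-allele frequency, minor-allele frequency).
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns.
#'   Row names are sample IDs, column names variant IDs.
#' @param samples Data frame with columns \code{sample_id}, \code{family_id},
#'   \code{father_id}, \code{mother_id}, \code{role} (one of father, mother,
#'   proband, sibling), \code{sex}, \code{batch}.
#' @param variants Data frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}; \code{afreq} (alt-allele frequency)
#'   and \code{maf} are computed from the dosages when absent.
#' @param validate Run invariant checks (default TRUE).
#' @return An object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(dosages, samples, variants, validate = TRUE) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) rownames(dosages) <- samples$sample_id
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$variant_id
  afreq <- colMeans(dosages, na.rm = TRUE) / 2
  if (is.null(variants$afreq)) variants$afreq <- unname(afreq)
  if (is.null(variants$maf)) variants$maf <- pmin(variants$afreq,
                                                  1 - variants$afreq)
  panel <- structure(list(dosages = dosages, samples = samples,
                          variants = variants),
                     class = "genotype_panel")
  if (validate) validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  d <- panel$dosages
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosages must be 0, 1, 2 or missing")
  if (nrow(d) != nrow(panel$samples))
    stop("dosage rows do not match sample table")
  if (ncol(d) != nrow(panel$variants))
    stop("dosage columns do not match variant table")
  af <- colMeans(d, na.rm = TRUE) / 2
  af[is.nan(af)] <- panel$variants$afreq[is.nan(af)]
  if (any(abs(af - panel$variants$afreq) > 1e-12, na.rm = TRUE))
    stop("stored allele frequencies disagree with dosages")
  s <- panel$samples
  pro <- s[s$role %in% c("proband", "sibling"), , drop = FALSE]
  for (i in seq_len(nrow(pro))) {
    for (p in c("father_id", "mother_id")) {
      pid <- pro[[p]][i]
      if (is.na(pid) || pid %in% c("", "0")) next
      j <- match(pid, s$sample_id)
      if (!is.na(j) && s$family_id[j] != pro$family_id[i])
        stop("parent ", pid, " of ", pro$sample_id[i],
             " belongs to a different family")
    }
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  cat("  roles:", paste(names(table(x$samples$role)),
                        table(x$samples$role), sep = "=", collapse = ", "),
      "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Read genotypes, pedigree and phenotypes into a panel
#'
#' Genotypes come either from a VCF (GT field converted to alt-allele
#' dosages, read through the vcfR package) or a PLINK-style \code{.traw}
#' text matrix (the COUNTED allele is the dosage allele). The pedigree file
#' is a FAM-like TSV with a header (\code{family_id}, \code{sample_id},
#' \code{father_id}, \code{mother_id}, \code{sex}, \code{role}, optionally
#' \code{batch}); samples present in the pedigree but not genotyped are
#' excluded with a warning.
#'
#' @param genotypes Path to a \code{.vcf} or \code{.traw} file.
#' @param pedigree Path to the FAM-like TSV.
#' @param phenotypes Optional path to a phenotype TSV (see
#'   \code{\link{read_phenotypes}}).
#' @param format \code{"auto"} (by extension), \code{"vcf"} or \code{"traw"}.
#' @param outcomes Passed to \code{\link{read_phenotypes}}.
#' @return A list with elements \code{panel} (a \code{genotype_panel}) and
#'   \code{phenotypes} (a data frame or NULL).
#' @export
read_genotypes <- function(genotypes, pedigree, phenotypes = NULL,
                           format = c("auto", "vcf", "traw"),
                           outcomes = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", genotypes)) "vcf" else "traw"
  geno <- if (format == "vcf") read_vcf_dosages(genotypes)
          else read_traw(genotypes)
  ped <- read.delim(pedigree, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("family_id", "sample_id", "father_id", "mother_id",
            "sex", "role")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop("pedigree file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(ped$batch)) ped$batch <- "batch1"

  missing_geno <- setdiff(ped$sample_id, rownames(geno$dosages))
  if (length(missing_geno)) {
    warning(length(missing_geno),
            " pedigree sample(s) missing from genotypes; excluded")
    ped <- ped[!ped$sample_id %in% missing_geno, , drop = FALSE]
  }
  extra <- setdiff(rownames(geno$dosages), ped$sample_id)
  if (length(extra))
    warning(length(extra), " genotyped sample(s) absent from pedigree; excluded")
  dos <- geno$dosages[ped$sample_id, , drop = FALSE]
  panel <- genotype_panel(dos, ped, geno$variants)
  phe <- if (!is.null(phenotypes))
    read_phenotypes(phenotypes, outcomes = outcomes) else NULL
  list(panel = panel, phenotypes = phe)
}

#' Read a phenotype table
#'
#' Outcome columns must be coded 0 = absent, 1 = present (missing allowed);
#' any other value is a fatal error.
#'
#' @param path TSV with a header; must contain \code{sample_id}.
#' @param outcomes Character vector of binary outcome columns to validate.
#'   Default: every column except \code{sample_id} and the covariates.
#' @param covariates Columns exempt from the binary check.
#' @return Data frame keyed by \code{sample_id}.
#' @export
read_phenotypes <- function(path, outcomes = NULL,
                            covariates = c("family_id", "age", "sex",
                                           "batch")) {
  phe <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(phe)) stop("phenotype file lacks sample_id")
  phe$sample_id <- as.character(phe$sample_id)
  if (is.null(outcomes))
    outcomes <- setdiff(names(phe), c("sample_id", covariates))
  for (oc in outcomes) {
    v <- phe[[oc]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("phenotype '", oc, "' has values outside {0, 1, missing}")
  }
  phe
}

read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # count alt alleles from GT strings like 0/1, 1|1, ./.
  count_alt <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) {
      if (any(x == "." ) || length(x) == 0) return(NA_real_)
      sum(as.numeric(x) > 0)
    }, numeric(1))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                       dimnames = list(NULL, colnames(gt)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  dos <- t(dos)  # samples x variants
  colnames(dos) <- variants$variant_id
  list(dosages = dos, variants = variants)
}

read_traw <- function(path) {
  tr <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("CHR", "SNP", "CM", "POS", "COUNTED", "ALT")
  miss <- setdiff(meta_cols, names(tr))
  if (length(miss)) stop(".traw lacks column(s): ",
                         paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(tr), meta_cols)
  dos <- t(as.matrix(tr[, sample_cols, drop = FALSE]))
  # traw sample headers are FID_IID; keep the IID part
  rownames(dos) <- sub("^[^_]*_", "", sample_cols)
  colnames(dos) <- tr$SNP
  variants <- data.frame(
    variant_id = tr$SNP, chrom = as.character(tr$CHR),
    pos = as.integer(tr$POS),
    ref = tr$ALT, alt = tr$COUNTED,  # dosage counts the COUNTED allele
    stringsAsFactors = FALSE)
  list(dosages = dos, variants = variants)
}

#' Write a genotype panel as a PLINK-style .traw text matrix
#' @param panel A \code{genotype_panel}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_traw <- function(panel, path) {
  v <- panel$variants
  d <- t(panel$dosages)
  hdr <- data.frame(CHR = v$chrom, SNP = v$variant_id, CM = 0, POS = v$pos,
                    COUNTED = v$alt, ALT = v$ref, stringsAsFactors = FALSE)
  m <- as.data.frame(d)
  names(m) <- paste(panel$samples$family_id, panel$samples$sample_id,
                    sep = "_")
  write.table(cbind(hdr, m), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel as a minimal sites+GT VCF
#' @param panel A \code{genotype_panel}.
#' @param path Output path (plain text).
#' @return Invisibly, \code{path}.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  d <- panel$dosages
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")),
             con)
  body <- cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                ".", "GT", t(gt))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write a FAM-like pedigree table
#' @param panel A \code{genotype_panel}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fam <- function(panel, path) {
  write.table(panel$samples, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
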