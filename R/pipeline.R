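#' Run the full trio PGS analysis from one configuration
#'
#' Drives the whole workflow: obtain a cohort (simulated from a
#' \code{simulate:} block, or read from files named in an \code{input:}
#' block), harmonize the summary statistics against the panel, score at the
#' p-value ladder and aggregate by PGS-PCA, compute ancestry PCs, run the
#' pTDT on complete trios, and fit the case-only association battery with
#' family-clustered sandwich errors. Optionally writes the pTDT table and
#' association table as TSVs.
#'
#' The configuration is a YAML file (or an equivalent list) with blocks:
#' \preformatted{
#' simulate:            # passed to sim_config()
#'   n_trios: 300
#'   n_variants: 500
#'   ...
#' # or, for real data:
#' # input:
#' #   genotypes: cohort.traw
#' #   pedigree: pedigree.fam.tsv
#' #   phenotypes: phenotypes.tsv
#' #   sumstats: sumstats.tsv
#' thresholds: [0.001, 0.01, 0.05, 0.1, 0.2, 0.5, 1.0]
#' maf_threshold: 0.05
#' n_pcs: 5
#' association:
#'   outcomes: [insomnia]
#'   covariates: [PC1, PC2, PC3, PC4, PC5, batch, age]
#'   sensitivity: none
#' }
#'
#' @param config Path to a YAML file or a list with the same structure.
#' @param out_dir Optional output directory for \code{ptdt.tsv} and
#'   \code{assoc.tsv}.
#' @return List with \code{cohort}, \code{harmonized}, \code{scores},
#'   \code{ancestry_pcs}, \code{deviations}, \code{ptdt},
#'   \code{ptdt_table}, \code{assoc} (an \code{assoc_battery} or NULL).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config

  if (!is.null(cfg$simulate)) {
    cohort <- simulate_trio_cohort(do.call(sim_config, cfg$simulate))
    panel <- cohort$panel
    phe <- cohort$phenotypes
    ss <- cohort$sumstats
  } else if (!is.null(cfg$input)) {
    gin <- read_genotypes(cfg$input$genotypes, cfg$input$pedigree,
                          cfg$input$phenotypes)
    panel <- gin$panel
    phe <- gin$phenotypes
    ss <- read_sumstats(cfg$input$sumstats,
                        column_map = list(variant_id = "SNP", chrom = "CHR",
                                          pos = "BP", effect_allele = "A1",
                                          other_allele = "A2",
                                          weight = "BETA", pvalue = "P"))
    cohort <- list(panel = panel, phenotypes = phe, sumstats = ss)
  } else stop("config needs a 'simulate' or 'input' block")

  thresholds <- if (!is.null(cfg$thresholds)) as.numeric(cfg$thresholds)
                else default_thresholds
  maf_thr <- if (!is.null(cfg$maf_threshold)) cfg$maf_threshold else 0.05
  hw <- harmonize(ss, panel, maf_threshold = maf_thr)
  scores <- pgs_pca(compute_raw_scores(panel, hw, thresholds))

  n_pcs <- if (!is.null(cfg$n_pcs)) cfg$n_pcs else 5
  pcs <- compute_ancestry_pcs(panel, k = n_pcs)

  devs <- trio_deviations(panel, scores)
  pt <- ptdt(devs)
  pt_tab <- ptdt_table(setNames(list(devs), "pgs"))

  assoc <- NULL
  if (!is.null(cfg$association) && !is.null(phe)) {
    ac <- cfg$association
    d <- phe
    pcs_child <- pcs[d$sample_id, , drop = FALSE]
    d <- cbind(d, as.data.frame(pcs_child))
    d$pgs <- unname(scores$pgs_pca[d$sample_id])
    covs <- if (!is.null(ac$covariates)) unlist(ac$covariates)
            else c(colnames(pcs), "batch", "age")
    specs <- expand.grid(predictor = "pgs",
                         outcome = unlist(ac$outcomes),
                         stringsAsFactors = FALSE)
    assoc <- assoc_battery(specs, d, covariates = covs,
                           cluster = "family_id",
                           sensitivity = if (!is.null(ac$sensitivity))
                             ac$sensitivity else "none")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(pt_tab, file.path(out_dir, "ptdt.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(assoc))
      write.table(as.data.frame(assoc), file.path(out_dir, "assoc.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write_scores(scores, file.path(out_dir, "scores.tsv"))
  }

  list(cohort = cohort, harmonized = hw, scores = scores,
       ancestry_pcs = pcs, deviations = devs, ptdt = pt,
       ptdt_table = pt_tab, assoc = assoc)
}
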