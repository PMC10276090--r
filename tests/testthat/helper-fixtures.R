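# Shared fixture builders. Everything is generated in code; no stored data.

# Minimal sample table with the columns genotype_panel() expects.
make_samples <- function(ids, family = ids, role = "proband",
                         father = "0", mother = "0") {
  data.frame(sample_id = ids, family_id = family,
             father_id = father, mother_id = mother,
             role = role, sex = 1L, batch = "batch1",
             stringsAsFactors = FALSE)
}

# Unrelated panel with explicit dosages and alleles.
make_panel <- function(dosages, ref, alt, variant_id = NULL,
                       samples = NULL) {
  m <- ncol(dosages)
  if (is.null(variant_id)) variant_id <- paste0("v", seq_len(m))
  if (is.null(samples))
    samples <- make_samples(paste0("s", seq_len(nrow(dosages))))
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- variant_id
  variants <- data.frame(variant_id = variant_id,
                         chrom = rep("1", m), pos = seq_len(m) * 100L,
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_panel(dosages, samples, variants)
}

# Summary stats data frame in canonical layout.
make_ss <- function(variant_id, effect, other, weight, pvalue,
                    chrom = "1", pos = seq_along(variant_id) * 100L) {
  ss <- data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                   effect_allele = effect, other_allele = other,
                   weight = weight, pvalue = pvalue,
                   stringsAsFactors = FALSE)
  class(ss) <- c("pgs_sumstats", "data.frame")
  ss
}

# A small hand-built trio panel: families f1 and f2 complete, f3 missing
# the mother's genotype row.
make_trio_panel <- function() {
  samples <- data.frame(
    sample_id = c("f1_fa", "f1_mo", "f1_ch", "f2_fa", "f2_mo", "f2_ch",
                  "f3_fa", "f3_ch"),
    family_id = rep(c("f1", "f2", "f3"), c(3, 3, 2)),
    father_id = c("0", "0", "f1_fa", "0", "0", "f2_fa", "0", "f3_fa"),
    mother_id = c("0", "0", "f1_mo", "0", "0", "f2_mo", "0", "f3_mo"),
    role = c("father", "mother", "proband", "father", "mother",
             "proband", "father", "proband"),
    sex = c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 1L), batch = "batch1",
    stringsAsFactors = FALSE)
  dos <- rbind(c(0, 1, 2), c(1, 1, 0), c(0, 1, 1),
               c(2, 0, 1), c(1, 1, 1), c(1, 0, 1),
               c(1, 2, 0), c(1, 1, 0))
  make_panel(dos, ref = c("A", "C", "G"), alt = c("G", "T", "C"),
             samples = samples)
}

# Direct step-up BH oracle, independent of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Naive per-SNP double-loop scoring oracle (missing imputed as 2*afreq).
score_oracle <- function(panel, hw, thresholds) {
  n <- nrow(panel$dosages)
  out <- matrix(0, n, length(thresholds))
  for (t in seq_along(thresholds)) {
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(nrow(hw))) {
        if (hw$pvalue[j] < thresholds[t]) {
          d <- panel$dosages[i, hw$variant_index[j]]
          if (is.na(d)) d <- 2 * panel$variants$afreq[hw$variant_index[j]]
          acc <- acc + hw$aligned_weight[j] * d
        }
      }
      out[i, t] <- acc
    }
  }
  out
}

# One full simulate -> harmonize -> score -> pTDT pass; returns the ptdt fit.
run_ptdt_once <- function(n_trios, h2, q, seed, n_variants = 100,
                          n_causal = 50, discovery_n = Inf,
                          maf_range = c(0.1, 0.5)) {
  cfg <- sim_config(n_trios = n_trios, n_variants = n_variants,
                    n_causal = n_causal, h2_pgs = h2,
                    ascertainment_quantile = q, maf_range = maf_range,
                    discovery_n = discovery_n, seed = seed)
  co <- simulate_trio_cohort(cfg)
  sc <- suppressWarnings(score_cohort(co))
  list(ptdt = ptdt(trio_deviations(co$panel, sc)),
       devs = trio_deviations(co$panel, sc))
}

# Independent brute-force oracle for the ascertained mid-parent deviation:
# direct Monte-Carlo on the infinitesimal model, no genotypes involved.
oracle_deviation <- function(h2, q, n = 1e4) {
  Gf <- rnorm(n); Gm <- rnorm(n); Mid <- (Gf + Gm) / 2
  Gc <- Mid + rnorm(n, 0, sqrt(0.5))
  L <- sqrt(h2) * Gc + sqrt(1 - h2) * rnorm(n)
  sel <- L > qnorm(1 - q)
  d <- (Gc[sel] - Mid[sel]) / sd(Mid[sel])
  c(mean = mean(d), se = sd(d) / sqrt(length(d)))
}

# Clustered binary data with exact marginal logistic model
# P(y=1|x) = plogis(b0 + b1*x) and within-family dependence induced by a
# Gaussian copula (exchangeable latent correlation rho).
sim_clustered_logistic <- function(n_fam, p_sib = 0.25, b0 = -1,
                                   b1 = log(1.5), rho = 0.5) {
  sizes <- 1 + rbinom(n_fam, 1, p_sib)
  fam <- rep(seq_len(n_fam), sizes)
  n <- length(fam)
  x <- rnorm(n)
  p <- plogis(b0 + b1 * x)
  u_f <- rnorm(n_fam)
  z <- sqrt(rho) * u_f[fam] + sqrt(1 - rho) * rnorm(n)
  y <- as.integer(pnorm(z) < p)
  data.frame(y = y, x = x, family_id = paste0("f", fam))
}
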