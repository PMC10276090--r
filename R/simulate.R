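#' Simulation configuration for synthetic trio cohorts
#'
#' Defines the generative model: unlinked biallelic variants in
#' Hardy-Weinberg/linkage equilibrium, random-mating parents, Mendelian
#' transmission to one child per family, a liability-threshold ascertainment
#' step on the child (liability = scaled true PGS + independent normal
#' environment), binary comorbid outcomes driven logistically by the child's
#' standardized true PGS, and a noisy discovery GWAS emitting per-variant
#' log-OR weights and p-values.
#'
#' @param n_trios Number of complete trios per cohort.
#' @param n_variants Number of simulated variants.
#' @param maf_range Range the per-variant allele frequency is drawn from.
#' @param n_causal Number of causal variants (must be >= 1 when
#'   \code{h2_pgs > 0}).
#' @param h2_pgs Fraction of liability variance explained by the causal
#'   variants, in [0, 1).
#' @param ascertainment_quantile Probands are retained when their liability
#'   exceeds the (1 - q) population quantile; q = 1 disables ascertainment.
#' @param outcomes List of outcome definitions, each a list with
#'   \code{name}, \code{intercept} (log-odds) and \code{beta} (log-odds per
#'   SD of true PGS).
#' @param n_cohorts Number of cohorts generated by
#'   \code{\link{simulate_cohorts}}.
#' @param missing_rate Completely-at-random dosage missingness in [0, 1).
#' @param discovery_n Effective discovery-GWAS sample size controlling the
#'   sampling noise of the emitted weights (per-variant SE
#'   \eqn{1/\sqrt{2 N p (1-p)}}); \code{Inf} gives noise-free weights.
#' @param sib_families Number of families given a second child (sibling),
#'   to exercise family-clustered analyses.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_trios = 328, n_variants = 1000,
                       maf_range = c(0.05, 0.5), n_causal = 200,
                       h2_pgs = 0.3, ascertainment_quantile = 0.05,
                       outcomes = list(list(name = "insomnia",
                                            intercept = -1.0,
                                            beta = log(1.5))),
                       n_cohorts = 1, missing_rate = 0,
                       discovery_n = 1e5, sib_families = 0,
                       seed = 1) {
  cfg <- list(n_trios = as.integer(n_trios),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              n_causal = as.integer(n_causal),
              h2_pgs = as.numeric(h2_pgs),
              ascertainment_quantile = as.numeric(ascertainment_quantile),
              outcomes = outcomes, n_cohorts = as.integer(n_cohorts),
              missing_rate = as.numeric(missing_rate),
              discovery_n = discovery_n,
              sib_families = as.integer(sib_families),
              seed = as.integer(seed))
  stopifnot(cfg$n_trios >= 1, cfg$n_variants >= 1,
            length(cfg$maf_range) == 2,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$n_causal >= 0, cfg$n_causal <= cfg$n_variants,
            cfg$h2_pgs >= 0, cfg$h2_pgs < 1,
            cfg$ascertainment_quantile > 0,
            cfg$ascertainment_quantile <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
              cfg$n_cohorts >= 1, cfg$sib_families >= 0)
  if (cfg$h2_pgs > 0 && cfg$n_causal < 1)
    stop("n_causal must be >= 1 when h2_pgs > 0")
  for (oc in cfg$outcomes) {
    if (is.null(oc$name) || is.null(oc$intercept) || is.null(oc$beta))
      stop("each outcome needs name, intercept and beta")
    if (!is.finite(oc$intercept))
      stop("outcome '", oc$name, "' has a non-finite intercept")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Variant map: allele frequencies and true per-allele effects scaled so the
# genetic variance of the raw PGS equals h2_pgs.
make_variant_map <- function(cfg) {
  m <- cfg$n_variants
  afreq <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  # strand-unambiguous ref/alt pairs by construction: synthetic variants
  # carry no strand uncertainty, so A/T and C/G pairs are never emitted
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(seq_len(m), function(i) {
    sample(setdiff(bases, c(ref[i], comp[[ref[i]]])), 1)
  }, character(1))
  beta <- numeric(m)
  causal <- rep(FALSE, m)
  if (cfg$n_causal > 0 && cfg$h2_pgs > 0) {
    causal[sample.int(m, cfg$n_causal)] <- TRUE
    raw <- rnorm(cfg$n_causal)
    vg <- sum(raw^2 * 2 * afreq[causal] * (1 - afreq[causal]))
    beta[causal] <- raw * sqrt(cfg$h2_pgs / vg)
  }
  data.frame(variant_id = sprintf("var%05d", seq_len(m)),
             chrom = as.character(1 + (seq_len(m) - 1) %% 22),
             pos = 10000L + seq_len(m) * 1000L,
             ref = unname(ref), alt = unname(alt),
             afreq_pop = afreq, beta_true = beta, causal = causal,
             stringsAsFactors = FALSE)
}

#' Simulate unrelated parental genotypes
#'
#' Each dosage is an independent Binomial(2, p_j) draw (random mating,
#' Hardy-Weinberg and linkage equilibrium).
#' @param n Number of individuals.
#' @param afreq Vector of alt-allele frequencies.
#' @return n x length(afreq) dosage matrix.
#' @export
simulate_parents <- function(n, afreq) {
  m <- length(afreq)
  matrix(rbinom(n * m, 2, rep(afreq, each = n)), nrow = n, ncol = m)
}

#' Mendelian transmission from two parents
#'
#' One allele is drawn uniformly from each parent's pair; the child dosage
#' is their sum. Missing parental dosages yield missing child dosages.
#' @param father,mother Dosage matrices (or vectors) with values 0/1/2/NA.
#' @return Child dosage matrix of the same shape.
#' @export
transmit <- function(father, mother) {
  f <- as.matrix(father); m <- as.matrix(mother)
  stopifnot(all(dim(f) == dim(m)))
  draw <- function(d) {
    a <- matrix(NA_real_, nrow(d), ncol(d))
    a[!is.na(d)] <- 0
    a[which(d == 2)] <- 1
    het <- !is.na(d) & d == 1
    a[het] <- rbinom(sum(het), 1, 0.5)
    a
  }
  draw(f) + draw(m)
}

# Standardized true PGS for a dosage matrix given the variant map:
# centered by 2*p*beta and scaled by the theoretical population SD.
true_pgs <- function(dos, vmap) {
  g <- as.vector(dos %*% vmap$beta_true)
  mu <- sum(2 * vmap$afreq_pop * vmap$beta_true)
  s2 <- sum(vmap$beta_true^2 * 2 * vmap$afreq_pop * (1 - vmap$afreq_pop))
  if (s2 == 0) return(g * 0)
  (g - mu) / sqrt(s2)
}

#' Simulate one ascertained trio cohort
#'
#' Generates parents, transmits genotypes to candidate children, computes
#' each child's liability (\eqn{\sqrt{h^2}\,} standardized true PGS +
#' \eqn{\sqrt{1-h^2}\,} N(0,1)), retains trios whose child liability
#' exceeds the (1 - q) population quantile until \code{n_trios} are
#' collected (regenerating in batches if needed), simulates binary
#' outcomes and covariates for the probands, emits discovery summary
#' statistics, and injects completely-at-random missingness.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param seed Optional override of \code{cfg$seed}.
#' @param cohort_label Label attached to the cohort.
#' @return A list of class \code{trio_cohort}: \code{panel}
#'   (\code{genotype_panel} of fathers, mothers and children),
#'   \code{phenotypes}, \code{sumstats} (\code{pgs_sumstats}),
#'   \code{truth} (true PGS and liability per child), \code{variant_map},
#'   \code{config}.
#' @export
simulate_trio_cohort <- function(cfg, seed = NULL,
                                 cohort_label = "cohort1") {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  set.seed(cfg$seed)
  vmap <- make_variant_map(cfg)
  q <- cfg$ascertainment_quantile
  thr <- if (q >= 1) -Inf else qnorm(1 - q)

  n_need <- cfg$n_trios
  batch <- max(50L, ceiling(n_need / q * 1.3))
  fa_l <- mo_l <- ch_l <- list()
  tp_l <- li_l <- list()
  got <- 0L; tries <- 0L
  while (got < n_need) {
    tries <- tries + 1L
    if (tries > 50L) stop("ascertainment failed to collect enough trios")
    fa <- simulate_parents(batch, vmap$afreq_pop)
    mo <- simulate_parents(batch, vmap$afreq_pop)
    ch <- transmit(fa, mo)
    tp <- true_pgs(ch, vmap)
    li <- sqrt(cfg$h2_pgs) * tp +
      sqrt(1 - cfg$h2_pgs) * rnorm(batch)
    keep <- which(li > thr)
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), n_need - got))]
      fa_l[[tries]] <- fa[take, , drop = FALSE]
      mo_l[[tries]] <- mo[take, , drop = FALSE]
      ch_l[[tries]] <- ch[take, , drop = FALSE]
      tp_l[[tries]] <- tp[take]; li_l[[tries]] <- li[take]
      got <- got + length(take)
    }
  }
  fa <- do.call(rbind, fa_l); mo <- do.call(rbind, mo_l)
  ch <- do.call(rbind, ch_l)
  tp <- unlist(tp_l); li <- unlist(li_l)
  n <- cfg$n_trios

  fam <- sprintf("fam%04d", seq_len(n))
  fid <- paste0(fam, "_fa"); mid <- paste0(fam, "_mo")
  cid <- paste0(fam, "_ch")

  # optional extra sibling in the first sib_families families
  nsib <- min(cfg$sib_families, n)
  if (nsib > 0) {
    sib <- transmit(fa[seq_len(nsib), , drop = FALSE],
                    mo[seq_len(nsib), , drop = FALSE])
    sib_tp <- true_pgs(sib, vmap)
    sid <- paste0(fam[seq_len(nsib)], "_sib")
  }

  dos <- rbind(fa, mo, ch)
  ids <- c(fid, mid, cid)
  roles <- rep(c("father", "mother", "proband"), each = n)
  fams <- rep(fam, 3)
  fathers <- c(rep("0", 2 * n), fid)
  mothers <- c(rep("0", 2 * n), mid)
  child_tp <- tp
  if (nsib > 0) {
    dos <- rbind(dos, sib)
    ids <- c(ids, sid)
    roles <- c(roles, rep("sibling", nsib))
    fams <- c(fams, fam[seq_len(nsib)])
    fathers <- c(fathers, fid[seq_len(nsib)])
    mothers <- c(mothers, mid[seq_len(nsib)])
  }
  rownames(dos) <- ids
  colnames(dos) <- vmap$variant_id

  if (cfg$missing_rate > 0) {
    nmiss <- rbinom(1, length(dos), cfg$missing_rate)
    if (nmiss > 0) dos[sample.int(length(dos), nmiss)] <- NA_real_
  }

  n_batches <- 3L
  samples <- data.frame(
    sample_id = ids, family_id = fams, father_id = fathers,
    mother_id = mothers, role = roles,
    sex = ifelse(roles == "father", 1L,
                 ifelse(roles == "mother", 2L,
                        sample(1:2, length(ids), replace = TRUE,
                               prob = c(0.85, 0.15)))),
    batch = paste0("batch", sample.int(n_batches, length(ids),
                                       replace = TRUE)),
    stringsAsFactors = FALSE)

  variants <- data.frame(variant_id = vmap$variant_id, chrom = vmap$chrom,
                         pos = vmap$pos, ref = vmap$ref, alt = vmap$alt,
                         stringsAsFactors = FALSE)
  panel <- genotype_panel(dos, samples, variants, validate = FALSE)

  child_ids <- c(cid, if (nsib > 0) sid)
  child_scores <- c(tp, if (nsib > 0) sib_tp)
  phe <- simulate_outcomes(cfg, child_ids, child_scores,
                           samples[match(child_ids, samples$sample_id), ])

  ss <- emit_discovery_sumstats(cfg, vmap)
  truth <- data.frame(sample_id = child_ids, true_pgs = child_scores,
                      liability = c(li, rep(NA_real_, length(child_ids) - n)),
                      stringsAsFactors = FALSE)
  structure(list(panel = panel, phenotypes = phe, sumstats = ss,
                 truth = truth, variant_map = vmap, config = cfg,
                 cohort_label = cohort_label),
            class = "trio_cohort")
}

#' Simulate binary outcomes and covariates for children
#'
#' Outcome probability is \code{plogis(intercept + beta * true PGS)} with
#' the true PGS on the standardized population scale. Also simulates age,
#' medication flags, and a parent-reported copy of each outcome (the parent
#' misses a reported symptom with probability 0.1), to support the
#' sensitivity-analysis modes.
#'
#' @param cfg A \code{sim_config}.
#' @param sample_ids Child sample IDs.
#' @param true_pgs Standardized true PGS per child.
#' @param samples Matching rows of the panel sample table (for sex, batch,
#'   family).
#' @return Phenotype data frame keyed by \code{sample_id}.
#' @export
simulate_outcomes <- function(cfg, sample_ids, true_pgs, samples) {
  n <- length(sample_ids)
  phe <- data.frame(sample_id = sample_ids,
                    family_id = samples$family_id,
                    age = round(runif(n, 5, 18), 1),
                    sex = samples$sex,
                    batch = samples$batch,
                    adhd_medication = rbinom(n, 1, 0.3),
                    sleep_medication = rbinom(n, 1, 0.15),
                    stringsAsFactors = FALSE)
  for (oc in cfg$outcomes) {
    p <- plogis(oc$intercept + oc$beta * true_pgs)
    y <- rbinom(n, 1, p)
    phe[[oc$name]] <- y
    phe[[paste0(oc$name, "_parent")]] <- y * rbinom(n, 1, 0.9)
  }
  phe
}

#' Emit noisy discovery summary statistics
#'
#' Each estimated weight is the true per-allele effect plus normal noise
#' with the standard GWAS-regression standard error
#' \eqn{1/\sqrt{2 N p (1-p)}} at the configured effective discovery sample
#' size; p-values are two-sided normal p-values of the weight/SE z-score.
#' With \code{discovery_n = Inf} weights equal the true effects, causal
#' p-values are set to 1e-300 and null p-values drawn uniformly.
#'
#' @param cfg A \code{sim_config}.
#' @param vmap Variant map from the same simulation (internal layout).
#' @return A \code{pgs_sumstats} data frame, oriented to the panel's alt
#'   allele (effect allele = alt).
#' @export
emit_discovery_sumstats <- function(cfg, vmap) {
  m <- nrow(vmap)
  se <- 1 / sqrt(2 * cfg$discovery_n * vmap$afreq_pop *
                   (1 - vmap$afreq_pop))
  if (is.infinite(cfg$discovery_n)) {
    w <- vmap$beta_true
    p <- ifelse(vmap$causal, 1e-300, runif(m))
  } else {
    w <- vmap$beta_true + rnorm(m, 0, se)
    z <- w / se
    p <- 2 * pnorm(-abs(z))
    p[p <= 0] <- .Machine$double.xmin
  }
  ss <- data.frame(variant_id = vmap$variant_id, chrom = vmap$chrom,
                   pos = vmap$pos, effect_allele = vmap$alt,
                   other_allele = vmap$ref, weight = w, pvalue = p,
                   eaf = vmap$afreq_pop, stringsAsFactors = FALSE)
  class(ss) <- c("pgs_sumstats", "data.frame")
  ss
}

#' Simulate several cohorts from one configuration
#'
#' Cohort k uses seed \code{cfg$seed + 1000 * k} so cohorts are independent
#' but jointly reproducible.
#' @param cfg A \code{sim_config}.
#' @return List of \code{trio_cohort} objects of length \code{n_cohorts}.
#' @export
simulate_cohorts <- function(cfg) {
  lapply(seq_len(cfg$n_cohorts), function(k)
    simulate_trio_cohort(cfg, seed = (cfg$seed + 1000L * k) %%
                           .Machine$integer.max,
                         cohort_label = paste0("cohort", k)))
}

#' Check Mendelian consistency of a trio panel
#'
#' For every (child, variant) pair with all three dosages observed, the
#' child dosage must be attainable from one allele per parent: at least
#' the number of homozygous-alt parents and at most the number of parents
#' carrying any alt allele.
#'
#' @param panel A \code{genotype_panel} with pedigree roles.
#' @return List with \code{n_checked}, \code{n_consistent},
#'   \code{fraction_consistent}.
#' @export
mendelian_consistency <- function(panel) {
  s <- panel$samples
  d <- panel$dosages
  kids <- which(s$role %in% c("proband", "sibling"))
  n_checked <- 0L; n_ok <- 0L
  fa_idx <- match(s$father_id[kids], s$sample_id)
  mo_idx <- match(s$mother_id[kids], s$sample_id)
  for (i in seq_along(kids)) {
    if (is.na(fa_idx[i]) || is.na(mo_idx[i])) next
    cd <- d[kids[i], ]; fd <- d[fa_idx[i], ]; md <- d[mo_idx[i], ]
    ok_obs <- !is.na(cd) & !is.na(fd) & !is.na(md)
    lo <- (fd == 2) + (md == 2)
    hi <- (fd >= 1) + (md >= 1)
    good <- ok_obs & cd >= lo & cd <= hi
    n_checked <- n_checked + sum(ok_obs)
    n_ok <- n_ok + sum(good, na.rm = TRUE)
  }
  list(n_checked = n_checked, n_consistent = n_ok,
       fraction_consistent = if (n_checked) n_ok / n_checked else NA_real_)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes genotypes (\code{.traw} or \code{.vcf}), a FAM-like pedigree,
#' phenotype and sumstats TSVs, and a truth table (true PGS, liability).
#' @param cohort A \code{trio_cohort}.
#' @param dir Output directory (created if needed).
#' @param format \code{"traw"} or \code{"vcf"}.
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir, format = c("traw", "vcf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, paste0("genotypes.", format)),
    pedigree = file.path(dir, "pedigree.fam.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    sumstats = file.path(dir, "sumstats.tsv"),
    truth = file.path(dir, "truth.tsv"))
  if (format == "traw") write_traw(cohort$panel, paths["genotypes"])
  else write_vcf(cohort$panel, paths["genotypes"])
  write_fam(cohort$panel, paths["pedigree"])
  write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_sumstats(cohort$sumstats, paths["sumstats"])
  write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
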