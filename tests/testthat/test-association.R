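# data for closed-form checks: 2x2 table (a,b,c,d) = (10,40,20,30),
# OR = (10*30)/(40*20) = 0.375
table_data <- function() {
  data.frame(
    y = c(rep(1, 10), rep(1, 40), rep(0, 20), rep(0, 30)),
    x = c(rep(1, 10), rep(0, 40), rep(1, 20), rep(0, 30)),
    sample_id = paste0("s", 1:100),
    family_id = paste0("f", 1:100))
}

test_that("logistic beta reproduces the 2x2 contingency closed form", {
  d <- table_data()
  a <- pgs_assoc("y", "x", d, covariates = character(0),
                 cluster = "family_id", standardize = FALSE)
  expect_equal(a$beta, log(0.375), tolerance = 1e-8)
  expect_equal(a$odds_ratio, 0.375, tolerance = 1e-8)
})

test_that("intercept-only fit recovers the logit of the prevalence", {
  d <- table_data()  # prevalence 0.5 overall; use the reference fit
  a <- pgs_assoc("y", "x", d, covariates = character(0),
                 cluster = "family_id", standardize = FALSE)
  expect_equal(unname(coef(a$fit_ref)), log(0.5 / 0.5), tolerance = 1e-8)
  d2 <- d; d2$y <- rep(c(1, 0, 0, 0), 25)
  a2 <- pgs_assoc("y", "x", d2, covariates = character(0),
                  cluster = "family_id", standardize = FALSE)
  expect_equal(unname(coef(a2$fit_ref)), log(1 / 3), tolerance = 1e-8)
})

test_that("clustered coefficients equal the plain logistic MLE", {
  set.seed(51)
  d <- sim_clustered_logistic(150)
  d$sample_id <- paste0("s", seq_len(nrow(d)))
  a <- pgs_assoc("y", "x", d, covariates = character(0),
                 cluster = "family_id", standardize = FALSE)
  ref <- glm(y ~ x, data = d, family = binomial())
  expect_equal(unname(coef(a$fit)), unname(coef(ref)), tolerance = 1e-8)
})

test_that("singleton-cluster sandwich equals the HC0 oracle", {
  set.seed(52)
  n <- 120
  d <- data.frame(y = rbinom(n, 1, 0.4), x = rnorm(n), z = rnorm(n))
  fit <- glm(y ~ x + z, data = d, family = binomial())
  V <- cluster_sandwich(fit, seq_len(n))
  # brute-force HC0: A^-1 (sum_i r_i^2 x_i x_i^T) A^-1
  X <- model.matrix(fit); mu <- fitted(fit); r <- d$y - mu
  A <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    xi <- X[i, ]
    A <- A + mu[i] * (1 - mu[i]) * tcrossprod(xi)
    B <- B + r[i]^2 * tcrossprod(xi)
  }
  V_oracle <- solve(A) %*% B %*% solve(A)
  expect_equal(unname(V), unname(V_oracle), tolerance = 1e-10)
})

test_that("sandwich agrees with the sandwich package's vcovCL", {
  skip_if_not_installed("sandwich")
  set.seed(53)
  d <- sim_clustered_logistic(100)
  fit <- glm(y ~ x, data = d, family = binomial())
  V <- cluster_sandwich(fit, d$family_id)
  V_pkg <- sandwich::vcovCL(fit, cluster = d$family_id, type = "HC0",
                            cadjust = FALSE)
  # bread() reuses the final IRLS working weights, so agreement is limited
  # by glm's convergence tolerance rather than exact arithmetic
  expect_equal(unname(V), unname(V_pkg), tolerance = 1e-5)
})

test_that("pairing duplicated rows doubles the robust variance", {
  set.seed(54)
  n <- 80
  d <- data.frame(y = rbinom(n, 1, 0.5), x = rnorm(n))
  d2 <- rbind(d, d)
  pair_id <- rep(seq_len(n), 2)
  fit <- glm(y ~ x, data = d2, family = binomial())
  V_clustered <- cluster_sandwich(fit, pair_id)
  V_singleton <- cluster_sandwich(fit, seq_len(2 * n))
  expect_equal(unname(V_clustered), unname(2 * V_singleton),
               tolerance = 1e-10)
})

test_that("a single all-encompassing cluster is an error", {
  d <- table_data()
  fit <- glm(y ~ x, data = d, family = binomial())
  expect_error(cluster_sandwich(fit, rep("all", 100)), "one cluster")
})

test_that("Nagelkerke delta R2 follows the likelihood formula exactly", {
  set.seed(55)
  n <- 400
  x <- rnorm(n); z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x + 0.3 * z))
  full <- glm(y ~ x + z, family = binomial())
  null <- glm(y ~ z, family = binomial())
  ref <- glm(y ~ 1, family = binomial())
  ll_f <- as.numeric(logLik(full)); ll_n <- as.numeric(logLik(null))
  ll_r <- as.numeric(logLik(ref))
  got <- nagelkerke_delta(ll_n, ll_f, ll_r, n)
  nag <- function(ll) (1 - exp(2 / n * (ll_r - ll))) /
    (1 - exp(2 / n * ll_r))
  expect_equal(got, nag(ll_f) - nag(ll_n), tolerance = 1e-12)
  expect_gte(got, 0); expect_lte(got, 1)
})

test_that("Nagelkerke delta is 0 for identical models and 1 at the bound", {
  expect_equal(nagelkerke_delta(-50, -50, -80, 100), 0)
  expect_equal(nagelkerke_r2(0, -60, 100), 1)
  expect_error(nagelkerke_delta(-50, -60, -80, 100), "below null")
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(0.001, 0.9)), c(0.002, 0.9))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  set.seed(56)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
  }
})

test_that("per-SD odds ratio is invariant to predictor rescaling", {
  set.seed(57)
  d <- sim_clustered_logistic(200)
  d$sample_id <- paste0("s", seq_len(nrow(d)))
  a1 <- pgs_assoc("y", "x", d, covariates = character(0),
                  cluster = "family_id")
  d$x <- d$x * 3.7
  a2 <- pgs_assoc("y", "x", d, covariates = character(0),
                  cluster = "family_id")
  expect_equal(a2$odds_ratio, a1$odds_ratio, tolerance = 1e-10)
  expect_equal(a2$pvalue, a1$pvalue, tolerance = 1e-10)
})

test_that("a simulated per-SD odds ratio of 1.5 is recovered at n = 5000", {
  set.seed(58)
  n <- 5000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + log(1.5) * x))
  d <- data.frame(y = y, x = x, sample_id = paste0("s", 1:n),
                  family_id = paste0("f", 1:n))
  a <- pgs_assoc("y", "x", d, covariates = character(0),
                 cluster = "family_id")
  expect_lt(abs(a$beta - log(1.5)), 3 * a$robust_se)
})

test_that("sensitivity modes behave as filters and covariate additions", {
  set.seed(59)
  cfg <- sim_config(n_trios = 400, n_variants = 50, n_causal = 20,
                    ascertainment_quantile = 1, seed = 59)
  co <- simulate_trio_cohort(cfg)
  d <- co$phenotypes
  d$pgs <- co$truth$true_pgs[match(d$sample_id, co$truth$sample_id)]
  base_args <- list(outcome = "insomnia", predictor = "pgs",
                    covariates = c("age"), cluster = "family_id")

  # (c) is vacuous when nobody takes sleep medication
  d_none <- d; d_none$sleep_medication <- 0
  a_plain <- do.call(pgs_assoc, c(base_args, list(data = d_none)))
  a_c <- do.call(pgs_assoc, c(base_args, list(
    data = d_none, sensitivity = "exclude_sleep_medicated")))
  expect_equal(a_c$beta, a_plain$beta, tolerance = 1e-12)
  expect_equal(a_c$n, a_plain$n)

  # (c) drops medicated children otherwise
  a_c2 <- do.call(pgs_assoc, c(base_args, list(
    data = d, sensitivity = "exclude_sleep_medicated")))
  expect_equal(a_c2$n, sum(d$sleep_medication == 0))

  # (b) adds sex and ADHD medication to the model
  a_b <- do.call(pgs_assoc, c(base_args, list(
    data = d, sensitivity = "extra_covariates")))
  expect_true(all(c("sex", "adhd_medication") %in%
                    names(coef(a_b$fit))))

  # (a) swaps in the parent-reported outcome
  a_a <- do.call(pgs_assoc, c(base_args, list(
    data = d, sensitivity = "parent_report_only")))
  ref <- glm(insomnia_parent ~ I(pgs / sd(pgs)) + age, data = d,
             family = binomial())
  expect_equal(a_a$beta, unname(coef(ref)[2]), tolerance = 1e-8)
})

test_that("an association battery of one test leaves its p-value unadjusted", {
  set.seed(60)
  d <- sim_clustered_logistic(150)
  d$sample_id <- paste0("s", seq_len(nrow(d)))
  specs <- data.frame(predictor = "x", outcome = "y",
                      stringsAsFactors = FALSE)
  out <- assoc_battery(specs, d, covariates = character(0),
                       cluster = "family_id")
  expect_equal(nrow(out), 1)
  expect_equal(out$p_fdr, out$p)
  expect_error(assoc_battery(list(), d), "empty")
})

test_that("battery results carry BH-corrected p-values and per-test n", {
  set.seed(61)
  cfg <- sim_config(n_trios = 300, n_variants = 40, n_causal = 10,
                    ascertainment_quantile = 1,
                    outcomes = list(
                      list(name = "insomnia", intercept = -1, beta = 0.3),
                      list(name = "hypersomnia", intercept = -2, beta = 0),
                      list(name = "restless", intercept = -0.5, beta = 0.1)),
                    seed = 61)
  co <- simulate_trio_cohort(cfg)
  d <- co$phenotypes
  d$pgs <- co$truth$true_pgs[match(d$sample_id, co$truth$sample_id)]
  d$insomnia[1:10] <- NA
  specs <- data.frame(predictor = "pgs",
                      outcome = c("insomnia", "hypersomnia", "restless"),
                      stringsAsFactors = FALSE)
  out <- assoc_battery(specs, d, covariates = c("age"),
                       cluster = "family_id")
  expect_equal(out$p_fdr, p.adjust(out$p, "BH"))
  expect_equal(out$n[1], 290)
  expect_equal(out$n[2], 300)
  expect_true(all(out$delta_r2 >= 0 & out$delta_r2 <= 1))
})

test_that("constant outcomes and separation are caught", {
  d <- data.frame(y = rep(0, 50), x = rnorm(50),
                  sample_id = paste0("s", 1:50),
                  family_id = paste0("f", 1:50))
  expect_error(pgs_assoc("y", "x", d, covariates = character(0)),
               "constant")
  d2 <- data.frame(y = rep(c(0, 1), each = 25),
                   x = c(rnorm(25, -5), rnorm(25, 5)),
                   sample_id = paste0("s", 1:50),
                   family_id = paste0("f", 1:50))
  expect_error(suppressWarnings(
    pgs_assoc("y", "x", d2, covariates = character(0))), "separation")
})
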