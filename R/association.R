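#' Family-clustered sandwich covariance for a logistic fit
#'
#' GEE-style robust covariance under an independence working correlation:
#' coefficients are the ordinary logistic MLE, and the covariance is
#' \eqn{A^{-1} B A^{-1}} with \eqn{A} the observed information and
#' \eqn{B = \sum_c g_c g_c^\top}, \eqn{g_c = \sum_{i \in c} x_i (y_i -
#' \hat\mu_i)} summed within each cluster. With every cluster a singleton
#' this is the HC0 heteroscedasticity-robust estimator.
#'
#' @param fit A \code{glm} fit with \code{family = binomial()}.
#' @param cluster Cluster identifier per row of the fitted data.
#' @return Robust covariance matrix of the coefficients.
#' @export
cluster_sandwich <- function(fit, cluster) {
  X <- model.matrix(fit)
  y <- fit$y
  mu <- fitted(fit)
  if (length(cluster) != nrow(X))
    stop("cluster vector length does not match the fitted rows")
  cluster <- as.character(cluster)
  if (length(unique(cluster)) < 2)
    stop("all rows fall in one cluster; no replication to estimate from")
  w <- mu * (1 - mu)
  A <- crossprod(X, X * w)
  G <- rowsum(X * (y - mu), cluster)
  B <- crossprod(G)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Nagelkerke pseudo R-squared
#'
#' \eqn{R^2 = [1 - \exp((2/n)(LL_{ref} - LL_{model}))] /
#' [1 - \exp((2/n) LL_{ref})]}, with the intercept-only model as the
#' reference.
#' @param ll_model Log-likelihood of the model.
#' @param ll_ref Log-likelihood of the reference (intercept-only) model.
#' @param n Number of observations.
#' @return R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(ll_model, ll_ref, n) {
  cs <- 1 - exp((2 / n) * (ll_ref - ll_model))
  denom <- 1 - exp((2 / n) * ll_ref)
  if (denom <= 0) return(0)
  max(0, min(1, cs / denom))
}

#' Nagelkerke delta R-squared between null and full models
#'
#' Difference of the full (covariates + PGS) and null (covariates-only)
#' Nagelkerke R-squared, both against the intercept-only reference.
#' @param ll_null Log-likelihood of the covariates-only model.
#' @param ll_full Log-likelihood of the full model.
#' @param ll_ref Log-likelihood of the intercept-only reference model.
#' @param n Number of observations.
#' @param tol Tolerance for \code{ll_full < ll_null} (a larger violation
#'   indicates a fitting problem and is an error).
#' @return Delta R-squared, bounded to [0, 1].
#' @export
nagelkerke_delta <- function(ll_null, ll_full, ll_ref, n, tol = 1e-6) {
  if (ll_full < ll_null - tol)
    stop("full-model log-likelihood below null model; fit problem")
  max(0, nagelkerke_r2(ll_full, ll_ref, n) -
        nagelkerke_r2(ll_null, ll_ref, n))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1).
#' @param pvalues Vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order; empty in, empty out.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

check_separation <- function(fit) {
  if (!fit$converged)
    stop("logistic fit did not converge (", fit$iter, " iterations)")
  co <- coef(fit)
  big <- abs(co) > 15
  mu <- fitted(fit)
  if (any(big) && (any(mu < 1e-8) || any(mu > 1 - 1e-8)))
    stop("(quasi-)separation detected for coefficient(s): ",
         paste(names(co)[big], collapse = ", "))
  invisible(fit)
}

#' Case-only logistic association of a PGS with a binary outcome
#'
#' Fits \code{outcome ~ PGS + covariates} by maximum-likelihood logistic
#' regression on complete cases, with the PGS standardized to SD 1 so the
#' odds ratio is per SD, and corrects the standard errors for family
#' clustering with the GEE-independence sandwich estimator. Reports the
#' per-SD odds ratio with robust 95\% CI, robust Wald p-value, and the
#' Nagelkerke delta R-squared between the covariates-only and full models.
#'
#' Sensitivity modes mirror the usual robustness checks in clinical PGS
#' analyses: \code{parent_report_only} substitutes the parent-reported
#' outcome column (\code{<outcome>_parent}); \code{extra_covariates} adds
#' sex and ADHD-medication status to the covariates;
#' \code{exclude_sleep_medicated} drops children on sleep medication.
#'
#' @param outcome Name of the binary outcome column.
#' @param predictor Name of the PGS column (or a named numeric vector
#'   merged in by sample_id).
#' @param data Data frame with outcome, predictor, covariates and cluster
#'   columns.
#' @param covariates Covariate column names (default: top 5 ancestry PCs,
#'   batch, age).
#' @param cluster Cluster (family) column name, or NULL for independent
#'   rows.
#' @param sensitivity One of \code{"none"}, \code{"parent_report_only"},
#'   \code{"extra_covariates"}, \code{"exclude_sleep_medicated"}.
#' @param standardize Standardize the predictor to SD 1 (default TRUE).
#' @param r2_reference Reference model for the Nagelkerke difference:
#'   \code{"intercept"} (default: full-vs-intercept minus
#'   null-vs-intercept) or \code{"null"} (full vs covariates-only).
#' @param ci_quantile \code{"normal"} (1.96) or \code{"t"} quantile for
#'   the 95\% CI on the log-odds scale.
#' @return Object of class \code{pgs_assoc} with fields \code{n},
#'   \code{beta}, \code{robust_se}, \code{odds_ratio}, \code{ci_low},
#'   \code{ci_high}, \code{pvalue}, \code{nagelkerke_delta_r2}, the three
#'   \code{glm} fits, and the call metadata.
#' @export
pgs_assoc <- function(outcome, predictor, data,
                      covariates = c(paste0("PC", 1:5), "batch", "age"),
                      cluster = "family_id",
                      sensitivity = c("none", "parent_report_only",
                                      "extra_covariates",
                                      "exclude_sleep_medicated"),
                      standardize = TRUE,
                      r2_reference = c("intercept", "null"),
                      ci_quantile = c("normal", "t")) {
  sensitivity <- match.arg(sensitivity)
  r2_reference <- match.arg(r2_reference)
  ci_quantile <- match.arg(ci_quantile)

  if (is.numeric(predictor) && !is.null(names(predictor))) {
    data$.pgs <- unname(predictor[data$sample_id])
    predictor_col <- ".pgs"
    predictor_name <- "pgs"
  } else {
    predictor_col <- predictor
    predictor_name <- predictor
    if (!predictor_col %in% names(data))
      stop("predictor column '", predictor_col, "' not in data")
  }

  used_outcome <- outcome
  if (sensitivity == "parent_report_only") {
    used_outcome <- paste0(outcome, "_parent")
    if (!used_outcome %in% names(data))
      stop("parent-report column '", used_outcome, "' not in data")
  }
  if (sensitivity == "extra_covariates")
    covariates <- unique(c(covariates, "sex", "adhd_medication"))
  if (sensitivity == "exclude_sleep_medicated") {
    if (!"sleep_medication" %in% names(data))
      stop("sleep_medication column required for this sensitivity mode")
    data <- data[!is.na(data$sleep_medication) &
                   data$sleep_medication == 0, , drop = FALSE]
  }

  need <- c(used_outcome, predictor_col, covariates,
            if (!is.null(cluster)) cluster)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("column(s) missing from data: ",
                         paste(miss, collapse = ", "))
  cc <- complete.cases(data[, need, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < 2) stop("fewer than 2 complete cases for ", outcome)
  y <- d[[used_outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome '", used_outcome,
                                 "' is not binary 0/1")
  if (length(unique(y)) < 2)
    stop("outcome '", used_outcome, "' is constant in the analyzed rows")

  x <- d[[predictor_col]]
  if (standardize) x <- x / sd(x)
  d$.x_std <- x

  cov_terms <- if (length(covariates))
    paste(covariates, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste0(used_outcome, " ~ .x_std + ",
                                     cov_terms))
  f_null <- stats::as.formula(paste0(used_outcome, " ~ ", cov_terms))
  f_ref <- stats::as.formula(paste0(used_outcome, " ~ 1"))
  fit <- glm(f_full, data = d, family = binomial())
  check_separation(fit)
  fit_null <- glm(f_null, data = d, family = binomial())
  fit_ref <- glm(f_ref, data = d, family = binomial())

  V <- if (is.null(cluster)) cluster_sandwich(fit, seq_len(n))
       else cluster_sandwich(fit, d[[cluster]])
  beta <- coef(fit)[".x_std"]
  se <- sqrt(V[".x_std", ".x_std"])
  qv <- if (ci_quantile == "normal") qnorm(0.975)
        else qt(0.975, df = n - length(coef(fit)))
  p <- 2 * pnorm(-abs(beta / se))
  ll_ref <- if (r2_reference == "intercept") as.numeric(logLik(fit_ref))
            else as.numeric(logLik(fit_null))
  dr2 <- nagelkerke_delta(as.numeric(logLik(fit_null)),
                          as.numeric(logLik(fit)), ll_ref, n)
  structure(list(outcome = outcome, predictor = predictor_name,
                 sensitivity = sensitivity, n = n,
                 beta = unname(beta), robust_se = unname(se),
                 odds_ratio = exp(unname(beta)),
                 ci_low = exp(unname(beta - qv * se)),
                 ci_high = exp(unname(beta + qv * se)),
                 pvalue = unname(p), nagelkerke_delta_r2 = dr2,
                 fit = fit, fit_null = fit_null, fit_ref = fit_ref,
                 robust_vcov = V, covariates = covariates),
            class = "pgs_assoc")
}

#' @export
print.pgs_assoc <- function(x, ...) {
  cat("Case-only PGS association (family-clustered sandwich SEs)\n")
  cat(sprintf("  %s ~ %s  (n = %d%s)\n", x$outcome, x$predictor, x$n,
              if (x$sensitivity != "none")
                paste0(", sensitivity: ", x$sensitivity) else ""))
  cat(sprintf("  OR per SD = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$pvalue))
  cat(sprintf("  Nagelkerke delta R2 = %.5f\n", x$nagelkerke_delta_r2))
  invisible(x)
}

#' @export
coef.pgs_assoc <- function(object, ...) coef(object$fit)

#' @export
confint.pgs_assoc <- function(object, parm, level = 0.95, ...) {
  q <- qnorm(1 - (1 - level) / 2)
  c(lower = exp(object$beta - q * object$robust_se),
    upper = exp(object$beta + q * object$robust_se))
}

#' Run a battery of PGS-outcome associations with FDR correction
#'
#' One \code{\link{pgs_assoc}} fit per (predictor, outcome) pair, with
#' Benjamini-Hochberg correction applied across the battery's p-values.
#'
#' @param specs Data frame with columns \code{predictor} and
#'   \code{outcome} (one row per pair), or a list of argument lists for
#'   \code{pgs_assoc}.
#' @param data Data frame passed to each fit.
#' @param ... Shared arguments forwarded to \code{pgs_assoc} (covariates,
#'   cluster, sensitivity, ...).
#' @return Data frame of class \code{assoc_battery} with columns
#'   \code{pgs}, \code{outcome}, \code{n}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{p_fdr}, \code{delta_r2}.
#' @export
assoc_battery <- function(specs, data, ...) {
  if (is.data.frame(specs)) {
    specs <- lapply(seq_len(nrow(specs)), function(i)
      list(predictor = specs$predictor[i], outcome = specs$outcome[i]))
  }
  if (length(specs) == 0) stop("empty association battery")
  fits <- lapply(specs, function(sp) {
    args <- c(sp, list(data = data), list(...))
    do.call(pgs_assoc, args)
  })
  out <- do.call(rbind, lapply(fits, function(f)
    data.frame(pgs = f$predictor, outcome = f$outcome, n = f$n,
               or = f$odds_ratio, ci_low = f$ci_low, ci_high = f$ci_high,
               p = f$pvalue, delta_r2 = f$nagelkerke_delta_r2,
               stringsAsFactors = FALSE)))
  out$p_fdr <- bh_fdr(out$p)
  out <- out[, c("pgs", "outcome", "n", "or", "ci_low", "ci_high",
                 "p", "p_fdr", "delta_r2")]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("assoc_battery", "data.frame")
  out
}

#' @export
print.assoc_battery <- function(x, digits = 3, ...) {
  cat("PGS association battery (", nrow(x), " tests, BH-FDR corrected)\n",
      sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
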