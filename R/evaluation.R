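#' Predictive R-squared for a quantitative trait
#'
#' Ordinary least squares of the phenotype on the (scaled) score plus
#' covariates, against a covariates-only null. Reports the full-model
#' R-squared and the incremental R-squared (full minus null); with no
#' covariates the null is the intercept-only model and the two coincide.
#'
#' @param scores numeric score vector (typically z-scaled).
#' @param phenotype numeric phenotype vector.
#' @param covariates optional numeric data.frame/matrix of covariates.
#' @return data.frame with columns `metric`, `estimate`, `n`:
#'   rows `r2_full` and `r2_incremental`.
#' @export
r2Quantitative <- function(scores, phenotype, covariates = NULL) {
  dat <- data.frame(y = phenotype, score = scores)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  cc <- complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < 3L) stopData("fewer than 3 complete cases")
  X <- stats::model.matrix(~ ., data = dat[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopData("collinear model columns: %s",
             paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                   collapse = ", "))
  full <- lm(y ~ ., data = dat)
  null <- if (ncol(dat) > 2L) lm(y ~ . - score, data = dat) else
    lm(y ~ 1, data = dat)
  r2f <- summary(full)$r.squared
  r2n <- summary(null)$r.squared
  data.frame(metric = c("r2_full", "r2_incremental"),
             estimate = c(r2f, r2f - r2n), n = nrow(dat),
             stringsAsFactors = FALSE)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random case
#' outranks a random control, ties counting one half. Equals exhaustive
#' case-control pair counting.
#'
#' @param scores numeric score vector.
#' @param labels binary outcome (0/1 or logical), 1 = case.
#' @return data.frame with `metric = "auc"`, `estimate`, `n`, `cases`,
#'   `controls`.
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) stopData("labels must be binary 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopData("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  data.frame(metric = "auc", estimate = auc, n = n1 + n0, cases = n1,
             controls = n0, stringsAsFactors = FALSE)
}

#' Nagelkerke pseudo R-squared
#'
#' Logistic regression of the outcome on covariates plus score versus
#' covariates only;
#' `R2 = (1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))` with `L0`, `L1` the
#' maximized null and full likelihoods.
#'
#' @inheritParams aucScore
#' @param covariates optional covariate data.frame/matrix.
#' @return data.frame with `metric = "nagelkerke_r2"`, `estimate`, `n`,
#'   `cases`, `controls`.
#' @export
nagelkerkeR2 <- function(scores, labels, covariates = NULL) {
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) stopData("labels must be binary 0/1")
  dat <- data.frame(y = labels, score = scores)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  full <- tryCatch(glm(y ~ ., data = dat, family = binomial()),
                   warning = function(w) {
                     if (grepl("fitted probabilities", conditionMessage(w)))
                       stopNumeric("logistic fit separated; Nagelkerke R2 undefined")
                     suppressWarnings(glm(y ~ ., data = dat,
                                          family = binomial()))
                   })
  null <- if (ncol(dat) > 2L)
    suppressWarnings(glm(y ~ . - score, data = dat, family = binomial()))
  else glm(y ~ 1, data = dat, family = binomial())
  if (!full$converged || !null$converged)
    stopNumeric("logistic fit did not converge")
  ll1 <- as.numeric(logLik(full)); ll0 <- as.numeric(logLik(null))
  r2 <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  r2 <- min(max(r2, 0), 1)
  data.frame(metric = "nagelkerke_r2", estimate = r2, n = n,
             cases = sum(dat$y), controls = sum(1 - dat$y),
             stringsAsFactors = FALSE)
}

#' Top-decile odds ratio
#'
#' Partitions subjects at the 90th percentile of the score (boundary ties
#' all assigned to the top stratum) and reports the odds ratio of case
#' status in the top 10% versus the remaining 90%. Zero cells receive the
#' Haldane-Anscombe 0.5 correction, with a warning and a `corrected` flag.
#'
#' @inheritParams aucScore
#' @return data.frame with `metric = "top_decile_or"`, `estimate`, `n`,
#'   `cases`, `controls`, `corrected`.
#' @export
topDecileOR <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) stopData("labels must be binary 0/1")
  if (length(scores) < 10L) stopData("need at least 10 subjects")
  if (!sum(labels) || all(labels == 1L))
    stopData("both classes must be present")
  q <- quantile(scores, 0.9, names = FALSE)
  top <- scores >= q
  if (all(top) || !any(top)) stopData("all subjects fall in one stratum")
  a <- sum(top & labels == 1L); b <- sum(top & labels == 0L)
  c_ <- sum(!top & labels == 1L); d <- sum(!top & labels == 0L)
  corrected <- any(c(a, b, c_, d) == 0L)
  if (corrected) {
    warning("zero cell in the 2x2 table; applying the 0.5 correction")
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  data.frame(metric = "top_decile_or", estimate = (a * d) / (b * c_),
             n = length(scores), cases = sum(labels),
             controls = sum(1 - labels), corrected = corrected,
             stringsAsFactors = FALSE)
}

#' Cross-run weight concordance
#'
#' The per-SNP squared error between two posterior weight vectors (joined by
#' SNP id), the median squared error, and a paired two-sided t-test of the
#' two weight vectors — the protocol used to compare independent
#' implementations or replicate chains. Zero-variance differences are
#' handled explicitly (identical inputs give `t = 0`, `p = 1`).
#'
#' @param weightsA,weightsB [PosteriorWeights-class] objects or data.frames
#'   with columns `snp` and `beta`.
#' @return list with `squared_errors` (named per SNP), `median_sq_error`,
#'   `t_statistic`, `p_value`, `n_snps`.
#' @export
concordanceWeights <- function(weightsA, weightsB) {
  wa <- if (is(weightsA, "PosteriorWeights")) weightTable(weightsA) else weightsA
  wb <- if (is(weightsB, "PosteriorWeights")) weightTable(weightsB) else weightsB
  diffIds <- c(setdiff(wa$snp, wb$snp), setdiff(wb$snp, wa$snp))
  if (length(diffIds))
    stopData("SNP sets differ; symmetric difference: %s",
             paste(head(diffIds, 10L), collapse = ", "))
  m <- match(wa$snp, wb$snp)
  k <- nrow(wa)
  if (k < 2L) stopData("need at least 2 SNPs")
  d <- wa$beta - wb$beta[m]
  sq <- d^2
  names(sq) <- wa$snp
  sdd <- sd(d)
  if (sdd == 0) {
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pval <- if (mean(d) == 0) 1 else 0
  } else {
    tstat <- mean(d) / (sdd / sqrt(k))
    pval <- 2 * pt(-abs(tstat), df = k - 1)
  }
  list(squared_errors = sq, median_sq_error = median(sq),
       t_statistic = tstat, p_value = pval, n_snps = k)
}

#' Summarize metrics across replicate runs
#'
#' Mean and sample SD (denominator k-1) per metric across k replicate
#' evaluation results, the reporting shape "mean (SD)".
#'
#' @param results list of data.frames as returned by the metric functions
#'   (same `metric` rows in each), or a numeric vector of one metric's
#'   replicate values.
#' @return data.frame with columns `metric`, `mean`, `sd`, `k`. With a
#'   single replicate the SD is `NA` with a warning.
#' @export
replicateSummary <- function(results) {
  if (is.numeric(results))
    results <- lapply(results, function(v)
      data.frame(metric = "value", estimate = v))
  k <- length(results)
  if (k < 1L) stopData("no replicates")
  metrics <- results[[1]]$metric
  est <- vapply(results, function(r)
    r$estimate[match(metrics, r$metric)], numeric(length(metrics)))
  est <- matrix(est, nrow = length(metrics))
  if (k == 1L) {
    warning("single replicate: SD reported as NA")
    return(data.frame(metric = metrics, mean = est[, 1], sd = NA_real_,
                      k = 1L, stringsAsFactors = FALSE))
  }
  data.frame(metric = metrics, mean = rowMeans(est),
             sd = apply(est, 1L, sd), k = k, stringsAsFactors = FALSE)
}
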