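#' Align posterior weights to target variant allele coding
#'
#' Resolves the orientation of each weight's effect allele against the
#' target variant metadata using the same four-configuration logic as
#' summary-statistic harmonization (direct, swapped, strand-complement,
#' swapped-complement). Swapped configurations mark the SNP for dosage
#' complementation (`2 - dosage`) so the weighted allele count always refers
#' to the weight's effect allele; irresolvable SNPs are excluded with a
#' warning.
#'
#' @param weights a [PosteriorWeights-class] or its table.
#' @param variants data.frame with columns `snp`, `a1`, `a2` describing the
#'   genotype allele coding (e.g. from [readBim()]).
#' @return data.frame of the aligned weights with columns `snp`, `beta` and
#'   `flip` (logical: use `2 - dosage`).
#' @export
alignWeightAlleles <- function(weights, variants) {
  w <- if (is(weights, "PosteriorWeights")) weightTable(weights) else weights
  m <- match(w$snp, variants$snp)
  keep <- !is.na(m)
  w <- w[keep, , drop = FALSE]
  v <- variants[m[keep], , drop = FALSE]
  cfg <- alleleConfig(w$a1, w$a2, toupper(v$a1), toupper(v$a2))
  bad <- sum(is.na(cfg))
  if (bad)
    warning(sprintf("%d SNP(s) excluded: alleles irreconcilable with target",
                    bad))
  ok <- !is.na(cfg)
  data.frame(snp = w$snp[ok], beta = w$beta[ok],
             flip = cfg[ok] %in% c("swap", "swapcomp"),
             stringsAsFactors = FALSE)
}

#' Score individuals with posterior SNP weights
#'
#' Computes the weighted risk-allele sum for every individual,
#' `raw_i = sum_j w_j d_ij`, with `d_ij` the dosage of the weight's effect
#' allele (complemented as `2 - d` where the target coding is swapped), and
#' standardizes it to `z_score` with mean zero and unit SD. Missing dosages
#' are imputed as twice the effect-allele frequency observed in the scoring
#' cohort (`impute = "freq"`, default) or treated as zero dosage so the SNP
#' contributes nothing for that individual (`impute = "drop"`).
#'
#' @param weights a [PosteriorWeights-class] or its table.
#' @param dosages numeric matrix (individuals x SNPs) with dosages in
#'   \[0, 2\] or `NA`; columns named by SNP id, rows by individual id.
#' @param variants variant metadata for the dosage columns (see
#'   [alignWeightAlleles()]); defaults to the weights' own coding (no
#'   flips).
#' @param impute `"freq"` or `"drop"`.
#' @return data.frame with columns `id`, `raw_score`, `z_score`.
#' @export
scoreIndividuals <- function(weights, dosages, variants = NULL,
                             impute = c("freq", "drop")) {
  impute <- match.arg(impute)
  w <- if (is(weights, "PosteriorWeights")) weightTable(weights) else weights
  stopifnot(is.matrix(dosages), !is.null(colnames(dosages)))
  if (is.null(variants)) {
    aligned <- data.frame(snp = w$snp, beta = w$beta, flip = FALSE,
                          stringsAsFactors = FALSE)
    aligned <- aligned[aligned$snp %in% colnames(dosages), , drop = FALSE]
  } else {
    aligned <- alignWeightAlleles(w, variants)
    aligned <- aligned[aligned$snp %in% colnames(dosages), , drop = FALSE]
  }
  if (!nrow(aligned))
    stopData("no overlap between weight SNPs and genotype columns")

  G <- dosages[, aligned$snp, drop = FALSE]
  if (any(aligned$flip)) G[, aligned$flip] <- 2 - G[, aligned$flip]
  if (anyNA(G)) {
    fill <- if (impute == "freq") colMeans(G, na.rm = TRUE) else
      rep(0, ncol(G))
    for (j in which(colSums(is.na(G)) > 0L))
      G[is.na(G[, j]), j] <- fill[j]
  }
  raw <- unname(drop(G %*% aligned$beta))
  z <- if (length(unique(raw)) >= 2L) (raw - mean(raw)) / sd(raw) else
    rep(0, length(raw))
  data.frame(id = if (!is.null(rownames(dosages))) rownames(dosages) else
               as.character(seq_along(raw)),
             raw_score = raw, z_score = z, stringsAsFactors = FALSE)
}

#' Read / write score tables and dosage matrices
#'
#' Score tables are TSV with columns `id`, `raw_score`, `z_score`. Dosage
#' matrices are TSV with an `IID` first column and one column per SNP.
#'
#' @param scores data.frame from [scoreIndividuals()].
#' @param path file path.
#' @return `readDosages` returns a numeric matrix with individual row names
#'   and SNP column names.
#' @export
writeScores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  read.table(path, header = TRUE, stringsAsFactors = FALSE,
             colClasses = c("character", "numeric", "numeric"))
}

#' @rdname writeScores
#' @export
writeDosages <- function(dosages, path) {
  df <- data.frame(IID = rownames(dosages), dosages, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @export
readDosages <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
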