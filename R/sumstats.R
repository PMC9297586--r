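#' Read GWAS summary statistics
#'
#' Parses a header-ed, whitespace- or tab-delimited summary statistics file.
#' Columns may appear in any order; non-default column names are declared
#' through `columnMap`. Odds ratios are converted to log odds ratios on
#' input.
#'
#' @param path path to the summary statistics file.
#' @param columnMap named character vector mapping roles to column names in
#'   the file, e.g. `c(SNP = "rsid", A1 = "ALT", A2 = "REF", BETA = "b",
#'   P = "pval")`. Recognized roles: `SNP`, `A1`, `A2`, `BETA`, `OR`, `P`,
#'   `SE`. Defaults to identity names. Exactly one of `BETA`/`OR` and at
#'   least one of `P`/`SE` must resolve to a file column.
#' @return data.frame with columns `snp`, `a1`, `a2`, `beta_raw` (log-OR
#'   scale if `OR` supplied), `p` (NA if absent) and `se` (NA if absent).
#' @export
readSumStats <- function(path, columnMap = NULL) {
  if (!file.exists(path)) stopConfig("summary statistics file not found: %s", path)
  defaults <- c(SNP = "SNP", A1 = "A1", A2 = "A2", BETA = "BETA",
                OR = "OR", P = "P", SE = "SE")
  cm <- defaults
  if (!is.null(columnMap)) {
    bad <- setdiff(names(columnMap), names(defaults))
    if (length(bad))
      stopConfig("unknown column role(s): %s", paste(bad, collapse = ", "))
    cm[names(columnMap)] <- columnMap
  }
  dat <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)

  pick <- function(role) {
    if (cm[[role]] %in% names(dat)) dat[[cm[[role]]]] else NULL
  }
  for (role in c("SNP", "A1", "A2")) {
    if (is.null(pick(role)))
      stopConfig("required column for role %s ('%s') missing from %s",
                 role, cm[[role]], path)
  }
  eff <- pick("BETA"); or <- pick("OR")
  if (is.null(eff) && is.null(or))
    stopConfig("no effect column: need role BETA ('%s') or OR ('%s')",
               cm[["BETA"]], cm[["OR"]])
  pv <- pick("P"); se <- pick("SE")
  if (is.null(pv) && is.null(se))
    stopConfig("no uncertainty column: need role P ('%s') or SE ('%s')",
               cm[["P"]], cm[["SE"]])

  asNum <- function(x, what) {
    if (is.null(x)) return(rep(NA_real_, nrow(dat)))
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & x != "NA")
    if (length(bad))
      stopData("non-numeric %s at line(s) %s (header is line 1)",
               what, paste(head(bad + 1L, 5L), collapse = ", "))
    v
  }

  snp <- pick("SNP")
  dup <- unique(snp[duplicated(snp)])
  if (length(dup))
    stopData("duplicate SNP id(s) in sumstats: %s",
             paste(head(dup, 10L), collapse = ", "))

  if (!is.null(eff)) {
    beta_raw <- asNum(eff, "BETA")
  } else {
    orv <- asNum(or, "OR")
    if (any(orv <= 0, na.rm = TRUE))
      stopData("OR values must be > 0")
    beta_raw <- log(orv)
  }
  p <- asNum(pv, "P")
  if (any(!is.na(p) & (p <= 0 | p > 1)))
    stopData("P values outside (0, 1] at line(s) %s",
             paste(head(which(!is.na(p) & (p <= 0 | p > 1)) + 1L, 5L),
                   collapse = ", "))
  sev <- asNum(se, "SE")
  if (any(!is.na(sev) & sev < 0)) stopData("negative SE values")

  data.frame(snp = snp, a1 = toupper(pick("A1")), a2 = toupper(pick("A2")),
             beta_raw = beta_raw, p = p, se = sev,
             stringsAsFactors = FALSE)
}

#' Standardize marginal effects
#'
#' Converts per-allele marginal effects to the standardized scale used by the
#' Gibbs sampler. In the default p-value mode,
#' `beta_std = sign(beta_raw) * z(p) / sqrt(n)` with `z(p)` the upper
#' `p/2` standard-normal quantile; in SE mode,
#' `beta_std = (beta_raw / se) / sqrt(n)`. P-values below 1e-323 are floored
#' to keep the quantile finite.
#'
#' @param records data.frame from [readSumStats()].
#' @param n GWAS sample size (positive scalar).
#' @param mode `"p"` (default) or `"se"`.
#' @return `records` with an added `beta_std` column.
#' @export
standardizeEffects <- function(records, n, mode = c("p", "se")) {
  mode <- match.arg(mode)
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stopConfig("n must be a positive scalar sample size")
  if (mode == "p") {
    p <- records$p
    if (any(is.na(p)))
      stopData("p-value mode requires a P column for every row")
    if (any(p <= 0 | p > 1)) stopData("P values outside (0, 1]")
    p <- pmax(p, 1e-323)
    z <- qnorm(p / 2, lower.tail = FALSE)
    records$beta_std <- sign(records$beta_raw) * z / sqrt(n)
  } else {
    se <- records$se
    if (any(is.na(se) | se <= 0))
      stopData("SE mode requires a positive SE for every row")
    records$beta_std <- (records$beta_raw / se) / sqrt(n)
  }
  records
}

# allele complement; non-ACGT alleles (indel codes) map to NA so they can
# only match in the direct / swapped configurations
flipStrand <- function(a) {
  map <- c(A = "T", T = "A", C = "G", G = "C")
  out <- unname(map[a])
  out
}

isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# classify sumstats alleles against reference alleles; returns
# "direct", "swap", "comp", "swapcomp" or NA. Non-complement
# configurations take precedence so palindromic SNPs resolve
# deterministically.
alleleConfig <- function(a1, a2, ref_a1, ref_a2) {
  c1 <- flipStrand(a1); c2 <- flipStrand(a2)
  out <- rep(NA_character_, length(a1))
  out[is.na(out) & a1 == ref_a1 & a2 == ref_a2] <- "direct"
  out[is.na(out) & a1 == ref_a2 & a2 == ref_a1] <- "swap"
  ok <- !is.na(c1) & !is.na(c2)
  out[is.na(out) & ok & c1 == ref_a1 & c2 == ref_a2] <- "comp"
  out[is.na(out) & ok & c1 == ref_a2 & c2 == ref_a1] <- "swapcomp"
  out
}

#' Read a PLINK .bim variant list
#'
#' @param path path to a 6-column, header-less PLINK `.bim` file
#'   (chromosome, id, genetic distance, position, allele1, allele2).
#' @return data.frame with columns `chr`, `snp`, `bp`, `a1`, `a2`.
#'   Chromosome labels are normalized to strings without a `chr` prefix.
#' @export
readBim <- function(path) {
  if (!file.exists(path)) stopConfig("variant list (.bim) not found: %s", path)
  b <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (ncol(b) != 6L)
    stopData("%s: expected 6 .bim columns, found %d", path, ncol(b))
  data.frame(chr = sub("^chr", "", b[[1]]), snp = b[[2]],
             bp = as.integer(b[[4]]), a1 = toupper(b[[5]]),
             a2 = toupper(b[[6]]), stringsAsFactors = FALSE)
}

#' Harmonize summary statistics against reference and target variants
#'
#' Intersects standardized summary statistics with the LD reference SNP info
#' and the target variant list, resolving allele orientation. Matching
#' configurations are: direct, swapped (effect sign flipped),
#' strand-complement, and swapped-complement (sign flipped); palindromic
#' (A/T, C/G) pairs resolve through the non-complement configurations first
#' and can be excluded wholesale with `dropAmbiguous = TRUE`. Output SNP
#' order and allele orientation follow the reference.
#'
#' @param records data.frame from [standardizeEffects()] (must carry
#'   `beta_std`).
#' @param reference an [LDReference-class] object, or its SNP info
#'   data.frame.
#' @param bim data.frame from [readBim()], or `NULL` to skip the target
#'   intersection (e.g. when scoring is done elsewhere).
#' @param n GWAS sample size.
#' @param dropAmbiguous drop palindromic variants entirely.
#' @return a [HarmonizedSumStats-class] object.
#' @export
harmonizeSumStats <- function(records, reference, bim = NULL, n,
                              dropAmbiguous = FALSE) {
  if (!"beta_std" %in% names(records))
    stopConfig("records lack beta_std; run standardizeEffects() first")
  info <- if (is(reference, "LDReference")) snpInfo(reference) else reference

  m <- match(info$snp, records$snp)
  keep <- !is.na(m)
  sub <- records[m[keep], , drop = FALSE]
  ref <- info[keep, , drop = FALSE]

  cfg <- alleleConfig(sub$a1, sub$a2, ref$a1, ref$a2)
  ok <- !is.na(cfg)
  if (dropAmbiguous) ok <- ok & !isPalindromic(sub$a1, sub$a2)

  if (!is.null(bim)) {
    bm <- match(ref$snp, bim$snp)
    inBim <- !is.na(bm)
    bimCfg <- rep(NA_character_, nrow(ref))
    bimCfg[inBim] <- alleleConfig(bim$a1[bm[inBim]], bim$a2[bm[inBim]],
                                  ref$a1[inBim], ref$a2[inBim])
    ok <- ok & !is.na(bimCfg)
  }

  if (!any(ok))
    stopData(paste("no SNPs shared by sumstats, reference and target after",
                   "allele matching; check genome build and allele coding"))

  sub <- sub[ok, , drop = FALSE]
  ref <- ref[ok, , drop = FALSE]
  cfg <- cfg[ok]
  sgn <- ifelse(cfg %in% c("swap", "swapcomp"), -1, 1)

  out <- data.frame(snp = ref$snp, chr = ref$chr, bp = ref$bp,
                    a1 = ref$a1, a2 = ref$a2,
                    beta_std = sgn * sub$beta_std, maf = ref$maf,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new("HarmonizedSumStats", snps = out, n = as.integer(n))
}

#' Variant quality-control filter
#'
#' Removes variants failing any of: minor allele frequency at or below
#' `mafMin`; Hardy-Weinberg equilibrium p-value below `hwePmin`; absolute
#' MAF difference from an external reference above `mafDiffMax`.
#'
#' @param variants data.frame with columns `snp`, `maf`, and optionally
#'   `hwe_p` and `ref_maf` (rules without their column are skipped).
#' @param mafMin MAF threshold (default 0.01; variants with `maf <= mafMin`
#'   are removed).
#' @param hwePmin HWE p-value threshold (default 1e-10).
#' @param mafDiffMax maximum |maf - ref_maf| (default 0.10).
#' @return list with elements `kept` (filtered data.frame), `report`
#'   (data.frame `snp`, `rule`, one row per violated rule) and `counts`
#'   (named integer vector of removals per rule).
#' @export
qcFilter <- function(variants, mafMin = 0.01, hwePmin = 1e-10,
                     mafDiffMax = 0.10) {
  stopifnot(is.data.frame(variants), all(c("snp", "maf") %in% names(variants)))
  if (any(variants$maf < 0 | variants$maf > 0.5, na.rm = TRUE))
    stopData("maf outside [0, 0.5]")

  failMaf <- variants$maf <= mafMin
  failHwe <- if ("hwe_p" %in% names(variants))
    !is.na(variants$hwe_p) & variants$hwe_p < hwePmin else rep(FALSE, nrow(variants))
  failDiff <- if ("ref_maf" %in% names(variants))
    !is.na(variants$ref_maf) &
      abs(variants$maf - variants$ref_maf) > mafDiffMax
  else rep(FALSE, nrow(variants))

  report <- data.frame(
    snp = c(variants$snp[failMaf], variants$snp[failHwe],
            variants$snp[failDiff]),
    rule = c(rep("maf", sum(failMaf)), rep("hwe", sum(failHwe)),
             rep("maf_diff", sum(failDiff))),
    stringsAsFactors = FALSE)
  removed <- failMaf | failHwe | failDiff
  kept <- variants[!removed, , drop = FALSE]
  if (!nrow(kept)) warning("qcFilter removed every variant")
  list(kept = kept, report = report,
       counts = c(maf = sum(failMaf), hwe = sum(failHwe),
                  maf_diff = sum(failDiff)))
}

#' Hardy-Weinberg equilibrium test p-values
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against Hardy-Weinberg expectations, per SNP.
#'
#' @param dosages integer dosage matrix (individuals x SNPs, values 0/1/2).
#' @return numeric vector of p-values, one per SNP column.
#' @export
hwePvalues <- function(dosages) {
  apply(dosages, 2L, function(g) {
    g <- g[!is.na(g)]
    n <- length(g)
    if (!n) return(NA_real_)
    n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
    p <- (2 * n2 + n1) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    if (any(e == 0)) return(1)
    x2 <- sum((c(n0, n1, n2) - e)^2 / e)
    pchisq(x2, df = 1, lower.tail = FALSE)
  })
}
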