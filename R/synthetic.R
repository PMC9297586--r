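#' Synthetic study configuration
#'
#' Settings for the synthetic-data generator used to validate the whole
#' pipeline: cohort sizes, SNP panel, block-LD structure, additive polygenic
#' architecture, and trait type. Defaults describe a moderately polygenic
#' quantitative trait measured in a GWAS of 20,000 with a 2,000-SNP panel:
#' heritability 0.5, causal fraction 0.05, AR(1) within-block LD at
#' correlation 0.5 in blocks of 250 SNPs, MAFs uniform on \[0.05, 0.5\].
#'
#' @param nGwas,nTarget,nRef GWAS, target (scoring) and LD-reference cohort
#'   sizes.
#' @param p SNP count.
#' @param blockSize SNPs per LD block.
#' @param rho within-block latent AR(1) correlation, in \[0, 1).
#' @param mafRange length-2 range of target minor allele frequencies.
#' @param h2 narrow-sense heritability on the standardized scale, in
#'   \[0, 1\].
#' @param piCausal causal SNP fraction, in (0, 1\].
#' @param trait `"quantitative"` or `"binary"`.
#' @param prevalence case prevalence K for binary traits (liability
#'   threshold at the 1 - K quantile).
#' @param chrs chromosome label(s) to spread the blocks over (recycled
#'   across blocks).
#' @param seed integer seed; all generation is deterministic given it.
#' @return classed list of validated settings.
#' @export
simConfig <- function(nGwas = 20000L, nTarget = 2000L, nRef = 2000L,
                      p = 2000L, blockSize = 250L, rho = 0.5,
                      mafRange = c(0.05, 0.5), h2 = 0.5, piCausal = 0.05,
                      trait = c("quantitative", "binary"), prevalence = 0.2,
                      chrs = "1", seed = 1L) {
  trait <- match.arg(trait)
  stopifnot(nGwas >= 10, nTarget >= 2, nRef >= 2, p >= 2, blockSize >= 1,
            rho >= 0, rho < 1, length(mafRange) == 2L,
            mafRange[1] > 0, mafRange[2] <= 0.5, h2 >= 0, h2 <= 1,
            piCausal > 0, piCausal <= 1, prevalence > 0, prevalence < 1)
  structure(list(nGwas = as.integer(nGwas), nTarget = as.integer(nTarget),
                 nRef = as.integer(nRef), p = as.integer(p),
                 blockSize = as.integer(blockSize), rho = rho,
                 mafRange = mafRange, h2 = h2, piCausal = piCausal,
                 trait = trait, prevalence = prevalence,
                 chrs = as.character(chrs),
                 seed = as.integer(seed)), class = "simConfig")
}

# latent AR(1) haplotype block, thresholded at the MAF quantile
simHaploBlock <- function(n, mafs, rho) {
  B <- length(mafs)
  Z <- matrix(rnorm(n * B), n, B)
  if (rho > 0 && B > 1L) {
    s <- sqrt(1 - rho^2)
    for (j in 2:B) Z[, j] <- rho * Z[, j - 1] + s * Z[, j]
  }
  H <- matrix(0L, n, B)
  thr <- qnorm(mafs)
  for (j in seq_len(B)) H[, j] <- as.integer(Z[, j] < thr[j])
  H
}

#' Simulate block-LD genotype dosages
#'
#' Each SNP's two alleles per individual come from two independent latent
#' Gaussian haplotypes with AR(1) correlation `rho` within blocks (zero
#' between blocks), dichotomized at the normal quantile of the target MAF
#' and summed to 0/1/2 dosages. Hardy-Weinberg equilibrium holds by
#' construction. Target MAFs are drawn uniformly on `mafRange` (shared
#' across cohorts through the config seed).
#'
#' @param n number of individuals.
#' @param config a [simConfig()].
#' @param chr chromosome label(s) for the SNP info; a single label, or one
#'   per block (recycled over blocks).
#' @return list with `dosages` (n x p integer matrix, columns named
#'   `snp1..snpp`), `snpinfo` (chr, snp, bp, a1, a2, maf with realized
#'   MAF), and `target_maf`.
#' @export
simulateGenotypes <- function(n, config, chr = config$chrs) {
  p <- config$p
  nblk <- ceiling(p / config$blockSize)
  mafs <- runif(p, config$mafRange[1], config$mafRange[2])
  G <- matrix(0L, n, p)
  for (k in seq_len(nblk)) {
    i <- ((k - 1) * config$blockSize + 1):min(k * config$blockSize, p)
    G[, i] <- simHaploBlock(n, mafs[i], config$rho) +
      simHaploBlock(n, mafs[i], config$rho)
  }
  colnames(G) <- paste0("snp", seq_len(p))
  rownames(G) <- paste0("id", seq_len(n))
  f <- colMeans(G) / 2
  # contiguous runs of blocks per chromosome label
  blkChr <- sort(rep_len(as.character(chr), nblk))
  snpinfo <- data.frame(
    chr = blkChr[(seq_len(p) - 1L) %/% config$blockSize + 1L],
    snp = colnames(G), bp = seq_len(p) * 1000L,
    a1 = "A", a2 = "G", maf = pmin(f, 1 - f), stringsAsFactors = FALSE)
  list(dosages = G, snpinfo = snpinfo, target_maf = mafs)
}

#' Simulate an additive polygenic phenotype
#'
#' Draws a causal set of size `round(piCausal * p)` with standardized
#' effects `beta_true ~ N(0, h2 / (piCausal * p))`, builds the genetic value
#' on column-standardized dosages, and adds Gaussian noise whose variance is
#' set from the realized genetic variance (`var(g) (1 - h2) / h2`) so the
#' heritability ratio `Var(g)/Var(y)` lands on `h2` up to
#' noise-realization error. Binary traits dichotomize the liability at its
#' empirical `1 - prevalence` quantile.
#'
#' @param dosages dosage matrix from [simulateGenotypes()].
#' @param config a [simConfig()].
#' @return list with `phenotype` (numeric, or 0/1 for binary), `liability`,
#'   and `truth` (list: `beta_true`, `causal`, `h2_realized`, `freq`).
#' @export
simulatePhenotype <- function(dosages, config) {
  p <- ncol(dosages)
  nCausal <- max(1L, round(config$piCausal * p))
  causal <- sort(sample.int(p, nCausal))
  beta <- numeric(p)
  if (config$h2 > 0)
    beta[causal] <- rnorm(nCausal, 0, sqrt(config$h2 / nCausal))
  f <- colMeans(dosages) / 2
  Xs <- scale(dosages, center = 2 * f,
              scale = sqrt(2 * f * (1 - f)))
  g <- drop(Xs %*% beta)
  vg <- var(g)
  # noise variance tied to the realized genetic variance so the
  # heritability ratio hits h2 up to noise-realization error
  noiseVar <- if (config$h2 > 0 && vg > 0)
    vg * (1 - config$h2) / config$h2 else 1
  liab <- g + rnorm(nrow(dosages), 0, sqrt(noiseVar))
  h2r <- if (var(liab) > 0) vg / var(liab) else 0
  pheno <- if (config$trait == "binary")
    as.integer(liab > quantile(liab, 1 - config$prevalence)) else liab
  list(phenotype = pheno, liability = liab,
       truth = list(beta_true = beta, causal = causal, h2_realized = h2r,
                    freq = f))
}

#' Per-SNP marginal GWAS on the simulated cohort
#'
#' Quantitative traits: simple linear regression of the phenotype on each
#' dosage column. Binary traits: per-SNP logistic score test (effect
#' `U/V`, SE `1/sqrt(V)` with score `U = sum x (y - ybar)` and information
#' `V = ybar (1-ybar) sum (x - xbar)^2`). Emits the sumstats dialect read by
#' [readSumStats()].
#'
#' @param dosages dosage matrix (individuals x SNPs).
#' @param phenotype numeric or 0/1 vector.
#' @param snpinfo SNP info data.frame (for allele labels).
#' @param trait `"quantitative"` or `"binary"`.
#' @return data.frame with columns `SNP`, `A1`, `A2`, `BETA`, `SE`, `P`.
#' @export
marginalGWAS <- function(dosages, phenotype, snpinfo,
                         trait = c("quantitative", "binary")) {
  trait <- match.arg(trait)
  n <- nrow(dosages)
  xbar <- colMeans(dosages)
  sxx <- colSums(dosages^2) - n * xbar^2
  if (trait == "quantitative") {
    y <- phenotype - mean(phenotype)
    sxy <- drop(crossprod(dosages, y))
    beta <- sxy / sxx
    res2 <- sum(y^2) - beta * sxy           # per-SNP residual SS
    se <- sqrt(pmax(res2, 0) / ((n - 2) * sxx))
    z <- beta / se
  } else {
    ybar <- mean(phenotype)
    U <- drop(crossprod(dosages, phenotype - ybar))
    V <- ybar * (1 - ybar) * sxx
    beta <- U / V
    se <- 1 / sqrt(V)
    z <- U / sqrt(V)
  }
  pval <- 2 * pnorm(-abs(z))
  pval <- pmax(pval, 1e-323)
  data.frame(SNP = snpinfo$snp, A1 = snpinfo$a1, A2 = snpinfo$a2,
             BETA = beta, SE = se, P = pval, stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Generates GWAS, LD-reference and target cohorts from one architecture
#' (shared true effects), runs the marginal GWAS, and builds the blocked LD
#' reference from the reference cohort. With `dir` set, writes every input
#' format the other modules read: `sumstats.tsv`, `target.bim`,
#' `target_dosages.tsv`, `phenotype.tsv`, and the LD reference directory
#' `ldref/`.
#'
#' @param config a [simConfig()].
#' @param dir optional output directory.
#' @return list with `sumstats` (data.frame), `reference`
#'   ([LDReference-class]), `target` (list: dosages, bim, phenotype,
#'   covariates), `gwas` (list: dosages, phenotype), `truth`, and `config`.
#' @export
simulateStudy <- function(config = simConfig(), dir = NULL) {
  set.seed(config$seed)
  nAll <- config$nGwas + config$nTarget
  gen <- simulateGenotypes(nAll, config)
  ph <- simulatePhenotype(gen$dosages, config)

  gi <- seq_len(config$nGwas)
  ti <- config$nGwas + seq_len(config$nTarget)
  sumstats <- marginalGWAS(gen$dosages[gi, , drop = FALSE],
                           ph$phenotype[gi], gen$snpinfo, config$trait)

  refGen <- simulateGenotypes(config$nRef, config)
  reference <- computeLDBlocks(refGen$dosages, refGen$snpinfo,
                               blockSize = config$blockSize)

  targetD <- gen$dosages[ti, , drop = FALSE]
  bim <- data.frame(chr = gen$snpinfo$chr, snp = gen$snpinfo$snp,
                    bp = gen$snpinfo$bp, a1 = gen$snpinfo$a1,
                    a2 = gen$snpinfo$a2, stringsAsFactors = FALSE)
  covar <- data.frame(age = round(runif(config$nTarget, 30, 80)),
                      sex = rbinom(config$nTarget, 1, 0.5))
  pheno <- data.frame(IID = rownames(targetD), pheno = ph$phenotype[ti],
                      covar, stringsAsFactors = FALSE)

  out <- list(sumstats = sumstats, reference = reference,
              target = list(dosages = targetD, bim = bim, phenotype = pheno),
              gwas = list(dosages = gen$dosages[gi, , drop = FALSE],
                          phenotype = ph$phenotype[gi]),
              truth = ph$truth, config = config)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(sumstats, file.path(dir, "sumstats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(bim$chr, bim$snp, 0, bim$bp, bim$a1, bim$a2),
                file.path(dir, "target.bim"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeDosages(targetD, file.path(dir, "target_dosages.tsv"))
    write.table(pheno, file.path(dir, "phenotype.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    saveLDReference(reference, file.path(dir, "ldref"))
    out$dir <- dir
  }
  out
}
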