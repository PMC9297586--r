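#' Prior and chain configuration
#'
#' `priorConfig()` sets the continuous-shrinkage hyperparameters: local-scale
#' shape `a`, coupler shape `b`, and global shrinkage `phi` (a positive
#' number, or `"auto"` to learn it from the data). `mcmcConfig()` sets the
#' chain length; the `"benchmark"` preset is the 10,000-iteration
#' configuration (burn-in 5,000, thinning 5) used for full-scale runs, the
#' default a proportionally scaled-down 1,000/500/5.
#'
#' @param a,b positive shape parameters (defaults 1 and 0.5).
#' @param phi positive global shrinkage, or `"auto"`.
#' @param nIter,nBurnin,thin total iterations, burn-in, thinning interval.
#' @param seed integer seed; every run is reproducible from it.
#' @param preset `"default"` or `"benchmark"`; explicit arguments override.
#' @return a classed list of validated settings.
#' @export
priorConfig <- function(a = 1, b = 0.5, phi = "auto") {
  if (!is.numeric(a) || a <= 0 || !is.numeric(b) || b <= 0)
    stopConfig("a and b must be > 0")
  auto <- identical(phi, "auto") || is.null(phi)
  if (!auto && (!is.numeric(phi) || phi <= 0))
    stopConfig("phi must be > 0 or 'auto'")
  structure(list(a = a, b = b, phi = if (auto) NA_real_ else phi,
                 phiAuto = auto), class = "priorConfig")
}

#' @rdname priorConfig
#' @export
mcmcConfig <- function(nIter = NULL, nBurnin = NULL, thin = NULL, seed = 42L,
                       preset = c("default", "benchmark")) {
  preset <- match.arg(preset)
  base <- if (preset == "benchmark") c(10000L, 5000L, 5L) else c(1000L, 500L, 5L)
  nIter <- as.integer(if (is.null(nIter)) base[1] else nIter)
  nBurnin <- as.integer(if (is.null(nBurnin)) base[2] else nBurnin)
  thin <- as.integer(if (is.null(thin)) base[3] else thin)
  if (nBurnin >= nIter) stopConfig("nBurnin must be < nIter")
  if (thin < 1L || (nIter - nBurnin) %/% thin < 1L)
    stopConfig("(nIter - nBurnin)/thin must be >= 1")
  structure(list(nIter = nIter, nBurnin = nBurnin, thin = thin,
                 seed = as.integer(seed)), class = "mcmcConfig")
}

#' Generalized inverse Gaussian variates
#'
#' Draws from the GIG distribution with density proportional to
#' `x^(lambda-1) exp(-(rho x + chi/x)/2)` on `x > 0`. `chi = 0` (with
#' `lambda > 0`) is the Gamma(shape `lambda`, rate `rho/2`) limit. Uses R's
#' RNG stream, so results are reproducible under [set.seed()].
#'
#' @param n number of draws.
#' @param lambda real order parameter.
#' @param rho positive rate on `x`.
#' @param chi non-negative rate on `1/x`.
#' @return numeric vector of `n` positive draws.
#' @export
sampleGIG <- function(n, lambda, rho, chi) {
  stopifnot(length(lambda) == 1L, length(rho) == 1L, length(chi) == 1L)
  .gig_draws(as.integer(n), lambda, rho, chi)
}

#' Single conditional updates of the Gibbs sampler
#'
#' Low-level access to the full conditionals, mainly for validation: the
#' per-block effect-size draw
#' `beta ~ N(A^-1 bhat, (sigma2/n) A^-1)`, `A = D + diag(1/psi)`
#' (`drawBetaBlock`); the residual-variance draw
#' `1/sigma2 ~ Gamma((n+p)/2, e)` with rate
#' `e = max((n/2)(1 - 2 beta'bhat + quad), (n/2) sum(beta^2/psi))`
#' (`drawSigma2`, with `sigma2Rate` exposing `e`); the local-scale /
#' coupler pair `psi_j ~ min(GIG(a - 1/2, 2 delta_j, n beta_j^2 / sigma2), 1)`,
#' `delta_j ~ Gamma(a + b, psi_j + phi)` (`drawPsiDelta`); and the
#' global-shrinkage draw `w ~ Gamma(1, phi + 1)`,
#' `phi ~ Gamma(p b + 1/2, sum(delta) + w)` (`drawPhiAuto`).
#'
#' @param D block LD correlation matrix.
#' @param bhat standardized marginal effects for the block.
#' @param psi,delta,beta current local scales, couplers, effects.
#' @param sigma2,phi current residual variance and global shrinkage.
#' @param n GWAS sample size.
#' @param blocks list of `list(snps =, D =)` blocks covering `beta` in order.
#' @param a,b prior shapes.
#' @param ndraws number of independent draws to return (conditioning state
#'   held fixed).
#' @return `drawBetaBlock`: matrix (`ndraws` x block size); `drawSigma2`,
#'   `drawPhiAuto`: numeric vectors; `drawPsiDelta`: list of matrices
#'   `psi`, `delta` (`ndraws` x p); `sigma2Rate`: scalar.
#' @name conditionals
NULL

#' @rdname conditionals
#' @export
drawBetaBlock <- function(D, bhat, psi, sigma2, n, ndraws = 1L) {
  stopifnot(nrow(D) == length(bhat), length(psi) == length(bhat),
            all(psi > 0), sigma2 > 0, n > 0)
  .beta_block_draws(D, bhat, psi, sigma2, n, as.integer(ndraws))
}

#' @rdname conditionals
#' @export
sigma2Rate <- function(beta, bhat, blocks, psi, n) {
  quad <- 0
  off <- 0L
  for (b in blocks) {
    i <- off + seq_along(b$snps)
    A <- b$D + diag(1 / psi[i], length(i))
    quad <- quad + drop(crossprod(beta[i], A %*% beta[i]))
    off <- off + length(i)
  }
  max((n / 2) * (1 - 2 * sum(beta * bhat) + quad),
      (n / 2) * sum(beta^2 / psi))
}

#' @rdname conditionals
#' @export
drawSigma2 <- function(beta, bhat, blocks, psi, n, ndraws = 1L) {
  p <- length(beta)
  e <- sigma2Rate(beta, bhat, blocks, psi, n)
  if (!is.finite(e)) stopNumeric("non-finite residual-variance rate")
  1 / rgamma(ndraws, shape = (n + p) / 2, rate = e)
}

#' @rdname conditionals
#' @export
drawPsiDelta <- function(beta, delta, sigma2, phi, a, b, n, ndraws = 1L) {
  p <- length(beta)
  psiM <- matrix(0, ndraws, p)
  delM <- matrix(0, ndraws, p)
  for (j in seq_len(p)) {
    ps <- pmin(.gig_draws(as.integer(ndraws), a - 0.5, 2 * delta[j],
                          n * beta[j]^2 / sigma2), 1)
    psiM[, j] <- ps
    delM[, j] <- rgamma(ndraws, shape = a + b, rate = ps + phi)
  }
  list(psi = psiM, delta = delM)
}

#' @rdname conditionals
#' @export
drawPhiAuto <- function(delta, phi, b, ndraws = 1L) {
  p <- length(delta)
  w <- rgamma(ndraws, shape = 1, rate = phi + 1)
  rgamma(ndraws, shape = p * b + 0.5, rate = sum(delta) + w)
}

# derive an independent, reproducible seed per chromosome chain
chromSeed <- function(seed, k) as.integer((seed + 7919 * k) %% 2147483647L)

runChainOnBlocks <- function(blocks, bhat, n, prior, mcmc, keepTrace,
                             freeze = NULL) {
  p <- length(bhat)
  idx <- list(); off <- 0L
  for (k in seq_along(blocks)) {
    idx[[k]] <- off + seq_along(blocks[[k]]$snps)
    off <- off + length(blocks[[k]]$snps)
  }
  stopifnot(off == p)
  updatePsi <- is.null(freeze$psi)
  updateSigma2 <- is.null(freeze$sigma2)
  psi0 <- if (updatePsi) rep(1, p) else rep(freeze$psi, length.out = p)
  sigma0 <- if (updateSigma2) 1 else freeze$sigma2
  phi0 <- if (prior$phiAuto) 1 else prior$phi
  .cs_gibbs_chain(idx, lapply(blocks, `[[`, "D"), bhat, n,
                  prior$a, prior$b, phi0, prior$phiAuto,
                  mcmc$nIter, mcmc$nBurnin, mcmc$thin,
                  updatePsi, updateSigma2, psi0, sigma0, keepTrace)
}

#' Run the continuous-shrinkage Gibbs sampler
#'
#' Estimates posterior-mean SNP effects from harmonized summary statistics
#' and a blocked LD reference. Chromosomes are processed independently, each
#' with its own RNG stream derived from `mcmc$seed`, so per-chromosome
#' results are reproducible and parallel execution is identical to
#' sequential. Within a chromosome the fixed Gibbs scan per iteration is:
#' effect sizes block-by-block, then local scales and couplers, then global
#' shrinkage (auto mode), then residual variance. After burn-in every
#' `thin`-th draw contributes to the running posterior mean.
#'
#' @param sumstats a [HarmonizedSumStats-class] object.
#' @param reference an [LDReference-class]; subset to the sumstats SNPs
#'   internally.
#' @param prior a [priorConfig()].
#' @param mcmc an [mcmcConfig()].
#' @param betaScale `"standardized"` or `"allelic"` (standardized posterior
#'   mean divided by `sqrt(2 maf (1 - maf))`).
#' @param parallel run chromosomes on forked workers ([parallel::mclapply]);
#'   results are identical to sequential execution.
#' @param keepTrace retain the full matrix of post-burn-in effect draws in
#'   the diagnostics (memory grows with SNPs x kept draws).
#' @param freeze internal validation hook: `list(psi =, sigma2 =)` holds the
#'   named latent fixed instead of sampling it.
#' @return a [PosteriorWeights-class] object.
#' @export
runGibbs <- function(sumstats, reference, prior = priorConfig(),
                     mcmc = mcmcConfig(), betaScale = c("standardized",
                     "allelic"), parallel = FALSE, keepTrace = FALSE,
                     freeze = NULL) {
  betaScale <- match.arg(betaScale)
  stopifnot(is(sumstats, "HarmonizedSumStats"), is(reference, "LDReference"))
  ss <- sumstatsTable(sumstats)
  ref <- subsetReference(reference, ss$snp)
  info <- snpInfo(ref)
  m <- match(info$snp, ss$snp)
  if (anyNA(m)) stopData("reference/sumstats SNP mismatch after subsetting")
  bhat <- ss$beta_std[m]

  chrs <- unique(info$chr)
  perChr <- lapply(seq_along(chrs), function(k) {
    ch <- chrs[k]
    blocks <- Filter(function(b) b$chr == ch, ldBlocks(ref))
    i <- which(info$chr == ch)
    list(chr = ch, blocks = blocks, bhat = bhat[i], i = i,
         seed = chromSeed(mcmc$seed, k))
  })

  worker <- function(job) {
    set.seed(job$seed)
    fit <- runChainOnBlocks(job$blocks, job$bhat, gwasN(sumstats), prior,
                            mcmc, keepTrace, freeze)
    fit$chr <- job$chr
    fit$seed <- job$seed
    fit
  }
  fits <- if (parallel && length(perChr) > 1L) {
    parallel::mclapply(perChr, worker,
                       mc.cores = min(length(perChr),
                                      parallel::detectCores()))
  } else {
    lapply(perChr, worker)
  }
  for (f in fits) if (inherits(f, "try-error") || is.null(f$beta_mean))
    stopNumeric("chromosome chain failed: %s", paste(f, collapse = " "))

  beta <- numeric(nrow(info))
  for (k in seq_along(perChr)) beta[perChr[[k]]$i] <- fits[[k]]$beta_mean
  if (betaScale == "allelic")
    beta <- beta / sqrt(2 * info$maf * (1 - info$maf))

  diag <- list(
    chr = chrs,
    phi_mean = lapply(fits, `[[`, "phi_mean"),
    sigma2_mean = lapply(fits, `[[`, "sigma2_mean"),
    n_kept = fits[[1]]$n_kept,
    seeds = vapply(fits, `[[`, integer(1), "seed"),
    beta_var = lapply(fits, `[[`, "beta_var"),
    index = lapply(perChr, `[[`, "i"))
  if (keepTrace) diag$beta_trace <- lapply(fits, `[[`, "beta_trace")

  new("PosteriorWeights",
      weights = data.frame(chr = info$chr, snp = info$snp, bp = info$bp,
                           a1 = info$a1, a2 = info$a2, beta = beta,
                           stringsAsFactors = FALSE),
      scale = betaScale, diagnostics = diag)
}

#' Read / write posterior weight files
#'
#' Header-less, tab-separated, six columns per SNP: chromosome, id,
#' position, effect allele (A1), other allele, posterior effect size — the
#' layout external scoring tools consume.
#'
#' @param weights a [PosteriorWeights-class] object or its table.
#' @param path output / input file path.
#' @param scale scale label to attach on read.
#' @return `writeWeights` returns `path` invisibly; `readWeights` a
#'   [PosteriorWeights-class].
#' @export
writeWeights <- function(weights, path) {
  w <- if (is(weights, "PosteriorWeights")) weightTable(weights) else weights
  out <- data.frame(w$chr, w$snp, w$bp, w$a1, w$a2, sprintf("%.6e", w$beta))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeWeights
#' @export
readWeights <- function(path, scale = "standardized") {
  if (!file.exists(path)) stopConfig("weight file not found: %s", path)
  w <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chr", "snp", "bp", "a1", "a2", "beta"),
                  colClasses = c("character", "character", "integer",
                                 "character", "character", "numeric"))
  new("PosteriorWeights", weights = w, scale = scale, diagnostics = list())
}

#' Monte-Carlo standard errors of posterior mean weights
#'
#' Batch-means MCSE per SNP from the retained effect-size draws (requires
#' `keepTrace = TRUE` in [runGibbs()]). Used to set chain-variance-derived
#' tolerances when comparing replicate chains.
#'
#' @param weights a [PosteriorWeights-class] with stored traces.
#' @param nBatch number of batches (default 25).
#' @return numeric vector of MCSEs in weight-table SNP order.
#' @export
chainMCSE <- function(weights, nBatch = 25L) {
  d <- chainDiagnostics(weights)
  if (is.null(d$beta_trace))
    stopConfig("no stored trace; rerun runGibbs with keepTrace = TRUE")
  out <- numeric(nrow(weightTable(weights)))
  for (k in seq_along(d$beta_trace)) {
    tr <- d$beta_trace[[k]]
    kept <- nrow(tr)
    bs <- kept %/% nBatch
    if (bs < 2L) stopConfig("trace too short for %d batches", nBatch)
    grp <- rep(seq_len(nBatch), each = bs)
    bm <- apply(tr[seq_len(nBatch * bs), , drop = FALSE], 2L,
                function(x) tapply(x, grp, mean))
    out[d$index[[k]]] <- apply(bm, 2L, sd) / sqrt(nBatch)
  }
  out
}
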