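# Shared fixtures and independent oracles for the test suite.

# write a sumstats data.frame to a temp file, returning the path
writeSumstatsFile <- function(df, sep = "\t") {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}

# build an LDReference by hand from a snpinfo data.frame and block index list
makeRef <- function(snpinfo, blockIdx = list(seq_len(nrow(snpinfo))),
                    Dlist = NULL) {
  blocks <- lapply(seq_along(blockIdx), function(k) {
    i <- blockIdx[[k]]
    D <- if (is.null(Dlist)) diag(length(i)) else Dlist[[k]]
    list(chr = snpinfo$chr[i[1]], snps = snpinfo$snp[i], D = D)
  })
  new("LDReference", blocks = blocks, snpinfo = snpinfo)
}

toySnpinfo <- function(n, chr = "1", a1 = "A", a2 = "G", maf = 0.3) {
  data.frame(chr = chr, snp = paste0("rs", seq_len(n)), bp = seq_len(n) * 100L,
             a1 = a1, a2 = a2, maf = maf, stringsAsFactors = FALSE)
}

# exhaustive pair-counting AUC oracle
bruteAUC <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (x in cs) for (y in ct) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cs) * length(ct))
}

# GIG moments from the Bessel-function closed form:
# E[X^k] = (chi/rho)^(k/2) K_{lambda+k}(w) / K_lambda(w), w = sqrt(rho chi)
gigMomentsBessel <- function(lambda, rho, chi) {
  if (chi == 0) {
    m1 <- lambda / (rho / 2)
    return(list(mean = m1, var = lambda / (rho / 2)^2))
  }
  w <- sqrt(rho * chi)
  r <- sqrt(chi / rho)
  k0 <- besselK(w, abs(lambda))
  m1 <- r * besselK(w, abs(lambda + 1)) / k0
  m2 <- r^2 * besselK(w, abs(lambda + 2)) / k0
  list(mean = m1, var = m2 - m1^2)
}

# GIG mean by numerical quadrature of x * f(x)
gigMeanQuad <- function(lambda, rho, chi) {
  f <- function(x) x^(lambda - 1) * exp(-(rho * x + chi / x) / 2)
  z <- integrate(f, 0, Inf, rel.tol = 1e-10)$value
  integrate(function(x) x * f(x), 0, Inf, rel.tol = 1e-10)$value / z
}

# Nagelkerke R2 oracle by direct likelihood maximization on a refined grid
gridNagelkerke <- function(scores, labels) {
  n <- length(labels)
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * scores
    sum(labels * eta - log1p(exp(eta)))
  }
  best <- c(0, 0)
  rng0 <- seq(-5, 5, length.out = 41)
  rng1 <- seq(-5, 5, length.out = 41)
  for (rep in 1:4) {
    ll <- outer(rng0, rng1, Vectorize(loglik))
    i <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(rng0[i[1]], rng1[i[2]])
    h0 <- diff(rng0)[1]; h1 <- diff(rng1)[1]
    rng0 <- seq(best[1] - h0, best[1] + h0, length.out = 41)
    rng1 <- seq(best[2] - h1, best[2] + h1, length.out = 41)
  }
  ll1 <- loglik(best[1], best[2])
  b0 <- seq(-5, 5, length.out = 10001)
  ll0 <- max(vapply(b0, function(b) loglik(b, 0), numeric(1)))
  (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
}

# brute-force allele matcher: tries the four allele configurations
# explicitly for one SNP and returns the sign, or NA
bruteMatch <- function(a1, a2, ref1, ref2) {
  comp <- function(x) c(A = "T", T = "A", C = "G", G = "C")[x]
  if (a1 == ref1 && a2 == ref2) return(1)
  if (a1 == ref2 && a2 == ref1) return(-1)
  c1 <- comp(a1); c2 <- comp(a2)
  if (!is.na(c1) && !is.na(c2)) {
    if (c1 == ref1 && c2 == ref2) return(1)
    if (c1 == ref2 && c2 == ref1) return(-1)
  }
  NA_real_
}

# bivariate-normal orthant probability P(X < t1, Y < t2) for correlation r,
# by 1-D quadrature; used as the LD-attenuation oracle
orthantProb <- function(t1, t2, r) {
  integrate(function(x) dnorm(x) * pnorm((t2 - r * x) / sqrt(1 - r^2)),
            -Inf, t1, rel.tol = 1e-10)$value
}

# expected dosage correlation for adjacent SNPs after dichotomizing a
# latent AR(1) Gaussian at the MAF thresholds
expectedDosageCor <- function(maf1, maf2, rho) {
  t1 <- qnorm(maf1); t2 <- qnorm(maf2)
  p11 <- orthantProb(t1, t2, rho)
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

# small synthetic study shared across test files (memoized)
.fixtures <- new.env(parent = emptyenv())

smallStudy <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- simConfig(nGwas = 3000, nTarget = 400, nRef = 800, p = 120,
                     blockSize = 40, chrs = c("1", "2"), seed = 401)
    dir <- file.path(tempdir(), "small_study")
    .fixtures$small <- simulateStudy(cfg, dir = dir)
  }
  .fixtures$small
}

harmonizedSmall <- function() {
  if (is.null(.fixtures$small_hss)) {
    st <- smallStudy()
    rec <- standardizeEffects(readSumStats(file.path(st$dir, "sumstats.tsv")),
                              st$config$nGwas)
    .fixtures$small_hss <- harmonizeSumStats(
      rec, st$reference, readBim(file.path(st$dir, "target.bim")),
      st$config$nGwas)
  }
  .fixtures$small_hss
}

# full-scale study for the acceptance suite (built once, ~30 s)
fullStudy <- function() {
  if (is.null(.fixtures$full)) {
    .fixtures$full <- simulateStudy(simConfig(seed = 2025))
  }
  .fixtures$full
}

harmonizeStudy <- function(st, sumstats = st$sumstats) {
  f <- writeSumstatsFile(sumstats)
  rec <- standardizeEffects(readSumStats(f), st$config$nGwas)
  harmonizeSumStats(rec, st$reference, NULL, st$config$nGwas)
}

# CLI fixture: one simulated study directory shared across test files
cliFixture <- function() {
  if (is.null(.fixtures$cli)) {
    dir <- file.path(tempdir(), "cli_fixture")
    cmdSimulate(c("--out_dir", dir, "--n_gwas", "1500", "--n_target", "200",
                  "--n_ref", "500", "--p", "80", "--block-size", "20",
                  "--seed", "17"))
    .fixtures$cli <- dir
  }
  .fixtures$cli
}

inferArgs <- function(dir, out, extra = character(0)) {
  c("--sst_file", file.path(dir, "sumstats.tsv"),
    "--n_gwas", "1500",
    "--ref_dir", file.path(dir, "ldref"),
    "--bim_prefix", file.path(dir, "target"),
    "--out_dir", out,
    "--n_iter", "300", "--n_burnin", "150", "--thin", "3",
    "--seed", "99", extra)
}
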