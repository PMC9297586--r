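test_that("parsing is column-order invariant and converts OR to log(OR)", {
  df <- data.frame(SNP = c("rs1", "rs2"), A1 = c("A", "C"), A2 = c("G", "T"),
                   OR = c(1.0, 2.0), P = c(0.5, 0.01))
  rec <- readSumStats(writeSumstatsFile(df))
  expect_equal(rec$beta_raw, c(0, log(2)))

  shuffled <- df[, c("P", "OR", "A2", "A1", "SNP")]
  rec2 <- readSumStats(writeSumstatsFile(shuffled))
  expect_identical(rec, rec2)

  # whitespace-delimited variant parses identically
  rec3 <- readSumStats(writeSumstatsFile(df, sep = " "))
  expect_identical(rec, rec3)
})

test_that("custom column names map onto roles", {
  df <- data.frame(rsid = "rs9", eff = "A", oth = "G", b = 0.2, pval = 0.3)
  rec <- readSumStats(writeSumstatsFile(df),
                      columnMap = c(SNP = "rsid", A1 = "eff", A2 = "oth",
                                    BETA = "b", P = "pval"))
  expect_equal(rec$snp, "rs9")
  expect_equal(rec$beta_raw, 0.2)
  expect_error(readSumStats(writeSumstatsFile(df)), class = "prsConfigError")
})

test_that("parser rejects bad input with informative errors", {
  base <- data.frame(SNP = c("rs1", "rs2"), A1 = c("A", "C"),
                     A2 = c("G", "T"), BETA = c(0.1, -0.2), P = c(0.5, 0.1))
  noEff <- base[, setdiff(names(base), "BETA")]
  expect_error(readSumStats(writeSumstatsFile(noEff)),
               class = "prsConfigError", regexp = "BETA.*OR")

  bad <- base; bad$BETA <- c("0.1", "xx")
  expect_error(readSumStats(writeSumstatsFile(bad)),
               class = "prsDataError", regexp = "line")

  dup <- base; dup$SNP <- c("rs1", "rs1")
  expect_error(readSumStats(writeSumstatsFile(dup)),
               class = "prsDataError", regexp = "rs1")

  badp <- base; badp$P <- c(0, 0.5)
  expect_error(readSumStats(writeSumstatsFile(badp)), class = "prsDataError")
})

test_that("effect standardization matches the normal-quantile oracle", {
  rec <- data.frame(snp = c("a", "b", "c"), a1 = "A", a2 = "G",
                    beta_raw = c(0.3, -0.2, 0.15),
                    p = c(1.0, 0.05, 1e-8), se = NA_real_)
  out <- standardizeEffects(rec, 10000)
  expect_equal(out$beta_std[1], 0)
  expect_equal(out$beta_std[2], -qnorm(0.05 / 2, lower.tail = FALSE) / 100)
  expect_equal(out$beta_std[3], qnorm(5e-9, lower.tail = FALSE) / 100)

  # SE mode: z = beta/se, scaled by sqrt(n)
  rec$se <- c(0.1, 0.1, 0.03)
  out <- standardizeEffects(transform(rec, beta_raw = c(0.5, -0.2, 0.15)),
                            25, mode = "se")
  expect_equal(out$beta_std[1], (0.5 / 0.1) / 5)

  # p = 0 handled by flooring, extreme p stays finite
  tiny <- data.frame(snp = "t", a1 = "A", a2 = "G", beta_raw = 1,
                     p = 1e-323, se = NA_real_)
  expect_true(is.finite(standardizeEffects(tiny, 1e4)$beta_std))
  expect_error(standardizeEffects(transform(rec, p = c(2, .5, .5)), 100),
               class = "prsDataError")
})

test_that("harmonization resolves all four allele configurations", {
  info <- toySnpinfo(6, a1 = c("A", "A", "A", "A", "A", "C"),
                     a2 = c("G", "G", "G", "G", "T", "G"))
  rec <- data.frame(
    snp = info$snp,
    a1 = c("A", "G", "T", "C", "A", "G"),  # direct, swap, comp, swapcomp,
    a2 = c("G", "A", "C", "T", "T", "C"),  # palindromic A/T, mismatch (C/G vs G/C swap)
    beta_std = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE)
  ref <- makeRef(info)
  hss <- harmonizeSumStats(rec, ref, NULL, 1000)
  tab <- sumstatsTable(hss)

  oracle <- unname(mapply(bruteMatch, rec$a1, rec$a2, info$a1, info$a2))
  kept <- !is.na(oracle)
  expect_identical(tab$snp, info$snp[kept])
  expect_equal(tab$beta_std, 0.1 * oracle[kept])
  # the G/C sumstats against C/G reference resolves as a swap (sign flip)
  expect_equal(tab$beta_std[tab$snp == "rs6"], -0.1)
  # alleles reported in reference orientation
  expect_identical(tab$a1, info$a1[kept])
})

test_that("harmonization is idempotent and sign-flip consistent", {
  st <- smallStudy()
  rec <- standardizeEffects(readSumStats(file.path(st$dir, "sumstats.tsv")),
                            st$config$nGwas)
  h1 <- sumstatsTable(harmonizeSumStats(rec, st$reference, NULL,
                                        st$config$nGwas))
  # already-reference-oriented input: harmonizing again is the identity
  again <- data.frame(snp = h1$snp, a1 = h1$a1, a2 = h1$a2,
                      beta_std = h1$beta_std, stringsAsFactors = FALSE)
  h2 <- sumstatsTable(harmonizeSumStats(again, st$reference, NULL,
                                        st$config$nGwas))
  expect_equal(h2$beta_std, h1$beta_std)

  # swapping alleles and negating beta leaves the result unchanged
  swapped <- transform(rec, a1 = a2, a2 = a1, beta_std = -beta_std)
  h3 <- sumstatsTable(harmonizeSumStats(swapped, st$reference, NULL,
                                        st$config$nGwas))
  expect_equal(h3$beta_std, h1$beta_std)
})

test_that("palindromic variants can be dropped and empty overlap errors", {
  info <- toySnpinfo(2, a1 = c("A", "A"), a2 = c("T", "G"))
  rec <- data.frame(snp = info$snp, a1 = info$a1, a2 = info$a2,
                    beta_std = c(0.2, 0.3), stringsAsFactors = FALSE)
  ref <- makeRef(info)
  tab <- sumstatsTable(harmonizeSumStats(rec, ref, NULL, 100,
                                         dropAmbiguous = TRUE))
  expect_identical(tab$snp, "rs2")

  none <- transform(rec, snp = c("zz1", "zz2"))
  expect_error(harmonizeSumStats(none, ref, NULL, 100),
               class = "prsDataError", regexp = "allele|build")
})

test_that("QC filter removes exactly the variants violating each rule", {
  v <- data.frame(
    snp = paste0("v", 1:10),
    maf = c(0.009, rep(0.25, 9)),            # v1 fails the MAF rule
    hwe_p = c(1, 1e-12, rep(1, 8)),          # v2 fails HWE
    ref_maf = c(0.01, 0.25, 0.45, rep(0.25, 7)),  # v3 fails |dMAF| > 0.10
    stringsAsFactors = FALSE)
  res <- qcFilter(v)
  expect_identical(res$kept$snp, paste0("v", 4:10))
  expect_equal(unname(res$counts), c(1L, 1L, 1L))
  expect_setequal(res$report$snp, c("v1", "v2", "v3"))
  # removal counts sum to input - output when rules are disjoint
  expect_equal(sum(res$counts), nrow(v) - nrow(res$kept))
  # boundary: maf exactly 0.01 is removed (only strictly greater survives),
  # with a warning when nothing is left
  expect_warning(res1 <- qcFilter(data.frame(snp = "b", maf = 0.01)),
                 "every variant")
  expect_false("b" %in% res1$kept$snp)
})

test_that("bim reader normalizes chromosomes and validates shape", {
  f <- tempfile()
  writeLines(c("chr1\trs1\t0\t100\ta\tg", "2\trs2\t0\t200\tC\tT"), f)
  b <- readBim(f)
  expect_identical(b$chr, c("1", "2"))
  expect_identical(b$a1, c("A", "C"))
  writeLines("1\trs1\t0\t100\tA", f)
  expect_error(readBim(f), class = "prsDataError")
})
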