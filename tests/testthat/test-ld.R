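test_that("LD computation: self-correlation, independence bound, AR(1) oracle", {
  set.seed(10)
  # a SNP duplicated as two columns has off-diagonal exactly 1
  x <- rbinom(200, 2, 0.3)
  dos <- cbind(x, x + 0L)
  colnames(dos) <- c("s1", "s2")
  info <- toySnpinfo(2); info$snp <- c("s1", "s2")
  ref <- computeLDBlocks(dos, info, blockSize = 2L)
  expect_equal(ldBlocks(ref)[[1]]$D[1, 2], 1)

  # independent SNPs: |r| below the sampling-error bound 3/sqrt(n)
  n <- 50000
  cfg <- simConfig(nGwas = 100, nTarget = 2, nRef = 2, p = 6, blockSize = 6,
                   rho = 0, seed = 77)
  g <- simulateGenotypes(n, cfg)
  D <- cor(g$dosages)
  expect_lt(max(abs(D[upper.tri(D)])), 3 / sqrt(n) * 1.5)

  # AR(1) latent rho = 0.8: adjacent dosage correlation matches the
  # quadrature (orthant-probability) oracle within 0.05
  cfg8 <- simConfig(nGwas = 100, nTarget = 2, nRef = 2, p = 10,
                    blockSize = 10, rho = 0.8, mafRange = c(0.5, 0.5),
                    seed = 78)
  g8 <- simulateGenotypes(n, cfg8)
  D8 <- cor(g8$dosages)
  adj <- D8[cbind(1:9, 2:10)]
  expected <- expectedDosageCor(0.5, 0.5, 0.8)
  expect_true(all(abs(adj - expected) < 0.05))
})

test_that("constant SNP columns are rejected by name", {
  dos <- cbind(s1 = rep(1L, 50), s2 = rbinom(50, 2, 0.4))
  info <- toySnpinfo(2); info$snp <- c("s1", "s2")
  expect_error(computeLDBlocks(dos, info), class = "prsDataError",
               regexp = "s1")
})

test_that("block boundaries drive the partition and must cover all SNPs", {
  set.seed(11)
  dos <- matrix(rbinom(100 * 6, 2, 0.4), 100, 6)
  colnames(dos) <- paste0("rs", 1:6)
  info <- toySnpinfo(6)
  bounds <- data.frame(chr = "1", start = c(1, 301), end = c(300, 600))
  ref <- computeLDBlocks(dos, info, boundaries = bounds)
  expect_equal(vapply(ldBlocks(ref), function(b) length(b$snps), 1L),
               c(3L, 3L))
  short <- data.frame(chr = "1", start = 1, end = 300)
  expect_error(computeLDBlocks(dos, info, boundaries = short),
               class = "prsDataError", regexp = "rs4")
})

test_that("subsetting restricts D rows/cols in place and drops empty blocks", {
  set.seed(12)
  dos <- matrix(rbinom(500 * 6, 2, 0.4), 500, 6)
  colnames(dos) <- paste0("rs", 1:6)
  ref <- computeLDBlocks(dos, toySnpinfo(6), blockSize = 3L)

  # subset to everything is the identity
  all <- subsetReference(ref, paste0("rs", 1:6))
  expect_equal(ldBlocks(all), ldBlocks(ref))

  # one SNP per block: D collapses to [1]
  one <- subsetReference(ref, c("rs2", "rs5"))
  expect_equal(lapply(ldBlocks(one), `[[`, "D"),
               list(matrix(1, 1, 1), matrix(1, 1, 1)))

  # {1,3} of a 3-SNP block equals direct index subsetting
  sub <- subsetReference(ref, c("rs1", "rs3"))
  expect_equal(ldBlocks(sub)[[1]]$D,
               ldBlocks(ref)[[1]]$D[c(1, 3), c(1, 3)])

  # dropping a whole block keeps the remaining ones intact
  drop2 <- subsetReference(ref, c("rs4", "rs5", "rs6"))
  expect_length(ldBlocks(drop2), 1L)
  expect_error(subsetReference(ref, "nope"), class = "prsDataError")
})

test_that("save/load round trip is exact and idempotent", {
  set.seed(13)
  dos <- matrix(rbinom(300 * 5, 2, 0.35), 300, 5)
  colnames(dos) <- paste0("rs", 1:5)
  ref <- computeLDBlocks(dos, toySnpinfo(5), blockSize = 3L)

  d1 <- tempfile(); d2 <- tempfile()
  saveLDReference(ref, d1)
  back <- loadLDReference(d1)
  expect_equal(lapply(ldBlocks(back), `[[`, "D"),
               lapply(ldBlocks(ref), `[[`, "D"), tolerance = 0)
  expect_equal(snpInfo(back)$maf, snpInfo(ref)$maf, tolerance = 0)

  # save -> load -> save produces byte-identical block files
  saveLDReference(back, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("loader validates structure and rejects malformed references", {
  expect_error(loadLDReference(tempfile()), class = "prsDataError")

  set.seed(14)
  dos <- matrix(rbinom(200 * 4, 2, 0.4), 200, 4)
  colnames(dos) <- paste0("rs", 1:4)
  ref <- computeLDBlocks(dos, toySnpinfo(4), blockSize = 2L)
  d <- tempfile()
  saveLDReference(ref, d)
  blk <- file.path(d, "ldblk_0001.txt")
  writeLines(readLines(blk)[1:2], blk)  # truncate the matrix
  expect_error(loadLDReference(d), class = "prsDataError",
               regexp = "ldblk_0001")

  # class validity rejects asymmetric or non-unit-diagonal D
  bad <- matrix(c(1, .5, .2, 1), 2)
  expect_error(makeRef(toySnpinfo(2), list(1:2), list(bad)),
               regexp = "symmetric")
  bad2 <- matrix(c(0.9, .5, .5, 1), 2)
  expect_error(makeRef(toySnpinfo(2), list(1:2), list(bad2)),
               regexp = "diag")
  expect_error(makeRef(toySnpinfo(2), list(c(1L, 1L))),
               regexp = "two blocks|partition")
})
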