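#' Build a blocked LD reference from genotype dosages
#'
#' Computes, for each block of contiguous SNPs, the Pearson correlation
#' matrix of dosage columns from a reference cohort. Block boundaries either
#' come from a boundary table or default to fixed windows of `blockSize`
#' SNPs per chromosome.
#'
#' @param dosages numeric dosage matrix (individuals x SNPs, values in
#'   \[0, 2\]), columns ordered by genomic position and named by SNP id.
#' @param snpinfo data.frame with columns `chr`, `snp`, `bp`, `a1`, `a2`
#'   and optionally `maf` (computed from dosages when absent), rows matching
#'   the dosage columns.
#' @param boundaries optional data.frame with columns `chr`, `start`, `end`
#'   (1-based positions, end inclusive); every SNP must fall in exactly one
#'   interval. `NULL` uses fixed windows.
#' @param blockSize window size in SNPs when `boundaries` is `NULL`
#'   (default 1000).
#' @return an [LDReference-class] object.
#' @export
computeLDBlocks <- function(dosages, snpinfo, boundaries = NULL,
                            blockSize = 1000L) {
  stopifnot(is.matrix(dosages), nrow(snpinfo) == ncol(dosages))
  sds <- apply(dosages, 2L, sd)
  if (any(sds == 0 | is.na(sds)))
    stopData("constant genotype column(s): %s",
             paste(head(snpinfo$snp[sds == 0 | is.na(sds)], 10L),
                   collapse = ", "))
  if (!"maf" %in% names(snpinfo)) {
    f <- colMeans(dosages) / 2
    snpinfo$maf <- pmin(f, 1 - f)
  }
  snpinfo$chr <- as.character(snpinfo$chr)

  blockOf <- integer(nrow(snpinfo))
  if (is.null(boundaries)) {
    nb <- 0L
    for (ch in unique(snpinfo$chr)) {
      i <- which(snpinfo$chr == ch)
      blockOf[i] <- nb + (seq_along(i) - 1L) %/% blockSize + 1L
      nb <- max(blockOf[i])
    }
  } else {
    stopifnot(all(c("chr", "start", "end") %in% names(boundaries)))
    boundaries$chr <- as.character(boundaries$chr)
    for (j in seq_len(nrow(boundaries))) {
      i <- which(snpinfo$chr == boundaries$chr[j] &
                   snpinfo$bp >= boundaries$start[j] &
                   snpinfo$bp <= boundaries$end[j])
      blockOf[i] <- j
    }
    if (any(blockOf == 0L))
      stopData("block boundaries do not cover SNP(s): %s",
               paste(head(snpinfo$snp[blockOf == 0L], 10L), collapse = ", "))
  }

  blocks <- lapply(sort(unique(blockOf)), function(k) {
    i <- which(blockOf == k)
    D <- cor(dosages[, i, drop = FALSE])
    D <- (D + t(D)) / 2
    diag(D) <- 1
    dimnames(D) <- NULL
    list(chr = snpinfo$chr[i[1]], snps = snpinfo$snp[i], D = D)
  })
  new("LDReference",
      blocks = blocks,
      snpinfo = snpinfo[, c("chr", "snp", "bp", "a1", "a2", "maf")])
}

#' Restrict an LD reference to an analysis SNP set
#'
#' Subsets every block's correlation matrix (rows/columns in place) to the
#' SNPs retained after harmonization; empty blocks are dropped. Block
#' structure and SNP order are preserved.
#'
#' @param reference an [LDReference-class] object.
#' @param snps character vector of SNP ids to keep (e.g. from a
#'   [HarmonizedSumStats-class]), or the object itself.
#' @return an [LDReference-class] restricted to `snps`.
#' @export
subsetReference <- function(reference, snps) {
  if (is(snps, "HarmonizedSumStats")) snps <- sumstatsTable(snps)$snp
  missing <- setdiff(snps, snpInfo(reference)$snp)
  if (length(missing))
    stopData("SNP(s) absent from the LD reference: %s",
             paste(head(missing, 10L), collapse = ", "))
  blocks <- list()
  for (b in ldBlocks(reference)) {
    i <- which(b$snps %in% snps)
    if (!length(i)) next
    blocks[[length(blocks) + 1L]] <-
      list(chr = b$chr, snps = b$snps[i], D = b$D[i, i, drop = FALSE])
  }
  info <- snpInfo(reference)
  new("LDReference", blocks = blocks,
      snpinfo = info[info$snp %in% snps, , drop = FALSE])
}

#' Save / load a blocked LD reference
#'
#' Directory layout: `snpinfo.tsv` (columns CHR, SNP, BP, A1, A2, MAF),
#' `blocks.tsv` (manifest: block, chr, n_snps, file), and one whitespace-
#' delimited matrix file per block. Matrix entries are written with 17
#' significant digits so a save/load round trip reproduces every double
#' bit-exactly.
#'
#' @param reference an [LDReference-class] object.
#' @param dir directory (created if needed).
#' @return `saveLDReference` returns `dir` invisibly; `loadLDReference`
#'   returns an [LDReference-class] object (validated: symmetry, unit
#'   diagonal, partition).
#' @export
saveLDReference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- snpInfo(reference)
  out <- data.frame(CHR = info$chr, SNP = info$snp, BP = info$bp,
                    A1 = info$a1, A2 = info$a2, MAF = info$maf)
  write.table(out, file.path(dir, "snpinfo.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  blocks <- ldBlocks(reference)
  manifest <- data.frame(block = seq_along(blocks),
                         chr = vapply(blocks, `[[`, "", "chr"),
                         n_snps = vapply(blocks, function(b)
                           length(b$snps), integer(1)),
                         file = sprintf("ldblk_%04d.txt", seq_along(blocks)))
  write.table(manifest, file.path(dir, "blocks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (k in seq_along(blocks)) {
    con <- file(file.path(dir, manifest$file[k]), "w")
    writeLines(paste(blocks[[k]]$snps, collapse = "\t"), con)
    D <- blocks[[k]]$D
    writeLines(apply(D, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = "\t")), con)
    close(con)
  }
  invisible(dir)
}

#' @rdname saveLDReference
#' @export
loadLDReference <- function(dir) {
  sf <- file.path(dir, "snpinfo.tsv")
  mf <- file.path(dir, "blocks.tsv")
  if (!file.exists(sf) || !file.exists(mf))
    stopData("not an LD reference directory (missing %s)",
             if (file.exists(sf)) mf else sf)
  raw <- read.table(sf, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "character", "character", "numeric"))
  info <- data.frame(chr = raw$CHR, snp = raw$SNP, bp = raw$BP,
                     a1 = raw$A1, a2 = raw$A2, maf = raw$MAF,
                     stringsAsFactors = FALSE)
  manifest <- read.table(mf, header = TRUE, stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(nrow(manifest)), function(k) {
    path <- file.path(dir, manifest$file[k])
    if (!file.exists(path)) stopData("missing LD block file: %s", path)
    lines <- readLines(path)
    snps <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    D <- do.call(rbind, lapply(lines[-1], function(l)
      as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
    if (length(snps) != manifest$n_snps[k] || !is.matrix(D) ||
        nrow(D) != length(snps) || ncol(D) != length(snps) || anyNA(D))
      stopData("malformed LD block file: %s", path)
    list(chr = as.character(manifest$chr[k]), snps = snps, D = D)
  })
  ref <- new("LDReference", blocks = blocks, snpinfo = info)
  checkBlocksPSD(ref)
  ref
}

# PSD check (eigenvalues >= -1e-8) for every block; used on load and build
checkBlocksPSD <- function(reference, tol = 1e-8) {
  for (k in seq_along(ldBlocks(reference))) {
    D <- ldBlocks(reference)[[k]]$D
    if (!nrow(D)) next
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol)
      stopNumeric("LD block %d is not positive semi-definite (min eigenvalue %.3g)",
                  k, min(ev))
  }
  invisible(TRUE)
}
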