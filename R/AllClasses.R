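#' Harmonized GWAS summary statistics
#'
#' Per-SNP standardized marginal effects after intersection with an LD
#' reference and a target variant list, in reference allele orientation.
#' Column layout of the table slot: `snp`, `chr`, `bp`, `a1`, `a2`,
#' `beta_std`, `maf`.
#'
#' @slot snps data.frame of harmonized per-SNP records in reference order.
#' @slot n integer scalar, GWAS sample size.
#' @exportClass HarmonizedSumStats
setClass("HarmonizedSumStats",
         representation(snps = "data.frame", n = "integer"))

setValidity("HarmonizedSumStats", function(object) {
  s <- object@snps
  need <- c("snp", "chr", "bp", "a1", "a2", "beta_std", "maf")
  if (!all(need %in% names(s)))
    return(paste("snps must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$snp)) return("duplicate SNP ids")
  if (any(s$a1 == s$a2)) return("a1 == a2 for some SNP")
  if (nrow(s) && !all(is.finite(s$beta_std))) return("non-finite beta_std")
  if (nrow(s) && (any(s$maf <= 0) || any(s$maf > 0.5)))
    return("maf outside (0, 0.5]")
  if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
    return("n must be a positive integer scalar")
  TRUE
})

#' Blocked LD reference panel
#'
#' An ordered list of LD blocks, each a contiguous set of reference SNPs with
#' their correlation matrix `D` (symmetric, unit diagonal), plus the SNP info
#' table. Blocks partition the SNP set.
#'
#' @slot blocks list; each element is `list(chr =, snps =, D =)`.
#' @slot snpinfo data.frame with columns `chr`, `snp`, `bp`, `a1`, `a2`,
#'   `maf`, in genomic order matching the concatenated block SNPs.
#' @exportClass LDReference
setClass("LDReference",
         representation(blocks = "list", snpinfo = "data.frame"))

setValidity("LDReference", function(object) {
  info <- object@snpinfo
  need <- c("chr", "snp", "bp", "a1", "a2", "maf")
  if (!all(need %in% names(info)))
    return(paste("snpinfo must have columns:", paste(need, collapse = ", ")))
  ids <- unlist(lapply(object@blocks, `[[`, "snps"), use.names = FALSE)
  if (anyDuplicated(ids)) return("a SNP appears in two blocks")
  if (!identical(as.character(ids), as.character(info$snp)))
    return("block SNPs do not partition snpinfo in order")
  for (k in seq_along(object@blocks)) {
    b <- object@blocks[[k]]
    D <- b$D
    if (!is.matrix(D) || nrow(D) != length(b$snps))
      return(sprintf("block %d: D dimension mismatch", k))
    if (nrow(D) && max(abs(D - t(D))) > 1e-8)
      return(sprintf("block %d: D not symmetric", k))
    if (nrow(D) && any(diag(D) != 1))
      return(sprintf("block %d: diag(D) != 1", k))
  }
  TRUE
})

#' Posterior SNP weights
#'
#' Per-SNP posterior-mean effect sizes from the continuous-shrinkage Gibbs
#' sampler, in reference allele orientation. Table columns: `chr`, `snp`,
#' `bp`, `a1`, `a2`, `beta`.
#'
#' @slot weights data.frame of per-SNP posterior means.
#' @slot scale `"standardized"` (genotypes at unit variance) or `"allelic"`
#'   (per effect-allele copy; standardized scale divided by
#'   `sqrt(2 maf (1-maf))`).
#' @slot diagnostics list of chain diagnostics (per-chromosome posterior
#'   means of `phi` and `sigma2`, retained draw counts, seeds, optional
#'   traces).
#' @exportClass PosteriorWeights
setClass("PosteriorWeights",
         representation(weights = "data.frame", scale = "character",
                        diagnostics = "list"))

setValidity("PosteriorWeights", function(object) {
  w <- object@weights
  need <- c("chr", "snp", "bp", "a1", "a2", "beta")
  if (!all(need %in% names(w)))
    return(paste("weights must have columns:", paste(need, collapse = ", ")))
  if (nrow(w) && !all(is.finite(w$beta))) return("non-finite posterior weight")
  if (anyDuplicated(w$snp)) return("duplicate SNP ids")
  if (!object@scale %in% c("standardized", "allelic"))
    return("scale must be 'standardized' or 'allelic'")
  TRUE
})
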