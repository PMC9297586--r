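#' Accessors for shrinkPRS classes
#'
#' `snpInfo()` returns the SNP info table of an [LDReference-class];
#' `ldBlocks()` its list of blocks. `sumstatsTable()` and `gwasN()` return
#' the per-SNP table and GWAS sample size of a [HarmonizedSumStats-class].
#' `weightTable()`, `weightScale()` and `chainDiagnostics()` access a
#' [PosteriorWeights-class].
#'
#' @param x an object of the documented class.
#' @return The slot contents (data.frame, list, integer or character).
#' @name accessors
#' @aliases snpInfo ldBlocks sumstatsTable gwasN weightTable weightScale
#'   chainDiagnostics
NULL

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname accessors
#' @export
setGeneric("ldBlocks", function(x) standardGeneric("ldBlocks"))

#' @rdname accessors
#' @export
setGeneric("sumstatsTable", function(x) standardGeneric("sumstatsTable"))

#' @rdname accessors
#' @export
setGeneric("gwasN", function(x) standardGeneric("gwasN"))

#' @rdname accessors
#' @export
setGeneric("weightTable", function(x) standardGeneric("weightTable"))

#' @rdname accessors
#' @export
setGeneric("weightScale", function(x) standardGeneric("weightScale"))

#' @rdname accessors
#' @export
setGeneric("chainDiagnostics", function(x) standardGeneric("chainDiagnostics"))

#' @rdname accessors
setMethod("snpInfo", "LDReference", function(x) x@snpinfo)

#' @rdname accessors
setMethod("ldBlocks", "LDReference", function(x) x@blocks)

#' @rdname accessors
setMethod("sumstatsTable", "HarmonizedSumStats", function(x) x@snps)

#' @rdname accessors
setMethod("gwasN", "HarmonizedSumStats", function(x) x@n)

#' @rdname accessors
setMethod("weightTable", "PosteriorWeights", function(x) x@weights)

#' @rdname accessors
setMethod("weightScale", "PosteriorWeights", function(x) x@scale)

#' @rdname accessors
setMethod("chainDiagnostics", "PosteriorWeights", function(x) x@diagnostics)

#' @exportMethod show
setMethod("show", "HarmonizedSumStats", function(object) {
  cat(sprintf("HarmonizedSumStats: %d SNPs on %d chromosome(s), n = %d\n",
              nrow(object@snps), length(unique(object@snps$chr)), object@n))
  if (nrow(object@snps)) {
    cat("head of table:\n")
    print(head(object@snps, 3L))
  }
})

setMethod("show", "LDReference", function(object) {
  sz <- vapply(object@blocks, function(b) length(b$snps), integer(1))
  cat(sprintf("LDReference: %d SNPs in %d block(s) (block size %s)\n",
              nrow(object@snpinfo), length(object@blocks),
              if (length(sz)) paste(range(sz), collapse = "-") else "0"))
})

setMethod("show", "PosteriorWeights", function(object) {
  cat(sprintf("PosteriorWeights: %d SNPs, %s scale\n",
              nrow(object@weights), object@scale))
  d <- object@diagnostics
  if (!is.null(d$phi_mean))
    cat(sprintf("  posterior mean phi = %.4g, sigma2 = %.4g\n",
                mean(unlist(d$phi_mean)), mean(unlist(d$sigma2_mean))))
})
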