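#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a VariantSet
#'
#' @param sites annotation data.frame (see \code{\linkS4class{VariantSet}}).
#' @param gt integer genotype matrix (0/1/2/NA), sites x samples, with
#'   sample column names.
#' @param ad_ref,ad_alt,dp integer depth matrices of the same shape.
#' @return a \code{\linkS4class{VariantSet}}.
#' @export
VariantSet <- function(sites, gt, ad_ref, ad_alt, dp) {
  rownames(sites) <- NULL
  fix <- function(m) {
    storage.mode(m) <- "integer"
    dimnames(m) <- list(NULL, colnames(m))
    m
  }
  new("VariantSet", sites = sites, gt = fix(gt), ad_ref = fix(ad_ref),
      ad_alt = fix(ad_alt), dp = fix(dp))
}

#' @rdname accessors
#' @export
setMethod("variantSites", "VariantSet", function(object) object@sites)

#' @rdname accessors
#' @export
setMethod("genotypes", "VariantSet", function(object) object@gt)

#' @rdname accessors
#' @export
setMethod("altDepth", "VariantSet", function(object) object@ad_alt)

#' @rdname accessors
#' @export
setMethod("refDepth", "VariantSet", function(object) object@ad_ref)

#' @rdname accessors
#' @export
setMethod("readDepth", "VariantSet", function(object) object@dp)

#' @rdname accessors
#' @export
setMethod("sampleIds", "VariantSet", function(object) colnames(object@gt))

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet: %d sites x %d samples\n",
              nrow(object@sites), ncol(object@gt)))
  tab <- table(object@sites$csqclass)
  cat("  consequence classes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' Subset a VariantSet by site index and/or samples
#'
#' @param x a VariantSet.
#' @param i site indices (logical or integer).
#' @param j sample ids or indices.
#' @param ... unused.
#' @param drop ignored.
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@sites))
  if (missing(j)) j <- seq_len(ncol(x@gt))
  VariantSet(x@sites[i, , drop = FALSE], x@gt[i, j, drop = FALSE],
             x@ad_ref[i, j, drop = FALSE], x@ad_alt[i, j, drop = FALSE],
             x@dp[i, j, drop = FALSE])
})
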