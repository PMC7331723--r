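#' @include AllClasses.R AllGenerics.R variantset.R
NULL

#' Construct variant exclusion thresholds
#'
#' Defaults are the published cascade: exclude when (1) fewer than 3 reads
#' support the alternate allele in any sequenced affected; (2) population
#' AF exceeds 0.05 or more than 30 in-house carriers; (3) any population
#' homozygote exists; (4) synonymous; (5) 5' UTR or intronic outside the
#' splice-site window.
#'
#' @param min_alt_reads,max_pop_af,max_inhouse,exclude_pop_hom,splice_window_bp,exclude_utr3
#'   see \code{\linkS4class{FilterThresholds}}.
#' @return a \code{\linkS4class{FilterThresholds}}.
#' @export
filterThresholds <- function(min_alt_reads = 3L, max_pop_af = 0.05,
                             max_inhouse = 30L, exclude_pop_hom = TRUE,
                             splice_window_bp = 2L, exclude_utr3 = FALSE) {
  new("FilterThresholds", min_alt_reads = as.integer(min_alt_reads),
      max_pop_af = max_pop_af, max_inhouse = as.integer(max_inhouse),
      exclude_pop_hom = exclude_pop_hom,
      splice_window_bp = as.integer(splice_window_bp),
      exclude_utr3 = exclude_utr3)
}

.rule_names <- c("low_alt_reads", "common_or_recurrent", "population_homozygote",
                 "synonymous", "noncoding")

# per-rule failure predicates, each independent of the others; variants are
# attributed to the first failing rule in published order
.rule_fail_matrix <- function(vs, th, carrier_samples) {
  s <- variantSites(vs)
  unknown <- !s$csqclass %in% .csq_classes
  if (any(unknown))
    stop("unknown consequence class for variant(s): ",
         paste(s$id[unknown], collapse = ", "))
  ad <- altDepth(vs)[, carrier_samples, drop = FALSE]
  ad[is.na(ad)] <- 0L                    # a missing call supports nothing
  r1 <- apply(ad < th@min_alt_reads, 1L, any)
  r2 <- s$exac_af > th@max_pop_af | s$inhouse_n > th@max_inhouse
  r3 <- th@exclude_pop_hom & s$exac_hom > 0L
  r4 <- s$csqclass == "synonymous"
  r5 <- s$csqclass == "utr5" |
    (s$csqclass %in% c("intronic_near_splice", "intronic_deep") &
       !is.na(s$dist_to_exon) & s$dist_to_exon > th@splice_window_bp) |
    (th@exclude_utr3 & s$csqclass == "utr3")
  m <- cbind(r1, r2, r3, r4, r5)
  colnames(m) <- .rule_names
  m
}

#' Apply the five-rule exclusion cascade
#'
#' Rules are applied in the published order; each excluded variant is
#' attributed to the first rule it fails, so per-rule counts and survivors
#' always sum to the input count. Rule 1 (alternate-read support) is
#' evaluated on the sequenced affected samples and fails when any of them
#' has fewer than \code{min_alt_reads} alternate reads.
#'
#' @param vs a \code{\linkS4class{VariantSet}}.
#' @param thresholds a \code{\linkS4class{FilterThresholds}}.
#' @param carrier_samples sample ids on which rule 1 is evaluated
#'   (the sequenced affected individuals).
#' @param rule_order permutation of 1:5 (default identity); changing it
#'   changes only per-rule attribution, never the surviving set.
#' @return a \code{\linkS4class{FilterReport}}.
#' @export
applyFilters <- function(vs, thresholds = filterThresholds(),
                         carrier_samples, rule_order = 1:5) {
  stopifnot(identical(sort(rule_order), 1:5))
  m <- .rule_fail_matrix(vs, thresholds, carrier_samples)
  m <- m[, rule_order, drop = FALSE]
  first <- apply(m, 1L, function(r) if (any(r)) which(r)[1] else NA_integer_)
  s <- variantSites(vs)
  excl <- table(factor(colnames(m)[first], levels = .rule_names[rule_order]))
  rule_of <- stats::setNames(colnames(m)[first[!is.na(first)]],
                             s$id[!is.na(first)])
  new("FilterReport", n_input = nrow(s),
      excluded = stats::setNames(as.integer(excl), names(excl)),
      survivors = s$id[is.na(first)], rule_of = rule_of)
}

#' @rdname accessors
#' @export
setMethod("survivingVariants", "FilterReport", function(object)
  object@survivors)

#' @rdname accessors
#' @export
setMethod("excludedCounts", "FilterReport", function(object) object@excluded)

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d variants in, %d surviving\n",
              object@n_input, length(object@survivors)))
  for (r in names(object@excluded))
    cat(sprintf("  excluded by %-22s %d\n", paste0(r, ":"),
                object@excluded[[r]]))
})

#' Allele frequency as a percentage
#'
#' Returns 100 * alt_count / total_alleles at full precision;
#' \code{formatAlleleFrequency} renders it to two significant figures for
#' display (e.g. 3 alternate alleles out of 187,624 prints as
#' \code{"0.0016\%"}).
#'
#' @param alt_count number of alternate alleles observed.
#' @param total_alleles total alleles genotyped (> 0).
#' @return numeric percentage.
#' @export
computeAlleleFrequency <- function(alt_count, total_alleles) {
  if (total_alleles <= 0) stop("total_alleles must be > 0")
  if (alt_count > total_alleles) stop("alt_count exceeds total_alleles")
  100 * alt_count / total_alleles
}

#' @rdname computeAlleleFrequency
#' @param percent value from \code{computeAlleleFrequency}.
#' @export
formatAlleleFrequency <- function(percent) {
  paste0(format(signif(percent, 2), scientific = FALSE, trim = TRUE), "%")
}
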