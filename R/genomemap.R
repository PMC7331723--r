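#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a marker map for simulation
#'
#' Builds a genome of \code{n_chrom} chromosomes with markers at sorted
#' uniform positions. Founder alternate-allele frequencies are drawn from a
#' two-component mixture emulating an exome call set: with probability
#' \code{prop_common} a common polymorphism (AF ~ Uniform(0.05, 0.5)),
#' otherwise a rare variant (AF ~ Uniform(0, 0.001)). Common markers make
#' heterozygous calls informative against runs of homozygosity; rare
#' markers exercise the frequency-based exclusion rules.
#'
#' @param n_chrom number of chromosomes (default 4).
#' @param chrom_length_bp physical length per chromosome (default 120 Mb).
#' @param chrom_length_morgans genetic length per chromosome (default 1.2).
#' @param markers_per_chrom markers per chromosome (default 1000,
#'   approximately exome SNP density per unit genetic length).
#' @param prop_common mixture weight of the common component (default 0.7).
#' @param common_range,rare_range AF ranges of the two components.
#' @param seed integer seed.
#' @return a \code{\link{GenomeMap}}.
#' @export
makeGenomeMap <- function(n_chrom = 4, chrom_length_bp = 120e6,
                          chrom_length_morgans = 1.2,
                          markers_per_chrom = 1000, prop_common = 0.7,
                          common_range = c(0.05, 0.5),
                          rare_range = c(0, 0.001), seed = 1L) {
  stopifnot(markers_per_chrom >= 1, n_chrom >= 1)
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  ch <- data.frame(chrom = chroms,
                   length_bp = rep(chrom_length_bp, n_chrom),
                   length_morgans = rep(chrom_length_morgans, n_chrom),
                   stringsAsFactors = FALSE)
  mk <- do.call(rbind, lapply(chroms, function(cc) {
    pos <- sort(sample.int(chrom_length_bp, markers_per_chrom))
    is_common <- stats::runif(markers_per_chrom) < prop_common
    af <- ifelse(is_common,
                 stats::runif(markers_per_chrom, common_range[1], common_range[2]),
                 stats::runif(markers_per_chrom, rare_range[1], rare_range[2]))
    data.frame(chrom = cc, pos = pos, af = af, stringsAsFactors = FALSE)
  }))
  rownames(mk) <- NULL
  new("GenomeMap", chromosomes = ch, markers = mk)
}

#' @rdname accessors
#' @export
setMethod("markers", "GenomeMap", function(object) object@markers)

#' @rdname accessors
#' @export
setMethod("chromosomes", "GenomeMap", function(object) object@chromosomes)

setMethod("show", "GenomeMap", function(object) {
  cat(sprintf("GenomeMap: %d chromosome(s), %d markers, %.1f Morgans total\n",
              nrow(object@chromosomes), nrow(object@markers),
              sum(object@chromosomes$length_morgans)))
})
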