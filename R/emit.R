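#' @include genedrop.R variantset.R
NULL

#' Construct a genotyping noise model
#'
#' @param genotype_error_rate probability a true homozygous call is emitted
#'   heterozygous and vice versa (default 0.002).
#' @param mean_depth expected reads per site (default 40).
#' @param allele_balance expected alternate-read fraction at heterozygous
#'   sites (default 0.5).
#' @param base_error per-read error floor at homozygous sites
#'   (default 0.005).
#' @return a \code{\linkS4class{NoiseModel}}.
#' @export
noiseModel <- function(genotype_error_rate = 0.002, mean_depth = 40,
                       allele_balance = 0.5, base_error = 0.005) {
  new("NoiseModel", genotype_error_rate = genotype_error_rate,
      mean_depth = mean_depth, allele_balance = allele_balance,
      base_error = base_error)
}

# default consequence-class mixture for background variants; exome-like
# proportions chosen so every branch of the exclusion cascade is exercised
.default_csq_props <- c(missense = 0.25, synonymous = 0.25,
                        intronic_deep = 0.28, intronic_near_splice = 0.02,
                        utr5 = 0.05, utr3 = 0.05, intergenic = 0.05,
                        nonsense = 0.02, frameshift = 0.02,
                        splice_site = 0.01)

#' Emit noisy annotated variant calls from a simulated family
#'
#' Converts the true haplotype state of a \code{\link{FamilySim}} into a
#' multi-sample call set with read-level noise and annotation payloads.
#' Per sample and site: total depth ~ Poisson(\code{mean_depth}) (zero
#' depth yields a missing call); alternate reads ~ Binomial(depth, p) with
#' p = \code{allele_balance} at true heterozygous sites,
#' 1 - \code{base_error} at true hom-alt and \code{base_error} at true
#' hom-ref sites; the emitted genotype is the true genotype miscalled with
#' probability \code{genotype_error_rate} (hom to het; het to a random
#' hom). Background annotations: the population AF equals the founder
#' allele frequency of the map; consequence classes are drawn from
#' \code{csq_props}; population homozygote and in-house carrier counts are
#' binomial draws under Hardy-Weinberg at that AF. A planted variant
#' receives the annotation values of its \code{\link{plantedVariantSpec}}.
#'
#' @param sim a \code{\link{FamilySim}}.
#' @param noise a \code{\linkS4class{NoiseModel}}.
#' @param seed integer seed for the noise stream.
#' @param csq_props named numeric vector of consequence-class proportions.
#' @param inhouse_cohort_size in-house cohort size (default 1000 exomes).
#' @param pop_cohort_size reference-population size used for homozygote
#'   count draws (default 60706 individuals).
#' @return a \code{\linkS4class{VariantSet}}.
#' @export
emitVariants <- function(sim, noise = noiseModel(), seed = sim@seed,
                         csq_props = .default_csq_props,
                         inhouse_cohort_size = 1000L,
                         pop_cohort_size = 60706L) {
  stopifnot(is(noise, "NoiseModel"))
  if (!all(names(csq_props) %in% .csq_classes))
    stop("unknown consequence class in csq_props")
  set.seed(seed)
  gt <- trueGenotypes(sim)
  n_site <- nrow(gt); n_samp <- ncol(gt)
  mk <- markers(sim@map)

  # genotype miscalls
  e <- noise@genotype_error_rate
  if (e > 0) {
    u <- matrix(stats::runif(length(gt)), n_site)
    flip <- u < e
    out <- gt
    out[flip & gt != 1L] <- 1L
    het_flip <- flip & gt == 1L
    out[het_flip] <- 2L * (matrix(stats::runif(length(gt)), n_site)[het_flip] < 0.5)
    emitted <- out
  } else emitted <- gt

  dp <- matrix(stats::rpois(length(gt), noise@mean_depth), n_site,
               dimnames = dimnames(gt))
  p_alt <- matrix(noise@base_error, n_site, n_samp)
  p_alt[gt == 1L] <- noise@allele_balance
  p_alt[gt == 2L] <- 1 - noise@base_error
  ad_alt <- matrix(stats::rbinom(length(gt), dp, p_alt), n_site,
                   dimnames = dimnames(gt))
  ad_ref <- dp - ad_alt
  emitted[dp == 0L] <- NA_integer_

  # annotations
  af <- mk$af
  csq <- sample(names(csq_props), n_site, replace = TRUE, prob = csq_props)
  exac_hom <- stats::rbinom(n_site, pop_cohort_size, af^2)
  inhouse <- stats::rbinom(n_site, inhouse_cohort_size, 2 * af * (1 - af) + af^2)
  dist <- rep(NA_integer_, n_site)
  near <- csq == "intronic_near_splice"
  deep <- csq == "intronic_deep"
  dist[near] <- sample(1:2, sum(near), replace = TRUE)
  dist[deep] <- sample(3:20000, sum(deep), replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n_site, replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))

  sites <- data.frame(chrom = mk$chrom, pos = mk$pos,
                      id = paste0(mk$chrom, ":", mk$pos),
                      ref = ref, alt = unname(alt), csqclass = csq,
                      exac_af = af, exac_hom = exac_hom, inhouse_n = inhouse,
                      dist_to_exon = dist, stringsAsFactors = FALSE)

  pl <- sim@truth$planted
  if (!is.null(pl)) {
    i <- which(sites$chrom == pl$spec$chrom & sites$pos == pl$spec$pos)
    sites$csqclass[i] <- pl$spec$consequence
    sites$exac_af[i] <- pl$spec$annotated_af
    sites$exac_hom[i] <- pl$spec$annotated_hom
    sites$inhouse_n[i] <- pl$spec$inhouse_n
    sites$dist_to_exon[i] <- NA_integer_
  }
  VariantSet(sites, emitted, ad_ref, ad_alt, dp)
}
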