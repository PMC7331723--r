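#' @import methods
NULL

#' Pedigree container
#'
#' Holds a pedigree in the classic 6-column PED layout (family, individual,
#' father, mother, sex, affection), with \code{"0"} denoting a missing parent
#' and affection coded 0 = unknown, 1 = unaffected, 2 = affected. Supports
#' consanguineous loops (the same founder couple reachable through both
#' parents of an individual).
#'
#' @slot ped data.frame with columns \code{fam}, \code{id}, \code{father},
#'   \code{mother}, \code{sex} (1 = male, 2 = female), \code{affected}
#'   (0/1/2).
#' @export
setClass("Pedigree", representation(ped = "data.frame"))

setValidity("Pedigree", function(object) {
  p <- object@ped
  need <- c("fam", "id", "father", "mother", "sex", "affected")
  if (!all(need %in% names(p)))
    return(paste("ped must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$id)) return("duplicate individual ids")
  for (col in c("father", "mother")) {
    known <- p[[col]] == "0" | p[[col]] %in% p$id
    if (!all(known))
      return(sprintf("unknown %s id(s): %s", col,
                     paste(p[[col]][!known], collapse = ", ")))
  }
  half <- xor(p$father == "0", p$mother == "0")
  if (any(half))
    return("every non-founder must have both parents present")
  if (!all(p$sex %in% c(1L, 2L))) return("sex must be 1 or 2")
  if (!all(p$affected %in% c(0L, 1L, 2L)))
    return("affected must be 0 (unknown), 1 or 2")
  TRUE
})

#' Marker map of a simulated genome
#'
#' Chromosome sizes in base pairs and Morgans plus ordered marker positions
#' with founder alternate-allele frequencies. Recombination is modelled at a
#' uniform rate within each chromosome, so genetic position is proportional
#' to physical position.
#'
#' @slot chromosomes data.frame: \code{chrom}, \code{length_bp},
#'   \code{length_morgans}.
#' @slot markers data.frame: \code{chrom}, \code{pos} (1-based bp,
#'   strictly increasing within chromosome), \code{af} in [0, 1].
#' @export
setClass("GenomeMap",
         representation(chromosomes = "data.frame", markers = "data.frame"))

setValidity("GenomeMap", function(object) {
  ch <- object@chromosomes; mk <- object@markers
  if (!all(c("chrom", "length_bp", "length_morgans") %in% names(ch)))
    return("chromosomes needs chrom, length_bp, length_morgans")
  if (!all(c("chrom", "pos", "af") %in% names(mk)))
    return("markers needs chrom, pos, af")
  if (any(ch$length_bp <= 0) || any(ch$length_morgans < 0))
    return("chromosome lengths must be positive (genetic length >= 0)")
  if (!all(mk$chrom %in% ch$chrom)) return("marker on unknown chromosome")
  if (any(mk$af < 0 | mk$af > 1)) return("allele frequencies must be in [0,1]")
  bad <- vapply(split(mk$pos, mk$chrom), function(p) is.unsorted(p, strictly = TRUE),
                logical(1))
  if (any(bad)) return("marker positions must be strictly increasing per chromosome")
  TRUE
})

#' Genotyping noise model
#'
#' Parameters of the read-level noise applied when emitting variant calls
#' from true haplotypes: a symmetric genotype miscall rate (hom emitted as
#' het and vice versa), Poisson-distributed site depth, the expected
#' alternate-read fraction at heterozygous sites, and a base error floor
#' giving hom-ref sites occasional alternate reads.
#'
#' @slot genotype_error_rate numeric in [0,1].
#' @slot mean_depth positive numeric, expected reads per site.
#' @slot allele_balance numeric in [0,1], expected alt fraction for hets.
#' @slot base_error numeric in [0,1], per-read error floor at homozygous
#'   sites.
#' @export
setClass("NoiseModel", representation(genotype_error_rate = "numeric",
                                      mean_depth = "numeric",
                                      allele_balance = "numeric",
                                      base_error = "numeric"))

setValidity("NoiseModel", function(object) {
  pr <- c(object@genotype_error_rate, object@allele_balance, object@base_error)
  if (any(pr < 0 | pr > 1)) return("probabilities must be in [0,1]")
  if (object@mean_depth <= 0) return("mean_depth must be > 0")
  TRUE
})

#' Run-of-homozygosity calling parameters
#'
#' A qualifying span contains at least \code{min_snps} non-missing calls of
#' which at most \code{max_het} are heterozygous.
#'
#' @slot min_snps integer >= 1 (default 25).
#' @slot max_het integer >= 0 (default 2).
#' @export
setClass("ROHParams",
         representation(min_snps = "integer", max_het = "integer"))

setValidity("ROHParams", function(object) {
  if (object@min_snps < 1L) return("min_snps must be >= 1")
  if (object@max_het < 0L) return("max_het must be >= 0")
  TRUE
})

#' Variant exclusion thresholds
#'
#' Thresholds of the five-rule exclusion cascade: (1) alternate-read support
#' below \code{min_alt_reads} in any sequenced affected; (2) population
#' allele frequency above \code{max_pop_af} OR more than \code{max_inhouse}
#' carriers in the in-house cohort; (3) any population homozygote (when
#' \code{exclude_pop_hom}); (4) synonymous; (5) 5' UTR or intronic beyond
#' \code{splice_window_bp} of an exon (optionally also 3' UTR).
#'
#' @slot min_alt_reads integer (default 3).
#' @slot max_pop_af numeric (default 0.05).
#' @slot max_inhouse integer (default 30).
#' @slot exclude_pop_hom logical (default TRUE).
#' @slot splice_window_bp integer (default 2).
#' @slot exclude_utr3 logical (default FALSE): rule 5 read literally drops
#'   5' UTR variants only.
#' @export
setClass("FilterThresholds",
         representation(min_alt_reads = "integer", max_pop_af = "numeric",
                        max_inhouse = "integer", exclude_pop_hom = "logical",
                        splice_window_bp = "integer", exclude_utr3 = "logical"))

setValidity("FilterThresholds", function(object) {
  if (object@min_alt_reads < 0L || object@max_pop_af < 0 ||
      object@max_inhouse < 0L || object@splice_window_bp < 0L)
    return("thresholds must be non-negative")
  TRUE
})

#' Per-rule attrition report of the exclusion cascade
#'
#' Each input variant is attributed to the first rule it fails (rules
#' applied in order 1..5); survivors pass every rule. By construction
#' \code{n_input == sum(excluded) + length(survivors)}.
#'
#' @slot n_input integer, variants entering the cascade.
#' @slot excluded named integer vector, one count per rule in order.
#' @slot survivors character vector of surviving variant ids.
#' @slot rule_of named character: first failing rule per excluded variant.
#' @export
setClass("FilterReport",
         representation(n_input = "integer", excluded = "integer",
                        survivors = "character", rule_of = "character"))

setValidity("FilterReport", function(object) {
  if (object@n_input != sum(object@excluded) + length(object@survivors))
    return("attrition counts must sum to the input count")
  TRUE
})

#' Result of an autosomal recessive co-segregation check
#'
#' @slot consistent logical flag; TRUE iff no violations.
#' @slot violations data.frame with columns \code{individual},
#'   \code{genotype}, \code{reason} (one of \code{affected_not_homalt},
#'   \code{unaffected_homalt}, \code{obligate_carrier_not_het},
#'   \code{mendelian_error}).
#' @export
setClass("SegregationResult",
         representation(consistent = "logical", violations = "data.frame"))

setValidity("SegregationResult", function(object) {
  if (object@consistent != (nrow(object@violations) == 0L))
    return("consistent flag must match emptiness of the violation table")
  TRUE
})

#' Multi-sample variant calls with annotations
#'
#' The central call-set container: one row per bi-allelic site with its
#' annotation payload (consequence class, reference-population alternate
#' allele frequency and homozygote count, in-house cohort carrier count,
#' distance to the nearest exon for intronic classes), and per-sample
#' genotype (0/1/2 alternate-allele dosage, NA = missing), allelic depths
#' and total depth.
#'
#' @slot sites data.frame: \code{chrom}, \code{pos}, \code{id}, \code{ref},
#'   \code{alt}, \code{csqclass}, \code{exac_af}, \code{exac_hom},
#'   \code{inhouse_n}, \code{dist_to_exon} (NA for non-intronic classes).
#' @slot gt integer matrix sites x samples (0, 1, 2 or NA).
#' @slot ad_ref,ad_alt,dp integer matrices of reference / alternate /
#'   total read depths, same shape as \code{gt}.
#' @export
setClass("VariantSet",
         representation(sites = "data.frame", gt = "matrix",
                        ad_ref = "matrix", ad_alt = "matrix", dp = "matrix"))

.csq_classes <- c("missense", "nonsense", "frameshift", "splice_site",
                  "synonymous", "utr5", "utr3", "intronic_near_splice",
                  "intronic_deep", "intergenic")

setValidity("VariantSet", function(object) {
  s <- object@sites
  need <- c("chrom", "pos", "id", "ref", "alt", "csqclass", "exac_af",
            "exac_hom", "inhouse_n", "dist_to_exon")
  if (!all(need %in% names(s)))
    return(paste("sites must have columns:", paste(need, collapse = ", ")))
  for (m in c("gt", "ad_ref", "ad_alt", "dp")) {
    mm <- slot(object, m)
    if (nrow(mm) != nrow(s)) return(sprintf("%s rows must match sites", m))
    if (!identical(dim(mm), dim(object@gt)))
      return("all per-sample matrices must share dimensions")
  }
  if (is.null(colnames(object@gt))) return("gt must carry sample names")
  if (any(s$exac_af < 0 | s$exac_af > 1, na.rm = TRUE))
    return("exac_af must be in [0,1]")
  if (any(s$exac_hom < 0 | s$inhouse_n < 0, na.rm = TRUE))
    return("population counts must be non-negative")
  ok <- object@gt %in% c(0L, 1L, 2L) | is.na(object@gt)
  if (!all(ok)) return("genotypes must be 0, 1, 2 or NA")
  TRUE
})

#' A simulated family: pedigree, haplotypes, ground truth
#'
#' Result of gene-dropping founder haplotypes down a pedigree. Haplotype
#' state is stored as founder-haplotype origin labels per marker
#' (\code{origins}) plus the founder allele carried by each founder
#' haplotype (\code{founder_alleles}); an individual's genotype at a marker
#' is the sum of the alleles of its two origin labels. Ground truth
#' (autozygous IBD segments, planted-variant genotypes, crossover
#' positions) is kept alongside for recovery testing.
#'
#' @slot pedigree Pedigree.
#' @slot map GenomeMap.
#' @slot origins per-chromosome list of integer matrices (markers x
#'   2*N haplotype columns named \code{<id>_1}, \code{<id>_2}) holding
#'   founder-haplotype labels.
#' @slot founder_alleles per-chromosome list of 0/1 integer matrices
#'   (markers x 2*n_founders) of founder haplotype alleles.
#' @slot truth list: \code{ibd_segments} (data.frame individual, chrom,
#'   start_bp, end_bp, n_markers), \code{planted} (NULL or list with the
#'   planted-variant spec and per-individual genotypes),
#'   \code{crossovers} (per-meiosis crossover bp positions).
#' @slot seed integer seed the replicate was generated from.
#' @export
setClass("FamilySim",
         representation(pedigree = "Pedigree", map = "GenomeMap",
                        origins = "list", founder_alleles = "list",
                        truth = "list", seed = "integer"))
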