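#' @include AllClasses.R AllGenerics.R pedigree.R
NULL

.geno_codes <- c("homref", "het", "homalt", "missing")

.normalize_geno <- function(g) {
  if (is.numeric(g)) {
    out <- rep("missing", length(g))
    out[!is.na(g)] <- c("homref", "het", "homalt")[g[!is.na(g)] + 1L]
    names(out) <- names(g)
    g <- out
  }
  g[is.na(g)] <- "missing"
  bad <- !g %in% .geno_codes
  if (any(bad)) stop("unknown genotype code(s): ",
                     paste(unique(g[bad]), collapse = ", "))
  g
}

# alleles a parent genotype can transmit
.transmissible <- list(homref = 0L, het = c(0L, 1L), homalt = 1L)

#' Check co-segregation under a fully penetrant autosomal recessive model
#'
#' Collects violations of the recessive transmission pattern at a single
#' bi-allelic site: affected individuals must be homozygous for the
#' alternate allele; unaffected individuals must not be; a typed
#' unaffected parent of an affected child is an obligate carrier and must
#' be heterozygous; and a child's genotype must be reachable from its two
#' typed parents (Mendelian consistency). Missing genotypes and
#' individuals with unknown affection impose no constraint.
#'
#' @param ped a \code{\link{Pedigree}}.
#' @param genotypes named vector of per-individual genotypes, either
#'   character codes \code{homref}/\code{het}/\code{homalt}/\code{missing}
#'   or alternate-allele dosage 0/1/2 with NA for missing.
#' @return a \code{\linkS4class{SegregationResult}}.
#' @examples
#' ped <- buildPedigree(2, loop = "none")
#' ped <- setAffected(ped, "C1")
#' checkARSegregation(ped, c(FA = "het", MO = "het", C1 = "homalt",
#'                           C2 = "het"))
#' @export
checkARSegregation <- function(ped, genotypes) {
  g <- .normalize_geno(genotypes)
  p <- pedTable(ped)
  unknown <- setdiff(names(g), p$id)
  if (length(unknown))
    stop("genotyped individual(s) absent from pedigree: ",
         paste(unknown, collapse = ", "))
  gt_of <- function(id) if (id %in% names(g)) g[[id]] else "missing"
  aff_of <- function(id) p$affected[match(id, p$id)]
  v <- list()
  add <- function(id, reason)
    v[[length(v) + 1L]] <<- data.frame(individual = id,
                                       genotype = gt_of(id),
                                       reason = reason,
                                       stringsAsFactors = FALSE)

  for (id in p$id) {
    gt <- gt_of(id)
    if (gt == "missing") next
    if (aff_of(id) == 2L && gt != "homalt") add(id, "affected_not_homalt")
    if (aff_of(id) == 1L && gt == "homalt") add(id, "unaffected_homalt")
  }
  # obligate carriers: typed unaffected parents of any affected individual
  aff_ids <- p$id[p$affected == 2L]
  obligate <- unique(unlist(p[p$id %in% aff_ids, c("father", "mother")]))
  obligate <- setdiff(obligate, "0")
  for (id in obligate) {
    gt <- gt_of(id)
    if (gt == "missing" || aff_of(id) == 2L) next
    if (gt != "het") add(id, "obligate_carrier_not_het")
  }
  # Mendelian consistency against two typed parents
  for (i in seq_len(nrow(p))) {
    id <- p$id[i]; fa <- p$father[i]; mo <- p$mother[i]
    if (fa == "0") next
    gts <- c(gt_of(id), gt_of(fa), gt_of(mo))
    if (any(gts == "missing")) next
    possible <- outer(.transmissible[[gts[2]]], .transmissible[[gts[3]]], "+")
    dosage <- match(gts[1], c("homref", "het", "homalt")) - 1L
    if (!dosage %in% possible) add(id, "mendelian_error")
  }
  viol <- if (length(v)) do.call(rbind, v)
          else data.frame(individual = character(), genotype = character(),
                          reason = character(), stringsAsFactors = FALSE)
  new("SegregationResult", consistent = nrow(viol) == 0L, violations = viol)
}

#' @rdname accessors
#' @export
setMethod("isConsistent", "SegregationResult", function(object)
  object@consistent)

#' @rdname accessors
#' @export
setMethod("violations", "SegregationResult", function(object)
  object@violations)

setMethod("show", "SegregationResult", function(object) {
  if (object@consistent) {
    cat("SegregationResult: consistent with fully penetrant AR transmission\n")
  } else {
    cat(sprintf("SegregationResult: INCONSISTENT (%d violation(s))\n",
                nrow(object@violations)))
    print(object@violations)
  }
})

#' Tabulate carrier screening of a control cohort
#'
#' @param control_genotypes vector of genotypes (codes as in
#'   \code{\link{checkARSegregation}}); may be empty.
#' @return named integer vector: \code{carriers} (het) and
#'   \code{homozygotes} (hom-alt).
#' @export
screenControls <- function(control_genotypes) {
  if (!length(control_genotypes))
    return(c(carriers = 0L, homozygotes = 0L))
  g <- .normalize_geno(control_genotypes)
  c(carriers = sum(g == "het"), homozygotes = sum(g == "homalt"))
}
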