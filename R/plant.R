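#' @include genedrop.R
NULL

#' Describe a pathogenic variant to plant in a simulated family
#'
#' The variant enters the pedigree as a single copy on one haplotype of a
#' founder inside the consanguinity loop, so that homozygosity in a
#' descendant is homozygosity by descent. Annotation values default to a
#' very rare missense variant absent from population homozygotes and from
#' the in-house cohort (alternate AF 3/187,624).
#'
#' @param chrom,pos marker coordinates of the planted site (must be an
#'   existing marker position).
#' @param consequence consequence class (default \code{"missense"}).
#' @param annotated_af population (reference-database) alternate allele
#'   frequency annotated on the emitted variant.
#' @param annotated_hom annotated population homozygote count.
#' @param inhouse_n annotated in-house cohort carrier count.
#' @param source_ancestor id of the founder carrying the single copy
#'   (default \code{"GG1"}, a shared great-grandparent of the default
#'   first-cousin pedigree).
#' @param source_hap which of the founder's two haplotypes carries it.
#' @return a validated list of class \code{"plantedVariantSpec"}.
#' @export
plantedVariantSpec <- function(chrom, pos, consequence = "missense",
                               annotated_af = 3 / 187624,
                               annotated_hom = 0L, inhouse_n = 0L,
                               source_ancestor = "GG1", source_hap = 1L) {
  stopifnot(annotated_af >= 0, annotated_af <= 1, annotated_hom >= 0,
            inhouse_n >= 0, source_hap %in% 1:2)
  if (!consequence %in% .csq_classes)
    stop("unknown consequence class: ", consequence)
  structure(list(chrom = chrom, pos = as.integer(pos),
                 consequence = consequence, annotated_af = annotated_af,
                 annotated_hom = as.integer(annotated_hom),
                 inhouse_n = as.integer(inhouse_n),
                 source_ancestor = source_ancestor,
                 source_hap = as.integer(source_hap)),
            class = "plantedVariantSpec")
}

# single-locus gene drop: per-meiosis uniform parental haplotype choice,
# origin labels traced topologically. Cheap stage-1 of the rejection sampler.
.drop_locus <- function(ped) {
  p <- pedTable(ped)
  fnd <- founders(ped)
  og <- matrix(NA_integer_, 2L, nrow(p), dimnames = list(NULL, p$id))
  for (fi in seq_along(fnd))
    og[, fnd[fi]] <- c(.hap_label(fi, 1L), .hap_label(fi, 2L))
  choices <- list()
  for (id in .nonfounders_toposorted(ped)) {
    fa <- p$father[match(id, p$id)]; mo <- p$mother[match(id, p$id)]
    for (side in 1:2) {
      par_id <- if (side == 1L) fa else mo
      ch <- sample.int(2L, 1L)
      choices[[paste0(id, "<", par_id)]] <- ch
      og[side, id] <- og[ch, par_id]
    }
  }
  list(origins = og, choices = choices)
}

.source_label <- function(ped, spec) {
  fnd <- founders(ped)
  fi <- match(spec$source_ancestor, fnd)
  if (is.na(fi))
    stop("source_ancestor must be a founder: ", spec$source_ancestor)
  .hap_label(fi, spec$source_hap)
}

# write the planted allele into the founder haplotype matrix: the planted
# marker carries the alternate allele on the source haplotype only, so
# hom-alt is equivalent to autozygosity for that haplotype.
.apply_plant <- function(sim, spec) {
  mk <- markers(sim@map)
  idx <- which(mk$chrom == spec$chrom & mk$pos == spec$pos)
  if (!length(idx)) stop("planted position is not a marker position")
  cmk_idx <- which(mk$pos[mk$chrom == spec$chrom] == spec$pos)
  src <- .source_label(sim@pedigree, spec)
  fa <- sim@founder_alleles[[spec$chrom]]
  fa[cmk_idx, ] <- 0L
  fa[cmk_idx, src] <- 1L
  sim@founder_alleles[[spec$chrom]] <- fa

  og <- sim@origins[[spec$chrom]]
  ids <- pedTable(sim@pedigree)$id
  g <- vapply(ids, function(id)
    as.integer(og[cmk_idx, paste0(id, "_1")] == src) +
    as.integer(og[cmk_idx, paste0(id, "_2")] == src), integer(1))
  affected <- ids[g == 2L]
  sim@pedigree <- setAffected(sim@pedigree, affected)
  sim@truth$planted <- list(spec = spec, genotypes = g)
  sim
}

#' Plant a recessive pathogenic variant in a simulated family
#'
#' Places a single copy of the variant on the specified founder haplotype
#' and assigns affection status under full penetrance: an individual is
#' affected iff homozygous for the planted allele (equivalently,
#' homozygous by descent for the source haplotype). With
#' \code{n_affected_target} set, meioses are redrawn until exactly that
#' many children of the focal couple are affected, using an exact
#' two-stage sampler: inheritance at the planted locus alone is drawn and
#' screened first, then full chromosomes are drawn conditional on the
#' accepted single-locus inheritance (valid because the Haldane start
#' phase is uniform and independent of crossover positions).
#'
#' @param sim a \code{\link{FamilySim}} from \code{\link{geneDrop}}.
#' @param spec a \code{\link{plantedVariantSpec}}.
#' @param n_affected_target optional integer; exact number of affected
#'   children required.
#' @param max_attempts rejection bound (default 10000).
#' @param seed seed for the redraw (default: the sim's own seed).
#' @return an updated \code{\link{FamilySim}} with affection assigned and
#'   the planted record in its truth slot (including \code{attempts} when
#'   rejection sampling was used).
#' @export
plantVariant <- function(sim, spec, n_affected_target = NULL,
                         max_attempts = 10000L, seed = sim@seed) {
  stopifnot(inherits(spec, "plantedVariantSpec"))
  if (is.null(n_affected_target)) return(.apply_plant(sim, spec))

  ped <- sim@pedigree
  kids <- pedTable(ped)$id[pedTable(ped)$father != "0" &
                           pedTable(ped)$father == "FA"]
  if (n_affected_target > length(kids))
    stop("n_affected_target exceeds number of children")
  src <- .source_label(ped, spec)
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    d <- .drop_locus(ped)
    n_aff <- sum(d$origins[1L, kids] == src & d$origins[2L, kids] == src)
    if (n_aff == n_affected_target) {
      drop_seed <- sample.int(.Machine$integer.max, 1L)
      sim2 <- geneDrop(ped, sim@map, drop_seed,
                       .condition = list(chrom = spec$chrom, pos = spec$pos,
                                         choices = d$choices))
      sim2 <- .apply_plant(sim2, spec)
      sim2@truth$planted$attempts <- attempt
      sim2@seed <- as.integer(seed)
      return(sim2)
    }
  }
  stop(sprintf("affected-count target %d not reached in %d attempts",
               n_affected_target, max_attempts))
}
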