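#' @include AllClasses.R AllGenerics.R pedigree.R genomemap.R
NULL

# founder haplotype label of founder f (1-based among founders), hap h in 1:2
.hap_label <- function(founder_idx, h) 2L * (founder_idx - 1L) + h

# one meiosis on one chromosome under the Haldane model (no interference):
# crossover count ~ Poisson(genetic length in Morgans), positions uniform on
# the physical map (uniform recombination rate). Returns the transmitted
# origin-label vector. If `required` is given (list(pos=, choice=)), the
# start phase is set so the phase at `pos` equals `choice`; unconditionally
# the start phase is uniform and independent of crossover positions, so
# conditioning this way is exact.
.meiosis <- function(parent_origins, positions, length_bp, length_morgans,
                     required = NULL) {
  k <- stats::rpois(1L, length_morgans)
  xpos <- if (k > 0L) sort(stats::runif(k, 0, length_bp)) else numeric(0)
  seg <- findInterval(positions, xpos)          # crossovers before marker
  if (is.null(required)) {
    start <- sample.int(2L, 1L)
  } else {
    k_at <- sum(xpos < required$pos)
    start <- ((required$choice - 1L - k_at) %% 2L) + 1L
  }
  phase <- ((start - 1L + seg) %% 2L) + 1L
  list(gamete = parent_origins[cbind(seq_along(positions), phase)],
       crossovers = xpos)
}

#' Gene-drop founder haplotypes down a pedigree
#'
#' Assigns each founder two uniquely labelled haplotypes whose alleles are
#' independent Bernoulli draws at the map's founder allele frequencies,
#' then transmits haplotypes down the pedigree meiosis by meiosis with
#' Haldane (no-interference) recombination: crossover count per chromosome
#' ~ Poisson(genetic length in Morgans), crossover positions uniform.
#' Identity-by-descent is tracked exactly through founder-haplotype origin
#' labels; a marker is autozygous in an individual when both origin labels
#' coincide.
#'
#' @param ped a \code{\link{Pedigree}}.
#' @param map a \code{\link{GenomeMap}} with at least one marker.
#' @param seed integer seed.
#' @param .condition internal: exact single-locus conditioning used by
#'   \code{\link{plantVariant}} (list with \code{chrom}, \code{pos} and
#'   per-meiosis parental \code{choices}).
#' @return a \code{\link{FamilySim}} whose truth record holds per-individual
#'   autozygous IBD segments and per-meiosis crossover positions.
#' @examples
#' ped <- buildPedigree(n_children = 1)
#' map <- makeGenomeMap(n_chrom = 1, markers_per_chrom = 50, seed = 2)
#' sim <- geneDrop(ped, map, seed = 3)
#' autozygousFraction(sim, "C1")
#' @export
geneDrop <- function(ped, map, seed, .condition = NULL) {
  mk <- markers(map)
  if (nrow(mk) == 0L) stop("marker set is empty")
  set.seed(seed)
  p <- pedTable(ped)
  ids <- p$id
  fnd <- founders(ped)
  chroms <- chromosomes(map)$chrom
  hap_cols <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))

  founder_alleles <- list(); origins <- list(); crossovers <- list()
  for (ci in seq_along(chroms)) {
    cc <- chroms[ci]
    cmk <- mk[mk$chrom == cc, ]
    M <- nrow(cmk)
    fa <- matrix(0L, M, 2L * length(fnd))
    for (j in seq_len(2L * length(fnd)))
      fa[, j] <- as.integer(stats::runif(M) < cmk$af)
    colnames(fa) <- as.vector(rbind(paste0(fnd, "_1"), paste0(fnd, "_2")))
    founder_alleles[[cc]] <- fa

    og <- matrix(NA_integer_, M, 2L * length(ids))
    colnames(og) <- hap_cols
    for (fi in seq_along(fnd)) {
      og[, paste0(fnd[fi], "_1")] <- .hap_label(fi, 1L)
      og[, paste0(fnd[fi], "_2")] <- .hap_label(fi, 2L)
    }
    origins[[cc]] <- og
  }

  len_bp <- stats::setNames(chromosomes(map)$length_bp, chroms)
  len_m <- stats::setNames(chromosomes(map)$length_morgans, chroms)
  order_nf <- .nonfounders_toposorted(ped)
  for (id in order_nf) {
    fa_id <- p$father[match(id, ids)]
    mo_id <- p$mother[match(id, ids)]
    for (ci in seq_along(chroms)) {
      cc <- chroms[ci]
      pos <- mk$pos[mk$chrom == cc]
      for (side in 1:2) {
        par_id <- if (side == 1L) fa_id else mo_id
        key <- paste0(id, "<", par_id, ".", cc)
        req <- NULL
        if (!is.null(.condition) && .condition$chrom == cc) {
          req <- list(pos = .condition$pos,
                      choice = .condition$choices[[paste0(id, "<", par_id)]])
        }
        paro <- origins[[cc]][, paste0(par_id, c("_1", "_2")), drop = FALSE]
        m <- .meiosis(paro, pos, len_bp[[cc]], len_m[[cc]], req)
        origins[[cc]][, paste0(id, "_", side)] <- m$gamete
        crossovers[[key]] <- m$crossovers
      }
    }
  }

  truth <- list(ibd_segments = .ibd_segments(origins, mk, ids),
                planted = NULL, crossovers = crossovers)
  new("FamilySim", pedigree = ped, map = map, origins = origins,
      founder_alleles = founder_alleles, truth = truth,
      seed = as.integer(seed))
}

# autozygous runs (origin1 == origin2) per individual, as bp intervals
.ibd_segments <- function(origins, mk, ids) {
  out <- list()
  for (cc in names(origins)) {
    pos <- mk$pos[mk$chrom == cc]
    og <- origins[[cc]]
    for (id in ids) {
      eq <- og[, paste0(id, "_1")] == og[, paste0(id, "_2")]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      w <- which(r$values)
      if (length(w))
        out[[length(out) + 1L]] <- data.frame(
          individual = id, chrom = cc,
          start_bp = pos[starts[w]], end_bp = pos[ends[w]],
          n_markers = r$lengths[w], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(individual = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_markers = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @rdname accessors
#' @export
setMethod("truthRecord", "FamilySim", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("ibdSegments", "FamilySim", function(object)
  object@truth$ibd_segments)

#' @rdname accessors
#' @export
setMethod("sampleIds", "FamilySim", function(object)
  pedTable(object@pedigree)$id)

setMethod("show", "FamilySim", function(object) {
  cat(sprintf("FamilySim: %d individuals, %d markers (seed %d)%s\n",
              nrow(pedTable(object@pedigree)), nrow(markers(object@map)),
              object@seed,
              if (is.null(object@truth$planted)) ""
              else sprintf(", planted variant at %s:%d",
                           object@truth$planted$spec$chrom,
                           object@truth$planted$spec$pos)))
})

#' Fraction of markers autozygous in one individual
#'
#' A marker is autozygous when both haplotypes carry the same founder
#' haplotype label. The expectation of this fraction is the inbreeding
#' coefficient F (1/16 for offspring of first cousins).
#'
#' @param sim a \code{\link{FamilySim}}.
#' @param id individual id.
#' @return numeric fraction in [0, 1].
#' @export
autozygousFraction <- function(sim, id) {
  tot <- 0L; auto <- 0L
  for (cc in names(sim@origins)) {
    og <- sim@origins[[cc]]
    if (!paste0(id, "_1") %in% colnames(og)) stop("unknown individual: ", id)
    eq <- og[, paste0(id, "_1")] == og[, paste0(id, "_2")]
    tot <- tot + length(eq); auto <- auto + sum(eq)
  }
  auto / tot
}

#' True genotypes (alternate-allele dosage) of a simulated family
#'
#' @param sim a \code{\link{FamilySim}}.
#' @return integer matrix markers x individuals with values 0/1/2; rows in
#'   map order, named \code{chrom:pos}.
#' @export
trueGenotypes <- function(sim) {
  mk <- markers(sim@map)
  ids <- sampleIds(sim)
  gt <- matrix(NA_integer_, nrow(mk), length(ids),
               dimnames = list(paste0(mk$chrom, ":", mk$pos), ids))
  off <- 0L
  for (cc in names(sim@origins)) {
    og <- sim@origins[[cc]]
    fa <- sim@founder_alleles[[cc]]
    M <- nrow(og)
    rows <- seq_len(M)
    for (id in ids) {
      a1 <- fa[cbind(rows, og[, paste0(id, "_1")])]
      a2 <- fa[cbind(rows, og[, paste0(id, "_2")])]
      gt[off + rows, id] <- a1 + a2
    }
    off <- off + M
  }
  gt
}
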