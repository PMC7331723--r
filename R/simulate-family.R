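#' @include plant.R emit.R measurements.R
NULL

#' Simulate a complete study family
#'
#' One call produces every input the analysis pipeline consumes: a
#' consanguineous pedigree, gene-dropped haplotypes with a planted
#' recessive pathogenic variant and the affected-count structure of the
#' study family (default: 8 children, exactly 5 affected, first-cousin
#' parents), noisy annotated variant calls, reference norms and
#' simulated hand measurements, plus a phenotype table and the ground
#' truth. All randomness derives from the single \code{seed}; the stream
#' is split in documented order (map/pedigree, meioses, noise,
#' measurements/phenotypes) so every stage is independently
#' reproducible.
#'
#' @param seed master integer seed.
#' @param n_children,n_affected_target family structure (defaults 8 / 5);
#'   set \code{n_affected_target = NULL} to skip planting entirely.
#' @param loop consanguinity degree, see \code{\link{buildPedigree}}.
#' @param map a \code{\link{GenomeMap}} or NULL to build the default map.
#' @param planted a \code{\link{plantedVariantSpec}} or NULL for the
#'   default (a very rare missense variant at the central marker of
#'   chr1, one copy on haplotype 1 of founder GG1).
#' @param noise a \code{\linkS4class{NoiseModel}}.
#' @param mspec a \code{\link{measurementSimSpec}}.
#' @param norms reference norm table (default \code{\link{makeNormTable}}).
#' @param n_sequenced number of affected children treated as exome-
#'   sequenced (default 2, mirroring a sequenced sib pair).
#' @param max_attempts rejection bound for the affected-count target.
#' @return list of class \code{"familySimulation"}: \code{sim}
#'   (\code{\link{FamilySim}}), \code{variants}
#'   (\code{\linkS4class{VariantSet}}), \code{norms},
#'   \code{measurements}, \code{subjects}, \code{phenotypes},
#'   \code{sequenced} (ids), \code{seed}.
#' @export
simulateFamily <- function(seed, n_children = 8L, n_affected_target = 5L,
                           loop = "first_cousins", map = NULL,
                           planted = NULL, noise = noiseModel(),
                           mspec = measurementSimSpec(),
                           norms = makeNormTable(), n_sequenced = 2L,
                           max_attempts = 10000L) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 4L)  # map, meioses, noise, meas
  if (is.null(map)) map <- makeGenomeMap(seed = sub[1])
  ped <- buildPedigree(n_children = n_children, loop = loop)
  if (!is.null(n_affected_target) && is.null(planted)) {
    m1 <- markers(map)[markers(map)$chrom == chromosomes(map)$chrom[1], ]
    planted <- plantedVariantSpec(chrom = m1$chrom[1],
                                  pos = m1$pos[ceiling(nrow(m1) / 2)],
                                  source_ancestor = founders(ped)[1])
  }
  sim <- geneDrop(ped, map, sub[2])
  if (!is.null(planted)) {
    sim <- if (is.null(n_affected_target)) plantVariant(sim, planted)
           else plantVariant(sim, planted, n_affected_target,
                             max_attempts = max_attempts, seed = sub[2])
  }
  vs <- emitVariants(sim, noise, seed = sub[3])

  p <- pedTable(sim@pedigree)
  kids <- p[p$father == "FA", , drop = FALSE]
  subjects <- data.frame(individual = kids$id, sex = kids$sex,
                         age_years = round(seq(30, 68,
                                               length.out = max(nrow(kids), 2L))[seq_len(nrow(kids))], 1),
                         affected = kids$affected,
                         stringsAsFactors = FALSE)
  set.seed(sub[4])
  meas <- if (nrow(subjects)) {
    simulateMeasurements(norms, mspec, subjects,
                         seed = sample.int(.Machine$integer.max, 1L))
  } else data.frame(individual = character(), side = character(),
                    bone_id = character(), length_mm = numeric())
  aff <- subjects$affected == 2L
  phenotypes <- data.frame(
    individual = subjects$individual,
    height_cm = round(ifelse(aff, stats::rnorm(nrow(subjects), 156.5, 4),
                             stats::rnorm(nrow(subjects), 168, 7)), 1),
    myopia = aff,
    microspherophakia = aff & stats::runif(nrow(subjects)) < 0.8,
    ectopia_lentis = aff & stats::runif(nrow(subjects)) < 0.8,
    stringsAsFactors = FALSE)
  sequenced <- utils::head(subjects$individual[aff], n_sequenced)
  structure(list(sim = sim, variants = vs, norms = norms,
                 measurements = meas, subjects = subjects,
                 phenotypes = phenotypes, sequenced = sequenced,
                 seed = as.integer(seed)),
            class = "familySimulation")
}

#' Write the simulator ground truth as JSON
#'
#' Records autozygous IBD segments per individual, the planted-variant
#' spec with per-individual true genotypes, and per-meiosis crossover
#' positions.
#'
#' @param sim a \code{\link{FamilySim}}.
#' @param path output path.
#' @export
writeTruthJson <- function(sim, path) {
  tr <- truthRecord(sim)
  planted <- if (is.null(tr$planted)) NULL else list(
    spec = unclass(tr$planted$spec),
    genotypes = as.list(tr$planted$genotypes),
    attempts = tr$planted$attempts)
  jsonlite::write_json(list(ibd_segments = tr$ibd_segments,
                            planted = planted,
                            crossovers = tr$crossovers),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
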