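#' @include filters.R roh.R segregation.R simulate-family.R vcf-io.R
NULL

#' Intersect the three evidence layers into a candidate set
#'
#' A candidate variant must (i) survive the exclusion cascade, (ii) be
#' homozygous for the alternate allele in every sequenced affected
#' sample, and (iii) lie inside the shared ROH of the sequenced
#' affecteds. The provenance table records each surviving variant's
#' status under predicates (ii) and (iii).
#'
#' @param report a \code{\linkS4class{FilterReport}}.
#' @param shared shared-ROH data.frame (\code{chrom}, \code{start_bp},
#'   \code{end_bp}), e.g. from \code{\link{sharedROH}}.
#' @param vs the \code{\linkS4class{VariantSet}} the report was built
#'   from.
#' @param affected_samples sequenced affected sample ids.
#' @return list: \code{candidates} (data.frame ordered by chrom, pos)
#'   and \code{provenance} (all survivors with per-predicate flags).
#' @export
prioritizeCandidates <- function(report, shared, vs, affected_samples) {
  s <- variantSites(vs)
  surv <- s$id %in% survivingVariants(report)
  gt <- genotypes(vs)[, affected_samples, drop = FALSE]
  homalt <- rowSums(gt == 2L, na.rm = TRUE) == length(affected_samples) &
    rowSums(is.na(gt)) == 0L
  in_roh <- rep(FALSE, nrow(s))
  if (nrow(shared)) {
    q <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, width = 1L))
    r <- GenomicRanges::GRanges(shared$chrom,
                                IRanges::IRanges(shared$start_bp,
                                                 shared$end_bp))
    in_roh <- IRanges::overlapsAny(q, r)
  }
  prov <- data.frame(id = s$id, chrom = s$chrom, pos = s$pos,
                     csqclass = s$csqclass, exac_af = s$exac_af,
                     passed_filters = surv, homalt_in_affected = homalt,
                     in_shared_roh = in_roh, stringsAsFactors = FALSE)
  prov <- prov[surv, , drop = FALSE]
  cand <- prov[prov$homalt_in_affected & prov$in_shared_roh, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  rownames(prov) <- rownames(cand) <- NULL
  list(candidates = cand, provenance = prov)
}

#' Summarize cohort phenotypes
#'
#' @param cohort data.frame with \code{individual}, \code{height_cm} and
#'   any number of logical feature columns (e.g. \code{myopia}).
#' @return list: \code{mean_height_cm} (arithmetic mean over non-missing
#'   heights), \code{n}, and \code{features} (data.frame feature /
#'   numerator / denominator / fraction).
#' @examples
#' summarizePhenotypes(data.frame(individual = paste0("II-", c(2, 3, 5, 6, 8)),
#'                                height_cm = c(160, 149, 157, 161, 155.5),
#'                                myopia = TRUE))
#' @export
summarizePhenotypes <- function(cohort) {
  h <- cohort$height_cm[!is.na(cohort$height_cm)]
  if (!length(h)) stop("need at least one individual with a height")
  feat_cols <- names(cohort)[vapply(cohort, is.logical, logical(1))]
  features <- do.call(rbind, lapply(feat_cols, function(f) {
    x <- cohort[[f]][!is.na(cohort[[f]])]
    data.frame(feature = f, numerator = sum(x), denominator = length(x),
               fraction = if (length(x)) sum(x) / length(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(features))
    features <- data.frame(feature = character(), numerator = integer(),
                           denominator = integer(), fraction = numeric())
  list(mean_height_cm = mean(h), n = length(h), features = features)
}

#' Assemble a pipeline configuration
#'
#' Either \code{simulate} (arguments for \code{\link{simulateFamily}})
#' or \code{paths} (named list with \code{vcf}, \code{ped}, optionally
#' \code{norms} and \code{measurements}) must be given.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param simulate NULL or list of \code{\link{simulateFamily}}
#'   arguments (without \code{seed}).
#' @param paths NULL or list of input paths.
#' @param roh list of \code{\link{rohParams}} arguments.
#' @param filters list of \code{\link{filterThresholds}} arguments.
#' @param anthropometry list: \code{delta}, \code{marked_threshold}.
#' @param sequenced optional explicit sequenced-affected sample ids.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(outdir, seed = 1L, simulate = list(),
                           paths = NULL, roh = list(), filters = list(),
                           anthropometry = list(delta = 1.0,
                                                marked_threshold = -5),
                           sequenced = NULL) {
  if (is.null(simulate) && is.null(paths))
    stop("configuration needs either a simulation block or input paths")
  if (!is.null(paths)) {
    need <- c("vcf", "ped")
    if (!all(need %in% names(paths)))
      stop("paths must name at least: ", paste(need, collapse = ", "))
    for (p in unlist(paths)) if (!file.exists(p))
      stop("input path does not exist: ", p)
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, paths = paths, roh = roh,
                 filters = filters, anthropometry = anthropometry,
                 sequenced = sequenced),
            class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file whose top-level keys mirror the
#'   \code{pipelineConfig} arguments.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

.write_tsv_atomic <- function(x, path, ...) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(x, tmp, quote = FALSE, sep = "\t", row.names = FALSE,
                     ...)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full autozygosity-mapping pipeline
#'
#' Orchestrates simulate (or load), per-sample ROH calling, the
#' five-rule exclusion cascade, shared-ROH intersection, candidate
#' prioritization, co-segregation checking of each candidate against the
#' whole family, hand-profile comparison and the cohort phenotype
#' summary. All stage outputs are written atomically under
#' \code{config$outdir}; a line-delimited JSON run log records seeds,
#' thresholds, attrition and the candidate count. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the in-memory stage results:
#'   \code{variants}, \code{pedigree}, \code{sequenced}, \code{roh},
#'   \code{shared}, \code{report}, \code{candidates},
#'   \code{segregation}, \code{profiles}, \code{comparison},
#'   \code{phenotype_summary}, \code{truth} (NULL when running from
#'   files).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  log_con <- file(out("run_log.jsonl"), "w")
  on.exit(close(log_con))
  logj <- function(stage, ...)
    writeLines(jsonlite::toJSON(c(list(stage = stage), list(...)),
                                auto_unbox = TRUE, digits = NA), log_con)

  norms <- NULL; meas <- NULL; subjects <- NULL; pheno <- NULL; truth <- NULL
  if (!is.null(config$paths)) {
    vs <- readFamilyVcf(config$paths$vcf)
    ped <- readPed(config$paths$ped)
    if (!is.null(config$paths$norms)) norms <- readNormTable(config$paths$norms)
    if (!is.null(config$paths$measurements))
      meas <- readMeasurements(config$paths$measurements)
    if (!is.null(config$paths$subjects))
      subjects <- utils::read.table(config$paths$subjects, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
    if (!is.null(meas) && is.null(norms))
      stop("stage anthropometry: measurements given without norms")
    logj("load", vcf = config$paths$vcf, n_sites = nrow(variantSites(vs)))
  } else {
    fs <- do.call(simulateFamily, c(list(seed = config$seed),
                                    config$simulate))
    vs <- fs$variants; ped <- fs$sim@pedigree
    norms <- fs$norms; meas <- fs$measurements
    subjects <- fs$subjects; pheno <- fs$phenotypes
    truth <- truthRecord(fs$sim)
    writeFamilyVcf(vs, out("family.vcf"))
    writePed(ped, out("family.ped"))
    writeNormTable(norms, out("norms.tsv"))
    writeMeasurements(meas, out("measurements.tsv"))
    .write_tsv_atomic(subjects, out("subjects.tsv"))
    .write_tsv_atomic(pheno, out("phenotypes.tsv"))
    writeTruthJson(fs$sim, out("truth.json"))
    if (is.null(config$sequenced)) config$sequenced <- fs$sequenced
    logj("simulate", seed = config$seed,
         n_individuals = nrow(pedTable(ped)),
         n_affected = length(affectedIds(ped)),
         planted = !is.null(truth$planted))
  }

  sequenced <- config$sequenced
  if (is.null(sequenced) || !length(sequenced)) {
    aff <- intersect(affectedIds(ped), sampleIds(vs))
    sequenced <- if (length(aff)) utils::head(aff, 2L)
                 else utils::head(sampleIds(vs), 2L)
  }

  rp <- do.call(rohParams, config$roh)
  roh <- rohRegions(vs, sequenced, rp)
  writeROHTable(roh, out("roh.tsv"))
  shared <- sharedROH(roh, sequenced, allow_empty = TRUE)
  .write_tsv_atomic(shared, out("shared_roh.tsv"))
  logj("roh", samples = sequenced, min_snps = rp@min_snps,
       max_het = rp@max_het, n_regions = nrow(roh),
       n_shared = nrow(shared))

  th <- do.call(filterThresholds, config$filters)
  report <- applyFilters(vs, th, sequenced)
  .write_tsv_atomic(data.frame(rule = names(excludedCounts(report)),
                               excluded = as.integer(excludedCounts(report))),
                    out("filter_attrition.tsv"))
  writeFamilyVcf(vs[variantSites(vs)$id %in% survivingVariants(report), ],
                 out("survivors.vcf"))
  logj("filter", n_input = report@n_input,
       excluded = as.list(excludedCounts(report)),
       n_surviving = length(survivingVariants(report)),
       conserved = report@n_input ==
         sum(excludedCounts(report)) + length(survivingVariants(report)))

  pri <- prioritizeCandidates(report, shared, vs, sequenced)
  .write_tsv_atomic(pri$candidates, out("candidates.tsv"))
  .write_tsv_atomic(pri$provenance, out("candidate_provenance.tsv"))
  logj("prioritize", n_candidates = nrow(pri$candidates))

  seg <- NULL
  if (nrow(pri$candidates)) {
    idx <- match(pri$candidates$id[1], variantSites(vs)$id)
    fam <- intersect(sampleIds(ped), sampleIds(vs))
    seg <- checkARSegregation(ped, genotypes(vs)[idx, fam])
    .write_tsv_atomic(violations(seg), out("segregation_violations.tsv"))
    writeLines(sprintf("candidate %s: %s", pri$candidates$id[1],
                       if (isConsistent(seg)) "consistent with AR transmission"
                       else "INCONSISTENT"),
               out("segregation.txt"))
    logj("segregation", candidate = pri$candidates$id[1],
         consistent = isConsistent(seg))
  }

  profiles <- NULL; comparison <- NULL
  if (!is.null(meas) && nrow(meas) && !is.null(subjects)) {
    profiles <- profileHands(meas, norms, subjects)
    .write_tsv_atomic(profiles, out("profiles.tsv"))
    aff_flag <- if (is.logical(subjects$affected)) subjects$affected
                else subjects$affected == 2L
    aff_ids <- subjects$individual[aff_flag]
    pa <- profiles[profiles$individual %in% aff_ids, , drop = FALSE]
    pu <- profiles[!profiles$individual %in% aff_ids, , drop = FALSE]
    if (nrow(pa) && nrow(pu)) {
      comparison <- compareProfiles(pa, pu,
                                    delta = config$anthropometry$delta,
                                    marked_threshold = config$anthropometry$marked_threshold)
      jsonlite::write_json(comparison, out("hand_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      logj("anthropometry", difference = comparison$difference,
           brachydactyly = comparison$brachydactyly,
           n_marked = nrow(comparison$marked_bones))
    }
  }

  phen_sum <- NULL
  aff_with_height <- !is.null(pheno) &&
    any(pheno$individual %in% affectedIds(ped) & !is.na(pheno$height_cm))
  if (aff_with_height) {
    phen_sum <- summarizePhenotypes(pheno[pheno$individual %in%
                                            affectedIds(ped), , drop = FALSE])
    jsonlite::write_json(phen_sum, out("phenotype_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    logj("phenotypes", mean_height_cm = phen_sum$mean_height_cm,
         n = phen_sum$n)
  }

  invisible(list(variants = vs, pedigree = ped, sequenced = sequenced,
                 roh = roh, shared = shared, report = report,
                 candidates = pri$candidates, provenance = pri$provenance,
                 segregation = seg, profiles = profiles,
                 comparison = comparison, phenotype_summary = phen_sum,
                 truth = truth))
}
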