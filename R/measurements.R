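#' @include anthropometry.R
NULL

#' Specify the hand-measurement simulation
#'
#' Defaults reproduce the published pattern: unaffected bone z-scores
#' uniform in [-1, 1], affected in [-3, -1], plus two fixed unilateral
#' outliers (left first metacarpal at -7 SD in one affected sibling,
#' right first proximal phalanx at -5.3 SD in another).
#'
#' @param z_range_unaffected,z_range_affected length-2 numeric intervals
#'   (SD units).
#' @param outlier_bones data.frame with columns \code{individual},
#'   \code{side}, \code{bone_id}, \code{z}, or NULL. The default
#'   placeholder individuals \code{".A1"}/\code{".A2"} are remapped to
#'   the first two affected subjects by
#'   \code{\link{simulateMeasurements}}.
#' @return validated list of class \code{"measurementSimSpec"}.
#' @export
measurementSimSpec <- function(z_range_unaffected = c(-1, 1),
                               z_range_affected = c(-3, -1),
                               outlier_bones = data.frame(
                                 individual = c(".A1", ".A2"),
                                 side = c("left", "right"),
                                 bone_id = c("MC1", "PP1"),
                                 z = c(-7, -5.3),
                                 stringsAsFactors = FALSE)) {
  stopifnot(length(z_range_unaffected) == 2,
            diff(z_range_unaffected) >= 0,
            length(z_range_affected) == 2,
            diff(z_range_affected) >= 0)
  if (!is.null(outlier_bones) && nrow(outlier_bones) &&
      any(!is.finite(outlier_bones$z)))
    stop("outlier z values must be finite")
  structure(list(z_range_unaffected = z_range_unaffected,
                 z_range_affected = z_range_affected,
                 outlier_bones = outlier_bones),
            class = "measurementSimSpec")
}

#' Simulate hand-bone measurements with a planted z-structure
#'
#' For every subject, side and bone, draws a z-score uniformly from the
#' subject's group interval (affected or unaffected), overrides the
#' configured outlier bones to their fixed z, and emits the length
#' \code{mean + z * sd} under the subject's age- and sex-specific
#' reference moments. Recomputing z-scores from the emitted lengths with
#' \code{\link{profileHands}} recovers the planted values exactly.
#'
#' @param norms norm table covering every (bone, sex, age) requested.
#' @param spec a \code{\link{measurementSimSpec}}.
#' @param subjects data.frame: \code{individual}, \code{sex},
#'   \code{age_years}, \code{affected} (logical or 1/2 PED coding).
#' @param seed integer seed.
#' @return measurement data.frame: \code{individual}, \code{side},
#'   \code{bone_id}, \code{length_mm}.
#' @export
simulateMeasurements <- function(norms, spec, subjects, seed = 1L) {
  stopifnot(inherits(spec, "measurementSimSpec"))
  aff <- subjects$affected
  if (!is.logical(aff)) aff <- aff == 2L
  set.seed(seed)
  ob <- spec$outlier_bones
  if (!is.null(ob) && nrow(ob)) {
    # remap placeholder outlier carriers to the first affected subjects
    ph <- grepl("^\\.A[0-9]+$", ob$individual)
    idx <- as.integer(sub("^\\.A", "", ob$individual[ph]))
    aff_ids <- subjects$individual[aff]
    keep <- !ph | idx <= length(aff_ids)
    ob$individual[ph & keep] <- aff_ids[idx[idx <= length(aff_ids)]]
    ob <- ob[keep, , drop = FALSE]
  }
  rows <- expand.grid(bone_id = .hand_bones, side = c("left", "right"),
                      individual = subjects$individual,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(rows$individual, subjects$individual)
  lo <- ifelse(aff[i], spec$z_range_affected[1], spec$z_range_unaffected[1])
  hi <- ifelse(aff[i], spec$z_range_affected[2], spec$z_range_unaffected[2])
  z <- stats::runif(nrow(rows), lo, hi)
  if (!is.null(ob) && nrow(ob)) {
    key <- paste(rows$individual, rows$side, rows$bone_id)
    okey <- paste(ob$individual, ob$side, ob$bone_id)
    hit <- match(key, okey)
    z[!is.na(hit)] <- ob$z[hit[!is.na(hit)]]
  }
  len <- vapply(seq_len(nrow(rows)), function(r) {
    mo <- lookupNorm(norms, rows$bone_id[r], subjects$sex[i[r]],
                     subjects$age_years[i[r]])
    mo[["mean_mm"]] + z[r] * mo[["sd_mm"]]
  }, numeric(1))
  data.frame(individual = rows$individual, side = rows$side,
             bone_id = rows$bone_id, length_mm = len,
             stringsAsFactors = FALSE)
}
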