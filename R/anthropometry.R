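#' @include AllClasses.R AllGenerics.R
NULL

# the 19 tubular bones of one hand: 5 metacarpals, 5 proximal, 4 middle
# (the thumb has none) and 5 distal phalanges
.hand_bones <- c(paste0("MC", 1:5), paste0("PP", 1:5), paste0("MP", 2:5),
                 paste0("DP", 1:5))

#' Standardized bone length (z-score)
#'
#' @param length_mm observed length.
#' @param mean_mm,sd_mm reference moments for the bone, sex and age.
#' @return (length_mm - mean_mm) / sd_mm, in SD units.
#' @examples
#' zScore(40, 47, 1)    # -7
#' @export
zScore <- function(length_mm, mean_mm, sd_mm) {
  if (any(sd_mm <= 0)) stop("sd_mm must be > 0")
  (length_mm - mean_mm) / sd_mm
}

#' Look up age- and sex-specific reference moments
#'
#' Exact row if the age is tabulated; otherwise linear interpolation in
#' age between the two flanking rows. Ages outside the tabulated range
#' for that bone and sex are an error (no extrapolation).
#'
#' @param norms norm table: data.frame with columns \code{bone_id},
#'   \code{sex} (1/2), \code{age_years}, \code{mean_mm}, \code{sd_mm}.
#' @param bone bone id (e.g. \code{"MC1"}).
#' @param sex 1 = male, 2 = female.
#' @param age_years age, possibly fractional.
#' @return named numeric: \code{mean_mm}, \code{sd_mm}.
#' @export
lookupNorm <- function(norms, bone, sex, age_years) {
  r <- norms[norms$bone_id == bone & norms$sex == sex, , drop = FALSE]
  if (!nrow(r)) stop(sprintf("no norms for bone %s sex %d", bone, sex))
  r <- r[order(r$age_years), , drop = FALSE]
  if (age_years < min(r$age_years) || age_years > max(r$age_years))
    stop(sprintf("age %.2f outside tabulated range [%g, %g] for %s",
                 age_years, min(r$age_years), max(r$age_years), bone))
  m <- stats::approx(r$age_years, r$mean_mm, xout = age_years)$y
  s <- stats::approx(r$age_years, r$sd_mm, xout = age_years)$y
  c(mean_mm = m, sd_mm = s)
}

#' Metacarpophalangeal pattern profiles
#'
#' Standardizes every measured bone length against its age- and
#' sex-specific reference moments, one profile per (individual, side).
#'
#' @param measurements data.frame: \code{individual}, \code{side}
#'   (\code{"left"}/\code{"right"}), \code{bone_id}, \code{length_mm}.
#' @param norms norm table (see \code{\link{lookupNorm}}).
#' @param subjects data.frame: \code{individual}, \code{sex} (1/2),
#'   \code{age_years} (and optionally \code{affected}, carried through).
#' @return data.frame: \code{individual}, \code{side}, \code{bone_id},
#'   \code{length_mm}, \code{z}; empty for an empty measurement table.
#' @export
profileHands <- function(measurements, norms, subjects) {
  if (!nrow(measurements))
    return(data.frame(individual = character(), side = character(),
                      bone_id = character(), length_mm = numeric(),
                      z = numeric(), stringsAsFactors = FALSE))
  unknown <- setdiff(measurements$individual, subjects$individual)
  if (length(unknown))
    stop("measurement(s) for unknown individual(s): ",
         paste(unique(unknown), collapse = ", "))
  i <- match(measurements$individual, subjects$individual)
  z <- vapply(seq_len(nrow(measurements)), function(r) {
    mo <- lookupNorm(norms, measurements$bone_id[r], subjects$sex[i[r]],
                     subjects$age_years[i[r]])
    zScore(measurements$length_mm[r], mo[["mean_mm"]], mo[["sd_mm"]])
  }, numeric(1))
  out <- data.frame(individual = measurements$individual,
                    side = measurements$side,
                    bone_id = measurements$bone_id,
                    length_mm = measurements$length_mm, z = z,
                    stringsAsFactors = FALSE)
  out[order(out$individual, out$side, match(out$bone_id, .hand_bones)), ]
}

#' Compare affected and unaffected hand profiles
#'
#' Summarizes two groups of z-profiles: per-group mean z across all bones
#' and sides, their difference (affected minus unaffected), an overall
#' brachydactyly flag when the difference is at most \code{-delta}, and
#' per-bone "markedly shortened" flags for measurements with z at or
#' below \code{marked_threshold}.
#'
#' @param affected_profiles,unaffected_profiles profile data.frames from
#'   \code{\link{profileHands}}; each must be non-empty.
#' @param delta group-mean difference (SD units) defining brachydactyly
#'   (default 1.0).
#' @param marked_threshold per-bone z at or below which a bone is flagged
#'   markedly shortened (default -5).
#' @return list: \code{mean_z_affected}, \code{mean_z_unaffected},
#'   \code{difference}, \code{brachydactyly}, \code{marked_bones}
#'   (data.frame of flagged measurements from the affected group).
#' @export
compareProfiles <- function(affected_profiles, unaffected_profiles,
                            delta = 1.0, marked_threshold = -5) {
  if (!nrow(affected_profiles) || !nrow(unaffected_profiles))
    stop("both groups need at least one profile")
  ma <- mean(affected_profiles$z)
  mu <- mean(unaffected_profiles$z)
  marked <- affected_profiles[affected_profiles$z <= marked_threshold, ,
                              drop = FALSE]
  list(mean_z_affected = ma, mean_z_unaffected = mu,
       difference = ma - mu, brachydactyly = (ma - mu) <= -delta,
       marked_bones = marked)
}

#' Synthetic reference norms for hand-bone lengths
#'
#' Builds a side-agnostic reference table of adult hand-bone lengths
#' (mean and SD in mm per bone, sex and age). Values are synthetic but
#' physiologically plausible: metacarpals are the longest bones, lengths
#' shrink distally, female means are ~8\% below male means, a slight
#' linear age trend exercises interpolation, and SDs are ~7\% of the
#' mean. This table is a stand-in fixture for an external reference
#' atlas, not a reproduction of one.
#'
#' @param ages tabulated ages in years (default 18..80 by ~15).
#' @return norm data.frame: \code{bone_id}, \code{sex}, \code{age_years},
#'   \code{mean_mm}, \code{sd_mm}.
#' @export
makeNormTable <- function(ages = c(18, 30, 45, 60, 80)) {
  base <- c(MC1 = 46, MC2 = 68, MC3 = 65, MC4 = 58, MC5 = 53,
            PP1 = 32, PP2 = 42, PP3 = 46, PP4 = 43, PP5 = 34,
            MP2 = 25, MP3 = 29, MP4 = 27, MP5 = 19,
            DP1 = 22, DP2 = 17, DP3 = 18, DP4 = 18, DP5 = 16)
  g <- expand.grid(bone_id = .hand_bones, sex = 1:2, age_years = ages,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mean_mm <- base[g$bone_id] * ifelse(g$sex == 2L, 0.92, 1) -
    0.01 * (g$age_years - 18)
  data.frame(bone_id = g$bone_id, sex = g$sex, age_years = g$age_years,
             mean_mm = unname(mean_mm), sd_mm = unname(0.07 * mean_mm),
             stringsAsFactors = FALSE)
}

#' Read / write norm and measurement TSV files
#'
#' Plain tab-separated tables with a header row: norms carry
#' \code{bone_id}, \code{sex}, \code{age_years}, \code{mean_mm},
#' \code{sd_mm}; measurements carry \code{individual}, \code{side},
#' \code{bone_id}, \code{length_mm}.
#'
#' @param x table to write.
#' @param path file path.
#' @name measurement-io
NULL

#' @rdname measurement-io
#' @export
writeNormTable <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname measurement-io
#' @export
readNormTable <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)

#' @rdname measurement-io
#' @export
writeMeasurements <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname measurement-io
#' @export
readMeasurements <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
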