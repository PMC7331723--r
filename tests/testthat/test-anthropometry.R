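test_that("z-scores standardize against reference moments", {
  expect_equal(zScore(47, 47, 2), 0)
  expect_equal(zScore(47 - 7 * 2, 47, 2), -7)
  expect_equal(zScore(40 - 5.3 * 1.5, 40, 1.5), -5.3)
  expect_error(zScore(10, 10, 0), "sd_mm")
})

test_that("norm lookup interpolates linearly in age, never extrapolates", {
  norms <- makeNormTable(ages = c(20, 40))
  exact <- lookupNorm(norms, "MC2", 1, 20)
  row <- norms[norms$bone_id == "MC2" & norms$sex == 1 &
                 norms$age_years == 20, ]
  expect_equal(unname(exact), c(row$mean_mm, row$sd_mm))
  mid <- lookupNorm(norms, "MC2", 1, 30)
  rows <- norms[norms$bone_id == "MC2" & norms$sex == 1, ]
  expect_equal(mid[["mean_mm"]], mean(rows$mean_mm))
  expect_equal(mid[["sd_mm"]], mean(rows$sd_mm))
  expect_error(lookupNorm(norms, "MC2", 1, 95), "outside")
  expect_error(lookupNorm(norms, "XX9", 1, 30), "no norms")
})

test_that("profiles recover planted z-values through a full round-trip", {
  norms <- makeNormTable()
  subjects <- data.frame(individual = c("A1", "A2", "U1"),
                         sex = c(1L, 2L, 1L), age_years = c(50, 64, 40),
                         affected = c(2L, 2L, 1L))
  meas <- simulateMeasurements(norms, measurementSimSpec(), subjects,
                               seed = 91)
  prof <- profileHands(meas, norms, subjects)
  expect_equal(nrow(prof), 3L * 2L * 19L)
  # planted outliers come back exactly
  expect_equal(prof$z[prof$individual == "A1" & prof$side == "left" &
                        prof$bone_id == "MC1"], -7, tolerance = 1e-9)
  expect_equal(prof$z[prof$individual == "A2" & prof$side == "right" &
                        prof$bone_id == "PP1"], -5.3, tolerance = 1e-9)
  # groups stay inside their configured bands
  unaff <- prof$z[prof$individual == "U1"]
  expect_true(all(unaff >= -1 - 1e-9 & unaff <= 1 + 1e-9))
  aff <- prof$z[prof$individual %in% c("A1", "A2")]
  aff <- aff[aff > -4]   # outliers aside
  expect_true(all(aff >= -3 - 1e-9 & aff <= -1 + 1e-9))
})

test_that("degenerate profile inputs behave per contract", {
  norms <- makeNormTable()
  empty <- profileHands(data.frame(individual = character(),
                                   side = character(),
                                   bone_id = character(),
                                   length_mm = numeric()),
                        norms, data.frame(individual = character(),
                                          sex = integer(),
                                          age_years = numeric()))
  expect_equal(nrow(empty), 0L)
  subjects <- data.frame(individual = "A", sex = 1L, age_years = 30)
  flat <- do.call(rbind, lapply(c("MC1", "PP2", "DP5"), function(b) {
    mo <- lookupNorm(norms, b, 1, 30)
    data.frame(individual = "A", side = "left", bone_id = b,
               length_mm = mo[["mean_mm"]] - 2 * mo[["sd_mm"]])
  }))
  prof <- profileHands(flat, norms, subjects)
  expect_equal(prof$z, rep(-2, 3), tolerance = 1e-12)
  expect_error(profileHands(data.frame(individual = "NOBODY", side = "left",
                                       bone_id = "MC1", length_mm = 40),
                            norms, subjects), "NOBODY")
})

test_that("group comparison flags brachydactyly and marked shortening", {
  mk <- function(id, z) data.frame(individual = id, side = "left",
                                   bone_id = paste0("MC", seq_along(z)),
                                   length_mm = NA_real_, z = z)
  same <- compareProfiles(mk("A", rep(-0.5, 5)), mk("U", rep(-0.5, 5)))
  expect_equal(same$difference, 0)
  expect_false(same$brachydactyly)
  two <- compareProfiles(mk("A", rep(-2, 5)), mk("U", rep(0, 5)))
  expect_equal(two$difference, -2)
  expect_true(two$brachydactyly)
  expect_equal(nrow(two$marked_bones), 0L)
  expect_error(compareProfiles(mk("A", -1)[0, ], mk("U", 0)), "at least one")
})

test_that("only planted outlier bones carry the marked-shortening flag", {
  norms <- makeNormTable()
  subjects <- data.frame(individual = c("A1", "A2", "U1"),
                         sex = 1L, age_years = 45,
                         affected = c(2L, 2L, 1L))
  meas <- simulateMeasurements(norms, measurementSimSpec(), subjects,
                               seed = 17)
  prof <- profileHands(meas, norms, subjects)
  cmp <- compareProfiles(prof[prof$individual != "U1", ],
                         prof[prof$individual == "U1", ])
  expect_true(cmp$brachydactyly)
  got <- cmp$marked_bones[, c("individual", "side", "bone_id")]
  expect_equal(nrow(got), 2L)
  expect_setequal(paste(got$individual, got$side, got$bone_id),
                  c("A1 left MC1", "A2 right PP1"))
})

test_that("z-profiles are invariant to a common rescaling of units", {
  norms <- makeNormTable()
  subjects <- data.frame(individual = "A", sex = 1L, age_years = 30,
                         affected = 2L)
  meas <- simulateMeasurements(norms, measurementSimSpec(outlier_bones = NULL),
                               subjects, seed = 3)
  z1 <- profileHands(meas, norms, subjects)$z
  norms2 <- norms; norms2$mean_mm <- norms$mean_mm * 10
  norms2$sd_mm <- norms$sd_mm * 10
  meas2 <- meas; meas2$length_mm <- meas$length_mm * 10
  z2 <- profileHands(meas2, norms2, subjects)$z
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("norm and measurement tables round-trip through TSV", {
  norms <- makeNormTable(ages = c(20, 40))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeNormTable(norms, p1)
  expect_equal(readNormTable(p1), norms)
  meas <- data.frame(individual = "A", side = "left", bone_id = "MC1",
                     length_mm = 43.25)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeMeasurements(meas, p2)
  expect_equal(readMeasurements(p2), meas)
})
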