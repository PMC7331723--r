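# build a VariantSet directly from an annotation table; depths default to
# strong hom-alt support in both carrier samples
vs_from_table <- function(tab, alt1 = 20L, alt2 = 20L) {
  n <- nrow(tab)
  defaults <- data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
                         id = paste0("v", seq_len(n)), ref = "A", alt = "G",
                         csqclass = "missense", exac_af = 0, exac_hom = 0L,
                         inhouse_n = 0L, dist_to_exon = NA_integer_,
                         stringsAsFactors = FALSE)
  for (col in names(tab)) defaults[[col]] <- tab[[col]]
  gt <- matrix(2L, n, 2, dimnames = list(NULL, c("S1", "S2")))
  ad_alt <- cbind(S1 = rep_len(alt1, n), S2 = rep_len(alt2, n))
  ad_ref <- matrix(0L, n, 2, dimnames = dimnames(gt))
  VariantSet(defaults, gt, ad_ref, ad_alt, ad_alt + ad_ref)
}

test_that("each rule excludes its engineered variant, in published order", {
  tab <- data.frame(csqclass = c("missense",      # rule 1: low alt reads
                                 "missense",      # rule 2a: AF > 0.05
                                 "missense",      # rule 2b: > 30 in-house
                                 "missense",      # rule 3: population hom
                                 "synonymous",    # rule 4
                                 "utr5",          # rule 5
                                 rep("missense", 4)),  # 4 clean survivors
                    exac_af = c(0, 0.2, 0, 0, 0, 0, rep(0, 4)),
                    inhouse_n = c(0L, 0L, 45L, 0L, 0L, 0L, rep(0L, 4)),
                    exac_hom = c(0L, 0L, 0L, 3L, 0L, 0L, rep(0L, 4)))
  vs <- vs_from_table(tab)
  vs@ad_alt[1, "S1"] <- 2L   # rule 1 trips on a single sequenced affected
  rep <- applyFilters(vs, filterThresholds(), c("S1", "S2"))
  expect_equal(unname(excludedCounts(rep)), c(1L, 2L, 1L, 1L, 1L))
  expect_equal(length(survivingVariants(rep)), 4L)
  expect_equal(rep@n_input,
               sum(excludedCounts(rep)) + length(survivingVariants(rep)))
  expect_equal(unname(rep@rule_of["v1"]), "low_alt_reads")
})

test_that("a variant annotated like the index variant is retained", {
  vs <- vs_from_table(data.frame(csqclass = "missense",
                                 exac_af = 1.6e-5, exac_hom = 0L,
                                 inhouse_n = 0L))
  rep <- applyFilters(vs, filterThresholds(), c("S1", "S2"))
  expect_equal(survivingVariants(rep), "v1")
})

test_that("first-failing-rule attribution: an early rule masks later ones", {
  # fails rules 2, 3 and 4 simultaneously; attributed to rule 2 only
  vs <- vs_from_table(data.frame(csqclass = "synonymous", exac_af = 0.3,
                                 exac_hom = 10L))
  rep <- applyFilters(vs, filterThresholds(), c("S1", "S2"))
  expect_equal(unname(excludedCounts(rep)["common_or_recurrent"]), 1L)
  expect_equal(sum(excludedCounts(rep)), 1L)
})

test_that("rule 5 honours the splice window and the 5'/3' UTR distinction", {
  tab <- data.frame(csqclass = c("intronic_near_splice", "intronic_deep",
                                 "utr3", "utr5"),
                    dist_to_exon = c(2L, 50L, NA_integer_, NA_integer_))
  vs <- vs_from_table(tab)
  rep <- applyFilters(vs, filterThresholds(), c("S1", "S2"))
  # within-window intronic and (literally read) 3' UTR survive
  expect_setequal(survivingVariants(rep), c("v1", "v3"))
  rep2 <- applyFilters(vs, filterThresholds(exclude_utr3 = TRUE),
                       c("S1", "S2"))
  expect_setequal(survivingVariants(rep2), "v1")
})

test_that("rule order permutations change attribution, never survivors", {
  set.seed(77)
  tab <- data.frame(csqclass = sample(c("missense", "synonymous", "utr5",
                                        "intronic_deep"), 40, TRUE),
                    exac_af = sample(c(0, 0.001, 0.2), 40, TRUE),
                    exac_hom = sample(c(0L, 2L), 40, TRUE),
                    inhouse_n = sample(c(0L, 100L), 40, TRUE),
                    dist_to_exon = sample(c(NA_integer_, 1L, 500L), 40, TRUE))
  tab$dist_to_exon[!tab$csqclass %in%
                     c("intronic_deep", "intronic_near_splice")] <- NA_integer_
  tab$dist_to_exon[tab$csqclass %in%
                     c("intronic_deep", "intronic_near_splice") &
                     is.na(tab$dist_to_exon)] <- 500L
  vs <- vs_from_table(tab, alt1 = sample(c(1L, 30L), 40, TRUE))
  base <- applyFilters(vs, filterThresholds(), c("S1", "S2"))
  for (perm in list(5:1, c(3L, 1L, 5L, 2L, 4L))) {
    alt <- applyFilters(vs, filterThresholds(), c("S1", "S2"),
                        rule_order = perm)
    expect_setequal(survivingVariants(alt), survivingVariants(base))
    expect_equal(sum(excludedCounts(alt)), sum(excludedCounts(base)))
  }
})

test_that("tightening any threshold never grows the surviving set", {
  set.seed(78)
  tab <- data.frame(csqclass = sample(c("missense", "utr5", "intronic_deep"),
                                      30, TRUE),
                    exac_af = runif(30, 0, 0.1),
                    inhouse_n = sample(0:60, 30, TRUE),
                    dist_to_exon = NA_integer_)
  tab$dist_to_exon[tab$csqclass == "intronic_deep"] <- sample(1:10, sum(tab$csqclass == "intronic_deep"), TRUE)
  vs <- vs_from_table(tab, alt1 = sample(1:10, 30, TRUE))
  loose <- filterThresholds(min_alt_reads = 2, max_pop_af = 0.08,
                            max_inhouse = 50, splice_window_bp = 8)
  tight <- filterThresholds(min_alt_reads = 5, max_pop_af = 0.02,
                            max_inhouse = 10, splice_window_bp = 2)
  s_loose <- survivingVariants(applyFilters(vs, loose, c("S1", "S2")))
  s_tight <- survivingVariants(applyFilters(vs, tight, c("S1", "S2")))
  expect_true(all(s_tight %in% s_loose))
})

test_that("an unknown consequence class names the offending variant", {
  vs <- vs_from_table(data.frame(csqclass = c("missense", "weird")))
  expect_error(applyFilters(vs, filterThresholds(), c("S1", "S2")), "v2")
})

test_that("allele-frequency arithmetic and display", {
  expect_equal(computeAlleleFrequency(3, 187624), 100 * 3 / 187624)
  expect_equal(formatAlleleFrequency(computeAlleleFrequency(3, 187624)),
               "0.0016%")
  expect_equal(computeAlleleFrequency(0, 1000), 0)
  expect_equal(computeAlleleFrequency(1000, 1000), 100)
  expect_error(computeAlleleFrequency(1, 0), "total_alleles")
  expect_error(computeAlleleFrequency(5, 4), "exceeds")
})
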