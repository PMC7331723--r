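sim_small <- function(seed = 17, n_affected = 3L, n_children = 6L) {
  map <- makeGenomeMap(n_chrom = 2, chrom_length_bp = 5e7,
                       chrom_length_morgans = 0.6,
                       markers_per_chrom = 200, seed = 2)
  ped <- buildPedigree(n_children)
  spec <- plantedVariantSpec(chrom = "chr1",
                             pos = markers(map)$pos[100])
  sim <- geneDrop(ped, map, seed)
  plantVariant(sim, spec, n_affected_target = n_affected, seed = seed)
}

test_that("rejection sampling hits the affected-count target exactly", {
  sim <- sim_small(seed = 17, n_affected = 3L)
  p <- pedTable(sim@pedigree)
  kids <- p$id[p$father == "FA"]
  expect_equal(sum(p$affected[match(kids, p$id)] == 2L), 3L)
  expect_gte(truthRecord(sim)$planted$attempts, 1L)
})

test_that("full penetrance holds by construction", {
  sim <- sim_small(seed = 29, n_affected = 3L)
  g <- truthRecord(sim)$planted$genotypes
  p <- pedTable(sim@pedigree)
  expect_true(all(g[p$id[p$affected == 2L]] == 2L))
  expect_true(all(g[p$id[p$affected == 1L]] != 2L))
})

test_that("the planted site lies in a truth IBD segment of every affected", {
  for (seed in c(31, 57)) {
    sim <- sim_small(seed = seed, n_affected = 3L)
    pl <- truthRecord(sim)$planted$spec
    seg <- ibdSegments(sim)
    for (id in affectedIds(sim@pedigree)) {
      s <- seg[seg$individual == id & seg$chrom == pl$chrom, , drop = FALSE]
      expect_true(any(s$start_bp <= pl$pos & s$end_bp >= pl$pos),
                  label = sprintf("seed %d, %s covered", seed, id))
    }
  }
})

test_that("an unreachable affected-count target errors with the attempt count", {
  # without a consanguinity loop a child cannot be homozygous by descent
  ped <- buildPedigree(2, loop = "none")
  map <- makeGenomeMap(n_chrom = 1, markers_per_chrom = 20, seed = 4)
  sim <- geneDrop(ped, map, seed = 1)
  spec <- plantedVariantSpec(chrom = "chr1", pos = markers(map)$pos[10],
                             source_ancestor = "FA")
  expect_error(plantVariant(sim, spec, n_affected_target = 2L,
                            max_attempts = 50L),
               "50 attempts")
})

test_that("planting requires a founder source and a marker position", {
  sim <- geneDrop(buildPedigree(2),
                  makeGenomeMap(n_chrom = 1, markers_per_chrom = 20,
                                seed = 4), seed = 1)
  expect_error(plantVariant(sim, plantedVariantSpec("chr1", 123456789,
                                                    source_ancestor = "GG1")),
               "marker position")
  expect_error(plantVariant(sim, plantedVariantSpec(
    "chr1", markers(sim@map)$pos[1], source_ancestor = "C1")), "founder")
})

test_that("noiseless emission reproduces true genotypes and clean depths", {
  sim <- sim_small(seed = 41)
  noise <- noiseModel(genotype_error_rate = 0, mean_depth = 60,
                      base_error = 0)
  vs <- emitVariants(sim, noise, seed = 8)
  truth <- trueGenotypes(sim)
  gt <- genotypes(vs)
  called <- !is.na(gt)
  expect_true(all(gt[called] == truth[called]))
  # hom-ref samples have zero alternate reads when the error floor is 0
  expect_true(all(altDepth(vs)[truth == 0L] == 0L))
  expect_true(all(altDepth(vs) + refDepth(vs) == readDepth(vs)))
})

test_that("het-site alternate-read fraction matches the allele balance", {
  sim <- sim_small(seed = 43)
  vs <- emitVariants(sim, noiseModel(allele_balance = 0.4, mean_depth = 50),
                     seed = 9)
  truth <- trueGenotypes(sim)
  het <- truth == 1L & readDepth(vs) > 0L
  frac <- sum(altDepth(vs)[het]) / sum(readDepth(vs)[het])
  n_reads <- sum(readDepth(vs)[het])
  expect_lt(abs(frac - 0.4), 4 * sqrt(0.4 * 0.6 / n_reads))
})

test_that("the planted variant carries its configured annotations", {
  sim <- sim_small(seed = 47)
  vs <- emitVariants(sim, seed = 10)
  pl <- truthRecord(sim)$planted$spec
  s <- variantSites(vs)
  i <- which(s$chrom == pl$chrom & s$pos == pl$pos)
  expect_equal(s$csqclass[i], "missense")
  expect_equal(s$exac_af[i], 3 / 187624)
  expect_equal(s$exac_hom[i], 0L)
  expect_equal(s$inhouse_n[i], 0L)
})
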