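test_that("the rule at its stated minimum: 25 homozygous calls, one ROH", {
  pos <- seq(100L, by = 1000L, length.out = 25L)
  g <- rep(0L, 25L)
  r <- callROH(g, pos)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start_bp, 100L)
  expect_equal(r$end_bp, pos[25])
  expect_equal(r$n_snps, 25L)
  expect_equal(r$n_het, 0L)
  # one call short of the minimum span: nothing
  expect_equal(nrow(callROH(rep(2L, 24L), pos[1:24])), 0L)
})

test_that("60 calls with three spaced hets match the brute-force oracle", {
  g <- rep(0L, 60L)
  g[c(10, 30, 50) + 1L] <- 1L     # het at 0-based ordinals 10, 30, 50
  pos <- seq(1L, by = 500L, length.out = 60L)
  got <- callROH(g, pos, layer = "maximal")
  exp <- roh_bruteforce(g, pos, 25L, 2L)
  expect_equal(got[, c("start_bp", "end_bp", "n_snps", "n_het")], exp,
               ignore_attr = TRUE)
})

test_that("maximal spans equal brute-force enumeration on random instances", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(30:200, 1)
    g <- random_calls(n, p_het = runif(1, 0.02, 0.3),
                      p_miss = runif(1, 0, 0.2))
    pos <- sort(sample.int(1e6, n))
    prm <- rohParams(min_snps = sample(5:25, 1), max_het = sample(0:3, 1))
    got <- callROH(g, pos, params = prm, layer = "maximal")
    exp <- roh_bruteforce(g, pos, prm@min_snps, prm@max_het)
    expect_equal(got[, c("start_bp", "end_bp", "n_snps", "n_het")], exp,
                 ignore_attr = TRUE, label = paste("instance", i))
  }
})

test_that("missing calls are skipped, neither breaking nor padding spans", {
  g <- rep(0L, 30L)
  g[c(5, 12, 20)] <- NA_integer_
  pos <- seq(1L, by = 100L, length.out = 30L)
  r <- callROH(g, pos, params = rohParams(min_snps = 27, max_het = 0))
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_snps, 27L)   # 30 calls minus 3 missing
})

test_that("relaxing parameters never shrinks covered bases", {
  covered <- function(r) if (!nrow(r)) 0 else sum(r$end_bp - r$start_bp + 1)
  set.seed(303)
  for (i in 1:25) {
    n <- sample(50:150, 1)
    g <- random_calls(n, p_het = 0.15, p_miss = 0.05)
    pos <- sort(sample.int(1e5, n))
    base <- covered(callROH(g, pos, params = rohParams(20, 1)))
    expect_gte(covered(callROH(g, pos, params = rohParams(20, 2))), base)
    expect_gte(covered(callROH(g, pos, params = rohParams(10, 1))), base)
  }
})

test_that("merged regions union overlapping maximal spans", {
  set.seed(404)
  for (i in 1:20) {
    g <- random_calls(120, p_het = 0.2, p_miss = 0.1)
    pos <- sort(sample.int(1e5, 120))
    prm <- rohParams(min_snps = 10, max_het = 2)
    mx <- callROH(g, pos, params = prm, layer = "maximal")
    mg <- callROH(g, pos, params = prm, layer = "merged")
    if (!nrow(mx)) { expect_equal(nrow(mg), 0L); next }
    # merged regions are disjoint and cover exactly the maximal spans
    if (nrow(mg) > 1)
      expect_true(all(mg$start_bp[-1] > mg$end_bp[-nrow(mg)]))
    expect_true(all(vapply(seq_len(nrow(mx)), function(r)
      any(mg$start_bp <= mx$start_bp[r] & mg$end_bp >= mx$end_bp[r]),
      logical(1))))
  }
})

test_that("callROH validates its inputs", {
  expect_error(callROH(c(0L, 0L), c(10L, 5L)), "increasing")
  expect_error(callROH(c(0L, 0L), 1L), "equal length")
})

test_that("shared ROH is plain interval intersection", {
  one <- data.frame(sample = "A", chrom = "chr1", start_bp = 100L,
                    end_bp = 200L, n_snps = 30L, n_het = 0L)
  expect_equal(sharedROH(one, "A")[, c("start_bp", "end_bp")],
               data.frame(start_bp = 100L, end_bp = 200L))
  two <- rbind(one, data.frame(sample = "B", chrom = "chr1",
                               start_bp = 150L, end_bp = 300L,
                               n_snps = 30L, n_het = 0L))
  got <- sharedROH(two, c("A", "B"))
  expect_equal(got$start_bp, 150L)
  expect_equal(got$end_bp, 200L)
  disjoint <- rbind(one, data.frame(sample = "B", chrom = "chr1",
                                    start_bp = 500L, end_bp = 900L,
                                    n_snps = 30L, n_het = 0L))
  expect_equal(nrow(sharedROH(disjoint, c("A", "B"))), 0L)
  expect_error(sharedROH(one, c("A", "MISSING")), "MISSING")
})

test_that("ROH tables round-trip through their TSV form", {
  r <- data.frame(sample = c("A", "A"), chrom = c("chr1", "chr2"),
                  start_bp = c(10L, 99L), end_bp = c(500L, 1000L),
                  n_snps = c(30L, 41L), n_het = c(1L, 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeROHTable(r, path)
  expect_identical(readROHTable(path), r)
})
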