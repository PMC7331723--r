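# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately share no code with the package implementation.

# O(n^2) enumeration of maximal qualifying homozygous spans: every index
# window over the non-missing calls with >= min_snps calls and <= max_het
# heterozygous calls, keeping those not contained in a larger qualifying
# window. Returns bp intervals like callROH(layer = "maximal").
roh_bruteforce <- function(genotypes, positions, min_snps, max_het) {
  keep <- !is.na(genotypes)
  g <- genotypes[keep]; pos <- positions[keep]
  n <- length(g)
  wins <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1 < min_snps) next
    if (sum(g[i:j] == 1L) <= max_het) wins[[length(wins) + 1L]] <- c(i, j)
  }
  if (!length(wins)) return(data.frame(start_bp = integer(),
                                       end_bp = integer(),
                                       n_snps = integer(),
                                       n_het = integer()))
  w <- do.call(rbind, wins)
  maximal <- vapply(seq_len(nrow(w)), function(r) {
    !any(w[, 1] <= w[r, 1] & w[, 2] >= w[r, 2] &
           (w[, 2] - w[, 1]) > (w[r, 2] - w[r, 1]))
  }, logical(1))
  w <- w[maximal, , drop = FALSE]
  w <- w[order(w[, 1]), , drop = FALSE]
  data.frame(start_bp = pos[w[, 1]], end_bp = pos[w[, 2]],
             n_snps = w[, 2] - w[, 1] + 1L,
             n_het = vapply(seq_len(nrow(w)), function(r)
               sum(g[w[r, 1]:w[r, 2]] == 1L), integer(1)))
}

# rule-by-rule brute force for fully penetrant AR segregation in a trio
# (father FA, mother MO, child C1), genotypes as dosage 0/1/2, child
# affection TRUE/FALSE, parents unaffected. Returns TRUE when consistent.
trio_ar_consistent <- function(g_fa, g_mo, g_c, child_affected) {
  ok <- TRUE
  if (child_affected && g_c != 2) ok <- FALSE          # affected not hom-alt
  if (!child_affected && g_c == 2) ok <- FALSE         # unaffected hom-alt
  if (g_fa == 2 || g_mo == 2) ok <- FALSE              # unaffected parent hom-alt
  if (child_affected && (g_fa != 1 || g_mo != 1)) ok <- FALSE  # obligate carriers
  half <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)
  if (!g_c %in% outer(half(g_fa), half(g_mo), "+")) ok <- FALSE  # Mendelian
  ok
}

# random genotype vector for ROH oracle tests
random_calls <- function(n, p_het = 0.2, p_miss = 0.1) {
  x <- sample(c(0L, 1L, 2L), n, replace = TRUE,
              prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2))
  x[runif(n) < p_miss] <- NA_integer_
  x
}
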