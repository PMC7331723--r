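#' @include AllClasses.R AllGenerics.R variantset.R
NULL

#' Run-of-homozygosity calling parameters
#'
#' @param min_snps minimum non-missing calls in a qualifying span
#'   (default 25).
#' @param max_het maximum heterozygous calls tolerated in a span
#'   (default 2).
#' @return a \code{\linkS4class{ROHParams}}.
#' @export
rohParams <- function(min_snps = 25L, max_het = 2L) {
  new("ROHParams", min_snps = as.integer(min_snps),
      max_het = as.integer(max_het))
}

#' Call runs of homozygosity along one chromosome
#'
#' A qualifying span is a set of at least \code{min_snps} consecutive
#' non-missing genotype calls containing at most \code{max_het}
#' heterozygous calls. Missing calls are skipped: they neither interrupt a
#' span nor count towards its length. The function enumerates all
#' \emph{maximal} qualifying spans (extendable in neither direction) and,
#' for the default \code{layer = "merged"}, merges overlapping maximal
#' spans into reported regions whose \code{n_snps}/\code{n_het} totals are
#' recomputed over the merged extent (and may then exceed
#' \code{max_het}). Both layers are available.
#'
#' @param genotypes integer vector of calls along one chromosome, in
#'   position order: 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing.
#' @param positions 1-based bp positions, strictly increasing.
#' @param chrom chromosome id for the output.
#' @param params a \code{\linkS4class{ROHParams}}.
#' @param layer \code{"merged"} (default) or \code{"maximal"}.
#' @param sample sample id stamped on the output rows.
#' @return data.frame with columns \code{sample}, \code{chrom},
#'   \code{start_bp}, \code{end_bp} (1-based inclusive), \code{n_snps},
#'   \code{n_het}.
#' @export
callROH <- function(genotypes, positions, chrom = "chr1",
                    params = rohParams(), layer = c("merged", "maximal"),
                    sample = NA_character_) {
  layer <- match.arg(layer)
  if (length(genotypes) != length(positions))
    stop("genotypes and positions must have equal length")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  empty <- data.frame(sample = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      stringsAsFactors = FALSE)
  keep <- !is.na(genotypes)
  g <- genotypes[keep]; pos <- positions[keep]
  n <- length(g)
  if (n < params@min_snps) return(empty)
  het <- as.integer(g == 1L)
  H <- c(0L, cumsum(het))                 # H[i+1] = hets in g[1..i]
  k <- params@max_het
  het_idx <- which(het == 1L)
  # f(i): largest j such that span i..j holds <= k hets; blocked by the
  # (H[i] + k + 1)-th het overall. f is non-decreasing in i.
  blocker <- H[seq_len(n)] + k + 1L
  f <- ifelse(blocker > length(het_idx), n, het_idx[pmin(blocker, length(het_idx))] - 1L)
  f <- pmax(f, seq_len(n) - 1L)           # guard (f >= i-1 always holds)
  # maximal spans: i = 1, or f(i) > f(i-1); then require length >= min_snps
  is_max <- c(TRUE, f[-1L] > f[-n])
  starts <- which(is_max)
  ends <- f[starts]
  len_ok <- (ends - starts + 1L) >= params@min_snps
  starts <- starts[len_ok]; ends <- ends[len_ok]
  if (!length(starts)) return(empty)
  spans <- data.frame(start = starts, end = ends)
  if (layer == "merged") {
    merged <- list(); cs <- spans$start[1]; ce <- spans$end[1]
    if (nrow(spans) > 1) for (r in 2:nrow(spans)) {
      if (spans$start[r] <= ce + 0L) ce <- max(ce, spans$end[r])
      else { merged[[length(merged) + 1L]] <- c(cs, ce); cs <- spans$start[r]; ce <- spans$end[r] }
    }
    merged[[length(merged) + 1L]] <- c(cs, ce)
    m <- do.call(rbind, merged)
    spans <- data.frame(start = m[, 1], end = m[, 2])
  }
  data.frame(sample = sample, chrom = chrom,
             start_bp = pos[spans$start], end_bp = pos[spans$end],
             n_snps = spans$end - spans$start + 1L,
             n_het = H[spans$end + 1L] - H[spans$start],
             stringsAsFactors = FALSE)
}

#' Call ROH for selected samples of a VariantSet
#'
#' Applies \code{\link{callROH}} per sample and chromosome; spans never
#' cross chromosome boundaries.
#'
#' @param vs a \code{\linkS4class{VariantSet}}.
#' @param samples sample ids (default: all).
#' @param params a \code{\linkS4class{ROHParams}}.
#' @param layer passed to \code{\link{callROH}}.
#' @return combined data.frame of regions.
#' @export
rohRegions <- function(vs, samples = sampleIds(vs), params = rohParams(),
                       layer = "merged") {
  miss <- setdiff(samples, sampleIds(vs))
  if (length(miss)) stop("sample(s) not in call set: ",
                         paste(miss, collapse = ", "))
  s <- variantSites(vs)
  out <- list()
  for (cc in unique(s$chrom)) {
    i <- which(s$chrom == cc)
    for (sm in samples)
      out[[paste(cc, sm)]] <- callROH(genotypes(vs)[i, sm], s$pos[i],
                                      chrom = cc, params = params,
                                      layer = layer, sample = sm)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intersect ROH regions across samples
#'
#' Per chromosome, intersects the union of each listed sample's regions
#' across all samples, yielding the intervals homozygous in every sample.
#'
#' @param regions data.frame as produced by \code{\link{rohRegions}}
#'   (columns \code{sample}, \code{chrom}, \code{start_bp},
#'   \code{end_bp}).
#' @param samples sample ids to intersect over (>= 1); every id must
#'   appear in \code{regions$sample} (a sample with zero called regions
#'   must still be listed there is no requirement, but absence of any row
#'   for a listed sample is an error unless \code{allow_empty}).
#' @param allow_empty treat a listed sample with no rows as having no
#'   regions (result empty) instead of erroring (default FALSE).
#' @return data.frame \code{chrom}, \code{start_bp}, \code{end_bp}.
#' @export
sharedROH <- function(regions, samples, allow_empty = FALSE) {
  if (length(samples) < 1L) stop("need at least one sample")
  miss <- setdiff(samples, unique(regions$sample))
  if (length(miss) && !allow_empty)
    stop("no ROH rows for sample(s): ", paste(miss, collapse = ", "))
  lv <- unique(regions$chrom)
  grl <- lapply(samples, function(sm) {
    r <- regions[regions$sample == sm, , drop = FALSE]
    GenomicRanges::reduce(GenomicRanges::GRanges(
      factor(r$chrom, levels = lv),
      IRanges::IRanges(r$start_bp, r$end_bp)))
  })
  shared <- Reduce(GenomicRanges::intersect, grl)
  data.frame(chrom = as.character(GenomicRanges::seqnames(shared)),
             start_bp = GenomicRanges::start(shared),
             end_bp = GenomicRanges::end(shared),
             stringsAsFactors = FALSE)
}

#' Write / read an ROH region table
#'
#' Tab-separated with a commented header line documenting the 1-based
#' inclusive coordinate convention.
#'
#' @param regions region data.frame.
#' @param path file path.
#' @export
writeROHTable <- function(regions, path) {
  con <- file(path, "w")
  writeLines(paste("#", paste(names(regions), collapse = "\t"),
                   "(1-based inclusive coordinates)"), con)
  utils::write.table(regions, con, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeROHTable
#' @export
readROHTable <- function(path) {
  utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    col.names = c("sample", "chrom", "start_bp", "end_bp",
                                  "n_snps", "n_het"),
                    stringsAsFactors = FALSE)
}
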