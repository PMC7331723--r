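#' @include variantset.R
NULL

#' Write / read a multi-sample annotated VCF 4.2
#'
#' Serializes a \code{\linkS4class{VariantSet}} through Bioconductor's
#' VariantAnnotation: FORMAT fields \code{GT:AD:DP} and INFO keys
#' \code{CSQCLASS} (consequence class), \code{EXAC_AF} (reference
#' population alternate AF), \code{EXAC_HOM} (population homozygote
#' count), \code{INHOUSE_N} (in-house cohort carrier count) and
#' \code{DIST2EXON} (bp to the nearest exon, intronic classes only).
#' Genotypes, allelic depths and read depths round-trip bit-for-bit. The
#' header is normalized after writing (\code{##fileformat} first, no
#' volatile \code{##fileDate}) so identical inputs give byte-identical
#' files.
#'
#' @param vs a \code{\linkS4class{VariantSet}}.
#' @param path output path (plain-text \code{.vcf}).
#' @return \code{readFamilyVcf}: a \code{VariantSet};
#'   \code{writeFamilyVcf}: the path, invisibly.
#' @export
writeFamilyVcf <- function(vs, path) {
  s <- variantSites(vs)
  smp <- sampleIds(vs)
  n <- nrow(s)
  gt_code <- matrix("./.", n, length(smp), dimnames = list(NULL, smp))
  gt_code[vs@gt == 0L] <- "0/0"
  gt_code[vs@gt == 1L] <- "0/1"
  gt_code[vs@gt == 2L] <- "1/1"
  ad <- matrix(vector("list", n * length(smp)), nrow = n,
               ncol = length(smp), dimnames = list(NULL, smp))
  for (j in seq_along(smp))
    ad[, j] <- mapply(function(r, a) c(r, a), vs@ad_ref[, j], vs@ad_alt[, j],
                      SIMPLIFY = FALSE)
  hdr <- VariantAnnotation::VCFHeader(samples = smp)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    META = S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "R", "1"), Type = c("String", "Integer", "Integer"),
    Description = c("Genotype", "Allelic depths (ref,alt)", "Read depth"),
    row.names = c("GT", "AD", "DP"))
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "1", "1", "1"),
    Type = c("String", "Float", "Integer", "Integer", "Integer"),
    Description = c("Consequence class",
                    "Reference population alternate allele frequency",
                    "Reference population homozygote count",
                    "In-house cohort carrier count",
                    "Distance to nearest exon (bp, intronic classes)"),
    row.names = c("CSQCLASS", "EXAC_AF", "EXAC_HOM", "INHOUSE_N",
                  "DIST2EXON"))
  vcf <- VariantAnnotation::VCF(
    rowRanges = GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, width = 1L)),
    colData = S4Vectors::DataFrame(Samples = seq_along(smp), row.names = smp),
    exptData = list(header = hdr),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(s$ref),
      ALT = IRanges::CharacterList(as.list(s$alt)),
      QUAL = rep(NA_real_, n), FILTER = rep("PASS", n)),
    info = S4Vectors::DataFrame(CSQCLASS = s$csqclass, EXAC_AF = s$exac_af,
                                EXAC_HOM = as.integer(s$exac_hom),
                                INHOUSE_N = as.integer(s$inhouse_n),
                                DIST2EXON = as.integer(s$dist_to_exon)),
    geno = S4Vectors::SimpleList(GT = gt_code, AD = ad, DP = vs@dp))
  VariantAnnotation::writeVcf(vcf, path)
  # normalize header: fileformat must lead; drop the volatile fileDate
  ln <- readLines(path)
  ln <- ln[!grepl("^##file(format|Date)", ln)]
  writeLines(c("##fileformat=VCFv4.2", ln), path)
  invisible(path)
}

#' @rdname writeFamilyVcf
#' @export
readFamilyVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  inf <- VariantAnnotation::info(vcf)
  gt_code <- VariantAnnotation::geno(vcf)$GT
  gt <- matrix(NA_integer_, nrow(gt_code), ncol(gt_code),
               dimnames = list(NULL, colnames(gt_code)))
  gt[gt_code == "0/0"] <- 0L
  gt[gt_code %in% c("0/1", "1/0")] <- 1L
  gt[gt_code == "1/1"] <- 2L
  ad <- VariantAnnotation::geno(vcf)$AD
  take <- function(k) {
    m <- apply(ad, 2L, function(col) vapply(col, function(x)
      if (length(x) >= k) as.integer(x[k]) else NA_integer_, integer(1)))
    matrix(m, nrow(gt), dimnames = dimnames(gt))
  }
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                function(a) as.character(a)[1], character(1))
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                GenomicRanges::start(rr)),
    ref = as.character(VariantAnnotation::ref(vcf)), alt = alt,
    csqclass = inf$CSQCLASS, exac_af = inf$EXAC_AF,
    exac_hom = inf$EXAC_HOM, inhouse_n = inf$INHOUSE_N,
    dist_to_exon = inf$DIST2EXON, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  dp <- VariantAnnotation::geno(vcf)$DP
  dp <- matrix(as.integer(dp), nrow(gt), dimnames = dimnames(gt))
  VariantSet(sites, gt, take(1L), take(2L), dp)
}
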