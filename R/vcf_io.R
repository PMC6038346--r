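#' Write SNV/indel calls to a VCF file
#'
#' Emits the call table as VCF 4.2 records with DP, AC and AF INFO fields
#' and a FILTER column distinguishing reportable calls from those needing
#' manual review or orthogonal confirmation. Requires the Bioconductor
#' VariantAnnotation stack.
#'
#' @param calls A [call_variants()] result.
#' @param path Output path (".vcf").
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("VariantAnnotation is required for VCF output")
  }
  calls <- as_tibble(calls)
  needs_conf <- if ("needs_orthogonal_confirmation" %in% names(calls)) {
    calls$needs_orthogonal_confirmation
  } else rep(FALSE, nrow(calls))
  filt <- dplyr::case_when(
    needs_conf ~ "needs_confirmation",
    calls$low_confidence ~ "low_confidence",
    TRUE ~ "PASS"
  )
  vr <- VariantAnnotation::VRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos,
                              width = nchar(calls$ref)),
    ref = calls$ref, alt = calls$alt,
    totalDepth = calls$depth, altDepth = calls$alt_count,
    sampleNames = calls$sample
  )
  VariantAnnotation::softFilterMatrix(vr) <-
    matrix(filt == "PASS", ncol = 1, dimnames = list(NULL, "PASS"))
  vcf <- VariantAnnotation::asVCF(vr)
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read a truth-set VCF into a tibble
#'
#' Reads a (possibly AF-annotated) VCF into the column layout
#' [benchmark_calls()] expects.
#'
#' @param path VCF path.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt` and `af` when
#'   present.
#' @export
read_truth_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("VariantAnnotation is required for VCF input")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(rr$ALT))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = alt
  )
  info <- VariantAnnotation::info(vcf)
  if ("AF" %in% names(info)) out$af <- as.numeric(unlist(info$AF))
  out
}
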