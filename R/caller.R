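#' Calling and reportability thresholds
#'
#' The permissive calling thresholds (depth >= 6, alternate reads >= 3,
#' VAF >= 0.1, all comparisons inclusive) define which pileup evidence becomes
#' a call; the stricter pair (depth >= 10, alternate reads >= 4) gates
#' reportability. Base- and mapping-quality cutoffs are applied when the
#' pileup is built, so the caller trusts the quality-filtered counts it is
#' given. `hom_vaf` is the VAF above which a diploid call is labelled
#' homozygous (0.80 separates the binomial heterozygous/homozygous read-count
#' distributions with negligible overlap at depths of 20 and above).
#'
#' @param min_depth,min_alt,min_vaf Permissive calling thresholds.
#' @param min_base_quality,min_mapping_quality Phred cutoffs recorded for
#'   provenance; they gate reads at pileup construction, not here.
#' @param reportable_min_depth,reportable_min_alt Stricter reportability
#'   thresholds; must not be below their permissive counterparts.
#' @param hom_vaf Homozygosity VAF threshold for diploid zygosity.
#' @return A list of class `pv_caller_params`.
#' @export
caller_params <- function(min_depth = 6L, min_alt = 3L, min_vaf = 0.1,
                          min_base_quality = 20L, min_mapping_quality = 30L,
                          reportable_min_depth = 10L, reportable_min_alt = 4L,
                          hom_vaf = 0.8) {
  if (!(min_vaf > 0 && min_vaf <= 1)) abort("min_vaf must be in (0, 1]")
  if (reportable_min_depth < min_depth) {
    abort("reportable_min_depth must be >= min_depth")
  }
  if (reportable_min_alt < min_alt) {
    abort("reportable_min_alt must be >= min_alt")
  }
  structure(
    list(min_depth = as.integer(min_depth), min_alt = as.integer(min_alt),
         min_vaf = min_vaf, min_base_quality = as.integer(min_base_quality),
         min_mapping_quality = as.integer(min_mapping_quality),
         reportable_min_depth = as.integer(reportable_min_depth),
         reportable_min_alt = as.integer(reportable_min_alt),
         hom_vaf = hom_vaf),
    class = "pv_caller_params"
  )
}

#' Threshold-based SNV/indel calling from pileup evidence
#'
#' Emits a call for every non-reference allele whose quality-filtered evidence
#' satisfies depth >= `min_depth`, alternate count >= `min_alt` and
#' VAF >= `min_vaf` (inclusive comparisons). The VAF denominator is the
#' quality-filtered depth: the sum of allele counts at the position. Each
#' alternate allele of a multi-allelic column is evaluated independently.
#' Calls that pass these permissive thresholds but fail the stricter
#' reportability pair are annotated `low_confidence`; such calls are the
#' ones a reviewer would rescue or discard by manual inspection.
#'
#' @param pileup Long-format pileup: a data frame with columns `chrom`, `pos`
#'   (1-based), `ref`, `allele`, `count` and optionally `sample`. Counts must
#'   be reads passing the base/mapping-quality cutoffs; rows with zero counts
#'   are allowed and ignored.
#' @param params A [caller_params()] object.
#' @return A tibble of class `pv_calls`, ordered by sample, chrom, pos and
#'   alt, with columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_type` (SNV/insertion/deletion), `depth`, `alt_count`, `vaf`,
#'   `low_confidence`.
#' @examples
#' pu <- tibble::tibble(chrom = "1", pos = 100L, ref = "A",
#'                      allele = c("A", "G"), count = c(90L, 10L))
#' call_variants(pu)
#' @export
call_variants <- function(pileup, params = caller_params()) {
  pileup <- as_tibble(pileup)
  if (!"sample" %in% names(pileup)) pileup$sample <- "sample"
  if (any(pileup$count < 0)) abort("negative allele counts in pileup")
  depth_tbl <- pileup %>%
    group_by(.data$sample, .data$chrom, .data$pos) %>%
    summarise(depth = sum(.data$count), .groups = "drop")
  alts <- pileup %>%
    filter(.data$allele != .data$ref, .data$count > 0) %>%
    left_join(depth_tbl, by = c("sample", "chrom", "pos"))
  if (any(alts$count > alts$depth)) {
    abort("alternate allele count exceeds column depth")
  }
  calls <- alts %>%
    mutate(vaf = .data$count / .data$depth) %>%
    filter(.data$depth >= params$min_depth,
           .data$count >= params$min_alt,
           .data$vaf >= params$min_vaf)
  norm <- normalize_alleles(calls$pos, calls$ref, calls$allele)
  calls <- calls %>%
    mutate(pos = norm$pos, ref = norm$ref, alt = norm$alt,
           variant_type = variant_type_of(norm$ref, norm$alt),
           alt_count = .data$count,
           low_confidence = !(.data$depth >= params$reportable_min_depth &
                                .data$count >= params$reportable_min_alt)) %>%
    select("sample", "chrom", "pos", "ref", "alt", "variant_type",
           "depth", "alt_count", "vaf", "low_confidence") %>%
    arrange(.data$sample, .data$chrom, .data$pos, .data$alt)
  structure(calls, class = c("pv_calls", class(calls)))
}

variant_type_of <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1 & nchar(alt) == 1 ~ "SNV",
    nchar(alt) > nchar(ref) ~ "insertion",
    nchar(alt) < nchar(ref) ~ "deletion",
    TRUE ~ "complex"
  )
}

#' Parsimonious left-trimmed allele representation
#'
#' Canonicalises (pos, ref, alt) triples by trimming shared trailing bases,
#' then shared leading bases (advancing the position), always keeping at
#' least one base on each allele. Callers and benchmark comparators both use
#' this so that equivalent indel spellings match.
#'
#' @param pos,ref,alt Parallel vectors of 1-based positions and allele strings.
#' @return A list with components `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  n <- length(ref)
  pos <- as.integer(pos)
  if (n == 0) return(list(pos = pos, ref = ref, alt = alt))
  ref <- as.character(ref); alt <- as.character(alt)
  needs <- nchar(ref) > 1 | nchar(alt) > 1
  for (i in which(needs)) {
    r <- ref[i]; a <- alt[i]
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Flag calls meeting the stricter reportability gate
#'
#' A call is reportable when it passes the stricter evidence thresholds
#' (depth >= 10, alternate reads >= 4, VAF >= 0.1) and affects a tier-1 gene;
#' a tier-2 call additionally requires the triage-supplied phenotype-match
#' flag, reflecting that weakly associated genes are only reported when the
#' patient's phenotype is compatible with the published association.
#'
#' @param calls A `pv_calls` tibble (or compatible data frame) carrying a
#'   `gene` column; an optional logical `phenotype_match` column (default
#'   FALSE) marks tier-2 compatibility.
#' @param panel A [load_panel()] object.
#' @param params A [caller_params()] object.
#' @return `calls` with a logical `reportable` column.
#' @export
mark_reportable <- function(calls, panel, params = caller_params()) {
  calls <- as_tibble(calls)
  if (!"gene" %in% names(calls)) abort("calls must carry a gene column")
  unknown <- setdiff(unique(calls$gene), panel$symbol)
  if (length(unknown) > 0) {
    abort(paste0("call(s) in gene(s) absent from panel: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!"phenotype_match" %in% names(calls)) calls$phenotype_match <- FALSE
  calls %>%
    left_join(select(as_tibble(panel), "symbol", "tier"),
              by = c(gene = "symbol")) %>%
    mutate(reportable = .data$depth >= params$reportable_min_depth &
             .data$alt_count >= params$reportable_min_alt &
             .data$vaf >= params$min_vaf &
             (.data$tier == 1L | (.data$tier == 2L & .data$phenotype_match)))
}

#' Zygosity from VAF, sex and chromosome class
#'
#' Diploid loci (autosomes, and the X in females) are labelled homozygous when
#' the VAF reaches `hom_vaf`, else heterozygous. Male X loci are hemizygous
#' regardless of VAF. Mitochondrial loci get `NA`: heteroplasmy fractions do
#' not map onto diploid zygosity and are flagged rather than forced.
#'
#' @param vaf Numeric vector of variant allele fractions.
#' @param sex "male" or "female" (scalar or vector).
#' @param chrom_class "autosome", "X" or "MT" (scalar or vector).
#' @param hom_vaf Homozygosity threshold, default 0.8.
#' @return Character vector: "heterozygous", "homozygous", "hemizygous" or NA.
#' @export
genotype_zygosity <- function(vaf, sex, chrom_class = "autosome", hom_vaf = 0.8) {
  n <- length(vaf)
  sex <- rep_len(sex, n)
  chrom_class <- rep_len(chrom_class, n)
  if (!all(sex %in% c("male", "female"))) abort("sex must be male or female")
  dplyr::case_when(
    chrom_class == "MT" ~ NA_character_,
    chrom_class == "X" & sex == "male" ~ "hemizygous",
    vaf >= hom_vaf ~ "homozygous",
    TRUE ~ "heterozygous"
  )
}
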