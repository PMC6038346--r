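#' Homology-scan parameters
#'
#' @param dp_threshold Depth threshold defining the callability track
#'   (default 20, i.e. DP20).
#' @param sample_fraction Fraction of samples that must show imperfect
#'   callability for a region to be conflictive; the comparison is strict
#'   (default 0.5, so "more than half the cohort").
#' @param bleed_through_fraction Cohort fraction at or above which a variant
#'   inside a homologous region is suspected to be pseudogene bleed-through
#'   (default 0.9).
#' @return A list of class `pv_homology_params`.
#' @export
homology_params <- function(dp_threshold = 20L, sample_fraction = 0.5,
                            bleed_through_fraction = 0.9) {
  fr <- c(sample_fraction, bleed_through_fraction)
  if (any(fr <= 0 | fr > 1)) abort("fractions must be in (0, 1]")
  structure(list(dp_threshold = as.integer(dp_threshold),
                 sample_fraction = sample_fraction,
                 bleed_through_fraction = bleed_through_fraction),
            class = "pv_homology_params")
}

#' Conflictive regions from cohort-wide DP20 callability
#'
#' A region is conflictive when its DP20 callability is below 1 in strictly
#' more than `sample_fraction` of the cohort — a systematic, not sporadic,
#' coverage defect, typically caused by reads lost to a highly homologous
#' locus (pseudogene). An optional homology annotation (supplied as input,
#' not computed by genome self-alignment) marks which conflictive regions
#' have a known high-identity counterpart; only those gate downstream
#' confirmation requirements.
#'
#' @param callability A data frame with columns `sample`, `region`,
#'   `callability` (fractions in `[0, 1]` at DP20) and optionally `chrom`,
#'   `start`, `end`, `gene`.
#' @param homology Optional annotation: a data frame with columns `region`
#'   and `counterpart` describing the homologous counterpart of each
#'   annotated region.
#' @param params A [homology_params()] object.
#' @return A tibble with one row per conflictive region: `region`,
#'   `n_below`, `n_samples`, `fraction_below`, `homologous`, `counterpart`,
#'   plus any coordinate columns present in the input.
#' @export
find_conflictive_regions <- function(callability, homology = NULL,
                                     params = homology_params()) {
  callability <- as_tibble(callability)
  if (nrow(callability) == 0) abort("empty cohort: no callability rows")
  meta_cols <- intersect(c("chrom", "start", "end", "gene"), names(callability))
  out <- callability %>%
    group_by(across(dplyr::all_of(c("region", meta_cols)))) %>%
    summarise(n_below = sum(.data$callability < 1),
              n_samples = dplyr::n_distinct(.data$sample),
              .groups = "drop") %>%
    mutate(fraction_below = .data$n_below / .data$n_samples) %>%
    filter(.data$fraction_below > params$sample_fraction)
  if (is.null(homology)) {
    out$homologous <- FALSE
    out$counterpart <- NA_character_
  } else {
    out <- out %>%
      left_join(select(as_tibble(homology), "region", "counterpart"),
                by = "region") %>%
      mutate(homologous = !is.na(.data$counterpart))
  }
  arrange(out, .data$region)
}

#' Flag calls inside homologous conflictive regions
#'
#' Every call overlapping a homologous conflictive region is flagged
#' `needs_orthogonal_confirmation`: it cannot support a causative diagnosis
#' until an orthogonal method (e.g. long-range PCR plus Sanger) confirms it.
#' Calls in conflictive regions without a known homologous counterpart are
#' merely annotated `low_callability_region` — the coverage defect is real
#' but there is no identified source of misassigned reads.
#'
#' @param calls A data frame of calls carrying a `region` column (or `gene`
#'   when regions are gene-scoped).
#' @param regions A [find_conflictive_regions()] result.
#' @return `calls` with logical columns `needs_orthogonal_confirmation` and
#'   `low_callability_region`.
#' @export
flag_homology_variants <- function(calls, regions) {
  calls <- as_tibble(calls)
  key <- if ("region" %in% names(calls)) "region" else "gene"
  if (!key %in% names(calls)) abort("calls must carry a region or gene column")
  regions <- as_tibble(regions)
  hom <- regions$region[regions$homologous]
  nonhom <- regions$region[!regions$homologous]
  calls %>%
    mutate(needs_orthogonal_confirmation = .data[[key]] %in% hom,
           low_callability_region = .data[[key]] %in% nonhom)
}

#' Detect recurrent pseudogene bleed-through variants
#'
#' A true rare variant is private to a patient; a variant that appears inside
#' a homologous region in nearly every sample of the cohort is, with high
#' probability, the homologous locus's reference sequence bleeding into the
#' gene. Such variants are marked `suspected_bleed_through` and must be
#' resolved by a gene-specific assay before any clinical use.
#'
#' @param cohort_calls A data frame of calls across the cohort with columns
#'   `sample` and a variant key (`region` or `gene`, plus `pos`, `ref`,
#'   `alt` when available).
#' @param regions A [find_conflictive_regions()] result.
#' @param params A [homology_params()] object.
#' @param n_samples Total cohort size; defaults to the number of distinct
#'   samples in `cohort_calls`.
#' @return A tibble of suspected variants with their carrier fraction.
#' @export
detect_bleed_through <- function(cohort_calls, regions,
                                 params = homology_params(),
                                 n_samples = NULL) {
  cohort_calls <- as_tibble(cohort_calls)
  if (is.null(n_samples)) n_samples <- dplyr::n_distinct(cohort_calls$sample)
  if (n_samples < 10) {
    abort("bleed-through detection requires a cohort of at least 10 samples")
  }
  key <- if ("region" %in% names(cohort_calls)) "region" else "gene"
  hom <- as_tibble(regions)$region[as_tibble(regions)$homologous]
  var_cols <- intersect(c(key, "pos", "ref", "alt"), names(cohort_calls))
  cohort_calls %>%
    filter(.data[[key]] %in% hom) %>%
    distinct(across(dplyr::all_of(c("sample", var_cols)))) %>%
    group_by(across(dplyr::all_of(var_cols))) %>%
    summarise(n_carriers = n(), .groups = "drop") %>%
    mutate(carrier_fraction = .data$n_carriers / n_samples,
           suspected_bleed_through =
             .data$carrier_fraction >= params$bleed_through_fraction) %>%
    filter(.data$suspected_bleed_through)
}
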