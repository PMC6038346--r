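#' Copy-number calling parameters
#'
#' Thresholds for per-target copy-number detection against a pooled
#' background. The log2-ratio decision boundaries sit midway between the
#' expected values for adjacent copy states: a heterozygous deletion (CN 1)
#' is expected at log2(1/2) = -1 and a single-copy gain (CN 3) at
#' log2(3/2) = +0.585, so the defaults of -0.6 and +0.42 split the
#' CN1/CN2 and CN2/CN3 intervals symmetrically.
#'
#' @param het_del_log2_max Mean log2 ratio at or below which a run is called
#'   CN 1 (default -0.6).
#' @param dup_log2_min Mean log2 ratio at or above which a run is called CN 3
#'   (default +0.42).
#' @param hom_del_depth_max Maximum raw sample depth for a target to be a
#'   homozygous-deletion (zero-coverage) candidate (default 2 reads).
#' @param proper_coverage_floor Minimum background median depth for a
#'   zero-coverage target to be considered callable (default 50 reads).
#' @param min_targets_per_call Minimum run length of a call (default 1, so
#'   single-exon events are callable).
#' @param baf_imbalance_alpha Level of the combined allelic-imbalance test
#'   (default 0.01).
#' @param background_min_samples Minimum pooled-background size (default 8).
#' @return A list of class `pv_cnv_params`.
#' @export
cnv_params <- function(het_del_log2_max = -0.6, dup_log2_min = 0.42,
                       hom_del_depth_max = 2L, proper_coverage_floor = 50L,
                       min_targets_per_call = 1L, baf_imbalance_alpha = 0.01,
                       background_min_samples = 8L) {
  if (!(het_del_log2_max < 0 && dup_log2_min > 0)) {
    abort("het_del_log2_max must be negative and dup_log2_min positive")
  }
  structure(
    list(het_del_log2_max = het_del_log2_max, dup_log2_min = dup_log2_min,
         hom_del_depth_max = as.integer(hom_del_depth_max),
         proper_coverage_floor = as.integer(proper_coverage_floor),
         min_targets_per_call = as.integer(min_targets_per_call),
         baf_imbalance_alpha = baf_imbalance_alpha,
         background_min_samples = as.integer(background_min_samples)),
    class = "pv_cnv_params"
  )
}

#' Median-of-ratios depth normalisation against a pooled background
#'
#' Library size is removed by dividing each sample's per-target counts by its
#' own median; capture efficiency is removed by dividing by the background
#' median of the same per-target ratio. The result,
#' `log2((sample_t / sample_median) / median_bg(bg_t / bg_median))`, is 0 in
#' expectation for two copies, -1 for one and +0.585 for three. Targets whose
#' background median ratio is 0 are uninformative and masked.
#'
#' @param counts Long-format read counts: a data frame with columns
#'   `target_id`, `sample`, `count`, covering the test sample and the
#'   background pool on a shared target set.
#' @param sample Name of the test sample; all other samples form the
#'   background.
#' @param params A [cnv_params()] object (checked for
#'   `background_min_samples`).
#' @return A tibble of class `pv_depth_ratio` with columns `target_id`,
#'   `sample_count`, `bg_median_count`, `log2_ratio`, `masked`, ordered as the
#'   targets first appear in `counts`.
#' @export
normalize_depth <- function(counts, sample, params = cnv_params()) {
  counts <- as_tibble(counts)
  if (!sample %in% counts$sample) abort("test sample not present in counts")
  bg_samples <- setdiff(unique(counts$sample), sample)
  if (length(bg_samples) < params$background_min_samples) {
    abort(paste0("background has ", length(bg_samples), " samples; at least ",
                 params$background_min_samples, " required"))
  }
  target_order <- unique(counts$target_id)
  smp <- counts %>% filter(.data$sample == !!sample)
  if (any(smp$count < 0)) abort("negative read counts")
  smp_median <- median(smp$count)
  if (smp_median <= 0) abort("test sample median count is zero")
  bg <- counts %>%
    filter(.data$sample %in% bg_samples) %>%
    group_by(.data$sample) %>%
    mutate(ratio = .data$count / median(.data$count)) %>%
    ungroup() %>%
    group_by(.data$target_id) %>%
    summarise(bg_median_ratio = median(.data$ratio),
              bg_median_count = median(.data$count), .groups = "drop")
  out <- smp %>%
    select("target_id", sample_count = "count") %>%
    left_join(bg, by = "target_id") %>%
    mutate(
      masked = .data$bg_median_ratio <= 0,
      log2_ratio = if_else(
        .data$masked, NA_real_,
        log2((.data$sample_count / smp_median) / .data$bg_median_ratio)
      )
    ) %>%
    select("target_id", "sample_count", "bg_median_count", "log2_ratio",
           "masked") %>%
    arrange(match(.data$target_id, target_order))
  structure(out, class = c("pv_depth_ratio", class(out)), sample = sample)
}

#' Homozygous-deletion candidates from zero coverage
#'
#' Maximal runs of consecutive targets where the test sample has essentially
#' no reads (depth at or below `hom_del_depth_max`) while the background
#' median shows proper coverage (at least `proper_coverage_floor`) are
#' returned as copy-number 0 candidates. Targets poorly covered in everyone
#' are uncallable, not deleted, and are never candidates. Runs do not extend
#' across genes.
#'
#' @param ratios A [normalize_depth()] result.
#' @param targets Target metadata: a data frame with columns `target_id` and
#'   `gene`, ordered along the panel.
#' @param params A [cnv_params()] object.
#' @return A tibble with one row per candidate run: `gene`, `first_target`,
#'   `last_target`, `n_targets`.
#' @export
detect_zero_coverage <- function(ratios, targets, params = cnv_params()) {
  tbl <- left_join(as_tibble(targets), as_tibble(ratios), by = "target_id") %>%
    mutate(candidate = .data$sample_count <= params$hom_del_depth_max &
             .data$bg_median_count >= params$proper_coverage_floor)
  runs_of(tbl, tbl$candidate) %>%
    select("gene", "first_target", "last_target", "n_targets")
}

# contiguous TRUE runs of `flag` within gene, in row order
runs_of <- function(tbl, flag) {
  tbl$.flag <- flag
  tbl$.row <- seq_len(nrow(tbl))
  tbl %>%
    filter(.data$.flag) %>%
    group_by(.data$gene) %>%
    mutate(.run = cumsum(c(1L, as.integer(diff(.data$.row) != 1L)))) %>%
    group_by(.data$gene, .data$.run) %>%
    summarise(first_target = first(.data$target_id),
              last_target = last(.data$target_id),
              n_targets = n(),
              mean_log2_ratio = mean(.data$log2_ratio),
              .groups = "drop") %>%
    select(-".run")
}

#' Allelic-imbalance verdict for a candidate region
#'
#' Constitutionally heterozygous SNPs have B-allele fractions around 0.5;
#' copy-number change shifts them (to 1/3 or 2/3 under CN 3) or removes
#' heterozygosity altogether (CN 0/1). Each SNP is tested two-sided against
#' 0.5 with an exact binomial test and the per-SNP p-values are combined by
#' Fisher's method; the region verdict is "imbalanced" when the combined test
#' rejects at `alpha`, "uninformative" when the region has no heterozygous
#' SNPs. Separately, the complete absence of heterozygous SNPs across a
#' region where the background predicts many is itself deletion evidence,
#' exposed via [loh_support()].
#'
#' @param baf B-allele fractions of heterozygous SNPs in the region.
#' @param depth Read depths at those SNPs.
#' @param alpha Test level, default 0.01.
#' @return A list with `verdict` ("imbalanced", "balanced" or
#'   "uninformative"), `p_combined` and a per-SNP tibble.
#' @export
allelic_imbalance <- function(baf, depth, alpha = 0.01) {
  if (length(baf) == 0) {
    return(list(verdict = "uninformative", p_combined = NA_real_,
                snps = tibble(baf = double(), depth = integer(),
                              p = double())))
  }
  alt <- round(baf * depth)
  p <- purrr::map2_dbl(alt, depth, ~ binom.test(.x, .y, p = 0.5)$p.value)
  stat <- -2 * sum(log(pmax(p, .Machine$double.xmin)))
  p_comb <- pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  list(verdict = if (p_comb < alpha) "imbalanced" else "balanced",
       p_combined = p_comb,
       snps = tibble(baf = baf, depth = as.integer(depth), p = p))
}

#' Loss-of-heterozygosity support from absent heterozygous SNPs
#'
#' Under the background's heterozygous-SNP density, the count of
#' heterozygous SNPs expected over a region is approximately Poisson.
#' Observing none when many are expected supports a deletion.
#'
#' @param n_het Observed heterozygous SNP count in the region.
#' @param expected_het Expected count from the background density.
#' @param alpha Tail level, default 0.01.
#' @return TRUE when `n_het` is 0 and `P(Poisson(expected_het) = 0) < alpha`.
#' @export
loh_support <- function(n_het, expected_het, alpha = 0.01) {
  n_het == 0 & exp(-expected_het) < alpha
}

#' Integrate depth, zero-coverage and imbalance evidence into CNV calls
#'
#' Copy-number 0 comes from zero-coverage candidates (or a mean log2 ratio at
#' or below -3); CN 1 and CN 3 come from runs of targets whose mean log2
#' ratio crosses the deletion/duplication thresholds. Adjacent same-state
#' targets within a gene are merged into one event (rule-based run merging;
#' panel targets are exon-sized and sparse, so segmentation models add
#' nothing). Allelic-imbalance verdicts annotate confidence but never veto a
#' depth-supported call.
#'
#' @param ratios A [normalize_depth()] result.
#' @param targets Target metadata (`target_id`, `gene`), ordered along the
#'   panel.
#' @param params A [cnv_params()] object.
#' @param zero_cov Optional result of [detect_zero_coverage()]; computed from
#'   `ratios` when NULL.
#' @param imbalance Optional tibble (`gene`, `verdict`) of per-gene
#'   [allelic_imbalance()] verdicts used to annotate calls.
#' @return A tibble of class `pv_cnv_calls`: `gene`, `first_target`,
#'   `last_target`, `n_targets`, `state` (0, 1 or 3), `mean_log2_ratio`,
#'   `evidence` (comma-joined subset of depth, zero_coverage,
#'   allelic_imbalance).
#' @export
call_cnv <- function(ratios, targets, params = cnv_params(), zero_cov = NULL,
                     imbalance = NULL) {
  targets <- as_tibble(targets)
  if (is.null(zero_cov)) zero_cov <- detect_zero_coverage(ratios, targets, params)
  tbl <- left_join(targets, as_tibble(ratios), by = "target_id")
  in_zero <- rep(FALSE, nrow(tbl))
  if (nrow(zero_cov) > 0) {
    for (i in seq_len(nrow(zero_cov))) {
      a <- which(tbl$target_id == zero_cov$first_target[i])
      b <- which(tbl$target_id == zero_cov$last_target[i])
      in_zero[a:b] <- TRUE
    }
  }
  tbl <- tbl %>%
    mutate(state = dplyr::case_when(
      in_zero ~ 0L,
      .data$masked | is.na(.data$log2_ratio) ~ 2L,
      .data$log2_ratio <= -3 ~ 0L,
      .data$log2_ratio <= params$het_del_log2_max ~ 1L,
      .data$log2_ratio >= params$dup_log2_min ~ 3L,
      TRUE ~ 2L
    ))
  calls <- purrr::map(c(0L, 1L, 3L), function(s) {
    runs_of(tbl, tbl$state == s) %>% mutate(state = s)
  }) %>%
    bind_rows()
  if (nrow(calls) == 0) {
    out <- tibble(gene = character(), first_target = character(),
                  last_target = character(), n_targets = integer(),
                  state = integer(), mean_log2_ratio = double(),
                  evidence = character())
    return(structure(out, class = c("pv_cnv_calls", class(out))))
  }
  # a target can belong to at most one state by construction; overlapping
  # contradictory runs would indicate a bug
  covered <- purrr::pmap(calls, function(first_target, last_target, ...) {
    a <- which(tbl$target_id == first_target)
    b <- which(tbl$target_id == last_target)
    seq.int(a, b)
  })
  if (anyDuplicated(unlist(covered)) > 0) {
    abort("internal error: overlapping contradictory CNV calls")
  }
  calls <- calls %>%
    filter(.data$n_targets >= params$min_targets_per_call |
             .data$state == 0L) %>%
    mutate(evidence = dplyr::case_when(
      .data$state == 0L ~ "zero_coverage",
      TRUE ~ "depth"
    ))
  if (!is.null(imbalance)) {
    calls <- calls %>%
      left_join(as_tibble(imbalance), by = "gene") %>%
      mutate(evidence = if_else(
        !is.na(.data$verdict) & .data$verdict == "imbalanced",
        paste0(.data$evidence, ",allelic_imbalance"), .data$evidence)) %>%
      select(-"verdict")
  }
  out <- calls %>%
    arrange(match(.data$gene, unique(targets$gene)), .data$first_target) %>%
    select("gene", "first_target", "last_target", "n_targets", "state",
           "mean_log2_ratio", "evidence")
  structure(out, class = c("pv_cnv_calls", class(out)))
}
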