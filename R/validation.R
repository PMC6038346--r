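#' Benchmark calls against a truth set
#'
#' Matching is exact on the normalised (position, ref, alt) triple —
#' [normalize_alleles()] canonicalises both sides first, so equivalent indel
#' spellings match. Genotypes are not scored: the analytical validation
#' counts variant detection. True-negative accounting is per position: a
#' target position is a true negative when it bears neither a truth variant
#' nor a call.
#'
#' @param calls A data frame of calls with columns `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param truth The truth set: columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `type` (derived from the alleles when absent).
#' @param target_positions Total number of callable positions in the target
#'   space; truth positions must lie in `[1, target_positions]` when
#'   `check_space` is TRUE.
#' @param check_space Validate that truth loci fall inside the target space
#'   (default TRUE; positions are indexed 1..`target_positions`).
#' @return An object of class `pv_benchmark` with per-type and overall
#'   counts, sensitivity and specificity; see [tidy()] and [glance()].
#' @examples
#' truth <- tibble::tibble(chrom = "t", pos = 1:4, ref = "A", alt = "G")
#' calls <- truth[1:3, ]
#' glance(benchmark_calls(calls, truth, target_positions = 100))
#' @export
benchmark_calls <- function(calls, truth, target_positions,
                            check_space = TRUE) {
  calls <- as_tibble(calls)
  truth <- as_tibble(truth)
  if (check_space && nrow(truth) > 0 &&
      any(truth$pos < 1 | truth$pos > target_positions)) {
    bad <- truth$pos[truth$pos < 1 | truth$pos > target_positions][1]
    abort(paste0("truth locus outside target space: position ", bad))
  }
  key_of <- function(tbl) {
    norm <- normalize_alleles(tbl$pos, tbl$ref, tbl$alt)
    paste(tbl$chrom, norm$pos, norm$ref, norm$alt, sep = ":")
  }
  type_of <- function(tbl) {
    if ("type" %in% names(tbl)) {
      if_else(tbl$type == "SNV", "SNV", "indel")
    } else {
      if_else(variant_type_of(tbl$ref, tbl$alt) == "SNV", "SNV", "indel")
    }
  }
  truth_keys <- key_of(truth)
  call_keys <- unique(key_of(calls))
  truth_hit <- truth_keys %in% call_keys
  truth_type <- type_of(truth)
  fp_keys <- setdiff(call_keys, truth_keys)
  fp_positions <- length(unique(
    as.integer(stringr::str_split_fixed(fp_keys, ":", 4)[, 2])))
  truth_pos_n <- length(unique(truth$pos))
  clean_positions <- target_positions - truth_pos_n
  tn <- clean_positions - fp_positions
  per_type <- tibble(type = truth_type, hit = truth_hit) %>%
    group_by(.data$type) %>%
    summarise(tp = sum(.data$hit), fn = sum(!.data$hit),
              sensitivity = mean(.data$hit), .groups = "drop")
  sens <- if (nrow(truth) == 0) NA_real_ else mean(truth_hit)
  structure(
    list(per_type = per_type,
         tp = sum(truth_hit), fn = sum(!truth_hit),
         fp = length(fp_keys), tn = tn,
         n_truth = nrow(truth),
         target_positions = target_positions,
         clean_positions = clean_positions,
         sensitivity = sens,
         specificity = if (clean_positions > 0) tn / clean_positions
                       else NA_real_),
    class = "pv_benchmark"
  )
}

#' @export
print.pv_benchmark <- function(x, ...) {
  cat("Benchmark over ", x$target_positions, " target positions\n", sep = "")
  if (is.na(x$sensitivity)) {
    cat("  sensitivity: not applicable (empty truth set)\n")
  } else {
    cat(sprintf("  sensitivity: %.4f (%d/%d)\n", x$sensitivity, x$tp,
                x$n_truth))
    for (i in seq_len(nrow(x$per_type))) {
      cat(sprintf("    %s: %d/%d\n", x$per_type$type[i], x$per_type$tp[i],
                  x$per_type$tp[i] + x$per_type$fn[i]))
    }
  }
  cat(sprintf("  specificity: %.4f (%d/%d clean positions), %d FP calls\n",
              x$specificity, x$tn, x$clean_positions, x$fp))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pv_benchmark <- function(x, ...) {
  x$per_type
}

#' @exportS3Method generics::glance
glance.pv_benchmark <- function(x, ...) {
  tibble(tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
         sensitivity = x$sensitivity, specificity = x$specificity,
         n_truth = x$n_truth, target_positions = x$target_positions)
}

#' The six-SNP sample-tracking panel
#'
#' High-heterozygosity SNPs inside panel genes used to verify that the
#' sequenced library and the orthogonally genotyped specimen are the same
#' person. Population minor allele frequencies near 0.5 maximise the chance
#' that two different individuals disagree somewhere across the panel.
#'
#' @return A tibble with columns `snp_id`, `gene`, `maf`.
#' @export
tracking_panel <- function() {
  tibble(
    snp_id = c("rs10864198", "rs7598901", "rs2228557", "rs7624750",
               "rs734312", "rs2438349"),
    gene = c("USH2A", "ALMS1", "COL4A4", "OPA1", "WFS1", "ADGRV1"),
    maf = c(0.4531, 0.4736, 0.4657, 0.4683, 0.4633, 0.4830)
  )
}

#' Sample-tracking genotype concordance
#'
#' Compares the sequencing-derived genotypes at the tracking SNPs against
#' orthogonal (e.g. qPCR) genotypes. The check passes only when every SNP is
#' concordant; any mismatch fails with a sample-swap warning.
#'
#' @param ngs,orthogonal Data frames with columns `snp_id` and `genotype`.
#' @param panel The tracking panel, default [tracking_panel()].
#' @return A list with `pass` (logical) and `table` (per-SNP comparison).
#' @export
tracking_concordance <- function(ngs, orthogonal, panel = tracking_panel()) {
  ngs <- as_tibble(ngs)
  orthogonal <- as_tibble(orthogonal)
  for (nm in list(list(ngs, "ngs"), list(orthogonal, "orthogonal"))) {
    missing_snps <- setdiff(panel$snp_id, nm[[1]]$snp_id)
    if (length(missing_snps) > 0) {
      abort(paste0("missing ", nm[[2]], " genotype(s) for tracking SNP(s): ",
                   paste(missing_snps, collapse = ", ")))
    }
  }
  tab <- panel %>%
    left_join(rename(ngs, ngs_genotype = "genotype"), by = "snp_id") %>%
    left_join(rename(orthogonal, orthogonal_genotype = "genotype"),
              by = "snp_id") %>%
    mutate(concordant = .data$ngs_genotype == .data$orthogonal_genotype)
  pass <- all(tab$concordant)
  if (!pass) {
    warn(paste0("tracking genotype mismatch at ",
                paste(tab$snp_id[!tab$concordant], collapse = ", "),
                ": possible sample identity swap"))
  }
  list(pass = pass, table = tab)
}

#' Hardy-Weinberg probability that two unrelated samples share a genotype
#'
#' For a biallelic SNP at minor allele frequency `maf` under
#' Hardy-Weinberg equilibrium, two unrelated individuals carry the same
#' genotype with probability `sum(g^2)` over the three genotype
#' probabilities. The probability that two unrelated samples agree on the
#' whole tracking panel is the product over SNPs — the closed form against
#' which observed swap-detection power is checked.
#'
#' @param maf Vector of minor allele frequencies.
#' @return Per-SNP probability that two unrelated samples match.
#' @export
hw_genotype_match_prob <- function(maf) {
  p <- 1 - maf
  q <- maf
  (p^2)^2 + (2 * p * q)^2 + (q^2)^2
}
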