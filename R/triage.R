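#' Triage parameters
#'
#' Two rarity cut-offs drive variant filtering: a permissive 5% minor allele
#' frequency for variants with prior pathogenicity support (database-flagged
#' or predicted null alleles, where founder effects can push frequencies up)
#' and a strict 1% for everything else that affects the protein or RNA.
#'
#' @param maf_cutoff_strict MAF cut-off for database-supported / null
#'   variants (default 0.05).
#' @param maf_cutoff_default MAF cut-off for other protein/RNA-affecting
#'   variants (default 0.01); must be below the strict cut-off.
#' @return A list of class `pv_triage_params`.
#' @export
triage_params <- function(maf_cutoff_strict = 0.05, maf_cutoff_default = 0.01) {
  if (!(maf_cutoff_default < maf_cutoff_strict)) {
    abort("maf_cutoff_default must be below maf_cutoff_strict")
  }
  structure(list(maf_cutoff_strict = maf_cutoff_strict,
                 maf_cutoff_default = maf_cutoff_default),
            class = "pv_triage_params")
}

null_consequences <- c("nonsense", "frameshift_ptc", "canonical_splice",
                       "start_loss", "exon_deletion", "exon_duplication")

protein_affecting <- c(null_consequences, "missense", "inframe_indel")

#' Is a consequence predicted to create a null allele?
#'
#' Null alleles are those expected to abolish the gene product: nonsense,
#' frameshift with premature stop, canonical splice-site disruption, start
#' loss and complete exon deletions or duplications.
#'
#' @param consequence Character vector of consequence terms.
#' @return Logical vector; unknown terms return FALSE with a warning.
#' @export
predicted_null <- function(consequence) {
  known <- c(null_consequences, "missense", "synonymous", "inframe_indel",
             "other")
  unknown <- setdiff(unique(consequence), known)
  if (length(unknown) > 0) {
    warn(paste0("unknown consequence term(s) treated as non-null: ",
                paste(unknown, collapse = ", ")))
  }
  consequence %in% null_consequences
}

#' Population-frequency filter by variant class
#'
#' Variants with prior pathogenicity support — flagged disease-causing (DM)
#' by HGMD, pathogenic/likely pathogenic in ClinVar, or predicted null — are
#' kept below 5% MAF; other protein/RNA-affecting variants below 1%;
#' synonymous and other non-affecting variants are dropped. A variant with
#' no recorded MAF is treated as rare (MAF 0) and is never dropped on
#' frequency.
#'
#' @param variants A data frame with columns `population_maf` (NA = absent),
#'   `hgmd_dm` (logical), `clinvar_class` (P, LP, VUS, LB, B or none) and
#'   `consequence`.
#' @param params A [triage_params()] object.
#' @return `variants` with logical columns `strict_class` and `keep`.
#' @export
maf_filter <- function(variants, params = triage_params()) {
  variants <- as_tibble(variants)
  maf <- dplyr::coalesce(variants$population_maf, 0)
  strict <- variants$hgmd_dm |
    variants$clinvar_class %in% c("P", "LP") |
    predicted_null(variants$consequence)
  affecting <- variants$consequence %in% protein_affecting
  variants %>%
    mutate(strict_class = strict,
           keep = if_else(strict,
                          maf < params$maf_cutoff_strict,
                          affecting & maf < params$maf_cutoff_default))
}

# allele dosage a variant contributes to a biallelic requirement
allele_dosage <- function(zygosity) {
  dplyr::case_when(
    zygosity == "homozygous" ~ 2L,
    zygosity %in% c("heterozygous", "hemizygous") ~ 1L,
    TRUE ~ 0L
  )
}

#' Check variants in a gene against its inheritance modes
#'
#' A recessive (AR) gene needs biallelic qualifying variants: a homozygote,
#' or two or more variants assumed in trans (compound heterozygote, possibly
#' one SNV plus an overlapping CNV). A dominant (AD) gene needs a single
#' variant; de-novo-AD additionally requires the variant to be asserted de
#' novo. X-linked recessive genes need a hemizygous male (or homozygous
#' female); X-linked dominant accepts a hemizygous male or a heterozygous
#' female. Mitochondrial modes are never auto-consistent (heteroplasmy is
#' out of scope).
#'
#' @param modes Character vector of the gene's inheritance modes (subset of
#'   AR, AD, XR, XD, MT, de-novo-AD).
#' @param chrom_class "autosome", "X" or "MT".
#' @param variants Data frame of the case's qualifying variants in the gene,
#'   with columns `zygosity` and optionally `de_novo`.
#' @param sex "male" or "female".
#' @return A list with `consistent` (logical) and `label` (configuration:
#'   AR-biallelic, AD-het, de-novo-AD, XL-hemi, XL-het-female, or NA).
#' @export
inheritance_consistent <- function(modes, chrom_class, variants, sex) {
  if (length(modes) == 0) abort("gene has no inheritance modes")
  variants <- as_tibble(variants)
  if (!"de_novo" %in% names(variants)) variants$de_novo <- FALSE
  if (nrow(variants) == 0) {
    return(list(consistent = FALSE, label = NA_character_))
  }
  dosage <- sum(allele_dosage(variants$zygosity))
  any_hemi <- any(variants$zygosity == "hemizygous")
  any_hom <- any(variants$zygosity == "homozygous")
  any_het <- any(variants$zygosity == "heterozygous")
  for (mode in modes) {
    if (mode == "AR" && chrom_class == "autosome" && dosage >= 2) {
      return(list(consistent = TRUE, label = "AR-biallelic"))
    }
    if (mode == "AD" && (any_het || any_hom)) {
      return(list(consistent = TRUE, label = "AD-het"))
    }
    if (mode == "de-novo-AD" && any(variants$de_novo)) {
      return(list(consistent = TRUE, label = "de-novo-AD"))
    }
    if (mode %in% c("XR", "XD") && chrom_class == "X") {
      if (sex == "male" && any_hemi) {
        return(list(consistent = TRUE, label = "XL-hemi"))
      }
      if (sex == "female" && any_hom) {
        return(list(consistent = TRUE, label = "XL-hemi"))
      }
      if (mode == "XD" && sex == "female" && any_het) {
        return(list(consistent = TRUE, label = "XL-het-female"))
      }
    }
  }
  list(consistent = FALSE, label = NA_character_)
}

#' Tiered reportability of a classified variant
#'
#' Tier-1 genes report class 3-5 findings; class 1-2 findings lie within the
#' reference range and are suppressed. Tier-2 genes report only class 4-5
#' findings whose gene phenotype matches the patient. Findings in an
#' inheritance-inconsistent configuration are included for information only,
#' never as causative.
#'
#' @param acmg_class Integer vector of ACMG classes (1-5).
#' @param tier Integer vector of gene tiers (1 or 2).
#' @param phenotype_match Logical vector: does the tier-2 gene phenotype
#'   match the patient's?
#' @param consistent Logical vector from [inheritance_consistent()].
#' @return Character vector: "reported_with_class", "informative_only" or
#'   "suppressed".
#' @export
assign_reportability <- function(acmg_class, tier,
                                 phenotype_match = FALSE, consistent = TRUE) {
  n <- length(acmg_class)
  tier <- rep_len(tier, n)
  phenotype_match <- rep_len(phenotype_match, n)
  consistent <- rep_len(consistent, n)
  dplyr::case_when(
    tier == 1L & acmg_class >= 3L & consistent ~ "reported_with_class",
    tier == 1L & acmg_class >= 3L ~ "informative_only",
    tier == 2L & acmg_class >= 4L & phenotype_match & consistent ~
      "reported_with_class",
    tier == 2L & acmg_class >= 4L & phenotype_match ~ "informative_only",
    TRUE ~ "suppressed"
  )
}

#' Assign a causative diagnosis to one case
#'
#' A case is diagnosed when some gene carries an inheritance-consistent
#' configuration of class 4-5 variants, each either free of the
#' orthogonal-confirmation requirement or positively confirmed. The
#' diagnosis records the causative gene(s) and variants, the inheritance
#' pattern (AR, AD or XL), and a hidden-syndrome flag when the causative
#' gene's phenotype is exclusively syndromic while the patient presented as
#' non-syndromic. Cases that are only diagnosable when class-3 (VUS)
#' variants are counted as positive are marked `suspicious_vus`, not
#' diagnosed.
#'
#' @param case One row of a case table (a list or one-row data frame) with
#'   fields `case_id`, `sex`, `pretest_syndromic`.
#' @param variants The case's classified variants: columns `gene`,
#'   `zygosity`, `acmg_class`, `confirmed`, `homology_flagged`, `de_novo`,
#'   `variant_class`, `in_db`.
#' @param panel A [load_panel()] object.
#' @return A one-row tibble: `case_id`, `diagnosed`, `causative_genes`
#'   (list), `inheritance_pattern`, `configuration`, `hidden_syndrome`,
#'   `cnv_attributable`, `novel_db`, `suspicious_vus`.
#' @export
diagnose_case <- function(case, variants, panel) {
  case <- as_tibble(as.list(case))[1, ]
  variants <- as_tibble(variants)
  if (nrow(variants) > 0) {
    unknown <- setdiff(unique(variants$gene), panel$symbol)
    if (length(unknown) > 0) {
      abort(paste0("variant gene(s) absent from panel: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  for (col in c("confirmed", "homology_flagged", "de_novo", "in_db")) {
    if (!col %in% names(variants)) variants[[col]] <- FALSE
  }
  if (!"variant_class" %in% names(variants)) variants$variant_class <- "SNV"
  # a flagged variant without positive confirmation can never be causative
  eligible <- variants %>%
    filter(!.data$homology_flagged | .data$confirmed)

  config_for <- function(min_class) {
    qual <- eligible %>% filter(.data$acmg_class >= min_class)
    genes <- unique(qual$gene)
    hits <- purrr::map(genes, function(g) {
      meta <- panel[panel$symbol == g, ]
      vg <- qual[qual$gene == g, ]
      res <- inheritance_consistent(meta$inheritance_modes[[1]],
                                    meta$chrom_class, vg, case$sex)
      if (res$consistent) {
        tibble(gene = g, label = res$label,
               chrom_class = meta$chrom_class,
               phenotype_class = meta$phenotype_class,
               variants = list(vg))
      } else NULL
    })
    bind_rows(purrr::compact(hits))
  }

  strict <- config_for(4L)
  diagnosed <- nrow(strict) > 0
  suspicious <- FALSE
  if (!diagnosed) {
    lenient <- config_for(3L)
    suspicious <- nrow(lenient) > 0
  }
  if (diagnosed) {
    causative <- bind_rows(strict$variants)
    pattern <- dplyr::case_when(
      strict$chrom_class[1] == "X" ~ "XL",
      strict$label[1] == "AR-biallelic" ~ "AR",
      TRUE ~ "AD"
    )
    hidden <- any(strict$phenotype_class == "syndromic") &&
      !isTRUE(case$pretest_syndromic)
    tibble(case_id = case$case_id, diagnosed = TRUE,
           causative_genes = list(strict$gene),
           inheritance_pattern = pattern,
           configuration = strict$label[1],
           hidden_syndrome = hidden,
           cnv_attributable = any(stringr::str_starts(causative$variant_class,
                                                      "cnv")),
           novel_db = any(!causative$in_db),
           suspicious_vus = FALSE)
  } else {
    tibble(case_id = case$case_id, diagnosed = FALSE,
           causative_genes = list(character()),
           inheritance_pattern = NA_character_,
           configuration = NA_character_,
           hidden_syndrome = FALSE, cnv_attributable = FALSE,
           novel_db = FALSE, suspicious_vus = suspicious)
  }
}

#' Run classification and diagnosis over a whole cohort
#'
#' Classifies every variant from its criteria string (applying any recorded
#' expert overrides), then diagnoses each case with [diagnose_case()].
#'
#' @param cohort A list with elements `cases` and `variants`, as returned by
#'   [build_table_fixtures()].
#' @param panel A [load_panel()] object, default [example_panel()].
#' @return A tibble of class `pv_case_results`: the case table joined with
#'   per-case diagnosis columns.
#' @export
diagnose_cohort <- function(cohort, panel = example_panel()) {
  variants <- classify_variants(cohort$variants)
  results <- purrr::map(seq_len(nrow(cohort$cases)), function(i) {
    case <- cohort$cases[i, ]
    diagnose_case(case, variants[variants$case_id == case$case_id, ], panel)
  }) %>% bind_rows()
  out <- left_join(cohort$cases, results, by = "case_id")
  structure(out, class = c("pv_case_results", class(out)))
}

#' Cohort-level diagnostic-yield summary
#'
#' Aggregates per-case diagnoses into the cohort statistics a validation
#' report quotes: diagnostic yield (and yield counting suspicious VUS-only
#' cases as positive), the inheritance-pattern breakdown among diagnosed
#' cases, the fractions attributable to CNVs, revealing hidden syndromes and
#' explained by database-novel variants, and the count of distinct causative
#' genes.
#'
#' @param results A [diagnose_cohort()] result.
#' @return An object of class `pv_cohort_summary` (a list; see [tidy()] and
#'   [glance()] methods).
#' @export
summarize_cohort <- function(results) {
  results <- as_tibble(results)
  if (nrow(results) == 0) abort("empty cohort")
  n <- nrow(results)
  dx <- results[results$diagnosed, ]
  n_dx <- nrow(dx)
  pct <- function(k, d) if (d == 0) NA_real_ else 100 * k / d
  out <- list(
    n_cases = n,
    n_diagnosed = n_dx,
    yield_pct = pct(n_dx, n),
    n_suspicious_vus = sum(results$suspicious_vus),
    yield_with_vus_pct = pct(n_dx + sum(results$suspicious_vus), n),
    pattern_counts = dx %>% count(.data$inheritance_pattern),
    pct_ar = pct(sum(dx$inheritance_pattern == "AR"), n_dx),
    pct_ad = pct(sum(dx$inheritance_pattern == "AD"), n_dx),
    pct_xl = pct(sum(dx$inheritance_pattern == "XL"), n_dx),
    n_cnv = sum(dx$cnv_attributable),
    pct_cnv = pct(sum(dx$cnv_attributable), n_dx),
    n_hidden_syndrome = sum(dx$hidden_syndrome),
    pct_hidden_syndrome = pct(sum(dx$hidden_syndrome), n_dx),
    n_novel_db = sum(dx$novel_db),
    pct_novel_db = pct(sum(dx$novel_db), n_dx),
    n_causative_genes = length(unique(unlist(dx$causative_genes)))
  )
  structure(out, class = "pv_cohort_summary")
}

#' @export
print.pv_cohort_summary <- function(x, ...) {
  cat("Cohort of ", x$n_cases, " cases\n", sep = "")
  cat(sprintf("  diagnostic yield: %.1f%% (%d/%d)\n", x$yield_pct,
              x$n_diagnosed, x$n_cases))
  cat(sprintf("  counting suspicious VUS: %.1f%% (%d/%d)\n",
              x$yield_with_vus_pct, x$n_diagnosed + x$n_suspicious_vus,
              x$n_cases))
  cat(sprintf("  inheritance: %.1f%% AR / %.1f%% AD / %.1f%% XL\n",
              x$pct_ar, x$pct_ad, x$pct_xl))
  cat(sprintf("  CNV-attributable: %d/%d (%.1f%%)\n", x$n_cnv, x$n_diagnosed,
              x$pct_cnv))
  cat(sprintf("  hidden syndromes: %d/%d (%.1f%%)\n", x$n_hidden_syndrome,
              x$n_diagnosed, x$pct_hidden_syndrome))
  cat(sprintf("  explained by database-novel variants: %d/%d (%.1f%%)\n",
              x$n_novel_db, x$n_diagnosed, x$pct_novel_db))
  cat("  distinct causative genes: ", x$n_causative_genes, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pv_cohort_summary <- function(x, ...) {
  tibble(
    statistic = c("yield_pct", "yield_with_vus_pct", "pct_ar", "pct_ad",
                  "pct_xl", "pct_cnv", "pct_hidden_syndrome", "pct_novel_db"),
    value = c(x$yield_pct, x$yield_with_vus_pct, x$pct_ar, x$pct_ad,
              x$pct_xl, x$pct_cnv, x$pct_hidden_syndrome, x$pct_novel_db)
  )
}

#' @exportS3Method generics::glance
glance.pv_cohort_summary <- function(x, ...) {
  tibble(n_cases = x$n_cases, n_diagnosed = x$n_diagnosed,
         yield_pct = x$yield_pct, yield_with_vus_pct = x$yield_with_vus_pct,
         n_cnv = x$n_cnv, n_hidden_syndrome = x$n_hidden_syndrome,
         n_novel_db = x$n_novel_db,
         n_causative_genes = x$n_causative_genes)
}
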