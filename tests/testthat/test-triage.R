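test_that("null-allele prediction covers exactly the five null classes", {
  expect_true(predicted_null("nonsense"))
  expect_true(predicted_null("frameshift_ptc"))
  expect_true(predicted_null("canonical_splice"))
  expect_true(predicted_null("start_loss"))
  expect_true(predicted_null("exon_deletion"))
  expect_true(predicted_null("exon_duplication"))
  expect_false(predicted_null("missense"))
  expect_false(predicted_null("synonymous"))
  expect_warning(res <- predicted_null("weird_term"), "weird_term")
  expect_false(res)
})

test_that("MAF filtering applies 5% to supported variants and 1% otherwise", {
  variants <- tibble::tibble(
    population_maf = c(0.049, 0.051, 0.02, 0.009, NA, 0.001),
    hgmd_dm = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    clinvar_class = c("none", "none", "none", "none", "none", "none"),
    consequence = c("missense", "missense", "missense", "missense",
                    "missense", "synonymous"))
  out <- maf_filter(variants)
  expect_equal(out$keep, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  # predicted-null and ClinVar P/LP variants also get the permissive cut-off
  strict <- maf_filter(tibble::tibble(
    population_maf = c(0.03, 0.03),
    hgmd_dm = FALSE, clinvar_class = c("LP", "none"),
    consequence = c("missense", "nonsense")))
  expect_true(all(strict$keep))
  # absent MAF is never a reason to drop
  absent <- maf_filter(tibble::tibble(
    population_maf = NA_real_, hgmd_dm = FALSE,
    clinvar_class = "none", consequence = "missense"))
  expect_true(absent$keep)
})

test_that("inheritance consistency encodes biallelic, dominant and X-linked logic", {
  het <- tibble::tibble(zygosity = "heterozygous", de_novo = FALSE)
  hom <- tibble::tibble(zygosity = "homozygous", de_novo = FALSE)
  two_het <- tibble::tibble(zygosity = c("heterozygous", "heterozygous"),
                            de_novo = FALSE)
  hemi <- tibble::tibble(zygosity = "hemizygous", de_novo = FALSE)
  # AR gene, one het only: inconsistent
  expect_false(inheritance_consistent("AR", "autosome", het, "female")$consistent)
  # AR: homozygote or compound het (e.g. SNV + overlapping CNV)
  expect_true(inheritance_consistent("AR", "autosome", hom, "female")$consistent)
  ch <- inheritance_consistent("AR", "autosome", two_het, "male")
  expect_true(ch$consistent)
  expect_equal(ch$label, "AR-biallelic")
  # AD accepts a single het
  expect_true(inheritance_consistent("AD", "autosome", het, "female")$consistent)
  # de-novo-AD needs the de novo assertion
  dn <- dplyr::mutate(het, de_novo = TRUE)
  expect_false(inheritance_consistent("de-novo-AD", "autosome", het,
                                      "female")$consistent)
  expect_true(inheritance_consistent("de-novo-AD", "autosome", dn,
                                     "female")$consistent)
  # X-linked recessive male hemizygote
  xr <- inheritance_consistent("XR", "X", hemi, "male")
  expect_true(xr$consistent)
  expect_equal(xr$label, "XL-hemi")
  expect_false(inheritance_consistent("XR", "X", het, "female")$consistent)
  # X-linked dominant heterozygous female
  xd <- inheritance_consistent("XD", "X", het, "female")
  expect_true(xd$consistent)
  expect_equal(xd$label, "XL-het-female")
  expect_error(inheritance_consistent(character(0), "autosome", het, "male"),
               "modes")
})

test_that("reportability is tiered, class-gated and consistency-aware", {
  expect_equal(assign_reportability(2L, 1L), "suppressed")
  expect_equal(assign_reportability(3L, 1L), "reported_with_class")
  expect_equal(assign_reportability(4L, 1L, consistent = FALSE),
               "informative_only")
  expect_equal(assign_reportability(5L, 2L, phenotype_match = TRUE),
               "reported_with_class")
  expect_equal(assign_reportability(5L, 2L, phenotype_match = FALSE),
               "suppressed")
  expect_equal(assign_reportability(3L, 2L, phenotype_match = TRUE),
               "suppressed")
})

test_that("case diagnosis requires class 4-5, consistency and confirmation", {
  panel <- example_panel()
  cohort <- build_table_fixtures()
  variants <- classify_variants(cohort$variants)
  # homozygous class-5 USH2A in a syndromic-only gene: diagnosed, hidden syndrome
  oto004 <- diagnose_case(cohort$cases[cohort$cases$case_id == "OTO.004", ],
                          variants[variants$case_id == "OTO.004", ], panel)
  expect_true(oto004$diagnosed)
  expect_true(oto004$hidden_syndrome)
  expect_equal(oto004$inheritance_pattern, "AR")
  # homozygous VUS: not diagnosed, suspicious only
  oto044 <- diagnose_case(cohort$cases[cohort$cases$case_id == "OTO.044", ],
                          variants[variants$case_id == "OTO.044", ], panel)
  expect_false(oto044$diagnosed)
  expect_true(oto044$suspicious_vus)
  # no variants at all
  oto017 <- diagnose_case(cohort$cases[cohort$cases$case_id == "OTO.017", ],
                          variants[variants$case_id == "OTO.017", ], panel)
  expect_false(oto017$diagnosed)
  expect_false(oto017$suspicious_vus)
  # a pre-test syndromic phenotype is not a hidden syndrome
  oto010 <- diagnose_case(cohort$cases[cohort$cases$case_id == "OTO.010", ],
                          variants[variants$case_id == "OTO.010", ], panel)
  expect_true(oto010$diagnosed)
  expect_false(oto010$hidden_syndrome)
})

test_that("unconfirmed homology-flagged variants never support a diagnosis", {
  panel <- example_panel()
  cohort <- build_table_fixtures()
  variants <- classify_variants(cohort$variants)
  v <- variants[variants$case_id == "OTO.001", ]
  stopifnot(any(v$homology_flagged))
  v$confirmed <- FALSE
  res <- diagnose_case(cohort$cases[cohort$cases$case_id == "OTO.001", ],
                       v, panel)
  expect_false(res$diagnosed)
})

test_that("variants in genes outside the panel are an error", {
  panel <- example_panel()
  cohort <- build_table_fixtures()
  v <- classify_variants(cohort$variants)[1, ]
  v$gene <- "NOT_A_GENE"
  expect_error(diagnose_case(cohort$cases[1, ], v, panel), "absent from panel")
})

test_that("cohort summary aggregates a hand-checkable miniature", {
  panel <- load_panel(tibble::tibble(
    symbol = c("GA", "GB"), tier = 1, transcript = "NM",
    inheritance_modes = c("AR", "AD"), chrom_class = "autosome",
    phenotype_class = c("syndromic", "nonsyndromic")))
  cohort <- list(
    cases = tibble::tibble(
      case_id = c("c1", "c2", "c3"), sex = "female",
      pretest_syndromic = FALSE),
    variants = tibble::tibble(
      case_id = c("c1", "c2"), gene = c("GA", "GB"),
      zygosity = c("homozygous", "heterozygous"),
      criteria = c("PVS1,PM2,PM3", "PM2,PP3"),
      variant_class = c("cnv_del", "SNV"),
      in_db = c(FALSE, TRUE), de_novo = FALSE, confirmed = TRUE,
      homology_flagged = FALSE))
  s <- summarize_cohort(diagnose_cohort(cohort, panel))
  expect_equal(s$n_diagnosed, 1L)
  expect_equal(s$yield_pct, 100 / 3)
  expect_equal(s$n_suspicious_vus, 1L)   # c2's VUS is AD-consistent
  expect_equal(s$yield_with_vus_pct, 200 / 3)
  expect_equal(s$n_cnv, 1L)
  expect_equal(s$n_hidden_syndrome, 1L)
  expect_equal(s$n_causative_genes, 1L)
  expect_error(summarize_cohort(tibble::tibble()), "empty")
  # a single undiagnosed case gives zero yield
  one <- list(cases = tibble::tibble(case_id = "c9", sex = "male",
                                     pretest_syndromic = FALSE),
              variants = tibble::tibble(
                case_id = character(), gene = character(),
                zygosity = character(), criteria = character()))
  expect_equal(summarize_cohort(diagnose_cohort(one, panel))$yield_pct, 0)
})
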