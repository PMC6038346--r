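#' The packaged 50-case cohort fixture
#'
#' A transcription of a published diagnostic case series of 50 consecutive
#' patients with presumed hereditary sensorineural hearing loss (pre-screened
#' negative for the most common deafness loci): 21 cases with causative
#' findings (including the per-variant ACMG criteria strings, zygosities and
#' database-presence flags), 29 without, three of which carry suspicious
#' homozygous/hemizygous VUS configurations. Patient sex is only printed for
#' the hemizygous cases; the remaining assignments are a fixed synthetic set
#' reproducing the cohort's 21 male / 29 female split. The `provenance`
#' column records which stratum of the series each record came from.
#'
#' @return A list of class `pv_cohort` with tibbles `cases` (one row per
#'   patient) and `variants` (one row per candidate variant, with `criteria`
#'   strings consumable by [classify_variants()]).
#' @examples
#' cohort <- build_table_fixtures()
#' nrow(cohort$cases)
#' @export
build_table_fixtures <- function() {
  cases <- readr::read_tsv(
    system.file("extdata", "cohort_cases.tsv", package = "panelvar"),
    show_col_types = FALSE, progress = FALSE)
  variants <- readr::read_tsv(
    system.file("extdata", "cohort_variants.tsv", package = "panelvar"),
    col_types = readr::cols(override_class = readr::col_character(),
                            .default = readr::col_guess()),
    show_col_types = FALSE, progress = FALSE)
  structure(list(cases = cases, variants = variants), class = "pv_cohort")
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat("Cohort fixture: ", nrow(x$cases), " cases, ", nrow(x$variants),
      " candidate variants\n", sep = "")
  invisible(x)
}
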