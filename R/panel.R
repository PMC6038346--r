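#' Load and validate a panel definition
#'
#' A panel definition lists one row per gene with its evidence tier (1 = strong
#' or moderate disease association, 2 = weak or preliminary), reference
#' transcript, inheritance modes and associated phenotypes. Tier governs
#' reporting downstream: tier-1 genes are reported from class 3 (VUS) upwards,
#' tier-2 genes only for class 4-5 findings that match the patient phenotype.
#'
#' @param x A data frame with columns `symbol`, `tier`, `transcript`,
#'   `inheritance_modes` (comma-separated subset of AR, AD, XR, XD, MT,
#'   de-novo-AD), and optionally `chrom_class` (autosome/X/MT),
#'   `phenotype_class` (nonsyndromic/syndromic/both) and `phenotypes`;
#'   or the path of a TSV file with those columns.
#' @param version Optional version tag carried as an attribute (e.g. "v3").
#' @return A tibble of class `pv_panel`, one row per gene, with
#'   `inheritance_modes` split into a list column.
#' @examples
#' panel <- example_panel()
#' dplyr::count(panel, tier)
#' @export
load_panel <- function(x, version = NULL) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- as_tibble(x)
  required <- c("symbol", "tier", "transcript", "inheritance_modes")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("panel definition lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    out <- tibble(
      symbol = character(), tier = integer(), transcript = character(),
      chrom_class = character(), inheritance_modes = list(),
      phenotype_class = character(), phenotypes = character()
    )
    return(structure(out, class = c("pv_panel", class(out)), version = version))
  }
  dup <- x$symbol[duplicated(x$symbol)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene symbol(s) in panel: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!all(x$tier %in% c(1, 2))) {
    abort("panel tier must be 1 or 2")
  }
  modes <- x$inheritance_modes
  if (!is.list(modes)) {
    modes <- stringr::str_split(as.character(modes), stringr::fixed(","))
    modes <- purrr::map(modes, stringr::str_trim)
  }
  known_modes <- c("AR", "AD", "XR", "XD", "MT", "de-novo-AD")
  bad <- purrr::map_lgl(modes, ~ length(.x) == 0 || any(!.x %in% known_modes))
  if (any(bad)) {
    abort(paste0("empty or unknown inheritance modes for: ",
                 paste(x$symbol[bad], collapse = ", ")))
  }
  out <- tibble(
    symbol = as.character(x$symbol),
    tier = as.integer(x$tier),
    transcript = as.character(x$transcript),
    chrom_class = if ("chrom_class" %in% names(x)) as.character(x$chrom_class)
                  else "autosome",
    inheritance_modes = modes,
    phenotype_class = if ("phenotype_class" %in% names(x))
                        as.character(x$phenotype_class) else "nonsyndromic",
    phenotypes = if ("phenotypes" %in% names(x)) as.character(x$phenotypes)
                 else NA_character_
  )
  if (!all(out$chrom_class %in% c("autosome", "X", "MT"))) {
    abort("chrom_class must be one of autosome, X, MT")
  }
  structure(out, class = c("pv_panel", class(out)), version = version)
}

#' The shipped clinical panel definition (v3)
#'
#' Returns the 199-gene hearing-loss panel fixture (154 tier-1, 45 tier-2)
#' shipped with the package. Inheritance modes and phenotype classes are
#' curated for the genes that appear in the packaged case series; the
#' remaining genes carry a synthetic default annotation (AR and nonsyndromic,
#' XR for X-chromosomal genes, MT for mitochondrial loci).
#'
#' @return A `pv_panel` tibble, see [load_panel()].
#' @export
example_panel <- function() {
  load_panel(system.file("extdata", "panel_v3.tsv", package = "panelvar"),
             version = "v3")
}

#' Per-gene callability at depth thresholds
#'
#' Callability at threshold `t` (written DPt, e.g. DP20) is the fraction of a
#' gene's target bases covered by at least `t` reads. It is monotonically
#' non-increasing in `t` and is the quality currency of the panel: regions
#' below 100% DP20 callability feed the low-coverage report and the
#' conflictive-region scan.
#'
#' @param depth A data frame of per-base depths with columns `chrom`, `pos`
#'   (1-based), `depth` and optionally `sample` (a single implicit sample is
#'   assumed when absent).
#' @param targets Target regions: a data frame with columns `chrom`, `start`,
#'   `end` (0-based half-open), `gene` and optionally `label`.
#' @param thresholds Integer depth thresholds, default `c(10, 20, 50, 100)`.
#' @param panel Optional `pv_panel`; genes present in the panel but absent
#'   from `targets` are dropped from the result with a warning.
#' @return A tibble with columns `sample`, `gene`, `threshold`, `n_bases`,
#'   `callability`.
#' @export
compute_callability <- function(depth, targets, thresholds = c(10L, 20L, 50L, 100L),
                                panel = NULL) {
  depth <- as_tibble(depth)
  targets <- as_tibble(targets)
  if (!"sample" %in% names(depth)) depth$sample <- "sample"
  base_tbl <- expand_target_bases(targets)
  samples <- unique(depth$sample)
  per_sample <- purrr::map(samples, function(s) {
    d <- depth[depth$sample == s, c("chrom", "pos", "depth")]
    joined <- left_join(base_tbl, d, by = c("chrom", "pos"))
    if (anyNA(joined$depth)) {
      miss <- joined[is.na(joined$depth), ][1, ]
      abort(paste0("no depth value for target base ", miss$chrom, ":", miss$pos,
                   " (", miss$gene, "/", miss$label, ") in sample ", s))
    }
    purrr::map(thresholds, function(t) {
      joined %>%
        group_by(.data$gene) %>%
        summarise(n_bases = n(),
                  callability = mean(.data$depth >= t), .groups = "drop") %>%
        mutate(sample = s, threshold = as.integer(t))
    }) %>% bind_rows()
  }) %>% bind_rows()
  out <- per_sample %>% select("sample", "gene", "threshold", "n_bases", "callability")
  if (!is.null(panel)) {
    untargeted <- setdiff(panel$symbol, targets$gene)
    if (length(untargeted) > 0) {
      warn(paste0("panel gene(s) without target regions excluded from ",
                  "callability table: ", paste(untargeted, collapse = ", ")))
    }
  }
  out
}

# one row per (chrom, pos, gene, label) target base; 0-based half-open targets
# expand to 1-based positions start+1 .. end
expand_target_bases <- function(targets) {
  if (!"label" %in% names(targets)) targets$label <- NA_character_
  if (any(targets$start >= targets$end)) {
    abort("target regions must satisfy start < end (0-based half-open)")
  }
  purrr::pmap(
    list(targets$chrom, targets$start, targets$end, targets$gene, targets$label),
    function(chrom, start, end, gene, label) {
      tibble(chrom = chrom, pos = target_positions(start, end),
             gene = gene, label = label)
    }
  ) %>% bind_rows()
}

#' Positions below the DP20 reporting floor
#'
#' Lists, per sample and target region, the exact positions whose read depth
#' falls below the threshold (default 20). These positions are appended to the
#' individual patient report so that a negative finding can be read against
#' the regions where the assay had no power to call.
#'
#' @inheritParams compute_callability
#' @param dp Depth threshold, default 20.
#' @return A tibble with columns `sample`, `gene`, `label`, `chrom`, `n_low`
#'   and a `positions` list column of the sub-threshold positions; zero rows
#'   when every target base reaches the threshold.
#' @export
low_coverage_report <- function(depth, targets, dp = 20L) {
  depth <- as_tibble(depth)
  if (!"sample" %in% names(depth)) depth$sample <- "sample"
  base_tbl <- expand_target_bases(targets)
  samples <- unique(depth$sample)
  purrr::map(samples, function(s) {
    d <- depth[depth$sample == s, c("chrom", "pos", "depth")]
    joined <- left_join(base_tbl, d, by = c("chrom", "pos"))
    if (anyNA(joined$depth)) {
      miss <- joined[is.na(joined$depth), ][1, ]
      abort(paste0("no depth value for target base ", miss$chrom, ":", miss$pos,
                   " in sample ", s))
    }
    joined %>%
      filter(.data$depth < dp) %>%
      group_by(.data$gene, .data$label, .data$chrom) %>%
      summarise(n_low = n(), positions = list(sort(.data$pos)), .groups = "drop") %>%
      mutate(sample = s)
  }) %>%
    bind_rows() %>%
    select("sample", "gene", "label", "chrom", "n_low", "positions")
}
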