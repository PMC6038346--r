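acmg_codes <- function() {
  c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

acmg_default_strength <- function(code) {
  dplyr::case_when(
    code == "PVS1" ~ "very_strong",
    stringr::str_starts(code, "PS") ~ "strong",
    stringr::str_starts(code, "PM") ~ "moderate",
    stringr::str_starts(code, "PP") ~ "supporting",
    code == "BA1" ~ "stand_alone",
    stringr::str_starts(code, "BS") ~ "strong",
    stringr::str_starts(code, "BP") ~ "supporting"
  )
}

acmg_side <- function(code) {
  if_else(stringr::str_starts(code, "B"), "benign", "pathogenic")
}

wrap_strength <- c(PVS = "very_strong", PS = "strong", PM = "moderate",
                   PP = "supporting", BA = "stand_alone", BS = "strong",
                   BP = "supporting")

#' Parse ACMG criteria tokens, including strength modifiers
#'
#' Tokens follow the grammar `code` or `STRENGTH(code)`: a bare code (e.g.
#' `PM2`) applies at its default strength, while a wrapped form applies the
#' inner code at the wrapping strength — `PS(PM3)` is the in-trans
#' allelic-data criterion PM3 upgraded to strong, `PP(PM2)` is the rarity
#' criterion PM2 downgraded to supporting. Nesting is rejected, as are
#' wraps that cross the pathogenic/benign divide.
#'
#' @param tokens A character vector of tokens, or a single comma/semicolon
#'   separated string.
#' @return A tibble with columns `code`, `applied_strength`, `side`,
#'   `modified`.
#' @examples
#' parse_criteria("PVS1, PS(PM3), PP3")
#' @export
parse_criteria <- function(tokens) {
  if (length(tokens) == 1L && stringr::str_detect(tokens, "[,;]")) {
    tokens <- stringr::str_split(tokens, "[,;]")[[1]]
  }
  tokens <- stringr::str_trim(tokens)
  tokens <- tokens[!is.na(tokens) & tokens != ""]
  if (length(tokens) == 0) {
    return(tibble(code = character(), applied_strength = character(),
                  side = character(), modified = logical()))
  }
  parse_one <- function(tok) {
    if (tok %in% acmg_codes()) {
      return(tibble(code = tok, applied_strength = acmg_default_strength(tok),
                    side = acmg_side(tok), modified = FALSE))
    }
    m <- stringr::str_match(tok, "^(PVS|PS|PM|PP|BA|BS|BP)\\(([A-Z0-9]+)\\)$")
    if (is.na(m[1, 1]) || !m[1, 3] %in% acmg_codes()) {
      abort(paste0("cannot parse ACMG criterion token: '", tok, "'"))
    }
    wrap <- m[1, 2]; code <- m[1, 3]
    if (acmg_side(code) != acmg_side(wrap)) {
      abort(paste0("strength modifier crosses pathogenic/benign sides: '",
                   tok, "'"))
    }
    tibble(code = code, applied_strength = unname(wrap_strength[wrap]),
           side = acmg_side(code), modified = TRUE)
  }
  purrr::map(tokens, parse_one) %>% bind_rows()
}

#' Combine ACMG criteria into a five-class pathogenicity call
#'
#' Implements the ACMG/AMP combining rules as a total, deterministic function
#' of the applied-strength multiset. Pathogenic requires a very-strong
#' criterion backed by strong/moderate/supporting evidence, two strongs, or
#' one strong with sufficient moderate/supporting support; likely pathogenic
#' the familiar weaker combinations; benign requires stand-alone BA1 or two
#' strong benign criteria, likely benign one strong benign plus one
#' supporting or two supporting. A second very-strong criterion counts as
#' strong. When both a pathogenic and a benign rule fire the evidence is
#' contradictory and the variant is a VUS, as it is when no rule fires.
#'
#' @param criteria A [parse_criteria()] tibble, or a character vector /
#'   comma-separated string of tokens.
#' @return An object of class `pv_acmg`: a list with `class` (integer 1-5),
#'   `label`, `fired_rule`, `criteria` and `override` (NULL unless
#'   [apply_override()] was used).
#' @examples
#' acmg_classify("PVS1, PM2, PM3")$label
#' acmg_classify("PM2, PP3")$label
#' @export
acmg_classify <- function(criteria) {
  if (!is.data.frame(criteria)) criteria <- parse_criteria(criteria)
  path <- criteria[criteria$side == "pathogenic", ]
  ben <- criteria[criteria$side == "benign", ]
  nvs <- sum(path$applied_strength == "very_strong")
  ns <- sum(path$applied_strength == "strong") + max(nvs - 1L, 0L)
  nm <- sum(path$applied_strength == "moderate")
  np <- sum(path$applied_strength == "supporting")
  ba <- sum(ben$applied_strength == "stand_alone")
  nbs <- sum(ben$applied_strength == "strong")
  nbp <- sum(ben$applied_strength == "supporting")
  vs <- nvs >= 1

  path_rule <- if (vs && ns >= 1) "P:VS+S"
    else if (vs && nm >= 2) "P:VS+2M"
    else if (vs && nm >= 1 && np >= 1) "P:VS+M+P"
    else if (vs && np >= 2) "P:VS+2P"
    else if (ns >= 2) "P:2S"
    else if (ns == 1 && nm >= 3) "P:S+3M"
    else if (ns == 1 && nm == 2 && np >= 2) "P:S+2M+2P"
    else if (ns == 1 && nm == 1 && np >= 4) "P:S+M+4P"
    else if (vs && nm >= 1) "LP:VS+M"
    else if (ns == 1 && nm >= 1) "LP:S+M"
    else if (ns == 1 && np >= 2) "LP:S+2P"
    else if (nm >= 3) "LP:3M"
    else if (nm == 2 && np >= 2) "LP:2M+2P"
    else if (nm == 1 && np >= 4) "LP:M+4P"
    else NA_character_
  ben_rule <- if (ba >= 1) "B:BA1"
    else if (nbs >= 2) "B:2BS"
    else if (nbs == 1 && nbp >= 1) "LB:BS+BP"
    else if (nbp >= 2) "LB:2BP"
    else NA_character_

  if (!is.na(path_rule) && !is.na(ben_rule)) {
    cls <- 3L; rule <- "conflict"
  } else if (!is.na(path_rule)) {
    cls <- if (stringr::str_starts(path_rule, "P:")) 5L else 4L
    rule <- path_rule
  } else if (!is.na(ben_rule)) {
    cls <- if (stringr::str_starts(ben_rule, "B:")) 1L else 2L
    rule <- ben_rule
  } else {
    cls <- 3L; rule <- "none"
  }
  structure(list(class = cls, label = acmg_class_label(cls),
                 fired_rule = rule, criteria = criteria, override = NULL),
            class = "pv_acmg")
}

acmg_class_label <- function(class) {
  c("benign", "likely_benign", "VUS", "likely_pathogenic",
    "pathogenic")[class]
}

#' Manually override an ACMG classification
#'
#' Expert review can override the rule-derived class, but never silently:
#' the original class, the override and its justification are all retained.
#'
#' @param result A `pv_acmg` object.
#' @param class The overriding class (integer 1-5 or a class label).
#' @param justification Free-text justification; required.
#' @return The updated `pv_acmg` object.
#' @export
apply_override <- function(result, class, justification) {
  stopifnot(inherits(result, "pv_acmg"))
  if (missing(justification) || !nzchar(justification)) {
    abort("an override requires a justification")
  }
  if (is.character(class)) {
    class <- match(class, c("benign", "likely_benign", "VUS",
                            "likely_pathogenic", "pathogenic"))
  }
  if (is.na(class) || !class %in% 1:5) abort("override class must be 1-5")
  result$override <- list(original_class = result$class,
                          original_label = result$label,
                          justification = justification)
  result$class <- as.integer(class)
  result$label <- acmg_class_label(result$class)
  result
}

#' Classify a table of variants from their criteria strings
#'
#' Vectorised convenience over [acmg_classify()]: parses each row's criteria
#' string, applies the combining rules, then applies any per-row override
#' (recording that it happened). Rows whose rule-derived class differs from
#' a supplied `printed_class` can thereby be audited rather than silently
#' absorbed.
#'
#' @param variants A data frame with a `criteria` column; an optional
#'   `override_class` column ("" or NA for no override) forces the final
#'   class.
#' @return `variants` with columns `acmg_class`, `acmg_label`, `fired_rule`,
#'   `overridden` and `rule_class` (the pre-override class).
#' @export
classify_variants <- function(variants) {
  variants <- as_tibble(variants)
  res <- purrr::map(variants$criteria, acmg_classify)
  variants$rule_class <- purrr::map_int(res, "class")
  has_override <- if ("override_class" %in% names(variants)) {
    !is.na(variants$override_class) & nzchar(variants$override_class)
  } else rep(FALSE, nrow(variants))
  final <- purrr::pmap(
    list(res, has_override,
         if ("override_class" %in% names(variants)) variants$override_class
         else rep(NA_character_, nrow(variants))),
    function(r, ov, cls) {
      if (ov) apply_override(r, cls, "expert review override") else r
    })
  variants$acmg_class <- purrr::map_int(final, "class")
  variants$acmg_label <- purrr::map_chr(final, "label")
  variants$fired_rule <- purrr::map_chr(final, "fired_rule")
  variants$overridden <- has_override
  variants
}

#' @export
print.pv_acmg <- function(x, ...) {
  cat("ACMG classification: class ", x$class, " (", x$label, "), rule ",
      x$fired_rule, "\n", sep = "")
  if (!is.null(x$override)) {
    cat("  override from class ", x$override$original_class, ": ",
        x$override$justification, "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pv_acmg <- function(x, ...) {
  x$criteria
}

#' @exportS3Method generics::glance
glance.pv_acmg <- function(x, ...) {
  tibble(class = x$class, label = x$label, fired_rule = x$fired_rule,
         n_criteria = nrow(x$criteria), overridden = !is.null(x$override))
}
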