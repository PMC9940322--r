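#' Normalize a diagnosis, procedure or CPT code
#'
#' Administrative extracts print codes inconsistently: ICD-9-CM codes carry
#' decimal points (`769.1`), CPT codes are sometimes printed with thousands
#' separators (`99,468`), and whitespace creeps in. All matching in this
#' package happens on a normalized form with dots, commas and whitespace
#' removed and letters upper-cased (ICD-9 E/V prefixes, wildcard `x`).
#'
#' @param raw character vector of raw code strings.
#' @param system code system, one of `"ICD9_DX"`, `"ICD9_PC"`, `"CPT"`.
#'   Recycled to the length of `raw`.
#' @param allow_wildcard allow a trailing run of `X` wildcard characters
#'   (used when normalizing code-set patterns, never claims codes).
#' @return character vector of normalized codes.
#' @examples
#' normalize_code("99,468", "CPT")
#' normalize_code("769.12", "ICD9_DX")
#' normalize_code("96.71", "ICD9_PC")
#' @export
normalize_code <- function(raw, system, allow_wildcard = FALSE) {
  stopifnot(is.character(raw) || all(is.na(raw)))
  system <- match_code_system(system, length(raw))
  out <- toupper(gsub("[.,[:space:]]", "", as.character(raw)))
  bad <- !is.na(out) & out == ""
  if (any(bad)) {
    stop("code empty after normalization at position ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  shape <- if (allow_wildcard) "^[0-9EV][0-9]*X*$" else "^[0-9EV][0-9]+$"
  malformed <- !is.na(out) & !grepl(shape, out)
  if (any(malformed)) {
    stop("malformed code value(s): ",
         paste(unique(out[malformed]), collapse = ", "), call. = FALSE)
  }
  cpt_bad <- !is.na(out) & system == "CPT" & !grepl("^[0-9]{5}$", out)
  if (any(cpt_bad)) {
    stop("CPT codes must normalize to exactly 5 digits; offending value(s): ",
         paste(unique(out[cpt_bad]), collapse = ", "), call. = FALSE)
  }
  out
}

match_code_system <- function(system, n) {
  system <- as.character(system)
  ok <- system %in% c("ICD9_DX", "ICD9_PC", "CPT")
  if (!all(ok)) {
    stop("unknown code system: ", paste(unique(system[!ok]), collapse = ", "),
         call. = FALSE)
  }
  rep_len(system, n)
}

#' Match normalized codes against code-set patterns
#'
#' ICD-9 patterns follow family semantics: a trailing run of `x` wildcards
#' (`769.xx`) or a bare stem (`96.7`) both match any more specific code
#' sharing that stem as a prefix. CPT patterns are exact five-digit matches.
#' A system mismatch yields `FALSE`, never an error, so one claim line can
#' be screened against every condition's set.
#'
#' @param code normalized code (vector).
#' @param pattern normalized pattern, possibly with trailing `X` wildcards
#'   (vector, recycled against `code`).
#' @param code_system,pattern_system code systems of `code` and `pattern`.
#' @return logical vector.
#' @examples
#' code_matches("76912", "769XX", "ICD9_DX", "ICD9_DX")
#' code_matches("9670", "967", "ICD9_PC", "ICD9_PC")
#' code_matches("76801", "769XX", "ICD9_DX", "ICD9_DX")
#' @export
code_matches <- function(code, pattern, code_system, pattern_system) {
  n <- max(length(code), length(pattern))
  code <- rep_len(code, n)
  pattern <- rep_len(pattern, n)
  code_system <- rep_len(as.character(code_system), n)
  pattern_system <- rep_len(as.character(pattern_system), n)
  stem <- sub("X+$", "", pattern)
  hit <- ifelse(pattern_system == "CPT",
                code == pattern,
                startsWith(code, stem))
  hit & code_system == pattern_system & !is.na(code) & !is.na(pattern)
}

#' Default condition code sets
#'
#' The packaged code sets used to ascertain the five neonatal critical
#' conditions from claims: NICU admission (CPT neonatal critical/intensive
#' care codes, including the pre-2009 99295-99300 series), respiratory
#' distress syndrome (ICD-9-CM 769 family), neonatal seizures (779.0x),
#' assisted ventilation (ICD-9-CM procedure 96.7x invasive and 93.90
#' non-invasive), and birth injury (767 birth-trauma family).
#'
#' @param path path to a condition-code CSV
#'   (columns `condition`, `system`, `pattern`, `description`); defaults to
#'   the packaged file.
#' @return tibble with normalized `pattern` column.
#' @export
default_condition_codes <- function(path = system.file("extdata",
                                                       "condition_codes.csv",
                                                       package = "neoconcord")) {
  codes <- readr::read_csv(path, col_types = readr::cols(
    condition = readr::col_character(),
    system = readr::col_character(),
    pattern = readr::col_character(),
    description = readr::col_character()
  ), progress = FALSE)
  codes$pattern <- normalize_code(codes$pattern, codes$system,
                                  allow_wildcard = TRUE)
  codes
}

#' Condition definitions for the five neonatal critical conditions
#'
#' Each definition bundles a code set with its ascertainment window (days
#' postpartum, day of birth = day 0, window end inclusive), an optional
#' birth-year restriction, and whether maternal claims are also searched.
#' NICU admission carries the 2004-2010 restriction because the
#' birth-certificate NICU checkbox only exists on the post-2003 form
#' revision; the other conditions carry none.
#'
#' @param codes code-set tibble as returned by [default_condition_codes()].
#' @param window_days length of the postnatal ascertainment window.
#' @param use_mother_records search the linked mother's claims as well as
#'   the infant's. Either a single logical applied to all conditions or a
#'   named logical vector per condition.
#' @return named list of `condition_definition` objects.
#' @export
condition_definitions <- function(codes = default_condition_codes(),
                                  window_days = 30,
                                  use_mother_records = TRUE) {
  stopifnot(window_days > 0)
  nms <- c("NICU", "RDS", "SEIZURE", "AV", "BIRTH_INJURY")
  if (length(use_mother_records) == 1L && is.null(names(use_mother_records))) {
    use_mother_records <- stats::setNames(rep(use_mother_records, 5L), nms)
  }
  defs <- lapply(nms, function(nm) {
    structure(list(
      name = nm,
      codes = codes[codes$condition == nm, c("system", "pattern")],
      window_days = window_days,
      year_restriction = if (nm == "NICU") c(2004L, 2010L) else NULL,
      use_mother_records = isTRUE(unname(use_mother_records[nm]))
    ), class = "condition_definition")
  })
  stats::setNames(defs, nms)
}

#' @export
print.condition_definition <- function(x, ...) {
  yr <- if (is.null(x$year_restriction)) "none" else
    paste(x$year_restriction, collapse = "-")
  cat(sprintf(
    "<condition_definition> %s: %d code pattern(s), window 0-%d days, year restriction %s, mother records %s\n",
    x$name, nrow(x$codes), x$window_days, yr, x$use_mother_records))
  invisible(x)
}
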