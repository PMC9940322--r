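#' Ascertain condition status from claims for linked mother-infant pairs
#'
#' A pair is a case when at least one inpatient or outpatient claim, on the
#' infant's record or (when the definition says so) the linked mother's
#' record, in any diagnosis position, carries a code matching the
#' condition's code set with a service date inside the postnatal window
#' `[birth_date, birth_date + window_days]` (day of birth = day 0, both
#' ends inclusive). Delivery-type claims are never eligible encounters.
#' The result is invariant to claim row order, and adding claims can only
#' turn a noncase into a case.
#'
#' @param claims claims tibble with columns `person_id`, `record_type`
#'   (`inpatient`/`outpatient`/`delivery`), `service_date` (`Date`),
#'   `code_system`, `code` (normalized), `dx_position`.
#' @param pairs linked-pair tibble with columns `pair_id`, `infant_id`,
#'   `mother_id`, `birth_date`.
#' @param condition a `condition_definition`.
#' @return tibble with `pair_id` and `status`
#'   (`case`/`noncase`/`excluded_year`), one row per input pair.
#' @export
ascertain_max_cases <- function(claims, pairs, condition) {
  stopifnot(inherits(condition, "condition_definition"))
  require_columns(pairs, c("pair_id", "infant_id", "mother_id", "birth_date"),
                  "pairs")
  require_columns(claims, c("person_id", "record_type", "service_date",
                            "code_system", "code"), "claims")

  eligible <- claims[claims$record_type %in% c("inpatient", "outpatient"), ]
  hit <- rep(FALSE, nrow(eligible))
  for (i in seq_len(nrow(condition$codes))) {
    hit <- hit | code_matches(eligible$code, condition$codes$pattern[i],
                              eligible$code_system, condition$codes$system[i])
  }
  eligible <- eligible[hit, c("person_id", "service_date")]

  key <- tibble::tibble(
    pair_id = rep(pairs$pair_id, if (condition$use_mother_records) 2L else 1L),
    person_id = if (condition$use_mother_records)
      c(pairs$infant_id, pairs$mother_id) else pairs$infant_id,
    birth_date = rep(pairs$birth_date,
                     if (condition$use_mother_records) 2L else 1L)
  )
  matched <- dplyr::inner_join(key, eligible, by = "person_id",
                               relationship = "many-to-many")
  offset <- as.integer(matched$service_date - matched$birth_date)
  case_ids <- unique(matched$pair_id[offset >= 0L &
                                       offset <= condition$window_days])

  status <- ifelse(pairs$pair_id %in% case_ids, "case", "noncase")
  yr <- as.integer(format(pairs$birth_date, "%Y"))
  status[outside_year_restriction(yr, condition)] <- "excluded_year"
  tibble::tibble(pair_id = pairs$pair_id, status = status)
}

#' Ascertain condition status from birth-certificate checkboxes
#'
#' The certificate forces an explicit determination, so a checked box is a
#' case, an unchecked box a noncase, and a missing determination is
#' excluded from agreement tables rather than treated as absence (unlike
#' claims, where no code means no condition).
#'
#' @param bc birth-certificate tibble with one 0/1/NA column per condition
#'   (lower-case condition names) plus `cert_id` and `birth_date`.
#' @param pairs linked pairs carrying `pair_id` and `cert_id`.
#' @param condition a `condition_definition`.
#' @return tibble with `pair_id` and `status`
#'   (`case`/`noncase`/`excluded_missing`/`excluded_year`).
#' @export
ascertain_bc_cases <- function(bc, pairs, condition) {
  stopifnot(inherits(condition, "condition_definition"))
  col <- tolower(condition$name)
  if (!col %in% names(bc)) {
    stop("birth-certificate table has no determination column for condition ",
         condition$name, call. = FALSE)
  }
  require_columns(pairs, c("pair_id", "cert_id"), "pairs")
  rec <- dplyr::inner_join(pairs[, c("pair_id", "cert_id")],
                           bc[, c("cert_id", "birth_date", col)],
                           by = "cert_id")
  if (nrow(rec) != nrow(pairs)) {
    missing_ids <- setdiff(pairs$cert_id, bc$cert_id)
    stop("pairs reference certificates absent from the BC table: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  flag <- rec[[col]]
  status <- dplyr::case_when(
    is.na(flag) ~ "excluded_missing",
    flag == 1L ~ "case",
    TRUE ~ "noncase"
  )
  yr <- as.integer(format(rec$birth_date, "%Y"))
  status[outside_year_restriction(yr, condition)] <- "excluded_year"
  tibble::tibble(pair_id = rec$pair_id, status = status)
}

outside_year_restriction <- function(year, condition) {
  if (is.null(condition$year_restriction)) return(rep(FALSE, length(year)))
  year < condition$year_restriction[1] | year > condition$year_restriction[2]
}

#' Restrict linked pairs to the continuously enrolled cohort
#'
#' Keeps pairs in which both mother and infant hold Medicaid coverage over
#' the whole postnatal window `[birth_date, birth_date + window_days]`
#' (coverage through day `window_days` inclusive, matching the
#' ascertainment window). Abutting or overlapping enrollment spans are
#' merged before the check, so a person whose coverage is split across
#' contiguous spans still qualifies. Pairs with no enrollment record for
#' either member are excluded and logged.
#'
#' When a `condition` carrying a birth-year restriction is supplied (NICU
#' admission, restricted to 2004-2010 because the certificate checkbox only
#' exists from the 2004 form on), pairs born outside the restriction are
#' excluded as well.
#'
#' @param pairs linked-pair tibble (`pair_id`, `infant_id`, `mother_id`,
#'   `birth_date`).
#' @param enrollment spans tibble (`person_id`, `start_date`, `end_date`).
#' @param window_days required postpartum coverage, in days.
#' @param condition optional `condition_definition` whose
#'   `year_restriction`, if any, is applied.
#' @return list with `retained` (pair tibble) and `excluded` (pair tibble
#'   plus a `reason` column: `no_enrollment`, `incomplete_coverage` or
#'   `outside_year_restriction`).
#' @export
apply_cohort_filters <- function(pairs, enrollment, window_days = 30,
                                 condition = NULL) {
  require_columns(enrollment, c("person_id", "start_date", "end_date"),
                  "enrollment")
  spans <- merge_spans(enrollment)

  covered <- function(person_id, birth_date) {
    w_end <- birth_date + window_days
    x <- tibble::tibble(person_id = person_id, birth_date = birth_date,
                        w_end = w_end, .row = seq_along(person_id))
    j <- dplyr::inner_join(x, spans, by = "person_id",
                           relationship = "many-to-many")
    ok_rows <- j$.row[j$start_date <= j$birth_date & j$end_date >= j$w_end]
    has_rec <- x$.row %in% j$.row
    list(ok = x$.row %in% ok_rows, has_record = has_rec)
  }
  inf <- covered(pairs$infant_id, pairs$birth_date)
  mom <- covered(pairs$mother_id, pairs$birth_date)

  bad_year <- if (is.null(condition)) rep(FALSE, nrow(pairs)) else
    outside_year_restriction(as.integer(format(pairs$birth_date, "%Y")),
                             condition)
  reason <- dplyr::case_when(
    !inf$has_record | !mom$has_record ~ "no_enrollment",
    !inf$ok | !mom$ok ~ "incomplete_coverage",
    bad_year ~ "outside_year_restriction",
    TRUE ~ NA_character_
  )
  list(
    retained = pairs[is.na(reason), , drop = FALSE],
    excluded = dplyr::bind_cols(pairs[!is.na(reason), , drop = FALSE],
                                tibble::tibble(reason = reason[!is.na(reason)]))
  )
}

# Merge overlapping or abutting (end + 1 day = next start) spans per person.
merge_spans <- function(enrollment) {
  sp <- dplyr::arrange(enrollment, .data$person_id, .data$start_date)
  sp <- dplyr::group_by(sp, .data$person_id)
  sp <- dplyr::mutate(
    sp,
    new_block = cumsum(dplyr::lag(
      .data$start_date > cummax_date(.data$end_date) + 1L,
      default = TRUE))
  )
  sp <- dplyr::group_by(sp, .data$person_id, .data$new_block)
  out <- dplyr::summarise(sp,
                          start_date = min(.data$start_date),
                          end_date = max(.data$end_date), .groups = "drop")
  out[, c("person_id", "start_date", "end_date")]
}

cummax_date <- function(x) as.Date(cummax(as.integer(x)), origin = "1970-01-01")

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}
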