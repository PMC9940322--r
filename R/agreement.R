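#' Construct a 2x2 dual-source concordance table
#'
#' Cell `a` counts pairs flagged by both sources, `b` claims-only (MAX),
#' `c` certificate-only (BC), `d` neither. Excluded pairs (missing BC
#' determination, or outside a condition's birth-year restriction) sit in
#' none of the four cells and are tallied separately.
#'
#' @param a,b,c,d nonnegative cell counts.
#' @param condition,stratum optional labels (condition name, state).
#' @param n_excluded_missing pairs excluded for a missing BC determination.
#' @param n_excluded_year pairs excluded by a birth-year restriction.
#' @return an object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, condition = NA_character_,
                       stratum = NA_character_, n_excluded_missing = 0L,
                       n_excluded_year = 0L) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("cell counts must be nonnegative", call. = FALSE)
  }
  if (sum(cells) <= 0) stop("table total N must be positive", call. = FALSE)
  structure(list(condition = condition, stratum = stratum,
                 a = a, b = b, c = c, d = d,
                 n_excluded_missing = n_excluded_missing,
                 n_excluded_year = n_excluded_year),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<two_by_two> %s / %s\n", x$condition, x$stratum))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(BC = c("case", "noncase"),
                              MAX = c("case", "noncase")))
  print(m)
  cat(sprintf("N = %d, excluded: %d missing BC, %d outside years\n",
              x$a + x$b + x$c + x$d, x$n_excluded_missing, x$n_excluded_year))
  invisible(x)
}

#' Cross-classify per-source case flags into a 2x2 table
#'
#' Joins the claims-side and certificate-side flag streams on `pair_id`,
#' removes pairs excluded on either side (missing BC determination or
#' outside the year restriction) into the exclusion tallies, and counts
#' the remaining pairs into the four cells.
#'
#' @param max_flags,bc_flags tibbles with `pair_id` and `status` as
#'   returned by [ascertain_max_cases()] and [ascertain_bc_cases()]; the
#'   two must cover exactly the same pairs.
#' @param condition,stratum labels stored on the table.
#' @return a [two_by_two()] object.
#' @export
build_two_by_two <- function(max_flags, bc_flags, condition = NA_character_,
                             stratum = NA_character_) {
  require_columns(max_flags, c("pair_id", "status"), "max_flags")
  require_columns(bc_flags, c("pair_id", "status"), "bc_flags")
  only <- c(setdiff(max_flags$pair_id, bc_flags$pair_id),
            setdiff(bc_flags$pair_id, max_flags$pair_id))
  if (length(only)) {
    stop("pair(s) present in only one flag stream: ",
         paste(utils::head(only, 5L), collapse = ", "), call. = FALSE)
  }
  j <- dplyr::inner_join(max_flags, bc_flags, by = "pair_id",
                         suffix = c("_max", "_bc"))
  excl_year <- j$status_max == "excluded_year" | j$status_bc == "excluded_year"
  excl_miss <- !excl_year & j$status_bc == "excluded_missing"
  k <- j[!excl_year & !excl_miss, ]
  two_by_two(
    a = sum(k$status_max == "case" & k$status_bc == "case"),
    b = sum(k$status_max == "case" & k$status_bc == "noncase"),
    c = sum(k$status_max == "noncase" & k$status_bc == "case"),
    d = sum(k$status_max == "noncase" & k$status_bc == "noncase"),
    condition = condition, stratum = stratum,
    n_excluded_missing = sum(excl_miss),
    n_excluded_year = sum(excl_year)
  )
}

#' Cohen's kappa for a 2x2 concordance table
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po = (a + d) / N` and expected agreement under marginal
#' independence `pe = p_max * p_bc + (1 - p_max) * (1 - p_bc)`. For the
#' degenerate table with `pe = 1` (all mass in one cell) kappa is
#' undefined and returned as `NA`.
#'
#' @param x a `two_by_two`.
#' @return list with `po`, `pe`, `kappa`.
#' @examples
#' cohen_kappa(two_by_two(a = 10, b = 0, c = 0, d = 90))$kappa  # 1
#' cohen_kappa(two_by_two(a = 1, b = 9, c = 9, d = 81))$kappa   # 0
#' @export
cohen_kappa <- function(x) {
  stopifnot(inherits(x, "two_by_two"))
  n <- x$a + x$b + x$c + x$d
  po <- (x$a + x$d) / n
  pe <- ((x$a + x$b) / n) * ((x$a + x$c) / n) +
    ((x$c + x$d) / n) * ((x$b + x$d) / n)
  kappa <- if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  list(po = po, pe = pe, kappa = kappa)
}

#' Cross-source sensitivity
#'
#' Treats one source as if it were a gold standard and asks what fraction
#' of its cases the other source captured: with the certificate as
#' reference, `a / (a + c)` is the sensitivity of claims; with claims as
#' reference, `a / (a + b)` is the sensitivity of the certificate. Neither
#' source is actually a gold standard; the statistic quantifies mutual
#' capture only.
#'
#' @param x a `two_by_two`.
#' @param reference which source plays the gold standard: `"BC"` returns
#'   the claims-side (MAX) sensitivity, `"MAX"` the certificate-side.
#' @return a proportion, or `NA` when the reference has no cases.
#' @export
cross_sensitivity <- function(x, reference = c("BC", "MAX")) {
  stopifnot(inherits(x, "two_by_two"))
  reference <- match.arg(reference)
  denom <- if (reference == "BC") x$a + x$c else x$a + x$b
  if (denom <= 0) return(NA_real_)
  x$a / denom
}

#' Cases per 100 mother-infant pairs
#'
#' @param case_count number of ascertained cases.
#' @param denominator number of pairs at risk.
#' @return prevalence per 100 pairs.
#' @export
prevalence_per_100 <- function(case_count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  100 * case_count / denominator
}

#' Categorize kappa on the conventional agreement bands
#'
#' Bands on the percent scale (applied to kappa rounded half-up to one
#' decimal): poor (<= 20), fair (20-40], moderate (40-60],
#' substantial (60-80], high (> 80). The bands are contiguous half-open
#' intervals so every kappa maps to exactly one category.
#'
#' @param kappa kappa value(s) on the raw \[-1, 1\] scale.
#' @return character vector of category labels.
#' @examples
#' kappa_category(c(0.557, 0.628, 0.157))
#' @export
kappa_category <- function(kappa) {
  pct <- round_half_up(100 * kappa, 1)
  out <- dplyr::case_when(
    is.na(pct) ~ NA_character_,
    pct <= 20 ~ "poor",
    pct <= 40 ~ "fair",
    pct <= 60 ~ "moderate",
    pct <= 80 ~ "substantial",
    TRUE ~ "high"
  )
  out
}

#' Decompose ascertained cases by capturing source
#'
#' Splits the union of cases into claims-only (`b`), certificate-only
#' (`c`) and both (`a`), and reports the discordant share
#' `100 * (b + c) / (a + b + c)` — the percentage of all ascertained cases
#' that one source missed.
#'
#' @param x a `two_by_two`.
#' @return list with `only_max`, `only_bc`, `both`,
#'   `pct_discordant_of_union` (`NA` when no cases at all).
#' @export
discordance_decomposition <- function(x) {
  stopifnot(inherits(x, "two_by_two"))
  union <- x$a + x$b + x$c
  list(only_max = x$b, only_bc = x$c, both = x$a,
       pct_discordant_of_union =
         if (union <= 0) NA_real_ else 100 * (x$b + x$c) / union)
}

#' Recover an analysis denominator from a printed prevalence
#'
#' Inverts `prevalence = 100 * cases / N` to recover the denominator a
#' printed per-100 prevalence implies, together with the interval of
#' integers consistent with the prevalence's printed rounding (half-up on
#' the last printed digit).
#'
#' @param case_count case count the prevalence was computed from.
#' @param printed_prevalence_per100 the printed per-100 rate.
#' @param digits decimal places the prevalence was printed to.
#' @return list with `n_hat` (point reconstruction, rounded) and
#'   `feasible` (length-2 integer vector: every `N` in this closed range
#'   reproduces the printed value).
#' @examples
#' reconstruct_denominator(20548, 7.40)
#' @export
reconstruct_denominator <- function(case_count, printed_prevalence_per100,
                                    digits = 2) {
  if (printed_prevalence_per100 <= 0) {
    stop("printed prevalence must be positive", call. = FALSE)
  }
  half <- 0.5 * 10^(-digits)
  n_hat <- round(100 * case_count / printed_prevalence_per100)
  lo <- floor(100 * case_count / (printed_prevalence_per100 + half)) + 1
  hi <- floor(100 * case_count / (printed_prevalence_per100 - half))
  list(n_hat = as.integer(n_hat), feasible = as.integer(c(lo, hi)))
}

#' Round half away from zero on the final displayed digit
#'
#' Report rounding: `round_half_up(0.5, 0)` is 1 (base R's `round()`
#' rounds half to even). Used for every displayed statistic so table
#' output is reproducible digit-for-digit.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Full agreement summary for one condition and stratum
#'
#' One row with everything the concordance analysis reports for a table:
#' cell counts, observed/expected agreement, kappa (raw, percent and
#' category), both cross-sensitivities, both per-100 prevalences and the
#' discordant share of the case union. Raw unrounded values are returned;
#' rounding to the display convention is the caller's choice via
#' [round_half_up()].
#'
#' @param x a `two_by_two`.
#' @return one-row tibble.
#' @export
agreement_summary <- function(x) {
  stopifnot(inherits(x, "two_by_two"))
  n <- x$a + x$b + x$c + x$d
  kk <- cohen_kappa(x)
  dec <- discordance_decomposition(x)
  tibble::tibble(
    condition = x$condition, stratum = x$stratum,
    a = x$a, b = x$b, c = x$c, d = x$d, n = n,
    n_excluded_missing = x$n_excluded_missing,
    n_excluded_year = x$n_excluded_year,
    po = kk$po, pe = kk$pe, kappa = kk$kappa,
    kappa_pct = 100 * kk$kappa,
    kappa_category = kappa_category(kk$kappa),
    sens_max = cross_sensitivity(x, "BC"),
    sens_bc = cross_sensitivity(x, "MAX"),
    prev_max_per100 = prevalence_per_100(x$a + x$b, n),
    prev_bc_per100 = prevalence_per_100(x$a + x$c, n),
    pct_discordant_of_union = dec$pct_discordant_of_union
  )
}
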