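#' Normalize Social Security Numbers
#'
#' Strips non-digit characters; any value that is not exactly nine digits
#' afterwards is treated as absent (`NA`). Deterministic linkage matches on
#' this normalized form only.
#'
#' @param x character vector of raw SSN values.
#' @return character vector of nine-digit strings or `NA`.
#' @export
normalize_ssn <- function(x) {
  out <- gsub("[^0-9]", "", as.character(x))
  out[is.na(out) | nchar(out) != 9L] <- NA_character_
  out
}

#' Step 1: link mother-infant dyads by exact SSN match on both members
#'
#' A certificate carrying both the mother's and the infant's SSN is linked
#' when each SSN matches exactly one Medicaid person of the right role and
#' the certificate's SSN combination is unique. Any one-to-many match —
#' an SSN shared by several enrollees, duplicate certificates with the same
#' SSN pair, or an infant SSN appearing on several certificates — drops
#' every candidate involved and counts it as ambiguous: deterministic
#' linkage never guesses.
#'
#' @param max_people Medicaid person tibble (`person_id`, `role`
#'   (`mother`/`infant`), `ssn`, `case_id`, `birth_date`), SSNs normalized.
#' @param bc birth-certificate tibble (`cert_id`, `infant_ssn`,
#'   `mother_ssn`, `birth_date`, ...).
#' @return list with `pairs` (tibble `mother_id`, `infant_id`, `cert_id`,
#'   `linkage_path = "both_ssn_exact"`, `birth_date`), `n_ambiguous`, and
#'   `unlinked_certs` (cert ids not linked in this step).
#' @export
link_exact_ssn <- function(max_people, bc) {
  require_columns(max_people, c("person_id", "role", "ssn"), "max_people")
  require_columns(bc, c("cert_id", "infant_ssn", "mother_ssn", "birth_date"),
                  "bc")
  cand <- bc[!is.na(bc$infant_ssn) & !is.na(bc$mother_ssn), ]

  mothers <- max_people[max_people$role == "mother" & !is.na(max_people$ssn), ]
  infants <- max_people[max_people$role == "infant" & !is.na(max_people$ssn), ]
  n_mother_match <- tabulate_matches(cand$mother_ssn, mothers$ssn)
  n_infant_match <- tabulate_matches(cand$infant_ssn, infants$ssn)

  # duplicate certificates: same SSN combination, or one infant SSN on
  # several certificates (an infant can have at most one certificate)
  combo <- paste(cand$mother_ssn, cand$infant_ssn)
  dup_combo <- combo %in% combo[duplicated(combo)]
  dup_infant <- cand$infant_ssn %in% cand$infant_ssn[duplicated(cand$infant_ssn)]

  matched <- n_mother_match == 1L & n_infant_match == 1L
  ok <- matched & !dup_combo & !dup_infant
  ambiguous <- (n_mother_match > 1L | n_infant_match > 1L |
                  (matched & (dup_combo | dup_infant)))

  linked <- cand[ok, ]
  pairs <- tibble::tibble(
    mother_id = mothers$person_id[match(linked$mother_ssn, mothers$ssn)],
    infant_id = infants$person_id[match(linked$infant_ssn, infants$ssn)],
    cert_id = linked$cert_id,
    linkage_path = "both_ssn_exact",
    birth_date = linked$birth_date
  )
  list(pairs = pairs,
       n_ambiguous = sum(ambiguous),
       unlinked_certs = setdiff(bc$cert_id, pairs$cert_id))
}

tabulate_matches <- function(keys, pool) {
  as.integer(table(factor(pool, levels = unique(keys)))[as.character(keys)])
}

#' Step 2a: pair mothers and infants inside the Medicaid extract
#'
#' Infants are paired to mothers sharing the same Medicaid family
#' identifier (case ID) whose delivery claim date matches the infant's
#' birth date within `date_tolerance_days` (default 0: exact). An infant
#' matching several mothers is dropped as ambiguous; several infants
#' matching one mother (twins) are all retained as separate dyads.
#'
#' @param max_people Medicaid person tibble (see [link_exact_ssn()]).
#' @param deliveries tibble of delivery claim dates
#'   (`person_id` = mother, `delivery_date`).
#' @param date_tolerance_days maximum absolute difference in days between
#'   infant birth date and a delivery claim date.
#' @return list with `pairs` (`mother_id`, `infant_id`, `birth_date`) and
#'   `n_ambiguous`.
#' @export
pair_within_max <- function(max_people, deliveries, date_tolerance_days = 0) {
  stopifnot(date_tolerance_days >= 0)
  require_columns(deliveries, c("person_id", "delivery_date"), "deliveries")
  infants <- max_people[max_people$role == "infant" &
                          !is.na(max_people$case_id) &
                          !is.na(max_people$birth_date),
                        c("person_id", "case_id", "birth_date")]
  names(infants)[1] <- "infant_id"
  mothers <- max_people[max_people$role == "mother" &
                          !is.na(max_people$case_id),
                        c("person_id", "case_id")]
  names(mothers)[1] <- "mother_id"

  cand <- dplyr::inner_join(infants, mothers, by = "case_id",
                            relationship = "many-to-many")
  cand <- dplyr::inner_join(cand, deliveries,
                            by = c(mother_id = "person_id"),
                            relationship = "many-to-many")
  cand <- cand[abs(as.integer(cand$birth_date - cand$delivery_date)) <=
                 date_tolerance_days, ]
  cand <- dplyr::distinct(cand, .data$infant_id, .data$mother_id,
                          .data$birth_date)

  n_mothers <- table(cand$infant_id)
  ambiguous_infants <- names(n_mothers)[n_mothers > 1L]
  pairs <- cand[!cand$infant_id %in% ambiguous_infants,
                c("mother_id", "infant_id", "birth_date")]
  list(pairs = tibble::as_tibble(pairs),
       n_ambiguous = length(ambiguous_infants))
}

#' Step 2b: link within-Medicaid pairs to certificates by available SSN
#'
#' Each pair is linked to the certificate matched by whichever SSN is
#' available (the mother's, the infant's, or both, in which case both must
#' agree on the same certificate). A pair whose available SSNs match no
#' certificate, or more than one, stays unlinked; two pairs resolving to
#' the same certificate are both dropped.
#'
#' @param pairs output of [pair_within_max()] (`mother_id`, `infant_id`,
#'   `birth_date`).
#' @param max_people Medicaid person tibble supplying each member's SSN.
#' @param bc birth-certificate tibble restricted to certificates still
#'   unlinked after step 1.
#' @return list with `pairs` (adds `cert_id`,
#'   `linkage_path = "case_id_then_ssn"`), `n_ambiguous`, `n_unlinked`.
#' @export
link_pairs_to_bc <- function(pairs, max_people, bc) {
  ssn_of <- stats::setNames(max_people$ssn, max_people$person_id)
  m_ssn <- unname(ssn_of[pairs$mother_id])
  i_ssn <- unname(ssn_of[pairs$infant_id])

  cert_for <- function(ssn, bc_ssn) {
    hits <- lapply(ssn, function(s) {
      if (is.na(s)) NULL else bc$cert_id[!is.na(bc_ssn) & bc_ssn == s]
    })
    hits
  }
  by_mother <- cert_for(m_ssn, bc$mother_ssn)
  by_infant <- cert_for(i_ssn, bc$infant_ssn)

  resolve <- function(m, i, has_m, has_i) {
    if (has_m && has_i) m <- intersect(m, i)
    else if (has_i) m <- i
    m
  }
  certs <- mapply(resolve, by_mother, by_infant,
                  !is.na(m_ssn), !is.na(i_ssn), SIMPLIFY = FALSE)
  n_cand <- lengths(certs)
  no_ssn <- is.na(m_ssn) & is.na(i_ssn)

  cert_id <- as.character(ifelse(
    n_cand == 1L,
    vapply(certs, function(x)
      if (length(x) == 1L) x else NA_character_, character(1)),
    NA_character_))
  # certificate collisions across pairs: drop all involved
  collided <- !is.na(cert_id) & cert_id %in% cert_id[duplicated(cert_id)]
  keep <- !is.na(cert_id) & !collided

  linked <- pairs[keep, ]
  linked$cert_id <- cert_id[keep]
  linked$linkage_path <- "case_id_then_ssn"
  linked <- linked[, c("mother_id", "infant_id", "cert_id", "linkage_path",
                       "birth_date")]
  list(pairs = tibble::as_tibble(linked),
       n_ambiguous = sum((n_cand > 1L & !no_ssn) | collided),
       n_unlinked = sum(no_ssn | (n_cand == 0L & !no_ssn)))
}

#' Two-step deterministic mother-infant linkage
#'
#' Runs the full procedure: exact matching on both SSNs first, then, for
#' the remaining certificates and enrollees only, pairing inside the
#' Medicaid extract by family case ID plus delivery claim date and linking
#' those dyads to certificates by whichever single SSN is available. The
#' step order is fixed; a dyad linked in step 1 is never revisited in
#' step 2, and every ambiguity is dropped and counted, never resolved by
#' choice.
#'
#' @inheritParams link_exact_ssn
#' @inheritParams pair_within_max
#' @return list with `pairs` (all linked dyads, `pair_id` assigned from the
#'   certificate id) and `report` (a `linkage_report` list: candidate
#'   certificate count, per-path link counts, ambiguous and unlinked
#'   counts).
#' @export
link_two_step <- function(max_people, bc, deliveries,
                          date_tolerance_days = 0) {
  step1 <- link_exact_ssn(max_people, bc)

  remaining_people <- max_people[
    !(max_people$person_id %in% step1$pairs$infant_id), ]
  remaining_bc <- bc[bc$cert_id %in% step1$unlinked_certs, ]
  step2a <- pair_within_max(remaining_people, deliveries,
                            date_tolerance_days)
  # dyads whose infant already linked in step 1 are out; linked mothers may
  # recur (an older sibling linked by SSN does not block this birth)
  step2b <- link_pairs_to_bc(step2a$pairs, max_people, remaining_bc)

  pairs <- dplyr::bind_rows(step1$pairs, step2b$pairs)
  pairs$pair_id <- pairs$cert_id
  pairs <- pairs[, c("pair_id", "mother_id", "infant_id", "cert_id",
                     "linkage_path", "birth_date")]

  report <- structure(list(
    n_candidates = nrow(bc),
    n_linked_by_path = c(both_ssn_exact = nrow(step1$pairs),
                         case_id_then_ssn = nrow(step2b$pairs)),
    n_ambiguous_dropped = step1$n_ambiguous + step2a$n_ambiguous +
      step2b$n_ambiguous,
    n_unlinked = nrow(bc) - nrow(pairs),
    ppv_vs_truth = NA_real_
  ), class = "linkage_report")
  list(pairs = pairs, report = report)
}

#' Score linked pairs against known truth
#'
#' For synthetic cohorts (where the generating truth is available) computes
#' the positive predictive value of the linkage: the proportion of emitted
#' dyad-certificate links that are exactly correct on mother, infant and
#' certificate. Undefined (reported `NA`) when nothing was linked.
#'
#' @param pairs linked-pair tibble (`mother_id`, `infant_id`, `cert_id`,
#'   `linkage_path`).
#' @param truth truth tibble with the same three id columns.
#' @return a `linkage_report` with `ppv_vs_truth` filled in and the number
#'   of true pairs recovered.
#' @export
evaluate_linkage <- function(pairs, truth) {
  require_columns(truth, c("mother_id", "infant_id", "cert_id"), "truth")
  key <- function(d) paste(d$mother_id, d$infant_id, d$cert_id)
  correct <- sum(key(pairs) %in% key(truth))
  n_linked <- nrow(pairs)
  structure(list(
    n_candidates = nrow(truth),
    n_linked_by_path = table(pairs$linkage_path),
    n_ambiguous_dropped = NA_integer_,
    n_unlinked = nrow(truth) - correct,
    n_correct = correct,
    recall_vs_truth = correct / nrow(truth),
    ppv_vs_truth = if (n_linked == 0L) NA_real_ else correct / n_linked
  ), class = "linkage_report")
}

#' @export
print.linkage_report <- function(x, ...) {
  cat("<linkage_report>\n")
  cat("  candidates:", x$n_candidates, "\n")
  cat("  linked by path:",
      paste(names(x$n_linked_by_path), unclass(x$n_linked_by_path),
            sep = "=", collapse = ", "), "\n")
  cat("  ambiguous dropped:", x$n_ambiguous_dropped,
      " unlinked:", x$n_unlinked, "\n")
  if (!is.na(x$ppv_vs_truth))
    cat(sprintf("  PPV vs truth: %.4f\n", x$ppv_vs_truth))
  invisible(x)
}
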