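# Small in-code fixtures shared across test files.

make_pairs <- function(n = 1, birth = as.Date("2005-03-10")) {
  tibble::tibble(
    pair_id = sprintf("P%03d", seq_len(n)),
    infant_id = sprintf("I%03d", seq_len(n)),
    mother_id = sprintf("M%03d", seq_len(n)),
    cert_id = sprintf("C%03d", seq_len(n)),
    birth_date = rep(birth, length.out = n)
  )
}

make_claim <- function(person_id, date, code, system = "ICD9_DX",
                       record_type = "inpatient", dx_position = 1L) {
  tibble::tibble(person_id = person_id, linked_mother_id = NA_character_,
                 record_type = record_type, service_date = as.Date(date),
                 code_system = system, code = code,
                 dx_position = dx_position)
}

empty_claims <- function() make_claim(character(), as.Date(character()),
                                      character())[0, ]

make_bc <- function(pairs, nicu = 0L, rds = 0L, seizure = 0L, av = 0L,
                    birth_injury = 0L) {
  tibble::tibble(
    cert_id = pairs$cert_id,
    infant_ssn = NA_character_, mother_ssn = NA_character_,
    birth_date = pairs$birth_date,
    nicu = rep(as.integer(nicu), length.out = nrow(pairs)),
    rds = rep(as.integer(rds), length.out = nrow(pairs)),
    seizure = rep(as.integer(seizure), length.out = nrow(pairs)),
    av = rep(as.integer(av), length.out = nrow(pairs)),
    birth_injury = rep(as.integer(birth_injury), length.out = nrow(pairs))
  )
}

flags_tbl <- function(pair_id, status) {
  tibble::tibble(pair_id = pair_id, status = status)
}

# brute-force one-to-one audit used as linkage oracle on small fixtures:
# a link is admissible only if its key matches exactly one record on the
# other side, enumerated exhaustively
brute_force_unique_links <- function(left_keys, right_keys) {
  hits <- lapply(left_keys, function(k) which(right_keys == k))
  ok <- vapply(hits, length, integer(1)) == 1L
  right_idx <- ifelse(ok, vapply(hits, function(h)
    if (length(h) == 1L) h else NA_integer_, integer(1)), NA_integer_)
  # drop collisions on the right side too
  collided <- !is.na(right_idx) & right_idx %in% right_idx[duplicated(right_idx)]
  right_idx[collided] <- NA_integer_
  right_idx
}
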