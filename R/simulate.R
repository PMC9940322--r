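#' Default per-condition generative parameters
#'
#' True prevalence plus per-source sensitivity and specificity for each of
#' the five conditions. The values are working assumptions, loosely
#' motivated by published claims-validation PPVs (86-97% across the
#' conditions) and by the cross-capture pattern of the two sources
#' (certificates under-report most conditions but out-capture claims for
#' assisted ventilation); they are not estimates of any real population.
#'
#' @return tibble with columns `condition`, `true_prevalence`, `se_max`,
#'   `sp_max`, `se_bc`, `sp_bc`.
#' @export
default_sim_conditions <- function() {
  tibble::tribble(
    ~condition,     ~true_prevalence, ~se_max, ~sp_max, ~se_bc, ~sp_bc,
    "NICU",         0.080,            0.92,    0.9990,  0.60,   0.9950,
    "RDS",          0.030,            0.90,    0.9980,  0.15,   0.9990,
    "SEIZURE",      0.0025,           0.86,    0.9995,  0.06,   0.9999,
    "AV",           0.040,            0.30,    0.9990,  0.80,   0.9900,
    "BIRTH_INJURY", 0.015,            0.80,    0.9970,  0.02,   0.9995
  )
}

#' Build and validate a simulation configuration
#'
#' @param n_pairs number of mother-infant dyads to simulate.
#' @param seed root seed; every random stream in the generator derives a
#'   fixed sub-seed from it, so toggling one noise source leaves the
#'   others' draws unchanged.
#' @param conditions per-condition parameter tibble, see
#'   [default_sim_conditions()].
#' @param bc_missing_rate probability a certificate determination is
#'   missing, independently per condition (the linkage-study setting is
#'   just under 2%).
#' @param ssn_missing_rate_mother,ssn_missing_rate_infant probability the
#'   respective SSN is absent from the Medicaid extract.
#' @param birth_year_range inclusive birth-year span.
#' @param noise_claims_per_infant Poisson mean of unrelated claims per
#'   infant (codes matching no condition set).
#' @param mother_record_fraction probability a condition claim lands on
#'   the mother's record rather than the infant's.
#' @param source_correlation probability that, for a true case, the two
#'   sources share one detection draw instead of detecting independently
#'   (a shared-severity dependence knob; 0 = conditional independence).
#' @param window_days postnatal window used for claim service dates.
#' @param enrollment_gap_rate fraction of infants whose coverage ends
#'   before the window does (excluded by the cohort filter).
#' @return validated `simulation_config` list.
#' @export
simulation_config <- function(n_pairs = 10000, seed = 1,
                              conditions = default_sim_conditions(),
                              bc_missing_rate = 0.02,
                              ssn_missing_rate_mother = 0.15,
                              ssn_missing_rate_infant = 0.25,
                              birth_year_range = c(1999L, 2010L),
                              noise_claims_per_infant = 1,
                              mother_record_fraction = 0.10,
                              source_correlation = 0,
                              window_days = 30,
                              enrollment_gap_rate = 0) {
  props <- c(conditions$true_prevalence, conditions$se_max, conditions$sp_max,
             conditions$se_bc, conditions$sp_bc, bc_missing_rate,
             ssn_missing_rate_mother, ssn_missing_rate_infant,
             mother_record_fraction, source_correlation, enrollment_gap_rate)
  if (any(is.na(props)) || any(props < 0) || any(props > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_pairs > 0, noise_claims_per_infant >= 0, window_days > 0,
            birth_year_range[1] <= birth_year_range[2])
  structure(list(
    n_pairs = as.integer(n_pairs), seed = as.integer(seed),
    conditions = conditions, bc_missing_rate = bc_missing_rate,
    ssn_missing_rate_mother = ssn_missing_rate_mother,
    ssn_missing_rate_infant = ssn_missing_rate_infant,
    birth_year_range = as.integer(birth_year_range),
    noise_claims_per_infant = noise_claims_per_infant,
    mother_record_fraction = mother_record_fraction,
    source_correlation = source_correlation,
    window_days = as.integer(window_days),
    enrollment_gap_rate = enrollment_gap_rate
  ), class = "simulation_config")
}

# fixed sub-seed per named stream, derived from the root seed
stream_seed <- function(seed, stream) {
  offsets <- c(identity = 1L, truth = 2L, max = 3L, bc = 4L, noise = 5L,
               enrollment = 6L)
  (as.integer(seed) * 7L + offsets[[stream]] * 104729L) %% 2147483647L
}

#' Simulate a linked claims / birth-certificate cohort with known truth
#'
#' Generates the full set of tables the pipeline consumes: a Medicaid
#' person table (mothers and infants with case IDs and partially missing
#' SSNs), claims (condition claims emitted from latent truth through each
#' condition's claims sensitivity/specificity, plus delivery claims and
#' unrelated noise claims), enrollment spans, birth certificates (checkbox
#' determinations from the certificate-side sensitivity/specificity with
#' independent missingness), and the latent truth table that the emitted
#' files never reveal. Byte-identical output for identical config.
#'
#' @param config a [simulation_config()].
#' @return list of tibbles: `persons`, `claims`, `deliveries`,
#'   `enrollment`, `bc`, `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_pairs
  conds <- config$conditions
  code_pool <- default_condition_codes()

  ## identity stream: ids, SSNs, birth dates, case ids
  set.seed(stream_seed(config$seed, "identity"))
  pair_id <- sprintf("P%07d", seq_len(n))
  mother_id <- sprintf("M%07d", seq_len(n))
  infant_id <- sprintf("I%07d", seq_len(n))
  cert_id <- sprintf("C%07d", seq_len(n))
  case_id <- sprintf("F%07d", seq_len(n))
  ssn_pool <- sprintf("%09d", 99999999L + sample.int(900000000L, 2L * n))
  mother_ssn <- ssn_pool[seq_len(n)]
  infant_ssn <- ssn_pool[n + seq_len(n)]
  yrs <- config$birth_year_range
  year <- sample(yrs[1]:yrs[2], n, replace = TRUE)
  doy <- sample.int(365L, n, replace = TRUE)
  birth_date <- as.Date(sprintf("%d-01-01", year)) + (doy - 1L)
  mother_ssn_max <- replace(mother_ssn,
                            stats::runif(n) < config$ssn_missing_rate_mother,
                            NA_character_)
  infant_ssn_max <- replace(infant_ssn,
                            stats::runif(n) < config$ssn_missing_rate_infant,
                            NA_character_)

  ## truth stream
  set.seed(stream_seed(config$seed, "truth"))
  truth_mat <- sapply(conds$true_prevalence, function(p)
    stats::runif(n) < p)
  colnames(truth_mat) <- conds$condition

  ## claims-side detection + claim emission
  set.seed(stream_seed(config$seed, "max"))
  claim_rows <- vector("list", nrow(conds))
  bc_det_shared <- matrix(NA, n, nrow(conds))  # shared draws for correlation
  for (i in seq_len(nrow(conds))) {
    tr <- truth_mat[, i]
    u <- stats::runif(n)
    det <- ifelse(tr, u < conds$se_max[i], u < (1 - conds$sp_max[i]))
    bc_det_shared[, i] <- u  # reused only when source_correlation > 0
    idx <- which(det)
    if (!length(idx)) next
    set_i <- code_pool[code_pool$condition == conds$condition[i], ]
    pick <- sample.int(nrow(set_i), length(idx), replace = TRUE)
    concrete <- concretize_pattern(set_i$pattern[pick])
    on_mother <- stats::runif(length(idx)) < config$mother_record_fraction
    claim_rows[[i]] <- tibble::tibble(
      person_id = ifelse(on_mother, mother_id[idx], infant_id[idx]),
      linked_mother_id = ifelse(on_mother, NA_character_, mother_id[idx]),
      record_type = sample(c("inpatient", "outpatient"), length(idx),
                           replace = TRUE, prob = c(0.8, 0.2)),
      service_date = birth_date[idx] +
        sample.int(config$window_days + 1L, length(idx), replace = TRUE) - 1L,
      code_system = set_i$system[pick],
      code = concrete,
      dx_position = sample.int(5L, length(idx), replace = TRUE)
    )
  }

  ## certificate-side detection
  set.seed(stream_seed(config$seed, "bc"))
  bc_mat <- matrix(0L, n, nrow(conds))
  colnames(bc_mat) <- tolower(conds$condition)
  for (i in seq_len(nrow(conds))) {
    tr <- truth_mat[, i]
    u_ind <- stats::runif(n)
    shared <- stats::runif(n) < config$source_correlation
    u <- ifelse(tr & shared, bc_det_shared[, i], u_ind)
    det <- ifelse(tr, u < conds$se_bc[i], u_ind < (1 - conds$sp_bc[i]))
    flag <- as.integer(det)
    flag[stats::runif(n) < config$bc_missing_rate] <- NA_integer_
    bc_mat[, i] <- flag
  }

  ## noise stream: unrelated claims on infant records
  set.seed(stream_seed(config$seed, "noise"))
  noise_codes <- c("V3000", "V3001", "7746", "V053", "4659")
  n_noise <- stats::rpois(n, config$noise_claims_per_infant)
  who <- rep(seq_len(n), n_noise)
  noise <- if (length(who)) tibble::tibble(
    person_id = infant_id[who],
    linked_mother_id = mother_id[who],
    record_type = sample(c("inpatient", "outpatient"), length(who),
                         replace = TRUE, prob = c(0.3, 0.7)),
    service_date = birth_date[who] +
      sample.int(config$window_days + 1L, length(who), replace = TRUE) - 1L,
    code_system = "ICD9_DX",
    code = sample(noise_codes, length(who), replace = TRUE),
    dx_position = sample.int(5L, length(who), replace = TRUE)
  ) else NULL

  ## enrollment stream
  set.seed(stream_seed(config$seed, "enrollment"))
  gap <- stats::runif(n) < config$enrollment_gap_rate
  infant_end <- birth_date + ifelse(gap, config$window_days - 16L, 60L)
  enrollment <- tibble::tibble(
    person_id = c(mother_id, infant_id),
    start_date = c(birth_date - 270L, birth_date),
    end_date = c(birth_date + 60L, infant_end)
  )

  deliveries <- tibble::tibble(person_id = mother_id,
                               delivery_date = birth_date)
  delivery_claims <- tibble::tibble(
    person_id = mother_id, linked_mother_id = NA_character_,
    record_type = "delivery", service_date = birth_date,
    code_system = "ICD9_DX", code = "650", dx_position = 1L
  )

  persons <- tibble::tibble(
    person_id = c(mother_id, infant_id),
    role = rep(c("mother", "infant"), each = n),
    ssn = c(mother_ssn_max, infant_ssn_max),
    case_id = rep(case_id, 2L),
    birth_date = c(as.Date(rep(NA, n)), birth_date)
  )

  bc <- dplyr::bind_cols(
    tibble::tibble(cert_id = cert_id, infant_ssn = infant_ssn,
                   mother_ssn = mother_ssn, birth_date = birth_date),
    tibble::as_tibble(bc_mat)
  )

  truth <- dplyr::bind_cols(
    tibble::tibble(pair_id = pair_id, mother_id = mother_id,
                   infant_id = infant_id, cert_id = cert_id,
                   birth_date = birth_date),
    tibble::as_tibble(truth_mat)
  )

  claims <- dplyr::bind_rows(c(claim_rows, list(noise, delivery_claims)))
  claims <- dplyr::arrange(claims, .data$person_id, .data$service_date,
                           .data$code)
  list(persons = persons, claims = claims, deliveries = deliveries,
       enrollment = enrollment, bc = bc, truth = truth)
}

# replace trailing wildcards with concrete digits so emitted codes are
# real claim codes, not patterns
concretize_pattern <- function(pattern) {
  k <- nchar(pattern) - nchar(sub("X+$", "", pattern))
  stem <- sub("X+$", "", pattern)
  fill <- vapply(k, function(m)
    if (m == 0L) "" else paste(sample(0:9, m, replace = TRUE), collapse = ""),
    character(1))
  paste0(stem, fill)
}

#' Expected cell probabilities of the dual-source 2x2 table
#'
#' Under conditional independence of the two sources given true status,
#' the joint probability of each (claims, certificate) outcome follows by
#' total probability over the latent truth.
#'
#' @param pi true prevalence.
#' @param se_max,sp_max claims-side sensitivity and specificity.
#' @param se_bc,sp_bc certificate-side sensitivity and specificity.
#' @return named numeric vector `p11`, `p10`, `p01`, `p00`.
#' @export
expected_cell_probs <- function(pi, se_max, sp_max, se_bc, sp_bc) {
  c(p11 = pi * se_max * se_bc + (1 - pi) * (1 - sp_max) * (1 - sp_bc),
    p10 = pi * se_max * (1 - se_bc) + (1 - pi) * (1 - sp_max) * sp_bc,
    p01 = pi * (1 - se_max) * se_bc + (1 - pi) * sp_max * (1 - sp_bc),
    p00 = pi * (1 - se_max) * (1 - se_bc) + (1 - pi) * sp_max * sp_bc)
}

#' Closed-form kappa implied by a generative parameterization
#'
#' The analytic value Cohen's kappa converges to as the cohort grows,
#' given conditional independence of the sources. Used as the oracle for
#' simulator parameter-recovery checks.
#'
#' @inheritParams expected_cell_probs
#' @return kappa value (`NA` when expected agreement is 1).
#' @examples
#' expected_kappa(0.05, 0.9, 0.999, 0.4, 0.999)
#' @export
expected_kappa <- function(pi, se_max, sp_max, se_bc, sp_bc) {
  stopifnot(all(c(pi, se_max, sp_max, se_bc, sp_bc) >= 0),
            all(c(pi, se_max, sp_max, se_bc, sp_bc) <= 1))
  p <- expected_cell_probs(pi, se_max, sp_max, se_bc, sp_bc)
  po <- p[["p11"]] + p[["p00"]]
  pe <- (p[["p11"]] + p[["p10"]]) * (p[["p11"]] + p[["p01"]]) +
    (p[["p01"]] + p[["p00"]]) * (p[["p10"]] + p[["p00"]])
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}
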