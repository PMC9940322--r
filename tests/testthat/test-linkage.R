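# 20-certificate fixture with planted pathologies, used to audit step 1
# against a brute-force uniqueness check.
ssn_fixture <- function() {
  n <- 20
  m_ssn <- sprintf("%09d", 111111100 + 1:n)   # one person per SSN in claims
  i_ssn <- sprintf("%09d", 222222200 + 1:n)
  people <- tibble::tibble(
    person_id = c(sprintf("M%02d", 1:n), sprintf("I%02d", 1:n)),
    role = rep(c("mother", "infant"), each = n),
    ssn = c(m_ssn, i_ssn),
    case_id = rep(sprintf("F%02d", 1:n), 2),
    birth_date = c(as.Date(rep(NA, n)), as.Date("2005-01-01") + 1:n)
  )
  people$ssn[people$person_id == "I02"] <- NA  # absent in claims side
  bc_m <- m_ssn
  bc_i <- i_ssn
  bc_m[19:20] <- bc_m[18]            # certs 18-20 share one mother SSN
  bc_i[20] <- bc_i[19]               # certs 19/20 are duplicate certificates
  bc <- tibble::tibble(
    cert_id = sprintf("C%02d", 1:n),
    infant_ssn = bc_i, mother_ssn = bc_m,
    birth_date = as.Date("2005-01-01") + 1:n
  )
  bc$infant_ssn[1] <- NA             # no infant SSN -> not step-1 linkable
  list(bc = bc, people = people)
}

test_that("exact-SSN linkage emits only unique two-sided matches", {
  fx <- ssn_fixture()
  out <- link_exact_ssn(fx$people, fx$bc)

  # brute-force audit: admissible certs need both SSNs present, each
  # resolving to exactly one person, and no shared SSN among certificates
  bc2 <- fx$bc[!is.na(fx$bc$infant_ssn) & !is.na(fx$bc$mother_ssn), ]
  inf_pool <- fx$people$ssn[fx$people$role == "infant"]
  mom_pool <- fx$people$ssn[fx$people$role == "mother"]
  # infants and certificates must be one-to-one; a mother may recur across
  # siblings' certificates, so only count her claim-side matches
  mom_n <- vapply(bc2$mother_ssn, function(k)
    sum(mom_pool == k, na.rm = TRUE), integer(1))
  expected <- bc2$cert_id[
    !is.na(brute_force_unique_links(bc2$infant_ssn, inf_pool)) &
      mom_n == 1L &
      !bc2$infant_ssn %in% bc2$infant_ssn[duplicated(bc2$infant_ssn)]
  ]
  # mother SSN shared across certs 18-20 is fine per se (siblings), but the
  # duplicated infant SSN on certs 19/20 drops both
  expect_setequal(out$pairs$cert_id, expected)
  expect_true(all(out$pairs$linkage_path == "both_ssn_exact"))
  expect_false(any(c("C01", "C02", "C19", "C20") %in% out$pairs$cert_id))
  expect_true("C18" %in% out$pairs$cert_id)
  expect_equal(out$n_ambiguous, 2L)  # the duplicate-certificate pair
  expect_equal(anyDuplicated(out$pairs$infant_id), 0L)
  expect_equal(anyDuplicated(out$pairs$cert_id), 0L)
})

test_that("within-claims pairing matches case ID and delivery date", {
  people <- tibble::tibble(
    person_id = c("M1", "M2", "M3", "I1", "I2", "I3", "I4"),
    role = c(rep("mother", 3), rep("infant", 4)),
    ssn = NA_character_,
    case_id = c("F1", "F2", "F3", "F1", "F2", "F3", "F3"),
    birth_date = as.Date(c(NA, NA, NA, "2005-03-01", "2005-03-05",
                           "2005-07-01", "2005-07-01"))
  )
  deliveries <- tibble::tibble(
    person_id = c("M1", "M2", "M3"),
    delivery_date = as.Date(c("2005-03-01", "2004-08-17", "2005-07-01"))
  )
  out <- pair_within_max(people, deliveries, 0)
  # M1-I1 exact date; M2-I2 delivery 200 days off -> no pair;
  # M3 twins I3/I4 both retained
  expect_setequal(paste(out$pairs$mother_id, out$pairs$infant_id),
                  c("M1 I1", "M3 I3", "M3 I4"))
  expect_equal(out$n_ambiguous, 0L)
})

test_that("date tolerance behaves exactly over all offsets -3..+3", {
  base <- as.Date("2005-03-10")
  for (off in -3:3) {
    people <- tibble::tibble(
      person_id = c("M1", "I1"), role = c("mother", "infant"),
      ssn = NA_character_, case_id = "F1",
      birth_date = c(as.Date(NA), base))
    deliveries <- tibble::tibble(person_id = "M1",
                                 delivery_date = base + off)
    for (tol in 0:2) {
      got <- nrow(pair_within_max(people, deliveries, tol)$pairs)
      expect_equal(got, as.integer(abs(off) <= tol),
                   info = sprintf("offset %d tolerance %d", off, tol))
    }
  }
})

test_that("an infant matching two mothers within tolerance is dropped", {
  people <- tibble::tibble(
    person_id = c("M1", "M2", "I1"),
    role = c("mother", "mother", "infant"),
    ssn = NA_character_, case_id = "F1",
    birth_date = as.Date(c(NA, NA, "2005-03-10")))
  deliveries <- tibble::tibble(person_id = c("M1", "M2"),
                               delivery_date = as.Date("2005-03-10"))
  out <- pair_within_max(people, deliveries, 0)
  expect_equal(nrow(out$pairs), 0L)
  expect_equal(out$n_ambiguous, 1L)
})

test_that("pairs link to certificates by whichever SSN is available", {
  pairs <- tibble::tibble(
    mother_id = c("M1", "M2", "M3", "M4"),
    infant_id = c("I1", "I2", "I3", "I4"),
    birth_date = as.Date("2005-03-10") + 0:3)
  people <- tibble::tibble(
    person_id = c("M1", "M2", "M3", "M4", "I1", "I2", "I3", "I4"),
    role = rep(c("mother", "infant"), each = 4),
    ssn = c("111111111", NA, "333333333", NA,
            NA, "555555555", NA, NA),
    case_id = NA_character_, birth_date = as.Date(NA))
  bc <- tibble::tibble(
    cert_id = c("C1", "C2", "C3a", "C3b"),
    infant_ssn = c(NA, "555555555", "777777777", "888888888"),
    mother_ssn = c("111111111", NA, "333333333", "333333333"),
    birth_date = as.Date("2005-03-10") + 0:3)
  out <- link_pairs_to_bc(pairs, people, bc)
  # M1 by mother SSN; I2 by infant SSN; M3's SSN matches two certificates
  # with different infants -> dropped; M4/I4 have no SSN -> unlinked
  expect_setequal(out$pairs$cert_id, c("C1", "C2"))
  expect_equal(out$n_ambiguous, 1L)
  expect_equal(out$n_unlinked, 1L)
})

test_that("two-step linkage is order-invariant and never reuses a record", {
  set.seed(23)
  sim <- simulate_cohort(simulation_config(n_pairs = 500, seed = 23))
  res <- link_two_step(sim$persons, sim$bc, sim$deliveries)

  shuf <- link_two_step(sim$persons[sample(nrow(sim$persons)), ],
                        sim$bc[sample(nrow(sim$bc)), ],
                        sim$deliveries[sample(nrow(sim$deliveries)), ])
  expect_equal(dplyr::arrange(res$pairs, .data$pair_id),
               dplyr::arrange(shuf$pairs, .data$pair_id))

  expect_equal(anyDuplicated(res$pairs$infant_id), 0L)
  expect_equal(anyDuplicated(res$pairs$cert_id), 0L)
  tot <- sum(res$report$n_linked_by_path) + res$report$n_unlinked
  expect_equal(tot, res$report$n_candidates)
})

test_that("complete unique identifiers are recovered perfectly", {
  cfg <- simulation_config(n_pairs = 400, seed = 5,
                           ssn_missing_rate_mother = 0,
                           ssn_missing_rate_infant = 0)
  sim <- simulate_cohort(cfg)
  res <- link_two_step(sim$persons, sim$bc, sim$deliveries)
  expect_equal(nrow(res$pairs), 400L)
  expect_true(all(res$pairs$linkage_path == "both_ssn_exact"))
  rep <- evaluate_linkage(res$pairs, sim$truth)
  expect_equal(rep$ppv_vs_truth, 1)
  expect_equal(rep$recall_vs_truth, 1)
})

test_that("linkage PPV arithmetic and empty-set degeneracy", {
  truth <- tibble::tibble(mother_id = sprintf("M%d", 1:100),
                          infant_id = sprintf("I%d", 1:100),
                          cert_id = sprintf("C%d", 1:100))
  pairs <- truth
  pairs$cert_id[1] <- "C999"  # one wrong link
  pairs$linkage_path <- "both_ssn_exact"
  expect_equal(evaluate_linkage(pairs, truth)$ppv_vs_truth, 0.99)
  expect_true(is.na(evaluate_linkage(pairs[0, ], truth)$ppv_vs_truth))
})

test_that("SSN normalization keeps only clean nine-digit values", {
  expect_equal(normalize_ssn(c("123-45-6789", " 123456789 ", "12345678",
                               "1234567890", NA)),
               c("123456789", "123456789", NA, NA, NA))
})
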