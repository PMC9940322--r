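defs <- condition_definitions()

test_that("claims ascertainment honors code set, window and record owner", {
  pairs <- make_pairs(1)
  birth <- pairs$birth_date

  rds_day5 <- make_claim("I001", birth + 5, "7690")
  expect_equal(ascertain_max_cases(rds_day5, pairs, defs$RDS)$status, "case")

  rds_day45 <- make_claim("I001", birth + 45, "7690")
  expect_equal(ascertain_max_cases(rds_day45, pairs, defs$RDS)$status,
               "noncase")

  # window is closed on both ends, day of birth = day 0
  expect_equal(ascertain_max_cases(
    make_claim("I001", birth + 30, "7690"), pairs, defs$RDS)$status, "case")
  expect_equal(ascertain_max_cases(
    make_claim("I001", birth + 31, "7690"), pairs, defs$RDS)$status, "noncase")
  expect_equal(ascertain_max_cases(
    make_claim("I001", birth - 1, "7690"), pairs, defs$RDS)$status, "noncase")

  # mother-record claims count
  mom_seiz <- make_claim("M001", birth + 2, "77900")
  expect_equal(ascertain_max_cases(mom_seiz, pairs, defs$SEIZURE)$status,
               "case")
  no_mom <- condition_definitions(use_mother_records = FALSE)
  expect_equal(ascertain_max_cases(mom_seiz, pairs, no_mom$SEIZURE)$status,
               "noncase")

  # delivery-type claims are not eligible encounters
  del <- make_claim("M001", birth + 2, "77900", record_type = "delivery")
  expect_equal(ascertain_max_cases(del, pairs, defs$SEIZURE)$status, "noncase")

  # any diagnosis position qualifies
  pos9 <- make_claim("I001", birth + 1, "76781", dx_position = 9L)
  expect_equal(ascertain_max_cases(pos9, pairs, defs$BIRTH_INJURY)$status,
               "case")

  expect_equal(ascertain_max_cases(empty_claims(), pairs, defs$RDS)$status,
               "noncase")
})

test_that("one claim can satisfy several conditions; systems never cross", {
  pairs <- make_pairs(1)
  cl <- dplyr::bind_rows(
    make_claim("I001", pairs$birth_date + 1, "9671", system = "ICD9_PC"),
    make_claim("I001", pairs$birth_date + 1, "99468", system = "CPT")
  )
  expect_equal(ascertain_max_cases(cl, pairs, defs$AV)$status, "case")
  expect_equal(ascertain_max_cases(cl, pairs, defs$NICU)$status, "case")
  # a dx-coded 9671 is 967.1 poisoning, not the 96.71 procedure
  dx_967 <- make_claim("I001", pairs$birth_date + 1, "9671",
                       system = "ICD9_DX")
  expect_equal(ascertain_max_cases(dx_967, pairs, defs$AV)$status, "noncase")
})

test_that("ascertainment is order-invariant, monotone and window-local", {
  set.seed(11)
  pairs <- make_pairs(20)
  random_claims <- function(n, window_only = TRUE) {
    offs <- if (window_only) sample(0:30, n, replace = TRUE) else
      sample(c(-40:-1, 31:90), n, replace = TRUE)
    make_claim(sample(c(pairs$infant_id, pairs$mother_id), n, replace = TRUE),
               pairs$birth_date[1] + offs,
               sample(c("7690", "76919", "4659", "V3000"), n, replace = TRUE),
               record_type = sample(c("inpatient", "outpatient"), n,
                                    replace = TRUE))
  }
  for (rep in 1:10) {
    cl <- random_claims(30)
    base <- ascertain_max_cases(cl, pairs, defs$RDS)

    shuffled <- cl[sample(nrow(cl)), ]
    expect_equal(ascertain_max_cases(shuffled, pairs, defs$RDS), base)

    # adding claims never demotes a case; removing never promotes
    more <- ascertain_max_cases(dplyr::bind_rows(cl, random_claims(10)),
                                pairs, defs$RDS)
    expect_true(all(!(base$status == "case" & more$status == "noncase")))
    fewer <- ascertain_max_cases(cl[1:15, ], pairs, defs$RDS)
    expect_true(all(!(base$status == "noncase" & fewer$status == "case")))

    # claims strictly outside the window never change any flag
    polluted <- dplyr::bind_rows(cl, random_claims(20, window_only = FALSE))
    expect_equal(ascertain_max_cases(polluted, pairs, defs$RDS), base)
  }
})

test_that("certificate ascertainment maps checked/unchecked/missing", {
  pairs <- make_pairs(3)
  bc <- make_bc(pairs, rds = c(1L, 0L, NA))
  out <- ascertain_bc_cases(bc, pairs, defs$RDS)
  expect_equal(out$status, c("case", "noncase", "excluded_missing"))
  expect_error(ascertain_bc_cases(bc[, -which(names(bc) == "av")],
                                  pairs, defs$AV), "AV")
})

test_that("NICU year restriction excludes births outside 2004-2010", {
  pairs <- make_pairs(3)
  pairs$birth_date <- as.Date(c("2002-06-01", "2005-06-01", "2011-01-01"))
  bc <- make_bc(pairs, nicu = 1L)
  cl <- make_claim(pairs$infant_id, pairs$birth_date + 1, "99468",
                   system = "CPT")
  expect_equal(ascertain_max_cases(cl, pairs, defs$NICU)$status,
               c("excluded_year", "case", "excluded_year"))
  expect_equal(ascertain_bc_cases(bc, pairs, defs$NICU)$status,
               c("excluded_year", "case", "excluded_year"))
  # no restriction for the other conditions
  bc2 <- make_bc(pairs, rds = 1L)
  expect_equal(ascertain_bc_cases(bc2, pairs, defs$RDS)$status, rep("case", 3))
})

test_that("cohort filter requires both members covered through day 30", {
  pairs <- make_pairs(4)
  birth <- pairs$birth_date[1]
  enr <- tibble::tibble(
    person_id = c("I001", "M001",          # full coverage
                  "I002", "M002",          # infant ends day 29 -> out
                  "I003", "M003",          # split spans, abutting -> in
                  "I004"),                 # mother missing entirely -> out
    start_date = c(birth, birth - 100,
                   birth, birth - 100,
                   birth, birth - 100,
                   birth),
    end_date = c(birth + 60, birth + 60,
                 birth + 29, birth + 60,
                 birth + 10, birth + 60,
                 birth + 60)
  )
  enr <- dplyr::bind_rows(enr, tibble::tibble(
    person_id = "I003", start_date = birth + 11, end_date = birth + 45))
  out <- apply_cohort_filters(pairs, enr, 30)
  expect_setequal(out$retained$pair_id, c("P001", "P003"))
  expect_equal(out$excluded$reason[out$excluded$pair_id == "P002"],
               "incomplete_coverage")
  expect_equal(out$excluded$reason[out$excluded$pair_id == "P004"],
               "no_enrollment")

  # with a year-restricted condition, out-of-range births are excluded too
  pairs$birth_date <- as.Date(c("2002-06-01", "2005-06-01", "2005-06-01",
                                "2005-06-01"))
  enr_all <- tibble::tibble(
    person_id = c(pairs$infant_id, pairs$mother_id),
    start_date = rep(pairs$birth_date, 2) - 100,
    end_date = rep(pairs$birth_date, 2) + 60
  )
  out2 <- apply_cohort_filters(pairs, enr_all, 30,
                               condition = defs$NICU)
  expect_equal(out2$excluded$pair_id, "P001")
  expect_equal(out2$excluded$reason, "outside_year_restriction")
})
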