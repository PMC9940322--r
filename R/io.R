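#' Table schemas
#'
#' All pipeline tables are comma-separated UTF-8 text with a mandatory
#' header, ISO-8601 dates and empty fields for absent values:
#'
#' * claims: `person_id, linked_mother_id, record_type, service_date,
#'   code_system, code, dx_position`
#' * birth certificates: `cert_id, infant_ssn, mother_ssn, birth_date,
#'   nicu, rds, seizure, av, birth_injury` (determinations 1/0/empty)
#' * enrollment: `person_id, start_date, end_date`
#' * persons: `person_id, role, ssn, case_id, birth_date`
#' * linked pairs: `pair_id, mother_id, infant_id, cert_id, linkage_path,
#'   birth_date`
#'
#' Readers validate the header, vocabularies and date formats and reject a
#' malformed file naming the offending line and column; codes and SSNs are
#' normalized on the way in.
#'
#' @name table_schemas
NULL

io_stop <- function(path, line, column, msg) {
  stop(sprintf("%s: line %s, column %s: %s", path, line, column, msg),
       call. = FALSE)
}

read_schema <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(
                                    .default = readr::col_character()),
                                  progress = FALSE))
  extra <- setdiff(header, names(cols))
  miss <- setdiff(names(cols), header)
  if (length(extra) || length(miss)) {
    io_stop(path, 1, paste(c(extra, miss), collapse = ", "),
            "header does not match documented schema")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    comment = "#", na = "")
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  df
}

parse_date_col <- function(df, col, path) {
  raw <- df[[col]]
  out <- as.Date(raw, format = "%Y-%m-%d")
  bad <- which(!is.na(raw) & is.na(out))
  if (length(bad)) {
    io_stop(path, bad[1] + 1L, col,
            paste0("unparseable ISO-8601 date: ", raw[bad[1]]))
  }
  df[[col]] <- out
  df
}

parse_vocab_col <- function(df, col, vocab, path, allow_na = FALSE) {
  raw <- df[[col]]
  bad <- which(!(raw %in% vocab) & !(allow_na & is.na(raw)))
  if (length(bad)) {
    io_stop(path, bad[1] + 1L, col,
            paste0("value '", raw[bad[1]], "' not in {",
                   paste(vocab, collapse = ", "), "}"))
  }
  df
}

#' Read a claims table
#'
#' @param path CSV path (see [table_schemas]).
#' @return tibble of typed claim records, codes normalized.
#' @export
read_claims <- function(path) {
  df <- read_schema(path, c(person_id = "c", linked_mother_id = "c",
                            record_type = "c", service_date = "D",
                            code_system = "c", code = "c",
                            dx_position = "i"))
  df <- parse_vocab_col(df, "record_type",
                        c("inpatient", "outpatient", "delivery"), path)
  df <- parse_vocab_col(df, "code_system", c("ICD9_DX", "ICD9_PC", "CPT"),
                        path)
  df <- parse_date_col(df, "service_date", path)
  df$dx_position <- as.integer(df$dx_position)
  if (any(is.na(df$code))) {
    io_stop(path, which(is.na(df$code))[1] + 1L, "code", "code is empty")
  }
  df$code <- normalize_code(df$code, df$code_system)
  tibble::as_tibble(df)
}

#' Read a birth-certificate table
#'
#' @param path CSV path (see [table_schemas]).
#' @return tibble with 0/1/NA determination columns and normalized SSNs.
#' @export
read_bc <- function(path) {
  flags <- c("nicu", "rds", "seizure", "av", "birth_injury")
  df <- read_schema(path, stats::setNames(
    rep("c", 4 + length(flags)),
    c("cert_id", "infant_ssn", "mother_ssn", "birth_date", flags)))
  df <- parse_date_col(df, "birth_date", path)
  for (fl in flags) {
    df <- parse_vocab_col(df, fl, c("0", "1"), path, allow_na = TRUE)
    df[[fl]] <- as.integer(df[[fl]])
  }
  df$infant_ssn <- normalize_ssn(df$infant_ssn)
  df$mother_ssn <- normalize_ssn(df$mother_ssn)
  tibble::as_tibble(df)
}

#' Read an enrollment-span table
#'
#' @param path CSV path (see [table_schemas]).
#' @return tibble of coverage spans.
#' @export
read_enrollment <- function(path) {
  df <- read_schema(path, c(person_id = "c", start_date = "D",
                            end_date = "D"))
  df <- parse_date_col(df, "start_date", path)
  df <- parse_date_col(df, "end_date", path)
  bad <- which(df$end_date < df$start_date)
  if (length(bad)) {
    io_stop(path, bad[1] + 1L, "end_date", "span ends before it starts")
  }
  tibble::as_tibble(df)
}

#' Read a Medicaid person table
#'
#' @param path CSV path (see [table_schemas]).
#' @return tibble of persons with normalized SSNs.
#' @export
read_persons <- function(path) {
  df <- read_schema(path, c(person_id = "c", role = "c", ssn = "c",
                            case_id = "c", birth_date = "D"))
  df <- parse_vocab_col(df, "role", c("mother", "infant"), path)
  df <- parse_date_col(df, "birth_date", path)
  df$ssn <- normalize_ssn(df$ssn)
  tibble::as_tibble(df)
}

#' Read a linked-pair table
#'
#' @param path CSV path (see [table_schemas]).
#' @return tibble of linked mother-infant pairs.
#' @export
read_pairs <- function(path) {
  df <- read_schema(path, c(pair_id = "c", mother_id = "c",
                            infant_id = "c", cert_id = "c",
                            linkage_path = "c", birth_date = "D"))
  df <- parse_vocab_col(df, "linkage_path",
                        c("both_ssn_exact", "case_id_then_ssn"), path)
  parse_date_col(df, "birth_date", path)
}

#' Write a pipeline table
#'
#' Plain `readr::write_csv()` with the package's dialect (empty field for
#' `NA`); the inverse of the corresponding reader.
#'
#' @param x tibble.
#' @param path output CSV path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

#' Load and validate a pipeline configuration
#'
#' YAML file with the stage settings: input/output paths, the condition
#' code-set file, window and linkage-tolerance settings, and (for
#' simulated runs) the generator parameters and seed.
#'
#' @param path YAML config path.
#' @return named list of settings with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(window_days = 30, date_tolerance_days = 0,
                   stratum = "SIM", seed = 1, out_dir = ".")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$simulate)) {
    for (nm in c("claims", "persons", "bc", "enrollment")) {
      if (is.null(cfg[[nm]])) {
        stop("config must name a '", nm,
             "' input file (or set 'simulate')", call. = FALSE)
      }
      if (!file.exists(cfg[[nm]])) {
        stop("config input path does not resolve: ", cfg[[nm]],
             call. = FALSE)
      }
    }
  }
  cfg
}

#' Run the full concordance pipeline
#'
#' Chains the stages: obtain input tables (simulate from config, or read
#' the configured files), link mother-infant dyads to certificates,
#' filter to the continuously enrolled cohort, ascertain all five
#' conditions from both sources, and build the per-condition agreement
#' report. Intermediate and final tables are written to `out_dir`.
#'
#' @param config list from [read_pipeline_config()], or a path to a YAML
#'   config.
#' @return list with `pairs`, `linkage_report`, `agreement` (report
#'   tibble, one row per condition), and `truth` (simulated runs only),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim <- simulate_cohort(do.call(simulation_config, sim_args))
    persons <- sim$persons; claims <- sim$claims; bc <- sim$bc
    enrollment <- sim$enrollment; deliveries <- sim$deliveries
    truth <- sim$truth
  } else {
    persons <- read_persons(config$persons)
    claims <- read_claims(config$claims)
    bc <- read_bc(config$bc)
    enrollment <- read_enrollment(config$enrollment)
    deliveries <- claims[claims$record_type == "delivery",
                         c("person_id", "service_date")]
    names(deliveries)[2] <- "delivery_date"
    truth <- NULL
  }

  linked <- link_two_step(persons, bc, deliveries,
                          config$date_tolerance_days)
  pairs <- linked$pairs
  filt <- apply_cohort_filters(pairs, enrollment, config$window_days)
  cohort <- filt$retained

  defs <- condition_definitions(window_days = config$window_days)
  reports <- lapply(defs, function(def) {
    mx <- ascertain_max_cases(claims, cohort, def)
    bcf <- ascertain_bc_cases(bc, cohort, def)
    agreement_summary(build_two_by_two(mx, bcf, def$name, config$stratum))
  })
  agreement <- dplyr::bind_rows(reports)

  write_table(pairs, file.path(out_dir, "pairs.csv"))
  write_table(agreement, file.path(out_dir, "agreement_report.csv"))
  write_table(filt$excluded, file.path(out_dir, "cohort_exclusions.csv"))

  invisible(list(pairs = pairs, linkage_report = linked$report,
                 cohort = cohort, agreement = agreement, truth = truth))
}
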