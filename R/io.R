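# Cohort CSV I/O with validation, scenario orchestration, and run manifests.

COHORT_SCHEMA_HEADER <- "# pelower cohort schema v1"

COHORT_NUMERIC <- c("age", "weight", "height", "interpregnancy_interval",
                    "ga_screening", "sbp", "dbp", "uta_pi", "plgf",
                    "ga_delivery", "g_pe", "g_other")
COHORT_LOGICAL <- c("smoker", "family_history_pe", "chronic_hypertension",
                    "sle_aps", "pe")
COHORT_REQUIRED <- c("age", "weight", "height", "ethnic_group", "smoker",
                     "family_history_pe", "conception", "parity",
                     "interpregnancy_interval", "chronic_hypertension",
                     "diabetes", "sle_aps", "ga_screening", "sbp", "dbp",
                     "uta_pi", "plgf")

#' Validate a cohort table
#'
#' Checks every row against the documented invariants: covariate ranges
#' (age 12-60 years, weight 30-250 kg, height 120-210 cm, screening gestation
#' 11.0-14.2 weeks), known categorical levels, interpregnancy interval
#' present exactly when parous, positive biomarkers, and
#' `50 <= dbp < sbp <= 260` mm Hg.
#'
#' @param cohort A cohort data frame.
#' @return A data frame of validation errors (`row`, `field`, `message`);
#'   zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  errs <- list()
  flag <- function(rows, field, message) {
    rows <- which(rows)
    if (length(rows))
      errs[[length(errs) + 1L]] <<- data.frame(
        row = rows, field = field, message = message,
        stringsAsFactors = FALSE)
  }
  num <- function(field) suppressWarnings(as.numeric(cohort[[field]]))
  in_range <- function(field, lo, hi) {
    x <- num(field)
    flag(is.na(x) & !is.na(cohort[[field]]), field, "not numeric")
    flag(!is.na(x) & (x < lo | x > hi), field,
         sprintf("outside [%g, %g]", lo, hi))
  }
  in_range("age", 12, 60)
  in_range("weight", 30, 250)
  in_range("height", 120, 210)
  in_range("ga_screening", 11.0, 14.2)
  for (field in names(CATEGORICAL_LEVELS)) {
    x <- as.character(cohort[[field]])
    flag(!is.na(x) & !x %in% CATEGORICAL_LEVELS[[field]], field,
         "unknown level")
  }
  nulli <- as.character(cohort$parity) == "nulliparous"
  ipi <- num("interpregnancy_interval")
  flag(!is.na(nulli) & nulli & !is.na(ipi), "interpregnancy_interval",
       "must be absent for nulliparous women")
  flag(!is.na(nulli) & !nulli & is.na(ipi), "interpregnancy_interval",
       "required for parous women")
  for (field in c("uta_pi", "plgf")) {
    x <- num(field)
    flag(!is.na(x) & x <= 0, field, "must be > 0")
  }
  sbp <- num("sbp"); dbp <- num("dbp")
  flag(is.na(sbp) | is.na(dbp), "sbp/dbp", "blood pressure required")
  bad_bp <- !is.na(sbp) & !is.na(dbp) &
    !(dbp >= 50 & dbp < sbp & sbp <= 260)
  flag(bad_bp, "sbp/dbp", "must satisfy 50 <= dbp < sbp <= 260")
  if (length(errs)) do.call(rbind, errs)
  else data.frame(row = integer(0), field = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Read and write cohort CSV files
#'
#' The canonical cohort format is a comma-separated file with a schema
#' header comment line, one row per singleton pregnancy, and the documented
#' columns: maternal characteristics (`age` years, `weight` kg, `height` cm,
#' `ethnic_group`, `smoker`, `family_history_pe`, `conception`, `parity`,
#' `interpregnancy_interval` years — empty when nulliparous,
#' `chronic_hypertension`, `diabetes`, `sle_aps`, `ga_screening` weeks),
#' blood pressure (`sbp`, `dbp` mm Hg), biomarkers (`uta_pi`, `plgf` pg/mL),
#' and, when outcomes are known, `pe` (logical) and `ga_delivery` (weeks).
#' Missing values are empty fields. Semicolon or locale dialects are
#' rejected, not guessed.
#'
#' @param path CSV file path.
#' @param skip_invalid Drop invalid rows with a warning instead of aborting.
#' @return `read_cohort()` returns the validated cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) && grepl(";", first, fixed = TRUE))
    stop("semicolon-delimited files are not supported; expected CSV")
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                 na.strings = "")
  if (nrow(df) == 0) stop("cohort file contains no rows")
  missing_cols <- setdiff(COHORT_REQUIRED, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (f in intersect(COHORT_NUMERIC, names(df)))
    df[[f]] <- as.numeric(df[[f]])
  for (f in intersect(COHORT_LOGICAL, names(df)))
    df[[f]] <- as.logical(df[[f]])
  errs <- validate_cohort(df)
  if (nrow(errs)) {
    if (!skip_invalid) {
      stop(sprintf(
        "%d validation error(s); first: row %d, %s: %s",
        nrow(errs), errs$row[1], errs$field[1], errs$message[1]))
    }
    bad <- unique(errs$row)
    warning("dropping ", length(bad), " invalid row(s)")
    df <- df[-bad, , drop = FALSE]
    if (nrow(df) == 0) stop("no valid rows remain")
  }
  df
}

#' @rdname read_cohort
#' @param cohort A cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(COHORT_SCHEMA_HEADER, con)
  write.csv(cohort, con, row.names = FALSE, na = "")
  invisible(path)
}

params_hash <- function(params) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_params(params, tmp)
  unname(tools::md5sum(tmp))
}

run_manifest <- function(policy, params, n_read, n_scored, n_treated,
                         seed = NA, input = NA_character_) {
  stopifnot(n_treated <= n_scored)
  structure(list(
    package_version = as.character(packageVersion("pelower")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params_hash = params_hash(params),
    policy = unclass(policy),
    seed = seed,
    input = input,
    rows = list(read = n_read, scored = n_scored, treated = n_treated)
  ), class = "pe_manifest")
}

#' Run a counterfactual blood-pressure scenario
#'
#' The full analysis for one policy: score the cohort, apply the policy and
#' re-score treated pregnancies, aggregate into a scenario table, and
#' (optionally) write report files plus a run manifest recording the
#' parameter hash, policy, row counts and software version.
#'
#' @param cohort Cohort data frame (or path handled by [read_cohort()]).
#' @param policy A [pe_policy()] or built-in policy name.
#' @param params A `pe_params` object.
#' @param out_prefix Optional file-path prefix for report files; when given,
#'   `<prefix>.csv/.txt/.json` and `<prefix>-manifest.json` are written.
#' @param baseline Optional pre-computed [score_cohort()] result.
#' @return List of class `pe_scenario_run`: `table` ([scenario_table()]),
#'   `rescore` ([rescore_cohort()]), `manifest`, and `paths` when files were
#'   written.
#' @export
run_scenario <- function(cohort, policy, params = default_params(),
                         out_prefix = NULL, baseline = NULL) {
  input <- NA_character_
  if (is.character(cohort) && length(cohort) == 1) {
    input <- cohort
    cohort <- read_cohort(cohort)
  }
  if (is.character(policy)) policy <- builtin_policy(policy)
  rs <- rescore_cohort(cohort, policy, params, baseline = baseline)
  tab <- scenario_table(cohort, rs$baseline, rs$counterfactual, rs$treated)
  manifest <- run_manifest(policy, params, n_read = nrow(cohort),
                           n_scored = nrow(cohort),
                           n_treated = sum(rs$treated), input = input)
  paths <- NULL
  if (!is.null(out_prefix)) {
    paths <- write_scenario_report(tab, out_prefix)
    mpath <- paste0(out_prefix, "-manifest.json")
    jsonlite::write_json(unclass(manifest), mpath, auto_unbox = TRUE,
                         digits = NA, na = "null")
    paths <- c(paths, manifest = mpath)
  }
  structure(list(table = tab, rescore = rs, manifest = manifest,
                 paths = paths),
            class = "pe_scenario_run")
}

#' @export
print.pe_scenario_run <- function(x, ...) {
  print(x$rescore$policy)
  print(x$table)
  invisible(x)
}

#' Sweep a set of blood-pressure policies over one cohort
#'
#' Scores the cohort once, then evaluates each policy against the shared
#' baseline.
#'
#' @param cohort Cohort data frame.
#' @param policies List of [pe_policy()] objects or built-in names; default
#'   is the four policies studied.
#' @param params A `pe_params` object.
#' @return Named list of [run_scenario()] results.
#' @export
sweep_policies <- function(cohort,
                           policies = names(BUILTIN_POLICIES),
                           params = default_params()) {
  baseline <- score_cohort(cohort, params)
  out <- lapply(policies, function(p)
    run_scenario(cohort, p, params, baseline = baseline))
  names(out) <- vapply(policies, function(p)
    if (is.character(p)) p else
      sprintf("t%g-%g", p$dbp_threshold, p$dbp_target), character(1))
  out
}
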