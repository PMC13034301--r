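# Expected incidence and treatment-benefit summaries: expected case counts
# from decimal risks, relative/absolute risk reduction, number needed to
# treat, and scenario tables over gestational-age bands and cohort scopes.

BAND_IDS <- c("lt32", "lt34", "preterm_lt37", "term_ge37", "all")
BAND_RISK_COLS <- c(lt32 = "r_lt32", lt34 = "r_lt34",
                    preterm_lt37 = "r_lt37", term_ge37 = "r_term",
                    all = "r_all")

#' Expected number of cases from decimal risks
#'
#' The model-implied number of pre-eclampsia cases in a group is the sum of
#' the individual decimal risks.
#'
#' @param risks Numeric vector of probabilities in `[0, 1]`.
#' @return The sum of the risks (a decimal count).
#' @export
#' @examples
#' expected_count(c(0.1, 0.2, 0.3))
expected_count <- function(risks) {
  risks <- as.numeric(risks)
  if (any(is.na(risks)) || any(risks < 0 | risks > 1))
    stop("risks must be probabilities in [0, 1]")
  sum(risks)
}

#' Relative and absolute risk reduction and number needed to treat
#'
#' Given the expected case count without treatment (`e_untreated`), under
#' treatment (`e_treated`) and the number of pregnancies `n`:
#' \itemize{
#'   \item relative risk reduction `rrr = 100 * (e_u - e_t) / e_u` (percent;
#'     `NA` when `e_u = 0`),
#'   \item absolute risk reduction `arr = 100 * (e_u - e_t) / n` (percentage
#'     points),
#'   \item number needed to treat to benefit `nnt = n / (e_u - e_t)` (`NA`
#'     when the counts are equal).
#' }
#' `arr * nnt = 100` identically whenever both are defined.
#'
#' @param e_untreated,e_treated Expected decimal case counts (>= 0).
#' @param n Number of pregnancies in scope (> 0).
#' @return A list with numeric `rrr`, `arr`, `nnt`.
#' @export
#' @examples
#' risk_reduction_metrics(173, 118, 859)$nnt # 15.6 to one decimal place
risk_reduction_metrics <- function(e_untreated, e_treated, n) {
  if (n <= 0) stop("n must be > 0")
  if (e_untreated < 0 || e_treated < 0)
    stop("expected counts must be >= 0")
  diff <- e_untreated - e_treated
  list(
    rrr = if (e_untreated > 0) 100 * diff / e_untreated else NA_real_,
    arr = 100 * diff / n,
    nnt = if (diff != 0) n / diff else NA_real_
  )
}

observed_band_counts <- function(pe, ga_delivery) {
  c(lt32 = sum(pe & ga_delivery < 32),
    lt34 = sum(pe & ga_delivery < 34),
    preterm_lt37 = sum(pe & ga_delivery < 37),
    term_ge37 = sum(pe & ga_delivery >= 37),
    all = sum(pe))
}

#' Scenario table: observed, expected and counterfactual incidence by band
#'
#' Aggregates per-pregnancy band risks into a table with one row per
#' gestational-age band and scope (whole cohort and the treated subgroup):
#' the number of pregnancies in scope, the observed case count (when outcome
#' columns `pe` and `ga_delivery` are present in `cohort`), the expected
#' counts without and with treatment (sums of decimal risks), and the
#' relative risk reduction, absolute risk reduction and number needed to
#' treat computed from the unrounded sums. Counts and percentages are
#' rounded only for display by [format_scenario_table()].
#'
#' @param cohort Cohort data frame (outcome columns optional).
#' @param baseline_risks,counterfactual_risks [score_cohort()]-style data
#'   frames aligned with `cohort`.
#' @param treated Logical vector: treated under the policy.
#' @return A data frame of class `pe_scenario` with columns `scope`, `band`,
#'   `n`, `observed`, `expected_untreated`, `expected_treated`, `rrr`,
#'   `arr`, `nnt`.
#' @export
scenario_table <- function(cohort, baseline_risks, counterfactual_risks,
                           treated) {
  n <- nrow(cohort)
  if (nrow(baseline_risks) != n || nrow(counterfactual_risks) != n ||
      length(treated) != n)
    stop("cohort, risks and treated flags must be aligned")
  has_obs <- all(c("pe", "ga_delivery") %in% names(cohort))
  scopes <- list(whole_cohort = rep(TRUE, n), treated_subgroup = treated)
  rows <- list()
  for (scope in names(scopes)) {
    sel <- scopes[[scope]]
    obs <- if (has_obs && any(sel)) {
      observed_band_counts(as.logical(cohort$pe[sel]),
                           cohort$ga_delivery[sel])
    } else {
      setNames(rep(NA_real_, length(BAND_IDS)), BAND_IDS)
    }
    for (band in BAND_IDS) {
      col <- BAND_RISK_COLS[[band]]
      e_u <- expected_count(baseline_risks[[col]][sel])
      e_t <- expected_count(counterfactual_risks[[col]][sel])
      met <- if (sum(sel) > 0) risk_reduction_metrics(e_u, e_t, sum(sel))
             else list(rrr = NA_real_, arr = NA_real_, nnt = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, band = band, n = sum(sel), observed = obs[[band]],
        expected_untreated = e_u, expected_treated = e_t,
        rrr = met$rrr, arr = met$arr, nnt = met$nnt,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pe_scenario", "data.frame")
  out
}

#' Format a scenario table for display
#'
#' Renders a [scenario_table()] as aligned text in the layout of the study
#' report tables: rows are gestational-age bands, columns are the observed
#' count (with percent of scope), the expected count without and with
#' treatment, and the relative risk reduction. Counts are rounded to
#' integers and percentages to two decimals at display time only.
#'
#' @param tab A `pe_scenario` data frame.
#' @param scope `"whole_cohort"` or `"treated_subgroup"`.
#' @return A character vector of lines, invisibly printed by `cat()`-style
#'   callers.
#' @export
format_scenario_table <- function(tab, scope = "whole_cohort") {
  sub <- tab[tab$scope == scope, , drop = FALSE]
  n <- sub$n[1]
  labels <- c(lt32 = "  <32 weeks", lt34 = "  <34 weeks",
              preterm_lt37 = "Preterm (<37 weeks)",
              term_ge37 = "Term (>=37 weeks)", all = "All pre-eclampsia")
  fmt_cell <- function(count) {
    if (is.na(count)) return("-")
    sprintf("%d (%.2f)", round(count), 100 * count / n)
  }
  header <- sprintf("%-21s %-14s %-14s %-14s %8s", "Pre-eclampsia type",
                    "Observed", "Expected", "Treated", "RRR (%)")
  lines <- c(sprintf("Scope: %s (n=%d)", scope, n), header)
  order <- c("preterm_lt37", "lt32", "lt34", "term_ge37", "all")
  for (band in order) {
    r <- sub[sub$band == band, ]
    lines <- c(lines, sprintf(
      "%-21s %-14s %-14s %-14s %8.2f", labels[[band]],
      fmt_cell(r$observed), fmt_cell(r$expected_untreated),
      fmt_cell(r$expected_treated), r$rrr))
  }
  lines
}

#' @export
print.pe_scenario <- function(x, ...) {
  for (scope in unique(x$scope)) {
    cat(format_scenario_table(x, scope), sep = "\n")
    cat("\n")
  }
  invisible(x)
}

#' Write scenario report files
#'
#' Writes a [scenario_table()] as a CSV of unrounded values, an aligned-text
#' rendering per scope, and a JSON summary.
#'
#' @param tab A `pe_scenario` data frame.
#' @param path_prefix File-path prefix; `.csv`, `.txt` and `.json` are
#'   appended.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario_report <- function(tab, path_prefix) {
  paths <- c(csv = paste0(path_prefix, ".csv"),
             txt = paste0(path_prefix, ".txt"),
             json = paste0(path_prefix, ".json"))
  write.csv(tab, paths[["csv"]], row.names = FALSE)
  lines <- unlist(lapply(unique(tab$scope),
                         function(s) c(format_scenario_table(tab, s), "")))
  writeLines(lines, paths[["txt"]])
  jsonlite::write_json(split(tab[, -1], tab$scope), paths[["json"]],
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}
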