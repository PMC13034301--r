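test_that("expected counts are sums of decimal risks", {
  expect_equal(expected_count(c(0, 0, 0)), 0)
  expect_equal(expected_count(c(0.1, 0.2, 0.3)), 0.6)
  expect_equal(expected_count(rev(c(0.1, 0.2, 0.3))), 0.6)
  expect_error(expected_count(c(0.5, 1.2)), "probabilities")
})

test_that("expected counts match the Monte-Carlo event rate", {
  set.seed(314)
  risks <- runif(50, 0, 0.3)
  reps <- 20000L
  draws <- rbinom(length(risks) * reps, 1, rep(risks, times = reps))
  n_total <- length(draws)
  se <- sqrt(sum(risks * (1 - risks)) * reps) / n_total
  expect_lt(abs(mean(draws) - expected_count(risks) / length(risks)),
            3 * se)
})

test_that("risk-reduction metrics satisfy their identities", {
  m <- risk_reduction_metrics(100, 60, 1000)
  expect_equal(m$rrr, 40)
  expect_equal(m$arr, 4)
  expect_equal(m$nnt, 25)
  expect_equal(m$arr * m$nnt, 100, tolerance = 1e-6)

  same <- risk_reduction_metrics(50, 50, 200)
  expect_equal(same$rrr, 0)
  expect_equal(same$arr, 0)
  expect_true(is.na(same$nnt))

  zero <- risk_reduction_metrics(0, 0, 10)
  expect_true(is.na(zero$rrr))
  expect_error(risk_reduction_metrics(-1, 0, 10), ">= 0")
  expect_error(risk_reduction_metrics(1, 0, 0), "n must")
})

make_risks <- function(r32, r34, r37, rall) {
  data.frame(r_lt32 = r32, r_lt34 = r34, r_lt37 = r37,
             r_term = rall - r37, r_all = rall)
}

test_that("scenario tables reproduce hand arithmetic on a toy cohort", {
  co <- toy_cohort(4)
  co$pe <- c(TRUE, FALSE, FALSE, TRUE)
  co$ga_delivery <- c(33, 40, 39, 38)
  base <- make_risks(c(.01, .02, .005, .03), c(.02, .03, .01, .05),
                     c(.05, .08, .02, .10), c(.20, .25, .06, .40))
  cf <- base
  cf[4, ] <- make_risks(.02, .03, .06, .30) # row 4 treated
  treated <- c(FALSE, FALSE, FALSE, TRUE)

  tab <- scenario_table(co, base, cf, treated)
  wc_all <- tab[tab$scope == "whole_cohort" & tab$band == "all", ]
  expect_equal(wc_all$n, 4)
  expect_equal(wc_all$observed, 2)
  expect_equal(wc_all$expected_untreated, 0.91)
  expect_equal(wc_all$expected_treated, 0.81)
  expect_equal(wc_all$rrr, 100 * 0.10 / 0.91, tolerance = 1e-9)
  expect_equal(wc_all$nnt, 4 / 0.10, tolerance = 1e-9)

  tr_37 <- tab[tab$scope == "treated_subgroup" & tab$band == "preterm_lt37", ]
  expect_equal(tr_37$n, 1)
  expect_equal(tr_37$observed, 0)
  expect_equal(tr_37$expected_untreated, 0.10)
  expect_equal(tr_37$expected_treated, 0.06)

  # observed band assignment: preterm iff delivery < 37 weeks
  wc_pt <- tab[tab$scope == "whole_cohort" & tab$band == "preterm_lt37", ]
  wc_term <- tab[tab$scope == "whole_cohort" & tab$band == "term_ge37", ]
  expect_equal(wc_pt$observed, 1)
  expect_equal(wc_term$observed, 1)
})

test_that("scenario tables satisfy the structural invariants", {
  co <- random_cohort(300, seed = 8)
  p <- default_params()
  rs <- rescore_cohort(co, builtin_policy("t80"), p)
  tab <- scenario_table(co, rs$baseline, rs$counterfactual, rs$treated)

  for (scope in c("whole_cohort", "treated_subgroup")) {
    s <- tab[tab$scope == scope, ]
    e <- function(band, col) s[s$band == band, col]
    # band consistency: all = preterm + term, for both risk columns
    for (col in c("expected_untreated", "expected_treated")) {
      expect_equal(e("all", col),
                   e("preterm_lt37", col) + e("term_ge37", col),
                   tolerance = 1e-9)
    }
    ok <- !is.na(s$nnt)
    expect_equal(s$arr[ok] * s$nnt[ok], rep(100, sum(ok)),
                 tolerance = 1e-6)
  }
  # untreated rows contribute zero difference: whole-cohort reduction
  # equals treated-subgroup reduction exactly
  for (band in unique(tab$band)) {
    wc <- tab[tab$scope == "whole_cohort" & tab$band == band, ]
    tr <- tab[tab$scope == "treated_subgroup" & tab$band == band, ]
    expect_equal(wc$expected_untreated - wc$expected_treated,
                 tr$expected_untreated - tr$expected_treated,
                 tolerance = 1e-9)
  }

  # identical counterfactual: every rrr is zero
  tab0 <- scenario_table(co, rs$baseline, rs$baseline,
                         rep(TRUE, nrow(co)))
  expect_true(all(tab0$rrr == 0))

  # row order invariance
  perm <- sample(nrow(co))
  tab_p <- scenario_table(co[perm, ], rs$baseline[perm, ],
                          rs$counterfactual[perm, ], rs$treated[perm])
  expect_equal(tab_p$expected_untreated, tab$expected_untreated,
               tolerance = 1e-9)
  expect_equal(tab_p$rrr, tab$rrr, tolerance = 1e-9)
})

test_that("scenario reports render and write all formats", {
  co <- toy_cohort(4)
  co$pe <- c(TRUE, FALSE, FALSE, TRUE)
  co$ga_delivery <- c(33, 40, 39, 38)
  base <- make_risks(c(.01, .02, .005, .03), c(.02, .03, .01, .05),
                     c(.05, .08, .02, .10), c(.20, .25, .06, .40))
  tab <- scenario_table(co, base, base, c(FALSE, FALSE, FALSE, TRUE))
  lines <- format_scenario_table(tab, "whole_cohort")
  expect_true(any(grepl("All pre-eclampsia", lines)))

  prefix <- file.path(withr::local_tempdir(), "scenario")
  paths <- write_scenario_report(tab, prefix)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["csv"]])
  expect_equal(back$expected_untreated, tab$expected_untreated,
               tolerance = 1e-12)
  js <- jsonlite::read_json(paths[["json"]])
  expect_named(js, c("whole_cohort", "treated_subgroup"),
               ignore.order = TRUE)
})
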