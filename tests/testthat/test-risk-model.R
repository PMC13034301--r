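test_that("prior mean is additive in covariate effects", {
  p <- default_params()
  p$prior$intercept <- 52
  p$prior$effects <- list(
    categorical = c("chronic_hypertension" = -8,
                    "ethnic_group:black" = -3,
                    "smoker" = -2),
    linear = list()
  )
  ref <- reference_profile()
  expect_identical(prior_ga_mean(ref, p), 52)

  cht <- ref; cht$chronic_hypertension <- TRUE
  expect_identical(prior_ga_mean(cht, p), 44)

  both_a <- ref; both_a$ethnic_group <- "black"; both_a$smoker <- TRUE
  both_b <- ref; both_b$smoker <- TRUE; both_b$ethnic_group <- "black"
  expect_identical(prior_ga_mean(both_a, p), 47)
  expect_identical(prior_ga_mean(both_a, p), prior_ga_mean(both_b, p))
})

test_that("unknown categorical levels are rejected by name", {
  ref <- reference_profile()
  ref$ethnic_group <- "martian"
  expect_error(prior_ga_mean(ref, default_params()), "martian")
  expect_error(expected_log10_marker("MAP", ref, default_params()),
               "martian")
})

test_that("MoM regression is linear and round-trips through compute_mom", {
  p <- default_params()
  ref <- reference_profile()
  expect_equal(expected_log10_marker("MAP", ref, p), log10(85))

  heavier <- ref; heavier$weight <- ref$weight + 20
  c_w <- p$markers$MAP$regression$linear$weight$coef
  expect_equal(expected_log10_marker("MAP", heavier, p),
               log10(85) + 20 * c_w)

  e <- expected_log10_marker("PLGF", ref, p)
  expect_equal(compute_mom(10^e, e), 1)
  expect_error(expected_log10_marker("BMI", ref, p), "unknown marker")
})

test_that("compute_mom follows the multiples-of-median definition", {
  expect_equal(compute_mom(85, log10(85)), 1)
  expect_equal(compute_mom(170, log10(85)), 2)
  expect_equal(log10(compute_mom(85, log10(85))), 0)
  expect_error(compute_mom(-1, log10(85)), "> 0")
})

test_that("posterior reduces to the truncated prior without marker information", {
  p <- default_params()
  mu <- 58
  closed_form <- function(ct) {
    (pnorm(ct, mu, p$prior$sd) - pnorm(p$grid$min, mu, p$prior$sd)) /
      (1 - pnorm(p$grid$min, mu, p$prior$sd))
  }
  # no markers supplied
  b0 <- band_risks(posterior_ga_distribution(mu, p), p)
  expect_equal(b0$r_lt37, closed_form(37), tolerance = 1e-6)
  expect_equal(b0$r_all, closed_form(p$grid$max), tolerance = 1e-6)

  # all likelihood slopes zero: markers carry no information
  p0 <- p
  for (k in names(p0$markers)) p0$markers[[k]]$slope <- 0
  b1 <- band_risks(posterior_ga_distribution(
    mu, p0, c(MAP = 0.3, UTAPI = -0.2, PLGF = 0.4)), p0)
  expect_equal(b1$r_lt32, closed_form(32), tolerance = 1e-6)
  expect_equal(b1$r_all, b0$r_all, tolerance = 1e-9)
})

test_that("posterior mass is normalised and bands are nested (property)", {
  p <- default_params()
  set.seed(42)
  for (i in 1:25) {
    mu <- runif(1, 45, 70)
    moms <- c(MAP = rnorm(1, 0, 0.05), UTAPI = rnorm(1, 0, 0.15),
              PLGF = rnorm(1, 0, 0.2))
    keep <- sample(c(TRUE, FALSE), 3, replace = TRUE)
    dens <- posterior_ga_distribution(mu, p, moms[keep])
    expect_lt(abs(sum(dens$mass) + dens$p_beyond - 1), 1e-9)
    b <- band_risks(dens, p)
    expect_true(b$r_lt32 <= b$r_lt34 + 1e-15)
    expect_true(b$r_lt34 <= b$r_lt37 + 1e-15)
    expect_true(b$r_lt37 <= b$r_all + 1e-15)
    expect_lt(abs(b$r_all - (b$r_lt37 + b$r_term)), 1e-9)
    expect_true(b$r_all <= 1)
  }
})

test_that("elevated MAP MoM pulls the posterior earlier (brute-force check)", {
  p <- default_params()
  mu <- 55
  post_mean <- function(params, moms) {
    d <- posterior_ga_distribution(mu, params, moms)
    # mean over the grid part, conditional on pre-eclampsia
    sum(d$mid * d$mass) / sum(d$mass)
  }
  moms <- c(MAP = 0.08)
  m_default <- post_mean(p, moms)
  p_fine <- p; p_fine$grid$step <- p$grid$step / 10
  m_fine <- post_mean(p_fine, moms)
  prior_mean_trunc <- post_mean(p, numeric(0))
  expect_lt(m_default, prior_mean_trunc)
  expect_equal(m_default, m_fine, tolerance = 1e-4)
})

test_that("band risks integrate hand-built densities correctly", {
  p <- default_params()
  mids <- pelower:::grid_mids(p$grid)

  point <- function(at) {
    mass <- as.numeric(mids == mids[which.min(abs(mids - at))])
    list(mid = mids, mass = mass, p_beyond = 0)
  }
  b <- band_risks(point(30), p)
  expect_equal(c(b$r_lt32, b$r_lt34, b$r_lt37, b$r_all, b$r_term),
               c(1, 1, 1, 1, 0))

  beyond <- list(mid = mids, mass = rep(0, length(mids)), p_beyond = 1)
  b <- band_risks(beyond, p)
  expect_equal(c(b$r_lt32, b$r_lt34, b$r_lt37, b$r_term, b$r_all),
               rep(0, 5))

  uniform <- list(mid = mids,
                  mass = (mids >= 36 & mids <= 38) /
                    sum(mids >= 36 & mids <= 38),
                  p_beyond = 0)
  b <- band_risks(uniform, p)
  expect_equal(b$r_lt37, 0.5, tolerance = 1e-9)
  expect_equal(b$r_term, 0.5, tolerance = 1e-9)
  expect_equal(b$r_all, 1)
})

test_that("halving the grid step leaves band risks unchanged to 1e-4", {
  p <- default_params()
  moms <- c(MAP = 0.05, UTAPI = 0.1, PLGF = -0.15)
  r1 <- band_risks(posterior_ga_distribution(55, p, moms), p)$r_all
  p2 <- p; p2$grid$step <- p$grid$step / 2
  r2 <- band_risks(posterior_ga_distribution(55, p2, moms), p2)$r_all
  expect_lt(abs(r1 - r2), 1e-4)
})

test_that("grid posterior matches adaptive quadrature on random draws", {
  set.seed(99)
  edges_pool <- seq(30, 42, by = 0.05)
  for (i in 1:20) {
    p <- default_params()
    p$prior$intercept <- runif(1, 48, 66)
    p$prior$sd <- runif(1, 6, 12)
    for (k in names(p$markers)) {
      p$markers[[k]]$slope <- rnorm(1, 0, 0.02)
      p$markers[[k]]$changepoint <- sample(edges_pool, 1)
    }
    mu <- runif(1, 45, 68)
    moms <- c(MAP = rnorm(1, 0, 0.05), UTAPI = rnorm(1, 0, 0.15),
              PLGF = rnorm(1, 0, 0.2))
    moms <- moms[sample(c(TRUE, FALSE, TRUE), 3, replace = TRUE)]
    got <- band_risks(posterior_ga_distribution(mu, p, moms), p)
    want <- oracle_band_risks(mu, p, moms)
    for (f in names(want))
      expect_lt(abs(got[[f]] - want[[f]]), 1e-5,
                label = sprintf("draw %d field %s abs error", i, f))
  }
})

test_that("risk increases monotonically with MAP MoM under defaults", {
  p <- default_params()
  moms <- seq(-0.05, 0.1, by = 0.025)
  r <- vapply(moms, function(m)
    band_risks(posterior_ga_distribution(58, p, c(MAP = m)), p)$r_lt37,
    numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("vectorised cohort scoring agrees with the per-row posterior path", {
  co <- random_cohort(25, seed = 5)
  p <- default_params()
  scored <- score_cohort(co, p)
  for (i in c(1, 7, 25)) {
    b <- risk_profile(co[i, , drop = FALSE], p)
    expect_equal(scored$r_all[i], b$r_all, tolerance = 1e-12)
    expect_equal(scored$r_lt37[i], b$r_lt37, tolerance = 1e-12)
  }
  # missing markers take the marginalising path
  co$plgf[3] <- NA
  co$uta_pi[3] <- NA
  scored2 <- score_cohort(co, p)
  b3 <- band_risks(posterior_ga_distribution(
    scored2$mu[3], p, c(MAP = scored2$log10_mom_map[3])), p)
  expect_equal(scored2$r_all[3], b3$r_all, tolerance = 1e-12)
})

test_that("risk-vs-dbp profiles behave like the underlying model", {
  p <- default_params()
  low <- toy_cohort(1)                 # reference woman, low pressures
  high <- low
  high$chronic_hypertension <- TRUE
  high$sbp <- 150; high$dbp <- 95; high$plgf <- 20; high$uta_pi <- 2.2
  dbps <- seq(70, 95, by = 5)

  r_low <- risk_profile_vs_dbp(low, dbps, p)
  r_high <- risk_profile_vs_dbp(high, dbps, p)
  expect_true(all(diff(r_low$r_all) > 0))          # risk rises with dbp
  expect_true(all(r_high$r_all > r_low$r_all))     # high-risk curve above

  # a single point on the series equals the standard pipeline at that bp
  one <- risk_profile_vs_dbp(low, low$dbp, p)
  expect_equal(one$r_all, risk_profile(low, p)$r_all, tolerance = 1e-12)

  # non-informative likelihood gives a flat series
  p0 <- p
  for (k in names(p0$markers)) p0$markers[[k]]$slope <- 0
  flat <- risk_profile_vs_dbp(low, dbps, p0)
  expect_lt(diff(range(flat$r_all)), 1e-12)
})
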