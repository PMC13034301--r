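# Personalised competing-risks model for the gestational age at delivery
# with pre-eclampsia (PE). The prior N(mu, sigma^2), with mu shifted
# additively by maternal factors, is updated by Gaussian likelihoods for the
# observed biomarker log10 multiples-of-median and integrated over a
# gestational-age grid; mass beyond the grid maximum means no PE before
# delivery.

#' Prior mean gestational age at delivery with pre-eclampsia
#'
#' Evaluates the prior mean of the survival-time model: the intercept plus
#' additive shifts for maternal characteristics (negative shifts move the
#' distribution earlier, i.e. increase risk). Covariates absent from the
#' effect list contribute nothing.
#'
#' @param profile A one-row data frame (or cohort of rows) of maternal
#'   characteristics; see [read_cohort()] for the column schema.
#' @param params A [default_params()]-style `pe_params` object.
#' @return Numeric vector of prior means, in weeks, one per row.
#' @export
#' @examples
#' p <- default_params()
#' prior_ga_mean(reference_profile(), p)
prior_ga_mean <- function(profile, params) {
  check_levels(profile)
  linear_predictor(profile, params$prior$intercept, params$prior$effects)
}

#' Reference maternal profile
#'
#' A profile at the reference level of every covariate (white, parous with no
#' previous pre-eclampsia, spontaneous conception, no medical history) and at
#' the centring value of every continuous term, so that all prior and MoM
#' regression effects evaluate to zero. Useful as a test and documentation
#' baseline.
#'
#' @return A one-row data frame.
#' @export
reference_profile <- function() {
  data.frame(
    age = 31, weight = 69, height = 164,
    ethnic_group = "white", smoker = FALSE, family_history_pe = FALSE,
    conception = "spontaneous", parity = "parous_no_pe",
    interpregnancy_interval = 2.9,
    chronic_hypertension = FALSE, diabetes = "none", sle_aps = FALSE,
    ga_screening = 12.7,
    stringsAsFactors = FALSE
  )
}

#' Expected log10 biomarker value for a maternal profile
#'
#' The multiples-of-median denominator: the expected value of the marker on
#' the log10 scale given maternal characteristics, from the per-marker MoM
#' regression.
#'
#' @param marker_id One of `"MAP"`, `"UTAPI"`, `"PLGF"`.
#' @inheritParams prior_ga_mean
#' @return Numeric vector of expected log10 marker values.
#' @export
expected_log10_marker <- function(marker_id, profile, params) {
  if (!marker_id %in% MARKER_IDS)
    stop("unknown marker_id: ", marker_id)
  check_levels(profile)
  reg <- params$markers[[marker_id]]$regression
  linear_predictor(profile, reg$intercept, reg)
}

#' Multiple of the median
#'
#' @param observed Observed marker value (original units, > 0).
#' @param expected_log10 Expected log10 value for the individual's
#'   covariates, from [expected_log10_marker()].
#' @return MoM = observed / 10^expected_log10. The log10 MoM is
#'   `log10(compute_mom(...))`.
#' @export
#' @examples
#' compute_mom(170, log10(85)) # 2
compute_mom <- function(observed, expected_log10) {
  if (any(!is.na(observed) & observed <= 0))
    stop("observed marker values must be > 0")
  observed / 10^expected_log10
}

# Mean log10 MoM profile m_k(g): slope_k * (g - changepoint_k) below the
# changepoint, 0 at and beyond it. Returns a length(g) x 3 matrix.
marker_mean_log10mom <- function(g, params) {
  out <- vapply(MARKER_IDS, function(k) {
    m <- params$markers[[k]]
    m$slope * pmin(g - m$changepoint, 0)
  }, numeric(length(g)))
  matrix(out, nrow = length(g), dimnames = list(NULL, MARKER_IDS))
}

grid_mids <- function(grid) {
  seq(grid$min + grid$step / 2, grid$max - grid$step / 2, by = grid$step)
}

grid_edges <- function(grid) {
  seq(grid$min, grid$max, by = grid$step)
}

#' Posterior distribution of gestational age at delivery with pre-eclampsia
#'
#' Updates the truncated Gaussian prior on the gestational-age grid with the
#' multivariate Gaussian likelihood of the observed log10 MoM values.
#' Markers absent from `log10_moms` (or `NA`) are marginalised out of the
#' likelihood; the residual covariance is restricted to the present markers.
#' The cell mass at grid midpoint g is proportional to the exact prior mass
#' of the cell times the likelihood at g; the atom beyond the grid maximum
#' (no pre-eclampsia before delivery) uses the prior tail mass times the
#' likelihood at the censored regime, where all MoM means are zero.
#'
#' @param mu Prior mean in weeks (from [prior_ga_mean()]).
#' @param params A `pe_params` object.
#' @param log10_moms Named numeric vector of observed log10 MoM values; any
#'   subset of `c("MAP", "UTAPI", "PLGF")`.
#' @return An object of class `ga_density`: list with `mid` (grid
#'   midpoints), `mass` (normalised cell masses), `p_beyond` (atom mass) and
#'   `grid`.
#' @export
posterior_ga_distribution <- function(mu, params, log10_moms = numeric(0)) {
  stopifnot(is.finite(mu))
  grid <- params$grid
  mids <- grid_mids(grid)
  if (!length(mids)) stop("empty gestational-age grid")
  edges <- grid_edges(grid)
  prior_cell <- diff(pnorm(edges, mu, params$prior$sd))
  prior_beyond <- 1 - pnorm(grid$max, mu, params$prior$sd)

  log10_moms <- log10_moms[!is.na(log10_moms)]
  present <- intersect(MARKER_IDS, names(log10_moms))
  if (length(present)) {
    x <- log10_moms[present]
    sig <- params$sigma[present, present, drop = FALSE]
    a <- tryCatch(solve(sig), error = function(e)
      stop("residual covariance restricted to present markers is singular"))
    m <- marker_mean_log10mom(mids, params)[, present, drop = FALSE]
    dev <- sweep(-m, 2, x, "+")          # x - m(g), per grid point
    loglik <- -0.5 * rowSums((dev %*% a) * dev)
    loglik_beyond <- -0.5 * drop(x %*% a %*% x)
  } else {
    loglik <- rep(0, length(mids))
    loglik_beyond <- 0
  }
  top <- max(loglik, loglik_beyond)
  w <- prior_cell * exp(loglik - top)
  w_beyond <- prior_beyond * exp(loglik_beyond - top)
  tot <- sum(w) + w_beyond
  if (tot <= 0) stop("posterior has zero mass on the grid")
  structure(list(mid = mids, mass = w / tot, p_beyond = w_beyond / tot,
                 grid = grid),
            class = "ga_density")
}

#' Gestational-age band risks
#'
#' Integrates a normalised gestational-age density into the risk bands of
#' interest: pre-eclampsia with delivery before 32, 34 and 37 weeks, at term
#' (37 weeks up to the grid maximum), and at any gestation on the grid. Mass
#' beyond the grid maximum counts as no pre-eclampsia.
#'
#' @param density A `ga_density` object (or a list with `mid`, `mass`,
#'   `p_beyond`).
#' @param params A `pe_params` object (used for the band cut-offs).
#' @return An object of class `ga_risk_profile`: the density plus `r_lt32`,
#'   `r_lt34`, `r_lt37`, `r_term`, `r_all`.
#' @export
band_risks <- function(density, params) {
  cuts <- sort(params$band_cuts)
  mid <- density$mid
  mass <- density$mass
  r <- vapply(cuts, function(ct) sum(mass[mid < ct]), numeric(1))
  r_all <- sum(mass)
  structure(list(
    mid = mid, mass = mass, p_beyond = density$p_beyond,
    r_lt32 = r[[1]], r_lt34 = r[[2]], r_lt37 = r[[3]],
    r_term = r_all - r[[3]], r_all = r_all
  ), class = "ga_risk_profile")
}

#' @export
print.ga_risk_profile <- function(x, ...) {
  cat("Pre-eclampsia risk profile (competing-risks model)\n")
  cat(sprintf("  <32 wk: %8.6f   <34 wk: %8.6f   <37 wk: %8.6f\n",
              x$r_lt32, x$r_lt34, x$r_lt37))
  cat(sprintf("  term:   %8.6f   any:    %8.6f   (no PE: %8.6f)\n",
              x$r_term, x$r_all, x$p_beyond))
  invisible(x)
}

# log10 MoM panel for a cohort: MAP reconstructed from blood pressure,
# UtA-PI and PlGF from their columns; NA where a marker is missing.
cohort_log10_moms <- function(cohort, params) {
  map_obs <- mean_arterial_pressure(cohort$sbp, cohort$dbp)
  obs <- cbind(MAP = map_obs,
               UTAPI = as.numeric(cohort$uta_pi %||% rep(NA_real_, nrow(cohort))),
               PLGF = as.numeric(cohort$plgf %||% rep(NA_real_, nrow(cohort))))
  exp_log10 <- vapply(MARKER_IDS, expected_log10_marker,
                      numeric(nrow(cohort)),
                      profile = cohort, params = params)
  exp_log10 <- matrix(exp_log10, nrow = nrow(cohort),
                      dimnames = list(NULL, MARKER_IDS))
  log10(obs) - exp_log10
}

#' Score a cohort with the competing-risks model
#'
#' Computes, for every pregnancy, the prior mean, the biomarker log10 MoM
#' values (MAP is reconstructed from systolic and diastolic pressure), the
#' posterior gestational-age distribution, and the band risks. Rows with a
#' full marker panel are scored with a vectorised kernel; rows with missing
#' markers fall back to the per-row path, marginalising absent markers.
#'
#' @param cohort A cohort data frame; see [read_cohort()].
#' @param params A `pe_params` object.
#' @param chunk_size Rows per vectorised block (memory/time trade-off).
#' @return A data frame with one row per pregnancy: `mu`,
#'   `log10_mom_map/utapi/plgf`, and `r_lt32`, `r_lt34`, `r_lt37`, `r_term`,
#'   `r_all`.
#' @export
score_cohort <- function(cohort, params = default_params(),
                         chunk_size = 5000L) {
  validate_params(params)
  n <- nrow(cohort)
  mu <- prior_ga_mean(cohort, params)
  lmom <- cohort_log10_moms(cohort, params)

  grid <- params$grid
  mids <- grid_mids(grid)
  edges <- grid_edges(grid)
  cuts <- sort(params$band_cuts)
  idx <- lapply(cuts, function(ct) mids < ct)

  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL,
                                c("r_lt32", "r_lt34", "r_lt37",
                                  "r_term", "r_all")))
  full <- !apply(is.na(lmom), 1, any)

  if (any(full)) {
    a <- solve(params$sigma)
    m <- marker_mean_log10mom(mids, params)       # G x 3
    am <- a %*% t(m)                              # 3 x G
    mam <- colSums(t(m) * am)                     # G
    rows <- which(full)
    for (start in seq(1, length(rows), by = chunk_size)) {
      ri <- rows[start:min(start + chunk_size - 1L, length(rows))]
      x <- lmom[ri, , drop = FALSE]               # m x 3
      q <- rowSums((x %*% a) * x)                 # m
      cross <- x %*% am                           # m x G
      loglik <- -0.5 * (q - 2 * cross + rep(mam, each = length(ri)))
      loglik_beyond <- -0.5 * q
      top <- pmax(apply(loglik, 1, max), loglik_beyond)
      z <- pnorm(outer(rep(1, length(ri)), edges),
                 mean = mu[ri], sd = params$prior$sd)
      cell <- z[, -1, drop = FALSE] - z[, -ncol(z), drop = FALSE]
      w <- cell * exp(loglik - top)
      w_beyond <- (1 - z[, ncol(z)]) * exp(loglik_beyond - top)
      tot <- rowSums(w) + w_beyond
      r_all <- rowSums(w) / tot
      out[ri, "r_all"] <- r_all
      out[ri, "r_lt32"] <- rowSums(w[, idx[[1]], drop = FALSE]) / tot
      out[ri, "r_lt34"] <- rowSums(w[, idx[[2]], drop = FALSE]) / tot
      out[ri, "r_lt37"] <- rowSums(w[, idx[[3]], drop = FALSE]) / tot
      out[ri, "r_term"] <- r_all - out[ri, "r_lt37"]
    }
  }
  for (i in which(!full)) {
    lm_i <- lmom[i, ]
    dens <- posterior_ga_distribution(mu[i], params, lm_i[!is.na(lm_i)])
    b <- band_risks(dens, params)
    out[i, ] <- c(b$r_lt32, b$r_lt34, b$r_lt37, b$r_term, b$r_all)
  }
  data.frame(mu = mu,
             log10_mom_map = lmom[, "MAP"],
             log10_mom_utapi = lmom[, "UTAPI"],
             log10_mom_plgf = lmom[, "PLGF"],
             out)
}

#' Risk profile for one pregnancy
#'
#' Convenience wrapper: prior mean, MoM panel and posterior band risks for a
#' single row.
#'
#' @param profile A one-row cohort data frame including `sbp`, `dbp` and
#'   (optionally) `uta_pi`, `plgf`.
#' @param params A `pe_params` object.
#' @return A `ga_risk_profile`.
#' @export
risk_profile <- function(profile, params = default_params()) {
  stopifnot(nrow(profile) == 1)
  mu <- prior_ga_mean(profile, params)
  lmom <- drop(cohort_log10_moms(profile, params))
  band_risks(posterior_ga_distribution(mu, params, lmom[!is.na(lmom)]),
             params)
}

#' Risk of pre-eclampsia as a function of diastolic blood pressure
#'
#' Evaluates the overall pre-eclampsia risk for one pregnancy across a range
#' of diastolic blood pressures, with systolic pressure co-varying linearly
#' (`sbp(d) = sbp - sbp_ratio * (dbp - d)`) as in the intervention model, so
#' that the series traces the counterfactual risk attained by lowering (or
#' raising) diastolic pressure from its observed value.
#'
#' @param profile One-row cohort data frame (observed `sbp`, `dbp` included).
#' @param dbp_range Increasing numeric vector of diastolic pressures, mm Hg.
#' @param params A `pe_params` object.
#' @param sbp_ratio mm Hg systolic change per mm Hg diastolic change.
#' @return Data frame with `dbp`, `sbp`, `map` and `r_all`.
#' @export
risk_profile_vs_dbp <- function(profile, dbp_range,
                                params = default_params(),
                                sbp_ratio = 5.8 / 4.6) {
  stopifnot(nrow(profile) == 1, !is.unsorted(dbp_range))
  rows <- profile[rep(1, length(dbp_range)), , drop = FALSE]
  rows$sbp <- profile$sbp - sbp_ratio * (profile$dbp - dbp_range)
  rows$dbp <- dbp_range
  scored <- score_cohort(rows, params)
  data.frame(dbp = dbp_range, sbp = rows$sbp,
             map = mean_arterial_pressure(rows$sbp, rows$dbp),
             r_all = scored$r_all)
}
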