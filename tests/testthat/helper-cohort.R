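# Shared fixtures: tiny hand-built cohorts, randomised valid rows, an
# independent quadrature oracle for the posterior, and a cached default
# synthetic cohort reused by the slower end-to-end tests.

toy_cohort <- function(n = 4) {
  base <- reference_profile()
  cohort <- base[rep(1, n), , drop = FALSE]
  rownames(cohort) <- NULL
  cohort$sbp <- c(112, 125, 138, 150)[seq_len(n)]
  cohort$dbp <- c(68, 78, 88, 96)[seq_len(n)]
  cohort$uta_pi <- c(1.5, 1.7, 1.9, 2.3)[seq_len(n)]
  cohort$plgf <- c(45, 38, 30, 22)[seq_len(n)]
  cohort
}

random_cohort <- function(n, seed) {
  simulate_cohort(default_generator_config(n = n, seed = seed))
}

# Posterior band risks by adaptive quadrature, independent of the grid
# implementation: integrates prior density times likelihood piecewise
# between the grid bounds, band cuts and marker changepoints.
oracle_band_risks <- function(mu, params, log10_moms = numeric(0)) {
  grid <- params$grid
  marker_ids <- c("MAP", "UTAPI", "PLGF")
  present <- intersect(marker_ids, names(log10_moms))
  lik <- function(g) {
    if (!length(present)) return(rep(1, length(g)))
    sig <- params$sigma[present, present, drop = FALSE]
    a <- solve(sig)
    x <- log10_moms[present]
    vapply(g, function(gi) {
      m <- vapply(present, function(k) {
        mk <- params$markers[[k]]
        mk$slope * min(gi - mk$changepoint, 0)
      }, numeric(1))
      dev <- x - m
      exp(-0.5 * drop(dev %*% a %*% dev))
    }, numeric(1))
  }
  f <- function(g) stats::dnorm(g, mu, params$prior$sd) * lik(g)
  cps <- vapply(c("MAP", "UTAPI", "PLGF"),
                function(k) params$markers[[k]]$changepoint, numeric(1))
  knots <- sort(unique(c(grid$min, params$band_cuts, grid$max,
                         cps[cps > grid$min & cps < grid$max])))
  seg <- function(lo, hi) {
    pieces <- knots[knots > lo & knots < hi]
    bounds <- c(lo, pieces, hi)
    sum(vapply(seq_len(length(bounds) - 1), function(i)
      stats::integrate(f, bounds[i], bounds[i + 1],
                       rel.tol = 1e-12, abs.tol = 1e-14)$value,
      numeric(1)))
  }
  atom <- (1 - pnorm(grid$max, mu, params$prior$sd)) *
    (if (length(present)) {
      sig <- params$sigma[present, present, drop = FALSE]
      x <- log10_moms[present]
      exp(-0.5 * drop(x %*% solve(sig) %*% x))
    } else 1)
  cuts <- sort(params$band_cuts)
  m_lt <- vapply(cuts, function(ct) seg(grid$min, ct), numeric(1))
  m_all <- seg(grid$min, grid$max)
  tot <- m_all + atom
  list(r_lt32 = m_lt[1] / tot, r_lt34 = m_lt[2] / tot,
       r_lt37 = m_lt[3] / tot, r_term = (m_all - m_lt[3]) / tot,
       r_all = m_all / tot)
}

# Default 50,000-pregnancy cohort and its scores, computed once per test run.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_fixture <- function() {
  if (is.null(.acceptance_cache$cohort)) {
    cfg <- default_generator_config(n = 50000, seed = 20260926)
    .acceptance_cache$config <- cfg
    .acceptance_cache$cohort <- simulate_cohort(cfg)
    .acceptance_cache$scores <- score_cohort(.acceptance_cache$cohort,
                                             cfg$params)
  }
  list(config = .acceptance_cache$config,
       cohort = .acceptance_cache$cohort,
       scores = .acceptance_cache$scores)
}
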