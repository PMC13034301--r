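# Model parameters: prior survival-time model, biomarker MoM regressions,
# likelihood slopes/changepoints, residual covariance, integration grid.

MARKER_IDS <- c("MAP", "UTAPI", "PLGF")

ETHNIC_LEVELS <- c("white", "black", "south_asian", "east_asian", "mixed")
PARITY_LEVELS <- c("nulliparous", "parous_no_pe", "parous_prior_pe")
DIABETES_LEVELS <- c("none", "type1", "type2")
CONCEPTION_LEVELS <- c("spontaneous", "assisted")

CATEGORICAL_LEVELS <- list(
  ethnic_group = ETHNIC_LEVELS,
  parity       = PARITY_LEVELS,
  diabetes     = DIABETES_LEVELS,
  conception   = CONCEPTION_LEVELS
)

#' Default risk-model parameters
#'
#' Returns the full parameter set of the competing-risks pre-eclampsia model:
#' the Gaussian prior on gestational age at delivery with pre-eclampsia
#' (intercept, additive covariate shifts, standard deviation), per-marker
#' multiples-of-median regressions on the log10 scale, the piecewise-linear
#' likelihood means (slope and changepoint per marker), the 3x3 residual
#' covariance of the log10 MoM values, the integration grid, and the
#' gestational-age band cut-offs.
#'
#' The published coefficient estimates of the screening model this engine is
#' structured after are not public; the values returned here are documented
#' synthetic defaults, chosen so that a default synthetic cohort reproduces
#' incidences at the scale reported for large unselected screening
#' populations (about 0.8\% preterm and 2.1\% term pre-eclampsia) and so that
#' earlier pre-eclampsia corresponds to higher MAP and UtA-PI MoM and lower
#' PlGF MoM. All values are configurable; see [read_params()].
#'
#' Covariate effect terms are named either `"field:level"` for categorical
#' fields (reference levels `white`, `parous_no_pe`, `none`, `spontaneous`
#' carry no term) or `"field"` for logical fields; linear terms carry a
#' coefficient and a centring value.
#'
#' @return An object of class `pe_params` (a named list).
#' @export
#' @examples
#' p <- default_params()
#' p$prior$intercept
default_params <- function() {
  p <- list(
    prior = list(
      intercept = 63.4, # weeks; mean GA at delivery with PE, reference woman
      sd = 10,          # weeks
      effects = list(
        categorical = c(
          "chronic_hypertension"    = -9.0,
          "sle_aps"                 = -6.0,
          "smoker"                  = 0.5,
          "family_history_pe"      = -2.0,
          "ethnic_group:black"      = -3.0,
          "ethnic_group:south_asian" = -1.5,
          "ethnic_group:east_asian" = -0.5,
          "ethnic_group:mixed"      = -1.0,
          "parity:nulliparous"      = -1.5,
          "parity:parous_prior_pe"  = -7.0,
          "diabetes:type1"          = -6.0,
          "diabetes:type2"          = -4.0,
          "conception:assisted"     = -2.0
        ),
        linear = list(
          weight = list(coef = -0.07, center = 69),
          height = list(coef = 0.05, center = 164),
          age    = list(coef = -0.12, center = 31),
          interpregnancy_interval = list(coef = -0.2, center = 2.9)
        )
      )
    ),
    markers = list(
      MAP = list(
        regression = list(
          intercept = log10(85),
          categorical = c("chronic_hypertension" = 0.045,
                          "ethnic_group:black" = 0.005,
                          "smoker" = -0.004),
          linear = list(weight = list(coef = 0.0013, center = 69),
                        age = list(coef = 0.0006, center = 31))
        ),
        slope = -0.005,   # log10 MoM per week of (g - changepoint), g < g0
        changepoint = 42  # weeks; MoM mean is 0 at and beyond this gestation
      ),
      UTAPI = list(
        regression = list(
          intercept = log10(1.6),
          categorical = c("ethnic_group:black" = 0.02),
          linear = list(weight = list(coef = -0.0012, center = 69),
                        ga_screening = list(coef = -0.03, center = 12.7))
        ),
        slope = -0.018,
        changepoint = 42
      ),
      PLGF = list(
        regression = list(
          intercept = log10(40),
          categorical = c("ethnic_group:black" = 0.08,
                          "smoker" = 0.10),
          linear = list(weight = list(coef = -0.003, center = 69),
                        ga_screening = list(coef = 0.09, center = 12.7))
        ),
        slope = 0.025,
        changepoint = 42
      )
    ),
    sigma = NULL,          # filled below
    grid = list(min = 24, max = 42, step = 0.05),
    band_cuts = c(32, 34, 37)
  )
  sds <- c(MAP = 0.038, UTAPI = 0.120, PLGF = 0.170)
  cors <- diag(3)
  dimnames(cors) <- list(MARKER_IDS, MARKER_IDS)
  cors["MAP", "UTAPI"] <- cors["UTAPI", "MAP"] <- 0.05
  cors["MAP", "PLGF"] <- cors["PLGF", "MAP"] <- -0.05
  cors["UTAPI", "PLGF"] <- cors["PLGF", "UTAPI"] <- -0.15
  p$sigma <- diag(sds) %*% cors %*% diag(sds)
  dimnames(p$sigma) <- list(MARKER_IDS, MARKER_IDS)
  structure(p, class = "pe_params")
}

#' Validate a `pe_params` object
#'
#' Checks structural invariants: positive prior standard deviation, a
#' symmetric positive-definite residual covariance, an increasing grid whose
#' band cut-offs fall on grid cell edges inside `(min, max)`, and a positive
#' step.
#'
#' @param params A `pe_params` object.
#' @return `params`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_params <- function(params) {
  stopifnot(is.list(params))
  if (!is.numeric(params$prior$sd) || params$prior$sd <= 0)
    stop("prior$sd must be > 0")
  s <- params$sigma
  if (!is.matrix(s) || nrow(s) != 3 || ncol(s) != 3)
    stop("sigma must be a 3x3 matrix")
  if (max(abs(s - t(s))) > 1e-10) stop("sigma must be symmetric")
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("sigma must be positive definite")
  g <- params$grid
  if (g$step <= 0) stop("grid step must be > 0")
  if (g$min >= g$max) stop("grid min must be below grid max")
  cuts <- params$band_cuts
  if (any(cuts <= g$min) || any(cuts >= g$max))
    stop("band cut-offs must lie strictly inside the grid")
  off <- (cuts - g$min) / g$step
  if (any(abs(off - round(off)) > 1e-8))
    stop("band cut-offs must fall on grid cell edges")
  miss <- setdiff(MARKER_IDS, names(params$markers))
  if (length(miss))
    stop("missing marker definitions: ", paste(miss, collapse = ", "))
  invisible(params)
}

#' Read and write model parameters as YAML
#'
#' The full `pe_params` structure round-trips through a nested YAML file, one
#' section per component (`prior`, `markers`, `sigma`, `grid`, `band_cuts`).
#' A versioned default configuration ships with the package at
#' `system.file("extdata", "default-params.yaml", package = "pelower")`.
#'
#' @param path Path to a YAML parameter file.
#' @return `read_params()` returns a validated `pe_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$prior$effects$categorical <- unlist(raw$prior$effects$categorical) %||%
    numeric(0)
  for (k in names(raw$markers)) {
    cc <- raw$markers[[k]]$regression$categorical
    raw$markers[[k]]$regression$categorical <- unlist(cc) %||% numeric(0)
  }
  raw$sigma <- matrix(unlist(raw$sigma), 3, 3, byrow = TRUE,
                      dimnames = list(MARKER_IDS, MARKER_IDS))
  raw$band_cuts <- as.numeric(raw$band_cuts)
  params <- structure(raw, class = "pe_params")
  validate_params(params)
  params
}

#' @rdname read_params
#' @param params A `pe_params` object.
#' @export
write_params <- function(params, path) {
  out <- unclass(params)
  out$prior$effects$categorical <- as.list(out$prior$effects$categorical)
  for (k in names(out$markers)) {
    cc <- out$markers[[k]]$regression$categorical
    out$markers[[k]]$regression$categorical <- as.list(cc)
  }
  out$sigma <- lapply(seq_len(nrow(params$sigma)),
                      function(i) as.list(unname(params$sigma[i, ])))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.pe_params <- function(x, ...) {
  cat("Pre-eclampsia competing-risks model parameters\n")
  cat(sprintf("  prior: GA ~ N(%.2f + shifts, %.2f^2) weeks\n",
              x$prior$intercept, x$prior$sd))
  for (k in MARKER_IDS) {
    m <- x$markers[[k]]
    cat(sprintf("  %-5s: slope %+0.4f log10 MoM/week, changepoint %.1f wk\n",
                k, m$slope, m$changepoint))
  }
  cat(sprintf("  grid: [%.1f, %.1f] step %.3f weeks; band cuts %s\n",
              x$grid$min, x$grid$max, x$grid$step,
              paste(x$band_cuts, collapse = "/")))
  invisible(x)
}

# Evaluate intercept + categorical/logical offsets + centred linear terms for
# each row of a cohort-like data frame. `spec` holds $categorical (named
# numeric, "field:level" or "field") and $linear (field -> coef, center).
linear_predictor <- function(cohort, intercept, spec) {
  out <- rep(intercept, nrow(cohort))
  cats <- spec$categorical %||% numeric(0)
  for (term in names(cats)) {
    if (grepl(":", term, fixed = TRUE)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      x <- as.character(cohort[[parts[1]]]) == parts[2]
    } else {
      x <- as.logical(cohort[[term]])
    }
    x[is.na(x)] <- FALSE
    out <- out + cats[[term]] * x
  }
  for (field in names(spec$linear %||% list())) {
    lt <- spec$linear[[field]]
    x <- cohort[[field]]
    if (is.null(x)) next
    x <- as.numeric(x)
    x[is.na(x)] <- lt$center # e.g. interpregnancy interval when nulliparous
    out <- out + lt$coef * (x - lt$center)
  }
  out
}

# Reject unknown categorical levels with a named-level error.
check_levels <- function(cohort) {
  for (field in names(CATEGORICAL_LEVELS)) {
    if (is.null(cohort[[field]])) next
    lev <- unique(as.character(cohort[[field]]))
    bad <- setdiff(lev[!is.na(lev)], CATEGORICAL_LEVELS[[field]])
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s", field,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
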