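#' Fit the median-effect (Hill) model to single-agent dose response
#'
#' Least-squares fit of the log-linearized median-effect equation
#' \code{log(fa / (1 - fa)) = m * log(D) - m * log(Dm)}: \code{Dm} is the
#' dose of half-maximal effect (the IC50 when the effect is growth
#' inhibition) and \code{m} the sigmoidicity. Points with fa exactly 0 or 1
#' carry no information on the log-odds scale and are excluded with a count.
#'
#' @param doses Positive doses (uM).
#' @param fraction_affected Fraction-affected values in [0, 1].
#' @return Object of class \code{median_effect_fit}: \code{Dm}, \code{m},
#'   \code{r} (correlation of the log-linearized fit), \code{n_points}
#'   (usable points), \code{n_excluded}.
#' @export
fit_median_effect <- function(doses, fraction_affected) {
  stopifnot(length(doses) == length(fraction_affected))
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(fraction_affected < 0 | fraction_affected > 1)) {
    stop("fraction_affected must lie in [0, 1]")
  }
  usable <- fraction_affected > 0 & fraction_affected < 1
  n_excluded <- sum(!usable)
  d <- doses[usable]; fa <- fraction_affected[usable]
  if (length(d) < 2) stop("need at least 2 points with fa strictly in (0, 1)")
  x <- log(d); y <- log(fa / (1 - fa))
  fit <- stats::lm.fit(cbind(1, x), y)
  m <- unname(fit$coefficients[2])
  if (!is.finite(m) || m <= 0) {
    stop("median-effect slope must be positive; dose response is not ",
         "monotone increasing")
  }
  Dm <- exp(-unname(fit$coefficients[1]) / m)
  r <- if (stats::var(y) > 0) stats::cor(x, y) else 1
  structure(list(Dm = Dm, m = m, r = r, n_points = length(d),
                 n_excluded = n_excluded),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("Median-effect fit: Dm (IC50) = %.4g uM, m = %.4g, r = %.4f (%d points)\n",
              x$Dm, x$m, x$r, x$n_points))
  invisible(x)
}

#' Dose required for a given effect level under a median-effect fit
#'
#' \code{Dx(fa) = Dm * (fa / (1 - fa))^(1/m)}.
#'
#' @param fit A \code{median_effect_fit}.
#' @param fa Effect levels strictly inside (0, 1).
#' @return Doses, same length as \code{fa}.
#' @export
dose_for_effect <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly in (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index over a range of effect levels
#'
#' Non-constant-ratio combination index for a dose pair (d1, d2):
#' \code{CI(fa) = d1 / Dx1(fa) + d2 / Dx2(fa)}, where Dx is the single-agent
#' dose producing the effect level fa under each drug's median-effect fit.
#' CI < 1 indicates Loewe synergy, CI = 1 additivity, CI > 1 antagonism.
#'
#' @param fit_a,fit_b Single-agent \code{median_effect_fit}s.
#' @param d1,d2 Combination doses of drugs A and B (d2 = 0 degenerates to
#'   single-agent A).
#' @param fa_levels Effect levels to evaluate; default a grid spanning
#'   20%-80% growth inhibition.
#' @return data.frame with columns \code{fa} and \code{ci}.
#' @export
combination_index <- function(fit_a, fit_b, d1, d2,
                              fa_levels = seq(0.20, 0.80, by = 0.05)) {
  if (any(fa_levels <= 0 | fa_levels >= 1)) {
    stop("fa_levels must lie strictly in (0, 1)")
  }
  ci <- d1 / dose_for_effect(fit_a, fa_levels) +
    d2 / dose_for_effect(fit_b, fa_levels)
  data.frame(fa = fa_levels, ci = ci)
}

#' Classify a Bliss delta into the additivity/synergy bands
#'
#' Bands on the percentage-point delta (100 x (observed - expected)):
#' below -10 antagonism; -10 to 10 inclusive additive; above 10 up to 20
#' synergistic; above 20 markedly synergistic. The -10/+10 boundaries belong
#' to Additive and +20 to Synergistic (conservative toward additivity).
#'
#' @param delta_pct Numeric deltas in percentage points.
#' @return Character vector of class labels.
#' @export
classify_bliss <- function(delta_pct) {
  ifelse(delta_pct < -10, "Antagonism",
         ifelse(delta_pct <= 10, "Additive",
                ifelse(delta_pct <= 20, "Synergistic", "Markedly Synergistic")))
}

#' Bliss independence scoring of a combination checkerboard
#'
#' Under Bliss independence, two independently acting agents with
#' single-agent fraction-affected A and B combine to an expected effect
#' \code{A + B - A * B}. Each checkerboard cell is scored by
#' \code{delta_pct = 100 * (observed - expected)}; positive deltas indicate
#' synergy and negative antagonism. Replicate plates are averaged and the
#' SEM of the delta reported.
#'
#' @param single_a,single_b Single-agent fraction-affected margins, one value
#'   per dose of drug A (rows) and drug B (columns), in [0, 1].
#' @param combo A \code{dose_response_matrix} whose \code{effects} is a
#'   matrix, or a 3-d array with replicates in the third dimension.
#' @return data.frame of class \code{bliss_table}, one row per cell:
#'   \code{dose_a}, \code{dose_b}, \code{observed}, \code{expected},
#'   \code{delta_pct}, \code{sem_pct} (NA with one replicate), \code{class}.
#' @export
bliss_matrix <- function(single_a, single_b, combo) {
  stopifnot(inherits(combo, "dose_response_matrix"))
  if (any(single_a < 0 | single_a > 1) || any(single_b < 0 | single_b > 1)) {
    stop("single-agent effects must lie in [0, 1]")
  }
  eff <- combo$effects
  if (length(dim(eff)) == 2) eff <- array(eff, dim = c(dim(eff), 1))
  if (dim(eff)[1] != length(single_a) || dim(eff)[2] != length(single_b)) {
    stop("combination matrix dimensions do not match the single-agent margins")
  }
  n_rep <- dim(eff)[3]
  expected <- outer(single_a, single_b, function(a, b) a + b - a * b)
  obs_mean <- apply(eff, c(1, 2), mean)
  delta_rep <- sweep(eff, c(1, 2), expected) * 100
  sem <- if (n_rep > 1) {
    apply(delta_rep, c(1, 2), stats::sd) / sqrt(n_rep)
  } else {
    matrix(NA_real_, length(single_a), length(single_b))
  }
  delta <- 100 * (obs_mean - expected)
  res <- data.frame(
    dose_a = rep(combo$doses_a, times = length(combo$doses_b)),
    dose_b = rep(combo$doses_b, each = length(combo$doses_a)),
    observed = as.vector(obs_mean),
    expected = as.vector(expected),
    delta_pct = as.vector(delta),
    sem_pct = as.vector(sem),
    class = classify_bliss(as.vector(delta)),
    stringsAsFactors = FALSE)
  class(res) <- c("bliss_table", "data.frame")
  res
}

#' Normalize raw growth signal to fraction affected
#'
#' Growth inhibition relative to vehicle: \code{1 - treated / vehicle},
#' clipped to [0, 1].
#'
#' @param treated Raw treated-well signal (e.g. methylene-blue absorbance).
#' @param vehicle Vehicle-control signal (scalar or same shape).
#' @return Fraction affected in [0, 1].
#' @export
growth_inhibition <- function(treated, vehicle) {
  if (any(vehicle <= 0)) stop("vehicle signal must be positive")
  pmin(pmax(1 - treated / vehicle, 0), 1)
}
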