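# Marine-reservoir-corrected calibration of 14C determinations against a
# mixture of atmospheric and marine calibration curves weighted by the
# estimated marine diet fraction.

#' Construct a radiocarbon calibration curve
#'
#' @param grid Calendar ages (cal BP), strictly monotone; stored
#'   ascending.
#' @param mu Conventional 14C age (BP) at each grid point.
#' @param sigma 1-sigma curve uncertainty (14C years), `> 0` everywhere.
#' @param name Curve name.
#' @return A `cal_curve` object.
#' @export
cal_curve <- function(grid, mu, sigma, name = "curve") {
  stopifnot(length(grid) == length(mu), length(grid) == length(sigma))
  if (length(grid) < 2) stop("curve needs at least 2 grid points",
                             call. = FALSE)
  d <- diff(grid)
  if (!(all(d > 0) || all(d < 0))) {
    stop("curve grid must be strictly monotone", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("curve sigma must be > 0 everywhere",
                            call. = FALSE)
  o <- order(grid)
  structure(list(grid = grid[o], mu = mu[o], sigma = sigma[o], name = name),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve> %s: %d points, %.0f-%.0f cal BP\n",
              x$name, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Parse an IntCal-style calibration curve file
#'
#' Expects the distribution convention: comment lines starting with `#`,
#' then delimited columns with cal BP, 14C age BP and 1-sigma error as
#' the first three fields (comma or whitespace separated).
#'
#' @param path File path.
#' @param name Curve name; defaults to the file name.
#' @return A [cal_curve()].
#' @export
parse_curve <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("no data rows in curve file: ", path, call. = FALSE)
  }
  sep <- if (grepl(",", lines[1])) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           strip.white = TRUE)
  if (ncol(tab) < 3) {
    stop("curve file needs >= 3 columns (cal BP, 14C BP, sigma): ", path,
         call. = FALSE)
  }
  for (j in 1:3) {
    if (!is.numeric(tab[[j]])) {
      stop("non-numeric values in column ", j, " of ", path, call. = FALSE)
    }
  }
  cal_curve(tab[[1]], tab[[2]], tab[[3]], name)
}

# linear interpolation of mu and sigma at arbitrary cal BP
curve_at <- function(curve, calbp) {
  list(
    mu = stats::approx(curve$grid, curve$mu, calbp, rule = 1)$y,
    sigma = stats::approx(curve$grid, curve$sigma, calbp, rule = 1)$y
  )
}

#' A radiocarbon determination with its dietary marine fraction
#'
#' @param lab_id Laboratory identifier.
#' @param c14_age Conventional 14C age (BP).
#' @param sd Measurement error (14C years), `> 0`.
#' @param f_marine Fraction of marine carbon in the dated individual's
#'   diet, in \[0, 1\].
#' @param f_sd Standard deviation of `f_marine` (default 0: point
#'   estimate, matching common mixed-curve practice).
#' @return A `determination` object.
#' @export
determination <- function(lab_id, c14_age, sd, f_marine = 0, f_sd = 0) {
  if (sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  if (f_marine < 0 || f_marine > 1) {
    stop("`f_marine` must lie in [0, 1]", call. = FALSE)
  }
  if (f_sd < 0) stop("`f_sd` must be >= 0", call. = FALSE)
  structure(list(lab_id = lab_id, c14_age = c14_age, sd = sd,
                 f_marine = f_marine, f_sd = f_sd),
            class = "determination")
}

#' Local marine reservoir correction
#'
#' Offset of the local marine 14C reservoir from the global marine
#' calibration curve. The default (-83 +/- 34 14C years) is the local
#' value for the southeast Pacific used for Rapa Nui material.
#'
#' @param delta_r Reservoir offset (14C years).
#' @param sd Uncertainty (14C years), `>= 0`.
#' @return A `reservoir_correction` object.
#' @export
reservoir_correction <- function(delta_r = -83, sd = 34) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  structure(list(delta_r = delta_r, sd = sd), class = "reservoir_correction")
}

#' Mix atmospheric and marine calibration curves by diet fraction
#'
#' On the 1-year resampled intersection of the two grids:
#' `mu = (1-f) mu_atm + f (mu_mar + delta_r)` and
#' `sigma^2 = (1-f)^2 sigma_atm^2 + f^2 (sigma_mar^2 + sd_dr^2) +
#' (mu_mar + delta_r - mu_atm)^2 f_sd^2`. The reservoir offset is applied
#' to the marine curve before mixing. At `f = 0` the atmospheric curve is
#' returned unchanged (on the common grid); at `f = 1` with a zero
#' reservoir correction, the marine curve.
#'
#' @param atm,mar Atmospheric and marine [cal_curve()]s.
#' @param f Marine diet fraction in \[0, 1\].
#' @param f_sd Standard deviation of `f`.
#' @param dr A [reservoir_correction()].
#' @return The mixed [cal_curve()].
#' @export
mix_curves <- function(atm, mar, f, f_sd = 0, dr = reservoir_correction()) {
  stopifnot(inherits(atm, "cal_curve"), inherits(mar, "cal_curve"),
            inherits(dr, "reservoir_correction"))
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]", call. = FALSE)
  lo <- max(min(atm$grid), min(mar$grid))
  hi <- min(max(atm$grid), max(mar$grid))
  if (lo >= hi) stop("curves have disjoint cal BP ranges", call. = FALSE)
  grid <- seq(ceiling(lo), floor(hi), by = 1)
  a <- curve_at(atm, grid)
  m <- curve_at(mar, grid)
  mu_mar <- m$mu + dr$delta_r
  mu <- (1 - f) * a$mu + f * mu_mar
  var <- (1 - f)^2 * a$sigma^2 + f^2 * (m$sigma^2 + dr$sd^2) +
    (mu_mar - a$mu)^2 * f_sd^2
  cal_curve(grid, mu, sqrt(var),
            sprintf("%.0f%% %s + %.0f%% %s", 100 * (1 - f), atm$name,
                    100 * f, mar$name))
}

#' Calibrate a radiocarbon determination against a curve
#'
#' Posterior over calendar age theta on the curve's 1-year grid:
#' `p(theta) proportional to exp(-(age - mu(theta))^2 /
#' (2 (sd^2 + sigma(theta)^2)))`, normalized to sum to one. Intervals are
#' highest posterior density regions found by greedy mass accumulation
#' over grid years, reported in calendar years AD (`AD = 1950 - cal BP`).
#'
#' @param det A [determination()].
#' @param curve A [cal_curve()].
#' @param level Interval probability level, default `0.954`.
#' @return A `calibration_result`: list with `posterior` (tibble:
#'   `cal_bp`, `prob`), `intervals` (tibble: `from_ad`, `to_ad`, `mass`),
#'   `level`, and `truncated` (TRUE when > 0.1% of unnormalized mass sits
#'   on a grid edge, indicating the curve window clips the posterior).
#' @export
calibrate <- function(det, curve, level = 0.954) {
  stopifnot(inherits(det, "determination"), inherits(curve, "cal_curve"))
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)",
                                     call. = FALSE)
  grid <- seq(ceiling(min(curve$grid)), floor(max(curve$grid)), by = 1)
  cv <- curve_at(curve, grid)
  var <- det$sd^2 + cv$sigma^2
  loglik <- -0.5 * (det$c14_age - cv$mu)^2 / var - 0.5 * log(var)
  w <- exp(loglik - max(loglik))
  prob <- w / sum(w)
  truncated <- (prob[1] + prob[length(prob)]) > 0.001
  if (truncated) {
    warning("posterior mass at grid edge exceeds 0.1%; curve window may ",
            "truncate the date", call. = FALSE)
  }
  intervals <- hpd_intervals(grid, prob, level)
  structure(
    list(posterior = tibble::tibble(cal_bp = grid, prob = prob),
         intervals = intervals, level = level, truncated = truncated,
         curve = curve$name, lab_id = det$lab_id),
    class = "calibration_result"
  )
}

# greedy HPD: take grid years in decreasing probability until >= level,
# then merge adjacent years into intervals
hpd_intervals <- function(grid, prob, level) {
  o <- order(prob, decreasing = TRUE)
  cum <- cumsum(prob[o])
  n_in <- which(cum >= level)[1]
  if (is.na(n_in)) n_in <- length(prob)
  sel <- sort(grid[o[seq_len(n_in)]])
  breaks <- which(diff(sel) > 1)
  starts <- sel[c(1, breaks + 1)]
  ends <- sel[c(breaks, length(sel))]
  mass <- vapply(seq_along(starts), function(i) {
    sum(prob[grid >= starts[i] & grid <= ends[i]])
  }, numeric(1))
  # cal BP descending = AD ascending; from_ad <= to_ad
  tibble::tibble(from_ad = 1950 - ends, to_ad = 1950 - starts, mass = mass)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s on %s, %.1f%% intervals:\n",
              x$lab_id, x$curve, 100 * x$level))
  print(x$intervals, ...)
  invisible(x)
}

#' Diet-weighted mixed-curve calibration
#'
#' Builds the mixed calibration curve from the determination's marine
#' diet fraction, then calibrates against it. With `f_marine = 0` the
#' result is identical to plain atmospheric calibration.
#'
#' @param det A [determination()] carrying `f_marine` (and optionally
#'   `f_sd`).
#' @param atm,mar Atmospheric and marine [cal_curve()]s.
#' @param dr A [reservoir_correction()].
#' @param level Interval probability level.
#' @return A `calibration_result` with the `f_marine` used recorded in
#'   `$f_marine`.
#' @export
calibrate_with_diet <- function(det, atm, mar, dr = reservoir_correction(),
                                level = 0.954) {
  mixed <- mix_curves(atm, mar, det$f_marine, det$f_sd, dr)
  out <- calibrate(det, mixed, level)
  out$f_marine <- det$f_marine
  out
}
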