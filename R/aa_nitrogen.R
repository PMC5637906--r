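# Trophic-position and marine-fraction inference from d15N of glutamic
# acid (trophic amino acid) and phenylalanine (source amino acid), with
# first-order error propagation and the terrestrial end-member
# sensitivity sweep.

#' Constants parameterizing the glutamic acid / phenylalanine trophic model
#'
#' `beta` values are the d15N difference between glutamic acid and
#' phenylalanine in primary producers (aquatic photoautotrophs vs C3
#' vascular plants); `delta_glu_phe` is the per-trophic-step 15N
#' enrichment of glutamic acid over phenylalanine (TDF). The terrestrial
#' beta enters the trophic-position formulas with a positive sign
#' (+8.4 permil), the marine beta with its negative value (-3.4 permil).
#' Constant uncertainties default to zero and enter only the propagated
#' standard deviations, never the point estimates.
#'
#' @param beta_marine,beta_terrestrial Producer glu-phe offsets (permil).
#' @param delta_glu_phe Trophic discrimination factor (permil), `> 0`.
#' @param sd_beta_marine,sd_beta_terrestrial,sd_delta Uncertainties
#'   (permil), `>= 0`.
#' @return A `nitrogen_params` object.
#' @export
nitrogen_params <- function(beta_marine = -3.4,
                            beta_terrestrial = 8.4,
                            delta_glu_phe = 7.6,
                            sd_beta_marine = 0,
                            sd_beta_terrestrial = 0,
                            sd_delta = 0) {
  if (!(delta_glu_phe > 0)) stop("`delta_glu_phe` must be > 0", call. = FALSE)
  sds <- c(sd_beta_marine, sd_beta_terrestrial, sd_delta)
  if (any(sds < 0)) stop("constant uncertainties must be >= 0", call. = FALSE)
  structure(
    list(beta_marine = beta_marine, beta_terrestrial = beta_terrestrial,
         delta_glu_phe = delta_glu_phe,
         sd_beta_marine = sd_beta_marine,
         sd_beta_terrestrial = sd_beta_terrestrial,
         sd_delta = sd_delta),
    class = "nitrogen_params"
  )
}

#' Paired glutamic acid / phenylalanine d15N measurement
#'
#' @param d15n_glu,d15n_phe Consumer d15N of glutamic acid and
#'   phenylalanine (permil).
#' @param sd_glu,sd_phe Analytical standard deviations (permil), `>= 0`.
#' @return A `paired_delta` object.
#' @export
paired_delta <- function(d15n_glu, sd_glu = 0, d15n_phe, sd_phe = 0) {
  if (any(c(sd_glu, sd_phe) < 0)) stop("sds must be >= 0", call. = FALSE)
  structure(
    list(d15n_glu = d15n_glu, sd_glu = sd_glu,
         d15n_phe = d15n_phe, sd_phe = sd_phe),
    class = "paired_delta"
  )
}

#' Global human trophic level reference
#'
#' The empirical average global human trophic level derived from FAO food
#' supply data is 2.21, ranging 2.04 to 2.76 across national diets.
#'
#' @param level Trophic level to assume, default `2.21`.
#' @param lo,hi Reference range bounds.
#' @param sd Uncertainty on `level` used in propagation, default `0`.
#' @return An `htl_spec` object.
#' @export
htl_spec <- function(level = 2.21, lo = 2.04, hi = 2.76, sd = 0) {
  if (!(lo <= level && level <= hi)) {
    stop("`level` must lie in [lo, hi]", call. = FALSE)
  }
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  structure(list(level = level, lo = lo, hi = hi, sd = sd),
            class = "htl_spec")
}

tp_result <- function(tp, sd, assumption) {
  structure(list(tp = tp, sd = sd, assumption = assumption),
            class = "tp_result")
}

#' @export
print.tp_result <- function(x, ...) {
  cat(sprintf("<tp_result> TP = %.2f +/- %.2f (%s diet)\n",
              x$tp, x$sd, x$assumption))
  invisible(x)
}

f_marine_result <- function(f, sd, method) {
  structure(list(f = f, sd = sd, method = method,
                 feasible = f >= 0 & f <= 1),
            class = "f_marine_result")
}

#' @export
print.f_marine_result <- function(x, ...) {
  cat(sprintf("<f_marine_result> f = %.2f +/- %.2f (%s)%s\n",
              x$f, x$sd, x$method,
              if (all(x$feasible)) "" else " [mass balance violated]"))
  invisible(x)
}

#' Trophic position assuming a fully marine diet
#'
#' `TP = (d15N_glu - d15N_phe + beta_marine) / Delta + 1`, with the
#' standard deviation by first-order propagation over the two measured
#' values and both constants.
#'
#' @param p A [paired_delta()].
#' @param k A [nitrogen_params()].
#' @return A `tp_result`.
#' @export
tp_marine <- function(p, k = nitrogen_params()) {
  stopifnot(inherits(p, "paired_delta"), inherits(k, "nitrogen_params"))
  tp_from_beta(p, k, k$beta_marine, k$sd_beta_marine, "marine")
}

#' Trophic position assuming a fully terrestrial (C3 plant) diet
#'
#' `TP = (d15N_glu - d15N_phe + beta_terrestrial) / Delta + 1` with
#' `beta_terrestrial = +8.4` permil by default.
#'
#' @inheritParams tp_marine
#' @return A `tp_result`.
#' @export
tp_terrestrial <- function(p, k = nitrogen_params()) {
  stopifnot(inherits(p, "paired_delta"), inherits(k, "nitrogen_params"))
  tp_from_beta(p, k, k$beta_terrestrial, k$sd_beta_terrestrial, "terrestrial")
}

tp_from_beta <- function(p, k, beta, sd_beta, assumption) {
  d <- k$delta_glu_phe
  num <- p$d15n_glu - p$d15n_phe + beta
  tp <- num / d + 1
  # partials: d/dglu = 1/D, d/dphe = -1/D, d/dbeta = 1/D, d/dDelta = -num/D^2
  var <- (p$sd_glu^2 + p$sd_phe^2 + sd_beta^2) / d^2 +
    (num / d^2)^2 * k$sd_delta^2
  tp_result(tp, sqrt(var), assumption)
}

#' Trophic position for a mixed marine/terrestrial diet
#'
#' `TP = (d15N_glu - d15N_phe + (1-f) beta_terr + f beta_mar) / Delta + 1`.
#' At `f = 0` this reproduces [tp_terrestrial()], at `f = 1`
#' [tp_marine()]. The propagated sd includes the uncertainty of `f`.
#'
#' @inheritParams tp_marine
#' @param f Marine protein fraction, in \[0, 1\].
#' @param f_sd Standard deviation of `f`, `>= 0`.
#' @return A `tp_result`.
#' @export
tp_mixed <- function(p, f, k = nitrogen_params(), f_sd = 0) {
  stopifnot(inherits(p, "paired_delta"), inherits(k, "nitrogen_params"))
  if (any(f < 0 | f > 1)) stop("`f` must lie in [0, 1]", call. = FALSE)
  if (any(f_sd < 0)) stop("`f_sd` must be >= 0", call. = FALSE)
  d <- k$delta_glu_phe
  beta_mix <- (1 - f) * k$beta_terrestrial + f * k$beta_marine
  num <- p$d15n_glu - p$d15n_phe + beta_mix
  tp <- num / d + 1
  var <- (p$sd_glu^2 + p$sd_phe^2 +
            ((1 - f) * k$sd_beta_terrestrial)^2 +
            (f * k$sd_beta_marine)^2 +
            ((k$beta_marine - k$beta_terrestrial) * f_sd)^2) / d^2 +
    (num / d^2)^2 * k$sd_delta^2
  tp_result(tp, sqrt(var), "mixed")
}

#' Marine fraction implied by an assumed human trophic level
#'
#' Solves the mixed-diet trophic position equation for the marine
#' fraction at an assumed consumer trophic level:
#' `f = (Delta (TP - 1) + d15N_phe - d15N_glu - beta_terr) /
#'      (beta_mar - beta_terr)`.
#'
#' @inheritParams tp_marine
#' @param htl An [htl_spec()] giving the assumed trophic level.
#' @return An `f_marine_result` with `method = "htl"`.
#' @export
f_marine_htl <- function(p, htl = htl_spec(), k = nitrogen_params()) {
  stopifnot(inherits(p, "paired_delta"), inherits(htl, "htl_spec"),
            inherits(k, "nitrogen_params"))
  if (k$beta_marine == k$beta_terrestrial) {
    stop("degenerate model: beta_marine equals beta_terrestrial",
         call. = FALSE)
  }
  d <- k$delta_glu_phe
  den <- k$beta_marine - k$beta_terrestrial
  num <- d * (htl$level - 1) + p$d15n_phe - p$d15n_glu - k$beta_terrestrial
  f <- num / den
  # partials of f = num/den:
  #   d/dglu = -1/den ; d/dphe = 1/den ; d/dDelta = (TP-1)/den
  #   d/dTP  = Delta/den
  #   d/dbeta_terr = (num - den)/den^2   (num depends on -beta_terr,
  #                                       den on -beta_terr)
  #   d/dbeta_mar  = -num/den^2
  var <- (p$sd_glu^2 + p$sd_phe^2 +
            ((htl$level - 1) * k$sd_delta)^2 +
            (d * htl$sd)^2 +
            ((num - den) / den * k$sd_beta_terrestrial)^2 +
            (num / den * k$sd_beta_marine)^2) / den^2
  f_marine_result(f, sqrt(var), "htl")
}

#' Invert the phenylalanine mass balance for the terrestrial end member
#'
#' A consumer's phenylalanine d15N is a linear mix of its marine and
#' terrestrial baselines; given the consumer value, a marine fraction and
#' the marine end member, the implied terrestrial end member is
#' `(phe_consumer - f * phe_marine) / (1 - f)`.
#'
#' @param phe_consumer Consumer d15N_phe (permil).
#' @param f Marine fraction, `< 1`.
#' @param phe_marine Marine end-member d15N_phe (permil).
#' @return Implied terrestrial end-member d15N_phe (permil).
#' @export
infer_terrestrial_endmember <- function(phe_consumer, f, phe_marine) {
  if (any(f >= 1)) {
    stop("`f` must be < 1: a fully marine consumer carries no terrestrial signal",
         call. = FALSE)
  }
  (phe_consumer - f * phe_marine) / (1 - f)
}

#' Marine fraction from phenylalanine d15N two-source mass balance
#'
#' `f = (phe_consumer - terr) / (mar - terr)` between the terrestrial and
#' marine phenylalanine baselines, with the two-source propagated sd. The
#' defaults carry the archaeological totora reed (22.7 +/- 0.9 permil)
#' and the lowest measured marine fish (0.4 +/- 0.6 permil).
#'
#' @param phe_consumer Consumer d15N_phe (permil); vectorized.
#' @param phe_sd Consumer analytical sd (permil).
#' @param terr,mar [end_member()]s on the d15N_phe scale.
#' @return An `f_marine_result` with `method = "phe"`.
#' @export
f_marine_phe <- function(phe_consumer, phe_sd = 0,
                         terr = end_member(22.7, 0.9, label = "totora reed"),
                         mar = end_member(0.4, 0.6, label = "lowest fish")) {
  check_mixing_pair(terr, mar)
  if (any(phe_sd < 0)) stop("`phe_sd` must be >= 0", call. = FALSE)
  f <- (phe_consumer - terr$mean) / (mar$mean - terr$mean)
  sd <- two_source_sd(phe_consumer, phe_sd, terr$mean, terr$sd,
                      mar$mean, mar$sd)
  f_marine_result(f, sd, "phe")
}

#' Monte Carlo check of a propagated standard deviation
#'
#' Draws independent Gaussian inputs and pushes them through one of the
#' five estimators; the empirical sd of the outputs is the reference the
#' analytic (delta-method) sds are validated against in the test suite.
#'
#' @param estimator One of `"tp_marine"`, `"tp_terrestrial"`,
#'   `"tp_mixed"`, `"f_marine_htl"`, `"f_marine_phe"`.
#' @param p A [paired_delta()] (ignored for `"f_marine_phe"`).
#' @param k A [nitrogen_params()].
#' @param n Number of draws.
#' @param f,f_sd Marine fraction and sd (for `"tp_mixed"`).
#' @param htl An [htl_spec()] (for `"f_marine_htl"`).
#' @param phe_consumer,phe_sd,terr,mar Inputs for `"f_marine_phe"`.
#' @return Empirical standard deviation of the estimator output.
#' @export
monte_carlo_sd <- function(estimator, p = NULL, k = nitrogen_params(),
                           n = 1e6, f = 0.5, f_sd = 0, htl = htl_spec(),
                           phe_consumer = NULL, phe_sd = 0,
                           terr = NULL, mar = NULL) {
  draw <- function(mean, sd) stats::rnorm(n, mean, sd)
  if (estimator == "f_marine_phe") {
    x <- draw(phe_consumer, phe_sd)
    t <- draw(terr$mean, terr$sd)
    m <- draw(mar$mean, mar$sd)
    return(stats::sd((x - t) / (m - t)))
  }
  glu <- draw(p$d15n_glu, p$sd_glu)
  phe <- draw(p$d15n_phe, p$sd_phe)
  bm <- draw(k$beta_marine, k$sd_beta_marine)
  bt <- draw(k$beta_terrestrial, k$sd_beta_terrestrial)
  dl <- draw(k$delta_glu_phe, k$sd_delta)
  out <- switch(
    estimator,
    tp_marine = (glu - phe + bm) / dl + 1,
    tp_terrestrial = (glu - phe + bt) / dl + 1,
    tp_mixed = {
      fs <- draw(f, f_sd)
      (glu - phe + (1 - fs) * bt + fs * bm) / dl + 1
    },
    f_marine_htl = {
      tp <- draw(htl$level, htl$sd)
      (dl * (tp - 1) + phe - glu - bt) / (bm - bt)
    },
    stop("unknown estimator: ", estimator, call. = FALSE)
  )
  stats::sd(out)
}

#' Sensitivity of marine fraction and mixed trophic position to the
#' terrestrial phenylalanine end member
#'
#' For each candidate terrestrial end-member value the sweep recomputes
#' the phenylalanine marine fraction and the mixed-diet trophic position
#' for a human and a rat average, flags rows violating mass balance
#' (f outside \[0, 1\]) and rows where the rat's mixed trophic position
#' falls below 2.0 (impossible for an omnivorous rat, so those
#' end-member solutions are excluded).
#'
#' @param p_human,p_rat [paired_delta()] averages for humans and rats.
#' @param terr_grid Candidate terrestrial d15N_phe end members (permil),
#'   all above the marine end member.
#' @param mar_em Marine [end_member()] on the d15N_phe scale.
#' @param k A [nitrogen_params()].
#' @param terr_sd sd attached to each grid value (permil).
#' @param rat_tp_floor Minimum admissible rat mixed trophic position.
#' @return A tibble with one row per (grid value, species).
#' @export
sensitivity_sweep <- function(p_human, p_rat, terr_grid,
                              mar_em = end_member(1.0, 0.9,
                                                  label = "average fish"),
                              k = nitrogen_params(), terr_sd = 0.9,
                              rat_tp_floor = 2.0) {
  if (length(terr_grid) == 0) stop("empty terrestrial grid", call. = FALSE)
  if (any(terr_grid <= mar_em$mean)) {
    stop("grid values must exceed the marine end member", call. = FALSE)
  }
  one_species <- function(species, p) {
    rows <- lapply(terr_grid, function(tv) {
      fm <- f_marine_phe(p$d15n_phe, p$sd_phe,
                         terr = end_member(tv, terr_sd),
                         mar = mar_em)
      f_clip <- min(max(fm$f, 0), 1)  # TP evaluated at the nearest feasible f
      tp <- tp_mixed(p, f_clip, k, f_sd = fm$sd)
      tibble::tibble(
        terr_phe = tv, species = species,
        f_marine = fm$f, f_sd = fm$sd,
        tp_mixed = tp$tp, tp_sd = tp$sd,
        mass_balance_ok = fm$feasible
      )
    })
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(one_species("human", p_human),
                          one_species("rat", p_rat))
  # flag grid rows whose rat solution is below the omnivory floor
  rat_by_terr <- out[out$species == "rat", c("terr_phe", "tp_mixed")]
  floor_ok <- rat_by_terr$tp_mixed[match(out$terr_phe, rat_by_terr$terr_phe)] >=
    rat_tp_floor
  out$rat_floor_ok <- floor_ok
  out
}
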