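# Synthetic food-web generator: forward models of the nitrogen
# mass-balance equations, the four-cluster EAA fingerprint structure,
# and bulk collagen mixing, with the ground truth emitted alongside so
# every estimator can be tested for parameter recovery.

#' Specification of a synthetic isotope food web
#'
#' Defaults reproduce the study conditions the estimators assume: a
#' marine phenylalanine baseline near 0-1 permil, a manipulated-soil
#' terrestrial baseline near 22.7 permil, a 7.6 permil per-step trophic
#' enrichment of glutamic acid over phenylalanine, analytical replicate
#' sds of 0.41 permil (nitrogen) and 0.38 permil (carbon), and four EAA
#' d13C source clusters (two marine, two plant).
#'
#' @param seed Integer seed; all simulation is deterministic given it.
#' @param marine_phe_em,terr_phe_em `c(mean, sd)` of the marine and
#'   terrestrial phenylalanine d15N end members (permil).
#' @param trophic_step Per-trophic-step glu-phe enrichment (permil).
#' @param beta_mar,beta_terr Producer glu-phe offsets (permil).
#' @param analytical_sd_n,analytical_sd_c Analytical replicate sds
#'   (permil) for nitrogen and carbon.
#' @param n_per_group Training samples per EAA source group.
#' @param consumer_f_true Vector of true marine fractions, one consumer
#'   each, all in \[0, 1\].
#' @param consumer_tp_true True trophic positions; `NULL` samples each
#'   uniformly from the empirical global human range \[2.04, 2.76\].
#' @param eaa_group_means Named list mapping group label to a named,
#'   zero-sum vector of centered per-EAA d13C means (permil).
#' @param eaa_sd Within-group EAA scatter (permil).
#' @return A `food_web_spec` object.
#' @export
food_web_spec <- function(seed = 1,
                          marine_phe_em = c(0.4, 0.6),
                          terr_phe_em = c(22.7, 0.9),
                          trophic_step = 7.6,
                          beta_mar = -3.4,
                          beta_terr = 8.4,
                          analytical_sd_n = 0.41,
                          analytical_sd_c = 0.38,
                          n_per_group = 8,
                          consumer_f_true = rep(0.5, 10),
                          consumer_tp_true = NULL,
                          eaa_group_means = default_eaa_group_means(),
                          eaa_sd = 0.38) {
  stopifnot(marine_phe_em[2] >= 0, terr_phe_em[2] >= 0,
            analytical_sd_n >= 0, analytical_sd_c >= 0, eaa_sd >= 0,
            n_per_group >= 2)
  if (any(consumer_f_true < 0 | consumer_f_true > 1)) {
    stop("`consumer_f_true` must lie in [0, 1]", call. = FALSE)
  }
  for (g in names(eaa_group_means)) {
    if (abs(sum(eaa_group_means[[g]])) > 1e-9) {
      stop("group means must be centered (sum to 0): ", g, call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), marine_phe_em = marine_phe_em,
         terr_phe_em = terr_phe_em, trophic_step = trophic_step,
         beta_mar = beta_mar, beta_terr = beta_terr,
         analytical_sd_n = analytical_sd_n,
         analytical_sd_c = analytical_sd_c,
         n_per_group = n_per_group,
         consumer_f_true = consumer_f_true,
         consumer_tp_true = consumer_tp_true,
         eaa_group_means = eaa_group_means, eaa_sd = eaa_sd),
    class = "food_web_spec"
  )
}

#' Default centered EAA d13C means of the four synthetic source groups
#'
#' Two marine and two plant clusters, well separated in the
#' leucine/phenylalanine/valine subspace, each vector summing to zero.
#' @return Named list of named numeric vectors (permil).
#' @export
default_eaa_group_means <- function() {
  list(
    `Marine-I`  = c(Leu = -1.0, Lys = 2.0, Phe = -2.5, Val = 1.5),
    `Marine-II` = c(Leu = 1.5, Lys = 0.5, Phe = -3.0, Val = 1.0),
    `Plant-I`   = c(Leu = -2.0, Lys = -1.0, Phe = 3.5, Val = -0.5),
    `Plant-II`  = c(Leu = 0.5, Lys = -2.0, Phe = 2.0, Val = -0.5)
  )
}

with_spec_seed <- function(spec, offset, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed + offset)
  force(code)
}

#' Simulate paired glu/phe d15N consumers with known marine fractions
#'
#' Forward model: each consumer's phenylalanine baseline is the convex
#' mix `f * marine + (1-f) * terrestrial` of end-member draws; glutamic
#' acid is then set so the mixed-diet trophic position equation holds
#' exactly at (`f_true`, `tp_true`); Gaussian analytical noise is added
#' to both amino acids last. With zero noise every estimator inverts the
#' simulation exactly.
#'
#' @param spec A [food_web_spec()].
#' @return A list with `samples` (a `sample_set` of consumers plus the
#'   two end-member producer reference rows) and `truth` (tibble:
#'   `sample_id`, `f_true`, `tp_true`, `phe_baseline`).
#' @export
simulate_nitrogen <- function(spec) {
  stopifnot(inherits(spec, "food_web_spec"))
  n <- length(spec$consumer_f_true)
  with_spec_seed(spec, 0L, {
    f <- spec$consumer_f_true
    tp <- spec$consumer_tp_true
    if (is.null(tp)) tp <- stats::runif(n, 2.04, 2.76)
    stopifnot(length(tp) == n)
    # per-consumer baseline: end-member means (population scatter enters
    # through the end-member sds only when drawing producers)
    phe_base <- f * spec$marine_phe_em[1] + (1 - f) * spec$terr_phe_em[1]
    beta_mix <- (1 - f) * spec$beta_terr + f * spec$beta_mar
    # invert the mixed TP equation for glu
    glu_true <- (tp - 1) * spec$trophic_step - beta_mix + phe_base
    noise <- spec$analytical_sd_n
    phe_obs <- phe_base + stats::rnorm(n, 0, noise)
    glu_obs <- glu_true + stats::rnorm(n, 0, noise)
    ids <- sprintf("SYN%03d", seq_len(n))

    samples <- tibble::tibble(
      sample_id = c(ids, "TERR-EM", "MAR-EM"),
      category = c(rep("human", n), "reed", "fish"),
      origin = c(rep("archaeological", n + 1), "modern"),
      bulk_d13c = NA_real_, bulk_d15n = NA_real_, cn_molar = NA_real_
    )
    aa <- tibble::tibble(
      sample_id = c(ids, ids, "TERR-EM", "MAR-EM"),
      element = "N",
      aa = c(rep("Glx", n), rep("Phe", n), "Phe", "Phe"),
      mean = c(glu_obs, phe_obs, spec$terr_phe_em[1], spec$marine_phe_em[1]),
      sd = c(rep(noise, 2 * n), spec$terr_phe_em[2], spec$marine_phe_em[2]),
      n = 6L
    )
    truth <- tibble::tibble(sample_id = ids, f_true = f, tp_true = tp,
                            phe_baseline = phe_base)
    list(samples = new_sample_set(samples, aa), truth = truth)
  })
}

#' Simulate centered EAA d13C training patterns and mixed consumers
#'
#' Training patterns are group means plus independent Gaussian scatter
#' (`eaa_sd`), re-centered row-wise; consumers are convex combinations of
#' the group means plus analytical noise, re-centered. Ground-truth
#' mixing weights accompany each consumer.
#'
#' @param spec A [food_web_spec()].
#' @param consumer_weights Matrix (consumers x groups, rows summing to 1)
#'   of true source proportions; default one consumer per entry of
#'   `spec$consumer_f_true`, splitting the marine share equally between
#'   the marine groups and the rest equally between the plant groups.
#' @return A list with `training` (centered tibble), `assignment` (named
#'   vector id -> group), `consumers` (centered tibble), and `truth`
#'   (tibble of true weights per consumer).
#' @export
simulate_eaa <- function(spec, consumer_weights = NULL) {
  stopifnot(inherits(spec, "food_web_spec"))
  groups <- names(spec$eaa_group_means)
  eaas <- names(spec$eaa_group_means[[1]])
  mu <- do.call(rbind, spec$eaa_group_means)    # groups x eaas
  if (is.null(consumer_weights)) {
    marine <- grepl("^Marine", groups)
    consumer_weights <- t(vapply(spec$consumer_f_true, function(f) {
      w <- numeric(length(groups))
      w[marine] <- f / sum(marine)
      w[!marine] <- (1 - f) / sum(!marine)
      w
    }, numeric(length(groups))))
    colnames(consumer_weights) <- groups
  }
  stopifnot(ncol(consumer_weights) == length(groups),
            all(abs(rowSums(consumer_weights) - 1) < 1e-9))

  with_spec_seed(spec, 1L, {
    n_tr <- spec$n_per_group
    training <- do.call(rbind, lapply(groups, function(g) {
      vals <- matrix(rep(mu[g, ], each = n_tr), nrow = n_tr) +
        matrix(stats::rnorm(n_tr * length(eaas), 0, spec$eaa_sd),
               nrow = n_tr)
      colnames(vals) <- eaas
      tibble::as_tibble(vals)
    }))
    training <- tibble::add_column(
      training,
      sample_id = sprintf("TR-%s-%02d", rep(groups, each = n_tr),
                          rep(seq_len(n_tr), length(groups))),
      .before = 1
    )
    assignment <- stats::setNames(rep(groups, each = n_tr),
                                  training$sample_id)

    n_co <- nrow(consumer_weights)
    co_vals <- consumer_weights %*% mu +
      matrix(stats::rnorm(n_co * length(eaas), 0, spec$analytical_sd_c),
             nrow = n_co)
    colnames(co_vals) <- eaas
    consumers <- tibble::add_column(
      tibble::as_tibble(co_vals),
      sample_id = sprintf("CO%03d", seq_len(n_co)), .before = 1
    )
    for (aa in eaas) {
      consumers[[paste0("sd_", aa)]] <- spec$analytical_sd_c
    }
    truth <- tibble::as_tibble(consumer_weights)
    truth <- tibble::add_column(truth, sample_id = consumers$sample_id,
                                .before = 1)
    list(
      training = center_patterns(training, eaas),
      assignment = assignment,
      consumers = center_patterns(consumers, eaas),
      truth = truth
    )
  })
}

#' Simulate bulk collagen d13C/d15N for a cohort with known marine
#' fractions
#'
#' `d13c = terr + f (mar - terr) + noise`; d15N is generated analogously
#' between nominal terrestrial and marine collagen values so the output
#' can be plotted like a bulk isotope biplot.
#'
#' @param spec A [food_web_spec()].
#' @param terr_em,mar_em Collagen-basis [end_member()]s for d13C.
#' @param noise_sd Gaussian noise sd (permil) applied to both elements;
#'   defaults to `spec$analytical_sd_c`.
#' @return A list with `samples` (a `sample_set` with bulk values) and
#'   `truth` (tibble: `sample_id`, `f_true`).
#' @export
simulate_bulk <- function(spec,
                          terr_em = end_member(-21.6, 2.0,
                                               label = "terrestrial"),
                          mar_em = end_member(-12.4, 1.5, label = "marine"),
                          noise_sd = NULL) {
  stopifnot(inherits(spec, "food_web_spec"))
  check_mixing_pair(terr_em, mar_em)
  if (is.null(noise_sd)) noise_sd <- spec$analytical_sd_c
  n <- length(spec$consumer_f_true)
  with_spec_seed(spec, 2L, {
    f <- spec$consumer_f_true
    d13c <- terr_em$mean + f * (mar_em$mean - terr_em$mean) +
      stats::rnorm(n, 0, noise_sd)
    # nominal bulk d15N food web: terrestrial collagen 14, marine 18
    d15n <- 14 + f * (18 - 14) + stats::rnorm(n, 0, noise_sd)
    ids <- sprintf("BLK%03d", seq_len(n))
    samples <- tibble::tibble(
      sample_id = ids, category = "human", origin = "archaeological",
      bulk_d13c = d13c, bulk_d15n = d15n, cn_molar = 3.2
    )
    aa <- tibble::tibble(sample_id = character(), element = character(),
                         aa = character(), mean = numeric(),
                         sd = numeric(), n = integer())
    list(samples = new_sample_set(samples, aa),
         truth = tibble::tibble(sample_id = ids, f_true = f))
  })
}

#' Write the synthetic CSV fixture set used by the test suite
#'
#' Emits the nitrogen sample tables, the EAA training/assignment/consumer
#' tables, the bulk cohort, and a small synthetic calibration curve pair,
#' all derived deterministically from the `food_web_spec` seed so two
#' invocations
#' produce byte-identical files.
#'
#' @param outdir Writable directory (created if absent).
#' @param spec A [food_web_spec()].
#' @return Invisibly, a named character vector of the written paths.
#' @export
make_fixture_files <- function(outdir, spec = food_web_spec()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  nit <- simulate_nitrogen(spec)
  write_samples(nit$samples, p("nitrogen_samples.csv"), p("nitrogen_aa.csv"))
  utils::write.csv(nit$truth, p("nitrogen_truth.csv"), row.names = FALSE,
                   quote = FALSE)

  eaa <- simulate_eaa(spec)
  utils::write.csv(eaa$training, p("eaa_training.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(
    tibble::tibble(sample_id = names(eaa$assignment),
                   group = unname(eaa$assignment)),
    p("eaa_assignment.csv"), row.names = FALSE, quote = FALSE
  )
  utils::write.csv(eaa$consumers, p("eaa_consumers.csv"), row.names = FALSE,
                   quote = FALSE)

  blk <- simulate_bulk(spec)
  write_samples(blk$samples, p("bulk_samples.csv"), p("bulk_aa.csv"))

  # small synthetic calibration curves: linear atmospheric, offset marine
  grid <- seq(0, 1000, by = 20)
  atm <- data.frame(calbp = grid, c14 = grid + 30, sigma = 15)
  mar <- data.frame(calbp = grid, c14 = grid + 30 + 400, sigma = 25)
  write_curve <- function(df, path, name) {
    con <- file(path, "w")
    writeLines(sprintf("# synthetic %s calibration curve", name), con)
    writeLines("# cal BP, 14C age BP, sigma", con)
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    close(con)
  }
  write_curve(atm, p("synthetic_atm.14c"), "atmospheric")
  write_curve(mar, p("synthetic_mar.14c"), "marine")

  paths <- c(
    nitrogen_samples = p("nitrogen_samples.csv"),
    nitrogen_aa = p("nitrogen_aa.csv"),
    nitrogen_truth = p("nitrogen_truth.csv"),
    eaa_training = p("eaa_training.csv"),
    eaa_assignment = p("eaa_assignment.csv"),
    eaa_consumers = p("eaa_consumers.csv"),
    bulk_samples = p("bulk_samples.csv"),
    bulk_aa = p("bulk_aa.csv"),
    atm_curve = p("synthetic_atm.14c"),
    mar_curve = p("synthetic_mar.14c")
  )
  invisible(paths)
}
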