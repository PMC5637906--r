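# Essential amino acid d13C fingerprinting: sample-mean centering, PCA
# grouping of training data, and a Bayesian mixing model estimating
# dietary source proportions for consumers.

EAA_DEFAULT <- c("Leu", "Lys", "Phe", "Val")

#' Center essential amino acid d13C patterns to their sample means
#'
#' Fingerprinting relies on the relative pattern of d13C across essential
#' amino acids, not absolute values; each sample's values are therefore
#' shifted to a zero mean over the included amino acids. Centering is
#' idempotent and the centered values of each row sum to zero.
#'
#' @param patterns A data frame with a `sample_id` column and one numeric
#'   column per essential amino acid (permil). Replicate-sd columns named
#'   `sd_<AA>` are carried through unchanged.
#' @param include Amino acids defining the centering mean; all must be
#'   present.
#' @return The centered tibble, with attribute `centered = TRUE` and
#'   attribute `center_eaas` recording the set used.
#' @export
center_patterns <- function(patterns, include = EAA_DEFAULT) {
  patterns <- tibble::as_tibble(patterns)
  missing <- setdiff(include, names(patterns))
  if (length(missing)) {
    stop("missing essential amino acid column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(patterns[include])
  if (anyNA(vals)) stop("NA values in essential amino acid columns",
                        call. = FALSE)
  centered <- vals - rowMeans(vals)
  patterns[include] <- centered
  attr(patterns, "centered") <- TRUE
  attr(patterns, "center_eaas") <- include
  patterns
}

check_centered <- function(patterns, include) {
  if (!isTRUE(attr(patterns, "centered"))) {
    stop("patterns must be centered first (see center_patterns())",
         call. = FALSE)
  }
  used <- attr(patterns, "center_eaas")
  if (!setequal(used, include)) {
    stop("centering used EAA set {", paste(used, collapse = ", "),
         "} but this step requires {", paste(include, collapse = ", "),
         "}; re-center with the matching set", call. = FALSE)
  }
  invisible(TRUE)
}

#' Principal component analysis of centered EAA patterns
#'
#' Standard PCA (via [stats::prcomp()]) of the centered d13C values.
#' Component signs are fixed deterministically by making the
#' largest-magnitude element of each loading vector positive, so repeated
#' runs and duplicated data give identical scores.
#'
#' @param training A centered pattern tibble from [center_patterns()].
#' @param include Amino acids entering the PCA (must match the centering
#'   set).
#' @return A list with `scores` (tibble: `sample_id`, `PC1`, ...),
#'   `loadings` (matrix), and `explained` (proportion of variance per
#'   component).
#' @export
pca_scores <- function(training, include = EAA_DEFAULT) {
  check_centered(training, include)
  if (nrow(training) < 3) stop("need at least 3 patterns for PCA",
                               call. = FALSE)
  x <- as.matrix(training[include])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (ncol(pc$rotation) < length(include)) {
    warning("rank-deficient input: fewer components than amino acids",
            call. = FALSE)
  }
  # deterministic sign: largest |loading| element positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- tibble::as_tibble(pc$x)
  scores <- tibble::add_column(scores, sample_id = training$sample_id,
                               .before = 1)
  list(scores = scores,
       loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Summarize training patterns into food source groups
#'
#' Group membership is an explicit input (typically read off a PCA scores
#' plot, e.g. Marine-I fish/marine mammal/seabird, Marine-II mussels, and
#' two plant clusters), never assigned silently. Each group is summarized
#' by the per-amino-acid mean and sd of its members' centered values.
#'
#' @param training A centered pattern tibble.
#' @param assignment Named character vector mapping `sample_id` to group
#'   label; every training id must be assigned.
#' @param include Amino acids to summarize (must match the centering set).
#' @return A `source_groups` object: tibble with columns `group`, `aa`,
#'   `mean`, `sd`, `n`.
#' @export
build_source_groups <- function(training, assignment,
                                include = EAA_DEFAULT) {
  check_centered(training, include)
  unknown <- setdiff(names(assignment), training$sample_id)
  if (length(unknown)) {
    stop("assignment references unknown sample_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unassigned <- setdiff(training$sample_id, names(assignment))
  if (length(unassigned)) {
    stop("unassigned training sample(s): ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  grp <- unname(assignment[training$sample_id])
  rows <- lapply(sort(unique(grp)), function(g) {
    sub <- as.matrix(training[grp == g, include])
    tibble::tibble(
      group = g, aa = include,
      mean = colMeans(sub),
      sd = if (nrow(sub) >= 2) apply(sub, 2, stats::sd) else rep(0, ncol(sub)),
      n = nrow(sub)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "center_eaas") <- include
  class(out) <- c("source_groups", class(out))
  out
}

#' MCMC settings for the Bayesian mixing model
#'
#' @param n_iter Post-warmup iterations per chain.
#' @param n_warmup Warmup (discarded) iterations per chain.
#' @param n_chains Number of chains (default 4).
#' @param step Random-walk step size on the additive log-ratio scale.
#' @param seed Random seed (mandatory for reproducible posteriors).
#' @param rhat_threshold Convergence flag threshold for split R-hat.
#' @return A `mix_mcmc_control` list.
#' @export
mix_mcmc_control <- function(n_iter = 4000, n_warmup = 1000, n_chains = 4,
                             step = 0.35, seed = 1,
                             rhat_threshold = 1.05) {
  stopifnot(n_iter > 0, n_warmup >= 0, n_chains >= 2, step > 0)
  list(n_iter = n_iter, n_warmup = n_warmup, n_chains = n_chains,
       step = step, seed = seed, rhat_threshold = rhat_threshold)
}

#' Bayesian source mixing model on centered EAA d13C values
#'
#' Estimates the proportional contribution of each food source group to a
#' consumer's essential amino acids. Model: proportions `p` have a flat
#' Dirichlet prior; the consumer's centered value for amino acid `k` is
#' `Normal(sum_i p_i mu_ik, sigma_k^2)` with
#' `sigma_k^2 = consumer analytical variance + sum_i p_i^2 s_ik^2 +
#' model error variance`. Lysine typically participates in centering and
#' PCA but is excluded from this likelihood (default EAA set Leu, Phe,
#' Val) because it separates marine from terrestrial sources poorly.
#'
#' Sampling is random-walk Metropolis on the additive log-ratio transform
#' of the simplex (the flat Dirichlet prior contributes the log-Jacobian
#' `sum_k log p_k`), run as `n_chains` parallel chains; convergence is
#' flagged via split R-hat.
#'
#' @param consumer One-row centered pattern tibble (or a named numeric
#'   vector of centered values). Optional `sd_<AA>` columns supply the
#'   consumer analytical sd per amino acid.
#' @param sources A `source_groups` object from [build_source_groups()].
#' @param use_eaas Amino acids entering the likelihood.
#' @param mcmc A [mix_mcmc_control()].
#' @param model_error_sd Residual model standard deviation (permil);
#'   defaults to the analytical replicate scale 0.4.
#' @return A `mixture_posterior`: list with `draws` (matrix, one column
#'   per source), `summary` (tibble: source, mean, sd, 68% and 95%
#'   credible bounds), and `diagnostics` (R-hat per source, acceptance
#'   rate, effective sample size, `converged` flag).
#' @export
fit_mixture <- function(consumer, sources, use_eaas = c("Leu", "Phe", "Val"),
                        mcmc = mix_mcmc_control(),
                        model_error_sd = 0.4) {
  stopifnot(inherits(sources, "source_groups"))
  center_set <- attr(sources, "center_eaas")
  if (!all(use_eaas %in% center_set)) {
    stop("use_eaas must be a subset of the centering set {",
         paste(center_set, collapse = ", "), "}", call. = FALSE)
  }
  if (is.data.frame(consumer)) {
    stopifnot(nrow(consumer) == 1)
    if (isTRUE(attr(consumer, "centered"))) {
      check_centered(consumer, center_set)
    } else {
      # row subsets may drop the centering attributes; verify numerically
      if (!all(center_set %in% names(consumer)) ||
          abs(sum(as.numeric(consumer[1, center_set]))) > 1e-6) {
        stop("consumer pattern is not centered on the source centering set {",
             paste(center_set, collapse = ", "),
             "}; center with center_patterns() using that set", call. = FALSE)
      }
    }
    y <- as.numeric(consumer[1, use_eaas])
    sd_cols <- paste0("sd_", use_eaas)
    y_sd <- vapply(sd_cols, function(cn) {
      if (cn %in% names(consumer)) as.numeric(consumer[[cn]][1]) else 0
    }, numeric(1))
  } else {
    if (is.null(names(consumer)) || !all(use_eaas %in% names(consumer))) {
      stop("consumer vector must be named with the amino acids in use_eaas",
           call. = FALSE)
    }
    y <- as.numeric(consumer[use_eaas])
    y_sd <- rep(0, length(use_eaas))
  }

  groups <- unique(sources$group)
  K <- length(groups)
  if (K < 2) stop("need at least 2 sources", call. = FALSE)
  mu <- sapply(groups, function(g) {
    sources$mean[sources$group == g][match(use_eaas,
                                           sources$aa[sources$group == g])]
  })                                           # n_eaa x K
  s2 <- sapply(groups, function(g) {
    sources$sd[sources$group == g][match(use_eaas,
                                         sources$aa[sources$group == g])]
  })^2
  mu <- matrix(mu, nrow = length(use_eaas))
  s2 <- matrix(s2, nrow = length(use_eaas))

  base_var <- y_sd^2 + model_error_sd^2

  # log posterior at simplex points given as columns of P (K x m)
  log_post <- function(P) {
    pred <- mu %*% P                            # n_eaa x m
    vark <- s2 %*% P^2 + base_var               # n_eaa x m
    ll <- colSums(-0.5 * (y - pred)^2 / vark - 0.5 * log(vark))
    ll + colSums(log(P))                        # flat-Dirichlet Jacobian
  }
  alr_to_p <- function(theta) {                 # (K-1) x m -> K x m
    e <- rbind(exp(theta), 1)
    sweep(e, 2, colSums(e), "/")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(mcmc$seed)

  m <- mcmc$n_chains
  theta <- matrix(stats::rnorm((K - 1) * m, 0, 0.5), nrow = K - 1)
  lp <- log_post(alr_to_p(theta))
  total <- mcmc$n_warmup + mcmc$n_iter
  keep <- array(NA_real_, dim = c(mcmc$n_iter, m, K))
  n_acc <- 0
  step <- mcmc$step
  for (it in seq_len(total)) {
    prop <- theta + matrix(stats::rnorm((K - 1) * m, 0, step),
                           nrow = K - 1)
    lp_prop <- log_post(alr_to_p(prop))
    acc <- log(stats::runif(m)) < (lp_prop - lp)
    theta[, acc] <- prop[, acc]
    lp[acc] <- lp_prop[acc]
    if (it <= mcmc$n_warmup) {
      # Robbins-Monro step adaptation toward ~30% acceptance, warmup only
      step <- exp(log(step) + (mean(acc) - 0.3) / sqrt(it))
    } else {
      keep[it - mcmc$n_warmup, , ] <- t(alr_to_p(theta))
      n_acc <- n_acc + sum(acc)
    }
  }
  acc_rate <- n_acc / (mcmc$n_iter * m)

  rhat <- vapply(seq_len(K), function(k) split_rhat(keep[, , k]), numeric(1))
  ess <- vapply(seq_len(K), function(k) ess_basic(keep[, , k]), numeric(1))
  draws <- matrix(keep, ncol = K,
                  dimnames = list(NULL, groups))

  qs <- apply(draws, 2, stats::quantile,
              probs = c(0.025, 0.16, 0.84, 0.975))
  summary <- tibble::tibble(
    source = groups,
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    ci68_lo = qs[2, ], ci68_hi = qs[3, ],
    ci95_lo = qs[1, ], ci95_hi = qs[4, ]
  )
  converged <- all(is.finite(rhat)) && max(rhat) < mcmc$rhat_threshold
  if (!converged) {
    warning("mixing model chains not converged (max split R-hat = ",
            sprintf("%.3f", max(rhat)), "); treat posterior with caution",
            call. = FALSE)
  }
  structure(
    list(draws = draws, summary = summary,
         diagnostics = list(rhat = stats::setNames(rhat, groups),
                            ess = stats::setNames(ess, groups),
                            acceptance = acc_rate,
                            converged = converged),
         use_eaas = use_eaas),
    class = "mixture_posterior"
  )
}

# split R-hat over an iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# crude effective sample size from lag-1 autocorrelation, summed chains
ess_basic <- function(x) {
  n <- nrow(x) * ncol(x)
  rho <- mean(apply(x, 2, function(ch) {
    a <- stats::acf(ch, lag.max = 1, plot = FALSE)$acf[2]
    if (is.na(a)) 0 else a
  }))
  rho <- min(max(rho, 0), 0.999)
  n * (1 - rho) / (1 + rho)
}

#' @export
print.mixture_posterior <- function(x, ...) {
  cat("<mixture_posterior>",
      if (x$diagnostics$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$summary, ...)
  invisible(x)
}

#' Aggregate posterior proportions over the marine source groups
#'
#' Sums the marine sources' proportions draw by draw, then summarizes, so
#' the credible interval reflects the joint posterior, not a sum of
#' marginal intervals.
#'
#' @param post A `mixture_posterior`.
#' @param marine_labels Source names to aggregate (non-empty subset).
#' @return A one-row tibble: mean, sd, 68% and 95% credible bounds of the
#'   combined marine proportion.
#' @export
aggregate_marine <- function(post, marine_labels) {
  stopifnot(inherits(post, "mixture_posterior"))
  if (length(marine_labels) == 0) stop("empty marine label set", call. = FALSE)
  unknown <- setdiff(marine_labels, colnames(post$draws))
  if (length(unknown)) {
    stop("unknown source label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  agg <- rowSums(post$draws[, marine_labels, drop = FALSE])
  q <- stats::quantile(agg, c(0.025, 0.16, 0.84, 0.975))
  tibble::tibble(
    mean = mean(agg), sd = stats::sd(agg),
    ci68_lo = q[[2]], ci68_hi = q[[3]],
    ci95_lo = q[[1]], ci95_hi = q[[4]]
  )
}
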