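eaas <- c("Leu", "Lys", "Phe", "Val")

test_that("centering subtracts the sample mean and is idempotent", {
  raw <- tibble::tibble(sample_id = "x", Leu = -20, Lys = -22, Phe = -24,
                        Val = -26)
  c1 <- center_patterns(raw, eaas)
  expect_equal(as.numeric(c1[1, eaas]), c(3, 1, -1, -3))
  expect_equal(sum(as.numeric(c1[1, eaas])), 0, tolerance = 1e-9)
  c2 <- center_patterns(c1, eaas)
  expect_equal(as.numeric(c2[1, eaas]), as.numeric(c1[1, eaas]))
  # uniform pattern centers to all zeros
  flat <- center_patterns(tibble::tibble(sample_id = "y", Leu = -20,
                                         Lys = -20, Phe = -20, Val = -20),
                          eaas)
  expect_equal(as.numeric(flat[1, eaas]), rep(0, 4))
  expect_error(center_patterns(raw[, -2], eaas), "Leu")
})

test_that("PCA separates synthetic clusters deterministically", {
  spec <- food_web_spec(seed = 21, n_per_group = 10,
                        eaa_group_means = default_eaa_group_means()[c(1, 3)])
  sim <- simulate_eaa(spec, consumer_weights = matrix(c(1, 0), nrow = 1,
                      dimnames = list(NULL, c("Marine-I", "Plant-I"))))
  pc <- pca_scores(sim$training, eaas)
  grp <- sim$assignment[pc$scores$sample_id]
  s1 <- pc$scores$PC1[grp == "Marine-I"]
  s2 <- pc$scores$PC1[grp == "Plant-I"]
  # zero overlap between the two clusters on PC1
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  # duplicated dataset gives identical scores (sign convention fixed)
  dup <- pca_scores(sim$training, eaas)
  expect_identical(pc$scores, dup$scores)
  # explained variance proportions sum to one
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  expect_error(pca_scores(sim$training[1:2, ], eaas), "at least 3")
})

test_that("source group summaries are order invariant and recover means", {
  spec <- food_web_spec(seed = 8, n_per_group = 12)
  sim <- simulate_eaa(spec)
  g <- build_source_groups(sim$training, sim$assignment, eaas)
  expect_setequal(unique(g$group), names(default_eaa_group_means()))
  # group means within 2 sd/sqrt(n) of the generating means (centering of
  # noisy rows perturbs them slightly, hence the guard band on top)
  mu <- default_eaa_group_means()
  for (grp in names(mu)) {
    est <- g$mean[g$group == grp][match(eaas, g$aa[g$group == grp])]
    expect_lt(max(abs(est - mu[[grp]])), 2 * spec$eaa_sd / sqrt(12) + 0.2)
  }
  # permuting member order leaves the summaries unchanged
  perm <- sample(nrow(sim$training))
  tr2 <- sim$training[perm, ]
  attr(tr2, "centered") <- TRUE
  attr(tr2, "center_eaas") <- eaas
  g2 <- build_source_groups(tr2, sim$assignment, eaas)
  expect_equal(g2, g)
  # identical patterns give zero sd
  same <- center_patterns(
    tibble::tibble(sample_id = c("a", "b"), Leu = -20, Lys = -22,
                   Phe = -24, Val = -26), eaas)
  g3 <- build_source_groups(same, c(a = "G", b = "G"), eaas)
  expect_equal(unname(g3$sd), rep(0, 4))
  expect_error(build_source_groups(same, c(zz = "G"), eaas), "unknown|unassigned")
})

test_that("mixture posterior draws are valid probability vectors", {
  src <- two_distant_sources()
  post <- fit_mixture(c(Leu = -2, Phe = 3, Val = -1), src,
                      mcmc = mix_mcmc_control(n_iter = 1000, seed = 2))
  expect_true(all(abs(rowSums(post$draws) - 1) < 1e-9))
  expect_true(all(post$summary$mean >= 0 & post$summary$mean <= 1))
})

test_that("a consumer sitting on one source's mean is assigned to it", {
  src <- two_distant_sources()
  a_mean <- src$mean[src$group == "A"]
  names(a_mean) <- src$aa[src$group == "A"]
  post <- fit_mixture(a_mean, src, mcmc = mix_mcmc_control(seed = 5))
  expect_gt(post$summary$mean[post$summary$source == "A"], 0.9)
})

test_that("identical sources are non-identifiable but their sum is recovered", {
  training <- center_patterns(tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    Leu = rep(c(-2, -2, -2), 2), Phe = rep(3, 6), Val = rep(-1, 6)
  ), c("Leu", "Phe", "Val"))
  src <- build_source_groups(
    training, stats::setNames(rep(c("A", "B"), each = 3),
                              training$sample_id),
    c("Leu", "Phe", "Val"))
  post <- fit_mixture(c(Leu = -2, Phe = 3, Val = -1), src,
                      mcmc = mix_mcmc_control(seed = 6))
  ma <- post$summary$mean[post$summary$source == "A"]
  mb <- post$summary$mean[post$summary$source == "B"]
  expect_equal(unname(ma + mb), 1, tolerance = 1e-9)
  # near-symmetric marginals
  expect_lt(abs(ma - mb), 0.1)
})

test_that("an uninformative likelihood returns the flat prior", {
  src <- two_distant_sources()
  post <- fit_mixture(c(Leu = 0, Phe = 0, Val = 0), src,
                      mcmc = mix_mcmc_control(n_iter = 8000, seed = 9),
                      model_error_sd = 1e4)
  expect_equal(unname(post$summary$mean), c(0.5, 0.5), tolerance = 0.05)
})

test_that("posteriors are bit-identical for a fixed seed", {
  src <- two_distant_sources()
  y <- c(Leu = -1, Phe = 1.5, Val = -0.5)
  p1 <- fit_mixture(y, src, mcmc = mix_mcmc_control(n_iter = 1000, seed = 31))
  p2 <- fit_mixture(y, src, mcmc = mix_mcmc_control(n_iter = 1000, seed = 31))
  expect_identical(p1$summary, p2$summary)
  expect_identical(p1$draws, p2$draws)
})

test_that("EAA-set mismatch between centering and mixing is a hard error", {
  src <- two_distant_sources()   # centered on Leu/Phe/Val
  raw <- center_patterns(tibble::tibble(sample_id = "c", Leu = -20,
                                        Lys = -22, Phe = -24, Val = -26),
                         eaas)
  expect_error(fit_mixture(raw, src), "re-center|centering set")
  expect_error(fit_mixture(c(Leu = -2, Phe = 3, Val = -1), src,
                           use_eaas = c("Leu", "Lys")), "subset")
})

test_that("marine aggregation is draw-wise and linear in expectation", {
  spec <- food_web_spec(seed = 12, consumer_f_true = 0.55)
  sim <- simulate_eaa(spec)
  g <- build_source_groups(sim$training, sim$assignment, eaas)
  post <- fit_mixture(sim$consumers[1, ], g,
                      mcmc = mix_mcmc_control(seed = 13))
  agg <- aggregate_marine(post, c("Marine-I", "Marine-II"))
  s <- post$summary
  expect_equal(agg$mean,
               sum(s$mean[s$source %in% c("Marine-I", "Marine-II")]),
               tolerance = 1e-12)
  # synthetic 0.55-marine consumer: 95% CI covers the truth
  expect_true(agg$ci95_lo <= 0.55 && 0.55 <= agg$ci95_hi)
  # aggregating every source gives exactly one
  all_agg <- aggregate_marine(post, unique(g$group))
  expect_equal(all_agg$mean, 1, tolerance = 1e-12)
  expect_equal(all_agg$sd, 0, tolerance = 1e-9)
  expect_error(aggregate_marine(post, character(0)), "empty")
  expect_error(aggregate_marine(post, "Nope"), "unknown")
})
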