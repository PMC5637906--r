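k0 <- nitrogen_params()
human <- paired_delta(18.1, 0.4, 11.5, 0.4)
rat <- paired_delta(14.9, 0.4, 10.4, 0.4)

test_that("trophic positions reproduce the published human and rat averages", {
  expect_equal(tp_marine(human, k0)$tp, 1.42, tolerance = 0.005)
  expect_equal(tp_terrestrial(human, k0)$tp, 2.97, tolerance = 0.005)
  expect_equal(tp_marine(rat, k0)$tp, 1.145, tolerance = 0.005)
  expect_equal(tp_terrestrial(rat, k0)$tp, 2.70, tolerance = 0.005)
})

test_that("producer and herbivore baselines give integer trophic positions", {
  # producer: glu - phe = -beta_marine -> TP = 1 exactly
  p1 <- paired_delta(3.4, 0, 0, 0)
  expect_equal(tp_marine(p1, k0)$tp, 1)
  # terrestrial herbivore: glu - phe = Delta - beta_terr -> TP = 2 exactly
  p2 <- paired_delta(7.6 - 8.4, 0, 0, 0)
  expect_equal(tp_terrestrial(p2, k0)$tp, 2)
})

test_that("mixed trophic position interpolates between the diet extremes", {
  p <- paired_delta(18.2, 0.4, 11.6, 0.4)   # glu - phe = 6.6
  expect_equal(tp_mixed(p, 0.5, k0)$tp, 2.197, tolerance = 0.001)
  m0 <- tp_mixed(p, 0, k0)
  t <- tp_terrestrial(p, k0)
  expect_equal(m0$tp, t$tp)
  expect_equal(m0$sd, t$sd)
  m1 <- tp_mixed(p, 1, k0)
  m <- tp_marine(p, k0)
  expect_equal(m1$tp, m$tp)
  expect_equal(m1$sd, m$sd)
  expect_error(tp_mixed(p, 1.2, k0), "\\[0, 1\\]")
  # monotone non-increasing in f when beta_terr > beta_mar
  set.seed(3)
  for (i in 1:20) {
    p_r <- paired_delta(runif(1, 10, 20), 0, runif(1, 5, 12), 0)
    f <- sort(runif(5))
    tps <- vapply(f, function(fi) tp_mixed(p_r, fi, k0)$tp, numeric(1))
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("HTL-based marine fraction matches the published human average", {
  p <- paired_delta(18.2, 0.4, 11.6, 0.4)
  r <- f_marine_htl(p, htl_spec(), k0)
  expect_equal(r$f, 0.49, tolerance = 0.005)
  expect_equal(r$method, "htl")
  # consistency: HTL equal to the terrestrial TP implies f = 0, marine TP f = 1
  expect_equal(f_marine_htl(p, htl_spec(tp_terrestrial(p, k0)$tp,
                                        lo = 0, hi = 5), k0)$f, 0,
               tolerance = 1e-12)
  expect_equal(f_marine_htl(p, htl_spec(tp_marine(p, k0)$tp,
                                        lo = 0, hi = 5), k0)$f, 1,
               tolerance = 1e-12)
  expect_error(f_marine_htl(p, htl_spec(),
                            nitrogen_params(beta_marine = 8.4)),
               "degenerate")
})

test_that("terrestrial end-member inversion matches the mass balance", {
  expect_equal(infer_terrestrial_endmember(11.6, 0.5, 1.0), 22.2)
  expect_equal(infer_terrestrial_endmember(11.6, 0, 1.0), 11.6)
  # forward mixing applied to the output recovers the consumer value
  set.seed(4)
  for (i in 1:25) {
    phe <- runif(1, 5, 15); f <- runif(1, 0, 0.95); m <- runif(1, 0, 2)
    t <- infer_terrestrial_endmember(phe, f, m)
    expect_equal(f * m + (1 - f) * t, phe, tolerance = 1e-12)
  }
  expect_error(infer_terrestrial_endmember(11.6, 1, 1.0), "< 1")
})

test_that("phenylalanine marine fraction matches the published estimates", {
  expect_equal(f_marine_phe(11.6)$f, 0.50, tolerance = 0.005)
  expect_equal(f_marine_phe(14.0)$f, 0.39, tolerance = 0.005)
  expect_equal(f_marine_phe(22.7)$f, 0)
  expect_true(f_marine_phe(11.6)$feasible)
  expect_false(f_marine_phe(25)$feasible)
})

test_that("HTL and phenylalanine estimators agree through the inversion", {
  # setting the terrestrial end member to the Eq.-6 style inversion of the
  # HTL solution makes the two marine-fraction routes coincide
  p <- paired_delta(18.2, 0, 11.6, 0)
  f_htl <- f_marine_htl(p, htl_spec(), k0)$f
  mar <- 1.0
  terr <- infer_terrestrial_endmember(p$d15n_phe, f_htl, mar)
  f_phe <- f_marine_phe(p$d15n_phe, 0, end_member(terr, 0),
                        end_member(mar, 0))$f
  expect_equal(f_phe, f_htl, tolerance = 1e-10)
})

test_that("delta-method sds agree with Monte Carlo for every estimator", {
  set.seed(99)
  n <- 1e6
  k <- nitrogen_params(sd_beta_marine = 0.3, sd_beta_terrestrial = 0.4,
                       sd_delta = 0.3)
  p <- paired_delta(18.1, 0.5, 11.5, 0.5)

  expect_equal(tp_marine(p, k)$sd,
               monte_carlo_sd("tp_marine", p, k, n), tolerance = 0.02)
  expect_equal(tp_terrestrial(p, k)$sd,
               monte_carlo_sd("tp_terrestrial", p, k, n), tolerance = 0.02)
  expect_equal(tp_mixed(p, 0.5, k, f_sd = 0.05)$sd,
               monte_carlo_sd("tp_mixed", p, k, n, f = 0.5, f_sd = 0.05),
               tolerance = 0.02)
  expect_equal(f_marine_htl(p, htl_spec(sd = 0.1), k)$sd,
               monte_carlo_sd("f_marine_htl", p, k, n,
                              htl = htl_spec(sd = 0.1)),
               tolerance = 0.02)
  # RN035-style inputs for the two-source phenylalanine estimator
  terr <- end_member(22.7, 0.9); mar <- end_member(0.4, 0.6)
  expect_equal(f_marine_phe(14.0, 0.4, terr, mar)$sd,
               monte_carlo_sd("f_marine_phe", phe_consumer = 14.0,
                              phe_sd = 0.4, terr = terr, mar = mar, n = n),
               tolerance = 0.02)
  # all-zero inputs give zero sd everywhere
  p0 <- paired_delta(18.1, 0, 11.5, 0)
  expect_equal(tp_marine(p0, k0)$sd, 0)
  expect_equal(tp_mixed(p0, 0.5, k0)$sd, 0)
  expect_equal(f_marine_htl(p0, htl_spec(), k0)$sd, 0)
  expect_equal(f_marine_phe(11.6, 0, end_member(22.7), end_member(0.4))$sd, 0)
})

test_that("terrestrial end-member sweep flags infeasible and low-rat rows", {
  p_h <- paired_delta(18.2, 0.4, 11.6, 0.4)  # glu - phe = 6.6
  p_r <- paired_delta(15.9, 0.4, 11.4, 0.4)  # glu - phe = 4.5
  mar <- end_member(1.0, 0.9, label = "average fish")
  sw <- sensitivity_sweep(p_h, p_r, c(14, 16, 18, 20, 22.7), mar)
  expect_equal(nrow(sw), 10)
  row227 <- sw[sw$terr_phe == 22.7 & sw$species == "human", ]
  expect_equal(row227$f_marine, 0.51, tolerance = 0.01)
  expect_equal(row227$tp_mixed, 2.19, tolerance = 0.015)
  # grid value below the consumer's phe violates mass balance (f > 1)
  sw_low <- sensitivity_sweep(p_h, p_r, c(11.0, 22.7), mar)
  expect_false(sw_low$mass_balance_ok[sw_low$terr_phe == 11.0 &
                                        sw_low$species == "human"])
  # rat omnivory floor eliminates high-end-member solutions
  expect_false(all(sw$rat_floor_ok))
  expect_error(sensitivity_sweep(p_h, p_r, numeric(0), mar), "empty")
  expect_error(sensitivity_sweep(p_h, p_r, c(0.5), mar), "exceed")
})

test_that("human-rat mixed-TP gap stays below the published bound", {
  p_h <- paired_delta(18.2, 0, 11.6, 0)
  p_r <- paired_delta(15.9, 0, 11.4, 0)
  mar <- end_member(1.0, 0.9)
  grid <- seq(14, 22.7, by = 0.1)
  sw <- sensitivity_sweep(p_h, p_r, grid, mar)
  ok <- sw$mass_balance_ok & sw$rat_floor_ok
  h <- sw[sw$species == "human" & ok, c("terr_phe", "tp_mixed")]
  r <- sw[sw$species == "rat" & ok, c("terr_phe", "tp_mixed")]
  shared <- intersect(h$terr_phe, r$terr_phe)
  gap <- abs(h$tp_mixed[match(shared, h$terr_phe)] -
               r$tp_mixed[match(shared, r$terr_phe)])
  expect_lt(max(gap), 0.37)
})
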