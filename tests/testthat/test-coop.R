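# Reactivities, power laws, couplings, bootstrap and BH selection.

test_that("reactivity profile matches the exact enumeration reference", {
  model <- coupled_model(J12 = -1)
  sim <- synth_binding_trajectories(model, n_frames = 8000, seed = 31)
  V_B <- 437
  grid <- 10^seq(-2.8, -2.2, length.out = 5)
  rc <- reactivity_profile(sim$binding, V_B = V_B, concentrations = grid)
  expect_true(all(rc$R >= 0 & rc$R <= 1))
  # exact reference at the exactly calibrated chemical potential
  oB <- sim$exact$omega_B
  for (C in grid) {
    target <- C * V_B / 1.660539
    f <- function(bm) sum((0:model$N_max) *
                            exp(bm * 0:model$N_max) * oB) /
      sum(exp(bm * 0:model$N_max) * oB) - target
    bm <- uniroot(f, c(-30, 10), tol = 1e-13)$root
    ref <- synth_exact_reference(model, bm)
    got <- rc$R[rc$concentration_M == C]
    expect_lt(max(abs(got - ref$R) / pmax(ref$R, 0.01)), 0.15)
  }
  # monotone in concentration for every site
  for (nuc in unique(rc$nucleotide)) {
    r <- rc$R[rc$nucleotide == nuc]
    expect_true(all(diff(r) > 0))
  }
})

test_that("never-bound nucleotides have zero reactivity; degenerate single-N input reduces to plain frequency", {
  model <- synth_binding_model(M = 2, e = c(0, 50), S_B = 8, N_max = 2)
  sim <- synth_binding_trajectories(model, n_frames = 3000, seed = 12)
  rc <- reactivity_profile(sim$binding, V_B = 900,
                           concentrations = c(1e-3, 2e-3))
  expect_true(all(rc$R[rc$nucleotide == "nuc2"] < 1e-6))

  # frames at a single occupancy: weights are uniform, so the weighted
  # bound frequency is the unweighted one
  bt <- sim$binding[sim$binding$k_A == 1 & sim$binding$trajectory_N == 1, ]
  occ <- occupancies_from_binding(bt)
  cm <- build_count_matrix(occ)
  pf <- structure(list(omega_A = c(1, 1, 0), omega_B = c(1, 1, 1),
                       gauge = "omega0", N_max = 2L, converged = TRUE),
                  class = "partition_functions")
  w <- frame_weights(pf, 0.7, cm, occ)
  p1 <- sum(w$weight * bt$nuc1)
  expect_equal(p1, mean(bt$nuc1), tolerance = 1e-12)
})

test_that("power-law fits are exact on noiseless curves and unbiased under noise", {
  C <- 10^seq(-3, -2, length.out = 20)
  f1 <- fit_power_law(C, 2 * C)
  expect_equal(f1$beta, 1, tolerance = 1e-10)
  expect_equal(f1$alpha, 2, tolerance = 1e-10)
  f2 <- fit_power_law(C, 3 * C^1.5)
  expect_equal(f2$beta, 1.5, tolerance = 1e-10)
  expect_equal(f2$alpha, 3, tolerance = 1e-10)
  expect_error(fit_power_law(C, c(-1, (2 * C)[-1])), "nonpositive")
  expect_error(fit_power_law(C[1:2], 2 * C[1:2], c_min = 1, c_max = 2),
               "at least two")

  # multiplicative lognormal noise: mean recovered slope within 2 SE
  set.seed(77)
  n_rep <- 400
  betas <- replicate(n_rep, {
    R <- 3 * C^1.3 * exp(rnorm(length(C), 0, 0.1))
    fit_power_law(C, R)$beta
  })
  expect_lt(abs(mean(betas) - 1.3), 2 * sd(betas) / sqrt(n_rep))
})

test_that("coupling free energy follows the odds-ratio formula", {
  expect_equal(coupling_free_energy(c(p00 = .25, p01 = .25, p10 = .25, p11 = .25)), 0)
  # ratio (p11 p00)/(p10 p01) = e -> -1 kT (cooperative); the odds ratio is
  # invariant under the final normalization
  p <- c(p00 = 0.5, p01 = 0.2, p10 = 0.2, p11 = exp(1) * 0.2 * 0.2 / 0.5)
  p <- p / sum(p)
  expect_equal(coupling_free_energy(p), -1, tolerance = 1e-12)
  expect_true(is.na(coupling_free_energy(c(p00 = .5, p01 = .5, p10 = 0, p11 = 0))))
  expect_error(coupling_free_energy(c(p00 = .5, p01 = .5, p10 = .5, p11 = .5)),
               "sum to 1")
  # kcal/mol conversion at 300 K
  expect_equal(coupling_free_energy(p, temperature = 300, units = "kcal/mol"),
               -0.0019872041 * 300, tolerance = 1e-9)
})

test_that("coupling matrix recovers the ground-truth coupling sign and value", {
  model <- coupled_model(J12 = -1)
  sim <- synth_binding_trajectories(model, n_frames = 8000, seed = 41)
  occ <- sim$occupancies
  cm <- build_count_matrix(occ)
  pf <- solve_partition_functions(cm)
  buf <- buffer_spec(V_B = 437, concentration = 5.7e-3)
  w <- frame_weights(pf, mu_from_concentration(pf, buf), cm, occ)
  M <- coupling_matrix(sim$binding, w)
  expect_true(is.na(M[1, 1]))
  expect_equal(M[1, 2], M[2, 1])
  expect_lt(M[1, 2], 0)
  expect_equal(unname(M[1, 2]), -1, tolerance = 0.35)
  # uncoupled pair stays near zero
  expect_lt(abs(M[1, 3]), 0.3)
})

test_that("Dirichlet bootstrap weights are proper and constants have zero spread", {
  reps <- bayesian_bootstrap(function(w) {
    expect_equal(sum(w), length(w), tolerance = 1e-12)
    42
  }, trajectory_Ns = 1:5, n_iter = 50, seed = 9)
  expect_equal(sd(reps[, 1]), 0)
  expect_error(bayesian_bootstrap(identity, trajectory_Ns = 1L, n_iter = 2),
               "at least two")
  r1 <- bayesian_bootstrap(function(w) sum(w * 1:4), 1:4, n_iter = 20, seed = 5)
  r2 <- bayesian_bootstrap(function(w) sum(w * 1:4), 1:4, n_iter = 20, seed = 5)
  expect_identical(r1, r2)
})

test_that("bootstrap SD of a trajectory mean tracks the classical standard error", {
  set.seed(123)
  x <- rnorm(19, mean = 5, sd = 2)          # per-trajectory statistic
  reps <- bayesian_bootstrap(function(w) mean(w * x), seq_along(x),
                             n_iter = 10000, seed = 4)
  classical <- sd(x) / sqrt(length(x))
  expect_equal(sd(reps[, 1]) / classical, 1, tolerance = 0.2)
})

test_that("fractional trajectory weights flow through the solver", {
  p <- lattice_pipeline(lattice_model(3, 5, N_max = 6), 2000, seed = 55)
  w <- c(`1` = 1.4, `2` = 0.6, `3` = 1.0, `4` = 0.8, `5` = 1.2, `6` = 1.0)
  rc <- reweight_counts(p$counts, w)
  expect_equal(sum(rc$L), sum(p$counts$L * w), tolerance = 1e-9)
  pf <- solve_partition_functions(rc, init = p$pf)
  expect_true(pf$converged)
  expect_lt(pf$iterations, p$pf$iterations + 5)
})

test_that("BH step-up matches the manual worked example and guards its inputs", {
  p <- c(0.001, 0.008, 0.039, 0.041)
  # manual step-up: largest i with p_(i) <= i alpha / m is i = 4
  expect_equal(bh_select(p, alpha = 0.05, m = 4), rep(TRUE, 4))
  expect_equal(bh_select(rep(1, 6), alpha = 0.05), rep(FALSE, 6))
  expect_equal(bh_select(0.009, alpha = 0.01), TRUE)
  expect_error(bh_select(p, alpha = 0.05, m = 3), "does not match")
  expect_error(bh_select(c(0.5, 1.2)), "p-values")
})

test_that("BH on uniform-null p-values rejects at most at the nominal rate", {
  set.seed(6)
  n_rep <- 2000
  any_rej <- replicate(n_rep, any(bh_select(runif(10), alpha = 0.05)))
  rate <- mean(any_rej)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("bootstrap sign p-values use the finite-sample correction", {
  expect_equal(bootstrap_sign_pvalue(c(-1, -2, -3), -1.5), 1 / 4)
  expect_equal(bootstrap_sign_pvalue(c(-1, -2, 3), -1.5), 2 / 4)
  expect_equal(bootstrap_sign_pvalue(c(1, 1), 0), 1)
})

test_that("8 analyzed nucleotides give 28 simultaneous pair hypotheses", {
  expect_identical(n_pair_hypotheses(8), 28L)
  expect_identical(n_pair_hypotheses(2), 1L)
})

test_that("coupling bootstrap CIs cover the ground truth", {
  # calibrated coverage of nominal 95% intervals, scaled-down study
  model <- coupled_model(J12 = -1)
  buf <- buffer_spec(V_B = 437, concentration = 5.7e-3)
  n_rep <- 40
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- synth_binding_trajectories(model, n_frames = 2500, seed = 1000 + r)
    occ <- sim$occupancies
    cm <- build_count_matrix(occ)
    pf <- solve_partition_functions(cm)
    est_at <- function(counts, pf0, tw = NULL) {
      w <- frame_weights(pf0, mu_from_concentration(pf0, buf), counts, occ,
                         traj_weights = tw)
      p <- pair_state_frequencies(sim$binding, w, "nuc1", "nuc2")
      coupling_free_energy(p)
    }
    point <- est_at(cm, pf)
    reps <- bayesian_bootstrap(function(tw) {
      rc <- reweight_counts(cm, tw)
      est_at(rc, solve_partition_functions(rc, init = pf, likelihood_trace = FALSE), tw)
    }, trajectory_Ns = 1:model$N_max, n_iter = 150, seed = 2000 + r)
    se <- sd(reps[, 1], na.rm = TRUE)
    covered[r] <- abs(point - (-1)) <= 1.96 * se
  }
  expect_gte(mean(covered), 0.90)
})
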