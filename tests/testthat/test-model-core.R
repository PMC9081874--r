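test_that("sigmoid obeys the logistic contract", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(0, h = 2.5), 1.25)
  expect_equal(sigmoid(100), 1)
  expect_equal(sigmoid(-100), 0)
  v <- seq(-8, 8, length.out = 41)
  expect_equal(sigmoid(v) + sigmoid(-v), rep(1, length(v)))
  expect_equal(sigmoid(v, h = 3) + sigmoid(-v, h = 3), rep(3, length(v)))
  expect_true(all(diff(sigmoid(v)) > 0))
  expect_error(sigmoid(NaN), "non-finite")
  expect_error(sigmoid(Inf), "non-finite")
})

test_that("drift matches the rate equations at forced points", {
  p <- node_params(tau_e = 12, tau_i = 7, w_ee = 5, w_ei = 4, w_ie = 3,
                   w_ii = 2, B_e = 1, B_i = 2)
  # (1 - E) factor kills the gain term at E = 1
  for (I in c(0, 0.3, 1)) {
    expect_equal(drift(1, I, p, J_e = 2)$dE, -1 / p$tau_e)
  }
  # bare sigmoid at the origin with no recurrent coupling
  p0 <- node_params(tau_e = 9, B_e = 1.5)
  d0 <- drift(0, 0, p0, J_e = 0.7)
  expect_equal(d0$dE, sigmoid(0.7 - 1.5) / 9)
  expect_gte(d0$dE, 0)
  expect_error(drift(NA, 0, p), "non-finite")
})

test_that("drift vanishes at equilibria found by the root-finder", {
  set.seed(11)
  for (k in 1:5) {
    p <- random_params()
    J <- runif(1, -4, 4)
    eq <- find_equilibria(p, J)
    for (r in seq_len(nrow(eq))) {
      d <- drift(eq$E[r], eq$I[r], p, J_e = J + p$B_e)
      expect_lt(max(abs(c(d$dE, d$dI))), 1e-9)
    }
  }
})

test_that("the deterministic flow keeps the unit box forward-invariant", {
  p <- regime_params("limit_cycle")
  for (J in c(-3, 0, 4)) {
    for (st in list(c(0, 0), c(1, 1), c(0, 1), c(1, 0))) {
      d <- drift(st[1], st[2], p, J_e = J + p$B_e)
      if (st[1] == 1) expect_lt(d$dE, 0) else expect_gte(d$dE, 0)
      if (st[2] == 1) expect_lt(d$dI, 0) else expect_gte(d$dI, 0)
    }
  }
})

test_that("external_input is the row-wise adjacency sum scaled by G", {
  A <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  c2 <- connectome(A)
  expect_equal(unname(external_input(c(0.9, 0.5), c2, G = 0.7)), c(0.35, 0))
  expect_equal(unname(external_input(c(0.9, 0.5), c2, G = 0)), c(0, 0))
  # brute-force double loop on a random 10-node instance
  set.seed(21)
  A10 <- matrix(rbinom(100, 1, 0.4), 10, 10); diag(A10) <- 0
  c10 <- connectome(A10)
  E <- runif(10)
  expected <- vapply(1:10, function(a) 1.3 * sum(A10[a, ] * E), numeric(1))
  expect_equal(unname(external_input(E, c10, 1.3)), expected)
  # linear in G and superposed in E
  E2 <- runif(10)
  expect_equal(external_input(E, c10, 2.6), 2 * external_input(E, c10, 1.3))
  expect_equal(external_input(E + E2, c10, 1.3),
               external_input(E, c10, 1.3) + external_input(E2, c10, 1.3))
  expect_error(external_input(runif(9), c10, 1), "length")
})

test_that("total_input subtracts the threshold elementwise", {
  expect_equal(total_input(0, 1.5), -1.5)
  expect_equal(total_input(3.3, 3.3), 0)
  J <- c(0.2, 1, 4); B <- c(1, 1, 2)
  expect_equal(total_input(J, B), J - B)
})

test_that("z-scoring follows the sample-SD convention", {
  d <- zscore_densities(c(1, 2, 3), c(10, 20, 60))
  expect_equal(d$e_z, c(-1, 0, 1))
  expect_equal(mean(d$i_z), 0)
  expect_equal(stats::sd(d$i_z), 1)
  # affine invariance of the raw scale
  d2 <- zscore_densities(5 + 2 * c(1, 2, 3), 0.1 * c(10, 20, 60))
  expect_equal(d2$e_z, d$e_z)
  expect_equal(d2$i_z, d$i_z)
  # population convention gives unit population SD
  ds <- zscore_densities(c(1, 2, 3), c(10, 20, 60), convention = "population")
  expect_equal(stats::sd(ds$e_z) * sqrt(2 / 3), 1)
  set.seed(5)
  dr <- zscore_densities(rlnorm(40), rlnorm(40))
  expect_equal(mean(dr$e_z), 0)
  expect_equal(stats::sd(dr$e_z), 1)
  expect_error(zscore_densities(rep(2, 5), 1:5), "constant excitatory")
  expect_error(zscore_densities(1:5, rep(1, 5)), "constant inhibitory")
  expect_error(zscore_densities(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("perturbation fields scale linearly with sigma and reject
           non-positive weights", {
  d <- zscore_densities(c(1, 2, 3), c(3, 2, 1), labels = c("A", "B", "C"))
  f0 <- perturbation_field(d, 0)
  expect_equal(f0$R_e, rep(0, 3))
  expect_equal(f0$R_i, rep(0, 3))
  f <- perturbation_field(d, 0.2)
  expect_equal(f$R_e, 0.2 * d$e_z)
  f2 <- perturbation_field(d, 0.4)
  expect_equal(f2$R_e, 2 * f$R_e)
  expect_equal(f2$R_i, 2 * f$R_i)
  # sigma = 1 would give R = -1 at region A (e_z = -1): rejected by name
  expect_error(perturbation_field(d, 1.2), "A")
  expect_error(perturbation_field(d, -0.1), "non-negative")
})

test_that("apply_perturbations touches only the prescribed weights", {
  nominal <- regime_params("limit_cycle")
  n <- 5
  zf <- zero_field(n)
  expect_identical(apply_perturbations(nominal, zf),
                   rep(list(nominal), n))
  f <- zero_field(n)
  f$R_e <- rep(0.1, n)
  pp <- apply_perturbations(nominal, f)[[1]]
  expect_equal(pp$w_ee, nominal$w_ee * 1.1)
  expect_equal(pp$w_ie, nominal$w_ie * 1.1)
  expect_equal(pp$w_ii, nominal$w_ii)
  expect_equal(pp$w_ei, nominal$w_ei)
  expect_equal(pp$tau_e, nominal$tau_e)
  expect_equal(pp$B_e, nominal$B_e)
  # random 37-region field against an explicit elementwise loop
  set.seed(8)
  d <- zscore_densities(rlnorm(37), rlnorm(37))
  fr <- perturbation_field(d, 0.3)
  per <- apply_perturbations(nominal, fr)
  for (a in seq_len(37)) {
    expect_equal(per[[a]]$w_ee, nominal$w_ee * (1 + 0.3 * d$e_z[a]))
    expect_equal(per[[a]]$w_ie, nominal$w_ie * (1 + 0.3 * d$e_z[a]))
    expect_equal(per[[a]]$w_ii, nominal$w_ii * (1 + 0.3 * d$i_z[a]))
    expect_equal(per[[a]]$w_ei, nominal$w_ei * (1 + 0.3 * d$i_z[a]))
  }
  # perturbed weights are continuous and monotone in sigma
  sig <- seq(0, 0.5, by = 0.05)
  w <- vapply(sig, function(s) {
    apply_perturbations(nominal, perturbation_field(d, s))[[3]]$w_ee
  }, numeric(1))
  expect_true(all(diff(w) != 0))
  expect_true(all(diff(w) > 0) || all(diff(w) < 0))
})

test_that("build_network validates and reproduces the homogeneous case", {
  set.seed(3)
  A <- matrix(rbinom(36, 1, 0.5), 6, 6); diag(A) <- 0
  con <- connectome(A)
  nominal <- regime_params("fixed_point")
  hom <- build_network(con, nominal, G = 0.5)
  expect_length(hom$params, 6)
  expect_identical(hom$params, rep(list(nominal), 6))
  d <- zscore_densities(rlnorm(6), rlnorm(6), labels = con$labels)
  het0 <- build_network(con, nominal, G = 0.5,
                        field = perturbation_field(d, 0))
  expect_identical(het0$params, hom$params)
  expect_error(build_network(con, nominal, G = -1), "non-negative")
  expect_error(build_network(con, nominal, G = 0.5, field = zero_field(5)),
               "regions")
})

test_that("node parameters round-trip through flat key-value serialization", {
  p <- regime_params("hysteresis")
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(p), f)
  back <- do.call(node_params, yaml::read_yaml(f))
  expect_equal(back, p)
  unlink(f)
})

test_that("parameter sets quoted in V and s convert to mV and ms", {
  p_vs <- node_params(tau_e = 0.01, tau_i = 0.02, a_e = 1000, a_i = 1500,
                      w_ee = 1.6e-5, w_ei = 1.2e-5, w_ie = 1.5e-5,
                      w_ii = 3e-6, B_e = 0.0015, B_i = 0.0037)
  p <- params_from_vs(p_vs)
  expect_equal(p$tau_e, 10)
  expect_equal(p$B_e, 1.5)
  expect_equal(p$a_e, 1)
  expect_equal(p$w_ee, 16)
})

test_that("invalid node parameters are rejected with named offenders", {
  expect_error(node_params(tau_e = 0), "tau_e")
  expect_error(node_params(a_i = -1), "a_e, a_i", fixed = TRUE)
  expect_error(node_params(w_ei = -2), "w_ei")
  expect_error(update_params(regime_params("fixed_point"), nope = 1), "unknown")
})
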