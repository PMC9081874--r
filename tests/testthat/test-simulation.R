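# a network of isolated nodes (empty adjacency, G = 0) pinned at a fixed
# external drive: the workhorse for single-node simulator contracts
isolated_pair <- function(p, G = 0) {
  build_network(connectome(matrix(0, 2, 2)), p, G = G)
}

test_that("a noise-free run started at a stable equilibrium stays put", {
  p <- regime_params("limit_cycle")
  J_tot <- 1    # outside the oscillatory window: unique stable equilibrium
  eq <- find_equilibria(p, J_tot)
  st <- wcnet:::equilibrium_stability(p, eq$E, eq$I, J_tot)
  expect_equal(st$stability, "stable")
  cfg <- sim_config(dt = 0.1, T = 1000, transient = 0, noise_s = 0,
                    seed = 1, init = list(E = eq$E, I = eq$I))
  r <- simulate_network(isolated_pair(p), cfg, J_const = J_tot + p$B_e)
  expect_lt(max(abs(r$E - eq$E)), 1e-9)   # 1e4 steps
  expect_lt(max(abs(r$I - eq$I)), 1e-9)
})

test_that("the same seed gives bit-identical trajectories", {
  st <- tiny_study(N = 6, seed = 9, T = 800)
  r1 <- simulate_network(st$model, st$cfg)
  r2 <- simulate_network(st$model, st$cfg)
  expect_identical(r1$E, r2$E)
  expect_identical(r1$I, r2$I)
  cfg3 <- st$cfg; cfg3$seed <- st$cfg$seed + 1L
  r3 <- simulate_network(st$model, cfg3)
  expect_false(identical(r1$E, r3$E))
})

test_that("oscillation period near onset matches the Hopf eigenfrequency", {
  p <- regime_params("limit_cycle")
  d <- annotate_diagram(trace_branches(p, c(-3, 0), 61), envelope = FALSE)
  hopf <- d$hopfs[which.max(d$hopfs$J_tot), ]   # upper Hopf point
  J <- hopf$J_tot - 0.1                          # just inside the window
  tr <- wcnet:::integrate_single_node(p, J, 0.3, 0.3, T = 4000, dt = 0.05,
                                      store_every = 4L)
  E <- tr$E[-(1:10000)]                          # discard settling
  up <- which(diff(sign(E - mean(E))) > 0)
  periods <- diff(up) * 0.2                      # stored step = 0.2 ms
  expect_gt(length(periods), 10)
  expect_equal(mean(periods), 2 * pi / hopf$im, tolerance = 0.1)
})

test_that("transient removal drops exactly the documented window", {
  p <- regime_params("fixed_point")
  r <- simulate_network(isolated_pair(p), sim_config(seed = 2),
                        J_const = p$B_e)
  expect_equal(ncol(r$E), 1.2e6)   # default: 1.2e5 ms at dt = 0.1 ms
  rt <- remove_transient(r)
  expect_equal(ncol(r$E) - ncol(rt$E), 10000)   # 1 s at 0.1 ms steps
  expect_equal(max(rt$t) - min(rt$t) + rt$cfg$dt,
               rt$cfg$T - rt$cfg$transient)
  expect_error(remove_transient(rt), "already removed")
  # transient = 0 is the identity
  r0 <- remove_transient(r, transient = 0)
  expect_identical(r0$E, r$E)
})

test_that("input ranges follow the coupling term along the trajectory", {
  A <- rbind(c(0, 1, 1, 0),
             c(0, 0, 1, 1),
             c(1, 0, 0, 0),
             c(0, 0, 0, 0))   # region 4 has no afferents
  con <- connectome(A)
  p <- update_params(regime_params("fixed_point"), B_e = 2)
  cfg <- sim_config(T = 2000, transient = 500, seed = 4, store_every = 5L)
  m0 <- build_network(con, p, G = 0)
  rng0 <- input_ranges(remove_transient(simulate_network(m0, cfg)))
  expect_true(all(rng0$Je_min == 0 & rng0$Je_max == 0))
  expect_equal(rng0$Jtot_min, rep(-2, 4))
  m <- build_network(con, p, G = 0.9)
  r <- remove_transient(simulate_network(m, cfg))
  rng <- input_ranges(r)
  expect_equal(rng$Je_min[4], 0)
  expect_equal(rng$Je_max[4], 0)
  # brute-force recomputation over the stored trajectory
  J <- 0.9 * (A %*% r$E)
  for (a in 1:4) {
    expect_equal(rng$Je_min[a], min(J[a, ]))
    expect_equal(rng$Je_max[a], max(J[a, ]))
  }
  expect_error(input_ranges(simulate_network(m, cfg)), "transient")
})

test_that("regime occupancy partitions experienced inputs by attractor", {
  st <- tiny_study(N = 12, seed = 1, regime = "limit_cycle", G = 0.5,
                   B_e = 1.5, T = 4e3)
  r <- remove_transient(simulate_network(st$model, st$cfg))
  d <- annotate_diagram(trace_branches(regime_params("limit_cycle"),
                                       c(-2.6, 1), 81), envelope = FALSE)
  # homogeneous model: every region is cut at the same boundaries
  occ <- regime_occupancy(r, d)
  expect_true(all(occ$label %in% c("fixed_point", "limit_cycle", "bistable")))
  cuts <- unique(occ$J_hi[occ$label == "limit_cycle"])
  rngs <- input_ranges(r)
  inner <- occ[occ$J_hi < max(rngs$Jtot_max) - 1e-9, ]
  expect_true(all(table(inner$J_hi) >= 1))
  # heterogeneous model at sigma = 0.2: regions differ in both range and
  # rules; some span both attractor types, some only one
  mh <- build_network(st$con, regime_params("limit_cycle"), G = 0.5,
                      field = perturbation_field(st$dens, 0.2))
  rh <- remove_transient(simulate_network(mh, st$cfg))
  diags <- lapply(mh$params, function(pp)
    annotate_diagram(trace_branches(pp, c(-2.8, 1.2), 61), envelope = FALSE))
  occh <- regime_occupancy(rh, diags)
  per_region <- tapply(occh$label, occh$region, function(x) length(unique(x)))
  expect_gt(max(per_region), 1)    # some regions access both dynamics
  expect_equal(min(per_region), 1) # others stay in a single regime
})

test_that("carpet data reorders rows and downsamples columns", {
  st <- tiny_study(N = 6, seed = 12, T = 1500)
  r <- remove_transient(simulate_network(st$model, st$cfg))
  labs <- st$con$labels
  cd_id <- carpet_data(r, ordering = labs, downsample = 1L)
  expect_identical(cd_id$E, r$E)
  perm <- rev(labs)
  cd <- carpet_data(r, ordering = perm)
  expect_identical(cd$E, r$E[match(perm, labs), ])
  expect_setequal(rownames(cd$E), rownames(r$E))
  cd3 <- carpet_data(r, ordering = labs, downsample = 3L)
  expect_identical(cd3$E, r$E[, seq(3, ncol(r$E), by = 3)])
  expect_error(carpet_data(r, ordering = c(labs[-1], "NOPE")), "NOPE")
  expect_error(carpet_data(r, ordering = labs[-1]), "permutation")
})

test_that("default noise almost never clips the unit box", {
  st <- tiny_study(N = 8, seed = 6, T = 5e3)
  r <- simulate_network(st$model, st$cfg)
  n_updates <- 2 * 8 * (st$cfg$T / st$cfg$dt)
  expect_lt(r$n_clipped / n_updates, 1e-6)
})

test_that("stationary variance under small noise matches the linearised
           (Lyapunov) prediction", {
  p <- regime_params("limit_cycle")
  J_tot <- 1
  eq <- find_equilibria(p, J_tot)
  A <- jacobian(p, eq$E, eq$I, J_tot)
  s <- 1e-4
  # solve A P + P A' + s^2 I = 0 for the stationary covariance P
  K <- kronecker(diag(2), A) + kronecker(A, diag(2))
  P <- matrix(solve(K, -as.vector(s^2 * diag(2))), 2, 2)
  cfg <- sim_config(dt = 0.05, T = 1e5, transient = 2000, noise_s = s,
                    seed = 3, init = list(E = eq$E, I = eq$I))
  r <- remove_transient(simulate_network(isolated_pair(p), cfg,
                                         J_const = J_tot + p$B_e))
  expect_equal(stats::var(r$E[1, ]), P[1, 1], tolerance = 0.2)
  expect_equal(stats::var(r$I[1, ]), P[2, 2], tolerance = 0.2)
})

test_that("the deterministic integrator converges at first order in dt", {
  st <- tiny_study(N = 5, seed = 10)
  model <- st$model
  run_end <- function(dt) {
    cfg <- sim_config(dt = dt, T = 50, transient = 0, noise_s = 0, seed = 1,
                      init = list(E = 0.3, I = 0.2))
    r <- simulate_network(model, cfg)
    c(r$E[, ncol(r$E)], r$I[, ncol(r$I)])
  }
  ref <- run_end(0.003125)
  dts <- c(0.4, 0.2, 0.1, 0.05)
  errs <- vapply(dts, function(dt) max(abs(run_end(dt) - ref)), numeric(1))
  slope <- stats::coef(stats::lm(log(errs) ~ log(dts)))[2]
  expect_equal(unname(slope), 1, tolerance = 0.2)
  expect_true(all(diff(errs) < 0))  # halving dt shrinks the error
})

test_that("blow-up aborts with the offending region named", {
  # the drift is bounded and states are clipped, so divergence can only
  # come from absurdly large noise increments — which must be caught
  p <- regime_params("fixed_point")
  cfg <- sim_config(dt = 0.1, T = 10, transient = 0, noise_s = 5e3, seed = 1)
  expect_error(simulate_network(isolated_pair(p), cfg),
               "blow-up in region 1 at step 1")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(T = 500, transient = 600), "transient")
  expect_error(sim_config(noise_s = -1), "noise_s")
})
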