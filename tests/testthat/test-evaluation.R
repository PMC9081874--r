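test_that("compute_fc matches the covariance-formula oracle", {
  set.seed(17)
  X <- matrix(rnorm(500), nrow = 5)   # 5 regions x 100 samples
  rownames(X) <- paste0("R", 1:5)
  fc <- compute_fc(X)
  for (a in 1:4) for (b in (a + 1):5) {
    expect_equal(fc[a, b], pearson_oracle(X[a, ], X[b, ]))
  }
  expect_equal(unname(diag(unclass(fc))), rep(1, 5))
  # identical series correlate at 1, mirrored series at -1
  Y <- rbind(A = X[1, ], B = X[1, ], C = 1 - X[1, ], D = X[2, ])
  fcy <- compute_fc(Y)
  expect_equal(fcy["A", "B"], 1)
  expect_equal(fcy["A", "C"], -1)
  # constant series are rejected by name
  Z <- rbind(A = X[1, ], BAD = rep(0.5, 100))
  expect_error(compute_fc(Z), "BAD")
})

test_that("FC matrices from the pipeline satisfy the FC invariants", {
  st <- tiny_study(N = 6, seed = 2, T = 1500)
  fc <- compute_fc(remove_transient(simulate_network(st$model, st$cfg)))
  expect_true(isSymmetric(unclass(fc)))
  expect_equal(unname(diag(unclass(fc))), rep(1, 6))
  expect_true(all(fc >= -1 & fc <= 1))
  expect_identical(rownames(fc), st$con$labels)
  # and the validator rejects each broken invariant distinctly
  m <- unclass(fc)
  m2 <- m; m2[1, 2] <- m2[1, 2] + 0.2
  expect_error(as_fc(m2), "symmetric")
  m3 <- m; m3[2, 2] <- 0.7
  expect_error(as_fc(m3), "diagonal")
  m4 <- m; m4[1, 3] <- m4[3, 1] <- 1.4
  expect_error(as_fc(m4), "\\[-1, 1\\]")
})

test_that("fcfc_score is a rank correlation over unique pairs", {
  set.seed(23)
  n <- 9
  m <- matrix(runif(n * n, -0.5, 0.9), n, n)
  m <- (m + t(m)) / 2; diag(m) <- 1
  fc <- as_fc(m)
  expect_equal(fcfc_score(fc, fc), 1)
  # rank reversal of the unique pairs gives -1
  neg <- -unclass(fc); diag(neg) <- 1
  expect_equal(fcfc_score(fc, as_fc(neg)), -1)
  # invariance under a strictly monotone transform (cube preserves order)
  cub <- unclass(fc)^3; diag(cub) <- 1
  expect_equal(fcfc_score(fc, as_fc(cub)), 1)
  set.seed(4)
  m2 <- matrix(runif(n * n, -1, 1), n, n); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 1
  fc2 <- as_fc(m2)
  expect_equal(fcfc_score(fc, as_fc(tanh(3 * unclass(fc2)) + diag(n) * (1 - tanh(3)))),
               fcfc_score(fc, fc2))
  # symmetric in its arguments
  expect_equal(fcfc_score(fc, fc2), fcfc_score(fc2, fc))
  # invariant under simultaneous relabeling of regions
  perm <- sample(n)
  pfc <- as_fc(unclass(fc)[perm, perm])
  pfc2 <- as_fc(unclass(fc2)[perm, perm])
  expect_equal(fcfc_score(pfc, pfc2), fcfc_score(fc, fc2))
  # label mismatch and too-small matrices are rejected
  bad <- unclass(fc2); rownames(bad)[1] <- colnames(bad)[1] <- "X1"
  expect_error(fcfc_score(fc, as_fc(bad)), "labels")
  expect_error(fcfc_score(as_fc(diag(2)), as_fc(diag(2))), "3 regions")
})

test_that("scfc_score ranks structural pairs against FC", {
  set.seed(31)
  A <- matrix(rbinom(64, 1, 0.4), 8, 8); diag(A) <- 0
  con <- connectome(A)
  S <- pmax(A, t(A))
  # an FC built as a monotone function of the pair values rank-matches SC
  m <- 0.1 + 0.5 * S; diag(m) <- 1
  dimnames(m) <- list(con$labels, con$labels)
  expect_equal(scfc_score(con, as_fc(m)), 1)
  # random target against a rank-correlation oracle (average ranks for ties)
  t <- matrix(runif(64, -1, 1), 8, 8); t <- (t + t(t)) / 2; diag(t) <- 1
  dimnames(t) <- list(con$labels, con$labels)
  tf <- as_fc(t)
  or <- cor(rank(S[upper.tri(S)]), rank(t[upper.tri(t)]))
  expect_equal(scfc_score(con, tf), or)
  # a fully connected graph has no structural variance to rank
  A1 <- matrix(1, 4, 4); diag(A1) <- 0
  expect_error(scfc_score(connectome(A1), as_fc(diag(4))), "constant")
})

test_that("replicate scores are deterministic in the seed set", {
  # limit-cycle regime: noise-free trajectories still oscillate, so FC
  # stays well-defined when the noise is switched off below
  st <- tiny_study(N = 6, seed = 3, regime = "limit_cycle", G = 0.5,
                   B_e = 1.5, T = 1500)
  target <- synth_target_fc(st$model, st$cfg, 0, n_avg = 1)
  rs1 <- replicate_scores(st$model, st$cfg, target, n_rep = 3, seed_base = 7)
  rs2 <- replicate_scores(st$model, st$cfg, target, n_rep = 3, seed_base = 7)
  expect_identical(rs1$rho, rs2$rho)
  expect_equal(rs1$seeds, 7:9)
  expect_length(rs1$errors, 0)
  # noise-free replicates with identical initial conditions coincide
  cfg0 <- st$cfg; cfg0$noise_s <- 0; cfg0$init <- list(E = 0.3, I = 0.25)
  rs0 <- replicate_scores(st$model, cfg0, target, n_rep = 3, seed_base = 1)
  expect_equal(rs0$sd, 0)
  expect_equal(length(unique(rs0$rho)), 1)
  rs_one <- replicate_scores(st$model, st$cfg, target, n_rep = 1)
  expect_true(is.na(rs_one$sd))
})

test_that("a 1x1 sweep reduces to replicate_scores", {
  st <- tiny_study(N = 6, seed = 5, T = 1500)
  target <- synth_target_fc(st$model, st$cfg, 0.05, noise_seed = 3)
  rs <- replicate_scores(st$model, st$cfg, target, n_rep = 2, seed_base = 11)
  sw <- sweep_grid(st$model, G_values = st$model$G,
                   Be_values = st$model$nominal$B_e,
                   st$cfg, target, n_rep = 2, seed_base = 11)
  expect_equal(nrow(sw$grid), 1)
  expect_equal(sw$grid$mean, rs$mean)
  expect_equal(unname(unlist(sw$grid[paste0("rho_rep", 1:2)])), rs$rho)
  expect_error(sweep_grid(st$model, numeric(0), 1, st$cfg, target), "non-empty")
})

test_that("the sigma = 0 sweep cell reproduces the homogeneous score
           bit-for-bit", {
  st <- tiny_study(N = 8, seed = 21, regime = "limit_cycle", G = 0.5,
                   B_e = 1.5, T = 2000)
  target <- synth_target_fc(st$model, st$cfg, 0.05, noise_seed = 8)
  hom <- replicate_scores(st$model, st$cfg, target, n_rep = 2, seed_base = 5)
  sw <- sigma_sweep(st$model, c(0, 0.2), st$dens, st$cfg, target,
                    n_rep = 2, seed_base = 5)
  expect_identical(sw$grid$mean[1], hom$mean)
  expect_identical(unname(unlist(sw$grid[1, paste0("rho_rep", 1:2)])), hom$rho)
  expect_true(all(sw$grid$feasible))
  # an infeasible sigma is marked, not clamped
  sw2 <- sigma_sweep(st$model, c(0, 50), st$dens, st$cfg, target,
                     n_rep = 1, seed_base = 5)
  expect_false(sw2$grid$feasible[2])
  expect_true(is.na(sw2$grid$mean[2]))
})

test_that("scores detect the model's own connectome against a shuffled one", {
  st <- tiny_study(N = 10, seed = 33, regime = "limit_cycle", G = 0.5,
                   B_e = 1.5, T = 4e3)
  target <- synth_target_fc(st$model, st$cfg, 0.02, noise_seed = 2, n_avg = 2)
  same <- replicate_scores(st$model, st$cfg, target, n_rep = 2,
                           seed_base = 41)$mean
  set.seed(9)
  Ashuf <- st$con$A[sample(10), ]
  diag(Ashuf) <- 0
  mshuf <- build_network(connectome(Ashuf, labels = st$con$labels),
                         regime_params("limit_cycle"), G = 0.5)
  shuf <- replicate_scores(mshuf, st$cfg, target, n_rep = 2,
                           seed_base = 41)$mean
  expect_gt(same, shuf)
})

test_that("permutation test degenerates to p = 1 when heterogeneity is off", {
  st <- tiny_study(N = 6, seed = 13, T = 1200)
  target <- synth_target_fc(st$model, st$cfg, 0.05, noise_seed = 4)
  # sigma = 0: every permuted field is the zero field, so all null scores
  # equal the observed score and the p-value is its maximal 1
  pt <- permutation_test(st$model, st$dens, sigma = 0, st$cfg, target,
                         n_perm = 19, n_rep = 1, seed_base = 3)
  expect_equal(pt$p_value, 1)
  expect_true(all(pt$null == pt$observed))
  expect_gte(pt$p_value, 1 / (pt$n_perm + 1))
  expect_error(permutation_test(st$model, st$dens, 0, st$cfg, target,
                                n_perm = 5), "at least 19")
})
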