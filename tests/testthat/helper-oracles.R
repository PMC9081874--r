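# Independent oracles used by the tests. These deliberately re-implement
# the dynamics inline (no calls into the package's solvers) so that they
# stay independent of the code paths they check.

# RHS of the single-node system in the J_tot coordinate, written out from
# the model equations.
oracle_rhs <- function(p, E, I, J_tot) {
  S <- function(v) p$h / (1 + exp(-v))
  c((-E + (1 - E) * S(p$a_e * p$w_ee * E - p$w_ei * I + J_tot)) / p$tau_e,
    (-I + (1 - I) * S(p$a_i * p$w_ie * E - p$w_ii * I - p$B_i)) / p$tau_i)
}

# Dense grid sign-scan for equilibria in the unit box: a cell whose corners
# show a sign change in both drift components is a candidate; candidates
# are refined by damped Newton with finite-difference Jacobians and then
# deduplicated.
grid_equilibria_oracle <- function(p, J_tot, n = 200, dedup = 1e-5) {
  g <- seq(0, 1, length.out = n + 1)
  Em <- matrix(g, n + 1, n + 1)                 # rows: E
  Im <- matrix(g, n + 1, n + 1, byrow = TRUE)   # cols: I
  S <- function(v) p$h / (1 + exp(-v))
  dE <- (-Em + (1 - Em) * S(p$a_e * p$w_ee * Em - p$w_ei * Im + J_tot)) / p$tau_e
  dI <- (-Im + (1 - Im) * S(p$a_i * p$w_ie * Em - p$w_ii * Im - p$B_i)) / p$tau_i
  sE <- sign(dE); sI <- sign(dI)
  chg <- function(s) {
    a <- s[-(n + 1), -(n + 1)]
    (a * s[-1, -(n + 1)] <= 0) | (a * s[-(n + 1), -1] <= 0) |
      (a * s[-1, -1] <= 0)
  }
  cand <- which(chg(sE) & chg(sI), arr.ind = TRUE)
  if (!nrow(cand)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("E", "I"))))
  fd_jac <- function(x) {
    h <- 1e-7
    cbind((oracle_rhs(p, x[1] + h, x[2], J_tot) -
             oracle_rhs(p, x[1] - h, x[2], J_tot)) / (2 * h),
          (oracle_rhs(p, x[1], x[2] + h, J_tot) -
             oracle_rhs(p, x[1], x[2] - h, J_tot)) / (2 * h))
  }
  roots <- list()
  for (k in seq_len(nrow(cand))) {
    x <- c(g[cand[k, 1]] + 0.5 / n, g[cand[k, 2]] + 0.5 / n)
    ok <- FALSE
    for (it in 1:50) {
      f <- oracle_rhs(p, x[1], x[2], J_tot)
      if (max(abs(f)) < 1e-13) { ok <- TRUE; break }
      step <- tryCatch(solve(fd_jac(x), f), error = function(e) NULL)
      if (is.null(step)) break
      if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
      x <- pmin(pmax(x - step, -0.01), 1.01)
    }
    if (ok && all(x >= -1e-9) && all(x <= 1 + 1e-9)) {
      roots[[length(roots) + 1]] <- pmin(pmax(x, 0), 1)
    }
  }
  if (!length(roots)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("E", "I"))))
  m <- do.call(rbind, roots)
  m <- m[order(m[, 1]), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  if (nrow(m) > 1) {
    for (k in 2:nrow(m)) {
      if (any(apply(m[seq_len(k - 1), , drop = FALSE][keep[seq_len(k - 1)], ,
                                                      drop = FALSE], 1,
                    function(r) max(abs(r - m[k, ])) < dedup))) {
        keep[k] <- FALSE
      }
    }
  }
  m <- m[keep, , drop = FALSE]
  colnames(m) <- c("E", "I")
  m
}

# brute-force Pearson correlation via the covariance formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / sqrt(sum((x - mean(x))^2) / (n - 1)) / sqrt(sum((y - mean(y))^2) / (n - 1))
}

# random valid node parameters covering the model's working ranges
random_params <- function() {
  node_params(tau_e = runif(1, 5, 20), tau_i = runif(1, 5, 40),
              a_e = runif(1, 0.5, 2), a_i = runif(1, 0.5, 2),
              w_ee = runif(1, 0, 16), w_ei = runif(1, 0, 16),
              w_ie = runif(1, 0, 16), w_ii = runif(1, 0, 8),
              B_e = runif(1, 0, 5), B_i = runif(1, 0, 5))
}

# small ready-made study used across tests
tiny_study <- function(N = 8, seed = 42L, regime = "fixed_point",
                       G = 0.8, B_e = 2, T = 4e3) {
  spec <- synth_spec(N = N, n_groups = min(4L, N), seed = seed)
  con <- synth_connectome(spec)
  dens <- synth_densities(spec)
  dens$labels <- con$labels
  model <- build_network(con, update_params(regime_params(regime), B_e = B_e),
                         G = G)
  cfg <- sim_config(T = T, transient = 500, seed = seed, store_every = 10L)
  list(spec = spec, con = con, dens = dens, model = model, cfg = cfg)
}
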