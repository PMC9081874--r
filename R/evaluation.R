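#' Functional connectivity of a simulation
#'
#' Pairwise Pearson correlations between the excitatory time series of all
#' regions, computed over the full retained (post-transient) window with no
#' windowing — static FC.
#'
#' @param r A \code{wc_sim} with transient removed, or an N x T numeric
#'   matrix of regional time series (rows = regions).
#' @return Object of class \code{wc_fc}: symmetric N x N correlation matrix
#'   with unit diagonal and region labels as dimnames.
#' @export
compute_fc <- function(r) {
  if (inherits(r, "wc_sim")) {
    if (!r$transient_removed) stop("remove the transient before computing FC")
    E <- r$E
  } else {
    E <- as.matrix(r)
  }
  if (ncol(E) < 2) stop("need at least 2 time samples to compute FC")
  sds <- apply(E, 1, stats::sd)
  if (any(sds == 0)) {
    labs <- rownames(E)
    if (is.null(labs)) labs <- paste0("R", seq_len(nrow(E)))
    stop("constant activity time series (correlation undefined) in region(s): ",
         paste(labs[sds == 0], collapse = ", "))
  }
  fc <- stats::cor(t(E))
  diag(fc) <- 1
  as_fc(fc)
}

#' Construct/validate an FC matrix object
#'
#' @param m Symmetric numeric matrix with unit diagonal and entries in
#'   [-1, 1].
#' @return A \code{wc_fc} object.
#' @export
as_fc <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("FC matrix must be square")
  if (any(!is.finite(m))) stop("FC matrix has non-finite entries")
  if (max(abs(m - t(m))) > 1e-8) stop("FC matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("FC matrix must have unit diagonal")
  if (any(m < -1 - 1e-8) || any(m > 1 + 1e-8)) stop("FC entries must lie in [-1, 1]")
  m[m > 1] <- 1; m[m < -1] <- -1
  m <- (m + t(m)) / 2
  diag(m) <- 1
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("R", seq_len(nrow(m))), paste0("R", seq_len(nrow(m))))
  }
  class(m) <- c("wc_fc", "matrix")
  m
}

# strictly-upper-triangle vector of unique pairwise values
upper_vals <- function(m) m[upper.tri(m)]

#' FC-FC score: Spearman agreement of two FC matrices
#'
#' The Spearman rank correlation between the N(N-1)/2 unique pairwise FC
#' values (strict upper triangle, diagonal excluded) of a model FC and a
#' target FC. Rank correlation is used to capture a potentially nonlinear
#' but monotone relationship; ties get average ranks.
#'
#' @param model_fc,target_fc \code{wc_fc} matrices with identical labels in
#'   identical order (N >= 3).
#' @return A single correlation in [-1, 1].
#' @export
fcfc_score <- function(model_fc, target_fc) {
  if (nrow(model_fc) != nrow(target_fc)) stop("FC matrices differ in size")
  if (nrow(model_fc) < 3) stop("need at least 3 regions for an FC-FC score")
  if (!identical(rownames(model_fc), rownames(target_fc))) {
    stop("FC matrices have mismatched region labels")
  }
  stats::cor(upper_vals(unclass(model_fc)), upper_vals(unclass(target_fc)),
             method = "spearman")
}

#' SC-FC score: direct structure-function rank correlation
#'
#' Spearman correlation between the structural connectome and the target FC
#' over unique region pairs. FC is undirected, so the directed adjacency is
#' first reduced to one value per pair; the default takes
#' \code{max(A[a,b], A[b,a])} (a pair is connected if either direction is),
#' with \code{"mean"} and \code{"both"} (logical AND) as alternatives.
#'
#' @param c A \code{wc_connectome}.
#' @param target_fc A \code{wc_fc} with matching region count.
#' @param reduce Directed-to-pair reduction: \code{"max"} (default),
#'   \code{"mean"}, or \code{"both"}.
#' @return A single correlation in [-1, 1].
#' @export
scfc_score <- function(c, target_fc, reduce = c("max", "mean", "both")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(c, "wc_connectome"))
  if (c$n != nrow(target_fc)) stop("connectome and FC differ in region count")
  S <- switch(reduce,
              max = pmax(c$A, t(c$A)),
              mean = (c$A + t(c$A)) / 2,
              both = (c$A * t(c$A)))
  sv <- upper_vals(S)
  if (stats::sd(sv) == 0) {
    stop("structural pair values are constant: SC-FC correlation undefined")
  }
  stats::cor(sv, upper_vals(unclass(target_fc)), method = "spearman")
}

#' Replicate FC-FC scores over random seeds
#'
#' Run the full simulate -> FC -> score pipeline \code{n_rep} times with
#' seeds \code{seed_base, seed_base + 1, ...} and summarise as mean and SD
#' (SD is NA for a single replicate). A failed replicate is recorded with
#' its error message, never silently dropped.
#'
#' @param model A \code{wc_network}.
#' @param cfg A \code{wc_sim_config} (its seed field is overridden per
#'   replicate).
#' @param target_fc Target \code{wc_fc}.
#' @param n_rep Number of replicates (>= 1).
#' @param seed_base First seed.
#' @return List with \code{rho} (length n_rep, NA where failed),
#'   \code{mean}, \code{sd}, \code{seeds}, \code{errors}.
#' @export
replicate_scores <- function(model, cfg, target_fc, n_rep = 5,
                             seed_base = 1L) {
  if (n_rep < 1) stop("n_rep must be >= 1")
  seeds <- seed_base + seq_len(n_rep) - 1L
  errors <- character(0)
  rho <- vapply(seeds, function(s) {
    cfg$seed <- as.integer(s)
    tryCatch({
      r <- remove_transient(simulate_network(model, cfg))
      fcfc_score(compute_fc(r), target_fc)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- sprintf("seed %d: %s", s, conditionMessage(e))
      NA_real_
    })
  }, numeric(1))
  ok <- rho[!is.na(rho)]
  list(rho = rho, mean = if (length(ok)) mean(ok) else NA_real_,
       sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
       seeds = seeds, errors = errors)
}

#' Sweep the coupling-threshold plane for FC-FC fit
#'
#' Evaluate \code{\link{replicate_scores}} on every cell of a G x B_e grid,
#' setting the excitatory threshold uniformly across regions (a homogeneous
#' sweep). Cells are independent: each uses the same replicate seed set.
#'
#' @param model_template A \code{wc_network} whose G and B_e are overridden
#'   cell by cell.
#' @param G_values,Be_values Non-empty numeric axes.
#' @param cfg A \code{wc_sim_config}.
#' @param target_fc Target \code{wc_fc}.
#' @param n_rep Replicates per cell.
#' @param seed_base First replicate seed.
#' @return Object of class \code{wc_sweep}: list(grid — data.frame with G,
#'   B_e, mean, sd, and one column per replicate —, G_values, Be_values,
#'   axis = "G_Be", n_rep, seeds).
#' @export
sweep_grid <- function(model_template, G_values, Be_values, cfg, target_fc,
                       n_rep = 5, seed_base = 1L) {
  if (!length(G_values) || !length(Be_values)) stop("sweep axes must be non-empty")
  stopifnot(inherits(model_template, "wc_network"))
  cells <- expand.grid(G = G_values, B_e = Be_values,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    nominal <- update_params(model_template$nominal, B_e = cells$B_e[k])
    m <- build_network(model_template$connectome, nominal,
                       G = cells$G[k], field = model_template$field)
    replicate_scores(m, cfg, target_fc, n_rep, seed_base)
  })
  grid <- cbind(cells,
                mean = vapply(res, `[[`, numeric(1), "mean"),
                sd = vapply(res, function(x) ifelse(is.na(x$sd), NA_real_, x$sd),
                            numeric(1)))
  reps <- matrix(vapply(res, `[[`, numeric(n_rep), "rho"),
                 ncol = n_rep, byrow = TRUE,
                 dimnames = list(NULL, paste0("rho_rep", seq_len(n_rep))))
  structure(list(grid = cbind(grid, reps), G_values = G_values,
                 Be_values = Be_values, axis = "G_Be", n_rep = n_rep,
                 seeds = seed_base + seq_len(n_rep) - 1L),
            class = "wc_sweep")
}

#' @export
print.wc_sweep <- function(x, ...) {
  best <- x$grid[which.max(x$grid$mean), ]
  cat(sprintf("Sweep over %s: %d cells x %d replicates; best mean rho = %.3f\n",
              x$axis, nrow(x$grid), x$n_rep, best$mean))
  print(best, row.names = FALSE)
  invisible(x)
}

#' Best-scoring cell of a sweep
#'
#' @param x A \code{wc_sweep}.
#' @return One-row data.frame: the cell with the highest mean score.
#' @export
sweep_best <- function(x) {
  stopifnot(inherits(x, "wc_sweep"))
  x$grid[which.max(x$grid$mean), , drop = FALSE]
}

#' Sweep the heterogeneity scaling parameter
#'
#' Score the model at each value of the density-to-parameter scaling
#' \code{sigma}, rebuilding the heterogeneous network per value. The
#' \code{sigma = 0} cell is the homogeneous model and reproduces its score
#' bit-for-bit under matching seeds. A sigma whose perturbation would force
#' non-positive weights is marked infeasible (NA scores) rather than
#' clamped.
#'
#' @param model_template A \code{wc_network} providing connectome, nominal
#'   parameters and G.
#' @param sigma_values Non-negative sigma axis (default includes 0 and the
#'   0.2 working point).
#' @param densities A \code{wc_densities}.
#' @param cfg,target_fc,n_rep,seed_base As in \code{\link{sweep_grid}}.
#' @return A \code{wc_sweep} with axis \code{"sigma"} and a
#'   \code{feasible} column.
#' @export
sigma_sweep <- function(model_template, sigma_values = seq(0, 1, by = 0.1),
                        densities, cfg, target_fc, n_rep = 5, seed_base = 1L) {
  if (!length(sigma_values)) stop("sigma axis must be non-empty")
  if (any(sigma_values < 0)) stop("sigma values must be >= 0")
  stopifnot(inherits(model_template, "wc_network"), inherits(densities, "wc_densities"))
  res <- lapply(sigma_values, function(s) {
    field <- tryCatch(perturbation_field(densities, s), error = function(e) NULL)
    if (is.null(field)) return(NULL)
    m <- build_network(model_template$connectome, model_template$nominal,
                       G = model_template$G, field = field)
    replicate_scores(m, cfg, target_fc, n_rep, seed_base)
  })
  feasible <- !vapply(res, is.null, logical(1))
  grid <- data.frame(
    sigma = sigma_values,
    mean = vapply(res, function(x) if (is.null(x)) NA_real_ else x$mean, numeric(1)),
    sd = vapply(res, function(x) if (is.null(x) || is.na(x$sd)) NA_real_ else x$sd,
                numeric(1)),
    feasible = feasible)
  reps <- matrix(vapply(res, function(x) if (is.null(x)) rep(NA_real_, n_rep) else x$rho,
                        numeric(n_rep)),
                 ncol = n_rep, byrow = TRUE,
                 dimnames = list(NULL, paste0("rho_rep", seq_len(n_rep))))
  structure(list(grid = cbind(grid, reps), sigma_values = sigma_values,
                 axis = "sigma", n_rep = n_rep,
                 seeds = seed_base + seq_len(n_rep) - 1L),
            class = "wc_sweep")
}

#' Permutation test of the cell-density heterogeneity map
#'
#' Does the measured assignment of excitatory/inhibitory densities to
#' regions explain the target FC better than chance? Each null draw applies
#' one random permutation jointly to the (e, i) z-score pairs (preserving
#' the match between e and i but shuffling their assignment to regions),
#' rebuilds the heterogeneous model at the given sigma, and records the
#' mean FC-FC score. The one-sided p-value is
#' \code{(1 + #\{null >= observed\}) / (n_perm + 1)}.
#'
#' @param model_template A \code{wc_network} providing connectome, nominal
#'   parameters and G.
#' @param densities A \code{wc_densities} (the measured map).
#' @param sigma Heterogeneity scaling at which to test.
#' @param cfg,target_fc,n_rep,seed_base As in \code{\link{sweep_grid}}.
#' @param n_perm Number of permutations (>= 19).
#' @param perm_seed Seed for drawing permutations.
#' @return Object of class \code{wc_perm_test}: list(observed, null
#'   (length n_perm, NA where infeasible), p_value, n_perm, perm_seed,
#'   n_infeasible).
#' @export
permutation_test <- function(model_template, densities, sigma, cfg, target_fc,
                             n_perm = 199, n_rep = 5, seed_base = 1L,
                             perm_seed = 1000L) {
  if (n_perm < 19) stop("n_perm must be at least 19")
  stopifnot(inherits(densities, "wc_densities"))
  score_at <- function(d) {
    field <- perturbation_field(d, sigma)
    m <- build_network(model_template$connectome, model_template$nominal,
                       G = model_template$G, field = field)
    replicate_scores(m, cfg, target_fc, n_rep, seed_base)$mean
  }
  observed <- score_at(densities)
  n <- length(densities$e_z)
  set.seed(perm_seed)
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  null <- vapply(perms, function(pr) {
    d <- densities
    d$e_raw <- d$e_raw[pr]; d$i_raw <- d$i_raw[pr]
    d$e_z <- d$e_z[pr]; d$i_z <- d$i_z[pr]
    tryCatch(score_at(d), error = function(e) NA_real_)
  }, numeric(1))
  ok <- null[!is.na(null)]
  p <- (1 + sum(ok >= observed)) / (length(ok) + 1)
  structure(list(observed = observed, null = null, p_value = p,
                 n_perm = n_perm, perm_seed = perm_seed,
                 n_infeasible = sum(is.na(null))),
            class = "wc_perm_test")
}

#' @export
print.wc_perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed mean rho = %.3f vs %d density permutations; p = %.3f\n",
    x$observed, x$n_perm, x$p_value))
  if (x$n_infeasible) cat(sprintf("  (%d infeasible permutations)\n", x$n_infeasible))
  invisible(x)
}
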