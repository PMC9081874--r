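#' Simulation configuration
#'
#' Settings for the stochastic (Euler-Maruyama) network integration. The
#' defaults reproduce the reference protocol: step 0.1 ms, 1.2e5 ms total,
#' 1 s transient discarded, additive white noise of standard deviation
#' 1.3e-5 applied to both state variables, scaled by sqrt(dt) per step.
#'
#' @param dt Integration step (ms, > 0).
#' @param T Total simulated duration (ms, > transient).
#' @param transient Initial window discarded by \code{\link{remove_transient}}
#'   (ms, >= 0).
#' @param noise_s Noise standard deviation (per sqrt(ms); >= 0; 0 gives
#'   deterministic forward Euler).
#' @param noise_on_I Apply noise to the inhibitory variable too (default
#'   TRUE; FALSE restricts noise to E).
#' @param seed Integer RNG seed.
#' @param init Initial state: \code{"default"} (E = I = 0.25 plus seeded
#'   jitter of SD 1e-3), \code{"low"} (0.05), \code{"high"} (0.9),
#'   \code{"random"} (uniform in [0, 1]), or a list with numeric vectors
#'   \code{E} and \code{I}.
#' @param store_every Store every k-th integration step (default 1).
#' @return Object of class \code{wc_sim_config}.
#' @export
sim_config <- function(dt = 0.1, T = 1.2e5, transient = 1000,
                       noise_s = 1.3e-5, noise_on_I = TRUE,
                       seed = 1L, init = "default", store_every = 1L) {
  if (dt <= 0) stop("dt must be > 0")
  if (transient < 0) stop("transient must be >= 0")
  if (T <= transient) stop("T must exceed the transient window")
  if (noise_s < 0) stop("noise_s must be >= 0")
  store_every <- as.integer(store_every)
  if (store_every < 1L) stop("store_every must be >= 1")
  structure(list(dt = dt, T = T, transient = transient,
                 noise_mu = 0, noise_s = noise_s, noise_on_I = noise_on_I,
                 seed = as.integer(seed), init = init,
                 store_every = store_every),
            class = "wc_sim_config")
}

initial_state <- function(cfg, n) {
  if (is.list(cfg$init)) {
    E0 <- cfg$init$E; I0 <- cfg$init$I
    if (length(E0) == 1L) E0 <- rep(E0, n)
    if (length(I0) == 1L) I0 <- rep(I0, n)
    if (length(E0) != n || length(I0) != n) stop("initial state length mismatch")
    return(list(E = E0, I = I0))
  }
  switch(cfg$init,
    default = list(E = pmin(pmax(0.25 + stats::rnorm(n, 0, 1e-3), 0), 1),
                   I = pmin(pmax(0.25 + stats::rnorm(n, 0, 1e-3), 0), 1)),
    low = list(E = rep(0.05, n), I = rep(0.05, n)),
    high = list(E = rep(0.9, n), I = rep(0.9, n)),
    random = list(E = stats::runif(n), I = stats::runif(n)),
    stop("unknown initial-state preset: ", cfg$init))
}

#' Simulate the coupled network by Euler-Maruyama
#'
#' Fixed-step stochastic integration of the coupled Wilson-Cowan system:
#' \code{x_{k+1} = x_k + f(x_k) dt + s sqrt(dt) xi}, with i.i.d. standard
#' normal \code{xi} per state variable and step. The same seed gives a
#' bit-identical result. After each step the state is clipped to [0, 1]
#' (the deterministic flow cannot leave the box, but noise can); the number
#' of clipped coordinates is recorded. An excursion beyond |x| > 10 aborts
#' with a diagnostic naming the first offending region and step.
#'
#' @param model A \code{wc_network}.
#' @param cfg A \code{wc_sim_config}.
#' @param J_const Optional per-region constant external drive (mV) added to
#'   the coupling term; scalar or length N (default 0). Used for isolated
#'   node studies at a pinned input.
#' @return Object of class \code{wc_sim}: list(t, E, I, seed,
#'   transient_removed, n_clipped, cfg, model). \code{E} and \code{I} are
#'   N x T_steps matrices with region labels as rownames.
#' @export
simulate_network <- function(model, cfg = sim_config(), J_const = 0) {
  stopifnot(inherits(model, "wc_network"), inherits(cfg, "wc_sim_config"))
  n <- model$connectome$n
  if (length(J_const) == 1L) J_const <- rep(J_const, n)
  if (length(J_const) != n) stop("J_const must be scalar or length N")
  n_steps <- round(cfg$T / cfg$dt)
  set.seed(cfg$seed)
  st <- initial_state(cfg, n)
  res <- wc_integrate_cpp(model$connectome$A, model$G,
                          param_vec(model, "tau_e"), param_vec(model, "tau_i"),
                          param_vec(model, "a_e"), param_vec(model, "a_i"),
                          param_vec(model, "w_ee"), param_vec(model, "w_ei"),
                          param_vec(model, "w_ie"), param_vec(model, "w_ii"),
                          param_vec(model, "B_e"), param_vec(model, "B_i"),
                          param_vec(model, "h"), J_const,
                          st$E, st$I, cfg$dt, n_steps, cfg$store_every,
                          cfg$noise_s, cfg$noise_on_I)
  rownames(res$E) <- rownames(res$I) <- model$connectome$labels
  t <- seq_len(ncol(res$E)) * cfg$dt * cfg$store_every
  structure(list(t = t, E = res$E, I = res$I, seed = cfg$seed,
                 transient_removed = FALSE, n_clipped = res$n_clipped,
                 cfg = cfg, model = model),
            class = "wc_sim")
}

#' @export
print.wc_sim <- function(x, ...) {
  cat(sprintf(
    "Simulation: %d regions x %d samples (dt = %g ms, seed %d)%s; %g clipped steps\n",
    nrow(x$E), ncol(x$E), x$cfg$dt, x$seed,
    if (x$transient_removed) ", transient removed" else "", x$n_clipped))
  invisible(x)
}

#' Discard the initial transient
#'
#' Drop the first \code{transient / (dt * store_every)} stored samples so
#' downstream statistics reflect steady-state dynamics. Removing the
#' transient twice is an error.
#'
#' @param r A \code{wc_sim}.
#' @param transient Window to discard (ms); defaults to the simulation
#'   config's value.
#' @return The trimmed \code{wc_sim}, flagged as transient-removed.
#' @export
remove_transient <- function(r, transient = NULL) {
  stopifnot(inherits(r, "wc_sim"))
  if (r$transient_removed) stop("transient already removed")
  if (is.null(transient)) transient <- r$cfg$transient
  n_drop <- round(transient / (r$cfg$dt * r$cfg$store_every))
  if (n_drop >= ncol(r$E)) stop("transient window covers the whole simulation")
  if (n_drop > 0) {
    keep <- (n_drop + 1):ncol(r$E)
    r$t <- r$t[keep]; r$E <- r$E[, keep, drop = FALSE]
    r$I <- r$I[, keep, drop = FALSE]
  }
  r$transient_removed <- TRUE
  r
}

#' Per-region input ranges experienced during a simulation
#'
#' Evaluate the coupling term \code{J_e(t) = G A E(t)} along the stored
#' trajectory and report each region's [min, max], in both the raw drive
#' coordinate \code{J_e} and the net-input coordinate
#' \code{J_tot = J_e - B_e}.
#'
#' @param r A \code{wc_sim} with transient removed.
#' @return A data.frame with columns region, group, Je_min, Je_max,
#'   Jtot_min, Jtot_max.
#' @export
input_ranges <- function(r) {
  stopifnot(inherits(r, "wc_sim"))
  if (!r$transient_removed) stop("remove the transient before computing input ranges")
  model <- r$model
  J <- model$G * (model$connectome$A %*% r$E)  # N x T
  B_e <- param_vec(model, "B_e")
  data.frame(region = model$connectome$labels,
             group = model$connectome$groups,
             Je_min = apply(J, 1, min), Je_max = apply(J, 1, max),
             Jtot_min = apply(J, 1, min) - B_e,
             Jtot_max = apply(J, 1, max) - B_e,
             row.names = NULL)
}

#' Attractor occupancy of each region's experienced input range
#'
#' Partition the range of net input \code{J_tot} each region experienced
#' during a simulation by the fold and Hopf points of that region's own
#' bifurcation diagram, labelling each segment by the attractor type there
#' (\code{"fixed_point"}, \code{"limit_cycle"}, or \code{"bistable"}). In a
#' homogeneous model all regions share the same partition boundaries; with
#' cell-density heterogeneity, regions differ in both their experienced
#' range and their diagram, and a region may span several attractor types.
#'
#' @param r A \code{wc_sim} with transient removed.
#' @param diagrams A list of \code{wc_bifurcation} diagrams, one per region
#'   (or a single diagram recycled for all regions). A diagram whose
#'   analysed range does not cover a region's experienced range is re-traced
#'   over the extended range automatically.
#' @return A data.frame with columns region, group, J_lo, J_hi, label.
#' @export
regime_occupancy <- function(r, diagrams) {
  stopifnot(inherits(r, "wc_sim"))
  rng <- input_ranges(r)
  n <- nrow(rng)
  if (inherits(diagrams, "wc_bifurcation")) diagrams <- rep(list(diagrams), n)
  if (length(diagrams) != n) stop("need one bifurcation diagram per region")
  out <- vector("list", n)
  for (a in seq_len(n)) {
    d <- diagrams[[a]]
    lo <- rng$Jtot_min[a]; hi <- rng$Jtot_max[a]
    if (lo < d$J_range[1] || hi > d$J_range[2]) {
      d <- trace_branches(d$params,
                          J_range = c(min(lo, d$J_range[1]) - 0.5,
                                      max(hi, d$J_range[2]) + 0.5),
                          resolution = d$resolution)
      d <- annotate_diagram(d, envelope = FALSE)
    }
    bounds <- sort(unique(c(lo, hi,
                            d$folds$J_tot[d$folds$J_tot > lo & d$folds$J_tot < hi],
                            d$hopfs$J_tot[d$hopfs$J_tot > lo & d$hopfs$J_tot < hi])))
    if (length(bounds) < 2) bounds <- c(lo, hi)
    seg <- data.frame(region = rng$region[a], group = rng$group[a],
                      J_lo = bounds[-length(bounds)], J_hi = bounds[-1])
    seg$label <- vapply(seq_len(nrow(seg)), function(k) {
      attractor_label(d, (seg$J_lo[k] + seg$J_hi[k]) / 2)
    }, character(1))
    out[[a]] <- seg
  }
  do.call(rbind, out)
}

#' Carpet-plot matrix: regions ordered by anatomical grouping
#'
#' Reorder the excitatory activity matrix for a node x time heat map, and
#' optionally downsample columns for plotting.
#'
#' @param r A \code{wc_sim} with transient removed.
#' @param ordering Character vector of region labels giving the desired row
#'   order (a permutation of the simulated regions); defaults to grouping
#'   order (stable sort of the groups).
#' @param downsample Keep every k-th time sample (default 1 = all).
#' @return A list with the reordered matrix \code{E}, matching \code{t},
#'   \code{regions}, and \code{groups} annotation.
#' @export
carpet_data <- function(r, ordering = NULL, downsample = 1L) {
  stopifnot(inherits(r, "wc_sim"))
  if (!r$transient_removed) stop("remove the transient before building carpet data")
  labs <- r$model$connectome$labels
  if (is.null(ordering)) ordering <- labs[order(r$model$connectome$groups)]
  unknown <- setdiff(ordering, labs)
  if (length(unknown)) stop("unknown region(s) in ordering: ",
                            paste(unknown, collapse = ", "))
  if (length(ordering) != length(labs) || anyDuplicated(ordering)) {
    stop("ordering must be a permutation of the simulated regions")
  }
  idx <- match(ordering, labs)
  cols <- seq(downsample, ncol(r$E), by = downsample)
  list(E = r$E[idx, cols, drop = FALSE], t = r$t[cols],
       regions = ordering,
       groups = r$model$connectome$groups[idx])
}
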