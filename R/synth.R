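#' Specification for a synthetic study
#'
#' Parameters of the synthetic connectome / cell-density / target-FC
#' generator. The defaults emulate the statistical structure of the real
#' inputs the analysis is designed for: a dense directed binary cortical
#' graph over 37 regions with heterogeneous in-degree, positively
#' correlated excitatory and inhibitory density maps with region-level
#' variation around a mean, and six anatomical groupings.
#'
#' @param N Region count (default 37).
#' @param edge_density Expected fraction of off-diagonal ones (default 0.3).
#' @param degree_heterogeneity \code{"heavy_tailed"} (default; long-tailed
#'   in-degree propensities so high in-degree hub regions exist) or
#'   \code{"uniform"}.
#' @param ei_correlation Target correlation between e and i raw densities
#'   (default 0.7).
#' @param density_cv Coefficient of variation of the raw densities
#'   (default 0.2).
#' @param n_groups Number of anatomical groupings (default 6).
#' @param seed Integer seed.
#' @return Object of class \code{wc_synth_spec}.
#' @export
synth_spec <- function(N = 37, edge_density = 0.3,
                       degree_heterogeneity = c("heavy_tailed", "uniform"),
                       ei_correlation = 0.7, density_cv = 0.2,
                       n_groups = 6, seed = 1L) {
  degree_heterogeneity <- match.arg(degree_heterogeneity)
  if (N < 2) stop("N must be >= 2")
  if (edge_density <= 0 || edge_density > 1) stop("edge_density must be in (0, 1]")
  if (abs(ei_correlation) > 1) stop("ei_correlation must lie in [-1, 1]")
  if (density_cv <= 0) stop("density_cv must be > 0")
  structure(list(N = as.integer(N), edge_density = edge_density,
                 degree_heterogeneity = degree_heterogeneity,
                 ei_correlation = ei_correlation, density_cv = density_cv,
                 n_groups = as.integer(n_groups), seed = as.integer(seed)),
            class = "wc_synth_spec")
}

synth_labels <- function(N) sprintf("SYN%02d", seq_len(N))

synth_groups <- function(N, n_groups) {
  grp <- paste0("Group", seq_len(n_groups))
  sort(grp[1 + (seq_len(N) - 1) %% n_groups])
}

#' Generate a synthetic directed binary connectome
#'
#' Draws a zero-diagonal binary digraph with the requested expected edge
#' density. In heavy-tailed mode each region gets a lognormal in-degree
#' propensity, so some regions collect many more afferents than others —
#' the driver of diverse net inputs in the coupled model; in uniform mode
#' every off-diagonal entry is an independent Bernoulli draw.
#'
#' @param spec A \code{wc_synth_spec}.
#' @return A \code{wc_connectome}.
#' @export
synth_connectome <- function(spec) {
  stopifnot(inherits(spec, "wc_synth_spec"))
  set.seed(spec$seed)
  N <- spec$N
  prop <- if (spec$degree_heterogeneity == "heavy_tailed") {
    w <- stats::rlnorm(N, meanlog = 0, sdlog = 0.8)
    w / mean(w)
  } else rep(1, N)
  # per-row edge probability proportional to the row's propensity; capped
  # at 1 with the residual mass redistributed so the expected overall
  # density still matches the request
  p_row <- spec$edge_density * prop
  for (it in 1:100) {
    over <- p_row > 1
    if (!any(over)) break
    deficit <- sum(p_row[over] - 1)
    p_row[over] <- 1
    if (all(over)) break
    p_row[!over] <- p_row[!over] + deficit * p_row[!over] / sum(p_row[!over])
  }
  p_row <- pmin(p_row, 1)
  A <- matrix(0, N, N)
  for (a in seq_len(N)) {
    A[a, -a] <- stats::rbinom(N - 1, 1, p_row[a])
  }
  connectome(A, labels = synth_labels(N),
             groups = synth_groups(N, spec$n_groups))
}

#' Generate synthetic excitatory/inhibitory cell-density maps
#'
#' Draws a correlated bivariate Gaussian latent per region and exponentiates
#' it, giving positive lognormal raw densities whose coefficient of
#' variation matches \code{density_cv} and whose e-i correlation targets
#' \code{ei_correlation}. With \code{ei_correlation = 1} the two z-scored
#' maps are exactly equal (common latent).
#'
#' @param spec A \code{wc_synth_spec}.
#' @param mean_e,mean_i Mean raw densities (cells per unit volume; defaults
#'   emulate cortical excitatory ~8e4 and inhibitory ~1.2e4 cells/mm^3).
#' @return A \code{wc_densities}.
#' @export
synth_densities <- function(spec, mean_e = 8e4, mean_i = 1.2e4) {
  stopifnot(inherits(spec, "wc_synth_spec"))
  set.seed(spec$seed + 1L)
  N <- spec$N
  rho <- spec$ei_correlation
  s <- sqrt(log(1 + spec$density_cv^2))  # lognormal sigma for the target CV
  z1 <- stats::rnorm(N)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(N)
  e_raw <- mean_e * exp(s * z1 - s^2 / 2)
  i_raw <- mean_i * exp(s * z2 - s^2 / 2)
  zscore_densities(e_raw, i_raw, labels = synth_labels(N))
}

#' Generate a synthetic target FC matrix
#'
#' Produce a stand-in for an empirical group-average FC by forward
#' simulation of a ground-truth model. Like the group-average FC it
#' emulates (a mean over many subjects), the target can average the FC of
#' \code{n_avg} independent ground-truth runs (mean taken in Fisher-z
#' space). Observation noise is then added symmetrically: the unique
#' pairwise correlations are jittered in Fisher-z space with SD
#' \code{observation_noise_sd}, back-transformed, re-symmetrised, the
#' diagonal reset to 1 and entries clipped to [-1, 1]. The target is
#' deliberately drawn from the same model family so that parameter-recovery
#' questions are well-posed.
#'
#' @param model Ground-truth \code{wc_network}.
#' @param cfg A \code{wc_sim_config}; run k uses seed \code{cfg$seed + k - 1}.
#' @param observation_noise_sd Fisher-z jitter SD (0 = noiseless target).
#' @param noise_seed Seed for the observation noise draw.
#' @param n_avg Number of ground-truth runs averaged (default 1).
#' @return A \code{wc_fc}.
#' @export
synth_target_fc <- function(model, cfg, observation_noise_sd = 0,
                            noise_seed = 99L, n_avg = 1L) {
  stopifnot(n_avg >= 1)
  zsum <- NULL
  for (k in seq_len(n_avg)) {
    cfg_k <- cfg
    cfg_k$seed <- as.integer(cfg$seed + k - 1L)
    r <- remove_transient(simulate_network(model, cfg_k))
    fc <- compute_fc(r)
    z <- atanh(pmin(pmax(fc[upper.tri(fc)], -1 + 1e-12), 1 - 1e-12))
    zsum <- if (is.null(zsum)) z else zsum + z
  }
  m <- unclass(fc)
  ut <- upper.tri(m)
  z <- zsum / n_avg
  if (observation_noise_sd > 0) {
    set.seed(noise_seed)
    z <- z + stats::rnorm(sum(ut), 0, observation_noise_sd)
  }
  m[ut] <- tanh(z)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  as_fc(m)
}

#' Write a complete miniature synthetic study to disk
#'
#' Generates a small (default N = 12) connectome, density map, run config
#' and target FC planted at a known regime and working point, and writes
#' them in the package's interchange formats together with a manifest of
#' md5 checksums. Re-running with the same seed reproduces identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param N Region count (default 12).
#' @param regime Planted regime name (default \code{"limit_cycle"}).
#' @param G,B_e Planted working point.
#' @param observation_noise_sd Target-FC observation noise (Fisher-z SD).
#' @param T Ground-truth simulation length (ms).
#' @param n_avg Ground-truth runs averaged into the target (group-average
#'   emulation).
#' @return Invisibly, a list with the generated objects, file paths and the
#'   manifest data.frame.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, N = 12,
                               regime = "limit_cycle", G = 0.5, B_e = 1.5,
                               observation_noise_sd = 0.05, T = 1e4,
                               n_avg = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- synth_spec(N = N, n_groups = min(6L, N), seed = seed)
  con <- synth_connectome(spec)
  dens <- synth_densities(spec)
  dens$labels <- con$labels
  nominal <- update_params(regime_params(regime), B_e = B_e)
  model <- build_network(con, nominal, G = G)
  cfg <- sim_config(T = T, seed = seed + 500L, store_every = 10L)
  target <- synth_target_fc(model, cfg, observation_noise_sd,
                            noise_seed = seed + 900L, n_avg = n_avg)
  paths <- list(
    connectome = file.path(out_dir, "connectome.csv"),
    regions = file.path(out_dir, "regions.tsv"),
    densities = file.path(out_dir, "densities.tsv"),
    target_fc = file.path(out_dir, "target_fc.csv"),
    config = file.path(out_dir, "config.yaml"))
  write_adjacency(con, paths$connectome)
  write_region_table(con, paths$regions)
  write_densities(dens, paths$densities)
  write_fc(target, paths$target_fc)
  run_cfg <- list(regime = regime, G = G, B_e = B_e, sigma = 0,
                  simulation = list(dt = cfg$dt, T = cfg$T,
                                    transient = cfg$transient,
                                    noise_s = cfg$noise_s,
                                    store_every = cfg$store_every),
                  seed = as.integer(seed))
  yaml::write_yaml(run_cfg, paths$config)
  files <- unlist(paths)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         row.names = NULL)
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(connectome = con, densities = dens, model = model,
                 target_fc = target, cfg = cfg, paths = paths,
                 manifest = manifest))
}
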