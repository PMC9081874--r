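#' @useDynLib wcnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Numerical tolerances for the bifurcation machinery
#'
#' @param root_resid Equilibrium residual tolerance.
#' @param fold_bisect,hopf_bisect Bisection tolerance for fold/Hopf
#'   locations (mV).
#' @param dedup Duplicate-root merge distance.
#' @param scan_points Points in the equilibrium sign scan.
#' @param osc_amp Peak-to-peak E amplitude above which dynamics count as
#'   oscillatory.
#' @return Named list of tolerances, accepted by the \code{tol} arguments.
#' @export
bif_tol <- function(root_resid = 1e-9, fold_bisect = 1e-6, hopf_bisect = 1e-6,
                    dedup = 1e-5, scan_points = 1001L, osc_amp = 1e-4) {
  list(root_resid = root_resid, fold_bisect = fold_bisect,
       hopf_bisect = hopf_bisect, dedup = dedup,
       scan_points = as.integer(scan_points), osc_amp = osc_amp)
}

# Inhibitory nullcline: the unique I solving dI/dt = 0 at fixed E.
# g(I) = -I + (1 - I) S(a_i w_ie E - w_ii I - B_i) is strictly decreasing
# with g(0) > 0 > g(1), so the root is bracketed on [0, 1]. Vectorised
# bisection over E (60 halvings reach ~1e-18, beyond double precision).
i_nullcline <- function(p, E) {
  g <- function(I) {
    -I + (1 - I) * sigmoid(p$a_i * p$w_ie * E - p$w_ii * I - p$B_i, p$h)
  }
  lo <- rep(0, length(E)); hi <- rep(1, length(E))
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    lo <- ifelse(pos, mid, lo)
    hi <- ifelse(pos, hi, mid)
  }
  (lo + hi) / 2
}

# Newton polish of a candidate equilibrium in the J_tot coordinate.
newton_polish <- function(p, E, I, J_tot, max_iter = 30, resid = 1e-12) {
  for (k in seq_len(max_iter)) {
    f <- drift_jtot(E, I, p, J_tot)
    fv <- c(f$dE, f$dI)
    if (max(abs(fv)) < resid) break
    J <- jacobian(p, E, I, J_tot)
    step <- tryCatch(solve(J, fv), error = function(e) NULL)
    if (is.null(step)) break
    E <- min(max(E - step[1], 0), 1)
    I <- min(max(I - step[2], 0), 1)
  }
  c(E = E, I = I)
}

#' Equilibria of a single node at fixed net input
#'
#' Find all equilibria of the isolated Wilson-Cowan node in the unit box,
#' as a function of the net input \code{J_tot = J_e - B_e}. The system is
#' reduced to one dimension: for each E the inhibitory nullcline has a
#' unique solution I*(E) (the I-equation is strictly decreasing in I), and
#' the roots of the reduced E-equation are located by a dense sign scan
#' plus bisection, then polished by 2D Newton iteration. This model class
#' admits 1, 2 (at a fold) or 3 equilibria.
#'
#' @param p A \code{wc_params}.
#' @param J_tot Net input (mV, scalar).
#' @param tol Tolerance list from \code{bif_tol()}.
#' @return data.frame with columns E, I (one row per equilibrium, ordered
#'   by increasing E).
#' @export
find_equilibria <- function(p, J_tot, tol = bif_tol()) {
  stopifnot(inherits(p, "wc_params"), is.finite(J_tot))
  Eg <- seq(0, 1, length.out = tol$scan_points)
  Ig <- i_nullcline(p, Eg)
  hE <- (-Eg + (1 - Eg) *
           sigmoid(p$a_e * p$w_ee * Eg - p$w_ei * Ig + J_tot, p$h)) / p$tau_e
  roots <- list()
  sgn <- sign(hE)
  for (k in seq_len(length(Eg) - 1)) {
    if (sgn[k] == 0) { roots[[length(roots) + 1]] <- c(Eg[k], Ig[k]); next }
    if (sgn[k] * sgn[k + 1] < 0) {
      r <- stats::uniroot(function(E) {
        I <- i_nullcline(p, E)
        -E + (1 - E) * sigmoid(p$a_e * p$w_ee * E - p$w_ei * I + J_tot, p$h)
      }, c(Eg[k], Eg[k + 1]), tol = 1e-13)$root
      roots[[length(roots) + 1]] <- c(r, i_nullcline(p, r))
    }
  }
  if (sgn[length(Eg)] == 0) {
    roots[[length(roots) + 1]] <- c(1, Ig[length(Eg)])
  }
  if (!length(roots)) stop("internal error: no equilibrium bracketed (invalid parameters?)")
  pts <- t(vapply(roots, function(r) {
    newton_polish(p, r[1], r[2], J_tot, resid = tol$root_resid * 1e-3)
  }, numeric(2)))
  # deduplicate
  ord <- order(pts[, 1])
  pts <- pts[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(pts))
  if (nrow(pts) > 1) {
    for (k in 2:nrow(pts)) {
      if (max(abs(pts[k, ] - pts[k - 1, ])) < tol$dedup) keep[k] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  data.frame(E = pts[, 1], I = pts[, 2])
}

# eigenvalues + stability label of one equilibrium
equilibrium_stability <- function(p, E, I, J_tot) {
  J <- jacobian(p, E, I, J_tot)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev); im <- Im(ev)
  label <- if (all(re < 0)) "stable"
           else if (det(J) < 0) "unstable-saddle"
           else "unstable-focus"
  list(re1 = re[1], im1 = im[1], re2 = re[2], im2 = im[2], stability = label)
}

#' Trace equilibrium branches over a range of net input
#'
#' Sweep \code{J_tot} over a uniform grid, find all equilibria at each
#' value, attach eigenvalues and stability labels, and stitch points into
#' continuous branches by nearest-neighbour linking between consecutive
#' grid columns.
#'
#' @param p A \code{wc_params}.
#' @param J_range Length-2 numeric: analysed interval of \code{J_tot} (mV).
#' @param resolution Number of grid points (>= 3).
#' @param tol Tolerance list from \code{bif_tol()}.
#' @return Object of class \code{wc_bifurcation}: list with \code{points}
#'   (data.frame J_tot, E, I, re1, im1, re2, im2, stability, branch_id),
#'   \code{params}, \code{J_range}, \code{resolution}; fold/Hopf/envelope
#'   slots are filled by \code{\link{annotate_diagram}}.
#' @export
trace_branches <- function(p, J_range = c(-4, 6), resolution = 201L,
                           tol = bif_tol()) {
  stopifnot(inherits(p, "wc_params"), length(J_range) == 2, all(is.finite(J_range)))
  resolution <- as.integer(resolution)
  if (resolution < 3L) stop("resolution must be at least 3 points")
  Jg <- seq(J_range[1], J_range[2], length.out = resolution)
  rows <- vector("list", resolution)
  branch_heads <- list()   # branch_id -> last (E, I)
  next_id <- 1L
  link_tol <- 0.2
  for (k in seq_along(Jg)) {
    eq <- find_equilibria(p, Jg[k], tol)
    ids <- integer(nrow(eq))
    used <- logical(length(branch_heads))
    for (r in seq_len(nrow(eq))) {
      if (length(branch_heads)) {
        d <- vapply(branch_heads, function(hd)
          max(abs(hd - c(eq$E[r], eq$I[r]))), numeric(1))
        d[used] <- Inf
        j <- which.min(d)
        if (length(j) && is.finite(d[j]) && d[j] < link_tol) {
          ids[r] <- as.integer(names(branch_heads)[j]); used[j] <- TRUE
          next
        }
      }
      ids[r] <- next_id; next_id <- next_id + 1L
    }
    heads <- stats::setNames(
      lapply(seq_len(nrow(eq)), function(r) c(eq$E[r], eq$I[r])),
      as.character(ids))
    branch_heads <- heads
    st <- lapply(seq_len(nrow(eq)), function(r)
      equilibrium_stability(p, eq$E[r], eq$I[r], Jg[k]))
    rows[[k]] <- data.frame(
      J_tot = Jg[k], E = eq$E, I = eq$I,
      re1 = vapply(st, `[[`, numeric(1), "re1"),
      im1 = vapply(st, `[[`, numeric(1), "im1"),
      re2 = vapply(st, `[[`, numeric(1), "re2"),
      im2 = vapply(st, `[[`, numeric(1), "im2"),
      stability = vapply(st, `[[`, character(1), "stability"),
      branch_id = ids)
  }
  structure(list(points = do.call(rbind, rows), params = p,
                 J_range = J_range, resolution = resolution, tol = tol,
                 folds = NULL, hopfs = NULL, envelope = NULL),
            class = "wc_bifurcation")
}

#' @export
print.wc_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation diagram over J_tot in [%g, %g] (%d samples, %d branch(es))\n",
              x$J_range[1], x$J_range[2], x$resolution,
              length(unique(x$points$branch_id))))
  if (!is.null(x$folds)) cat(sprintf("  folds: %d\n", nrow(x$folds)))
  if (!is.null(x$hopfs)) cat(sprintf("  Hopf points: %d\n", nrow(x$hopfs)))
  if (!is.null(x$envelope)) {
    osc <- sum(x$envelope$E_max - x$envelope$E_min > x$tol$osc_amp)
    cat(sprintf("  limit-cycle envelope: %d oscillatory of %d samples\n",
                osc, nrow(x$envelope)))
  }
  invisible(x)
}

#' Saddle-node (fold) points of a traced diagram
#'
#' Locate the \code{J_tot} values where the equilibrium count changes (the
#' branch turns) by bisection on the root count, refined to the configured
#' tolerance. At a fold the two merging equilibria coincide and the
#' Jacobian determinant vanishes.
#'
#' @param d A \code{wc_bifurcation}.
#' @return data.frame with columns J_tot, E (possibly 0 rows).
#' @export
detect_folds <- function(d) {
  stopifnot(inherits(d, "wc_bifurcation"))
  p <- d$params; tol <- d$tol
  Jg <- sort(unique(d$points$J_tot))
  counts <- vapply(Jg, function(J) sum(d$points$J_tot == J), numeric(1))
  folds <- list()
  for (k in seq_len(length(Jg) - 1)) {
    if (counts[k] == counts[k + 1]) next
    lo <- Jg[k]; hi <- Jg[k + 1]
    c_lo <- counts[k]
    while (hi - lo > tol$fold_bisect) {
      mid <- (lo + hi) / 2
      c_mid <- nrow(find_equilibria(p, mid, tol))
      if (c_mid == c_lo) lo <- mid else hi <- mid
    }
    # E at the fold: the closest pair on the many-root side
    many <- if (counts[k] > counts[k + 1]) lo else hi
    eq <- find_equilibria(p, many, tol)
    if (nrow(eq) >= 2) {
      gaps <- diff(eq$E)
      j <- which.min(gaps)
      E_fold <- mean(eq$E[j:(j + 1)])
    } else E_fold <- eq$E[1]
    folds[[length(folds) + 1]] <- c(J_tot = (lo + hi) / 2, E = E_fold)
  }
  if (!length(folds)) return(data.frame(J_tot = numeric(0), E = numeric(0)))
  out <- as.data.frame(do.call(rbind, folds))
  out[order(out$J_tot), , drop = FALSE]
}

# follow the equilibrium nearest a target point at a given J
nearest_equilibrium <- function(p, J_tot, target, tol) {
  eq <- find_equilibria(p, J_tot, tol)
  j <- which.min(abs(eq$E - target[1]) + abs(eq$I - target[2]))
  c(E = eq$E[j], I = eq$I[j])
}

#' Hopf points along traced branches
#'
#' Scan each branch for a sign change of the real part of a complex
#' eigenvalue pair, and refine the crossing by bisection in \code{J_tot}
#' (re-solving for the tracked equilibrium at each midpoint). A crossing
#' only counts as a Hopf point if the imaginary part is nonzero there.
#'
#' @param d A \code{wc_bifurcation}.
#' @return data.frame with columns J_tot, E, im (|Im| of the eigenvalue
#'   pair at the crossing, i.e. the angular frequency in rad/ms).
#' @export
detect_hopf <- function(d) {
  stopifnot(inherits(d, "wc_bifurcation"))
  p <- d$params; tol <- d$tol
  pts <- d$points
  hopfs <- list()
  for (b in unique(pts$branch_id)) {
    bp <- pts[pts$branch_id == b, ]
    bp <- bp[order(bp$J_tot), ]
    if (nrow(bp) < 2) next
    for (k in seq_len(nrow(bp) - 1)) {
      complex_pair <- abs(bp$im1[k]) > 0 || abs(bp$im1[k + 1]) > 0
      if (!complex_pair) next
      if (bp$re1[k] == 0 || bp$re1[k] * bp$re1[k + 1] >= 0) next
      lo <- bp$J_tot[k]; hi <- bp$J_tot[k + 1]
      s_lo <- sign(bp$re1[k])
      target <- c(bp$E[k], bp$I[k])
      while (hi - lo > tol$hopf_bisect) {
        mid <- (lo + hi) / 2
        eqm <- nearest_equilibrium(p, mid, target, tol)
        st <- equilibrium_stability(p, eqm[1], eqm[2], mid)
        if (sign(st$re1) == s_lo) { lo <- mid; target <- eqm } else hi <- mid
      }
      Jh <- (lo + hi) / 2
      eqh <- nearest_equilibrium(p, Jh, target, tol)
      sth <- equilibrium_stability(p, eqh[1], eqh[2], Jh)
      if (abs(sth$im1) > 0) {
        hopfs[[length(hopfs) + 1]] <-
          c(J_tot = Jh, E = unname(eqh[1]), im = abs(sth$im1))
      }
    }
  }
  if (!length(hopfs)) {
    return(data.frame(J_tot = numeric(0), E = numeric(0), im = numeric(0)))
  }
  out <- as.data.frame(do.call(rbind, hopfs))
  out <- out[order(out$J_tot), , drop = FALSE]
  # merge duplicates found from both neighbouring branches
  if (nrow(out) > 1) {
    keep <- c(TRUE, diff(out$J_tot) > 10 * d$tol$hopf_bisect)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# integrate a single isolated node deterministically at pinned net input
integrate_single_node <- function(p, J_tot, E0, I0, T, dt = 0.05,
                                  store_every = 1L) {
  res <- wc_integrate_cpp(matrix(0, 1, 1), 0,
                          p$tau_e, p$tau_i, p$a_e, p$a_i,
                          p$w_ee, p$w_ei, p$w_ie, p$w_ii,
                          p$B_e, p$B_i, p$h, J_tot + p$B_e,
                          E0, I0,
                          dt, as.integer(round(T / dt)), as.integer(store_every),
                          0, FALSE)
  list(E = res$E[1, ], I = res$I[1, ])
}

#' Limit-cycle envelope by direct integration
#'
#' For each net-input value, integrate the deterministic isolated node to
#' its attractor (starting just off the most unstable equilibrium), discard
#' the settling transient, and record the min and max of E over the
#' remaining window. Where the attractor is a fixed point the envelope
#' collapses onto the equilibrium (width below the oscillation-amplitude
#' threshold); inside a Hopf window the width is the oscillation amplitude.
#'
#' @param p A \code{wc_params}.
#' @param J_grid Net-input values to probe (mV).
#' @param settle Settling time discarded before measuring (ms).
#' @param window Measurement window (ms).
#' @param dt Integration step (ms).
#' @param tol Tolerance list from \code{bif_tol()}.
#' @return data.frame with columns J_tot, E_min, E_max, oscillatory.
#' @export
limit_cycle_envelope <- function(p, J_grid, settle = 2000, window = 1000,
                                 dt = 0.05, tol = bif_tol()) {
  stopifnot(inherits(p, "wc_params"))
  out <- lapply(J_grid, function(J) {
    eq <- find_equilibria(p, J, tol)
    st <- lapply(seq_len(nrow(eq)), function(r)
      equilibrium_stability(p, eq$E[r], eq$I[r], J))
    re_max <- vapply(st, function(s) max(s$re1, s$re2), numeric(1))
    j <- which.max(re_max)
    E0 <- min(max(eq$E[j] + 0.01, 0), 1)
    I0 <- min(max(eq$I[j] + 0.01, 0), 1)
    tr <- integrate_single_node(p, J, E0, I0, T = settle + window, dt = dt,
                                store_every = max(1L, as.integer(round(0.5 / dt))))
    n_keep <- ceiling(length(tr$E) * window / (settle + window))
    Ew <- utils::tail(tr$E, n_keep)
    amp <- max(Ew) - min(Ew)
    if (amp > tol$osc_amp) {
      c(J_tot = J, E_min = min(Ew), E_max = max(Ew), oscillatory = 1)
    } else {
      Ef <- Ew[length(Ew)]
      c(J_tot = J, E_min = Ef, E_max = Ef, oscillatory = 0)
    }
  })
  out <- as.data.frame(do.call(rbind, out))
  out$oscillatory <- out$oscillatory > 0
  out
}

#' Annotate a diagram with folds, Hopf points and the oscillation envelope
#'
#' @param d A \code{wc_bifurcation} from \code{\link{trace_branches}}.
#' @param envelope Compute the simulation-based limit-cycle envelope
#'   (default TRUE when Hopf points are present, FALSE otherwise; force
#'   with TRUE/FALSE).
#' @param envelope_points Number of envelope grid samples.
#' @return The diagram with \code{folds}, \code{hopfs} and (optionally)
#'   \code{envelope} filled in.
#' @export
annotate_diagram <- function(d, envelope = NULL, envelope_points = 101L) {
  stopifnot(inherits(d, "wc_bifurcation"))
  d$folds <- detect_folds(d)
  d$hopfs <- detect_hopf(d)
  if (is.null(envelope)) envelope <- nrow(d$hopfs) > 0
  if (isTRUE(envelope)) {
    Jg <- seq(d$J_range[1], d$J_range[2], length.out = envelope_points)
    d$envelope <- limit_cycle_envelope(d$params, Jg, tol = d$tol)
  }
  d
}

#' Classify the dynamical regime of a diagram
#'
#' Labels follow the three canonical single-node regimes: a diagram with no
#' folds and no Hopf points is \code{"fixed_point"}; two or more folds with
#' a bistable window and no Hopf points is \code{"hysteresis"}; at least
#' one Hopf point with a non-empty oscillation envelope is
#' \code{"limit_cycle"}. A diagram exhibiting both folds and Hopf points is
#' reported as a composite label rather than forced into one class.
#'
#' @param d An annotated \code{wc_bifurcation} (see
#'   \code{\link{annotate_diagram}}).
#' @return Object of class \code{wc_regime}: list(label, n_folds, n_hopfs,
#'   oscillatory_window).
#' @export
classify_regime <- function(d) {
  stopifnot(inherits(d, "wc_bifurcation"))
  if (is.null(d$folds) || is.null(d$hopfs)) d <- annotate_diagram(d)
  n_folds <- nrow(d$folds); n_hopfs <- nrow(d$hopfs)
  has_envelope <- !is.null(d$envelope) && any(d$envelope$oscillatory)
  label <-
    if (n_folds >= 2 && (n_hopfs == 0 || !has_envelope)) "hysteresis"
    else if (n_hopfs >= 1 && has_envelope && n_folds == 0) "limit_cycle"
    else if (n_folds == 0 && n_hopfs == 0) "fixed_point"
    else paste(c(if (n_folds) "hysteresis", if (n_hopfs) "limit_cycle",
                 if (!n_folds && !n_hopfs) "fixed_point"), collapse = "+")
  structure(list(label = label, n_folds = n_folds, n_hopfs = n_hopfs,
                 oscillatory_window = has_envelope),
            class = "wc_regime")
}

#' @export
print.wc_regime <- function(x, ...) {
  cat(sprintf("Regime: %s (%d fold(s), %d Hopf point(s), oscillations: %s)\n",
              x$label, x$n_folds, x$n_hopfs, x$oscillatory_window))
  invisible(x)
}

# attractor type at one net-input value, used by regime_occupancy
attractor_label <- function(d, J_tot) {
  p <- d$params
  eq <- find_equilibria(p, J_tot, d$tol)
  st <- vapply(seq_len(nrow(eq)), function(r)
    equilibrium_stability(p, eq$E[r], eq$I[r], J_tot)$stability, character(1))
  n_stable <- sum(st == "stable")
  if (n_stable == 0) "limit_cycle"
  else if (n_stable >= 2) "bistable"
  else "fixed_point"
}

#' Family of diagrams under cell-density-style weight perturbations
#'
#' Re-trace the single-node bifurcation diagram under relative variations
#' of the coupling weights, in the four canonical modes: perturbing only
#' the excitatory outputs (\code{R_e}), only the inhibitory outputs
#' (\code{R_i}), both equally, or in opposition (\code{R_e = -R_i}).
#'
#' @param nominal A \code{wc_params}.
#' @param R_values Relative perturbation values (e.g.
#'   \code{seq(-0.1, 0.1, by = 0.05)}).
#' @param mode One of \code{"e_only"}, \code{"i_only"}, \code{"equal"},
#'   \code{"opposed"}.
#' @param J_range,resolution Passed to \code{\link{trace_branches}}.
#' @param annotate Annotate each diagram with folds/Hopfs (default TRUE).
#' @return Named list of \code{wc_bifurcation}, one per R value, with the
#'   (R_e, R_i) pair attached as attribute \code{"R"} on each element.
#' @export
perturbation_study <- function(nominal, R_values,
                               mode = c("e_only", "i_only", "equal", "opposed"),
                               J_range = c(-4, 6), resolution = 201L,
                               annotate = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(nominal, "wc_params"))
  out <- lapply(R_values, function(r) {
    R_e <- switch(mode, e_only = r, i_only = 0, equal = r, opposed = r)
    R_i <- switch(mode, e_only = 0, i_only = r, equal = r, opposed = -r)
    if (1 + R_e <= 0 || 1 + R_i <= 0) stop("perturbation makes weights non-positive")
    pp <- update_params(nominal,
                        w_ee = nominal$w_ee * (1 + R_e),
                        w_ie = nominal$w_ie * (1 + R_e),
                        w_ii = nominal$w_ii * (1 + R_i),
                        w_ei = nominal$w_ei * (1 + R_i))
    d <- trace_branches(pp, J_range, resolution)
    if (annotate) d <- annotate_diagram(d)
    attr(d, "R") <- c(R_e = R_e, R_i = R_i)
    d
  })
  names(out) <- sprintf("R=%g", R_values)
  out
}
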