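#' Wilson-Cowan node parameters
#'
#' Bundle the full parameter set of one Wilson-Cowan excitatory/inhibitory
#' neural-mass pair. Internal units are millivolts and milliseconds
#' throughout: time constants \code{tau_e}, \code{tau_i} in ms, sigmoid gain
#' scalings \code{a_e}, \code{a_i} in 1/mV, coupling weights \code{w_xy} in
#' mV*ms, firing thresholds \code{B_e}, \code{B_i} in mV, and the maximal
#' population rate \code{h} dimensionless (fixed to 1 in the standard model;
#' kept explicit so the sigmoid contract can be exercised at other values).
#'
#' @param tau_e,tau_i Time constants of excitation and inhibition (ms, > 0).
#' @param a_e,a_i Sigmoid gain scalings (1/mV, > 0).
#' @param w_ee,w_ei,w_ie,w_ii Coupling weights from population y to x in
#'   \code{w_xy} (mV*ms, >= 0).
#' @param B_e,B_i Firing thresholds (mV).
#' @param h Maximal population rate (dimensionless, default 1).
#' @return An object of class \code{wc_params} (a named list).
#' @examples
#' p <- node_params(w_ee = 12, w_ei = 10, w_ie = 12, w_ii = 2, B_i = 3)
#' @export
node_params <- function(tau_e = 10, tau_i = 10,
                        a_e = 1, a_i = 1,
                        w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0,
                        B_e = 0, B_i = 0, h = 1) {
  p <- list(tau_e = tau_e, tau_i = tau_i, a_e = a_e, a_i = a_i,
            w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
            B_e = B_e, B_i = B_i, h = h)
  p <- lapply(p, as.numeric)
  class(p) <- "wc_params"
  validate_node_params(p)
  p
}

validate_node_params <- function(p) {
  stopifnot(inherits(p, "wc_params"))
  num1 <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                 logical(1))
  if (!all(num1)) {
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(p)[!num1], collapse = ", "))
  }
  if (p$tau_e <= 0 || p$tau_i <= 0) stop("time constants tau_e, tau_i must be > 0")
  if (p$a_e <= 0 || p$a_i <= 0) stop("sigmoid gains a_e, a_i must be > 0")
  w <- unlist(p[c("w_ee", "w_ei", "w_ie", "w_ii")])
  if (any(w < 0)) {
    stop("negative coupling weight(s): ",
         paste(names(w)[w < 0], collapse = ", "))
  }
  if (p$h <= 0) stop("maximal rate h must be > 0")
  invisible(p)
}

#' @export
print.wc_params <- function(x, ...) {
  cat("Wilson-Cowan node parameters (mV, ms):\n")
  print(unlist(x))
  invisible(x)
}

#' Modify a subset of node parameters
#'
#' @param p A \code{wc_params} object.
#' @param ... Named scalar replacements (e.g. \code{B_e = 3.3}).
#' @return A validated \code{wc_params} object.
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "wc_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(repl)] <- lapply(repl, as.numeric)
  validate_node_params(p)
  p
}

#' Nominal single-node parameter regimes
#'
#' Three named parameter sets placing an isolated node, as a function of its
#' net input, in qualitatively different dynamical regimes:
#' \describe{
#'   \item{fixed_point}{a single stable equilibrium for every net input
#'     (weak recurrent excitation; monotone sigmoid-like response branch);}
#'   \item{hysteresis}{a bistable window bounded by two saddle-node
#'     bifurcations (strong recurrent excitation, fast weak inhibition);}
#'   \item{limit_cycle}{a window of stable oscillations bounded by two Hopf
#'     bifurcations (strong recurrent excitation balanced by slower
#'     inhibitory feedback).}
#' }
#' The sets are validated by topology — \code{\link{classify_regime}} on the
#' traced bifurcation diagram — rather than tied to any particular published
#' table.
#'
#' @param regime One of \code{"fixed_point"}, \code{"hysteresis"},
#'   \code{"limit_cycle"}.
#' @return A \code{wc_params} object.
#' @seealso \code{\link{trace_branches}}, \code{\link{classify_regime}}
#' @export
regime_params <- function(regime = c("fixed_point", "hysteresis", "limit_cycle")) {
  regime <- match.arg(regime)
  switch(regime,
    fixed_point = node_params(tau_e = 10, tau_i = 10, a_e = 1, a_i = 1,
                              w_ee = 3, w_ei = 3, w_ie = 3, w_ii = 1,
                              B_e = 2.8, B_i = 3),
    hysteresis = node_params(tau_e = 10, tau_i = 5, a_e = 1, a_i = 1,
                             w_ee = 12, w_ei = 3, w_ie = 3, w_ii = 2,
                             B_e = 3.7, B_i = 4),
    limit_cycle = node_params(tau_e = 10, tau_i = 20, a_e = 1, a_i = 1,
                              w_ee = 16, w_ei = 12, w_ie = 15, w_ii = 3,
                              B_e = 1.5, B_i = 3.7))
}

#' Convert a parameter set quoted in volts and seconds to mV and ms
#'
#' Model parameters are sometimes quoted with voltages in V and times in s.
#' Internally everything is mV and ms, so voltages (thresholds) scale by
#' 1000, gains (1/V) by 1/1000, time constants (s) by 1000 and the coupling
#' weights (V*s) by 1e6.
#'
#' @param p A \code{wc_params} whose fields are in V and s.
#' @return The same parameters expressed in mV and ms.
#' @export
params_from_vs <- function(p) {
  stopifnot(inherits(p, "wc_params"))
  node_params(tau_e = p$tau_e * 1e3, tau_i = p$tau_i * 1e3,
              a_e = p$a_e / 1e3, a_i = p$a_i / 1e3,
              w_ee = p$w_ee * 1e6, w_ei = p$w_ei * 1e6,
              w_ie = p$w_ie * 1e6, w_ii = p$w_ii * 1e6,
              B_e = p$B_e * 1e3, B_i = p$B_i * 1e3, h = p$h)
}
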