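#' Sigmoidal firing-rate function
#'
#' Logistic gain function \code{S(v) = h / (1 + exp(-v))}: strictly
#' increasing, with range (0, h) and midpoint h/2 at v = 0.
#'
#' @param v Membrane drive (mV-scaled, any finite value; vectorised).
#' @param h Maximal population rate (default 1).
#' @return Rates in (0, h), same shape as \code{v}.
#' @export
sigmoid <- function(v, h = 1) {
  if (any(!is.finite(v))) stop("sigmoid: non-finite input v")
  h / (1 + exp(-v))
}

# derivative of the sigmoid expressed through its value: S' = S (h - S) / h
sigmoid_deriv <- function(v, h = 1) {
  s <- sigmoid(v, h)
  s * (h - s) / h
}

#' Wilson-Cowan drift field for one node
#'
#' Deterministic time derivatives of the excitatory and inhibitory rates:
#' \deqn{\tau_e \dot E = -E + (1 - E)\, S(a_e w_{ee} E - w_{ei} I - B_e + J_e)}
#' \deqn{\tau_i \dot I = -I + (1 - I)\, S(a_i w_{ie} E - w_{ii} I - B_i)}
#' The \code{(1 - x)} refractory factors make the unit box forward-invariant
#' under the deterministic flow.
#'
#' @param E,I Population rates (finite; vectorised elementwise).
#' @param p A \code{wc_params} object.
#' @param J_e External excitatory drive (mV, default 0).
#' @return A list with components \code{dE} and \code{dI} (rate per ms).
#' @export
drift <- function(E, I, p, J_e = 0) {
  stopifnot(inherits(p, "wc_params"))
  if (any(!is.finite(E)) || any(!is.finite(I))) stop("drift: non-finite state")
  u <- p$a_e * p$w_ee * E - p$w_ei * I - p$B_e + J_e
  v <- p$a_i * p$w_ie * E - p$w_ii * I - p$B_i
  list(dE = (-E + (1 - E) * sigmoid(u, p$h)) / p$tau_e,
       dI = (-I + (1 - I) * sigmoid(v, p$h)) / p$tau_i)
}

#' Jacobian of the single-node drift
#'
#' Analytic 2x2 matrix of partial derivatives of \code{\link{drift}} with
#' respect to (E, I), evaluated in the net-input coordinate
#' \code{J_tot = J_e - B_e} (so \code{B_e} is absorbed into the argument).
#' Uses \code{S' = S (h - S) / h}.
#'
#' @param p A \code{wc_params} object.
#' @param E,I State (finite scalars).
#' @param J_tot Net input \code{J_e - B_e} (mV).
#' @return 2x2 numeric matrix, rows/cols ordered (E, I).
#' @export
jacobian <- function(p, E, I, J_tot) {
  stopifnot(inherits(p, "wc_params"), is.finite(E), is.finite(I), is.finite(J_tot))
  u <- p$a_e * p$w_ee * E - p$w_ei * I + J_tot
  v <- p$a_i * p$w_ie * E - p$w_ii * I - p$B_i
  su <- sigmoid(u, p$h); spu <- su * (p$h - su) / p$h
  sv <- sigmoid(v, p$h); spv <- sv * (p$h - sv) / p$h
  matrix(c(
    (-1 - su + (1 - E) * spu * p$a_e * p$w_ee) / p$tau_e,  # dE'/dE
    (1 - E) * spu * (-p$w_ei) / p$tau_e,                   # dE'/dI
    (1 - I) * spv * p$a_i * p$w_ie / p$tau_i,              # dI'/dE
    (-1 - sv + (1 - I) * spv * (-p$w_ii)) / p$tau_i        # dI'/dI
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("E", "I"), c("E", "I")))
}

# drift in the J_tot coordinate (B_e absorbed): used by the bifurcation module
drift_jtot <- function(E, I, p, J_tot) {
  drift(E, I, p, J_e = J_tot + p$B_e)
}
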