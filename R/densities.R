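#' Z-scored cell-density map
#'
#' Normalise raw per-region excitatory and inhibitory cell densities to
#' zero mean and unit sample standard deviation across regions (denominator
#' N - 1), so raw densities (1, 2, 3) map to z-scores (-1, 0, 1); the
#' population convention (denominator N) is available via
#' \code{convention}.
#'
#' @param e_raw,i_raw Positive per-region raw densities (cells per volume),
#'   equal length >= 2, non-constant.
#' @param labels Optional region labels (default names of \code{e_raw} or
#'   \code{"R1"...}).
#' @param convention \code{"sample"} (divide by N - 1, default) or
#'   \code{"population"} (divide by N).
#' @return An object of class \code{wc_densities} with fields \code{e_raw},
#'   \code{i_raw}, \code{e_z}, \code{i_z}, \code{labels}.
#' @export
zscore_densities <- function(e_raw, i_raw, labels = NULL,
                             convention = c("sample", "population")) {
  convention <- match.arg(convention)
  n <- length(e_raw)
  if (length(i_raw) != n) stop("e_raw and i_raw must have equal length")
  if (n < 2) stop("need at least 2 regions to z-score")
  if (any(!is.finite(e_raw)) || any(!is.finite(i_raw))) stop("non-finite density")
  if (any(e_raw <= 0) || any(i_raw <= 0)) stop("raw densities must be positive")
  zs <- function(x, what) {
    s <- stats::sd(x)
    if (s == 0) stop(sprintf("constant %s density vector: z-score undefined", what))
    if (convention == "population") s <- s * sqrt((n - 1) / n)
    (x - mean(x)) / s
  }
  if (is.null(labels)) labels <- names(e_raw)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  structure(list(e_raw = unname(e_raw), i_raw = unname(i_raw),
                 e_z = unname(zs(e_raw, "excitatory")),
                 i_z = unname(zs(i_raw, "inhibitory")),
                 labels = as.character(labels)),
            class = "wc_densities")
}

#' @export
print.wc_densities <- function(x, ...) {
  cat(sprintf("Cell-density map over %d regions; cor(e_raw, i_raw) = %.3f\n",
              length(x$e_raw), stats::cor(x$e_raw, x$i_raw)))
  invisible(x)
}

#' Per-region perturbation field from cell densities
#'
#' Map z-scored densities into relative weight perturbations through a
#' single scaling parameter: \code{R_e = sigma * e_z},
#' \code{R_i = sigma * i_z}. \code{sigma = 0} reproduces the spatially
#' homogeneous model. A field with any \code{1 + R <= 0} is rejected,
#' because it would demand a non-positive coupling weight.
#'
#' @param d A \code{wc_densities} object.
#' @param sigma Non-negative scaling parameter.
#' @return Object of class \code{wc_field}: list(sigma, R_e, R_i, labels).
#' @export
perturbation_field <- function(d, sigma) {
  stopifnot(inherits(d, "wc_densities"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("sigma must be a single non-negative number")
  }
  R_e <- sigma * d$e_z
  R_i <- sigma * d$i_z
  bad <- which(1 + R_e <= 0 | 1 + R_i <= 0)
  if (length(bad)) {
    stop("perturbation would make weights non-positive in region(s): ",
         paste(d$labels[bad], collapse = ", "))
  }
  structure(list(sigma = sigma, R_e = R_e, R_i = R_i, labels = d$labels),
            class = "wc_field")
}

#' Zero perturbation field (homogeneous model)
#'
#' @param n Number of regions.
#' @param labels Optional labels.
#' @return A \code{wc_field} with sigma = 0 and all-zero perturbations.
#' @export
zero_field <- function(n, labels = NULL) {
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  structure(list(sigma = 0, R_e = rep(0, n), R_i = rep(0, n),
                 labels = as.character(labels)),
            class = "wc_field")
}

#' Apply a perturbation field to nominal parameters
#'
#' Scale the outputs of the excitatory population (\code{w_ee}, \code{w_ie})
#' by \code{1 + R_e} and the outputs of the inhibitory population
#' (\code{w_ii}, \code{w_ei}) by \code{1 + R_i}, region by region; every
#' other parameter is untouched.
#'
#' @param nominal A \code{wc_params} object (the hatted nominal weights).
#' @param field A \code{wc_field}.
#' @return A list of N \code{wc_params} objects, one per region.
#' @export
apply_perturbations <- function(nominal, field) {
  stopifnot(inherits(nominal, "wc_params"), inherits(field, "wc_field"))
  n <- length(field$R_e)
  lapply(seq_len(n), function(a) {
    if (field$R_e[a] == 0 && field$R_i[a] == 0) return(nominal)
    update_params(nominal,
                  w_ee = nominal$w_ee * (1 + field$R_e[a]),
                  w_ie = nominal$w_ie * (1 + field$R_e[a]),
                  w_ii = nominal$w_ii * (1 + field$R_i[a]),
                  w_ei = nominal$w_ei * (1 + field$R_i[a]))
  })
}
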