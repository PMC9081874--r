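#' Assemble a connectome-coupled network model
#'
#' Combine a connectome, a nominal node parameter set, a global coupling
#' constant and (optionally) a cell-density perturbation field into a fully
#' validated network model. With \code{field = NULL} (or a zero field) all
#' regions share the identical nominal parameters — the homogeneous model.
#'
#' @param c A \code{wc_connectome}.
#' @param nominal A \code{wc_params} object (nominal/hatted weights).
#' @param G Global coupling constant (mV*ms, >= 0).
#' @param field Optional \code{wc_field}; region count must match.
#' @return Object of class \code{wc_network}: list(connectome, params
#'   (length-N list of \code{wc_params}), G, field).
#' @export
build_network <- function(c, nominal, G, field = NULL) {
  stopifnot(inherits(c, "wc_connectome"), inherits(nominal, "wc_params"))
  if (!is.numeric(G) || length(G) != 1L || !is.finite(G) || G < 0) {
    stop("G must be a single non-negative number")
  }
  if (is.null(field)) field <- zero_field(c$n, c$labels)
  stopifnot(inherits(field, "wc_field"))
  if (length(field$R_e) != c$n) {
    stop(sprintf("field covers %d regions but connectome has %d",
                 length(field$R_e), c$n))
  }
  params <- apply_perturbations(nominal, field)
  structure(list(connectome = c, nominal = nominal, params = params,
                 G = G, field = field),
            class = "wc_network")
}

#' @export
print.wc_network <- function(x, ...) {
  het <- x$field$sigma > 0
  cat(sprintf("Wilson-Cowan network: %d regions, G = %g, %s (sigma = %g)\n",
              x$connectome$n, x$G,
              if (het) "heterogeneous" else "homogeneous", x$field$sigma))
  invisible(x)
}

# extract one per-region parameter as a vector (used by the integrator)
param_vec <- function(net, name) {
  vapply(net$params, function(p) p[[name]], numeric(1))
}
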