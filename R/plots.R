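#' Plot a bifurcation diagram
#'
#' Reproduces the standard single-node view: stable equilibria as solid
#' lines, unstable as dotted, the limit-cycle envelope as a shaded band,
#' folds and Hopf points as markers, with optional vertical guides marking
#' an experienced input range.
#'
#' @param d An annotated \code{wc_bifurcation}.
#' @param J_lines Optional numeric vector of J_tot guides (e.g. the range
#'   experienced in a network simulation).
#' @return A ggplot object.
#' @export
plot_bifurcation <- function(d, J_lines = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bifurcation needs the ggplot2 package")
  }
  stopifnot(inherits(d, "wc_bifurcation"))
  pts <- d$points
  pts$kind <- ifelse(pts$stability == "stable", "stable", "unstable")
  g <- ggplot2::ggplot(pts, ggplot2::aes(x = J_tot, y = E))
  if (!is.null(d$envelope) && any(d$envelope$oscillatory)) {
    env <- d$envelope[d$envelope$oscillatory, ]
    g <- g + ggplot2::geom_ribbon(
      data = env, ggplot2::aes(x = J_tot, ymin = E_min,
                               ymax = E_max),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.3)
  }
  g <- g + ggplot2::geom_line(
    ggplot2::aes(linetype = kind,
                 group = interaction(branch_id, kind))) +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dotted"))
  if (!is.null(d$folds) && nrow(d$folds)) {
    g <- g + ggplot2::geom_point(data = d$folds, shape = 15, size = 2,
                                 colour = "darkred")
  }
  if (!is.null(d$hopfs) && nrow(d$hopfs)) {
    g <- g + ggplot2::geom_point(data = d$hopfs, shape = 17, size = 2,
                                 colour = "darkblue")
  }
  if (!is.null(J_lines)) {
    g <- g + ggplot2::geom_vline(xintercept = J_lines, colour = "grey50",
                                 linetype = "dashed")
  }
  g + ggplot2::labs(x = "J_tot (mV)", y = "E (rate)") + ggplot2::theme_minimal()
}

#' Heat map of a parameter sweep
#'
#' @param s A \code{wc_sweep} with axis \code{"G_Be"}.
#' @return A ggplot object (mean FC-FC score per cell).
#' @export
plot_sweep <- function(s) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sweep needs the ggplot2 package")
  }
  stopifnot(inherits(s, "wc_sweep"), s$axis == "G_Be")
  ggplot2::ggplot(s$grid, ggplot2::aes(x = G, y = B_e,
                                       fill = mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  midpoint = 0, name = "rho_FCFC") +
    ggplot2::labs(x = "G (mV ms)", y = "B_e (mV)") +
    ggplot2::theme_minimal()
}

#' Carpet plot of simulated activity
#'
#' @param cd Output of \code{\link{carpet_data}}.
#' @return A ggplot object (node x time heat map, rows grouped
#'   anatomically).
#' @export
plot_carpet <- function(cd) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_carpet needs the ggplot2 package")
  }
  df <- data.frame(
    region = factor(rep(cd$regions, times = ncol(cd$E)),
                    levels = rev(cd$regions)),
    t = rep(cd$t, each = nrow(cd$E)),
    E = as.vector(cd$E))
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = region,
                                   fill = E)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "E") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
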