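#' Directed binary connectome
#'
#' Wrap an N x N binary directed adjacency matrix together with region
#' acronyms and anatomical grouping labels. The convention is
#' \code{A[a, b] = 1} iff region b projects to region a, so row sums are
#' in-degrees and the coupling term for region a sums over row a.
#'
#' @param A N x N numeric matrix with entries in \{0, 1\} and zero diagonal.
#' @param labels Character vector of N unique region acronyms. Defaults to
#'   rownames of \code{A}, else \code{"R1"..."RN"}.
#' @param groups Character vector of N anatomical grouping labels (optional;
#'   defaults to a single group).
#' @return An object of class \code{wc_connectome}.
#' @export
connectome <- function(A, labels = NULL, groups = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  n <- nrow(A)
  if (n < 2) stop("connectome needs at least 2 regions")
  if (!is.numeric(A) || any(!is.finite(A))) stop("adjacency entries must be finite numeric")
  if (any(A != 0 & A != 1)) stop("non-binary adjacency entries found")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero (no self-loops)")
  storage.mode(A) <- "double"
  if (is.null(labels)) labels <- rownames(A)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must equal region count")
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (is.null(groups)) groups <- rep("all", n)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must equal region count")
  dimnames(A) <- list(labels, labels)
  structure(list(A = A, labels = labels, groups = groups, n = n),
            class = "wc_connectome")
}

#' @export
print.wc_connectome <- function(x, ...) {
  cat(sprintf("Directed binary connectome: %d regions, %d edges (density %.3f)\n",
              x$n, sum(x$A), sum(x$A) / (x$n * (x$n - 1))))
  cat("Groups:", paste(unique(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' In-degree of each region
#'
#' @param c A \code{wc_connectome}.
#' @return Named integer vector of row sums (number of afferent projections).
#' @export
in_degree <- function(c) {
  stopifnot(inherits(c, "wc_connectome"))
  rowSums(c$A)
}

#' Inter-regional excitatory drive
#'
#' The external input each region receives from its afferent neighbours:
#' \code{J_e[a] = G * sum_b A[a, b] * E[b]} (mV).
#'
#' @param E_vec Per-region excitatory rates (length N).
#' @param c A \code{wc_connectome}.
#' @param G Global coupling constant (>= 0).
#' @return Numeric vector of length N, named by region.
#' @export
external_input <- function(E_vec, c, G) {
  stopifnot(inherits(c, "wc_connectome"))
  if (length(E_vec) != c$n) {
    stop(sprintf("external_input: E_vec has length %d but connectome has %d regions",
                 length(E_vec), c$n))
  }
  drop(G * (c$A %*% E_vec))
}

#' Net input after the threshold offset
#'
#' \code{J_tot = J_e - B_e}: the coordinate in which all single-node
#' bifurcation diagrams are expressed.
#'
#' @param J_e External drive (mV; vectorised).
#' @param B_e Excitatory firing threshold (mV; scalar or per-region).
#' @return \code{J_e - B_e}.
#' @export
total_input <- function(J_e, B_e) J_e - B_e
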