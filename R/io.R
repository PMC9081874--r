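#' Read a directed binary adjacency matrix
#'
#' Expects a square numeric CSV with region labels as both the header row
#' and the first column; the file's label order defines the canonical
#' region order for everything downstream. Non-square, non-binary,
#' self-loop and duplicate-label inputs are each rejected with a distinct
#' message. An optional region table supplies anatomical groupings.
#'
#' @param path Adjacency CSV.
#' @param region_path Optional region table TSV (columns \code{region},
#'   \code{group}) merged by label.
#' @return A \code{wc_connectome}.
#' @export
read_adjacency <- function(path, region_path = NULL) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  A <- as.matrix(df)
  if (nrow(A) != ncol(A)) stop("adjacency file is not square: ", path)
  if (!identical(rownames(A), colnames(A))) {
    stop("adjacency row and column labels disagree: ", path)
  }
  if (anyDuplicated(rownames(A))) stop("duplicate region labels in ", path)
  if (!is.numeric(A)) stop("adjacency entries must be numeric: ", path)
  if (any(A != 0 & A != 1)) stop("non-binary adjacency entries in ", path)
  if (any(diag(A) != 0)) stop("self-loops (non-zero diagonal) in ", path)
  groups <- NULL
  if (!is.null(region_path)) {
    rt <- read_region_table(region_path)
    missing <- setdiff(rownames(A), rt$region)
    if (length(missing)) {
      stop("region(s) in adjacency but absent from region table: ",
           paste(missing, collapse = ", "))
    }
    groups <- rt$group[match(rownames(A), rt$region)]
  }
  connectome(A, labels = rownames(A), groups = groups)
}

#' @rdname read_adjacency
#' @param c A \code{wc_connectome} to write.
#' @export
write_adjacency <- function(c, path) {
  stopifnot(inherits(c, "wc_connectome"))
  utils::write.csv(as.data.frame(c$A), path, quote = FALSE)
  invisible(path)
}

#' Read or write a region metadata table
#'
#' Tab-separated with columns \code{region} and \code{group}.
#'
#' @param path Region TSV.
#' @return data.frame with columns region, group.
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("region table not found: ", path)
  rt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region", "group")
  miss <- setdiff(need, names(rt))
  if (length(miss)) stop("region table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(rt$region)) stop("duplicate regions in region table: ", path)
  rt[need]
}

#' @rdname read_region_table
#' @param c A \code{wc_connectome} to write.
#' @export
write_region_table <- function(c, path) {
  stopifnot(inherits(c, "wc_connectome"))
  utils::write.table(data.frame(region = c$labels, group = c$groups),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-region cell densities
#'
#' Tab-separated with columns \code{region}, \code{e_density},
#' \code{i_density}. Rows are aligned to the connectome's label order (so
#' file row order never matters) and z-scored on load over the included
#' regions.
#'
#' @param path Densities TSV.
#' @param c A \code{wc_connectome} defining the canonical region order.
#' @return A \code{wc_densities} aligned to \code{c$labels}.
#' @export
read_densities <- function(path, c) {
  if (!file.exists(path)) stop("densities file not found: ", path)
  stopifnot(inherits(c, "wc_connectome"))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region", "e_density", "i_density")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("densities file missing column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(c$labels, df$region)
  if (length(absent)) {
    stop("region(s) missing from densities file: ", paste(absent, collapse = ", "))
  }
  extra <- setdiff(df$region, c$labels)
  if (length(extra)) {
    stop("region(s) in densities file but absent from connectome: ",
         paste(extra, collapse = ", "))
  }
  df <- df[match(c$labels, df$region), ]
  if (any(df$e_density < 0) || any(df$i_density < 0)) {
    stop("negative densities in ", path)
  }
  zscore_densities(df$e_density, df$i_density, labels = c$labels)
}

#' @rdname read_densities
#' @param d A \code{wc_densities} to write.
#' @export
write_densities <- function(d, path) {
  stopifnot(inherits(d, "wc_densities"))
  utils::write.table(data.frame(region = d$labels, e_density = d$e_raw,
                                i_density = d$i_raw),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write an FC matrix
#'
#' Square CSV with header labels, validated against the FC invariants
#' (symmetry, unit diagonal, entries in [-1, 1]).
#'
#' @param path FC CSV.
#' @return A \code{wc_fc}.
#' @export
read_fc <- function(path) {
  if (!file.exists(path)) stop("FC file not found: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_fc(as.matrix(df))
}

#' @rdname read_fc
#' @param fc A \code{wc_fc} to write.
#' @export
write_fc <- function(fc, path) {
  utils::write.csv(as.data.frame(unclass(fc)), path, quote = FALSE)
  invisible(path)
}

# schema of the run configuration: every key with its default (NULL =
# required). Surfaced defaults match the documented design choices.
config_schema <- function() {
  list(
    regime = "fixed_point", G = 0.65, B_e = NULL, sigma = 0,
    seed = 1L, n_rep = 5L, n_perm = 199L,
    simulation = list(dt = 0.1, T = 1.2e5, transient = 1000,
                      noise_s = 1.3e-5, noise_on_I = TRUE, store_every = 1L),
    sweep = list(G_values = seq(0, 1, length.out = 21),
                 Be_values = seq(1, 5, length.out = 21)),
    tolerances = list(root_resid = 1e-9, fold_bisect = 1e-6,
                      hopf_bisect = 1e-6, dedup = 1e-5, osc_amp = 1e-4),
    paths = list(connectome = NULL, regions = NULL, densities = NULL,
                 target_fc = NULL, out_dir = "results"))
}

merge_config <- function(schema, user, where = "") {
  unknown <- setdiff(names(user), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste(paste0(where, unknown), collapse = ", "))
  }
  for (k in names(schema)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      schema[[k]] <- merge_config(schema[[k]],
                                  if (is.null(user[[k]])) list() else user[[k]],
                                  where = paste0(where, k, "."))
    } else if (!is.null(user[[k]])) {
      schema[[k]] <- user[[k]]
    }
  }
  schema
}

#' Read and validate a run configuration
#'
#' YAML key-value config with schema validation: unknown keys are an error
#' (never silently ignored), missing keys take the documented defaults, and
#' every numeric tolerance is surfaced. \code{B_e = NULL} in the result
#' means "use the regime's nominal threshold".
#'
#' @param path YAML config file; omit to obtain the pure defaults.
#' @return Named list with the full, defaulted configuration.
#' @export
read_config <- function(path = NULL) {
  schema <- config_schema()
  if (is.null(path)) return(schema)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(schema, user)
  if (!cfg$regime %in% c("fixed_point", "hysteresis", "limit_cycle")) {
    stop("config field 'regime' must name a shipped regime, got: ", cfg$regime)
  }
  for (f in c("connectome", "regions", "densities", "target_fc")) {
    pth <- cfg$paths[[f]]
    if (!is.null(pth) && !file.exists(pth)) {
      stop(sprintf("config paths.%s refers to a missing file: %s", f, pth))
    }
  }
  cfg
}

#' Write run results and a reproducibility manifest
#'
#' Writes any named list of data.frames as TSV files under \code{out_dir},
#' plus \code{manifest.json} recording the configuration, seeds, package
#' version, wall-clock time and md5 checksums of every written file — the
#' information needed to re-run the deterministic stages exactly.
#'
#' @param results Named list of data.frames (one TSV each).
#' @param out_dir Output directory (created if needed).
#' @param config The run configuration to embed in the manifest.
#' @param seeds Integer vector of seeds used.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(results, out_dir, config = list(), seeds = integer(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(results[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(
    package = "wcnet",
    version = as.character(utils::packageVersion("wcnet")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds, config = config,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Export a bifurcation diagram
#'
#' Long-format TSV of the equilibrium branches (J_tot, E, I, branch_id,
#' stability) plus a JSON sidecar holding folds, Hopf points and the
#' oscillation envelope.
#'
#' @param d An annotated \code{wc_bifurcation}.
#' @param path Output TSV path; the sidecar takes the same name with
#'   extension \code{.json}.
#' @return Invisibly, the two paths.
#' @export
write_diagram <- function(d, path) {
  stopifnot(inherits(d, "wc_bifurcation"))
  utils::write.table(d$points[c("J_tot", "E", "I", "branch_id", "stability")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(J_range = d$J_range, params = unclass(d$params),
                            folds = d$folds, hopfs = d$hopfs,
                            envelope = d$envelope),
                       side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(path, side))
}
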