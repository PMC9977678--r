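#' Run configuration
#'
#' Bundles every tunable threshold of the pipeline in one object. Defaults
#' are the published analysis settings: 5 um dendrogram cut for transcript
#' clustering, 10 um neighbourhood-graph radius (inclusive), 10 um strict-<
#' radius for neighbour-expression counting, m = 1000 label permutations,
#' alpha = 0.05, 10 px label expansion at 0.138 um/px, segments kept only
#' with >= 3 molecules and >= 3 genes, and the 4 um strict-< dual-channel
#' spot co-expression threshold.
#'
#' @param cut_height dendrogram cut height in um for transcript clustering.
#' @param graph_radius neighbourhood-graph edge radius in um (edges connect
#'   centroids no further apart than this; inclusive comparison).
#' @param neighbour_count_radius radius in um for counting query transcripts
#'   around reference clusters (strict `<` comparison).
#' @param k_cap diagnostic neighbour cap: a warning is raised when any vertex
#'   has more than `k_cap - 1` within-radius neighbours, the regime in which a
#'   capped k-nearest-neighbour search would have truncated the radius query.
#'   The search used here is exact and uncapped.
#' @param n_permutations number of label permutations m for the null.
#' @param alpha significance level used to convert permutation p-values into
#'   per-slide interaction/avoidance signs.
#' @param expand_distance_px nuclear label expansion distance in pixels
#'   (Euclidean, centre-to-centre).
#' @param pixel_size raster pixel edge length in um.
#' @param min_molecules,min_genes segment retention thresholds (a segment is
#'   kept iff it has at least `min_molecules` molecules AND `min_genes`
#'   distinct genes).
#' @param spot_threshold dual-channel co-expression distance in um: a green
#'   spot is "active" iff its nearest red spot is strictly closer than this.
#' @param rng_seed master seed for all randomness.
#' @param marker_genes genes whose transcripts are clustered into cell-type
#'   proxies. Defaults to the six-marker immune panel used for IBD colon
#'   sections (CD4 T cells, eosinophils, CD8 T cells, B cells, Treg cells,
#'   monocytes).
#' @return an object of class `run_config` (a validated named list).
#' @examples
#' cfg <- run_config(rng_seed = 7)
#' cfg$cut_height
#' @export
run_config <- function(cut_height = 5,
                       graph_radius = 10,
                       neighbour_count_radius = 10,
                       k_cap = 41L,
                       n_permutations = 1000L,
                       alpha = 0.05,
                       expand_distance_px = 10L,
                       pixel_size = 0.138,
                       min_molecules = 3L,
                       min_genes = 3L,
                       spot_threshold = 4,
                       rng_seed = 1L,
                       marker_genes = c("CD4", "SIGLEC8", "CD8A",
                                        "CD19", "FOXP3", "FCN1")) {
  cfg <- list(
    cut_height = cut_height,
    graph_radius = graph_radius,
    neighbour_count_radius = neighbour_count_radius,
    k_cap = as.integer(k_cap),
    n_permutations = as.integer(n_permutations),
    alpha = alpha,
    expand_distance_px = as.integer(expand_distance_px),
    pixel_size = pixel_size,
    min_molecules = as.integer(min_molecules),
    min_genes = as.integer(min_genes),
    spot_threshold = spot_threshold,
    rng_seed = as.integer(rng_seed),
    marker_genes = as.character(marker_genes)
  )
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  for (f in c("cut_height", "graph_radius", "neighbour_count_radius",
              "pixel_size", "spot_threshold")) {
    if (!is_number(cfg[[f]]) || cfg[[f]] <= 0) {
      sc_stop(sprintf("config field '%s' must be a positive number", f),
              "spatcoloc_config_error")
    }
  }
  if (!is_count(cfg$n_permutations, min = 1L)) {
    sc_stop("config field 'n_permutations' must be an integer >= 1",
            "spatcoloc_config_error")
  }
  if (!is_number(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    sc_stop("config field 'alpha' must lie in (0, 1)", "spatcoloc_config_error")
  }
  if (!is_count(cfg$expand_distance_px)) {
    sc_stop("config field 'expand_distance_px' must be a non-negative integer",
            "spatcoloc_config_error")
  }
  for (f in c("min_molecules", "min_genes", "k_cap")) {
    if (!is_count(cfg[[f]], min = 1L)) {
      sc_stop(sprintf("config field '%s' must be a positive integer", f),
              "spatcoloc_config_error")
    }
  }
  invisible(cfg)
}

#' Read a run configuration from a JSON file
#'
#' The file is a flat JSON object whose keys mirror [run_config()] argument
#' names; keys not present fall back to the defaults. Unknown keys are an
#' error so typos cannot silently revert a threshold to its default.
#'
#' @param path path to a JSON file.
#' @param ... overrides applied on top of the file values (highest
#'   precedence), e.g. from command-line flags.
#' @return a `run_config` object.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) {
    sc_stop(sprintf("config file not found: %s", path), "spatcoloc_io_error")
  }
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    sc_stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
            "spatcoloc_config_error")
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("spatcoloc run configuration\n")
  for (f in setdiff(names(x), "marker_genes")) {
    cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  }
  cat(sprintf("  %-22s %s\n", "marker_genes",
              paste(x$marker_genes, collapse = ", ")))
  invisible(x)
}
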