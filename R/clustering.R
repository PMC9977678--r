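## Segmentation-free stand-in for cells: same-gene molecules are grouped by
## unweighted average-linkage hierarchical clustering of their 2D Euclidean
## distances, with the dendrogram cut at a fixed height (default 5 um).
## A cluster of marker-gene molecules then represents one cell of the type
## that gene marks.

#' Cluster the molecules of one gene in one slide/ROI
#'
#' Unweighted average linkage (UPGMA: the distance between two clusters is
#' the arithmetic mean over all inter-cluster point pairs) applied to the
#' pairwise Euclidean distances of the 2D coordinates; flat clusters are the
#' result of realizing every merge with height `<= cut_height` (boundary
#' inclusive). Average linkage is used instead of single linkage to prevent
#' chaining of stray molecules between cells.
#'
#' Determinism: tied merges are resolved to the lexicographically smallest
#' pair of current cluster ids, a cluster's id being the smallest input
#' index among its members. Cluster labels are numbered 1..k in ascending
#' id order.
#'
#' @param x,y molecule coordinates in um (equal length, >= 1 point).
#' @param cut_height dendrogram cut height in um.
#' @return an integer vector of cluster labels, one per input point.
#' @examples
#' cluster_gene(c(0, 4, 8), c(0, 0, 0), cut_height = 5)  # 1 1 2
#' @export
cluster_gene <- function(x, y, cut_height = 5) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(integer(0))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    sc_stop("cluster_gene: coordinates must be finite", "spatcoloc_input_error")
  }
  if (!is_number(cut_height) || cut_height <= 0) {
    sc_stop("cut_height must be > 0", "spatcoloc_config_error")
  }
  if (length(x) > 50000L) {
    sc_stop(paste0("more than 50000 molecules for one gene/ROI; the quadratic ",
                   "distance matrix is impractical - tile the ROI into smaller ",
                   "regions and cluster each tile"), "spatcoloc_scale_error")
  }
  .avg_linkage_cut(as.numeric(x), as.numeric(y), cut_height)
}

#' Cluster all marker genes across slides and ROIs
#'
#' Runs [cluster_gene()] independently for every (gene, slide, ROI)
#' combination: molecules of different genes or different ROIs never
#' co-cluster, mirroring per-image analysis. Molecules of non-marker genes
#' are left untouched (they remain available to the neighbour-expression
#' comparison).
#'
#' @param table a [transcript_table()].
#' @param marker_genes character vector of genes to cluster (defaults to
#'   `config$marker_genes`).
#' @param config a [run_config()].
#' @return an object of class `cluster_set`: a data frame with one row per
#'   cluster (`cluster_id` globally unique, `gene`, `slide_id`, `roi_id`,
#'   `x_um`, `y_um` centroid, `size`) and a `members` attribute (list of
#'   integer row indices into `table`, one element per cluster).
#' @export
cluster_all <- function(table, marker_genes = NULL, config = run_config()) {
  stopifnot(inherits(table, "transcript_table"))
  if (is.null(marker_genes)) marker_genes <- config$marker_genes
  if (length(marker_genes) == 0L) {
    sc_stop("marker_genes must be nonempty", "spatcoloc_config_error")
  }
  units <- unique(as.data.frame(table)[c("slide_id", "roi_id")])
  out <- list()
  members <- list()
  next_id <- 1L
  for (u in seq_len(nrow(units))) {
    in_unit <- table$slide_id == units$slide_id[u] &
      table$roi_id == units$roi_id[u]
    for (g in marker_genes) {
      idx <- which(in_unit & table$gene == g)
      if (length(idx) == 0L) {
        sc_warn(sprintf("marker gene '%s' absent from slide %s / ROI %s",
                        g, units$slide_id[u], units$roi_id[u]),
                "spatcoloc_missing_marker")
        next
      }
      lab <- cluster_gene(table$x_um[idx], table$y_um[idx],
                          cut_height = config$cut_height)
      k <- max(lab)
      cl <- data.frame(
        cluster_id = next_id:(next_id + k - 1L),
        gene = g,
        slide_id = units$slide_id[u],
        roi_id = units$roi_id[u],
        x_um = vapply(seq_len(k), function(c) mean(table$x_um[idx][lab == c]), 0),
        y_um = vapply(seq_len(k), function(c) mean(table$y_um[idx][lab == c]), 0),
        size = tabulate(lab, k),
        stringsAsFactors = FALSE)
      members <- c(members, lapply(seq_len(k), function(c) idx[lab == c]))
      next_id <- next_id + k
      out[[length(out) + 1L]] <- cl
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(cluster_id = integer(), gene = character(),
               slide_id = character(), roi_id = character(),
               x_um = numeric(), y_um = numeric(), size = integer())
  }
  rownames(res) <- NULL
  attr(res, "members") <- members
  class(res) <- c("cluster_set", class(res))
  res
}
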