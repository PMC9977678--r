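## Neighbour-expression comparison: do reference clusters that sit next to a
## partner type (e.g. eosinophil-marker clusters with a CD4 neighbour) carry
## more query transcripts nearby than reference clusters that do not? Group
## means are formed per ROI and compared with a two-sided paired Wilcoxon
## signed-rank test across ROIs.

#' Partition reference clusters by partner association
#'
#' A reference cluster is "associated" iff it has at least one graph edge to
#' a partner-type cluster; the two groups partition the reference clusters.
#'
#' @param graph a [build_graph()] result.
#' @param reference reference type (gene).
#' @param partner partner type (gene).
#' @return list with integer vectors `associated` and `non_associated` of
#'   `cluster_id`s.
#' @export
partition_by_association <- function(graph, reference, partner) {
  stopifnot(inherits(graph, "proximity_graph"))
  v <- graph$vertices
  ref_idx <- which(v$type == reference)
  if (!length(ref_idx)) {
    sc_warn(sprintf("no '%s' clusters in the graph; empty partition", reference),
            "spatcoloc_missing_type")
    return(list(associated = integer(0), non_associated = integer(0)))
  }
  e <- graph$edges
  assoc <- logical(nrow(v))
  if (nrow(e)) {
    t1 <- v$type[e[, 1]]; t2 <- v$type[e[, 2]]
    hit <- e[t1 == reference & t2 == partner, 1]
    hit <- c(hit, e[t2 == reference & t1 == partner, 2])
    assoc[unique(hit)] <- TRUE
  }
  list(associated = v$cluster_id[ref_idx][assoc[ref_idx]],
       non_associated = v$cluster_id[ref_idx][!assoc[ref_idx]])
}

#' Count query transcripts around reference clusters
#'
#' For each reference cluster, the number of individual query-gene molecules
#' at Euclidean distance strictly less than `radius` from the cluster
#' centroid (the counting radius is strict `<`, unlike the inclusive graph
#' radius). Query molecules come from the full transcript table and need not
#' be marker genes.
#'
#' @param clusters a `cluster_set` subset (the reference clusters), one
#'   slide/ROI.
#' @param table the full [transcript_table()] (same slide/ROI).
#' @param query_genes character vector of query genes.
#' @param radius counting radius in um, strict `<`.
#' @return integer matrix, clusters x query genes, with `cluster_id`
#'   rownames.
#' @export
count_query_neighbours <- function(clusters, table, query_genes, radius = 10) {
  df <- as.data.frame(clusters)
  out <- matrix(0L, nrow(df), length(query_genes),
                dimnames = list(as.character(df$cluster_id), query_genes))
  for (g in query_genes) {
    qi <- which(table$gene == g)
    if (!length(qi)) {
      sc_warn(sprintf("query gene '%s' absent from the table; zero counts", g),
              "spatcoloc_missing_type")
      next
    }
    qx <- table$x_um[qi]; qy <- table$y_um[qi]
    r2 <- radius^2
    out[, g] <- vapply(seq_len(nrow(df)), function(i) {
      sum((qx - df$x_um[i])^2 + (qy - df$y_um[i])^2 < r2)
    }, 0L)
  }
  out
}

#' Exact two-sided paired Wilcoxon signed-rank test
#'
#' Differences of exactly zero are dropped; tied absolute differences
#' receive mid-ranks. For up to 25 informative pairs the null distribution
#' of the signed-rank statistic W (sum of ranks of positive differences) is
#' computed exactly by enumerating sign assignments via its generating
#' function, ties included; beyond that a normal approximation with
#' tie-corrected variance and continuity correction is used. The two-sided
#' p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' `stats::wilcox.test` is not used because it abandons the exact
#' distribution in the presence of ties or zeros, which this comparison
#' (small integer count differences across ROIs) routinely produces.
#'
#' @param x numeric vector: first group values (e.g. associated-group means
#'   per ROI), or the paired differences when `y` is `NULL`.
#' @param y optional second group values, same length and pairing as `x`.
#' @return list with `W` (signed-rank statistic), `p` (two-sided), `n_pairs`
#'   (informative pairs after dropping zeros), `n_zero`, `exact` (logical)
#'   and `undefined` (TRUE when every difference is zero; then `W` and `p`
#'   are `NA`).
#' @examples
#' paired_wilcoxon(c(1.2, 0.8, 2.0, 1.1, 0.6))$p  # all positive, n = 5: 0.0625
#' @export
paired_wilcoxon <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  if (!length(d) || any(!is.finite(d))) {
    sc_stop("paired_wilcoxon needs finite differences", "spatcoloc_input_error")
  }
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    sc_warn("all paired differences are zero; test undefined",
            "spatcoloc_undefined")
    return(list(W = NA_real_, p = NA_real_, n_pairs = 0L, n_zero = n_zero,
                exact = NA, undefined = TRUE))
  }
  r <- rank(abs(d))            # mid-ranks on ties
  W <- sum(r[d > 0])
  if (n <= 25L) {
    ## exact null via generating function over doubled ranks (integers even
    ## with mid-ranks); coefficient k = number of sign vectors with 2W = k
    r2 <- as.integer(round(2 * r))
    coef <- numeric(sum(r2) + 1L)   # index k+1 holds count for 2W = k
    coef[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), coef[seq_len(length(coef) - ri)])
      coef <- coef + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(coef[seq_len(w2 + 1L)]) / total
    p_ge <- sum(coef[(w2 + 1L):length(coef)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(W = W, p = p, n_pairs = n, n_zero = n_zero, exact = exact,
       undefined = FALSE)
}

#' Neighbour-expression comparison across ROIs
#'
#' For every (slide, ROI): build the proximity graph over marker clusters,
#' split the reference clusters into partner-associated vs non-associated,
#' count query transcripts within the strict-< counting radius of each
#' reference centroid, and form the two group means (mean count per
#' reference cluster). Per query gene, ROIs contributing both groups enter a
#' two-sided paired Wilcoxon signed-rank test of associated vs
#' non-associated means.
#'
#' @param table a [transcript_table()].
#' @param reference reference marker gene (cluster type whose surroundings
#'   are probed).
#' @param partner partner marker gene defining association.
#' @param query_genes genes whose molecules are counted (need not be
#'   markers).
#' @param config a [run_config()]; `graph_radius` (inclusive) defines
#'   association, `neighbour_count_radius` (strict `<`) defines counting.
#' @return an object of class `neighbour_expression`: list with `per_roi`
#'   (data frame: slide/ROI, query gene, group sizes and means) and `tests`
#'   (data frame per query gene: `W`, `p`, `n_pairs`).
#' @export
neighbour_expression <- function(table, reference, partner, query_genes,
                                 config = run_config()) {
  markers <- unique(c(config$marker_genes, reference, partner))
  clusters <- suppressWarnings(cluster_all(table, marker_genes = markers,
                                           config = config))
  units <- unique(as.data.frame(clusters)[c("slide_id", "roi_id")])
  rows <- list()
  for (u in seq_len(nrow(units))) {
    sub <- clusters[clusters$slide_id == units$slide_id[u] &
                      clusters$roi_id == units$roi_id[u], , drop = FALSE]
    graph <- build_graph(sub, radius = config$graph_radius,
                         k_cap = config$k_cap)
    part <- partition_by_association(graph, reference, partner)
    tab_u <- table[table$slide_id == units$slide_id[u] &
                     table$roi_id == units$roi_id[u], , drop = FALSE]
    for (grp in c("associated", "non_associated")) {
      ids <- part[[grp]]
      if (!length(ids)) next
      refs <- sub[sub$cluster_id %in% ids, , drop = FALSE]
      cnt <- suppressWarnings(
        count_query_neighbours(refs, tab_u, query_genes,
                               radius = config$neighbour_count_radius))
      for (g in query_genes) {
        rows[[length(rows) + 1L]] <- data.frame(
          slide_id = units$slide_id[u], roi_id = units$roi_id[u],
          gene = g, group = grp, n_clusters = nrow(refs),
          mean_count = mean(cnt[, g]), stringsAsFactors = FALSE)
      }
    }
  }
  per_roi <- if (length(rows)) do.call(rbind, rows) else
    data.frame(slide_id = character(), roi_id = character(), gene = character(),
               group = character(), n_clusters = integer(),
               mean_count = numeric())
  tests <- do.call(rbind, lapply(query_genes, function(g) {
    sub <- per_roi[per_roi$gene == g, , drop = FALSE]
    wide <- merge(
      sub[sub$group == "associated",
          c("slide_id", "roi_id", "mean_count")],
      sub[sub$group == "non_associated",
          c("slide_id", "roi_id", "mean_count")],
      by = c("slide_id", "roi_id"), suffixes = c("_assoc", "_non"))
    if (nrow(wide) == 0L) {
      return(data.frame(gene = g, W = NA_real_, p = NA_real_, n_pairs = 0L,
                        stringsAsFactors = FALSE))
    }
    wt <- withCallingHandlers(
      paired_wilcoxon(wide$mean_count_assoc, wide$mean_count_non),
      warning = function(w) {
        if (inherits(w, "spatcoloc_undefined")) invokeRestart("muffleWarning")
      })
    data.frame(gene = g, W = wt$W, p = wt$p, n_pairs = nrow(wide),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_roi = per_roi, tests = tests,
                 reference = reference, partner = partner),
            class = "neighbour_expression")
}

#' @export
print.neighbour_expression <- function(x, ...) {
  cat(sprintf("neighbour_expression: %s clusters by %s association\n",
              x$reference, x$partner))
  print(x$tests)
  invisible(x)
}
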