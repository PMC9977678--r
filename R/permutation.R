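## Vertex-label permutation test for cross-type proximity and the signed
## fraction-of-slides score. The edge set is held fixed; the multiset of
## vertex type labels (all marker types jointly) is uniformly permuted m
## times, the cross-type edge count recomputed each time, and both
## one-sided p-values taken as P = (b + 1) / (m + 1), b being the number of
## permutations at least (resp. at most) as extreme as the observed count.
## The test therefore conditions on tissue composition and spatial
## structure: only the assignment of types to positions is randomized.

#' Label-permutation test for one type pair on one slide/ROI
#'
#' @param graph a [build_graph()] result with at least 2 vertices and 1 edge.
#' @param gene_a,gene_b the type pair to test (`gene_a == gene_b` tests
#'   within-type clustering).
#' @param m number of permutations.
#' @param alpha significance level converting p-values to a sign.
#' @param seed integer seed (reproducible null).
#' @return an object of class `permutation_result`: list with `type_pair`,
#'   `observed_edges`, `m`, `b_greater`, `b_less`, `p_greater`, `p_less`
#'   (each `(b + 1)/(m + 1)`), `sign` (+1 interaction, -1 avoidance, 0
#'   neither; when both tails fall below `alpha` the smaller p decides),
#'   `null_mean`, `alpha`, `slide_id`, `roi_id`.
#' @export
permutation_test <- function(graph, gene_a, gene_b, m = 1000L, alpha = 0.05,
                             seed = 1L) {
  stopifnot(inherits(graph, "proximity_graph"))
  if (!is_count(m, min = 1L)) {
    sc_stop("m must be an integer >= 1", "spatcoloc_config_error")
  }
  n <- nrow(graph$vertices)
  if (n < 2L || nrow(graph$edges) < 1L) {
    sc_stop("permutation test needs a graph with >= 2 vertices and >= 1 edge",
            "spatcoloc_degenerate")
  }
  types <- graph$vertices$type
  if (length(unique(types)) < 2L) {
    sc_stop("permutation test needs >= 2 distinct vertex types (degenerate null)",
            "spatcoloc_degenerate")
  }
  ## integer coding: only a/b membership matters for the count
  code <- integer(n)
  code[types == gene_a] <- 1L
  code[types == gene_b] <- if (gene_a == gene_b) 1L else 2L
  e1 <- graph$edges[, 1]
  e2 <- graph$edges[, 2]
  count_fun <- if (gene_a == gene_b) {
    function(pc) sum(pc[e1] == 1L & pc[e2] == 1L)
  } else {
    function(pc) sum(pc[e1] + pc[e2] == 3L & pc[e1] != pc[e2])
  }
  observed <- count_fun(code)
  null_counts <- with_seed(seed, {
    vapply(seq_len(m), function(i) count_fun(code[sample.int(n)]), 0L)
  })
  b_greater <- sum(null_counts >= observed)
  b_less <- sum(null_counts <= observed)
  p_greater <- (b_greater + 1) / (m + 1)
  p_less <- (b_less + 1) / (m + 1)
  sgn <- 0L
  if (p_greater <= alpha && (p_less > alpha || p_greater <= p_less)) sgn <- 1L
  if (p_less <= alpha && (p_greater > alpha || p_less < p_greater)) sgn <- -1L
  structure(list(type_pair = c(gene_a, gene_b),
                 observed_edges = observed,
                 m = as.integer(m),
                 b_greater = b_greater, b_less = b_less,
                 p_greater = p_greater, p_less = p_less,
                 sign = sgn,
                 null_mean = mean(null_counts),
                 alpha = alpha,
                 slide_id = graph$slide_id, roi_id = graph$roi_id),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation_result %s-%s (slide %s): observed %d, ",
                     "null mean %.2f, p_greater %.4g, p_less %.4g, sign %+d\n"),
              x$type_pair[1], x$type_pair[2], x$slide_id, x$observed_edges,
              x$null_mean, x$p_greater, x$p_less, x$sign))
  invisible(x)
}

canonical_pair <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Aggregate per-slide permutation results into the proximity score
#'
#' For each type pair, score = (number of slides with sign +1 minus number
#' with sign -1) divided by the number of slides testable for that pair.
#' The score lies in `[-1, +1]`: +1 means the pair was significantly closer
#' than chance on every slide (interaction), -1 significantly farther
#' (avoidance). Slides where a pair was untestable (type absent, empty
#' graph) simply contribute no result and are excluded from that pair's
#' denominator.
#'
#' @param results list of [permutation_test()] results (possibly several
#'   slides x several pairs).
#' @return an object of class `proximity_scores`: data frame with `gene_a`,
#'   `gene_b`, `score`, `n_slides`, `n_pos`, `n_neg`; the symmetric score
#'   matrix is attached as attribute `"matrix"` and the per-slide results as
#'   attribute `"results"`.
#' @export
proximity_score <- function(results) {
  if (inherits(results, "permutation_result")) results <- list(results)
  if (!length(results)) {
    sc_stop("no permutation results to aggregate", "spatcoloc_input_error")
  }
  keys <- vapply(results, function(r) canonical_pair(r$type_pair[1], r$type_pair[2]), "")
  slides <- vapply(results, function(r) paste(r$slide_id, r$roi_id), "")
  if (anyDuplicated(paste(keys, slides))) {
    sc_stop("more than one result for the same (slide/ROI, type pair)",
            "spatcoloc_input_error")
  }
  signs <- vapply(results, `[[`, 0L, "sign")
  out <- do.call(rbind, lapply(unique(keys), function(k) {
    g <- strsplit(k, "|", fixed = TRUE)[[1]]
    s <- signs[keys == k]
    data.frame(gene_a = g[1], gene_b = g[length(g)],
               score = (sum(s == 1L) - sum(s == -1L)) / length(s),
               n_slides = length(s), n_pos = sum(s == 1L), n_neg = sum(s == -1L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  genes <- sort(unique(c(out$gene_a, out$gene_b)))
  mat <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
  for (r in seq_len(nrow(out))) {
    mat[out$gene_a[r], out$gene_b[r]] <- out$score[r]
    mat[out$gene_b[r], out$gene_a[r]] <- out$score[r]
  }
  attr(out, "matrix") <- mat
  attr(out, "results") <- results
  class(out) <- c("proximity_scores", class(out))
  out
}

#' Full segmentation-free proximity pipeline
#'
#' Clusters marker transcripts per (gene, slide, ROI), builds the
#' fixed-radius neighbourhood graph per slide/ROI, runs the label
#' permutation test for every unordered marker pair present, and aggregates
#' the signed fraction-of-slides proximity score. Pairs untestable on a
#' slide (a type absent there, or an edgeless graph) are skipped and logged;
#' they reduce that pair's denominator.
#'
#' @param table a [transcript_table()].
#' @param config a [run_config()]; supplies marker genes, cut height,
#'   radius, m, alpha and master seed.
#' @param pairs optional two-column character matrix of type pairs to test;
#'   defaults to all unordered marker pairs (including within-type).
#' @param include_self also test within-type pairs when `pairs` is NULL.
#' @return a list: `scores` ([proximity_score()] output), `results`
#'   (per-slide [permutation_test()] list), `clusters` (the `cluster_set`),
#'   `skipped` (data frame of untestable slide/pair combinations).
#' @export
run_proximity_analysis <- function(table, config = run_config(), pairs = NULL,
                                   include_self = FALSE) {
  clusters <- suppressWarnings(cluster_all(table, config = config))
  if (is.null(pairs)) {
    g <- config$marker_genes
    pairs <- t(utils::combn(g, 2L))
    if (include_self) pairs <- rbind(pairs, cbind(g, g))
  }
  units <- unique(as.data.frame(clusters)[c("slide_id", "roi_id")])
  results <- list()
  skipped <- list()
  for (u in seq_len(nrow(units))) {
    sub <- clusters[clusters$slide_id == units$slide_id[u] &
                      clusters$roi_id == units$roi_id[u], , drop = FALSE]
    graph <- build_graph(sub, radius = config$graph_radius,
                         k_cap = config$k_cap)
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      testable <- a %in% graph$vertices$type && b %in% graph$vertices$type &&
        nrow(graph$edges) >= 1L && length(unique(graph$vertices$type)) >= 2L
      if (!testable) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(slide_id = units$slide_id[u], roi_id = units$roi_id[u],
                     gene_a = a, gene_b = b, stringsAsFactors = FALSE)
        next
      }
      res <- permutation_test(graph, a, b, m = config$n_permutations,
                              alpha = config$alpha,
                              seed = derive_seed(config$rng_seed,
                                                 (u - 1L) * nrow(pairs) + p))
      results[[length(results) + 1L]] <- res
    }
  }
  if (length(skipped)) {
    sc_log(sprintf("%d untestable (slide, pair) combination(s) skipped",
                   length(skipped)))
  }
  list(scores = if (length(results)) proximity_score(results) else NULL,
       results = results,
       clusters = clusters,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}
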