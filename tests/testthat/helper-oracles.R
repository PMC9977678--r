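## Independent brute-force oracles. Each recomputes its quantity from first
## principles along a different algorithmic route than the implementation it
## checks (from-scratch recomputation instead of incremental updates,
## all-pairs scans instead of spatial indexing, full enumeration instead of
## Monte Carlo).

## Average-linkage agglomeration with cut: at EVERY step all cluster-pair
## average distances are recomputed from the raw point distance matrix via
## indicator-matrix products (no Lance-Williams update), and the minimal
## pair is chosen scanning in ascending (id_a, id_b) order, ids being the
## smallest member indices.
oracle_avg_linkage <- function(x, y, cut) {
  n <- length(x)
  D <- as.matrix(dist(cbind(x, y)))
  groups <- as.list(seq_len(n))
  repeat {
    k <- length(groups)
    if (k == 1) break
    M <- matrix(0, k, n)
    for (g in seq_len(k)) M[g, groups[[g]]] <- 1
    S <- M %*% D %*% t(M)
    sizes <- vapply(groups, length, 0L)
    A <- S / outer(sizes, sizes)
    ids <- vapply(groups, min, 0L)
    o <- order(ids)
    best <- Inf; bi <- bj <- NA
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        i <- o[a]; j <- o[b]
        if (A[i, j] < best) { best <- A[i, j]; bi <- i; bj <- j }
      }
    }
    if (best > cut) break
    groups[[bi]] <- sort(c(groups[[bi]], groups[[bj]]))
    groups <- groups[-bj]
  }
  ids <- vapply(groups, min, 0L)
  groups <- groups[order(ids)]
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

## Fixed-radius graph: all-pairs thresholding (inclusive).
oracle_radius_edges <- function(x, y, radius) {
  n <- length(x)
  ei <- integer(0); ej <- integer(0)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= radius^2) {
          ei <- c(ei, i); ej <- c(ej, j)
        }
      }
    }
  }
  cbind(i = ei, j = ej)
}

## Exact permutation null for a 2-type labelled graph: uniform over all
## assignments of which vertices carry type a (equivalent to uniformly
## permuting the label multiset). Returns both exact tail probabilities of
## the cross-type edge count at the observed value.
oracle_perm_exact <- function(types, edges, a, b) {
  n <- length(types)
  cross_count <- function(lab) {
    t1 <- lab[edges[, 1]]; t2 <- lab[edges[, 2]]
    sum((t1 == a & t2 == b) | (t1 == b & t2 == a))
  }
  observed <- cross_count(types)
  n_a <- sum(types == a)
  subsets <- utils::combn(n, n_a)
  counts <- apply(subsets, 2, function(s) {
    lab <- rep(b, n); lab[s] <- a
    cross_count(lab)
  })
  list(observed = observed,
       p_ge = mean(counts >= observed),
       p_le = mean(counts <= observed))
}

## Exhaustive nearest-labelled-pixel expansion with lower-label tie-break.
oracle_expand <- function(px, dist_px) {
  nr <- nrow(px); nc <- ncol(px)
  lab_idx <- which(px > 0L, arr.ind = TRUE)
  out <- px
  if (nrow(lab_idx) == 0L || dist_px == 0L) return(out)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (px[r, c] > 0L) next
      d2 <- (lab_idx[, 1] - r)^2 + (lab_idx[, 2] - c)^2
      best <- min(d2)
      if (best <= dist_px^2) {
        cand <- px[lab_idx[d2 == best, , drop = FALSE]]
        out[r, c] <- min(cand)
      }
    }
  }
  out
}

## Full 2^n sign-vector enumeration of the paired Wilcoxon two-sided p
## (zeros dropped, mid-ranks on tied absolute differences).
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_le <- mean(W_all <= W_obs)
  p_ge <- mean(W_all >= W_obs)
  min(1, 2 * min(p_le, p_ge))
}

## Brute-force nearest red distance per green spot.
oracle_nearest_red <- function(gx, gy, rx, ry) {
  vapply(seq_along(gx), function(i) {
    if (!length(rx)) return(Inf)
    sqrt(min((rx - gx[i])^2 + (ry - gy[i])^2))
  }, 0)
}

## Quick transcript table builder for constructed cases.
make_table <- function(gene, x, y, slide = "S1", roi = "R1") {
  transcript_table(data.frame(
    slide_id = rep_len(slide, length(x)), roi_id = rep_len(roi, length(x)),
    gene = rep_len(gene, length(x)), x_um = x, y_um = y,
    stringsAsFactors = FALSE))
}

## Minimal hand-built proximity graph (vertex types + edge list), for tests
## that exercise the permutation machinery on constructed topologies.
make_graph <- function(types, edges, slide = "S1", roi = "R1") {
  structure(list(
    vertices = data.frame(cluster_id = seq_along(types), type = types,
                          x_um = seq_along(types), y_um = 0,
                          stringsAsFactors = FALSE),
    edges = matrix(as.integer(edges), ncol = 2,
                   dimnames = list(NULL, c("i", "j"))),
    radius = 10, slide_id = slide, roi_id = roi),
    class = "proximity_graph")
}

## Random connected 2-type labelled graph on n <= 8 vertices.
random_connected_graph <- function(n, p_edge = 0.45) {
  repeat {
    em <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(em)) < p_edge
    if (!any(keep)) next
    edges <- em[keep, , drop = FALSE]
    ## connectivity by label propagation
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(edges))) {
        a <- edges[e, 1]; b <- edges[e, 2]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) {
          comp[c(a, b)] <- m; changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (length(unique(comp)) != 1L) next
    types <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(types)) < 2L) next
    return(list(types = types, edges = edges))
  }
}
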