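test_that("association partitions reference clusters by partner edges", {
  ## reference at index 1 has a partner within 10 um; index 3 does not
  types <- c("SIGLEC8", "CD4", "SIGLEC8", "SIGLEC8")
  edges <- rbind(c(1, 2), c(3, 4))    # 3-4 is reference-reference, not partner
  g <- make_graph(types, edges)
  part <- partition_by_association(g, "SIGLEC8", "CD4")
  expect_equal(part$associated, 1L)
  expect_setequal(part$non_associated, c(3L, 4L))
  ## conservation: the two groups partition the reference clusters
  expect_equal(sort(c(part$associated, part$non_associated)),
               which(types == "SIGLEC8"))

  ## no partner clusters: everything non-associated
  g2 <- make_graph(c("SIGLEC8", "SIGLEC8"), rbind(c(1, 2)))
  part2 <- partition_by_association(g2, "SIGLEC8", "CD4")
  expect_length(part2$associated, 0L)
  expect_length(part2$non_associated, 2L)

  ## no reference clusters: empty partition with warning
  expect_warning(p3 <- partition_by_association(g2, "CD19", "CD4"),
                 class = "spatcoloc_missing_type")
  expect_length(p3$associated, 0L)
})

test_that("association partition equals a brute-force adjacency scan", {
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(6:40, 1)
    x <- runif(n, 0, 50); y <- runif(n, 0, 50)
    types <- sample(c("SIGLEC8", "CD4", "CD19"), n, replace = TRUE)
    edges <- oracle_radius_edges(x, y, 10)
    g <- make_graph(types, edges)
    part <- partition_by_association(g, "SIGLEC8", "CD4")
    for (i in which(types == "SIGLEC8")) {
      has_partner <- FALSE
      if (nrow(edges)) {
        for (e in seq_len(nrow(edges))) {
          a <- edges[e, 1]; b <- edges[e, 2]
          if ((a == i && types[b] == "CD4") || (b == i && types[a] == "CD4")) {
            has_partner <- TRUE
          }
        }
      }
      expect_equal(i %in% part$associated, has_partner)
    }
  }
})

test_that("query counting uses a strict radius and matches brute force", {
  clusters <- structure(
    data.frame(cluster_id = 1L, gene = "SIGLEC8", slide_id = "S1",
               roi_id = "R1", x_um = 0, y_um = 0, size = 1L),
    class = c("cluster_set", "data.frame"))
  ## 9.99 um counted, exactly 10.0 um not (strict <)
  tab <- make_table("CD80", x = c(9.99, 10.0), y = c(0, 0))
  cnt <- count_query_neighbours(clusters, tab, "CD80", radius = 10)
  expect_equal(unname(cnt[1, "CD80"]), 1L)
  ## absent query gene: zero with a warning
  expect_warning(z <- count_query_neighbours(clusters, tab, "NFKB1"),
                 class = "spatcoloc_missing_type")
  expect_equal(unname(z[1, "NFKB1"]), 0L)

  set.seed(63)
  qx <- runif(100, -15, 15); qy <- runif(100, -15, 15)
  tab2 <- make_table("CD80", x = qx + 20, y = qy + 20)  # keep coords >= 0
  clusters$x_um <- 20; clusters$y_um <- 20
  for (r in c(5, 10, 12)) {
    cnt <- count_query_neighbours(clusters, tab2, "CD80", radius = r)
    expect_equal(unname(cnt[1, "CD80"]), sum(qx^2 + qy^2 < r^2))
  }
  ## monotone in radius
  c5 <- count_query_neighbours(clusters, tab2, "CD80", radius = 5)
  c10 <- count_query_neighbours(clusters, tab2, "CD80", radius = 10)
  expect_lte(c5[1, 1], c10[1, 1])
})

test_that("paired Wilcoxon matches enumeration on constructed cases", {
  ## five all-positive differences: two-sided p = 2/2^5
  r <- paired_wilcoxon(c(1.2, 0.8, 2.0, 1.1, 0.6))
  expect_equal(r$p, 0.0625)
  expect_equal(r$W, 15)
  expect_true(r$exact)

  ## W at the null median: capped at 1
  r2 <- paired_wilcoxon(c(1, -1))
  expect_equal(r2$p, 1)

  ## all-zero differences: undefined signal
  expect_warning(r3 <- paired_wilcoxon(c(0, 0, 0)),
                 class = "spatcoloc_undefined")
  expect_true(r3$undefined)
  expect_true(is.na(r3$p))

  ## zeros dropped, remaining pair count reported
  r4 <- paired_wilcoxon(c(0, 3, -1, 0, 2))
  expect_equal(r4$n_pairs, 3L)
  expect_equal(r4$n_zero, 2L)
})

test_that("exact Wilcoxon equals 2^n sign enumeration, ties included", {
  set.seed(64)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    ## small integer differences generate many ties and some zeros
    d <- sample(-3:3, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    r <- paired_wilcoxon(d)
    expect_equal(r$p, oracle_wilcoxon(d))
  }
  ## agreement with stats::wilcox.test where its exact path applies (no ties)
  d <- c(1.3, -0.4, 2.2, 0.9, -1.7, 3.1, 0.25)
  expect_equal(paired_wilcoxon(d)$p,
               stats::wilcox.test(d, exact = TRUE)$p.value)
})

test_that("neighbour expression separates partner-associated references", {
  ## world: SIGLEC8 reference cells; CD4 partners co-localized with half of
  ## them; CD80 emitted only by cells riding on the partners - so CD80
  ## should be enriched near associated references
  cfg <- run_config(marker_genes = c("SIGLEC8", "CD4"), rng_seed = 3)
  tabs <- lapply(1:6, function(i) {
    specs <- list(cell_type_spec("E", "SIGLEC8"),
                  cell_type_spec("T", "CD4", cell_density = 150),
                  cell_type_spec("Q", "CD80", cell_density = 150,
                                 transcripts_per_cell = 6))
    ias <- list(interaction_spec("E", "T", "colocalized", pairing_prob = 1,
                                 jitter_sigma = 2),
                interaction_spec("T", "Q", "colocalized", pairing_prob = 1,
                                 jitter_sigma = 1))
    sim <- simulate_slide(specs, ias, background_rate = 0,
                          seed = derive_seed(777, i))
    sim$table$roi_id <- paste0("R", i)
    sim$table
  })
  tab <- transcript_table(do.call(rbind, tabs))
  ne <- suppressWarnings(
    neighbour_expression(tab, reference = "SIGLEC8", partner = "CD4",
                         query_genes = "CD80", config = cfg))
  wide <- merge(
    ne$per_roi[ne$per_roi$group == "associated", c("roi_id", "mean_count")],
    ne$per_roi[ne$per_roi$group == "non_associated", c("roi_id", "mean_count")],
    by = "roi_id")
  expect_gte(nrow(wide), 5L)
  expect_true(all(wide$mean_count.x > wide$mean_count.y))
  expect_lt(ne$tests$p, 0.05)
})
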