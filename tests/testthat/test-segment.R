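test_that("label expansion reproduces the discrete Euclidean disk", {
  ## distance 0 is the identity
  m <- matrix(0L, 8, 8); m[3, 3] <- 5L
  r <- label_raster(m, 0.138)
  expect_identical(expand_labels(r, 0L)$pixels, m)

  ## isolated pixel, distance 10: labelled set = lattice points with
  ## dx^2 + dy^2 <= 100; the count is verified by brute force here
  disk_size <- sum(outer((-10):10, (-10):10,
                         function(a, b) a^2 + b^2) <= 100)
  big <- matrix(0L, 25, 25); big[13, 13] <- 1L
  ex <- expand_labels(label_raster(big, 0.138), 10L)
  expect_equal(sum(ex$pixels > 0L), disk_size)
  expect_equal(disk_size, 317L)
  ## and the labelled region is exactly the disk
  d2 <- (row(big) - 13)^2 + (col(big) - 13)^2
  expect_equal(ex$pixels > 0L, d2 <= 100, ignore_attr = TRUE)

  ## two labels 6 px apart: the equidistant midline goes to the lower id
  m2 <- matrix(0L, 13, 13); m2[7, 4] <- 2L; m2[7, 10] <- 1L
  ex2 <- expand_labels(label_raster(m2, 0.138), 10L)
  expect_identical(ex2$pixels, oracle_expand(m2, 10L))
  expect_equal(ex2$pixels[7, 7], 1L)   # tie resolved to label 1
  expect_equal(ex2$pixels[7, 6], 2L)   # strictly nearer to label 2
})

test_that("expansion equals the exhaustive oracle and is monotone", {
  set.seed(61)
  for (rep in 1:10) {
    m <- matrix(0L, 32, 32)
    n_seeds <- sample(1:6, 1)
    idx <- sample(32 * 32, n_seeds)
    m[idx] <- sample(1:9, n_seeds, replace = TRUE)
    r <- label_raster(m, 0.138)
    prev <- m
    for (d in c(0L, 3L, 10L)) {
      ex <- expand_labels(r, d)$pixels
      expect_identical(ex, oracle_expand(m, d))
      ## monotone: labelled pixels at smaller distance stay labelled
      expect_true(all(ex[prev > 0L] > 0L))
      ## original labels untouched
      expect_identical(ex[m > 0L], m[m > 0L])
      prev <- ex
    }
  }
})

## a 10x10 um playground at 1 um/px with four single-pixel nuclei
toy_segments <- function() {
  m <- matrix(0L, 10, 10)
  m[2, 2] <- 1L; m[2, 8] <- 2L; m[8, 2] <- 3L; m[8, 8] <- 7L
  label_raster(m, 1)
}

test_that("transcript assignment is exact and conserves molecules", {
  ras <- toy_segments()
  tab <- make_table(
    gene = c("CD4", "CD4", "SIGLEC8", "CD4", "CD19", "CD4", "CD4"),
    x = c(1.5, 1.2, 1.7, 7.5, 7.5, 5.0, 25),
    y = c(1.5, 1.8, 1.3, 1.5, 1.4, 5.0, 3))
  st <- assign_transcripts(tab, ras)
  ## molecule at the centre of the label-7 pixel lands in segment 7
  tab7 <- make_table("CD4", 7.5, 7.5)
  st7 <- assign_transcripts(tab7, ras)
  expect_equal(st7$counts["7", "CD4"], 1L)
  ## segment 1: 3 molecules of 2 genes
  expect_equal(unname(st$counts["1", "CD4"]), 2L)
  expect_equal(unname(st$counts["1", "SIGLEC8"]), 1L)
  expect_equal(st$segments$n_molecules[st$segments$segment_id == 1L], 3L)
  expect_equal(st$segments$n_genes[st$segments$segment_id == 1L], 2L)
  ## conservation: assigned + unassigned + out-of-bounds = table size
  assigned <- sum(st$counts)
  expect_equal(assigned + st$n_unassigned + st$n_out_of_bounds, nrow(tab))
  expect_equal(st$n_out_of_bounds, 1L)   # the x = 25 molecule
  expect_equal(st$n_unassigned, 1L)      # the background molecule at (5,5)
  ## catchless segment kept with zero counts for audit
  expect_true(3L %in% st$segments$segment_id)
  expect_equal(st$segments$n_molecules[st$segments$segment_id == 3L], 0L)
})

test_that("segment filtering applies the molecule AND gene thresholds", {
  ## counts (molecules, genes): (2,2) (3,2) (2,2->via one gene) (3,3) (10,3)
  ras <- label_raster(matrix(rep(1:5, each = 4), 2, 10), 1)
  place <- function(seg, genes) {
    ## put |genes| molecules inside segment `seg` (columns 2*seg-1, 2*seg)
    make_table(genes, x = rep(2 * seg - 1.5, length(genes)),
               y = rep(0.5, length(genes)))
  }
  tab <- transcript_table(rbind(
    place(1, c("A", "B")),                       # 2 molecules, 2 genes
    place(2, c("A", "A", "B")),                  # 3 molecules, 2 genes
    place(3, c("A", "B")),                       # 2 molecules, 2 genes
    place(4, c("A", "B", "C")),                  # 3 molecules, 3 genes
    place(5, rep(c("A", "B", "C"), c(6, 2, 2))) # 10 molecules, 3 genes
  ))
  st <- filter_segments(assign_transcripts(tab, ras))
  expect_equal(st$segments$retained[order(st$segments$segment_id)],
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  ## idempotent
  expect_identical(filter_segments(st), st)
  ## boundary case: exactly 3 molecules of 3 genes is retained
  st4 <- st$segments[st$segments$segment_id == 4L, ]
  expect_true(st4$retained)
  expect_equal(st4$n_molecules, 3L)
})

test_that("double-positive fractions follow the stated definition", {
  ras <- label_raster(matrix(rep(1:4, each = 6), 2, 12), 1)
  place <- function(seg, genes) {
    make_table(genes, x = rep(3 * seg - 1.5, length(genes)),
               y = rep(0.5, length(genes)))
  }
  ## four segments positive for A (all retained), two also positive for B
  tab <- transcript_table(rbind(
    place(1, c("A", "B", "C")), place(2, c("A", "B", "D")),
    place(3, c("A", "C", "D")), place(4, c("A", "C", "E"))))
  st <- filter_segments(assign_transcripts(tab, ras))
  expect_equal(double_positive_fraction(st, "A", "B"), 0.5)
  ## absent co-gene: fraction 0 (not an error)
  expect_equal(double_positive_fraction(st, "A", "ZZZ"), 0)
  ## no gene_a-positive segment: undefined, NA with classed warning, not 0
  expect_warning(f <- double_positive_fraction(st, "ZZZ", "A"),
                 class = "spatcoloc_undefined")
  expect_true(is.na(f))
  ## unfiltered tables are refused
  expect_error(double_positive_fraction(assign_transcripts(tab, ras), "A", "B"),
               class = "spatcoloc_input_error")
})

test_that("co-localized cells yield mostly double-positive segments", {
  ## every CD4 cell is placed on a randomly drawn SIGLEC8 centre (jitter
  ## 1 um <= nucleus radius), so each CD4 nucleus overlaps an eosinophil
  ## transcript cloud and its segment should catch both markers. The CD4
  ## side is the denominator because pairing draws partners with
  ## replacement: every CD4 cell has a partner, while some SIGLEC8 cells
  ## are never drawn.
  specs <- list(cell_type_spec("A", "SIGLEC8", cell_density = 1000),
                cell_type_spec("B", "CD4", cell_density = 1000))
  ia <- interaction_spec("A", "B", "colocalized", pairing_prob = 1,
                         jitter_sigma = 1)
  sim <- simulate_slide(specs, list(ia), field = c(150, 150),
                        background_rate = 0, seed = 13)
  ras <- simulate_label_raster(sim$truth, nucleus_radius = 5,
                               pixel_size = 0.552)
  ex <- expand_labels(ras, 3L)
  st <- filter_segments(assign_transcripts(sim$table, ex),
                        min_molecules = 3, min_genes = 1)
  frac <- double_positive_fraction(st, "CD4", "SIGLEC8")
  expect_gte(frac, 0.9)
})
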