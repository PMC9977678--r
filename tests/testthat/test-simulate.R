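test_that("simulated slides are deterministic and respect their specs", {
  specs <- list(cell_type_spec("A", "CD4"), cell_type_spec("B", "SIGLEC8"))
  s1 <- simulate_slide(specs, seed = 11)
  s2 <- simulate_slide(specs, seed = 11)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth$centres, s2$truth$centres)
  s3 <- simulate_slide(specs, seed = 12)
  expect_false(identical(s1$table, s3$table))

  ## every non-background molecule has exactly one parent cell
  expect_true(all(s1$table$parent_cell %in% c(0L, s1$truth$centres$cell_id)))
  ## coordinates clamped to the field
  expect_true(all(s1$table$x_um >= 0 & s1$table$x_um <= 300))
  expect_true(all(s1$table$y_um >= 0 & s1$table$y_um <= 300))

  ## zero expected cells: background only
  none <- simulate_slide(list(cell_type_spec("A", "CD4", cell_density = 0)),
                         seed = 4)
  expect_equal(nrow(none$truth$centres), 0L)
  expect_true(all(none$table$parent_cell == 0L))
})

test_that("molecule totals follow the compound Poisson emission law", {
  ## 100 expected cells x 20 transcripts, no background: mean total 2000.
  ## A single slide's total has sd ~ sqrt(lambda*(mu + mu^2)) ~ 205 (the
  ## cell count itself is Poisson), so the 4*sqrt(2000) band is asserted on
  ## the mean over 10 seeds (se ~ 65).
  spec <- cell_type_spec("A", "CD4", cell_density = 400,
                         transcripts_per_cell = 20)
  totals <- vapply(1:10, function(i) {
    nrow(simulate_slide(list(spec), field = c(500, 500), background_rate = 0,
                        seed = derive_seed(21, i))$table)
  }, 0)
  expect_lt(abs(mean(totals) - 2000), 4 * sqrt(2000))
})

test_that("colocalized centres land next to their partners", {
  specs <- list(cell_type_spec("A", "CD4"), cell_type_spec("B", "SIGLEC8"))
  ia <- interaction_spec("A", "B", "colocalized", pairing_prob = 1,
                         jitter_sigma = 1)
  sim <- simulate_slide(specs, list(ia), seed = 31)
  cen <- sim$truth$centres
  a <- cen[cen$type == "A", ]; b <- cen[cen$type == "B", ]
  nearest <- vapply(seq_len(nrow(b)), function(i) {
    sqrt(min((a$x_um - b$x_um[i])^2 + (a$y_um - b$y_um[i])^2))
  }, 0)
  expect_lt(median(nearest), 3)
})

test_that("hard-core avoidance keeps centre pairs separated or errors out", {
  specs <- list(cell_type_spec("A", "CD4", cell_density = 150, scatter_sigma = 3),
                cell_type_spec("B", "SIGLEC8", cell_density = 150, scatter_sigma = 3))
  ia <- interaction_spec("A", "B", "avoiding", hardcore_distance = 30)
  sim <- simulate_slide(specs, list(ia), field = c(600, 600), seed = 41)
  cen <- sim$truth$centres
  a <- cen[cen$type == "A", ]; b <- cen[cen$type == "B", ]
  cross_min <- min(vapply(seq_len(nrow(b)), function(i) {
    min((a$x_um - b$x_um[i])^2 + (a$y_um - b$y_um[i])^2)
  }, 0))
  expect_gte(sqrt(cross_min), 30)

  ## geometrically infeasible packing reports a clear error
  dense <- list(cell_type_spec("A", "CD4", cell_density = 2000),
                cell_type_spec("B", "SIGLEC8", cell_density = 2000))
  expect_error(
    simulate_slide(dense, list(interaction_spec("A", "B", "avoiding",
                                                hardcore_distance = 50)),
                   field = c(300, 300), seed = 1),
    "infeasible", class = "spatcoloc_sim_error")
})

test_that("label rasterization draws nearest-centre disks", {
  ## single cell: pixel-centre disk count matches the lattice oracle
  truth <- list(centres = data.frame(cell_id = 1L, type = "A", gene = "CD4",
                                     x_um = 10, y_um = 10),
                field = c(20, 20), seed = 1)
  ras <- simulate_label_raster(truth, nucleus_radius = 5, pixel_size = 1)
  centres_x <- (col(ras$pixels) - 0.5) * 1
  centres_y <- (row(ras$pixels) - 0.5) * 1
  inside <- (centres_x - 10)^2 + (centres_y - 10)^2 <= 25
  expect_equal(ras$pixels > 0, inside, ignore_attr = TRUE)
  expect_lt(abs(sum(ras$pixels > 0) - pi * 25), 8)  # ~pi r^2 up to boundary px

  ## no cells: all-zero raster
  empty <- list(centres = truth$centres[0, ], field = c(20, 20), seed = 1)
  expect_equal(sum(simulate_label_raster(empty, 5, 1)$pixels), 0L)

  ## overlapping disks resolve to the nearer centre (brute force per pixel)
  truth2 <- list(centres = data.frame(cell_id = 1:2, type = "A", gene = "CD4",
                                      x_um = c(9, 11), y_um = c(10, 10)),
                 field = c(20, 20), seed = 1)
  ras2 <- simulate_label_raster(truth2, nucleus_radius = 5, pixel_size = 1)
  expect_setequal(unique(as.vector(ras2$pixels)), c(0L, 1L, 2L))
  for (rr in seq_len(nrow(ras2$pixels))) {
    for (cc in seq_len(ncol(ras2$pixels))) {
      lab <- ras2$pixels[rr, cc]
      if (lab == 0L) next
      d2 <- ((cc - 0.5) - truth2$centres$x_um)^2 +
        ((rr - 0.5) - truth2$centres$y_um)^2
      expect_equal(lab, which.min(d2))
    }
  }
})

test_that("spot-set construction honours the co-expression fraction", {
  ## f = 0: no green spot within the classifier threshold of any red
  s0 <- simulate_spot_sets(n_green = 60, coexpr_fraction = 0, seed = 5)
  d0 <- oracle_nearest_red(s0$green$spots$x_um, s0$green$spots$y_um,
                           s0$red$spots$x_um, s0$red$spots$y_um)
  expect_true(all(d0 >= 4))
  expect_false(any(s0$truth$true_active))

  ## f = 1, n = 50: every spot true-active with a partner at pair_distance
  s1 <- simulate_spot_sets(n_green = 50, coexpr_fraction = 1, seed = 6)
  expect_true(all(s1$truth$true_active))
  d1 <- oracle_nearest_red(s1$green$spots$x_um, s1$green$spots$y_um,
                           s1$red$spots$x_um, s1$red$spots$y_um)
  expect_true(all(d1 < 4))

  ## determinism
  expect_identical(simulate_spot_sets(n_green = 40, seed = 9)$red,
                   simulate_spot_sets(n_green = 40, seed = 9)$red)

  ## luminal bias places true-active spots in the upper third
  sb <- simulate_spot_sets(n_green = 200, coexpr_fraction = 0.5,
                           luminal_bias = 1, seed = 7)
  expect_true(all(sb$truth$y_um[sb$truth$true_active] < 600 / 3))
})
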