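## Synthetic marked point patterns and spot sets with known ground truth.
## Cells are compact clusters of same-gene molecules over a uniform molecular
## background; cross-type structure (co-localization, independence, hard-core
## avoidance) is imposed on the cell centres, so every downstream stage can
## be validated against the generating truth.

#' Cell type specification for the simulator
#'
#' Defaults describe an abundant immune cell type in inflamed colonic mucosa
#' imaged at molecule resolution: 300 cells/mm^2, on average 12 detected
#' marker transcripts per cell, scattered isotropically with a 1.0 um
#' Gaussian sd around the cell centre - transcripts confined to a compact
#' cell body (3 sigma ~ a lymphocyte-sized soma radius), so that one cell
#' yields one transcript cluster under the 5 um dendrogram cut. Larger
#' scatter (from about 1.5 um upward) makes cells shed satellite clusters,
#' which violates the one-cluster-per-cell premise of the segmentation-free
#' analysis; see the methods vignette.
#'
#' @param name cell type name.
#' @param marker_gene marker gene symbol whose molecules this type emits
#'   (defaults to `name`).
#' @param cell_density expected cells per mm^2 (homogeneous Poisson).
#' @param transcripts_per_cell Poisson mean of detected molecules per cell.
#' @param scatter_sigma isotropic Gaussian sd, in um, of molecule positions
#'   around the cell centre.
#' @return an object of class `cell_type_spec`.
#' @export
cell_type_spec <- function(name, marker_gene = name, cell_density = 300,
                           transcripts_per_cell = 12, scatter_sigma = 1.0) {
  stopifnot(is.character(name), nzchar(name),
            is.character(marker_gene), nzchar(marker_gene))
  if (!is_number(cell_density, min = 0)) {
    sc_stop("cell_density must be >= 0", "spatcoloc_config_error")
  }
  if (!is_number(transcripts_per_cell, min = 0)) {
    sc_stop("transcripts_per_cell must be >= 0", "spatcoloc_config_error")
  }
  if (!is_number(scatter_sigma) || scatter_sigma <= 0) {
    sc_stop("scatter_sigma must be > 0", "spatcoloc_config_error")
  }
  structure(list(name = name, marker_gene = marker_gene,
                 cell_density = cell_density,
                 transcripts_per_cell = transcripts_per_cell,
                 scatter_sigma = scatter_sigma),
            class = "cell_type_spec")
}

#' Cross-type interaction specification
#'
#' Controls the joint placement of two cell types' centres:
#' * `colocalized`: a fraction `pairing_prob` of type-b centres is replaced
#'   by a randomly chosen type-a centre plus isotropic Gaussian jitter
#'   (`jitter_sigma`), mimicking physical cell-cell contact;
#' * `independent`: both types are independent Poisson processes (the null
#'   the permutation test should not reject);
#' * `avoiding`: type-b centre proposals closer than `hardcore_distance` to
#'   any type-a centre are rejected and redrawn (hard-core thinning),
#'   mimicking spatial exclusion.
#'
#' @param type_a,type_b names of the two [cell_type_spec()]s involved.
#' @param mode one of `"colocalized"`, `"independent"`, `"avoiding"`.
#' @param pairing_prob fraction of type-b cells paired to a type-a centre
#'   (colocalized mode).
#' @param jitter_sigma Gaussian sd, um, of the paired-centre offset
#'   (colocalized mode).
#' @param hardcore_distance minimum allowed a-b centre separation, um
#'   (avoiding mode).
#' @return an object of class `interaction_spec`.
#' @export
interaction_spec <- function(type_a, type_b,
                             mode = c("colocalized", "independent", "avoiding"),
                             pairing_prob = 1, jitter_sigma = 2,
                             hardcore_distance = 30) {
  mode <- match.arg(mode)
  if (!is_number(pairing_prob) || pairing_prob < 0 || pairing_prob > 1) {
    sc_stop("pairing_prob must lie in [0, 1]", "spatcoloc_config_error")
  }
  if (mode == "avoiding" && (!is_number(hardcore_distance) || hardcore_distance <= 0)) {
    sc_stop("hardcore_distance must be > 0 in avoiding mode",
            "spatcoloc_config_error")
  }
  if (mode == "colocalized" && (!is_number(jitter_sigma) || jitter_sigma <= 0)) {
    sc_stop("jitter_sigma must be > 0 in colocalized mode",
            "spatcoloc_config_error")
  }
  structure(list(type_a = type_a, type_b = type_b, mode = mode,
                 pairing_prob = pairing_prob, jitter_sigma = jitter_sigma,
                 hardcore_distance = hardcore_distance),
            class = "interaction_spec")
}

#' Simulate one slide of molecule-resolved transcripts
#'
#' Cell centres are drawn per type as a homogeneous Poisson process at the
#' specified density; interaction specs then modify type-b centres
#' (replacement by jittered type-a centres, or hard-core thinning against
#' type-a). Each cell emits Poisson(`transcripts_per_cell`) molecules at its
#' centre plus Gaussian(`scatter_sigma`) offsets, clamped to the field.
#' Background molecules arrive uniformly at `background_rate` per mm^2 with
#' a marker gene drawn uniformly at random. Fully deterministic given
#' `seed`.
#'
#' @param specs list of [cell_type_spec()]s.
#' @param interactions list of [interaction_spec()]s (at most one per
#'   ordered type pair; each type may appear as `type_b` in at most one
#'   spec).
#' @param field numeric length-2, field width and height in um.
#' @param background_rate uniform background molecules per mm^2.
#' @param seed integer seed.
#' @param slide_id,roi_id identifiers stamped on every molecule.
#' @return a list with elements `table` (a [transcript_table()] with a
#'   `parent_cell` column: the emitting cell id, 0 for background) and
#'   `truth` (list: `centres` data frame with `cell_id`, `type`, `gene`,
#'   `x_um`, `y_um`; `field`; `seed`).
#' @export
simulate_slide <- function(specs, interactions = list(),
                           field = c(300, 300), background_rate = 100,
                           seed = 1L, slide_id = "S1", roi_id = "R1") {
  if (inherits(specs, "cell_type_spec")) specs <- list(specs)
  if (inherits(interactions, "interaction_spec")) interactions <- list(interactions)
  stopifnot(length(field) == 2L, all(field > 0))
  type_names <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(type_names)) {
    sc_stop("cell type names must be unique", "spatcoloc_config_error")
  }
  area_mm2 <- prod(field) / 1e6
  inter_by_b <- list()
  for (ia in interactions) {
    if (!all(c(ia$type_a, ia$type_b) %in% type_names)) {
      sc_stop("interaction references an unknown cell type", "spatcoloc_config_error")
    }
    if (!is.null(inter_by_b[[ia$type_b]])) {
      sc_stop(sprintf("type '%s' appears as type_b in more than one interaction",
                      ia$type_b), "spatcoloc_config_error")
    }
    inter_by_b[[ia$type_b]] <- ia
  }

  with_seed(seed, {
    ## centres, independent Poisson per type first
    centres <- lapply(specs, function(sp) {
      n <- rpois(1L, sp$cell_density * area_mm2)
      data.frame(type = rep(sp$name, n), gene = rep(sp$marker_gene, n),
                 x_um = runif(n, 0, field[1]), y_um = runif(n, 0, field[2]),
                 stringsAsFactors = FALSE)
    })
    names(centres) <- type_names

    ## impose interactions on type_b centres
    for (tb in names(inter_by_b)) {
      ia <- inter_by_b[[tb]]
      if (ia$mode == "independent") next
      a <- centres[[ia$type_a]]
      b <- centres[[tb]]
      if (ia$mode == "colocalized") {
        if (nrow(a) > 0 && nrow(b) > 0) {
          paired <- runif(nrow(b)) < ia$pairing_prob
          idx <- sample.int(nrow(a), sum(paired), replace = TRUE)
          b$x_um[paired] <- a$x_um[idx] + rnorm(sum(paired), 0, ia$jitter_sigma)
          b$y_um[paired] <- a$y_um[idx] + rnorm(sum(paired), 0, ia$jitter_sigma)
          b$x_um <- pmin(pmax(b$x_um, 0), field[1])
          b$y_um <- pmin(pmax(b$y_um, 0), field[2])
        }
      } else {  # avoiding: redraw b proposals inside the hard core
        if (nrow(a) > 0 && nrow(b) > 0) {
          h2 <- ia$hardcore_distance^2
          rejected <- 0L
          for (i in seq_len(nrow(b))) {
        repeat {
            d2 <- (a$x_um - b$x_um[i])^2 + (a$y_um - b$y_um[i])^2
            if (min(d2) >= h2) break
            rejected <- rejected + 1L
            if (rejected > 10000L) {
              sc_stop(paste0("hard-core thinning infeasible (>10000 rejected ",
                             "proposals); lower the cell density or the ",
                             "hardcore_distance"), "spatcoloc_sim_error")
            }
            b$x_um[i] <- runif(1, 0, field[1])
            b$y_um[i] <- runif(1, 0, field[2])
          }
          }
        }
      }
      centres[[tb]] <- b
    }

    centres <- do.call(rbind, c(centres, list(make.row.names = FALSE)))
    if (is.null(centres)) {
      centres <- data.frame(type = character(), gene = character(),
                            x_um = numeric(), y_um = numeric())
    }
    centres <- cbind(cell_id = seq_len(nrow(centres)), centres)

    ## molecules: per-cell Poisson emission with Gaussian scatter
    sigma_of <- stats::setNames(
      vapply(specs, `[[`, 0, "scatter_sigma"),
      type_names)
    tpc_of <- stats::setNames(
      vapply(specs, `[[`, 0, "transcripts_per_cell"),
      type_names)
    n_mol <- if (nrow(centres)) rpois(nrow(centres), tpc_of[centres$type]) else integer(0)
    parent <- rep(centres$cell_id, n_mol)
    gene <- rep(centres$gene, n_mol)
    sig <- rep(sigma_of[centres$type], n_mol)
    x <- rep(centres$x_um, n_mol) + rnorm(length(parent), 0, sig)
    y <- rep(centres$y_um, n_mol) + rnorm(length(parent), 0, sig)

    ## uniform background with a random marker gene
    marker_pool <- unique(vapply(specs, `[[`, "", "marker_gene"))
    n_bg <- rpois(1L, background_rate * area_mm2)
    if (n_bg > 0 && length(marker_pool) > 0) {
      x <- c(x, runif(n_bg, 0, field[1]))
      y <- c(y, runif(n_bg, 0, field[2]))
      gene <- c(gene, sample(marker_pool, n_bg, replace = TRUE))
      parent <- c(parent, rep(0L, n_bg))
    }

    tab <- transcript_table(data.frame(
      slide_id = rep(slide_id, length(x)), roi_id = rep(roi_id, length(x)),
      gene = gene,
      x_um = pmin(pmax(x, 0), field[1]),
      y_um = pmin(pmax(y, 0), field[2]),
      parent_cell = parent, stringsAsFactors = FALSE))

    list(table = tab,
         truth = list(centres = centres, field = field, seed = seed))
  })
}

#' Simulate several independent slides
#'
#' Per-slide seeds are derived from the master seed with [derive_seed()], so
#' slide i is reproducible in isolation.
#'
#' @inheritParams simulate_slide
#' @param n_slides number of slides.
#' @param seed master seed.
#' @return a list of [simulate_slide()] results; slide ids are `"S1"`,
#'   `"S2"`, ...
#' @export
simulate_slides <- function(n_slides, specs, interactions = list(),
                            field = c(300, 300), background_rate = 100,
                            seed = 1L) {
  lapply(seq_len(n_slides), function(i) {
    simulate_slide(specs, interactions, field, background_rate,
                   seed = derive_seed(seed, i), slide_id = paste0("S", i))
  })
}

#' Rasterize simulated nuclei into a label image
#'
#' Draws one disk of `nucleus_radius` per cell centre with integer label
#' equal to the cell id; a pixel belongs to a disk when its centre lies
#' within the radius, and pixels inside several disks take the nearer
#' centre's label (ties to the lower cell id).
#'
#' @param truth the `truth` element of a [simulate_slide()] result.
#' @param nucleus_radius nucleus disk radius in um, > 0.
#' @param pixel_size um per pixel edge.
#' @return a [label_raster()].
#' @export
simulate_label_raster <- function(truth, nucleus_radius, pixel_size = 0.138) {
  if (!is_number(nucleus_radius) || nucleus_radius <= 0) {
    sc_stop("nucleus_radius must be > 0", "spatcoloc_config_error")
  }
  nr <- ceiling(truth$field[2] / pixel_size)
  nc <- ceiling(truth$field[1] / pixel_size)
  px <- matrix(0L, nr, nc)
  if (nrow(truth$centres) == 0L) return(label_raster(px, pixel_size))
  best_d2 <- matrix(Inf, nr, nc)
  r2 <- nucleus_radius^2
  for (i in seq_len(nrow(truth$centres))) {
    cx <- truth$centres$x_um[i]; cy <- truth$centres$y_um[i]
    id <- truth$centres$cell_id[i]
    cols <- max(1L, floor((cx - nucleus_radius) / pixel_size) + 1L):
            min(nc, floor((cx + nucleus_radius) / pixel_size) + 1L)
    rows <- max(1L, floor((cy - nucleus_radius) / pixel_size) + 1L):
            min(nr, floor((cy + nucleus_radius) / pixel_size) + 1L)
    xc <- (cols - 0.5) * pixel_size
    yc <- (rows - 0.5) * pixel_size
    d2 <- outer(yc - cy, xc - cx, function(a, b) a^2 + b^2)
    upd <- d2 <= r2 & (d2 < best_d2[rows, cols] |
                         (d2 == best_d2[rows, cols] & id < px[rows, cols]))
    if (any(upd)) {
      sub_px <- px[rows, cols]
      sub_d2 <- best_d2[rows, cols]
      sub_px[upd] <- id
      sub_d2[upd] <- d2[upd]
      px[rows, cols] <- sub_px
      best_d2[rows, cols] <- sub_d2
    }
  }
  label_raster(px, pixel_size)
}

#' Simulate paired dual-channel spot sets
#'
#' Emulates the assumptions of the dual-channel co-expression classifier:
#' green spots (the cell population) are placed with a hard minimum mutual
#' separation of `spot_threshold + pair_distance`, an exact count
#' `round(coexpr_fraction * n_green)` of them ("true active") receives a red
#' partner spot at exactly `pair_distance`, and decoy red spots are rejected
#' until at least `spot_threshold` from every green spot. Under this
#' construction nearest-red-distance classification at `spot_threshold`
#' recovers the true labels without error and the active/basal ratio equals
#' f/(1-f).
#'
#' The crypt axis runs along y: the luminal third is `y < field_height/3`,
#' the basal third `y > 2*field_height/3`. `luminal_bias` is the probability
#' that a true-active green spot is placed in the luminal third (its y drawn
#' uniformly there) instead of uniformly over the field.
#'
#' @param n_green number of green spots.
#' @param coexpr_fraction fraction f in `[0, 1]` of green spots with a red
#'   partner.
#' @param pair_distance green-red partner distance in um; must be strictly
#'   below `spot_threshold`.
#' @param decoy_red_rate unpaired red spots per mm^2.
#' @param field field width and height in um.
#' @param luminal_bias probability in `[0, 1]` that a true-active spot lies
#'   in the luminal third.
#' @param spot_threshold the classifier threshold the construction must
#'   respect, um.
#' @param core_id core identifier.
#' @param seed integer seed.
#' @return a list: `green` and `red` [spot_set()]s and `truth` (data frame
#'   with one row per green spot: `spot`, `true_active`, `x_um`, `y_um`).
#' @export
simulate_spot_sets <- function(n_green = 500L, coexpr_fraction = 0.5,
                               pair_distance = 2, decoy_red_rate = 50,
                               field = c(600, 600), luminal_bias = 0,
                               spot_threshold = 4, core_id = "C1", seed = 1L) {
  stopifnot(is_count(n_green), length(field) == 2L, all(field > 0))
  if (!is_number(coexpr_fraction) || coexpr_fraction < 0 || coexpr_fraction > 1) {
    sc_stop("coexpr_fraction must lie in [0, 1]", "spatcoloc_config_error")
  }
  if (!is_number(pair_distance) || pair_distance <= 0 ||
      pair_distance >= spot_threshold) {
    sc_stop("pair_distance must satisfy 0 < pair_distance < spot_threshold",
            "spatcoloc_config_error")
  }
  min_sep <- spot_threshold + pair_distance
  with_seed(seed, {
    ## green spots with hard-core mutual separation (dart throwing)
    gx <- numeric(0); gy <- numeric(0)
    attempts <- 0L
    n_active <- as.integer(round(coexpr_fraction * n_green))
    is_active <- c(rep(TRUE, n_active), rep(FALSE, n_green - n_active))
    is_active <- sample(is_active)
    while (length(gx) < n_green) {
      i <- length(gx) + 1L
      x <- runif(1, 0, field[1])
      y <- if (is_active[i] && runif(1) < luminal_bias) {
        runif(1, 0, field[2] / 3)
      } else {
        runif(1, 0, field[2])
      }
      if (length(gx) == 0L || min((gx - x)^2 + (gy - y)^2) >= min_sep^2) {
        gx <- c(gx, x); gy <- c(gy, y)
      } else {
        attempts <- attempts + 1L
        if (attempts > 100000L) {
          sc_stop("green spot placement infeasible: too many hard-core rejections; enlarge the field or reduce n_green",
                  "spatcoloc_sim_error")
        }
      }
    }

    ## red partners at exactly pair_distance, kept inside the field
    rx <- numeric(0); ry <- numeric(0)
    for (i in which(is_active)) {
      repeat {
        th <- runif(1, 0, 2 * pi)
        x <- gx[i] + pair_distance * cos(th)
        y <- gy[i] + pair_distance * sin(th)
        if (x >= 0 && x <= field[1] && y >= 0 && y <= field[2]) break
      }
      rx <- c(rx, x); ry <- c(ry, y)
    }

    ## decoy reds rejected inside spot_threshold of any green
    n_decoy <- rpois(1L, decoy_red_rate * prod(field) / 1e6)
    placed <- 0L; rejections <- 0L
    while (placed < n_decoy) {
      x <- runif(1, 0, field[1]); y <- runif(1, 0, field[2])
      if (n_green == 0L || min((gx - x)^2 + (gy - y)^2) >= spot_threshold^2) {
        rx <- c(rx, x); ry <- c(ry, y); placed <- placed + 1L
      } else {
        rejections <- rejections + 1L
        if (rejections > 100000L) {
          sc_stop("decoy red placement infeasible: too many rejections",
                  "spatcoloc_sim_error")
        }
      }
    }

    green <- spot_set("green", data.frame(core_id = rep(core_id, n_green),
                                          x_um = gx, y_um = gy))
    red <- spot_set("red", data.frame(core_id = rep(core_id, length(rx)),
                                      x_um = rx, y_um = ry))
    truth <- data.frame(spot = seq_len(n_green), true_active = is_active,
                        x_um = gx, y_um = gy)
    list(green = green, red = red, truth = truth, field = field)
  })
}
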