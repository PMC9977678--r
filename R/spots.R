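## Dual-channel spot co-expression: a green-channel spot (the cell marker,
## e.g. MBP+ eosinophils) is "active" when its nearest red-channel spot
## (the activation marker, e.g. PD-L1) lies strictly closer than the
## co-expression threshold (default 4 um); otherwise it is "basal". The
## per-core active/basal count ratio and its luminal-vs-basal crypt-third
## comparison follow.

#' Classify green spots by nearest red-spot distance
#'
#' Distances are Euclidean, in 2D, or in 3D when both sets carry a z
#' coordinate (mixed dimensionality is an error). Green spots in a core
#' with no red spot get distance `Inf` and label `"basal"`.
#'
#' @param green,red [spot_set()]s from the same core collection.
#' @param threshold co-expression distance in um; strictly-closer-than
#'   comparison (a spot at exactly `threshold` is basal).
#' @return an object of class `spot_classification`: list with `spots`
#'   (data frame: `core_id`, coordinates, `nearest_red_um`, `label`) and
#'   `per_core` (data frame: `core_id`, `n_active`, `n_basal`, `ratio`,
#'   `ratio_defined`; `ratio` is `NA` when `n_basal` is 0).
#' @export
classify_spots <- function(green, red, threshold = 4) {
  stopifnot(inherits(green, "spot_set"), inherits(red, "spot_set"))
  if (!is_number(threshold) || threshold <= 0) {
    sc_stop("threshold must be > 0", "spatcoloc_config_error")
  }
  gz <- "z_um" %in% names(green$spots)
  rz <- "z_um" %in% names(red$spots)
  if (gz != rz && nrow(green$spots) > 0 && nrow(red$spots) > 0) {
    sc_stop("mixed 2D/3D spot sets: z must be present in both channels or neither",
            "spatcoloc_input_error")
  }
  use_z <- gz && rz
  g <- green$spots
  g$nearest_red_um <- rep(Inf, nrow(g))
  for (core in unique(g$core_id)) {
    gi <- which(g$core_id == core)
    ri <- which(red$spots$core_id == core)
    if (!length(ri)) next
    for (i in gi) {
      d2 <- (red$spots$x_um[ri] - g$x_um[i])^2 +
        (red$spots$y_um[ri] - g$y_um[i])^2
      if (use_z) d2 <- d2 + (red$spots$z_um[ri] - g$z_um[i])^2
      g$nearest_red_um[i] <- sqrt(min(d2))
    }
  }
  g$label <- ifelse(g$nearest_red_um < threshold, "active", "basal")
  per_core <- do.call(rbind, lapply(unique(g$core_id), function(core) {
    sub <- g[g$core_id == core, ]
    n_a <- sum(sub$label == "active")
    n_b <- sum(sub$label == "basal")
    data.frame(core_id = core, n_active = n_a, n_basal = n_b,
               ratio = if (n_b > 0) n_a / n_b else NA_real_,
               ratio_defined = n_b > 0, stringsAsFactors = FALSE)
  }))
  if (is.null(per_core)) {
    per_core <- data.frame(core_id = character(), n_active = integer(),
                           n_basal = integer(), ratio = numeric(),
                           ratio_defined = logical())
  }
  structure(list(spots = g, per_core = per_core, threshold = threshold,
                 dimensions = if (use_z) 3L else 2L),
            class = "spot_classification")
}

#' @export
print.spot_classification <- function(x, ...) {
  cat(sprintf(paste0("spot_classification (%dD, threshold %g um): %d green ",
                     "spot(s) in %d core(s), %d active / %d basal\n"),
              x$dimensions, x$threshold, nrow(x$spots), nrow(x$per_core),
              sum(x$spots$label == "active"), sum(x$spots$label == "basal")))
  invisible(x)
}

#' Active-to-basal ratio per core
#'
#' The number of active divided by the number of basal green spots in each
#' core. A core with zero basal spots has an undefined ratio: it is returned
#' as `NA` with `ratio_defined = FALSE` and a classed warning, never coerced
#' to a number. A core with no green spots at all is an error.
#'
#' @param classification a [classify_spots()] result.
#' @return data frame `core_id`, `n_active`, `n_basal`, `ratio`,
#'   `ratio_defined`.
#' @export
active_basal_ratio <- function(classification) {
  stopifnot(inherits(classification, "spot_classification"))
  pc <- classification$per_core
  if (nrow(pc) == 0L || any(pc$n_active + pc$n_basal == 0L)) {
    sc_stop("no green spots in at least one core; nothing to quantify",
            "spatcoloc_input_error")
  }
  if (any(!pc$ratio_defined)) {
    sc_warn(sprintf("%d core(s) have zero basal spots; their ratio is undefined (NA)",
                    sum(!pc$ratio_defined)), "spatcoloc_undefined")
  }
  pc
}

#' Read a crypt-thirds annotation table
#'
#' Delimited text with header `core_id, third, y_min_um, y_max_um`; `third`
#' is `"luminal"` or `"basal"`. The two ranges of one core must be disjoint.
#'
#' @param path path to the file.
#' @return data frame of class `thirds_annotation`.
#' @export
read_thirds_annotation <- function(path) {
  df <- read_delim_checked(path,
                           required = c("core_id", "third", "y_min_um", "y_max_um"),
                           numeric_cols = c("y_min_um", "y_max_um"))
  thirds_annotation(df)
}

#' Construct a crypt-thirds annotation
#'
#' Axis-range stand-in for manually drawn crypt-third regions: per core, a
#' y-range for the luminal (upper) third and one for the basal (lower)
#' third. A spot belongs to a third when `y_min_um <= y < y_max_um`.
#'
#' @param df data frame with `core_id`, `third` (`"luminal"`/`"basal"`),
#'   `y_min_um`, `y_max_um`.
#' @return the validated data frame with class `thirds_annotation`.
#' @export
thirds_annotation <- function(df) {
  req <- c("core_id", "third", "y_min_um", "y_max_um")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    sc_stop(sprintf("thirds annotation missing column(s): %s",
                    paste(miss, collapse = ", ")), "spatcoloc_format_error")
  }
  if (!all(df$third %in% c("luminal", "basal"))) {
    sc_stop("thirds annotation 'third' must be 'luminal' or 'basal'",
            "spatcoloc_format_error")
  }
  if (any(df$y_min_um >= df$y_max_um)) {
    sc_stop("thirds annotation needs y_min_um < y_max_um", "spatcoloc_format_error")
  }
  for (core in unique(df$core_id)) {
    sub <- df[df$core_id == core, ]
    if (nrow(sub) == 2L) {
      lo <- sub[which.min(sub$y_min_um), ]
      hi <- sub[which.max(sub$y_min_um), ]
      if (lo$y_max_um > hi$y_min_um) {
        sc_stop(sprintf("thirds of core '%s' overlap; ranges must be disjoint",
                        core), "spatcoloc_format_error")
      }
    }
  }
  class(df) <- unique(c("thirds_annotation", class(df)))
  df
}

#' Compare active-to-basal ratios between luminal and basal crypt thirds
#'
#' Spots are assigned to a third by the y-range point-in-region test, the
#' active/basal ratio is computed within each third, and the per-core
#' (luminal - basal) ratio differences enter a two-tailed paired Student's
#' t-test (exact t distribution, n - 1 degrees of freedom). Cores missing a
#' third, lacking green spots in a third, or with an undefined ratio in a
#' third are excluded from the pairing with a warning. Zero variance of the
#' differences with nonzero mean is flagged as degenerate rather than
#' producing an infinite t.
#'
#' @param classification a [classify_spots()] result.
#' @param annotation a [thirds_annotation()].
#' @return an object of class `thirds_comparison`: list with `per_core`
#'   (data frame: `core_id`, `luminal_ratio`, `basal_ratio`, `difference`),
#'   `t`, `p`, `df`, `n_cores`, `degenerate`.
#' @export
thirds_comparison <- function(classification, annotation) {
  stopifnot(inherits(classification, "spot_classification"),
            inherits(annotation, "thirds_annotation"))
  sp <- classification$spots
  rows <- list()
  dropped <- 0L
  for (core in unique(sp$core_id)) {
    ann <- annotation[annotation$core_id == core, ]
    if (!all(c("luminal", "basal") %in% ann$third)) {
      dropped <- dropped + 1L
      next
    }
    ratio_in <- function(third) {
      rng <- ann[ann$third == third, ]
      sub <- sp[sp$core_id == core &
                  sp$y_um >= rng$y_min_um & sp$y_um < rng$y_max_um, ]
      if (nrow(sub) == 0L) return(NA_real_)
      n_b <- sum(sub$label == "basal")
      if (n_b == 0L) return(NA_real_)
      sum(sub$label == "active") / n_b
    }
    lum <- ratio_in("luminal"); bas <- ratio_in("basal")
    if (is.na(lum) || is.na(bas)) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      core_id = core, luminal_ratio = lum, basal_ratio = bas,
      difference = lum - bas, stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    sc_warn(sprintf("%d core(s) excluded from the thirds pairing (missing third, no green spots, or undefined ratio)",
                    dropped), "spatcoloc_excluded_cores")
  }
  per_core <- if (length(rows)) do.call(rbind, rows) else
    data.frame(core_id = character(), luminal_ratio = numeric(),
               basal_ratio = numeric(), difference = numeric())
  n <- nrow(per_core)
  if (n < 2L) {
    return(structure(list(per_core = per_core, t = NA_real_, p = NA_real_,
                          df = NA_integer_, n_cores = n, degenerate = n < 2L),
                     class = "thirds_comparison"))
  }
  d <- per_core$difference
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      ## identical patterns in both thirds: no effect, p = 1 by convention
      return(structure(list(per_core = per_core, t = 0, p = 1,
                            df = n - 1L, n_cores = n, degenerate = FALSE),
                       class = "thirds_comparison"))
    }
    sc_warn("zero variance of nonzero paired differences; t statistic undefined",
            "spatcoloc_undefined")
    return(structure(list(per_core = per_core, t = NA_real_, p = NA_real_,
                          df = n - 1L, n_cores = n, degenerate = TRUE),
                     class = "thirds_comparison"))
  }
  tt <- stats::t.test(per_core$luminal_ratio, per_core$basal_ratio,
                      paired = TRUE)
  structure(list(per_core = per_core, t = unname(tt$statistic),
                 p = tt$p.value, df = unname(tt$parameter), n_cores = n,
                 degenerate = FALSE),
            class = "thirds_comparison")
}

#' @export
print.thirds_comparison <- function(x, ...) {
  cat(sprintf("thirds_comparison: %d core(s); paired t = %s, p = %s\n",
              x$n_cores,
              if (is.na(x$t)) "NA" else sprintf("%.3f", x$t),
              if (is.na(x$p)) "NA" else format.pval(x$p)))
  invisible(x)
}
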