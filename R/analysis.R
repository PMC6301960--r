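#' Count stratum-corneum and living-layer cells
#'
#' Partitions a snapshot into cornified cells (state `CORNEOCYTE`, the
#' stratum corneum) and living keratinocytes (stem, proliferative, spinous,
#' granular). The two counts always sum to the total cell number.
#'
#' @param snapshot a `sim_state` (or a bare cell data.frame).
#' @return named integer vector `c(n_corneocytes, n_living)`.
#' @export
count_layers <- function(snapshot) {
  cells <- if (inherits(snapshot, "sim_state")) snapshot$cells else snapshot
  n_c <- sum(cells$state == "CORNEOCYTE")
  c(n_corneocytes = as.integer(n_c),
    n_living = as.integer(nrow(cells) - n_c))
}

# cells whose ellipsoid intersects the section slab [y0, y0 + slab_um],
# with periodic wrapping in y
cells_in_slab <- function(cells, y0, slab_um, Ly) {
  yc <- y0 + slab_um / 2
  dy <- abs(wrap_diff(cells$y - yc, Ly))
  cells[dy <= slab_um / 2 + cells$a, , drop = FALSE]
}

# rasterize one snapshot slab onto an (x, z) pixel grid;
# returns an integer matrix: 0 empty, 1 living, 2 corneocyte, -1 masked
rasterize_section <- function(snapshot, spec, y0, slab_um, pixel_um) {
  cells <- if (inherits(snapshot, "sim_state")) snapshot$cells else snapshot
  Lx <- spec$domain_x_um
  sel <- cells_in_slab(cells, y0, slab_um, spec$domain_y_um)
  nx <- max(1L, round(Lx / pixel_um))
  xg <- (seq_len(nx) - 0.5) * pixel_um
  ymid <- y0 + slab_um / 2
  hprof <- membrane_height(spec, xg, rep(ymid, nx))
  zlo <- min(0, hprof, if (nrow(sel)) sel$z - sel$c else 0) - 2 * pixel_um
  zhi <- max(hprof, if (nrow(sel)) sel$z + sel$c else 1) + 2 * pixel_um
  nz <- max(1L, ceiling((zhi - zlo) / pixel_um))
  zg <- zlo + (seq_len(nz) - 0.5) * pixel_um
  img <- matrix(0L, nrow = nz, ncol = nx)
  paint <- function(rows, code) {
    for (k in rows) {
      a <- sel$a[k]; cc <- sel$c[k]
      # lateral pixel range (periodic in x)
      dx <- wrap_diff(xg - sel$x[k], Lx)
      cols <- which(abs(dx) <= a)
      if (!length(cols)) next
      for (jcol in cols) {
        half <- cc * sqrt(max(0, 1 - (dx[jcol] / a)^2))
        rows_z <- which(abs(zg - sel$z[k]) <= half)
        if (length(rows_z)) img[rows_z, jcol] <<- code
      }
    }
  }
  # living first; corneocytes painted last so they win ties
  paint(which(sel$state != "CORNEOCYTE"), 1L)
  paint(which(sel$state == "CORNEOCYTE"), 2L)
  # substrate exclusion: mask every pixel at or below the membrane profile
  for (jcol in seq_len(nx)) img[zg <= hprof[jcol], jcol] <- -1L
  list(img = img, x = xg, z = zg, membrane = hprof, pixel_um = pixel_um)
}

#' Cross-section areas per 100 um of section
#'
#' Rasterizes every cell intersecting the slab `y in [y0, y0 + slab_um]`
#' onto an (x, z) pixel grid (each cell drawn as its (a, c) ellipse
#' cross-section), masks out all pixels below the membrane/fiber profile
#' (mirroring the removal of fiber cross-sections from histology images),
#' and reports corneocyte-claimed and living-claimed areas normalised to
#' 100 um of section length. Where a corneocyte and a living cell overlap,
#' the pixel counts as stratum corneum.
#'
#' @param snapshot a `sim_state`.
#' @param spec a `membrane_spec`.
#' @param y0 slab start (um); the slab must lie inside the domain.
#' @param slab_um slab thickness (um), default 10 (a histology-like section).
#' @param pixel_um raster resolution (um), at most 1.
#' @return named numeric vector `c(sc_area_per100um, living_area_per100um)`
#'   in um^2 per 100 um of section.
#' @export
section_areas <- function(snapshot, spec, y0 = 0, slab_um = 10,
                          pixel_um = 0.25) {
  if (slab_um <= 0) stop("slab_um must be > 0")
  if (pixel_um > 1) stop("pixel_um must be <= 1")
  if (y0 < 0 || y0 + slab_um > spec$domain_y_um)
    stop("section slab lies outside the domain")
  ras <- rasterize_section(snapshot, spec, y0, slab_um, pixel_um)
  px2 <- pixel_um^2
  norm <- 100 / spec$domain_x_um
  c(sc_area_per100um = sum(ras$img == 2L) * px2 * norm,
    living_area_per100um = sum(ras$img == 1L) * px2 * norm)
}

#' Lateral thickness profiles and interface roughness
#'
#' Splits the domain into `bins x bins` lateral tiles. In each tile the
#' living thickness is the highest living-cell top minus the membrane height
#' at the tile center, and the stratum-corneum thickness is the highest
#' corneocyte top minus the highest living top (floored at zero). The
#' roughness is the standard deviation over tiles of the stratum-corneum /
#' living-layer interface height. Empty tiles contribute zero thickness.
#'
#' @param snapshot a `sim_state`.
#' @param spec a `membrane_spec`.
#' @param bins number of bins per lateral axis (>= 2).
#' @return list with `profile` (one row per tile: bin centers, membrane
#'   height, living and SC thickness, interface height),
#'   `mean_living_thickness_um`, `mean_sc_thickness_um` and
#'   `interface_roughness_um`.
#' @export
thickness_profiles <- function(snapshot, spec, bins = 32) {
  if (bins < 2) stop("bins must be >= 2")
  cells <- if (inherits(snapshot, "sim_state")) snapshot$cells else snapshot
  bx <- spec$domain_x_um / bins
  by <- spec$domain_y_um / bins
  ix <- pmin(bins - 1L, floor((cells$x %% spec$domain_x_um) / bx))
  iy <- pmin(bins - 1L, floor((cells$y %% spec$domain_y_um) / by))
  bin <- ix * bins + iy
  top <- cells$z + cells$c
  living <- cells$state %in% LIVING_STATES
  all_bins <- 0:(bins^2 - 1)
  cx <- (all_bins %/% bins + 0.5) * bx
  cy <- (all_bins %% bins + 0.5) * by
  hmem <- membrane_height(spec, cx, cy)
  max_by_bin <- function(sel) {
    out <- rep(NA_real_, length(all_bins))
    if (any(sel)) {
      agg <- tapply(top[sel], bin[sel], max)
      out[match(as.integer(names(agg)), all_bins)] <- agg
    }
    out
  }
  top_living <- max_by_bin(living)
  top_sc <- max_by_bin(!living)
  interface <- ifelse(is.na(top_living), hmem, top_living)
  t_living <- pmax(0, ifelse(is.na(top_living), 0, top_living - hmem))
  t_sc <- pmax(0, ifelse(is.na(top_sc), 0, top_sc - interface))
  profile <- data.frame(x = cx, y = cy, membrane_um = hmem,
                        living_thickness_um = t_living,
                        sc_thickness_um = t_sc,
                        interface_um = interface)
  # population standard deviation: the roughness of n tiles at heights
  # h +/- d is exactly d
  rough <- sqrt(mean((interface - mean(interface))^2))
  list(profile = profile,
       mean_living_thickness_um = mean(t_living),
       mean_sc_thickness_um = mean(t_sc),
       interface_roughness_um = rough)
}

#' Full per-snapshot layer metrics
#'
#' Convenience wrapper combining [count_layers()], [section_areas()] and
#' [thickness_profiles()] into one record.
#'
#' @inheritParams section_areas
#' @param bins bins per lateral axis for the thickness profiles.
#' @return a one-row data.frame of metrics.
#' @export
layer_metrics <- function(snapshot, spec, y0 = 0, slab_um = 10,
                          pixel_um = 0.25, bins = 32) {
  cl <- count_layers(snapshot)
  sa <- section_areas(snapshot, spec, y0 = y0, slab_um = slab_um,
                      pixel_um = pixel_um)
  tp <- thickness_profiles(snapshot, spec, bins = bins)
  data.frame(n_corneocytes = cl[["n_corneocytes"]],
             n_living = cl[["n_living"]],
             sc_area_per100um = sa[["sc_area_per100um"]],
             living_area_per100um = sa[["living_area_per100um"]],
             mean_sc_thickness_um = tp$mean_sc_thickness_um,
             mean_living_thickness_um = tp$mean_living_thickness_um,
             interface_roughness_um = tp$interface_roughness_um)
}

#' Render a cross-section image
#'
#' Draws the slab cross-section with the standard color code — basement
#' membrane green, living keratinocytes purple, cornified cells red — on a
#' white background, axes in um, and writes it as a PNG raster.
#'
#' @inheritParams section_areas
#' @param file output PNG path (if `NULL`, the RGB array is returned
#'   without writing).
#' @param colors named list overriding the `membrane`, `living`, `sc` and
#'   `background` RGB triples (values in [0, 1]).
#' @return invisibly, the H x W x 3 RGB array.
#' @export
render_section <- function(snapshot, spec, y0 = 0, slab_um = 10,
                           pixel_um = 0.25, file = NULL, colors = NULL) {
  default_cols <- list(membrane = c(0, 0.6, 0.2), living = c(0.5, 0, 0.5),
                       sc = c(0.85, 0.1, 0.1), background = c(1, 1, 1))
  cols <- utils::modifyList(default_cols, colors %||% list())
  ras <- rasterize_section(snapshot, spec, y0, slab_um, pixel_um)
  img <- ras$img
  nz <- nrow(img); nx <- ncol(img)
  rgb <- array(0, dim = c(nz, nx, 3))
  for (ch in 1:3) {
    plane <- matrix(cols$background[ch], nz, nx)
    plane[img == 1L] <- cols$living[ch]
    plane[img == 2L] <- cols$sc[ch]
    plane[img == -1L] <- cols$membrane[ch]
    rgb[, , ch] <- plane
  }
  rgb <- rgb[rev(seq_len(nz)), , , drop = FALSE]   # z up in image space
  if (!is.null(file)) png::writePNG(rgb, file)
  invisible(rgb)
}

#' Compare replicate metrics across conditions
#'
#' One-way ANOVA with Tukey honestly-significant-difference post-hoc pairwise
#' comparisons at alpha = 0.05, the standard analysis for multi-condition
#' replicate morphometry.
#'
#' @param metrics a data.frame with columns `condition` and `value` (one row
#'   per replicate).
#' @param alpha significance level for the Tukey flags.
#' @return list with `anova` (one-row data.frame: `F`, `df_between`,
#'   `df_within`, `p`) and `tukey` (one row per condition pair: `diff`,
#'   `lwr`, `upr`, `p_adj`, `significant`).
#' @export
compare_conditions <- function(metrics, alpha = 0.05) {
  stopifnot(is.data.frame(metrics),
            all(c("condition", "value") %in% names(metrics)))
  counts <- table(metrics$condition)
  if (length(counts) < 2) stop("need at least 2 conditions")
  if (any(counts < 2))
    stop("fewer than 2 replicates in condition(s): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  metrics$condition <- factor(metrics$condition)
  fit <- aov(value ~ condition, data = metrics)
  tab <- anova(fit)
  res <- list(anova = data.frame(F = tab[1, "F value"],
                                 df_between = tab[1, "Df"],
                                 df_within = tab[2, "Df"],
                                 p = tab[1, "Pr(>F)"]))
  if (!is.finite(res$anova$F)) res$anova$F <- 0   # zero within+between MS
  tk <- TukeyHSD(fit)$condition
  res$tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"],
                          significant = tk[, "p adj"] < alpha,
                          row.names = NULL)
  res
}
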