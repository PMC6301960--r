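#' Basement-membrane specification
#'
#' Defines the substrate surface on which the epidermis grows. Three kinds are
#' supported: a flat membrane (the zero surface), a sinusoidally undulating
#' membrane parameterised by peak-to-trough amplitude and wavelength (by
#' default a separable product sinusoid, isotropic in the plane; a 1D groove
#' variant is available via `grooves = TRUE`), and a textile-like grid of
#' orthogonal half-cylindrical fibers characterised by fiber thickness and
#' inter-fiber interval. Lengths are in micrometres; the lateral boundaries
#' are periodic and heights are always evaluated on wrapped coordinates.
#'
#' @param kind one of `"flat"`, `"sinusoidal"`, `"fiber_grid"`.
#' @param amplitude_um peak-to-trough amplitude of the sinusoid (um).
#' @param wavelength_um wavelength of the sinusoid (um).
#' @param fiber_thickness_um fiber diameter of the textile grid (um).
#' @param fiber_interval_um clear interval between adjacent fibers (um).
#' @param domain_x_um,domain_y_um lateral domain extents (um). Defaults match
#'   the 300 x 300 um region of interest used for full-scale runs.
#' @param grooves if `TRUE`, the sinusoid varies only along x (1D grooves)
#'   instead of the default 2D product form.
#' @return an object of class `membrane_spec`.
#' @export
membrane_spec <- function(kind = c("flat", "sinusoidal", "fiber_grid"),
                          amplitude_um = NULL, wavelength_um = NULL,
                          fiber_thickness_um = NULL, fiber_interval_um = NULL,
                          domain_x_um = 300, domain_y_um = 300,
                          grooves = FALSE) {
  kind <- match.arg(kind)
  if (!is.numeric(domain_x_um) || !is.numeric(domain_y_um) ||
      domain_x_um <= 0 || domain_y_um <= 0)
    stop("domain extents must be positive lengths (um)")
  spec <- list(kind = kind,
               kind_code = match(kind, c("flat", "sinusoidal", "fiber_grid")) - 1L,
               amplitude_um = amplitude_um, wavelength_um = wavelength_um,
               fiber_thickness_um = fiber_thickness_um,
               fiber_interval_um = fiber_interval_um,
               domain_x_um = as.numeric(domain_x_um),
               domain_y_um = as.numeric(domain_y_um),
               grooves = isTRUE(grooves))
  if (kind == "sinusoidal") {
    if (is.null(amplitude_um) || is.null(wavelength_um))
      stop("sinusoidal membrane requires amplitude_um and wavelength_um")
    if (amplitude_um < 0) stop("amplitude_um must be >= 0")
    if (wavelength_um <= 0) stop("wavelength_um must be > 0")
  } else if (kind == "fiber_grid") {
    if (is.null(fiber_thickness_um) || is.null(fiber_interval_um))
      stop("fiber_grid membrane requires fiber_thickness_um and fiber_interval_um")
    if (fiber_thickness_um <= 0 || fiber_interval_um <= 0)
      stop("fiber dimensions must be > 0")
    period <- fiber_thickness_um + fiber_interval_um
    for (L in c(domain_x_um, domain_y_um)) {
      k <- round(L / period)
      if (k < 1 || abs(L - k * period) / period > 0.01)
        stop(sprintf(paste0("fiber period %.3f um must divide the domain extent ",
                            "%.3f um within 1%% for consistent periodic boundaries"),
                     period, L))
    }
  }
  class(spec) <- "membrane_spec"
  spec
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat("<membrane_spec>", x$kind,
      sprintf("domain %.0f x %.0f um", x$domain_x_um, x$domain_y_um), "\n")
  if (x$kind == "sinusoidal")
    cat(sprintf("  amplitude %.1f um, wavelength %.1f um%s\n",
                x$amplitude_um, x$wavelength_um,
                if (x$grooves) " (1D grooves)" else ""))
  if (x$kind == "fiber_grid")
    cat(sprintf("  fiber thickness %.1f um, interval %.1f um\n",
                x$fiber_thickness_um, x$fiber_interval_um))
  invisible(x)
}

#' Packaged substrate texture presets
#'
#' The ten polyester textile geometries used as culture substrates (fiber
#' thickness and clear inter-fiber interval, um), plus a `"papillary"` row
#' with the measured human papillary-layer geometry: rete ridge height 51 um
#' (corresponding to fiber thickness) and undulation interval 105 um.
#'
#' @return a data.frame with columns `name`, `fiber_thickness_um`,
#'   `fiber_interval_um`.
#' @export
texture_presets <- function() {
  path <- system.file("extdata", "texture_presets.csv", package = "epidermsim",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = TRUE,
           colClasses = c("character", "numeric", "numeric"))
}

#' Build a fiber-grid membrane from a packaged texture preset
#'
#' The lateral domain is snapped to the nearest positive multiple of the fiber
#' period so periodic boundaries are consistent.
#'
#' @param name preset identifier, e.g. `"#255"` or `"papillary"`.
#' @param domain_um target lateral extent (um); the actual extent is the
#'   multiple of the fiber period closest to it (at least one period).
#' @return a `membrane_spec` of kind `"fiber_grid"`.
#' @export
membrane_preset <- function(name, domain_um = 300) {
  tab <- texture_presets()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1)
    stop("unknown preset '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  period <- row$fiber_thickness_um + row$fiber_interval_um
  L <- period * max(1, round(domain_um / period))
  membrane_spec("fiber_grid",
                fiber_thickness_um = row$fiber_thickness_um,
                fiber_interval_um = row$fiber_interval_um,
                domain_x_um = L, domain_y_um = L)
}

#' Membrane surface height
#'
#' Height z(x, y) of the basement-membrane surface in um, laterally periodic
#' with the domain. Flat membranes are the zero surface; the sinusoid is
#' h = (A/2) sin(2 pi x / lambda) sin(2 pi y / lambda) (so the peak-to-trough
#' excursion equals the amplitude); the fiber grid is the upper envelope of
#' orthogonal cylinders of diameter `fiber_thickness_um` resting on the base
#' plane z = 0, axes spaced one period apart.
#'
#' @param spec a `membrane_spec`.
#' @param x,y lateral coordinates (um), vectorised.
#' @return numeric vector of heights (um).
#' @export
membrane_height <- function(spec, x, y) {
  stopifnot(inherits(spec, "membrane_spec"))
  n <- max(length(x), length(y))
  cpp_membrane_height(unclass(spec), rep_len(as.numeric(x), n),
                      rep_len(as.numeric(y), n))
}

#' Vertical clearance and surface normal at a point
#'
#' Returns the vertical gap between a 3D position and the membrane surface
#' beneath it (negative gap means penetration) together with the outward unit
#' surface normal, computed from the analytic height gradient (finite
#' differences for the fiber envelope).
#'
#' @param spec a `membrane_spec`.
#' @param p a 3-vector `c(x, y, z)` or an n x 3 matrix of positions (um).
#' @return a list with `gap` (numeric vector, um) and `normal`
#'   (n x 3 matrix of unit vectors).
#' @export
membrane_gap <- function(spec, p) {
  stopifnot(inherits(spec, "membrane_spec"))
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3)
  res <- cpp_membrane_gap(unclass(spec), p[, 1], p[, 2], p[, 3])
  list(gap = res$gap, normal = res$normal)
}

#' Seed stem cells on the membrane surface
#'
#' Places stem cells on a jittered hexagonal lattice in the (x, y) plane and
#' projects them onto the membrane surface, so every returned position has
#' zero membrane gap. The lattice count is deterministic given the domain and
#' spacing; the jitter draws use the current RNG state, so results are
#' reproducible under [set.seed()].
#'
#' @param spec a `membrane_spec`.
#' @param spacing_um target mean nearest-neighbour spacing (um); must be at
#'   least one cell diameter (`2 * r0_um`).
#' @param jitter uniform positional jitter as a fraction of the spacing
#'   (default 0.1, i.e. +/-10%); use 0 for an exact lattice.
#' @param r0_um intrinsic cell radius used for the spacing precondition.
#' @return a data.frame with columns `x`, `y`, `z` (on-surface positions, um).
#' @export
place_stem_cells <- function(spec, spacing_um = 10, jitter = 0.1, r0_um = 5) {
  stopifnot(inherits(spec, "membrane_spec"))
  if (spacing_um <= 0) stop("spacing_um must be > 0")
  if (spacing_um < 2 * r0_um)
    stop("spacing_um must be at least one cell diameter (2 * r0_um)")
  if (spacing_um > min(spec$domain_x_um, spec$domain_y_um))
    stop("spacing_um exceeds the domain extent; no stem cells would fit")
  dy <- spacing_um * sqrt(3) / 2
  ny <- max(1L, round(spec$domain_y_um / dy))
  nx <- max(1L, round(spec$domain_x_um / spacing_um))
  row_y <- spec$domain_y_um / ny
  col_x <- spec$domain_x_um / nx
  j <- rep(seq_len(ny) - 1L, each = nx)
  i <- rep(seq_len(nx) - 1L, times = ny)
  x <- (i + 0.5 + 0.5 * (j %% 2L)) * col_x
  y <- (j + 0.5) * row_y
  n <- length(x)
  if (jitter > 0) {
    x <- x + runif(n, -jitter, jitter) * spacing_um
    y <- y + runif(n, -jitter, jitter) * spacing_um
  }
  x <- x %% spec$domain_x_um
  y <- y %% spec$domain_y_um
  data.frame(x = x, y = y, z = membrane_height(spec, x, y))
}
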