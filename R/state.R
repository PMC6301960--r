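#' Construct a simulation state
#'
#' A `sim_state` bundles the cell table with the simulation clock and the
#' cumulative birth/removal counters. The cell table has one row per cell
#' with columns `id`, `x`, `y`, `z` (um), `a`, `c` (ellipsoid semi-axes, um),
#' `state`, `age_in_state` (h), `anchor_x`, `anchor_y` (stem anchors, `NA`
#' otherwise) and `ca`. The exact identity
#' `nrow(cells) = n0 + births - removals` holds at every step of a run.
#'
#' @param cells data.frame of cells (missing columns are filled with
#'   defaults; at minimum `x`, `y`, `z`, `state` are required).
#' @param t simulation time (h).
#' @param births,removals cumulative counters.
#' @param r0_um intrinsic radius used to default the semi-axes.
#' @return an object of class `sim_state`.
#' @export
sim_state <- function(cells, t = 0, births = 0, removals = 0, r0_um = 5) {
  stopifnot(is.data.frame(cells))
  n <- nrow(cells)
  if (n > 0 && !all(c("x", "y", "z", "state") %in% names(cells)))
    stop("cells must have columns x, y, z, state")
  if (is.null(cells$id)) cells$id <- seq_len(n) - 1L
  if (is.null(cells$a)) cells$a <- rep(r0_um, n)
  if (is.null(cells$c)) cells$c <- rep(r0_um, n)
  if (is.null(cells$age_in_state)) cells$age_in_state <- numeric(n)
  if (is.null(cells$anchor_x)) cells$anchor_x <- rep(NA_real_, n)
  if (is.null(cells$anchor_y)) cells$anchor_y <- rep(NA_real_, n)
  if (is.null(cells$ca)) cells$ca <- numeric(n)
  if (anyDuplicated(cells$id)) stop("cell ids must be unique")
  if (n > 0) {
    bad <- !cells$state %in% STATE_LEVELS
    if (any(bad)) stop("unknown cell states: ",
                       paste(unique(cells$state[bad]), collapse = ", "))
    is_stem <- cells$state == "STEM"
    if (any(is_stem & is.na(cells$anchor_x)))
      stop("every STEM cell needs an anchor")
    if (any(!is_stem & !is.na(cells$anchor_x)))
      stop("non-STEM cells must not carry anchors")
    cells <- cells[order(cells$id), , drop = FALSE]
    rownames(cells) <- NULL
  }
  structure(list(cells = cells, t = as.numeric(t),
                 births = as.integer(births), removals = as.integer(removals)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  tab <- table(factor(x$cells$state, levels = STATE_LEVELS))
  cat(sprintf("<sim_state> t = %.1f h, %d cells (births %d, removals %d)\n",
              x$t, nrow(x$cells), x$births, x$removals))
  print(tab)
  invisible(x)
}

# convert a sim_state's cell table into the parallel vectors the C++ core
# expects; NA anchors are passed through (only read for stems)
state_vectors <- function(state) {
  cells <- state$cells
  list(x = as.numeric(cells$x), y = as.numeric(cells$y),
       z = as.numeric(cells$z), a = as.numeric(cells$a),
       c = as.numeric(cells$c), state = state_to_code(cells$state),
       age = as.numeric(cells$age_in_state),
       ax = as.numeric(cells$anchor_x), ay = as.numeric(cells$anchor_y),
       ca = as.numeric(cells$ca), id = as.integer(cells$id))
}

snapshot_to_state <- function(snap) {
  cells <- data.frame(id = snap$id, x = snap$x, y = snap$y, z = snap$z,
                      a = snap$a, c = snap$c, state = code_to_state(snap$state),
                      age_in_state = snap$age_in_state,
                      anchor_x = snap$anchor_x, anchor_y = snap$anchor_y,
                      ca = snap$ca)
  sim_state(cells, t = snap$t, births = snap$births, removals = snap$removals)
}
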