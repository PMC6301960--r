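# Shared helpers: cell-object conversion, an O(N^2) all-pairs force oracle
# independent of the grid neighbour search, and a contact-energy surrogate.

df_to_cells <- function(state) {
  cells <- state$cells
  lapply(seq_len(nrow(cells)), function(i) {
    anchor <- if (cells$state[i] == "STEM")
      c(cells$anchor_x[i], cells$anchor_y[i]) else NULL
    structure(list(id = cells$id[i],
                   pos = c(cells$x[i], cells$y[i], cells$z[i]),
                   r0 = 5, a = cells$a[i], c = cells$c[i],
                   state = cells$state[i],
                   age_in_state = cells$age_in_state[i],
                   anchor = anchor, ca = cells$ca[i], alive = TRUE),
              class = "epiderm_cell")
  })
}

# brute-force total forces: every pair once, plus membrane/anchor terms
brute_force_total <- function(state, spec, fp) {
  objs <- df_to_cells(state)
  n <- length(objs)
  F <- matrix(0, n, 3)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        fij <- pairwise_force(objs[[i]], objs[[j]], fp, spec)
        F[i, ] <- F[i, ] + fij
        F[j, ] <- F[j, ] - fij
      }
    }
  }
  for (i in seq_len(n)) F[i, ] <- F[i, ] + membrane_force(objs[[i]], spec, fp)
  F
}

# contact-energy surrogate: sum of squared pairwise overlaps plus squared
# membrane penetrations (the quantity gradient descent should not increase
# when noise and adhesion are off)
contact_energy <- function(state, spec, fp) {
  cells <- state$cells
  n <- nrow(cells)
  E <- 0
  wrapd <- function(d, L) d - L * round(d / L)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      dx <- wrapd(cells$x[i] - cells$x[j], spec$domain_x_um)
      dy <- wrapd(cells$y[i] - cells$y[j], spec$domain_y_um)
      dz <- cells$z[i] - cells$z[j]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      uz2 <- (dz / d)^2
      rad <- function(a, c) a * c / sqrt(c^2 * (1 - uz2) + a^2 * uz2)
      R <- rad(cells$a[i], cells$c[i]) + rad(cells$a[j], cells$c[j])
      E <- E + max(0, R - d)^2
    }
  }
  gaps <- membrane_gap(spec, as.matrix(cells[, c("x", "y", "z")]))$gap
  pen <- pmax(0, cells$c - gaps)
  pen[cells$state == "STEM"] <- 0
  E + sum(pen^2)
}

# quick lifecycle parameterisations used across tests
lp_frozen <- function(...) {
  lifecycle_params(division_period_h = 1e9, spinous_dur_h = 1e9,
                   granular_dur_h = 1e9, desquam_dur_h = 1e9, ...)
}
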