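lp <- lifecycle_params()

test_that("stem cells never change state and daughters start proliferative", {
  stem <- new_cell(0, c(5, 5, 0), state = "STEM", anchor = c(5, 5))
  out <- update_state(stem, gap = 100, dt = 5, lp)
  expect_equal(out$state, "STEM")
  expect_equal(out$age_in_state, 5)

  expect_error(attempt_division(new_cell(1, c(0, 0, 0)), 0.1, 0, lp),
               "STEM")
  # crowding above the cap suppresses division entirely
  set.seed(1)
  kids <- replicate(200, attempt_division(stem, dt = 5, local_density = 13,
                                          lp = lp), simplify = FALSE)
  expect_true(all(vapply(kids, is.null, logical(1))))
  # daughters are proliferative and placed in the upward hemisphere
  set.seed(2)
  for (k in 1:50) {
    d <- attempt_division(stem, dt = 1e6, local_density = 0, lp = lp,
                          new_id = 10L)
    expect_equal(d$state, "PROLIF")
    expect_gte(d$pos[3], stem$pos[3])
    expect_equal(sqrt(sum((d$pos - stem$pos)^2)), lp$daughter_offset_um)
  }
})

test_that("division events of an uncrowded stem match the exponential clock", {
  stem <- new_cell(0, c(0, 0, 0), state = "STEM", anchor = c(0, 0))
  T_h <- 24; dt <- 0.1
  n_steps <- T_h / dt
  reps <- 1500
  set.seed(101)
  counts <- vapply(seq_len(reps), function(r) {
    n <- 0L
    for (s in seq_len(n_steps))
      if (!is.null(attempt_division(stem, dt, 0, lp))) n <- n + 1L
    n
  }, integer(1))
  expect_equal(mean(counts), T_h / lp$division_period_h, tolerance = 0.05)
})

test_that("positional differentiation and the residence clocks are ordered", {
  cell <- new_cell(0, c(0, 0, 20), state = "PROLIF")
  # below the clearance threshold: stays proliferative
  out <- update_state(cell, gap = lp$diff_height_um - 1, dt = 0.5, lp)
  expect_equal(out$state, "PROLIF")
  # above it: becomes spinous within the same step, age resets
  out <- update_state(cell, gap = lp$diff_height_um + 1, dt = 0.5, lp)
  expect_equal(out$state, "SPINOUS")
  expect_equal(out$age_in_state, 0)

  expect_error(update_state(cell, gap = 1, dt = -1, lp), "dt")

  # transitions follow the strict forward order, no skips, no reversals
  order_idx <- function(s) match(s, c("PROLIF", "SPINOUS", "GRANULAR",
                                      "CORNEOCYTE"))
  set.seed(9)
  for (rep in 1:20) {
    c0 <- new_cell(0, c(0, 0, 50), state = "PROLIF")
    seen <- c0$state
    for (k in 1:400) {
      c0 <- update_state(c0, gap = 50, dt = 1, lp)
      if (c0$state != seen[length(seen)]) seen <- c(seen, c0$state)
      if (c0$state == "CORNEOCYTE") break
    }
    expect_true(all(diff(order_idx(seen)) == 1))
  }
})

test_that("spinous occupancy under constant influx matches the M/M/inf mean", {
  set.seed(20240)
  influx <- 3
  res <- simulate_influx_occupancy(influx, lp, t_total_h = 2600,
                                   dt_h = 0.25, burnin_h = 200)
  expect_equal(res$mean_occupancy, influx * lp$spinous_dur_h,
               tolerance = 0.05)
})

test_that("corneocyte flattening relaxes the aspect ratio and conserves volume", {
  corneo <- new_cell(0, c(0, 0, 40), state = "CORNEOCYTE")
  expect_identical(update_flattening(corneo, 0, lp), corneo)
  expect_error(update_flattening(new_cell(0, c(0, 0, 0)), 1, lp),
               "CORNEOCYTE")

  # after 10 time constants the aspect is within 1e-4 of its target
  relaxed <- update_flattening(corneo, 10 * lp$flatten_tau_h, lp)
  expect_lt(abs(relaxed$c / relaxed$a - lp$target_aspect),
            1e-4 * (1 - lp$target_aspect))

  # exact exponential-decay law for the aspect ratio
  q0 <- 1; dt <- 0.5
  stepped <- update_flattening(corneo, dt, lp)
  q_expected <- lp$target_aspect +
    (q0 - lp$target_aspect) * exp(-dt / lp$flatten_tau_h)
  expect_equal(stepped$c / stepped$a, q_expected, tolerance = 1e-12)

  # volume drift over 1e4 steps stays below 1e-8 relative
  v0 <- corneo$a^2 * corneo$c
  cc <- corneo
  for (k in 1:10000) cc <- update_flattening(cc, 0.01, lp)
  expect_lt(abs(cc$a^2 * cc$c - v0) / v0, 1e-8)
})

test_that("the calcium proxy is clamped and relaxes to its height target", {
  lp_ca <- lifecycle_params(calcium_on = TRUE)
  expect_error(update_calcium(new_cell(0, c(0, 0, 0)), 0, 1, lp), "disabled")

  cell <- new_cell(0, c(0, 0, 0), ca = 0.9)
  for (k in 1:50) cell <- update_calcium(cell, gap = 0, dt = 1, lp_ca)
  expect_lt(cell$ca, 1e-6)            # at the membrane the target is zero

  set.seed(5)
  cell <- new_cell(0, c(0, 0, 0), ca = 0.5)
  for (k in 1:200) {
    cell <- update_calcium(cell, gap = runif(1, -50, 200),
                           dt = runif(1, 0, 3), lp_ca)
    expect_gte(cell$ca, 0)
    expect_lte(cell$ca, 1)
  }

  # far above the granular band the target saturates at one
  cell <- new_cell(0, c(0, 0, 0), ca = 0)
  for (k in 1:50) cell <- update_calcium(cell, gap = 1000, dt = 1, lp_ca)
  expect_gt(cell$ca, 1 - 1e-6)

  # with the feature disabled, a run leaves every calcium value at zero
  flat <- membrane_spec("flat", domain_x_um = 60, domain_y_um = 60)
  traj <- simulate_epidermis(flat, T_total_h = 10, snapshot_every_h = 5,
                             seed = 4)
  expect_true(all(vapply(traj$snapshots,
                         function(s) all(s$cells$ca == 0), logical(1))))
})

test_that("cell constructor enforces shape and anchoring invariants", {
  expect_error(new_cell(0, c(0, 0, 0), state = "STEM"), "anchor")
  expect_error(new_cell(0, c(0, 0, 0), state = "PROLIF", anchor = c(0, 0)),
               "STEM")
  expect_error(new_cell(0, c(0, 0, 0), a = 4, c = 5), "spherical")
  expect_error(new_cell(0, c(0, 0, 0), state = "CORNEOCYTE", a = 10, c = 3),
               "volume")
  ok <- new_cell(0, c(0, 0, 0), state = "CORNEOCYTE", a = 125^(1 / 3) * 2^(1 / 3),
                 c = 125^(1 / 3) / 2^(2 / 3))
  expect_equal(ok$a^2 * ok$c, 125, tolerance = 1e-9)
})
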