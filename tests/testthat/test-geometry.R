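test_that("membrane heights match the analytic surfaces", {
  flat <- membrane_spec("flat", domain_x_um = 100, domain_y_um = 100)
  expect_equal(membrane_height(flat, runif(20, 0, 100), runif(20, 0, 100)),
               rep(0, 20))

  sinu <- membrane_spec("sinusoidal", amplitude_um = 50, wavelength_um = 100,
                        domain_x_um = 100, domain_y_um = 100)
  expect_equal(membrane_height(sinu, 25, 25), 25)       # product-sine peak
  expect_equal(membrane_height(sinu, 75, 25), -25)      # and trough
  expect_equal(membrane_height(sinu, 50, 37), 0)        # node line

  grooves <- membrane_spec("sinusoidal", amplitude_um = 50,
                           wavelength_um = 100, domain_x_um = 100,
                           domain_y_um = 100, grooves = TRUE)
  expect_equal(membrane_height(grooves, 25, c(5, 50, 95)), rep(25, 3))

  f255 <- membrane_preset("#255", domain_um = 300)
  expect_equal(f255$domain_x_um, 322)  # closest multiple of the 161 um period
  # top of a fiber on an axis equals the fiber thickness; clear gap is 0
  expect_equal(membrane_height(f255, 0, 50), 60)
  expect_equal(membrane_height(f255, 80.5, 80.5), 0)
})

test_that("membrane gap and normals are consistent with the height field", {
  sinu <- membrane_spec("sinusoidal", amplitude_um = 50, wavelength_um = 100,
                        domain_x_um = 100, domain_y_um = 100)
  res <- membrane_gap(sinu, c(25, 25, 30))
  expect_equal(res$gap, 5)
  flat <- membrane_spec("flat", domain_x_um = 100, domain_y_um = 100)
  res <- membrane_gap(flat, c(10, 10, 4))
  expect_equal(res$gap, 4)
  expect_equal(res$normal[1, ], c(0, 0, 1))

  set.seed(42)
  for (spec in list(flat, sinu,
                    membrane_preset("#255", domain_um = 161))) {
    p <- cbind(runif(1000, 0, spec$domain_x_um),
               runif(1000, 0, spec$domain_y_um), runif(1000, 0, 80))
    n <- membrane_gap(spec, p)$normal
    expect_equal(sqrt(rowSums(n^2)), rep(1, 1000), tolerance = 1e-9)
  }

  # normals agree with the central-difference gradient of the height field
  set.seed(7)
  x <- runif(200, 0, 100); y <- runif(200, 0, 100)
  eps <- 1e-4
  hx <- (membrane_height(sinu, x + eps, y) -
         membrane_height(sinu, x - eps, y)) / (2 * eps)
  hy <- (membrane_height(sinu, x, y + eps) -
         membrane_height(sinu, x, y - eps)) / (2 * eps)
  nrm <- cbind(-hx, -hy, 1) / sqrt(hx^2 + hy^2 + 1)
  got <- membrane_gap(sinu, cbind(x, y, 10))$normal
  expect_equal(got, nrm, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("membranes are laterally periodic with bounded height range", {
  specs <- list(
    membrane_spec("flat", domain_x_um = 100, domain_y_um = 100),
    membrane_spec("sinusoidal", amplitude_um = 50, wavelength_um = 50,
                  domain_x_um = 100, domain_y_um = 100),
    membrane_preset("#255", domain_um = 161))
  set.seed(1)
  for (spec in specs) {
    x <- runif(300, 0, spec$domain_x_um)
    y <- runif(300, 0, spec$domain_y_um)
    expect_equal(membrane_height(spec, x + spec$domain_x_um, y),
                 membrane_height(spec, x, y), tolerance = 1e-9)
    expect_equal(membrane_height(spec, x, y + spec$domain_y_um),
                 membrane_height(spec, x, y), tolerance = 1e-9)
    g <- seq(0, spec$domain_x_um, length.out = 512)
    h <- outer(g, g, function(a, b) membrane_height(spec, a, b))
    span <- max(h) - min(h)
    bound <- switch(spec$kind, flat = 0,
                    sinusoidal = spec$amplitude_um,
                    fiber_grid = spec$fiber_thickness_um)
    expect_lte(span, bound + 1e-9)
  }
})

test_that("membrane_spec validates its inputs", {
  expect_error(membrane_spec("sinusoidal", amplitude_um = -1,
                             wavelength_um = 100), "amplitude")
  expect_error(membrane_spec("sinusoidal", amplitude_um = 10,
                             wavelength_um = 0), "wavelength")
  # fiber period must divide the domain within 1%
  expect_error(membrane_spec("fiber_grid", fiber_thickness_um = 60,
                             fiber_interval_um = 101,
                             domain_x_um = 300, domain_y_um = 300),
               "period")
  expect_silent(membrane_spec("fiber_grid", fiber_thickness_um = 60,
                              fiber_interval_um = 101,
                              domain_x_um = 322, domain_y_um = 322))
})

test_that("packaged texture presets carry the full substrate table", {
  tab <- texture_presets()
  expect_equal(nrow(tab), 11)           # ten textiles plus papillary
  expect_equal(tab[tab$name == "#255", c("fiber_thickness_um",
                                         "fiber_interval_um")],
               data.frame(fiber_thickness_um = 60, fiber_interval_um = 101),
               ignore_attr = TRUE)
  pap <- tab[tab$name == "papillary", ]
  expect_equal(c(pap$fiber_thickness_um, pap$fiber_interval_um), c(51, 105))
  expect_error(membrane_preset("nope"), "#255")
})

test_that("stem seeding lies on the surface and is reproducible", {
  flat <- membrane_spec("flat", domain_x_um = 100, domain_y_um = 100)
  pts <- place_stem_cells(flat, spacing_um = 10, jitter = 0)
  expect_true(all(pts$z == 0))
  # hexagonal lattice: 10 columns x 12 rows (row pitch spacing * sqrt(3)/2),
  # count deterministic given domain and spacing
  expect_equal(nrow(pts), 120)

  sinu <- membrane_spec("sinusoidal", amplitude_um = 50, wavelength_um = 100,
                        domain_x_um = 100, domain_y_um = 100)
  set.seed(3)
  pts <- place_stem_cells(sinu, spacing_um = 10)
  gaps <- membrane_gap(sinu, as.matrix(pts))$gap
  expect_true(all(abs(gaps) < 1e-6))

  set.seed(11); a <- place_stem_cells(sinu, spacing_um = 10)
  set.seed(11); b <- place_stem_cells(sinu, spacing_um = 10)
  expect_identical(a, b)

  expect_error(place_stem_cells(flat, spacing_um = 4), "diameter")
  expect_error(place_stem_cells(flat, spacing_um = 500), "domain")
})
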