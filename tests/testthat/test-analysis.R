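flat100 <- membrane_spec("flat", domain_x_um = 100, domain_y_um = 100)

test_that("layer counts partition every snapshot", {
  cells <- data.frame(id = 1:8, x = 10, y = 10, z = 1:8 * 5,
                      a = 5, c = 5,
                      state = c("CORNEOCYTE", "CORNEOCYTE", "CORNEOCYTE",
                                "STEM", "PROLIF", "SPINOUS", "GRANULAR",
                                "SPINOUS"),
                      anchor_x = c(rep(NA, 3), 10, rep(NA, 4)),
                      anchor_y = c(rep(NA, 3), 10, rep(NA, 4)))
  st <- sim_state(cells)
  expect_equal(count_layers(st),
               c(n_corneocytes = 3L, n_living = 5L))
  expect_equal(count_layers(sim_state(data.frame())),
               c(n_corneocytes = 0L, n_living = 0L))
  for (seed in 1:20) {
    cloud <- make_fixture("random_cloud", list(n = 37), seed = seed)
    cl <- count_layers(cloud)
    expect_equal(sum(cl), nrow(cloud$cells))
  }
})

test_that("section areas match the analytic ellipse and the fine-grid oracle", {
  # one flattened corneocyte: area = pi * a * c within rasterisation error
  cells <- data.frame(id = 0L, x = 50, y = 5, z = 40, a = 10, c = 2,
                      state = "CORNEOCYTE")
  st <- sim_state(cells)
  got <- section_areas(st, flat100, y0 = 0, slab_um = 10, pixel_um = 0.25)
  expect_equal(got[["sc_area_per100um"]], pi * 10 * 2, tolerance = 0.02)
  expect_equal(got[["living_area_per100um"]], 0)

  # a cell wholly under a fiber is fully masked out
  f255 <- membrane_preset("#255", domain_um = 161)
  under <- sim_state(data.frame(id = 0L, x = 0, y = 80.5, z = 10,
                                a = 5, c = 5, state = "SPINOUS"))
  got <- section_areas(under, f255, y0 = 75.5, slab_um = 10, pixel_um = 0.25)
  expect_equal(unname(got), c(0, 0))

  # corneocytes claim contested pixels
  pair <- sim_state(data.frame(id = 0:1, x = 50, y = 5, z = c(40, 41),
                               a = 5, c = 5,
                               state = c("SPINOUS", "CORNEOCYTE")))
  areas <- section_areas(pair, flat100, y0 = 0, slab_um = 10,
                         pixel_um = 0.25)
  expect_equal(areas[["sc_area_per100um"]], pi * 25, tolerance = 0.02)
  expect_lt(areas[["living_area_per100um"]], pi * 25)

  # coarse rasterisation converges to the fine-grid oracle within 1%
  cloud <- make_fixture("random_cloud", list(n = 60), seed = 3)
  coarse <- section_areas(cloud, flat100, y0 = 40, slab_um = 10,
                          pixel_um = 0.25)
  fine <- section_areas(cloud, flat100, y0 = 40, slab_um = 10,
                        pixel_um = 0.05)
  expect_equal(coarse[["sc_area_per100um"]], fine[["sc_area_per100um"]],
               tolerance = 0.01)
  expect_equal(coarse[["living_area_per100um"]],
               fine[["living_area_per100um"]], tolerance = 0.01)

  expect_error(section_areas(cloud, flat100, y0 = 95, slab_um = 10),
               "outside")
})

test_that("thickness profiles recover constructed layer geometry exactly", {
  slab <- make_fixture("two_layer_slab",
                       list(living_top_um = 50, sc_thickness_um = 20,
                            spacing_um = 10, domain_um = 100))
  tp <- thickness_profiles(slab, flat100, bins = 10)
  expect_equal(tp$mean_living_thickness_um, 50)
  expect_equal(tp$mean_sc_thickness_um, 20)
  expect_equal(tp$interface_roughness_um, 0)

  # without corneocytes the stratum corneum is zero everywhere
  living_only <- slab
  living_only$cells <- living_only$cells[living_only$cells$state != "CORNEOCYTE", ]
  tp <- thickness_profiles(sim_state(living_only$cells), flat100, bins = 10)
  expect_equal(tp$mean_sc_thickness_um, 0)
  expect_true(all(tp$profile$sc_thickness_um == 0))

  # alternating +/- 5 um interface offsets give roughness exactly 5
  g <- (seq_len(10) - 0.5) * 10
  xy <- expand.grid(x = g, y = g)
  off <- 5 * (-1)^(seq_len(nrow(xy)))
  cells <- data.frame(id = seq_len(nrow(xy)) - 1L, x = xy$x, y = xy$y,
                      z = 45 + off, a = 5, c = 5, state = "SPINOUS")
  tp <- thickness_profiles(sim_state(cells), flat100, bins = 10)
  expect_equal(tp$interface_roughness_um, 5)

  expect_error(thickness_profiles(slab, flat100, bins = 1), "bins")
})

test_that("metrics are invariant under translation by one membrane period", {
  sinu <- membrane_spec("sinusoidal", amplitude_um = 40, wavelength_um = 50,
                        domain_x_um = 100, domain_y_um = 100)
  cloud <- make_fixture("random_cloud", list(n = 80), seed = 9)
  shifted <- cloud
  shifted$cells$x <- (shifted$cells$x + 50) %% 100
  a0 <- section_areas(cloud, sinu, y0 = 30, slab_um = 10)
  a1 <- section_areas(shifted, sinu, y0 = 30, slab_um = 10)
  expect_equal(a0, a1, tolerance = 0.01)
  t0 <- thickness_profiles(cloud, sinu, bins = 8)
  t1 <- thickness_profiles(shifted, sinu, bins = 8)
  expect_equal(t0$mean_living_thickness_um, t1$mean_living_thickness_um,
               tolerance = 1e-9)
  expect_equal(t0$interface_roughness_um, t1$interface_roughness_um,
               tolerance = 1e-9)
})

test_that("rendered sections use the documented color code and geometry", {
  empty <- sim_state(data.frame())
  img <- render_section(empty, flat100, y0 = 0, slab_um = 10,
                        pixel_um = 0.5)
  expect_equal(dim(img)[2], 100 / 0.5)
  # only background and membrane appear in an empty snapshot
  px <- unique(apply(matrix(img, ncol = 3), 1, paste, collapse = ","))
  expect_true(all(px %in% c("1,1,1", "0,0.6,0.2")))

  one <- sim_state(data.frame(id = 0L, x = 50, y = 5, z = 20, a = 5, c = 5,
                              state = "SPINOUS"))
  img <- render_section(one, flat100, y0 = 0, slab_um = 10, pixel_um = 0.5)
  px <- unique(apply(matrix(img, ncol = 3), 1, paste, collapse = ","))
  expect_true("0.5,0,0.5" %in% px)   # living cells are purple

  tmp <- tempfile(fileext = ".png")
  render_section(one, flat100, y0 = 0, slab_um = 10, pixel_um = 0.5,
                 file = tmp)
  expect_true(file.exists(tmp))
  back <- png::readPNG(tmp)
  expect_equal(dim(back)[1:2], dim(img)[1:2])
  unlink(tmp)
})

test_that("condition comparison reproduces the hand-computed ANOVA", {
  # groups {1,2,3} vs {4,5,6}: between-group MS 13.5, within-group MS 1
  d <- data.frame(condition = rep(c("a", "b"), each = 3),
                  value = c(1, 2, 3, 4, 5, 6))
  res <- compare_conditions(d)
  expect_equal(res$anova$F, 13.5)
  expect_equal(res$anova$df_between, 1)
  expect_equal(res$anova$df_within, 4)

  # two identical groups: no between-group variance at all
  d2 <- data.frame(condition = rep(c("a", "b"), each = 3),
                   value = rep(c(1, 2, 3), 2))
  expect_equal(compare_conditions(d2)$anova$F, 0)

  # Tukey significance is symmetric in the condition labels
  set.seed(88)
  d3 <- data.frame(condition = rep(c("a", "b", "c"), each = 4),
                   value = c(rnorm(4, 0), rnorm(4, 10), rnorm(4, 0.2)))
  r1 <- compare_conditions(d3)
  d3r <- d3[rev(seq_len(nrow(d3))), ]
  d3r$condition <- factor(d3r$condition, levels = c("c", "b", "a"))
  r2 <- compare_conditions(d3r)
  key <- function(p) vapply(strsplit(p, "-"), function(x)
    paste(sort(x), collapse = "|"), character(1))
  m1 <- setNames(r1$tukey$significant, key(r1$tukey$pair))
  m2 <- setNames(r2$tukey$significant, key(r2$tukey$pair))
  expect_equal(m1[sort(names(m1))], m2[sort(names(m1))])

  expect_error(compare_conditions(
    data.frame(condition = c("a", "a", "b"), value = 1:3)), "b")
})
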