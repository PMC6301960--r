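#' Deterministic test fixtures
#'
#' Hand-specifiable snapshots for unit testing and oracle checks:
#' `two_layer_slab` builds a lattice of living cells whose tops form an
#' exactly flat interface at `living_top_um` with corneocytes topping out at
#' `living_top_um + sc_thickness_um`; `single_stem` is one anchored stem at
#' the domain center; `random_cloud` is a reproducible cloud of `n` cells of
#' mixed states (including flattened corneocytes) for force-oracle tests.
#'
#' @param kind one of `"two_layer_slab"`, `"single_stem"`, `"random_cloud"`.
#' @param params named list of fixture parameters. `two_layer_slab`:
#'   `living_top_um` (50), `sc_thickness_um` (20), `spacing_um` (10),
#'   `domain_um` (100), `r0_um` (5). `single_stem`: `domain_um` (100),
#'   `r0_um` (5). `random_cloud`: `n` (200), `domain_um` (100), `zmax_um`
#'   (60), `r0_um` (5), `target_aspect` (0.2).
#' @param seed RNG seed (used by `random_cloud`).
#' @return a `sim_state`.
#' @export
make_fixture <- function(kind = c("two_layer_slab", "single_stem",
                                  "random_cloud"),
                         params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- function(name, default) params[[name]] %||% default
  r0 <- p("r0_um", 5)
  L <- p("domain_um", 100)
  if (kind == "two_layer_slab") {
    living_top <- p("living_top_um", 50)
    sc_thick <- p("sc_thickness_um", 20)
    spacing <- p("spacing_um", 10)
    if (living_top <= r0 || sc_thick <= 0 || spacing <= 0 || spacing > L)
      stop("invalid two_layer_slab parameters")
    g <- (seq_len(max(1, floor(L / spacing))) - 0.5) * spacing
    xy <- expand.grid(x = g, y = g)
    c_sc <- 2
    a_sc <- sqrt(r0^3 / c_sc)
    living <- data.frame(x = xy$x, y = xy$y, z = living_top - r0,
                         a = r0, c = r0, state = "SPINOUS")
    sc <- data.frame(x = xy$x, y = xy$y, z = living_top + sc_thick - c_sc,
                     a = a_sc, c = c_sc, state = "CORNEOCYTE")
    cells <- rbind(living, sc)
    cells$id <- seq_len(nrow(cells)) - 1L
    return(sim_state(cells, r0_um = r0))
  }
  if (kind == "single_stem") {
    cells <- data.frame(id = 0L, x = L / 2, y = L / 2, z = 0,
                        a = r0, c = r0, state = "STEM", age_in_state = 0,
                        anchor_x = L / 2, anchor_y = L / 2, ca = 0)
    return(sim_state(cells, r0_um = r0))
  }
  # random_cloud
  n <- p("n", 200)
  zmax <- p("zmax_um", 60)
  aspect <- p("target_aspect", 0.2)
  set.seed(seed)
  state <- sample(c("PROLIF", "SPINOUS", "GRANULAR", "CORNEOCYTE"), n,
                  replace = TRUE)
  q <- ifelse(state == "CORNEOCYTE",
              runif(n, aspect, 1), 1)
  cells <- data.frame(id = seq_len(n) - 1L,
                      x = runif(n, 0, L), y = runif(n, 0, L),
                      z = runif(n, r0, zmax),
                      a = r0 * q^(-1 / 3), c = r0 * q^(2 / 3),
                      state = state)
  sim_state(cells, r0_um = r0)
}

# shared driver: run one condition for each paired seed and collect metrics;
# the first replicate's final snapshot is kept for section rendering
run_condition <- function(name, spec, lp, fp, seeds, T_total_h,
                          snapshot_every_h, stem_spacing_um, bins,
                          keep = NULL) {
  do.call(rbind, lapply(seq_along(seeds), function(r) {
    traj <- simulate_epidermis(spec, lp = lp, fp = fp,
                               T_total_h = T_total_h,
                               snapshot_every_h = snapshot_every_h,
                               seed = seeds[r],
                               stem_spacing_um = stem_spacing_um)
    fin <- final_state(traj)
    if (r == 1 && is.environment(keep)) {
      keep$final_states[[name]] <- fin
      keep$specs[[name]] <- spec
    }
    cl <- count_layers(fin)
    tp <- thickness_profiles(fin, spec, bins = bins)
    data.frame(condition = name, replicate = r, seed = seeds[r],
               domain_x_um = spec$domain_x_um, domain_y_um = spec$domain_y_um,
               n_corneocytes = cl[["n_corneocytes"]],
               n_living = cl[["n_living"]],
               mean_living_thickness_um = tp$mean_living_thickness_um,
               mean_sc_thickness_um = tp$mean_sc_thickness_um,
               interface_roughness_um = tp$interface_roughness_um)
  }))
}

new_keep <- function() {
  env <- new.env()
  env$final_states <- list()
  env$specs <- list()
  env
}

#' Render one section image per condition of an experiment report
#'
#' @param ex an `epiderm_experiment` (from any experiment driver).
#' @param dir output directory for the PNG files.
#' @return invisibly, the written paths.
#' @export
render_experiment_sections <- function(ex, dir) {
  stopifnot(inherits(ex, "epiderm_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(ex$final_states)) {
    spec <- ex$specs[[nm]]
    path <- file.path(dir, paste0("section_", gsub("[^A-Za-z0-9]", "",
                                                   nm), ".png"))
    render_section(ex$final_states[[nm]], spec,
                   y0 = spec$domain_y_um / 2 - 5, slab_um = 10,
                   file = path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

summarise_conditions <- function(results) {
  metrics <- c("n_corneocytes", "n_living", "mean_living_thickness_um",
               "mean_sc_thickness_um", "interface_roughness_um")
  do.call(rbind, lapply(split(results, results$condition), function(d) {
    out <- data.frame(condition = d$condition[1], replicates = nrow(d))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- sd(d[[m]])
    }
    out
  }))
}

#' Flat versus sinusoidal membrane comparison
#'
#' Runs paired simulations (identical parameters, the same per-replicate
#' seeds in both conditions) on a flat membrane and a sinusoidal membrane —
#' by default amplitude 50 um and wavelength 100 um, matching the measured
#' human papillary geometry (rete ridge height 51 um, interval 105 um,
#' rounded) — and reports per-replicate stratum-corneum and living-layer
#' cell counts, their means, and the paired ordering sinusoidal > flat.
#'
#' @param replicates number of paired replicates (>= 3).
#' @param base_seed first seed; replicate r uses `base_seed + r - 1`.
#' @param amplitude_um,wavelength_um sinusoid geometry (um).
#' @param domain_um lateral domain extent (um). The default 100 um is a
#'   desk-scale domain (one-ninth the area of the full 300 um region of
#'   interest); pass `full_roi = TRUE` for the full extent.
#' @param full_roi run at the full 300 x 300 um region of interest.
#' @param T_total_h simulated hours per run.
#' @param snapshot_every_h snapshot interval (h).
#' @param stem_spacing_um stem lattice spacing (um).
#' @param bins lateral bins per axis for thickness profiles.
#' @param lp,fp lifecycle and force parameters.
#' @return list of class `epiderm_experiment` with `results` (one row per
#'   condition x replicate), `summary`, `wins` (number of paired replicates
#'   with sinusoidal > flat for each count), and the scale used.
#' @export
experiment_flat_vs_sinusoidal <- function(replicates = 5, base_seed = 1,
                                          amplitude_um = 50,
                                          wavelength_um = 100,
                                          domain_um = 100, full_roi = FALSE,
                                          T_total_h = 500,
                                          snapshot_every_h = 25,
                                          stem_spacing_um = 10, bins = 10,
                                          lp = lifecycle_params(),
                                          fp = force_params()) {
  if (replicates < 3) stop("replicates must be >= 3")
  if (full_roi) domain_um <- 300
  seeds <- base_seed + seq_len(replicates) - 1L
  flat <- membrane_spec("flat", domain_x_um = domain_um,
                        domain_y_um = domain_um)
  sinu <- membrane_spec("sinusoidal", amplitude_um = amplitude_um,
                        wavelength_um = wavelength_um,
                        domain_x_um = domain_um, domain_y_um = domain_um)
  keep <- new_keep()
  results <- rbind(
    run_condition("flat", flat, lp, fp, seeds, T_total_h,
                  snapshot_every_h, stem_spacing_um, bins, keep),
    run_condition("sinusoidal", sinu, lp, fp, seeds, T_total_h,
                  snapshot_every_h, stem_spacing_um, bins, keep))
  rownames(results) <- NULL
  f <- results[results$condition == "flat", ]
  s <- results[results$condition == "sinusoidal", ]
  wins <- c(n_corneocytes = sum(s$n_corneocytes > f$n_corneocytes),
            n_living = sum(s$n_living > f$n_living))
  structure(list(results = results, summary = summarise_conditions(results),
                 wins = wins, replicates = replicates,
                 domain_um = domain_um, full_roi = full_roi,
                 T_total_h = T_total_h, base_seed = base_seed,
                 final_states = keep$final_states, specs = keep$specs),
            class = "epiderm_experiment")
}

#' @export
print.epiderm_experiment <- function(x, ...) {
  cat("<epiderm_experiment>", nrow(x$summary), "conditions x",
      x$replicates, "replicates\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$wins))
    cat(sprintf("paired sinusoidal > flat: corneocytes %d/%d, living %d/%d\n",
                x$wins[["n_corneocytes"]], x$replicates,
                x$wins[["n_living"]], x$replicates))
  invisible(x)
}

# pick a lateral domain commensurate with the wavelength: the multiple of
# lambda nearest the target for lambda <= target, and lambda/2 above it
# (the product sinusoid tiles continuously, with a slope kink, at half
# periods)
sweep_domain <- function(wavelength_um, target_um) {
  if (wavelength_um <= target_um)
    wavelength_um * max(1, round(target_um / wavelength_um))
  else wavelength_um / 2
}

#' Amplitude/wavelength sweep of sinusoidal membranes
#'
#' Runs the simulator over a grid of sinusoid amplitudes and wavelengths
#' (amplitude 0 means a flat membrane) with paired per-replicate seeds, and
#' reports mean living-layer thickness and stratum-corneum count per
#' condition together with the Spearman rank correlations of thickness with
#' amplitude (expected positive) and with wavelength (expected negative).
#' Each condition's domain is snapped to a multiple of its wavelength near
#' `domain_um` and recorded in the table; thickness metrics are intensive,
#' so conditions remain comparable across domains.
#'
#' @param amplitudes,wavelengths numeric grids (um), at least 3 values each.
#' @param replicates runs per condition.
#' @param base_seed first seed of the paired-seed schedule.
#' @param domain_um target lateral extent (um).
#' @inheritParams experiment_flat_vs_sinusoidal
#' @return list of class `epiderm_experiment` with `results`, `table` (one
#'   row per (amplitude, wavelength) with replicate means and SD), and
#'   `spearman` (`rho_amplitude`, `rho_wavelength`).
#' @export
experiment_amplitude_wavelength_sweep <- function(amplitudes = c(10, 30, 50),
                                                  wavelengths = c(60, 100, 200),
                                                  replicates = 2,
                                                  base_seed = 1,
                                                  domain_um = 100,
                                                  T_total_h = 500,
                                                  snapshot_every_h = 50,
                                                  stem_spacing_um = 10,
                                                  bins = 10,
                                                  lp = lifecycle_params(),
                                                  fp = force_params()) {
  if (length(amplitudes) < 3 || length(wavelengths) < 3)
    stop("need at least 3 amplitudes and 3 wavelengths")
  seeds <- base_seed + seq_len(replicates) - 1L
  keep <- new_keep()
  grid <- expand.grid(amplitude_um = amplitudes, wavelength_um = wavelengths)
  results <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    A <- grid$amplitude_um[i]
    lam <- grid$wavelength_um[i]
    L <- sweep_domain(lam, domain_um)
    spec <- if (A == 0) {
      membrane_spec("flat", domain_x_um = L, domain_y_um = L)
    } else {
      membrane_spec("sinusoidal", amplitude_um = A, wavelength_um = lam,
                    domain_x_um = L, domain_y_um = L)
    }
    out <- run_condition(sprintf("A%g_L%g", A, lam), spec, lp, fp, seeds,
                         T_total_h, snapshot_every_h, stem_spacing_um, bins,
                         keep)
    out$amplitude_um <- A
    out$wavelength_um <- lam
    out
  }))
  rownames(results) <- NULL
  tab <- do.call(rbind, lapply(split(results, results$condition), function(d) {
    data.frame(amplitude_um = d$amplitude_um[1],
               wavelength_um = d$wavelength_um[1],
               domain_um = d$domain_x_um[1],
               mean_living_thickness_um = mean(d$mean_living_thickness_um),
               sd_living_thickness_um = sd(d$mean_living_thickness_um),
               mean_n_corneocytes = mean(d$n_corneocytes),
               sd_n_corneocytes = sd(d$n_corneocytes))
  }))
  tab <- tab[order(tab$amplitude_um, tab$wavelength_um), ]
  rownames(tab) <- NULL
  spearman <- c(
    rho_amplitude = cor(tab$amplitude_um, tab$mean_living_thickness_um,
                        method = "spearman"),
    rho_wavelength = cor(tab$wavelength_um, tab$mean_living_thickness_um,
                         method = "spearman"))
  structure(list(results = results, table = tab, spearman = spearman,
                 replicates = replicates, base_seed = base_seed,
                 summary = summarise_conditions(results),
                 final_states = keep$final_states, specs = keep$specs),
            class = "epiderm_experiment")
}

#' Textile substrate panel
#'
#' Runs fiber-grid simulations for a set of packaged textile presets plus a
#' flat control with paired seeds, compares stratum-corneum thickness of
#' each textile against the control by ANOVA with Tukey HSD, and reports a
#' thickness ranking. Per-preset domains are snapped to the fiber period;
#' thickness metrics are intensive so conditions remain comparable.
#'
#' @param presets character vector of preset names from [texture_presets()].
#' @param replicates runs per condition (>= 2 for the Tukey comparison).
#' @param base_seed first seed of the paired-seed schedule.
#' @param metric which replicate metric to compare across conditions.
#' @inheritParams experiment_flat_vs_sinusoidal
#' @return list of class `epiderm_experiment` with `results`, `summary`,
#'   `ranking` (condition names by decreasing mean of `metric`), and
#'   `comparison` (the [compare_conditions()] output).
#' @export
experiment_textile_panel <- function(presets = c("#200", "#255", "#300"),
                                     replicates = 3, base_seed = 1,
                                     domain_um = 100,
                                     metric = "mean_sc_thickness_um",
                                     T_total_h = 500,
                                     snapshot_every_h = 50,
                                     stem_spacing_um = 10, bins = 10,
                                     lp = lifecycle_params(),
                                     fp = force_params()) {
  tab <- texture_presets()
  unknown <- setdiff(presets, tab$name)
  if (length(unknown))
    stop("unknown preset(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(tab$name, collapse = ", "))
  seeds <- base_seed + seq_len(replicates) - 1L
  flat <- membrane_spec("flat", domain_x_um = domain_um,
                        domain_y_um = domain_um)
  keep <- new_keep()
  results <- run_condition("flat", flat, lp, fp, seeds, T_total_h,
                           snapshot_every_h, stem_spacing_um, bins, keep)
  for (nm in presets) {
    spec <- membrane_preset(nm, domain_um = domain_um)
    results <- rbind(results,
                     run_condition(nm, spec, lp, fp, seeds, T_total_h,
                                   snapshot_every_h, stem_spacing_um, bins,
                                   keep))
  }
  rownames(results) <- NULL
  summary <- summarise_conditions(results)
  means <- setNames(summary[[paste0(metric, "_mean")]], summary$condition)
  ranking <- names(sort(means, decreasing = TRUE))
  comparison <- if (replicates >= 2) {
    compare_conditions(data.frame(condition = results$condition,
                                  value = results[[metric]]))
  } else NULL
  structure(list(results = results, summary = summary, ranking = ranking,
                 comparison = comparison, metric = metric,
                 replicates = replicates, base_seed = base_seed,
                 final_states = keep$final_states, specs = keep$specs),
            class = "epiderm_experiment")
}
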