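#' Mechanical force and integration parameters
#'
#' Parameters of the overdamped center-based mechanics. The contact law is
#' linear repulsion below contact and linear adhesion up to `adh_range_um`
#' beyond contact; contact distances use direction-dependent ellipsoid radii
#' so flattened corneocytes stack into sheets. Forces are normalised by the
#' drag `gamma`, so the default stiffnesses are dimensionless-friendly.
#'
#' @param k_rep repulsion stiffness (force/um).
#' @param k_adh adhesion strength at contact (force).
#' @param adh_range_um adhesion cutoff beyond contact (um).
#' @param k_mem membrane repulsion stiffness (force/um).
#' @param k_anchor stem anchoring spring stiffness (force/um).
#' @param gamma drag coefficient (force h/um).
#' @param noise_amp random-motion amplitude (um h^-1/2); applied to
#'   proliferative, spinous and granular cells only.
#' @param dt_h integration timestep (h). A runtime guard aborts any step in
#'   which a cell would move more than half a cell radius.
#' @return an object of class `force_params`.
#' @export
force_params <- function(k_rep = 10, k_adh = 1, adh_range_um = 2,
                         k_mem = 20, k_anchor = 20, gamma = 1,
                         noise_amp = 0.2, dt_h = 0.02) {
  vals <- list(k_rep = k_rep, k_adh = k_adh, adh_range_um = adh_range_um,
               k_mem = k_mem, k_anchor = k_anchor, gamma = gamma,
               noise_amp = noise_amp, dt_h = dt_h)
  for (nm in c("k_rep", "k_adh", "k_mem", "k_anchor", "gamma", "dt_h"))
    if (!is.numeric(vals[[nm]]) || vals[[nm]] <= 0)
      stop(nm, " must be > 0")
  if (adh_range_um <= 0) stop("adh_range_um must be > 0")
  if (noise_amp < 0) stop("noise_amp must be >= 0")
  structure(lapply(vals, as.numeric), class = "force_params")
}

#' Keratinocyte lifecycle parameters
#'
#' Rates and durations of the per-cell stochastic state machine:
#' stem division (exponential clock, crowding-capped), positional
#' differentiation of proliferative cells once their clearance above the
#' membrane exceeds `diff_height_um`, exponential spinous and granular
#' residence clocks, volume-preserving corneocyte flattening toward
#' `target_aspect`, and desquamation of surface-exposed corneocytes.
#' These laws are conventional center-based reconstructions, not fitted
#' values; every default is overridable.
#'
#' @param division_period_h mean stem division interval (h).
#' @param division_jitter fractional jitter folded into the division rate.
#' @param crowding_cap division is suppressed while the number of neighbours
#'   within one cell diameter (2 r0) of the stem exceeds this count.
#' @param diff_height_um membrane clearance (um) above which a proliferative
#'   cell becomes spinous.
#' @param spinous_dur_h,granular_dur_h mean state residence times (h).
#' @param flatten_tau_h corneocyte flattening time constant (h).
#' @param target_aspect terminal corneocyte aspect ratio c/a (0 < value < 1).
#' @param desquam_dur_h mean corneocyte lifetime before shedding (h).
#' @param daughter_offset_um placement distance of a new daughter from the
#'   stem (um, at most one cell diameter).
#' @param r0_um intrinsic cell radius (um).
#' @param calcium_on enable the optional scalar calcium proxy, which scales
#'   the spinous-to-granular rate by the per-cell calcium level.
#' @param ca_tau_h relaxation time constant of the calcium proxy (h).
#' @return an object of class `lifecycle_params`.
#' @export
lifecycle_params <- function(division_period_h = 12, division_jitter = 0,
                             crowding_cap = 5, diff_height_um = 12,
                             spinous_dur_h = 24, granular_dur_h = 24,
                             flatten_tau_h = 6, target_aspect = 0.2,
                             desquam_dur_h = 16, daughter_offset_um = 5,
                             r0_um = 5, calcium_on = FALSE, ca_tau_h = 1) {
  for (v in list(division_period_h, spinous_dur_h, granular_dur_h,
                 flatten_tau_h, desquam_dur_h, diff_height_um, r0_um, ca_tau_h))
    if (!is.numeric(v) || v <= 0)
      stop("all lifecycle durations and lengths must be > 0")
  if (target_aspect <= 0 || target_aspect >= 1)
    stop("target_aspect must lie strictly between 0 and 1")
  if (daughter_offset_um <= 0 || daughter_offset_um > 2 * r0_um)
    stop("daughter_offset_um must be in (0, 2 * r0_um]")
  if (division_jitter < 0 || division_jitter >= 1)
    stop("division_jitter must be in [0, 1)")
  if (crowding_cap < 0) stop("crowding_cap must be >= 0")
  structure(list(division_period_h = as.numeric(division_period_h),
                 division_jitter = as.numeric(division_jitter),
                 crowding_cap = as.integer(crowding_cap),
                 diff_height_um = as.numeric(diff_height_um),
                 spinous_dur_h = as.numeric(spinous_dur_h),
                 granular_dur_h = as.numeric(granular_dur_h),
                 flatten_tau_h = as.numeric(flatten_tau_h),
                 target_aspect = as.numeric(target_aspect),
                 desquam_dur_h = as.numeric(desquam_dur_h),
                 daughter_offset_um = as.numeric(daughter_offset_um),
                 r0_um = as.numeric(r0_um),
                 calcium_on = isTRUE(calcium_on),
                 ca_tau_h = as.numeric(ca_tau_h)),
            class = "lifecycle_params")
}
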