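#' Wrap phase to (-pi, pi]
#'
#' @param x Phase in radians.
#' @return Wrapped phase.
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Vessel geometry specification
#'
#' @param center Numeric `c(x, y)` centre in mm.
#' @param radius Radius in mm (> 0).
#' @param peak_velocity Peak velocity in cm/s; may exceed venc to exercise
#'   phase aliasing.
#' @param profile `"uniform"` or `"parabolic"` (Poiseuille) velocity
#'   profile.
#' @param theta Vessel-to-main-field angle in radians (used by the
#'   oximetry cylinder model; default 0).
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(center, radius, peak_velocity,
                        profile = c("uniform", "parabolic"), theta = 0) {
  profile <- match.arg(profile)
  stopifnot(length(center) == 2, radius > 0)
  structure(list(center = center, radius = radius,
                 peak_velocity = peak_velocity, profile = profile,
                 theta = theta),
            class = "vessel_spec")
}

#' Image grid for phantom rasterization
#'
#' @param n Image size in pixels (n x n).
#' @param pixel_mm Pixel edge length in mm.
#' @return List of class `phantom_grid` with pixel-centre coordinate
#'   matrices `x`, `y` (mm, centred on 0) and `pixel_area_cm2`.
#' @export
phantom_grid <- function(n = 64, pixel_mm = 0.75) {
  stopifnot(n >= 4, pixel_mm > 0)
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  structure(list(n = as.integer(n), pixel_mm = pixel_mm,
                 x = matrix(ax, n, n), y = matrix(ax, n, n, byrow = TRUE),
                 pixel_area_cm2 = (pixel_mm / 10)^2),
            class = "phantom_grid")
}

#' Simulate a look-locker saturation-recovery series
#'
#' Evaluates the saturation-recovery readout model at every pulse index
#' and adds zero-mean Gaussian noise.
#'
#' @param r1_true True relaxation rate in 1/s (> 0).
#' @param s0 True equilibrium signal (> 0).
#' @param protocol An [look_locker_protocol()].
#' @param noise_sd Gaussian noise SD in signal units (>= 0).
#' @param seed RNG seed; fully determines the noisy output.
#' @return An [ll_series()] carrying a `ground_truth` attribute.
#' @export
gen_look_locker <- function(r1_true, s0, protocol = look_locker_protocol(),
                            noise_sd = 0, seed = 1) {
  if (r1_true <= 0 || s0 <= 0) stop("r1_true and s0 must be positive")
  stopifnot(noise_sd >= 0)
  n <- seq_len(protocol$n_phases)
  clean <- model_saturation_recovery(r1_true, s0, protocol, n)
  samples <- with_seed(seed, clean + rnorm(length(n), 0, noise_sd))
  out <- ll_series(samples, protocol)
  attr(out, "ground_truth") <- list(r1 = r1_true, s0 = s0, seed = seed)
  out
}

#' Simulate a background-suppressed pCASL control/label series
#'
#' Control images carry the background-suppression-attenuated equilibrium
#' magnetization (M0 times the recovery factor used by the calibration
#' inversion), labels differ from controls by the single-compartment
#' kinetic-model perfusion signal, and the calibration series is the
#' look-locker forward model per voxel — so the full quantification chain
#' (R1 fit, M0 calibration, kinetic inversion) round-trips to the true CBF.
#'
#' @param cbf_true Per-voxel true CBF in ml/100 g/min (>= 0).
#' @param m0_true Per-voxel true equilibrium magnetization (a.u.).
#' @param r1_tissue Per-voxel tissue relaxation rate in 1/s (recycled).
#' @param protocol A [pcasl_protocol()].
#' @param ll_protocol The calibration [look_locker_protocol()].
#' @param blood A `blood_properties` object (blood T1 of the simulation).
#' @param slice_index Per-voxel zero-based slice index (recycled).
#' @param noise_sd Gaussian noise SD added to control, label and
#'   calibration images (a.u.).
#' @param seed RNG seed.
#' @param lambda,alpha_eff Kinetic-model constants shared with
#'   [quantify_cbf()].
#' @return An [asl_series()] with a `ground_truth` attribute.
#' @export
gen_pcasl <- function(cbf_true, m0_true, r1_tissue = 0.77,
                      protocol = pcasl_protocol(),
                      ll_protocol = look_locker_protocol(),
                      blood = blood_properties(9.1, 0.44, 1.65),
                      slice_index = 0L, noise_sd = 0, seed = 1,
                      lambda = 0.9, alpha_eff = 0.85 * 0.95^2) {
  if (any(cbf_true < 0)) stop("cbf_true must be non-negative")
  if (length(m0_true) != length(cbf_true))
    stop("cbf_true and m0_true shapes differ")
  nvox <- length(cbf_true)
  r1_tissue <- rep_len(r1_tissue, nvox)
  slice_index <- rep_len(as.integer(slice_index), nvox)
  d <- bs_recovery_factor(r1_tissue, protocol, slice_index)
  ctrl_clean <- matrix(m0_true * d, nvox, protocol$n_pairs)
  dm <- kinetic_model_dm(cbf_true, m0_true, blood$t1_blood, protocol,
                         slice_index, lambda, alpha_eff)
  lab_clean <- ctrl_clean - dm
  calib_clean <- t(vapply(seq_len(nvox), function(v) {
    p <- ll_protocol
    p$slice_index <- slice_index[v]
    model_saturation_recovery(r1_tissue[v], m0_true[v], p,
                              seq_len(p$n_phases))
  }, numeric(ll_protocol$n_phases)))
  out <- with_seed(seed, {
    ctrl <- ctrl_clean + rnorm(length(ctrl_clean), 0, noise_sd)
    lab <- lab_clean + rnorm(length(lab_clean), 0, noise_sd)
    calib <- calib_clean + rnorm(length(calib_clean), 0, noise_sd)
    asl_series(ctrl, lab, calib, protocol, ll_protocol, slice_index)
  })
  attr(out, "ground_truth") <- list(cbf = cbf_true, m0 = m0_true,
                                    r1_tissue = r1_tissue,
                                    t1_blood = blood$t1_blood, seed = seed)
  out
}

# Rasterize vessel discs on a grid; errors on overlap. Returns a list of
# logical masks and the per-pixel true velocity field (cm/s).
rasterize_vessels <- function(vessels, grid) {
  velocity <- matrix(0, grid$n, grid$n)
  covered <- matrix(FALSE, grid$n, grid$n)
  masks <- vector("list", length(vessels))
  for (k in seq_along(vessels)) {
    vs <- vessels[[k]]
    r2 <- (grid$x - vs$center[1])^2 + (grid$y - vs$center[2])^2
    inside <- r2 <= vs$radius^2
    if (any(inside & covered)) stop("vessel discs overlap")
    covered <- covered | inside
    v <- if (vs$profile == "uniform") {
      vs$peak_velocity
    } else {
      vs$peak_velocity * (1 - r2[inside] / vs$radius^2)
    }
    velocity[inside] <- v
    masks[[k]] <- inside
  }
  list(masks = masks, velocity = velocity)
}

#' Simulate a velocity-encoded phase-contrast phantom
#'
#' Rasterizes cylindrical vessels (pixel-centre inclusion) on a grid, maps
#' in-vessel velocity to phase pi*v/venc wrapped to (-pi, pi], adds phase
#' noise, and records each vessel's discretized ground-truth flow (the sum
#' of pixel velocity times pixel area).
#'
#' @param vessels List of [vessel_spec()] objects (non-overlapping).
#' @param venc Velocity-encoding limit in cm/s (> 0).
#' @param grid A [phantom_grid()].
#' @param noise_sd Phase noise SD in radians.
#' @param seed RNG seed.
#' @return List of class `pcm_phantom`: `phase` (rad), `masks`,
#'   `velocity_true` (cm/s), `venc`, `pixel_area_cm2`, `ground_truth`
#'   (per-vessel `flow_ml_min`, `mean_velocity`, seed).
#' @export
gen_pcm_phantom <- function(vessels, venc = 100,
                            grid = phantom_grid(64, 0.75),
                            noise_sd = 0, seed = 1) {
  if (venc <= 0) stop("venc must be positive")
  if (inherits(vessels, "vessel_spec")) vessels <- list(vessels)
  ras <- rasterize_vessels(vessels, grid)
  phase_clean <- wrap_phase(pi * ras$velocity / venc)
  phase <- with_seed(seed,
    wrap_phase(phase_clean + rnorm(length(phase_clean), 0, noise_sd)))
  gt <- list(
    flow_ml_min = vapply(ras$masks, function(m)
      sum(ras$velocity[m]) * grid$pixel_area_cm2 * 60, numeric(1)),
    mean_velocity = vapply(ras$masks, function(m)
      mean(ras$velocity[m]), numeric(1)),
    seed = seed)
  structure(list(phase = phase, masks = ras$masks,
                 velocity_true = ras$velocity, venc = venc,
                 pixel_area_cm2 = grid$pixel_area_cm2, grid = grid,
                 ground_truth = gt),
            class = "pcm_phantom")
}

#' Simulate a dual-echo susceptibility-oximetry phantom
#'
#' A venous cylinder (the sagittal sinus) whose intravascular
#' susceptibility offset relative to tissue is
#' dchi = dchi_do * hct * (1 - svo2). The intravascular phase at each echo
#' is gamma * B0 * TE * (dchi/2) * (cos^2 theta - 1/3); extravascular
#' phase at the reference tissue ROI is zero. Gaussian phase noise is
#' added per echo.
#'
#' @param svo2_true True venous oxygen saturation fraction in `[0, 1]`.
#' @param hct Haematocrit fraction in (0, 1).
#' @param theta Vessel-to-field angle in radians (not the magic angle).
#' @param b0 Field strength in tesla (default 3).
#' @param te1,te2 Echo times in seconds (defaults 0.00816, 0.01783).
#' @param grid A [phantom_grid()].
#' @param sinus_radius_mm Sinus radius in mm (default 4).
#' @param noise_sd Phase noise SD in radians.
#' @param seed RNG seed.
#' @param dchi_do,gamma Susceptibility and gyromagnetic constants.
#' @return List of class `sbo_phantom`: `pair` (a [phase_echo_pair()]),
#'   `sinus_mask`, `tissue_mask`, `hct`, `ground_truth`.
#' @export
gen_sbo_phantom <- function(svo2_true, hct, theta = 0, b0 = 3,
                            te1 = 0.00816, te2 = 0.01783,
                            grid = phantom_grid(64, 0.69),
                            sinus_radius_mm = 4, noise_sd = 0, seed = 1,
                            dchi_do = nq_constants$dchi_do,
                            gamma = nq_constants$gamma) {
  stopifnot(svo2_true >= 0, svo2_true <= 1, hct > 0, hct < 1, te2 > te1)
  geom <- cos(theta)^2 - 1 / 3
  if (abs(geom) <= 1e-3)
    stop("degenerate geometry: vessel at the magic angle")
  r2 <- grid$x^2 + grid$y^2
  sinus <- r2 <= sinus_radius_mm^2
  tissue <- r2 > (2 * sinus_radius_mm)^2 & r2 <= (4 * sinus_radius_mm)^2
  dchi <- dchi_do * hct * (1 - svo2_true)
  ph <- function(te) ifelse(sinus, gamma * b0 * te * (dchi / 2) * geom, 0)
  pair <- with_seed(seed, phase_echo_pair(
    ph(te1) + rnorm(length(r2), 0, noise_sd),
    ph(te2) + rnorm(length(r2), 0, noise_sd),
    te1, te2, b0 = b0, theta = theta))
  structure(list(pair = pair, sinus_mask = sinus, tissue_mask = tissue,
                 hct = hct,
                 ground_truth = list(svo2 = svo2_true, hct = hct,
                                     dchi_ppm = dchi * 1e6, seed = seed)),
            class = "sbo_phantom")
}

#' Simulate a long-TE PRESS spectrum
#'
#' Frequency-domain spectrum with a residual-water Lorentzian at 4.70 ppm,
#' the NAA methyl singlet at 2.01 ppm, and the upright in-phase lactate
#' methyl doublet at 1.31 ppm (6.9 Hz splitting, equal component areas).
#' Line areas are concentration x proton count x exp(-TE/T2) times a
#' global scale; the unsuppressed-water reference area is emitted
#' alongside (water concentration from tissue fractions, 2 protons, water
#' T2 decay).
#'
#' @param conc Named vector `c(naa = , lactate = )` in mmol/l (>= 0).
#' @param tissue_fractions `c(gm, wm, csf)` summing to 1.
#' @param te Echo time in seconds (default 0.288).
#' @param linewidth Lorentzian FWHM in Hz (default 5, > 0).
#' @param noise_sd Gaussian noise SD added to both channels (a.u.).
#' @param seed RNG seed.
#' @param n_points Number of spectral points (default 1024).
#' @param sw_hz Spectral width in Hz (default 2000).
#' @param hz_per_ppm Hz per ppm (127.74 at 3 T).
#' @param t2s A [t2_table()].
#' @param scale Global amplitude scale (a.u.).
#' @param residual_water_frac Residual water area as a fraction of the
#'   unsuppressed reference (default 1e-5).
#' @return An [mrs_spectrum()] with a `ground_truth` attribute.
#' @export
gen_spectrum <- function(conc, tissue_fractions = c(0.6, 0.4, 0),
                         te = 0.288, linewidth = 5, noise_sd = 0, seed = 1,
                         n_points = 1024, sw_hz = 2000, hz_per_ppm = 127.74,
                         t2s = t2_table(), scale = 1,
                         residual_water_frac = 1e-5) {
  stopifnot(all(conc >= 0), all(c("naa", "lactate") %in% names(conc)))
  if (linewidth <= 0) stop("linewidth must be positive")
  if (abs(sum(tissue_fractions) - 1) > 1e-6)
    stop("tissue fractions must sum to 1")
  hw <- linewidth / 2
  df <- sw_hz / n_points
  f <- (seq_len(n_points) - n_points / 2) * df + 3.0 * hz_per_ppm
  ppm <- f / hz_per_ppm
  w_voxel <- voxel_water_concentration(tissue_fractions)
  water_ref <- scale * w_voxel * 2 * exp(-te / t2s$t2_h2o)
  a_naa <- scale * conc[["naa"]] * 3 * exp(-te / t2s$t2_naa)
  a_lac <- scale * conc[["lactate"]] * 3 * exp(-te / t2s$t2_lac)
  a_wres <- water_ref * residual_water_frac
  comp <- function(fn) {
    a_wres * fn(f, mrs_lines$water_ppm * hz_per_ppm, hw) +
      a_naa * fn(f, mrs_lines$naa_ppm * hz_per_ppm, hw) +
      a_lac / 2 * (fn(f, mrs_lines$lac_ppm * hz_per_ppm - mrs_lines$lac_j_hz / 2, hw) +
                   fn(f, mrs_lines$lac_ppm * hz_per_ppm + mrs_lines$lac_j_hz / 2, hw))
  }
  re_clean <- comp(lorentzian)
  im_clean <- comp(lorentzian_disp)
  out <- with_seed(seed, mrs_spectrum(
    ppm, re_clean + rnorm(n_points, 0, noise_sd),
    im_clean + rnorm(n_points, 0, noise_sd),
    te, water_ref, tissue_fractions, hz_per_ppm))
  attr(out, "ground_truth") <- list(conc = conc, scale = scale,
                                    linewidth = linewidth, seed = seed)
  out
}

#' Repeated-measures study design
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param session_lags Ordered session labels; the first is baseline.
#' @param grand_mean Population mean of the measurand.
#' @param between_sd Between-subject SD (>= 0).
#' @param within_sd Within-subject SD, scalar or one value per lag
#'   (>= 0; non-decreasing sequences emulate declining reproducibility).
#' @return An object of class `repeated_design`.
#' @export
repeated_design <- function(n_subjects, session_lags, grand_mean,
                            between_sd, within_sd) {
  stopifnot(n_subjects >= 2, length(session_lags) >= 2,
            between_sd >= 0, all(within_sd >= 0))
  within_sd <- rep_len(within_sd, length(session_lags))
  structure(list(n_subjects = as.integer(n_subjects),
                 session_lags = as.character(session_lags),
                 grand_mean = grand_mean, between_sd = between_sd,
                 within_sd = within_sd),
            class = "repeated_design")
}

#' Simulate a subject-by-session physiology table
#'
#' value(subject, lag) = subject_mean + within-noise(lag), with
#' subject_mean ~ Normal(grand_mean, between_sd) and within-noise(lag) ~
#' Normal(0, within_sd(lag)), independent across cells.
#'
#' @param design A [repeated_design()].
#' @param seed RNG seed.
#' @param measurand,units Metadata labels.
#' @return A [repeated_measures()] object with a `ground_truth` attribute.
#' @export
gen_repeated_physiology <- function(design, seed = 1,
                                    measurand = "measurand", units = "a.u.") {
  stopifnot(inherits(design, "repeated_design"))
  n <- design$n_subjects
  k <- length(design$session_lags)
  values <- with_seed(seed, {
    subj <- rnorm(n, design$grand_mean, design$between_sd)
    subj + matrix(rnorm(n * k), n, k) %*% diag(design$within_sd, k)
  })
  colnames(values) <- design$session_lags
  rownames(values) <- sprintf("S%02d", seq_len(n))
  out <- repeated_measures(values, measurand = measurand, units = units)
  attr(out, "ground_truth") <- list(design = design, seed = seed)
  out
}
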