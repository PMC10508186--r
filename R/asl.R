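#' Look-locker saturation-recovery series
#'
#' Container for one voxel's saturation-recovery readout.
#'
#' @param samples Numeric vector of readout signals, one per alpha pulse.
#' @param protocol An [look_locker_protocol()] object.
#' @return An object of class `ll_series`.
#' @export
ll_series <- function(samples, protocol) {
  stopifnot(inherits(protocol, "ll_protocol"),
            length(samples) == protocol$n_phases, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), protocol = protocol),
            class = "ll_series")
}

#' pCASL control/label series with calibration
#'
#' Voxels are stored flat: `control` and `label` are nvox x n_pairs
#' matrices, `calibration` an nvox x n_phases matrix of look-locker
#' samples, and `slice_index` gives each voxel's zero-based slice.
#'
#' @param control,label Numeric matrices, nvox x n_pairs.
#' @param calibration Numeric matrix, nvox x n_phases look-locker samples.
#' @param protocol A [pcasl_protocol()].
#' @param ll_protocol A [look_locker_protocol()] describing `calibration`.
#' @param slice_index Integer vector of per-voxel slice indices (recycled).
#' @return An object of class `asl_series`.
#' @export
asl_series <- function(control, label, calibration, protocol, ll_protocol,
                       slice_index = 0L) {
  control <- as.matrix(control); label <- as.matrix(label)
  calibration <- as.matrix(calibration)
  if (!identical(dim(control), dim(label)))
    stop("control and label dimensions differ")
  if (nrow(calibration) != nrow(control))
    stop("calibration voxel count does not match control/label images")
  stopifnot(inherits(protocol, "pcasl_protocol"),
            inherits(ll_protocol, "ll_protocol"),
            ncol(calibration) == ll_protocol$n_phases)
  structure(list(control = control, label = label, calibration = calibration,
                 protocol = protocol, ll_protocol = ll_protocol,
                 slice_index = rep_len(as.integer(slice_index), nrow(control))),
            class = "asl_series")
}

#' Saturation-recovery look-locker signal model
#'
#' Signal of the n-th readout pulse after saturation, for a train of
#' alpha-pulses every TR seconds starting TD seconds after saturation:
#' \deqn{S(n) = S_0 \sin\alpha \left[(1-e^{-TD\,R_1})(\cos\alpha\, e^{-TR\,R_1})^{n-1}
#'   + (1-e^{-TR\,R_1})\frac{1-(\cos\alpha\, e^{-TR\,R_1})^{n-1}}{1-\cos\alpha\, e^{-TR\,R_1}}\right]}
#'
#' @param r1 Longitudinal relaxation rate in 1/s (> 0).
#' @param s0 Equilibrium signal amplitude in arbitrary units.
#' @param protocol An [look_locker_protocol()].
#' @param n Pulse index (1-based), scalar or vector within 1..n_phases.
#' @return Model signal, same length as `n`.
#' @export
model_saturation_recovery <- function(r1, s0, protocol, n) {
  if (r1 <= 0) stop("r1 must be positive")
  stopifnot(all(n >= 1), all(n <= protocol$n_phases))
  a <- protocol$flip_angle * pi / 180
  td <- effective_td(protocol)
  e_tr <- exp(-protocol$tr * r1)
  q <- cos(a) * e_tr
  denom <- 1 - q
  stopifnot(denom > 0)  # guaranteed for flip < 90 deg, r1 > 0
  s0 * sin(a) * ((1 - exp(-td * r1)) * q^(n - 1) +
                 (1 - e_tr) * (1 - q^(n - 1)) / denom)
}

#' Fit R1 and S0 to a saturation-recovery series
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' [model_saturation_recovery()] to a look-locker series.
#'
#' @param series An [ll_series()].
#' @param init Optional numeric vector `c(r1, s0)` of starting values;
#'   defaults to r1 = 1 1/s and s0 = max(samples).
#' @return A list of class `r1_fit` with elements `r1`, `s0`,
#'   `residual_norm`, `converged`, `n_iterations`.
#' @export
fit_saturation_recovery <- function(series, init = NULL) {
  stopifnot(inherits(series, "ll_series"))
  y <- series$samples
  if (sum(is.finite(y)) < 3) stop("need at least 3 finite samples")
  if (all(y == 0)) stop("degenerate input: all-zero series")
  if (is.null(init)) init <- c(r1 = 1.0, s0 = max(y))
  n <- seq_len(series$protocol$n_phases)
  res_fn <- function(p) {
    y - model_saturation_recovery(max(p[1], 1e-8), p[2], series$protocol, n)
  }
  fit <- minpack.lm::nls.lm(
    par = c(r1 = unname(init[1]), s0 = unname(init[2])), fn = res_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 200))
  converged <- fit$info %in% 1:4 && fit$par[["r1"]] > 0 && fit$par[["s0"]] > 0
  structure(list(r1 = fit$par[["r1"]], s0 = fit$par[["s0"]],
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = converged, n_iterations = fit$niter),
            class = "r1_fit")
}

#' Background-suppression recovery factor of the control magnetization
#'
#' Longitudinal magnetization (as a fraction of M0) at readout, after
#' saturation at t = 0, relaxation to the first background-suppression
#' inversion at BS1, inversion, relaxation to BS2, a second inversion, and
#' relaxation until the readout delay TD:
#' \deqn{D = 1 - e^{-R_1(TD-BS_2)} + \left[-(1-e^{-R_1(BS_2-BS_1)})
#'   + (1-e^{-R_1 BS_1})e^{-R_1(BS_2-BS_1)}\right] e^{-R_1(TD-BS_2)}}
#' The mean of the early control images divided by D gives the calibrated
#' equilibrium magnetization M0.
#'
#' @param r1 Relaxation rate in 1/s (scalar or vector).
#' @param protocol A [pcasl_protocol()].
#' @param slice_index Zero-based slice index (recycled against `r1`).
#' @return D, same length as `r1`.
#' @export
bs_recovery_factor <- function(r1, protocol, slice_index = 0) {
  stopifnot(all(r1 > 0))
  td <- readout_td(protocol, slice_index)
  db <- protocol$bs2 - protocol$bs1
  e_tail <- exp(-r1 * (td - protocol$bs2))
  1 - e_tail + (-(1 - exp(-r1 * db)) +
                (1 - exp(-r1 * protocol$bs1)) * exp(-r1 * db)) * e_tail
}

#' Calibrated M0 from the initial pCASL control images
#'
#' Averages the first six control images per voxel and divides by the
#' background-suppression recovery factor [bs_recovery_factor()] evaluated
#' at each voxel's fitted R1 and slice timing.
#'
#' @param series An [asl_series()].
#' @param r1 Per-voxel relaxation rate vector (1/s); if missing, each
#'   voxel's calibration series is fitted with [fit_saturation_recovery()].
#' @param n_controls Number of leading control images to average (default 6).
#' @return List with `m0` (per-voxel), `valid` (logical mask; FALSE where
#'   the recovery factor is numerically degenerate), `r1` used.
#' @export
compute_m0 <- function(series, r1 = NULL, n_controls = 6) {
  stopifnot(inherits(series, "asl_series"))
  if (ncol(series$control) < n_controls)
    stop("need at least ", n_controls, " control images")
  if (is.null(r1)) {
    r1 <- apply(series$calibration, 1, function(s)
      fit_saturation_recovery(ll_series(s, series$ll_protocol))$r1)
  }
  stopifnot(length(r1) == nrow(series$control))
  d <- bs_recovery_factor(r1, series$protocol, series$slice_index)
  valid <- abs(d) >= 1e-6
  m0 <- rowMeans(series$control[, seq_len(n_controls), drop = FALSE])
  m0[valid] <- m0[valid] / d[valid]
  m0[!valid] <- NA_real_
  list(m0 = m0, valid = valid, r1 = r1)
}

#' Blood relaxation properties from haemoglobin concentration
#'
#' Converts haemoglobin concentration (mmol/l, haem-monomer convention) to
#' haematocrit, then to arterial blood T1 at 3 T via a linear relation
#' 1/T1b = c1 * Hct + c0.
#'
#' @param hgb Haemoglobin concentration in mmol/l.
#' @param c1,c0 Coefficients of the arterial Hct-to-R1 relation in 1/s
#'   (defaults 0.52 and 0.38).
#' @param hgb_to_hct Conversion from mmol/l monomer to haematocrit fraction
#'   (default 1.611 g/dl per mmol/l times 0.03 dl/g).
#' @return A list of class `blood_properties` with `hgb`, `hct`,
#'   `t1_blood` (s) and `clamped` flag.
#' @export
blood_t1_from_hgb <- function(hgb, c1 = 0.52, c0 = 0.38,
                              hgb_to_hct = 1.611 * 0.03) {
  stopifnot(hgb > 0)
  clamped <- FALSE
  if (hgb < 4 || hgb > 13) {
    warning("haemoglobin outside plausibility band (4, 13) mmol/l; clamped")
    hgb_used <- min(max(hgb, 4), 13)
    clamped <- TRUE
  } else hgb_used <- hgb
  hct <- hgb_used * hgb_to_hct
  t1 <- 1 / (c1 * hct + c0)
  structure(list(hgb = hgb, hct = hct, t1_blood = t1, clamped = clamped),
            class = "blood_properties")
}

#' Construct blood properties directly
#'
#' @param hgb Haemoglobin in mmol/l; @param hct haematocrit fraction;
#' @param t1_blood blood T1 in seconds.
#' @return A `blood_properties` list.
#' @export
blood_properties <- function(hgb, hct, t1_blood) {
  stopifnot(hgb > 0, hct > 0, hct < 1, t1_blood > 0.5, t1_blood < 3.5)
  structure(list(hgb = hgb, hct = hct, t1_blood = t1_blood, clamped = FALSE),
            class = "blood_properties")
}

#' Single-compartment kinetic-model perfusion difference signal
#'
#' Label-minus-control magnetization difference for a pCASL bolus of
#' duration tau read out at post-labelling delay pld (post-bolus regime),
#' used both to simulate and to invert perfusion-weighted data.
#'
#' @param cbf Perfusion in ml/100 g/min.
#' @param m0 Equilibrium magnetization (a.u.).
#' @param t1_blood Blood T1 in s.
#' @param protocol A [pcasl_protocol()].
#' @param slice_index Zero-based slice index for the per-slice PLD.
#' @param lambda Blood-brain partition coefficient in ml/g (default 0.9).
#' @param alpha_eff Effective labelling efficiency, inversion times
#'   background-suppression losses (default 0.85 * 0.95^2).
#' @return Difference signal, same shape as `cbf`.
#' @export
kinetic_model_dm <- function(cbf, m0, t1_blood, protocol, slice_index = 0,
                             lambda = 0.9, alpha_eff = 0.85 * 0.95^2) {
  pld_i <- protocol$pld + protocol$slice_dt * slice_index
  cbf * 2 * alpha_eff * t1_blood * m0 *
    (1 - exp(-protocol$tau / t1_blood)) * exp(-pld_i / t1_blood) /
    (6000 * lambda)
}

#' Quantitative CBF map from a pCASL series
#'
#' Averages the control-minus-label difference over pairs and inverts the
#' single-compartment kinetic model:
#' \deqn{CBF = \frac{6000\,\lambda\,\Delta M\, e^{PLD_i/T_{1b}}}
#'   {2\,\alpha_{eff}\,T_{1b}\,M_0\,(1-e^{-\tau/T_{1b}})}}
#' in ml/100 g/min, with the post-labelling delay corrected per slice.
#'
#' @param series An [asl_series()].
#' @param m0 Per-voxel calibrated M0 (from [compute_m0()]).
#' @param blood A `blood_properties` object supplying T1 of blood.
#' @param lambda Partition coefficient in ml/g (default 0.9).
#' @param alpha_eff Effective labelling efficiency (default 0.85 * 0.95^2).
#' @return A list of class `cbf_map` with `cbf` (per voxel), `valid` mask.
#' @export
quantify_cbf <- function(series, m0, blood, lambda = 0.9,
                         alpha_eff = 0.85 * 0.95^2) {
  stopifnot(inherits(series, "asl_series"), inherits(blood, "blood_properties"))
  stopifnot(length(m0) == nrow(series$control))
  dm <- rowMeans(series$control - series$label)
  valid <- is.finite(m0) & m0 > 0
  t1b <- blood$t1_blood
  pld_i <- series$protocol$pld + series$protocol$slice_dt * series$slice_index
  cbf <- rep(NA_real_, length(m0))
  cbf[valid] <- 6000 * lambda * dm[valid] * exp(pld_i[valid] / t1b) /
    (2 * alpha_eff * t1b * m0[valid] *
       (1 - exp(-series$protocol$tau / t1b)))
  structure(list(cbf = cbf, valid = valid), class = "cbf_map")
}

#' Grey-matter mean CBF
#'
#' Mean CBF over voxels whose grey-matter partial volume meets the
#' threshold and that carry a valid quantification.
#'
#' @param cbf A `cbf_map` from [quantify_cbf()].
#' @param gm_fraction Per-voxel grey-matter fraction in `[0, 1]`.
#' @param threshold Inclusion threshold on the fraction (default 0.8).
#' @return Mean CBF in ml/100 g/min.
#' @export
gm_mean_cbf <- function(cbf, gm_fraction, threshold = 0.8) {
  stopifnot(inherits(cbf, "cbf_map"), all(gm_fraction >= 0),
            all(gm_fraction <= 1), length(gm_fraction) == length(cbf$cbf))
  sel <- cbf$valid & gm_fraction >= threshold
  if (!any(sel)) stop("empty grey-matter selection")
  m <- mean(cbf$cbf[sel])
  if (m < 0) warning("negative grey-matter mean CBF")
  m
}
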