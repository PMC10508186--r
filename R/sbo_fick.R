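#' Dual-echo phase image pair
#'
#' @param phase_echo1,phase_echo2 Phase images (rad), same shape.
#' @param te1,te2 Echo times in seconds, te2 > te1 > 0.
#' @param b0 Main field strength in tesla (default 3).
#' @param theta Vessel-to-field angle in radians (default 0; the imaging
#'   plane is placed orthogonal to the sagittal sinus).
#' @return An object of class `phase_echo_pair`.
#' @export
phase_echo_pair <- function(phase_echo1, phase_echo2, te1, te2, b0 = 3,
                            theta = 0) {
  stopifnot(te1 > 0, te2 > te1, length(phase_echo1) == length(phase_echo2),
            all(is.finite(phase_echo1)), all(is.finite(phase_echo2)))
  structure(list(phase_echo1 = phase_echo1, phase_echo2 = phase_echo2,
                 te1 = te1, te2 = te2, b0 = b0, theta = theta),
            class = "phase_echo_pair")
}

#' Inter-echo vessel-minus-tissue phase difference
#'
#' Computes (mean sinus phase - mean tissue phase) at each echo and takes
#' the difference between echoes. Phase terms constant in echo time (coil
#' and static B0 offsets) cancel exactly; what remains is the
#' susceptibility-induced accrual over dte = te2 - te1.
#'
#' @param pair A [phase_echo_pair()].
#' @param sinus_mask,tissue_mask Logical masks, nonempty and disjoint.
#' @return List with `dphi` (rad) and `dte` (s).
#' @export
interecho_phase_difference <- function(pair, sinus_mask, tissue_mask) {
  stopifnot(inherits(pair, "phase_echo_pair"))
  sinus_mask <- as.logical(sinus_mask); tissue_mask <- as.logical(tissue_mask)
  if (!any(sinus_mask) || !any(tissue_mask)) stop("empty mask")
  if (any(sinus_mask & tissue_mask)) stop("sinus and tissue masks overlap")
  d_at <- function(ph) mean(ph[sinus_mask]) - mean(ph[tissue_mask])
  list(dphi = d_at(pair$phase_echo2) - d_at(pair$phase_echo1),
       dte = pair$te2 - pair$te1)
}

#' Venous oxygen saturation from the susceptibility phase shift
#'
#' Long-cylinder model: a vessel at angle theta to the main field with
#' intravascular susceptibility offset dchi relative to surrounding tissue
#' accrues intravascular phase \eqn{\gamma B_0 TE (\Delta\chi/2)(\cos^2\theta - 1/3)}.
#' Inverting the inter-echo difference gives
#' \deqn{\Delta\chi = \frac{2\,\Delta\phi}{\gamma B_0\,\Delta TE\,(\cos^2\theta - 1/3)}}
#' and, with the fully-deoxygenated susceptibility per unit haematocrit
#' dchi_do, \deqn{SvO_2 = 1 - \Delta\chi/(\Delta\chi_{do}\,Hct).}
#'
#' @param dphi Inter-echo vessel-minus-tissue phase difference (rad).
#' @param dte Echo-time difference in seconds.
#' @param hct Haematocrit fraction in (0, 1).
#' @param b0 Field strength in tesla (default 3).
#' @param theta Vessel-to-field angle in radians (default 0).
#' @param sao2 Optional arterial saturation fraction; when given, the
#'   arteriovenous difference avo2 = sao2 - svo2 is filled in.
#' @param dchi_do Susceptibility of fully deoxygenated blood per unit Hct,
#'   SI (default 4 * pi * 0.27e-6).
#' @param gamma Proton gyromagnetic ratio in rad/s/T.
#' @return A list of class `oximetry_result` with `svo2`, `sao2`, `avo2`
#'   (fractions), `delta_chi_ppm`, `out_of_range` flag, `dphi`, `dte`.
#' @export
svo2_from_phase <- function(dphi, dte, hct, b0 = 3, theta = 0, sao2 = NULL,
                            dchi_do = nq_constants$dchi_do,
                            gamma = nq_constants$gamma) {
  stopifnot(hct > 0, hct < 1, dte > 0, b0 > 0)
  geom <- cos(theta)^2 - 1 / 3
  if (abs(geom) <= 1e-3)
    stop("degenerate geometry: vessel at the magic angle")
  dchi <- 2 * dphi / (gamma * b0 * dte * geom)
  svo2 <- 1 - dchi / (dchi_do * hct)
  out_of_range <- svo2 < -0.05 || svo2 > 1.05
  if (out_of_range) warning("implausible SvO2 before clamping: ",
                            signif(svo2, 4))
  svo2 <- min(max(svo2, 0), 1)
  avo2 <- if (is.null(sao2)) NA_real_ else sao2 - svo2
  structure(list(svo2 = svo2, sao2 = if (is.null(sao2)) NA_real_ else sao2,
                 avo2 = avo2, delta_chi_ppm = dchi * 1e6,
                 out_of_range = out_of_range, dphi = dphi, dte = dte),
            class = "oximetry_result")
}

#' Fick-principle cerebral metabolic rate of oxygen
#'
#' CMRO2 = Hgb * CBF * A-V.O2 with haemoglobin in mmol/l (haem-monomer
#' convention: one mole of haem binds one mole of O2, so mmol/l of monomer
#' is umol/ml of O2 capacity), CBF in ml/100 g/min and the arteriovenous
#' saturation difference as a fraction.
#'
#' @param hgb Haemoglobin concentration in mmol/l.
#' @param cbf Cerebral blood flow in ml/100 g/min.
#' @param avo2 Arteriovenous oxygen saturation difference as a fraction.
#' @return CMRO2 in umol/100 g/min.
#' @export
fick_cmro2 <- function(hgb, cbf, avo2) {
  stopifnot(hgb >= 0, cbf >= 0, avo2 >= 0)
  hgb * cbf * avo2
}

#' Sagittal-sinus volumetric flow
#'
#' The oximetry sequence also velocity-encodes the sinus; flow is computed
#' exactly as for the feeding arteries.
#'
#' @param vel A `velocity_image` (venc 100 cm/s in the acquisition).
#' @param sinus_mask Logical sinus ROI.
#' @return A `flow_result` labelled "sagittal sinus".
#' @export
sinus_flow <- function(vel, sinus_mask) {
  vessel_flow(vel, sinus_mask, label = "sagittal sinus")
}
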