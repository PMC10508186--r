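#' Default pipeline configuration
#'
#' One configuration object governs both the phantom simulation and the
#' quantification so physical constants cannot silently diverge between
#' the forward and inverse models. Per-stage overrides (e.g., quantifying
#' with a deliberately wrong partition coefficient) can be made by editing
#' the returned list before passing it on.
#'
#' @param n_asl_voxels Number of grey-matter voxels simulated for ASL.
#' @param brain_volume_ml Parenchymal (GM+WM) volume in ml.
#' @param density Brain density in g/ml (default 1.05).
#' @param mrs_fractions Spectroscopy-voxel tissue fractions (gm, wm, csf).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(n_asl_voxels = 12, brain_volume_ml = 1200,
                               density = 1.05,
                               mrs_fractions = c(0.6, 0.4, 0)) {
  structure(list(
    ll_protocol = look_locker_protocol(),
    pcasl_protocol = pcasl_protocol(),
    t2s = t2_table(),
    lambda = 0.9,
    alpha_eff = 0.85 * 0.95^2,
    gm_threshold = 0.8,
    n_asl_voxels = as.integer(n_asl_voxels),
    asl_m0 = 1000,
    r1_tissue = 0.77,
    brain_volume_ml = brain_volume_ml,
    density = density,
    venc = 100,
    pcm_grid = phantom_grid(64, 0.75),
    sbo_grid = phantom_grid(64, 0.69),
    sinus_grid = phantom_grid(48, 0.69),
    b0 = 3,
    te1 = 0.00816, te2 = 0.01783,
    theta = 0,
    mrs_fractions = mrs_fractions,
    mrs_linewidth = 5,
    dchi_do = nq_constants$dchi_do,
    gamma = nq_constants$gamma), class = "run_config")
}

#' Ground-truth bundle for one synthetic session
#'
#' Defaults follow the baseline physiology of a young healthy adult:
#' global CBF near 57.5 ml/100 g/min, grey-matter ASL CBF near 59,
#' SaO2 97.5%, SvO2 68.8% (so A-V.O2 is 28.7 percentage points),
#' haemoglobin 9.1 mmol/l, NAA 10.1 and lactate 0.51 mmol/l.
#'
#' @param cbf_pcm Global CBF in ml/100 g/min.
#' @param cbf_asl Grey-matter CBF in ml/100 g/min.
#' @param sao2,svo2 Arterial and venous saturation fractions.
#' @param hgb Haemoglobin in mmol/l.
#' @param sinus_flow Sagittal-sinus flow in ml/min.
#' @param naa,lactate Metabolite concentrations in mmol/l.
#' @return A list of class `session_truth`; `avo2` and `cmro2` are derived
#'   (cmro2 uses the Fick product of the bundle's own values).
#' @export
session_truth <- function(cbf_pcm = 57.5, cbf_asl = 59.2, sao2 = 0.975,
                          svo2 = 0.688, hgb = 9.1, sinus_flow = 350,
                          naa = 10.1, lactate = 0.51) {
  avo2 <- sao2 - svo2
  structure(list(cbf_pcm = cbf_pcm, cbf_asl = cbf_asl, sao2 = sao2,
                 svo2 = svo2, avo2 = avo2, hgb = hgb,
                 sinus_flow = sinus_flow, naa = naa, lactate = lactate,
                 cmro2 = fick_cmro2(hgb, cbf_pcm, avo2)),
            class = "session_truth")
}

# Build non-overlapping artery specs whose discretized uniform-profile
# flow sums exactly to target_flow ml/min on the given grid.
arteries_for_flow <- function(target_flow, grid, radii_mm = c(2.5, 2.5, 1.6)) {
  centers <- list(c(-8, 0), c(8, 0), c(0, 10))
  probe <- lapply(seq_along(radii_mm), function(k)
    vessel_spec(centers[[k]], radii_mm[k], 1, "uniform"))
  npix <- vapply(rasterize_vessels(probe, grid)$masks, sum, integer(1))
  v <- target_flow / (sum(npix) * grid$pixel_area_cm2 * 60)
  lapply(seq_along(radii_mm), function(k)
    vessel_spec(centers[[k]], radii_mm[k], v, "uniform"))
}

#' Run one synthetic session end-to-end
#'
#' Generates every phantom input from a ground-truth bundle, runs the ASL,
#' phase-contrast, oximetry and spectroscopy quantification stages, and
#' assembles a one-row session physiology table. A failing stage flags its
#' fields and never aborts the remaining stages. Deterministic per seed.
#'
#' @param config A [default_run_config()] list.
#' @param truth A [session_truth()] bundle.
#' @param noise Named list of per-stage noise SDs
#'   (`asl` a.u., `pcm` rad, `sbo` rad, `mrs` a.u.), default all 0.
#' @param seed Integer seed; per-stage seeds are derived from it.
#' @param subject,lag Row labels.
#' @param fail_stages Character vector of stage names (`"asl"`, `"pcm"`,
#'   `"sbo"`, `"mrs"`) whose failure is injected, for testing degradation.
#' @return One-row data frame (class `session_physiology`) with columns
#'   subject, lag, cbf_pcm, cbf_asl_gm, svo2, sao2, avo2, cmro2,
#'   sinus_flow, hgb, naa, lactate, qc (comma-joined failed stages).
#' @export
run_session <- function(config = default_run_config(),
                        truth = session_truth(),
                        noise = list(asl = 0, pcm = 0, sbo = 0, mrs = 0),
                        seed = 1, subject = "S01", lag = "baseline",
                        fail_stages = character()) {
  stopifnot(inherits(config, "run_config"), inherits(truth, "session_truth"))
  noise <- utils::modifyList(list(asl = 0, pcm = 0, sbo = 0, mrs = 0), noise)
  qc <- character()
  blood <- blood_t1_from_hgb(truth$hgb)
  row <- data.frame(subject = subject, lag = lag, cbf_pcm = NA_real_,
                    cbf_asl_gm = NA_real_, svo2 = NA_real_,
                    sao2 = truth$sao2, avo2 = NA_real_, cmro2 = NA_real_,
                    sinus_flow = NA_real_, hgb = truth$hgb,
                    naa = NA_real_, lactate = NA_real_, qc = "",
                    stringsAsFactors = FALSE)

  stage <- function(name, expr) {
    if (name %in% fail_stages) {
      qc <<- c(qc, name)
      return(NULL)
    }
    tryCatch(expr, error = function(e) { qc <<- c(qc, name); NULL })
  }

  asl <- stage("asl", {
    nv <- config$n_asl_voxels
    series <- gen_pcasl(rep(truth$cbf_asl, nv), rep(config$asl_m0, nv),
                        r1_tissue = config$r1_tissue,
                        protocol = config$pcasl_protocol,
                        ll_protocol = config$ll_protocol, blood = blood,
                        noise_sd = noise$asl, seed = seed + 11L,
                        lambda = config$lambda, alpha_eff = config$alpha_eff)
    cal <- compute_m0(series)
    cbf <- quantify_cbf(series, cal$m0, blood, lambda = config$lambda,
                        alpha_eff = config$alpha_eff)
    gm_mean_cbf(cbf, rep(1, nv), config$gm_threshold)
  })
  if (!is.null(asl)) row$cbf_asl_gm <- asl

  pcm <- stage("pcm", {
    brain <- brain_weight(config$brain_volume_ml, config$density)
    target <- truth$cbf_pcm * brain$weight / 100
    vessels <- arteries_for_flow(target, config$pcm_grid)
    ph <- gen_pcm_phantom(vessels, venc = config$venc,
                          grid = config$pcm_grid, noise_sd = noise$pcm,
                          seed = seed + 23L)
    vel <- decode_velocity(ph$phase, ph$venc, ph$pixel_area_cm2)
    flows <- lapply(ph$masks, function(m) vessel_flow(vel, m))
    total_cbf(flows, brain)
  })
  if (!is.null(pcm)) row$cbf_pcm <- pcm

  sbo <- stage("sbo", {
    phan <- gen_sbo_phantom(truth$svo2, blood$hct, theta = config$theta,
                            b0 = config$b0, te1 = config$te1,
                            te2 = config$te2, grid = config$sbo_grid,
                            noise_sd = noise$sbo, seed = seed + 37L,
                            dchi_do = config$dchi_do, gamma = config$gamma)
    dp <- interecho_phase_difference(phan$pair, phan$sinus_mask,
                                     phan$tissue_mask)
    ox <- svo2_from_phase(dp$dphi, dp$dte, blood$hct, b0 = config$b0,
                          theta = config$theta, sao2 = truth$sao2,
                          dchi_do = config$dchi_do, gamma = config$gamma)
    sin_spec <- arteries_for_flow(truth$sinus_flow, config$sinus_grid,
                                  radii_mm = 3.5)
    sph <- gen_pcm_phantom(sin_spec, venc = config$venc,
                           grid = config$sinus_grid, noise_sd = noise$sbo,
                           seed = seed + 41L)
    svel <- decode_velocity(sph$phase, sph$venc, sph$pixel_area_cm2)
    list(ox = ox, sinus = sinus_flow(svel, sph$masks[[1]]))
  })
  if (!is.null(sbo)) {
    row$svo2 <- sbo$ox$svo2
    row$avo2 <- sbo$ox$avo2
    row$sinus_flow <- sbo$sinus$flow
    if (!is.na(row$cbf_pcm))
      row$cmro2 <- fick_cmro2(truth$hgb, row$cbf_pcm, row$avo2)
  }

  mrs <- stage("mrs", {
    spec <- gen_spectrum(c(naa = truth$naa, lactate = truth$lactate),
                         tissue_fractions = config$mrs_fractions,
                         linewidth = config$mrs_linewidth,
                         noise_sd = noise$mrs, seed = seed + 53L,
                         t2s = config$t2s)
    quantify_spectrum(spec, config$t2s,
                      linewidth_init = config$mrs_linewidth)
  })
  if (!is.null(mrs)) {
    row$naa <- mrs$naa$concentration
    row$lactate <- mrs$lactate$concentration
  }

  row$qc <- paste(qc, collapse = ",")
  # internal consistency: the emitted CMRO2 is the Fick product of the
  # emitted Hgb, PCM CBF and A-V.O2, whenever all three are present
  if (!is.na(row$cmro2))
    stopifnot(isTRUE(all.equal(row$cmro2,
                               fick_cmro2(row$hgb, row$cbf_pcm, row$avo2))))
  class(row) <- c("session_physiology", class(row))
  row
}

#' Run a multi-session cohort to a reproducibility report
#'
#' For each measurand's repeated-measures design, simulates the
#' subject-by-session table, summarises per-session means and SDs, and
#' assembles the baseline-versus-lag reproducibility table.
#'
#' @param designs Named list of [repeated_design()] objects, one per
#'   measurand.
#' @param seed Integer seed; each measurand uses a derived seed.
#' @return List with `session_summary` (measurand, session, mean, sd, n)
#'   and `repro_table` (one row per measurand and lag).
#' @export
run_cohort <- function(designs, seed = 1) {
  stopifnot(is.list(designs), length(designs) >= 1,
            !is.null(names(designs)))
  summaries <- list(); tables <- list()
  for (k in seq_along(designs)) {
    rm_k <- gen_repeated_physiology(designs[[k]], seed = seed + 101L * k,
                                    measurand = names(designs)[k])
    v <- rm_k$values
    summaries[[k]] <- data.frame(
      measurand = names(designs)[k], session = colnames(v),
      mean = colMeans(v, na.rm = TRUE),
      sd = apply(v, 2, stats::sd, na.rm = TRUE),
      n = colSums(is.finite(v)), row.names = NULL,
      stringsAsFactors = FALSE)
    tables[[k]] <- build_repro_table(rm_k)
  }
  list(session_summary = do.call(rbind, summaries),
       repro_table = do.call(rbind, tables))
}
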