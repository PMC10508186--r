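#' Physical constants used throughout the package
#'
#' Proton gyromagnetic ratio (rad/s/T), fully-deoxygenated blood
#' susceptibility per unit haematocrit (SI, dimensionless), and pure-water
#' molarity (mmol/l). All are configurable at the call sites that use them;
#' these are the package defaults.
#' @format Named list with elements `gamma`, `dchi_do`, `water_molarity`.
#' @export
nq_constants <- list(
  gamma         = 2.6751525e8,     # rad/s/T
  dchi_do       = 4 * pi * 0.27e-6, # per unit Hct, SI volume susceptibility
  water_molarity = 55510            # mmol/l
)

#' Look-locker saturation-recovery protocol
#'
#' Timing of the 16-phase look-locker readout used to fit R1: an initial
#' saturation delay `td0`, repeated small-flip-angle pulses every `tr`
#' seconds, and a per-slice acquisition offset so the effective saturation
#' delay for slice i is `td0 + slice_dt * slice_index`.
#'
#' @param td0 Initial saturation delay in seconds (default 0.05).
#' @param tr Interval between consecutive alpha pulses in seconds (default 0.52).
#' @param flip_angle Readout flip angle alpha in degrees (default 30).
#' @param n_phases Number of readout pulses (default 16).
#' @param slice_dt Slice timing difference in seconds (default 0.032).
#' @param slice_index Zero-based slice index (default 0).
#' @return An object of class `ll_protocol`.
#' @export
look_locker_protocol <- function(td0 = 0.05, tr = 0.52, flip_angle = 30,
                                 n_phases = 16, slice_dt = 0.032,
                                 slice_index = 0) {
  stopifnot(flip_angle > 0, flip_angle < 90, tr > 0, n_phases >= 2,
            td0 + slice_dt * slice_index > 0)
  structure(list(td0 = td0, tr = tr, flip_angle = flip_angle,
                 n_phases = as.integer(n_phases), slice_dt = slice_dt,
                 slice_index = as.integer(slice_index)),
            class = "ll_protocol")
}

#' Effective saturation delay of a look-locker protocol
#'
#' @param protocol An `ll_protocol`.
#' @return Slice-timing-corrected saturation delay in seconds.
#' @export
effective_td <- function(protocol) {
  protocol$td0 + protocol$slice_dt * protocol$slice_index
}

#' pCASL acquisition protocol
#'
#' Labelling/readout timing of the background-suppressed pCASL sequence.
#' The readout delay after the saturation that starts the magnetization
#' history is `base_td + slice_dt * slice_index` per slice.
#'
#' @param tau Labelling duration in seconds (default 1.8).
#' @param pld Post-labelling delay in seconds (default 1.8).
#' @param slice_dt Per-slice acquisition time in seconds (default 0.032).
#' @param bs1,bs2 Background-suppression inversion times in seconds after
#'   saturation (defaults 1.813 and 3.135).
#' @param n_pairs Number of label/control pairs (default 30).
#' @param base_td Readout delay of slice 0 in seconds (default 3.6).
#' @return An object of class `pcasl_protocol`.
#' @export
pcasl_protocol <- function(tau = 1.8, pld = 1.8, slice_dt = 0.032,
                           bs1 = 1.813, bs2 = 3.135, n_pairs = 30,
                           base_td = 3.6) {
  stopifnot(tau > 0, pld > 0, bs1 > 0, bs2 > bs1, base_td > bs2, n_pairs >= 1)
  structure(list(tau = tau, pld = pld, slice_dt = slice_dt, bs1 = bs1,
                 bs2 = bs2, n_pairs = as.integer(n_pairs), base_td = base_td),
            class = "pcasl_protocol")
}

#' Readout delay after saturation for a given slice
#'
#' @param protocol A `pcasl_protocol`.
#' @param slice_index Zero-based slice index (scalar or vector).
#' @return Readout delay in seconds.
#' @export
readout_td <- function(protocol, slice_index = 0) {
  protocol$base_td + protocol$slice_dt * slice_index
}

#' Metabolite and water T2 relaxation times
#'
#' Literature transverse relaxation times used for the T2-decay correction
#' of long-TE spectra, in seconds.
#'
#' @param t2_h2o Tissue water T2 (default 0.095).
#' @param t2_naa NAA methyl T2 (default 0.247).
#' @param t2_lac Lactate methyl T2 (default 0.240).
#' @return An object of class `t2_table`.
#' @export
t2_table <- function(t2_h2o = 0.095, t2_naa = 0.247, t2_lac = 0.240) {
  stopifnot(t2_h2o > 0, t2_naa > 0, t2_lac > 0)
  structure(list(t2_h2o = t2_h2o, t2_naa = t2_naa, t2_lac = t2_lac),
            class = "t2_table")
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
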