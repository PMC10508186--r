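#' Decode a velocity-encoded phase image
#'
#' Maps phase to velocity linearly, velocity = phase/pi * venc. Pixels at
#' the edge of the phase range are flagged as aliasing-suspected: a true
#' velocity beyond venc wraps into the range and cannot be distinguished
#' from a slow flow of opposite sign. Wrapped values are flagged, never
#' unwrapped.
#'
#' @param phase Phase image in radians, values in (-pi, pi].
#' @param venc Velocity-encoding limit in cm/s (> 0).
#' @param pixel_area Pixel area in cm^2.
#' @param n_dynamics Number of dynamics averaged upstream (metadata).
#' @param wrap_tol Phase margin (rad) within which a pixel is treated as
#'   potentially wrapped (default 1e-6).
#' @return A list of class `velocity_image` with `velocity` (cm/s),
#'   `venc`, `pixel_area`, `aliasing` (logical, same shape), `n_dynamics`.
#' @export
decode_velocity <- function(phase, venc, pixel_area, n_dynamics = 10L,
                            wrap_tol = 1e-6) {
  if (venc <= 0) stop("venc must be positive")
  stopifnot(pixel_area > 0, all(phase > -pi - 1e-12), all(phase <= pi + 1e-12))
  v <- phase / pi * venc
  structure(list(velocity = v, venc = venc, pixel_area = pixel_area,
                 aliasing = abs(phase) >= pi - wrap_tol,
                 n_dynamics = as.integer(n_dynamics)),
            class = "velocity_image")
}

#' Volumetric flow through a vessel ROI
#'
#' Mean velocity over the ROI times its cross-sectional area, converted to
#' ml/min. Exactly `flow = mean_velocity * area * 60` with area the pixel
#' count times pixel area.
#'
#' @param vel A `velocity_image` from [decode_velocity()].
#' @param roi Logical mask, same shape as the velocity image.
#' @param label Optional vessel label string.
#' @return A list of class `flow_result` with `mean_velocity` (cm/s),
#'   `area` (cm^2), `flow` (ml/min), `aliasing_suspected`, `label`.
#' @export
vessel_flow <- function(vel, roi, label = "synthetic") {
  stopifnot(inherits(vel, "velocity_image"),
            length(roi) == length(vel$velocity))
  roi <- as.logical(roi)
  if (!any(roi)) stop("empty ROI mask")
  mv <- mean(vel$velocity[roi])
  area <- sum(roi) * vel$pixel_area
  structure(list(mean_velocity = mv, area = area, flow = mv * area * 60,
                 aliasing_suspected = any(vel$aliasing[roi]), label = label),
            class = "flow_result")
}

#' Brain weight from parenchymal volume
#'
#' @param parenchymal_volume Grey plus white matter volume in ml (CSF
#'   excluded).
#' @param density Brain density in g/ml (default 1.05).
#' @return A list of class `brain_weight` with `parenchymal_volume`,
#'   `density`, `weight` (g).
#' @export
brain_weight <- function(parenchymal_volume, density = 1.05) {
  stopifnot(parenchymal_volume > 0, density > 0)
  structure(list(parenchymal_volume = parenchymal_volume, density = density,
                 weight = parenchymal_volume * density),
            class = "brain_weight")
}

#' Global CBF from feeding-artery flows
#'
#' Sums the arterial volumetric flows and normalises to brain weight,
#' returning ml/100 g/min.
#'
#' @param arterial_flows A list of `flow_result` objects (or one).
#' @param brain A `brain_weight` object.
#' @return Global CBF in ml/100 g/min.
#' @export
total_cbf <- function(arterial_flows, brain) {
  if (inherits(arterial_flows, "flow_result"))
    arterial_flows <- list(arterial_flows)
  stopifnot(length(arterial_flows) >= 1, inherits(brain, "brain_weight"))
  if (brain$weight <= 0) stop("brain weight must be positive")
  sum(vapply(arterial_flows, `[[`, numeric(1), "flow")) / brain$weight * 100
}
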