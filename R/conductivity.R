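#' Tissue conductivity model
#'
#' Electroporation opens nanoscale membrane pores, so bulk tissue
#' conductivity rises with the local field magnitude. The dynamic law is a
#' smoothed step from the baseline `sigma0` to the fully electroporated
#' ceiling `sigma_max` across a transition zone of width `e_width` centered
#' at `e_center`; the static law ignores the field and stays at `sigma0`.
#'
#' Defaults follow the values used for prostate: baseline 0.284 S/m
#' (low-voltage pre-pulse measurement), transition 800 V/cm wide centered at
#' 500 V/cm. `sigma_max` is the patient-specific parameter recovered by
#' [calibrate_sigma_max()].
#'
#' @param sigma0 Baseline conductivity (S/m), positive.
#' @param sigma_max Fully electroporated conductivity (S/m), >= `sigma0`.
#' @param e_center Transition center (V/cm).
#' @param e_width Transition width (V/cm), positive; the lower edge
#'   `e_center - e_width/2` must be non-negative.
#' @param mode `"dynamic"` or `"static"`.
#' @param smoothing Smoothing family for the transition; `"quintic"` (the
#'   minimal polynomial with a continuous second derivative at both edges)
#'   or `"cosine"` (C^1 only, for sensitivity checks).
#' @return An object of class `ire_tissue_model`.
#' @export
tissue_model <- function(sigma0 = 0.284, sigma_max = sigma0,
                         e_center = 500, e_width = 800,
                         mode = c("dynamic", "static"),
                         smoothing = c("quintic", "cosine")) {
  mode <- match.arg(mode)
  smoothing <- match.arg(smoothing)
  if (!is.numeric(sigma0) || sigma0 <= 0)
    stop("'sigma0' must be positive (S/m)")
  if (!is.numeric(sigma_max) || sigma_max < sigma0)
    stop("'sigma_max' must be >= 'sigma0'")
  if (!is.numeric(e_width) || e_width <= 0)
    stop("'e_width' must be positive (V/cm)")
  if (e_center - e_width / 2 < 0)
    stop("transition lower edge 'e_center - e_width/2' must be >= 0 V/cm")
  structure(
    list(sigma0 = sigma0, sigma_max = sigma_max, e_center = e_center,
         e_width = e_width, mode = mode, smoothing = smoothing),
    class = "ire_tissue_model")
}

#' @export
print.ire_tissue_model <- function(x, ...) {
  if (x$mode == "static") {
    cat(sprintf("Static tissue model: sigma0 = %.3g S/m\n", x$sigma0))
  } else {
    cat(sprintf(
      "Dynamic tissue model: %.3g -> %.3g S/m over [%g, %g] V/cm (%s step)\n",
      x$sigma0, x$sigma_max, x$e_center - x$e_width / 2,
      x$e_center + x$e_width / 2, x$smoothing))
  }
  invisible(x)
}

# s(t) on [0,1] with s(0)=0, s(1)=1; quintic has s'(edges)=s''(edges)=0.
smoothstep <- function(t, family = "quintic") {
  t <- pmin(pmax(t, 0), 1)
  switch(family,
         quintic = t^3 * (6 * t^2 - 15 * t + 10),
         cosine = (1 - cos(pi * t)) / 2,
         stop("unknown smoothing family"))
}

#' Conductivity at a given field magnitude
#'
#' Vectorized evaluation of the conductivity law. In dynamic mode the value
#' is `sigma0` below the transition zone, `sigma_max` above it, and a
#' C^2-continuous polynomial step in between; it is exactly
#' `(sigma0 + sigma_max)/2` at `e_center`. Static mode returns `sigma0`
#' regardless of the field.
#'
#' @param e_mag Field magnitude(s) (V/cm), non-negative.
#' @param model An `ire_tissue_model`.
#' @return Conductivity (S/m), same shape as `e_mag`.
#' @examples
#' m <- tissue_model(sigma_max = 0.72)
#' sigma_of_e(c(0, 500, 900), m)  # 0.284, 0.502, 0.720
#' @export
sigma_of_e <- function(e_mag, model) {
  stopifnot(inherits(model, "ire_tissue_model"))
  if (any(e_mag < 0, na.rm = TRUE))
    stop("field magnitude 'e_mag' must be non-negative")
  if (model$mode == "static") {
    out <- e_mag
    out[] <- model$sigma0
    return(out)
  }
  lower <- model$e_center - model$e_width / 2
  t <- (e_mag - lower) / model$e_width
  model$sigma0 + (model$sigma_max - model$sigma0) * smoothstep(t, model$smoothing)
}
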