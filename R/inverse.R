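#' Super-level-set volume of a field distribution
#'
#' Volume of the region where the (aggregated) field magnitude meets or
#' exceeds a contour value, over the whole tissue domain — the discrete
#' analogue of a volume integral above a field iso-contour.
#'
#' @param e_field 3-d array of field magnitudes (V/cm).
#' @param domain An `ire_domain`.
#' @param e_t Contour value(s) (V/cm), non-negative; vectorized.
#' @return Volume(s) in cm^3.
#' @export
superlevel_volume <- function(e_field, domain, e_t) {
  stopifnot(inherits(domain, "ire_domain"),
            identical(dim(e_field), as.integer(domain$dims)))
  if (any(e_t < 0)) stop("'e_t' must be non-negative (V/cm)")
  vv <- voxel_volume(domain)
  vapply(e_t, function(t) sum(e_field >= t) * vv, numeric(1))
}

# Super-level volumes at integer contours 1..k_max in one pass:
# count(e >= t) for integer t equals count(floor(e) >= t).
integer_level_volumes <- function(e_field, domain, k_max) {
  f <- pmin(floor(e_field), k_max)
  below <- cumsum(tabulate(f + 1, nbins = k_max + 1))  # counts with floor(e) < t
  counts <- length(e_field) - below[seq_len(k_max)]
  counts * voxel_volume(domain)
}

#' Extract the lethal threshold by volume matching
#'
#' Scans field contours in 1 V/cm increments and returns the contour whose
#' super-level-set volume is closest to the target ablation volume. Exact
#' matching is impossible on a voxel grid, so "matched" means nearest; ties
#' are broken toward the lower contour, which predicts the larger kill zone
#' and is therefore the conservative choice for planning.
#'
#' @param e_field 3-d array of aggregated field magnitudes (V/cm).
#' @param domain An `ire_domain`.
#' @param target_volume Observed ablation volume (cm^3); must be positive
#'   and no larger than the domain volume.
#' @return A list of class `ire_threshold`: `e_threshold` (integer V/cm),
#'   `matched_volume`, `target_volume` (cm^3).
#' @export
find_threshold <- function(e_field, domain, target_volume) {
  stopifnot(inherits(domain, "ire_domain"),
            identical(dim(e_field), as.integer(domain$dims)))
  total <- domain$edge_length^3
  if (!is.numeric(target_volume) || length(target_volume) != 1 ||
      target_volume <= 0 || target_volume > total)
    stop(sprintf("'target_volume' must lie in (0, %g] cm^3", total))
  k_max <- max(1L, as.integer(ceiling(max(e_field))))
  vols <- integer_level_volumes(e_field, domain, k_max)
  best <- which.min(abs(vols - target_volume))  # first minimum = lowest contour
  structure(list(e_threshold = as.integer(best),
                 matched_volume = vols[best],
                 target_volume = target_volume),
            class = "ire_threshold")
}

#' @export
print.ire_threshold <- function(x, ...) {
  cat(sprintf("Lethal threshold %d V/cm (matched %.2f cm^3 against target %.2f cm^3)\n",
              x$e_threshold, x$matched_volume, x$target_volume))
  invisible(x)
}

#' Calibrate the electroporated conductivity against measured current
#'
#' Finds the fully electroporated conductivity `sigma_max` whose simulated
#' dynamic-mode current for the first activation of the ordered plan (the
#' largest-spacing pair, the one the generator fires first) matches the
#' measured current. The delivered current is monotone non-decreasing in
#' `sigma_max`, so the one-dimensional match is solved by bisection; a
#' parametric grid sweep is retained for fidelity runs.
#'
#' @param domain An `ire_domain`.
#' @param electrodes List of `ire_electrode`.
#' @param plan An `ire_plan`; only its first row is solved.
#' @param measured_current Target current (A), positive. Clinically, the
#'   maximum current of the last ten pulses of the first pair activation.
#' @param sigma0 Baseline conductivity (S/m).
#' @param e_center,e_width Transition-zone parameters (V/cm) of the dynamic
#'   law.
#' @param upper Upper search bound for `sigma_max` (S/m).
#' @param current_tol Relative current mismatch at which the search stops.
#' @param bracket_tol Bracket width (S/m) at which the search stops.
#' @param method `"bisect"` (default) or `"sweep"` (grid of `sweep_step`).
#' @param sweep_step Grid step (S/m) for the sweep method.
#' @param control An `ire_solver_control`.
#' @return A list of class `ire_calibration`: `sigma_max_hat` (S/m),
#'   `achieved_current`, `target_current` (A), `search_iterations`,
#'   `converged`, and the bracketing currents `current_range`.
#' @export
calibrate_sigma_max <- function(domain, electrodes, plan, measured_current,
                                sigma0 = 0.284, e_center = 500, e_width = 800,
                                upper = 2.0, current_tol = 1e-3,
                                bracket_tol = 1e-4,
                                method = c("bisect", "sweep"),
                                sweep_step = 0.01,
                                control = solver_control()) {
  method <- match.arg(method)
  stopifnot(inherits(plan, "ire_plan"), nrow(plan) >= 1)
  if (!is.numeric(measured_current) || measured_current <= 0)
    stop("'measured_current' must be positive (A)")
  if (upper <= sigma0) stop("'upper' must exceed 'sigma0'")
  first <- plan[1, ]
  warm <- NULL
  n_eval <- 0L
  forward <- function(s_max) {
    sol <- solve_pair(domain, electrodes, c(first$source, first$sink),
                      first$voltage,
                      tissue_model(sigma0 = sigma0, sigma_max = s_max,
                                   e_center = e_center, e_width = e_width,
                                   mode = "dynamic"),
                      control = control, phi0 = warm)
    warm <<- sol$phi
    n_eval <<- n_eval + 1L
    sol$source_current
  }

  f_lo <- forward(sigma0)
  f_hi <- forward(upper)
  if (measured_current < f_lo * (1 - current_tol) ||
      measured_current > f_hi * (1 + current_tol))
    stop(sprintf(
      "measured current %.3f A is outside the achievable interval [%.3f, %.3f] A for sigma_max in [%.3g, %.3g] S/m",
      measured_current, f_lo, f_hi, sigma0, upper))

  if (method == "sweep") {
    grid <- seq(sigma0, upper, by = sweep_step)
    currents <- vapply(grid, forward, numeric(1))
    best <- which.min(abs(currents - measured_current))
    return(structure(
      list(sigma_max_hat = grid[best], achieved_current = currents[best],
           target_current = measured_current, search_iterations = n_eval,
           converged = abs(currents[best] - measured_current) <
             current_tol * measured_current ||
             sweep_step <= bracket_tol,
           current_range = c(f_lo, f_hi)),
      class = "ire_calibration"))
  }

  lo <- sigma0; hi <- upper
  best_s <- if (abs(f_lo - measured_current) <= abs(f_hi - measured_current)) sigma0 else upper
  best_i <- if (best_s == sigma0) f_lo else f_hi
  converged <- abs(best_i - measured_current) < current_tol * measured_current
  while (!converged && hi - lo > bracket_tol) {
    mid <- (lo + hi) / 2
    i_mid <- forward(mid)
    if (abs(i_mid - measured_current) < abs(best_i - measured_current)) {
      best_s <- mid; best_i <- i_mid
    }
    if (abs(i_mid - measured_current) < current_tol * measured_current) {
      converged <- TRUE
    } else if (i_mid < measured_current) lo <- mid else hi <- mid
  }
  structure(
    list(sigma_max_hat = best_s, achieved_current = best_i,
         target_current = measured_current, search_iterations = n_eval,
         converged = converged || hi - lo <= bracket_tol,
         current_range = c(f_lo, f_hi)),
    class = "ire_calibration")
}

#' @export
print.ire_calibration <- function(x, ...) {
  cat(sprintf("Calibrated sigma_max = %.4f S/m (current %.3f A vs measured %.3f A, %d solves)\n",
              x$sigma_max_hat, x$achieved_current, x$target_current,
              x$search_iterations))
  invisible(x)
}

#' Full per-patient inference chain
#'
#' Runs the complete procedure for one patient: (i) static plan solve and
#' volume matching for the static threshold; (ii) calibration of
#' `sigma_max` against the measured first-pair current; (iii) dynamic plan
#' solve with the calibrated conductivity and volume matching for the
#' dynamic threshold. If the measured current is absent, calibration and
#' the dynamic threshold are skipped (static-only mode).
#'
#' @param patient An `ire_patient` (from [generate_cohort()]), a patient
#'   configuration list, or a path to a patient config file
#'   (see [read_patient_config()]).
#' @param control An `ire_solver_control`.
#' @param ... Passed to [calibrate_sigma_max()] (e.g. `upper`,
#'   `current_tol`).
#' @return A list of class `ire_inference`: `threshold_static`,
#'   `threshold_dynamic` (V/cm), `sigma_max_hat` (S/m), `calibration`,
#'   `static_match`, `dynamic_match`, and the per-pair current tables.
#' @export
infer_patient <- function(patient, control = solver_control(), ...) {
  inp <- patient_inputs(patient)
  static_res <- run_plan(inp$domain, inp$electrodes, inp$plan,
                         tissue_model(sigma0 = inp$sigma0, mode = "static"),
                         control = control)
  static_match <- find_threshold(static_res$e_max, inp$domain,
                                 inp$target_volume)
  cal <- NULL; dyn_match <- NULL; dyn_res <- NULL
  if (!is.null(inp$measured_current)) {
    cal <- calibrate_sigma_max(inp$domain, inp$electrodes, inp$plan,
                               inp$measured_current, sigma0 = inp$sigma0,
                               e_center = inp$e_center, e_width = inp$e_width,
                               control = control, ...)
    dyn_model <- tissue_model(sigma0 = inp$sigma0,
                              sigma_max = cal$sigma_max_hat,
                              e_center = inp$e_center, e_width = inp$e_width,
                              mode = "dynamic")
    dyn_res <- run_plan(inp$domain, inp$electrodes, inp$plan, dyn_model,
                        control = control)
    dyn_match <- find_threshold(dyn_res$e_max, inp$domain, inp$target_volume)
  }
  structure(
    list(threshold_static = static_match$e_threshold,
         threshold_dynamic = if (!is.null(dyn_match)) dyn_match$e_threshold else NA_integer_,
         sigma_max_hat = if (!is.null(cal)) cal$sigma_max_hat else NA_real_,
         calibration = cal, static_match = static_match,
         dynamic_match = dyn_match,
         static_currents = static_res$currents,
         dynamic_currents = if (!is.null(dyn_res)) dyn_res$currents else NULL),
    class = "ire_inference")
}

#' @export
print.ire_inference <- function(x, ...) {
  cat(sprintf("IRE inference: static threshold %d V/cm; dynamic threshold %s V/cm; sigma_max_hat %s S/m\n",
              x$threshold_static,
              ifelse(is.na(x$threshold_dynamic), "NA", x$threshold_dynamic),
              ifelse(is.na(x$sigma_max_hat), "NA",
                     sprintf("%.3f", x$sigma_max_hat))))
  invisible(x)
}
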