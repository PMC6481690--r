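#' Enumerate electrode pairs
#'
#' All unordered pairs, including diagonals: for the clinical four-needle
#' square this is the six activations a NanoKnife session delivers.
#'
#' @param electrodes List of `ire_electrode` (length >= 2).
#' @return Two-column integer matrix (`source`, `sink`), one row per pair.
#' @export
enumerate_pairs <- function(electrodes) {
  n <- length(electrodes)
  if (n < 2) stop("at least 2 electrodes are required to form a pair")
  pairs <- t(utils::combn(n, 2))
  colnames(pairs) <- c("source", "sink")
  pairs
}

#' Voltage for a pair from the clinical distance rule
#'
#' The generator applies `ratio` volts per cm of electrode spacing, capped
#' at the hardware maximum (3000 V for the NanoKnife); spacings beyond
#' `cap/ratio` therefore receive a reduced effective ratio.
#'
#' @param spacing Electrode spacing (cm), positive.
#' @param ratio Planned voltage-to-distance ratio (V/cm), default 1500.
#' @param cap Hardware voltage limit (V), default 3000.
#' @return Applied voltage (V), vectorized over `spacing`.
#' @examples
#' pair_voltage(c(1.4, 2.0, 2.2))  # 2100, 3000, 3000
#' @export
pair_voltage <- function(spacing, ratio = 1500, cap = 3000) {
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be positive (cm)")
  pmin(ratio * spacing, cap)
}

#' Order activations by descending voltage
#'
#' The clinical generator activates from the highest voltage (largest
#' spacing) down. Voltages capped at the hardware limit tie, so larger
#' spacing breaks voltage ties (diagonals fire before sides); remaining
#' ties keep ascending (source, sink) index order, and the sort is stable.
#'
#' @param plan Data frame with columns `source`, `sink`, `spacing`,
#'   `voltage`.
#' @return The plan rows reordered, class `ire_plan`.
#' @export
order_plan <- function(plan) {
  stopifnot(is.data.frame(plan),
            all(c("source", "sink", "spacing", "voltage") %in% names(plan)))
  ord <- order(-plan$voltage, -plan$spacing, plan$source, plan$sink)
  out <- plan[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ire_plan", "data.frame")
  out
}

#' Build a treatment plan from electrode geometry
#'
#' Enumerates all pairs, applies the voltage-to-distance rule, and orders
#' activations from highest to lowest voltage. Pulse-train metadata (90
#' pulses of 70 us per pair) is carried as attributes for reporting; the
#' electrostatic model has no pulse-time dependence.
#'
#' @param electrodes List of `ire_electrode`.
#' @param ratio,cap Passed to [pair_voltage()].
#' @param pulses,pulse_length_us Pulse metadata attached as attributes.
#' @return An `ire_plan` data frame with columns `source`, `sink`,
#'   `spacing` (cm), `voltage` (V), ordered for delivery.
#' @examples
#' plan <- treatment_plan(place_electrode_grid(4, 2.0, 2.0))
#' plan  # diagonals (capped at 3000 V) first
#' @export
treatment_plan <- function(electrodes, ratio = 1500, cap = 3000,
                           pulses = 90L, pulse_length_us = 70) {
  pairs <- enumerate_pairs(electrodes)
  sp <- electrode_spacings(electrodes)
  spacing <- sp[pairs]
  plan <- data.frame(source = pairs[, 1], sink = pairs[, 2],
                     spacing = spacing,
                     voltage = pair_voltage(spacing, ratio, cap))
  plan <- order_plan(plan)
  attr(plan, "pulses") <- as.integer(pulses)
  attr(plan, "pulse_length_us") <- pulse_length_us
  attr(plan, "ratio") <- ratio
  attr(plan, "cap") <- cap
  plan
}

#' @export
print.ire_plan <- function(x, ...) {
  cat("IRE treatment plan (activation order):\n")
  df <- data.frame(pair = sprintf("%d-%d", x$source, x$sink),
                   spacing_cm = round(x$spacing, 3),
                   voltage_V = round(x$voltage))
  print.data.frame(df, row.names = FALSE)
  p <- attr(x, "pulses")
  if (!is.null(p))
    cat(sprintf("%d pulses of %g us per pair\n", p, attr(x, "pulse_length_us")))
  invisible(x)
}

#' Run a full treatment plan
#'
#' Solves every activation independently and aggregates by voxelwise
#' maxima: the overall field distribution is the maximum of the per-pair
#' field magnitudes, and (in dynamic mode) the overall conductivity map is
#' the maximum of the per-pair conductivities. Per-pair source currents are
#' collected in plan order.
#'
#' @param domain An `ire_domain`.
#' @param electrodes List of `ire_electrode`.
#' @param plan An `ire_plan` (see [treatment_plan()]).
#' @param model An `ire_tissue_model`.
#' @param control An `ire_solver_control`.
#' @param keep_solutions Keep the per-pair `ire_field` objects (memory
#'   permitting).
#' @return An object of class `ire_plan_result`: `e_max` (V/cm),
#'   `sigma_max_field` (S/m), `currents` (A, plan order), `converged`
#'   (per-pair flags), plus `domain`, `plan`, `model`.
#' @export
run_plan <- function(domain, electrodes, plan, model,
                     control = solver_control(), keep_solutions = FALSE) {
  stopifnot(inherits(plan, "ire_plan"), nrow(plan) >= 1)
  e_max <- array(0, dim = domain$dims)
  s_max <- array(0, dim = domain$dims)
  currents <- numeric(nrow(plan))
  conv <- logical(nrow(plan))
  sols <- if (keep_solutions) vector("list", nrow(plan)) else NULL
  for (r in seq_len(nrow(plan))) {
    sol <- tryCatch(
      solve_pair(domain, electrodes, c(plan$source[r], plan$sink[r]),
                 plan$voltage[r], model, control = control),
      error = function(e) stop(sprintf("pair %d-%d failed: %s",
                                       plan$source[r], plan$sink[r],
                                       conditionMessage(e)), call. = FALSE))
    e_max <- pmax(e_max, sol$e_mag)
    s_max <- pmax(s_max, sol$sigma)
    currents[r] <- sol$source_current
    conv[r] <- sol$converged
    if (keep_solutions) sols[[r]] <- sol
  }
  structure(
    list(e_max = e_max, sigma_max_field = s_max, currents = currents,
         converged = conv, domain = domain, plan = plan, model = model,
         solutions = sols),
    class = "ire_plan_result")
}

#' @export
print.ire_plan_result <- function(x, ...) {
  cat(sprintf("IRE plan result (%s model): %d activations, currents %s A\n",
              x$model$mode, nrow(x$plan),
              paste(sprintf("%.1f", x$currents), collapse = ", ")))
  invisible(x)
}
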