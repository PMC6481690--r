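#' Solver control parameters
#'
#' @param cg_tol Relative residual tolerance of the conjugate-gradient
#'   linear solver.
#' @param cg_maxit Maximum CG iterations per linear solve.
#' @param picard_tol Dynamic mode: stop when the relative change of the
#'   source current between successive conductivity updates falls below
#'   this value.
#' @param picard_maxit Maximum Picard (fixed-point) iterations.
#' @param relax Under-relaxation factor applied to the conductivity update,
#'   in (0, 1]; the 0.7 default damps the overshoot of the bare fixed-point
#'   map while keeping the iteration count low.
#' @param inactive_contrast Conductivity contrast cap for inactive
#'   electrodes retained as passive conductors: their conductivity is
#'   `min(metal, inactive_contrast * sigma0)`. Beyond a contrast of ~1e3 the
#'   solution is insensitive while conditioning degrades, so the default
#'   caps at 1e4.
#' @param include_inactive Keep non-active electrodes in each pair solve as
#'   high-conductivity inclusions (`TRUE`, default) or remove them.
#' @return A list of class `ire_solver_control`.
#' @export
solver_control <- function(cg_tol = 1e-7, cg_maxit = 20000L,
                           picard_tol = 1e-3, picard_maxit = 100L,
                           relax = 0.7, inactive_contrast = 1e4,
                           include_inactive = TRUE) {
  stopifnot(cg_tol > 0, cg_maxit > 0, picard_tol > 0, picard_maxit > 0,
            relax > 0, relax <= 1, inactive_contrast >= 1)
  structure(list(cg_tol = cg_tol, cg_maxit = as.integer(cg_maxit),
                 picard_tol = picard_tol, picard_maxit = as.integer(picard_maxit),
                 relax = relax, inactive_contrast = inactive_contrast,
                 include_inactive = isTRUE(include_inactive)),
            class = "ire_solver_control")
}

#' Solve the electrostatic problem for a fixed conductivity map
#'
#' Low-level linear solve of \eqn{\nabla\cdot\sigma\nabla\phi = 0} with
#' Dirichlet values on an arbitrary voxel set and zero normal current on the
#' outer cube boundary (electrical insulation). Cell-centered finite volumes
#' with harmonic-mean face conductivities; preconditioned conjugate
#' gradients. Exposed so analytic surrogates (parallel plates, concentric
#' cylinders) can be posed directly.
#'
#' @param domain An `ire_domain`.
#' @param sigma 3-d conductivity array (S/m) on the domain grid.
#' @param dirichlet Logical 3-d array: voxels with prescribed potential.
#' @param dirichlet_values 3-d array of potentials (V); only entries where
#'   `dirichlet` is `TRUE` are used.
#' @param control An `ire_solver_control`.
#' @param phi0 Optional warm-start potential array.
#' @return List with `phi` (V), `iterations`, `relative_residual`,
#'   `converged`.
#' @export
solve_field <- function(domain, sigma, dirichlet, dirichlet_values,
                        control = solver_control(), phi0 = NULL) {
  stopifnot(inherits(domain, "ire_domain"),
            identical(dim(sigma), as.integer(domain$dims)),
            identical(dim(dirichlet), as.integer(domain$dims)),
            identical(dim(dirichlet_values), as.integer(domain$dims)))
  if (!any(dirichlet)) stop("no Dirichlet voxels: the system is singular")
  if (any(sigma <= 0)) stop("conductivity must be positive everywhere")
  if (is.null(phi0)) phi0 <- array(0, dim = domain$dims)
  res <- .cg_solve(as.integer(domain$dims), as.numeric(sigma),
                   as.logical(dirichlet), as.numeric(dirichlet_values),
                   as.numeric(phi0), control$cg_tol, control$cg_maxit)
  if (!res$converged)
    warning(sprintf("CG did not reach tolerance (relative residual %.2e after %d iterations)",
                    res$relative_residual, res$iterations))
  res$phi <- array(res$phi, dim = domain$dims)
  res
}

#' Field magnitude from a potential array
#'
#' \eqn{|E| = |\nabla\phi|} by central differences in the interior and
#' one-sided differences at the domain boundary, in V/cm. This is the plain
#' kinematic gradient; solutions produced by [solve_pair()] carry a
#' flux-consistent magnitude that stays accurate next to electrode voxels.
#'
#' @param phi 3-d potential array (V).
#' @param domain An `ire_domain`.
#' @return 3-d array of |E| (V/cm).
#' @export
field_magnitude <- function(phi, domain) {
  stopifnot(inherits(domain, "ire_domain"),
            identical(dim(phi), as.integer(domain$dims)))
  h <- domain$spacing
  n <- domain$resolution
  d_axis <- function(a) {
    hi <- c(2:n, n)  # one-sided at the upper face
    lo <- c(1, 1:(n - 1))
    den <- array(2 * h, dim = domain$dims)
    idx <- slice.index(phi, a)
    den[idx == 1 | idx == n] <- h
    shift <- function(ord) {
      switch(a, phi[ord, , ], phi[, ord, ], phi[, , ord])
    }
    (shift(hi) - shift(lo)) / den
  }
  sqrt(d_axis(1)^2 + d_axis(2)^2 + d_axis(3)^2)
}

# Flux-consistent |E| (V/cm): face fluxes divided by the voxel conductivity,
# exact adjacent to Dirichlet (electrode) voxels where central differences
# are biased low.
flux_magnitude <- function(phi, sigma, domain) {
  array(.flux_field_magnitude(as.integer(domain$dims), as.numeric(phi),
                              as.numeric(sigma)) / domain$spacing,
        dim = domain$dims)
}

# Net conduction current (A) leaving a voxel region through its surface of
# voxel faces; domain faces are insulated (zero flux), so the accounting is
# closed for interior regions and for regions abutting the outer boundary.
# h converts face conductance to SI.
region_current <- function(phi, sigma, domain, region) {
  if (!any(region)) stop("empty region")
  h_m <- domain$spacing / CM_PER_M
  .region_outflux(as.integer(domain$dims), as.numeric(phi),
                  as.numeric(sigma), as.logical(region)) * h_m
}

#' Solve one electrode-pair activation
#'
#' Imposes the applied voltage on the source electrode's voxels and ground
#' on the sink's, keeps any remaining electrodes as passive conductive
#' inclusions, and solves the electrostatic problem. In dynamic mode the
#' conductivity is updated from the field magnitude by Picard fixed-point
#' iteration with under-relaxation until the source current stabilizes.
#'
#' @param domain An `ire_domain`.
#' @param electrodes List of `ire_electrode`.
#' @param active_pair Integer pair `c(source, sink)` indexing `electrodes`.
#' @param voltage Applied potential difference (V), positive.
#' @param model An `ire_tissue_model`.
#' @param control An `ire_solver_control`.
#' @param phi0,sigma_init Optional warm starts (potential array and tissue
#'   conductivity array) carried across calibration sweeps.
#' @return An object of class `ire_field`: `phi` (V), `e_mag` (V/cm,
#'   flux-consistent), `sigma` (S/m), `source_current` and `sink_current`
#'   (A), `iterations` (Picard count; 1 in static mode), `converged`,
#'   `source_mask`, `sink_mask`, `domain`, `voltage`, `pair`.
#' @export
solve_pair <- function(domain, electrodes, active_pair, voltage, model,
                       control = solver_control(), phi0 = NULL,
                       sigma_init = NULL) {
  stopifnot(inherits(domain, "ire_domain"), inherits(model, "ire_tissue_model"),
            length(active_pair) == 2)
  active_pair <- as.integer(active_pair)
  if (anyNA(active_pair) || any(active_pair < 1) ||
      any(active_pair > length(electrodes)) || active_pair[1] == active_pair[2])
    stop("'active_pair' must index two distinct electrodes")
  if (!is.numeric(voltage) || voltage <= 0) stop("'voltage' must be positive (V)")

  src_mask <- electrode_voxels(domain, electrodes[[active_pair[1]]])
  snk_mask <- electrode_voxels(domain, electrodes[[active_pair[2]]])
  if (!any(src_mask) || !any(snk_mask))
    stop("an active electrode rasterizes to no voxels; increase resolution")
  if (any(src_mask & snk_mask))
    stop("source and sink electrodes overlap on the grid")
  dir_mask <- src_mask | snk_mask
  dir_vals <- array(0, dim = domain$dims)
  dir_vals[src_mask] <- voltage

  inactive <- setdiff(seq_along(electrodes), active_pair)
  incl_mask <- array(FALSE, dim = domain$dims)
  incl_sigma <- min(2e6, control$inactive_contrast * model$sigma0)
  if (control$include_inactive && length(inactive)) {
    for (i in inactive) incl_mask <- incl_mask | electrode_voxels(domain, electrodes[[i]])
    incl_mask <- incl_mask & !dir_mask
  }

  metal <- vapply(electrodes[active_pair], `[[`, numeric(1), "conductivity")
  sigma_tissue <- if (is.null(sigma_init)) {
    array(model$sigma0, dim = domain$dims)
  } else sigma_init

  assemble <- function(sig_t) {
    s <- sig_t
    if (any(incl_mask)) s[incl_mask] <- incl_sigma
    s[src_mask] <- metal[1]
    s[snk_mask] <- metal[2]
    s
  }

  phi <- phi0
  prev_current <- NA_real_
  converged <- FALSE
  iter <- 0L
  static <- model$mode == "static"
  repeat {
    iter <- iter + 1L
    sigma_full <- assemble(sigma_tissue)
    sol <- solve_field(domain, sigma_full, dir_mask, dir_vals,
                       control = control, phi0 = phi)
    phi <- sol$phi
    i_src <- region_current(phi, sigma_full, domain, src_mask)
    if (static) { converged <- TRUE; break }
    e_mag <- flux_magnitude(phi, sigma_full, domain)
    sig_new <- sigma_of_e(e_mag, model)
    delta_sigma <- max(abs(sig_new - sigma_tissue))
    sigma_tissue <- sigma_tissue + control$relax * (sig_new - sigma_tissue)
    if (delta_sigma <= 1e-12 * model$sigma0) { converged <- TRUE; break }
    if (!is.na(prev_current) &&
        abs(i_src - prev_current) < control$picard_tol * abs(prev_current)) {
      converged <- TRUE; break
    }
    prev_current <- i_src
    if (iter >= control$picard_maxit) break
  }
  if (!converged)
    warning(sprintf("Picard iteration did not converge in %d iterations (last current %.4g A)",
                    iter, i_src))

  sigma_full <- assemble(sigma_tissue)
  e_mag <- flux_magnitude(phi, sigma_full, domain)
  i_src <- region_current(phi, sigma_full, domain, src_mask)
  i_snk <- -region_current(phi, sigma_full, domain, snk_mask)

  structure(
    list(phi = phi, e_mag = e_mag, sigma = sigma_full,
         source_current = i_src, sink_current = i_snk,
         iterations = iter, converged = converged,
         source_mask = src_mask, sink_mask = snk_mask,
         domain = domain, voltage = voltage, pair = active_pair),
    class = "ire_field")
}

#' @export
print.ire_field <- function(x, ...) {
  cat(sprintf("IRE pair solution: %d V across electrodes (%d, %d); I = %.3f A; %d iteration(s)%s\n",
              round(x$voltage), x$pair[1], x$pair[2], x$source_current,
              x$iterations, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Delivered current of a pair solution
#'
#' Conduction current through the closed surface of voxel faces enclosing
#' the chosen electrode (the discrete analogue of integrating the normal
#' current density over a surface between the electrodes). Source and sink
#' agree in magnitude up to the solver tolerance.
#'
#' @param solution An `ire_field` from [solve_pair()].
#' @param which `"source"` or `"sink"`.
#' @return Current (A).
#' @export
pair_current <- function(solution, which = c("source", "sink")) {
  stopifnot(inherits(solution, "ire_field"))
  which <- match.arg(which)
  mask <- if (which == "source") solution$source_mask else solution$sink_mask
  idx <- which(mask, arr.ind = TRUE)
  if (any(idx == 1L) || any(idx == solution$domain$resolution))
    stop("geometry error: electrode touches the domain boundary; enclosing surface is open")
  i <- region_current(solution$phi, solution$sigma, solution$domain, mask)
  if (which == "sink") -i else i
}
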