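#' Needle electrode
#'
#' The active (conductive) part of a NanoKnife-style needle electrode,
#' modeled as a stainless-steel cylinder; the insulated shaft and the sharp
#' tip are excluded from the model. The cylinder runs from `tip_position`
#' along `axis` for `exposure_length`.
#'
#' @param tip_position Start of the exposed cylinder, length-3 numeric (cm).
#' @param axis Unit direction vector of the needle. Must have unit norm to
#'   within 1e-9 (pass any vector through `axis / sqrt(sum(axis^2))`).
#' @param exposure_length Exposed length (cm); clinically 1.5 or 2.0.
#' @param radius Cylinder radius (cm). The probe diameter is not part of the
#'   treatment record; 0.05 cm (1 mm diameter needle) is the default.
#' @param conductivity Metal conductivity (S/m); stainless steel 2e6.
#' @return An object of class `ire_electrode`.
#' @export
electrode <- function(tip_position, axis = c(0, 0, 1), exposure_length,
                      radius = 0.05, conductivity = 2e6) {
  stopifnot(is.numeric(tip_position), length(tip_position) == 3,
            all(is.finite(tip_position)),
            is.numeric(axis), length(axis) == 3)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    stop("electrode 'axis' must be a unit vector (|axis| = 1 within 1e-9)")
  if (!is.numeric(exposure_length) || exposure_length <= 0)
    stop("electrode 'exposure_length' must be positive (cm)")
  if (!is.numeric(radius) || radius <= 0)
    stop("electrode 'radius' must be positive (cm)")
  stopifnot(conductivity > 0)
  structure(
    list(tip_position = as.numeric(tip_position), axis = as.numeric(axis),
         exposure_length = exposure_length, radius = radius,
         conductivity = conductivity),
    class = "ire_electrode")
}

electrode_midpoint <- function(el) {
  el$tip_position + el$axis * el$exposure_length / 2
}

# Strict containment of the electrode cylinder in the cube (axis-aligned
# bounding box check, adequate for the parallel needles the generator
# places; a one-voxel margin keeps Dirichlet voxels off the insulated
# boundary so enclosing flux surfaces stay closed).
electrode_inside_domain <- function(el, domain) {
  lo <- domain$origin - domain$edge_length / 2 + domain$spacing
  hi <- domain$origin + domain$edge_length / 2 - domain$spacing
  ends <- rbind(el$tip_position, el$tip_position + el$axis * el$exposure_length)
  r <- el$radius
  all(apply(ends, 2, min) - r > lo) && all(apply(ends, 2, max) + r < hi)
}

#' Place four electrodes on a square grid
#'
#' Emulates the clinical placement: parallel needles at the corners of a
#' square of side `spacing`, axes along z, exposure centered on `center`.
#'
#' @param n_electrodes Number of electrodes; the generator supports the
#'   four-needle square used in the trial.
#' @param spacing Square side (cm); clinically at most ~2.2.
#' @param exposure_length Exposed length per needle (cm).
#' @param center Center of the square and of the exposure, length-3 (cm).
#' @param domain Domain used for the containment check (default 7.5 cm cube).
#' @param radius,conductivity Passed to [electrode()].
#' @return List of `ire_electrode`, corner order (-,-), (+,-), (-,+), (+,+).
#' @examples
#' els <- place_electrode_grid(4, 2.0, 2.0)
#' round(dist(t(sapply(els, function(e) e$tip_position[1:2]))), 3)
#' @export
place_electrode_grid <- function(n_electrodes = 4, spacing, exposure_length,
                                 center = c(0, 0, 0),
                                 domain = make_domain(),
                                 radius = 0.05, conductivity = 2e6) {
  if (n_electrodes != 4)
    stop("the square-grid generator places exactly 4 electrodes")
  if (!is.numeric(spacing) || spacing <= 0)
    stop("'spacing' must be positive (cm)")
  if (spacing > 2.2)
    stop("'spacing' exceeds the 2.2 cm clinical placement limit; electrodes would sit outside the treatable margin")
  corners <- expand.grid(x = c(-1, 1), y = c(-1, 1)) * spacing / 2
  els <- lapply(seq_len(4), function(i) {
    electrode(tip_position = c(center[1] + corners$x[i],
                               center[2] + corners$y[i],
                               center[3] - exposure_length / 2),
              axis = c(0, 0, 1), exposure_length = exposure_length,
              radius = radius, conductivity = conductivity)
  })
  ok <- vapply(els, electrode_inside_domain, logical(1), domain = domain)
  if (!all(ok))
    stop(sprintf("electrode geometry error: %d electrode(s) extend outside the %g cm domain",
                 sum(!ok), domain$edge_length))
  els
}

#' Pairwise electrode spacings (cm)
#'
#' Distances between electrode midpoints — the quantity the clinical
#' voltage-to-distance rule applies to.
#'
#' @param electrodes List of `ire_electrode`.
#' @return A symmetric matrix of distances.
#' @export
electrode_spacings <- function(electrodes) {
  mids <- t(vapply(electrodes, electrode_midpoint, numeric(3)))
  as.matrix(stats::dist(mids))
}

# Rasterize an electrode cylinder to voxel occupancy. The radial acceptance
# is max(radius, spacing/2) so a needle thinner than a voxel still owns the
# nearest voxel column; the resulting grid-dependent effective radius is a
# documented discretization property shared by forward and inverse runs.
electrode_voxels <- function(domain, el) {
  cc <- axis_centers(domain)
  n <- domain$resolution
  grid_r <- max(el$radius, domain$spacing / 2)
  a <- el$axis
  t0 <- el$tip_position
  # general axis: distance of voxel center to segment
  if (all(abs(a - c(0, 0, 1)) < 1e-12)) {
    # fast path for the z-aligned needles the generator produces
    dx2 <- (cc[[1]] - t0[1])^2
    dy2 <- (cc[[2]] - t0[2])^2
    inz <- cc[[3]] >= t0[3] & cc[[3]] <= t0[3] + el$exposure_length
    rad <- outer(dx2, dy2, `+`) <= grid_r^2
    occ <- array(FALSE, dim = domain$dims)
    occ[, , inz] <- rad
    return(occ)
  }
  pts <- as.matrix(expand.grid(x = cc[[1]], y = cc[[2]], z = cc[[3]]))
  rel <- sweep(pts, 2, t0)
  s <- as.numeric(rel %*% a)
  along <- s >= 0 & s <= el$exposure_length
  perp2 <- rowSums(rel^2) - s^2
  array(along & perp2 <= grid_r^2, dim = domain$dims)
}
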