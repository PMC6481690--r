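#' Cubic simulation domain
#'
#' Builds the isotropic voxel grid on which fields are solved. The default
#' 7.5 cm cube is large enough to contain a prostate and the surrounding
#' gland; the grid is cell-centered and the cube is centered on `origin`.
#'
#' @param edge_length Cube edge (cm). Must be positive.
#' @param resolution Voxels per axis (>= 16).
#' @param origin Center of the cube, a length-3 numeric (cm).
#' @return An object of class `ire_domain`: a list with `edge_length`,
#'   `resolution`, `spacing` (cm), `origin`, and `dims`.
#' @examples
#' d <- make_domain(7.5, 75)
#' d$spacing   # 0.1 cm
#' @export
make_domain <- function(edge_length = 7.5, resolution = 64,
                        origin = c(0, 0, 0)) {
  if (!is.numeric(edge_length) || length(edge_length) != 1 ||
      !is.finite(edge_length) || edge_length <= 0)
    stop("invalid domain: 'edge_length' must be a positive number (cm)")
  resolution <- as.integer(resolution)
  if (length(resolution) != 1 || is.na(resolution) || resolution < 16)
    stop("invalid domain: 'resolution' must be an integer >= 16")
  stopifnot(is.numeric(origin), length(origin) == 3, all(is.finite(origin)))
  structure(
    list(edge_length = edge_length,
         resolution = resolution,
         spacing = edge_length / resolution,
         origin = as.numeric(origin),
         dims = rep(resolution, 3L)),
    class = "ire_domain")
}

#' @export
print.ire_domain <- function(x, ...) {
  cat(sprintf("IRE simulation domain: %.3g cm cube, %d^3 voxels (spacing %.4g cm)\n",
              x$edge_length, x$resolution, x$spacing))
  invisible(x)
}

#' Voxel-center coordinates along each axis
#'
#' @param domain An `ire_domain`.
#' @return List of three numeric vectors (cm), one per axis.
#' @export
axis_centers <- function(domain) {
  stopifnot(inherits(domain, "ire_domain"))
  h <- domain$spacing
  lapply(1:3, function(a) {
    domain$origin[a] - domain$edge_length / 2 + h * (seq_len(domain$resolution) - 0.5)
  })
}

#' Volume of one voxel (cm^3)
#' @param domain An `ire_domain`.
#' @export
voxel_volume <- function(domain) {
  stopifnot(inherits(domain, "ire_domain"))
  domain$spacing^3
}

new_mask <- function(domain, occupancy) {
  stopifnot(inherits(domain, "ire_domain"),
            is.logical(occupancy),
            identical(dim(occupancy), as.integer(domain$dims)))
  structure(list(domain = domain, occupancy = occupancy), class = "ire_mask")
}

#' Ablation mask volume (cm^3)
#'
#' Volume is occupied-voxel count times voxel volume. An empty mask returns
#' zero with a warning rather than erroring, so degenerate inversions are
#' visible but not fatal.
#'
#' @param mask An `ire_mask` (see [ellipsoid_mask()], [superlevel_mask()]).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "ire_mask"))
  n <- sum(mask$occupancy)
  if (n == 0) warning("mask is empty; volume is 0")
  n * voxel_volume(mask$domain)
}

#' @export
print.ire_mask <- function(x, ...) {
  cat(sprintf("IRE ablation mask: %d voxels, %.3f cm^3 on a %d^3 grid\n",
              sum(x$occupancy), sum(x$occupancy) * voxel_volume(x$domain),
              x$domain$resolution))
  invisible(x)
}

#' Rasterize an ellipsoid as an ablation mask
#'
#' A voxel is occupied when its center lies inside the ellipsoid
#' (center-inside rule), so the rasterized volume converges to
#' \eqn{4\pi abc/3} as the grid is refined.
#'
#' @param domain An `ire_domain`.
#' @param semiaxes Length-3 positive numeric, semi-axes (cm).
#' @param center Ellipsoid center (cm).
#' @return An `ire_mask`.
#' @export
ellipsoid_mask <- function(domain, semiaxes, center = c(0, 0, 0)) {
  stopifnot(inherits(domain, "ire_domain"),
            is.numeric(semiaxes), length(semiaxes) == 3, all(semiaxes > 0),
            is.numeric(center), length(center) == 3)
  cc <- axis_centers(domain)
  n <- domain$resolution
  u2 <- ((cc[[1]] - center[1]) / semiaxes[1])^2
  v2 <- ((cc[[2]] - center[2]) / semiaxes[2])^2
  w2 <- ((cc[[3]] - center[3]) / semiaxes[3])^2
  occ <- outer(outer(u2, v2, `+`), w2, `+`) < 1
  new_mask(domain, occ)
}

#' Super-level-set mask of a field
#'
#' The region where the field magnitude meets or exceeds a contour value;
#' its volume is the quantity matched against the observed ablation volume
#' during threshold inference.
#'
#' @param e_field 3-d array of field magnitudes (V/cm) on the domain grid.
#' @param domain An `ire_domain`.
#' @param e_t Contour value (V/cm), non-negative.
#' @return An `ire_mask`.
#' @export
superlevel_mask <- function(e_field, domain, e_t) {
  stopifnot(inherits(domain, "ire_domain"),
            identical(dim(e_field), as.integer(domain$dims)),
            is.numeric(e_t), length(e_t) == 1, e_t >= 0)
  new_mask(domain, e_field >= e_t)
}
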