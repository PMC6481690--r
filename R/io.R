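#' Write an ablation mask as NIfTI
#'
#' Stores the binary occupancy with the voxel spacing in the header so
#' volumes survive the round trip exactly.
#'
#' @param mask An `ire_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "ire_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$occupancy),
                               dim = mask$domain$dims))
  RNifti::pixdim(img) <- rep(mask$domain$spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ablation mask from NIfTI
#'
#' Rebuilds the cubic domain from the image dimensions and voxel spacing;
#' voxels with intensity > 0.5 are occupied.
#'
#' @param path Path to a NIfTI mask.
#' @return An `ire_mask`.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("expected a cubic 3-d mask image")
  h <- RNifti::pixdim(img)[1]
  domain <- make_domain(edge_length = d[1] * h, resolution = d[1])
  new_mask(domain, array(as.vector(img) > 0.5, dim = d))
}

#' Export a scalar field as legacy VTK
#'
#' Writes an ASCII STRUCTURED_POINTS dataset (point data at voxel centers)
#' readable by ParaView/VTK viewers, for visual inspection of field and
#' conductivity distributions.
#'
#' @param field 3-d numeric array on the domain grid.
#' @param domain An `ire_domain`.
#' @param path Output path (`.vtk`).
#' @param name Name of the scalar array.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, domain, path, name = "field") {
  stopifnot(inherits(domain, "ire_domain"),
            identical(dim(field), as.integer(domain$dims)))
  n <- domain$resolution
  h <- domain$spacing
  org <- domain$origin - domain$edge_length / 2 + h / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("irethreshold export:", name),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n, n, n),
               sprintf("ORIGIN %g %g %g", org[1], org[2], org[3]),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", n^3),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(formatC(as.vector(field), format = "g", digits = 7), con)
  invisible(path)
}

#' Write a cohort summary CSV
#'
#' @param cohort An `ire_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort_table(cohort), path, row.names = FALSE)
  invisible(path)
}
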