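# Normalize the three patient representations (synthetic patient object,
# materialized config, path to a config file) into the inputs the inference
# chain needs.
patient_inputs <- function(x) {
  if (is.character(x) && length(x) == 1) x <- read_patient_config(x)
  if (inherits(x, "ire_patient") || inherits(x, "ire_patient_config")) {
    if (is.null(x$ablation_volume) && is.null(x$target_volume))
      stop("patient has no target ablation volume")
    return(list(
      domain = x$domain, electrodes = x$electrodes, plan = x$plan,
      measured_current = x$measured_current,
      target_volume = if (!is.null(x$target_volume)) x$target_volume else x$ablation_volume,
      sigma0 = x$sigma0, e_center = x$e_center, e_width = x$e_width))
  }
  stop("'patient' must be an ire_patient, an ire_patient_config, or a config file path")
}

#' Read a patient treatment configuration
#'
#' Parses and validates a JSON patient config: domain settings, electrode
#' geometry, the activation plan (rebuilt from the voltage-to-distance rule
#' when absent), measurements (first-pair current, target ablation volume),
#' and the tissue model parameters. Units are fixed by the schema: cm for
#' lengths, V, A, cm^3, S/m, V/cm.
#'
#' @param path Path to a JSON config written by [write_patient_config()] or
#'   assembled by hand.
#' @return A list of class `ire_patient_config` with materialized
#'   `domain`, `electrodes`, `plan`, `measured_current` (NULL when not
#'   recorded; inference then runs static-only), `target_volume`, tissue
#'   parameters, and any ground-truth block carried through.
#' @export
read_patient_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- function(name) {
    if (is.null(cfg[[name]]))
      stop(sprintf("config field '%s' is required", name))
    cfg[[name]]
  }
  dm <- req("domain")
  if (is.null(dm$edge_length_cm) || is.null(dm$resolution))
    stop("config field 'domain' must provide 'edge_length_cm' and 'resolution'")
  domain <- make_domain(dm$edge_length_cm, dm$resolution)

  el <- req("electrodes")
  if (is.data.frame(el)) el <- split(el, seq_len(nrow(el)))
  electrodes <- lapply(el, function(e) {
    if (is.null(e$tip_position_cm) || is.null(e$exposure_length_cm))
      stop("each electrode needs 'tip_position_cm' and 'exposure_length_cm'")
    electrode(tip_position = unlist(e$tip_position_cm),
              axis = if (!is.null(e$axis)) unlist(e$axis) else c(0, 0, 1),
              exposure_length = e$exposure_length_cm,
              radius = if (!is.null(e$radius_cm)) e$radius_cm else 0.05)
  })
  names(electrodes) <- NULL
  bad <- !vapply(electrodes, electrode_inside_domain, logical(1), domain = domain)
  if (any(bad))
    stop(sprintf("electrode(s) %s extend outside the domain",
                 paste(which(bad), collapse = ", ")))

  proto <- cfg$protocol
  ratio <- if (!is.null(proto$ratio_v_per_cm)) proto$ratio_v_per_cm else 1500
  cap <- if (!is.null(proto$cap_v)) proto$cap_v else 3000

  if (!is.null(cfg$plan)) {
    pl <- as.data.frame(cfg$plan)
    need <- c("source", "sink", "spacing_cm", "voltage_v")
    if (!all(need %in% names(pl)))
      stop(sprintf("config 'plan' must have columns %s", paste(need, collapse = ", ")))
    if (any(pl$voltage_v > cap))
      stop(sprintf("plan voltage %g V exceeds the generator cap (%g V)",
                   max(pl$voltage_v), cap))
    if (any(pl$spacing_cm <= 0)) stop("plan spacings must be positive (cm)")
    rule_v <- pair_voltage(pl$spacing_cm, ratio, cap)
    if (any(abs(pl$voltage_v - rule_v) > 0.5))
      warning("plan voltages deviate from the voltage-to-distance rule")
    plan <- order_plan(data.frame(source = as.integer(pl$source),
                                  sink = as.integer(pl$sink),
                                  spacing = pl$spacing_cm,
                                  voltage = pl$voltage_v))
    attr(plan, "ratio") <- ratio; attr(plan, "cap") <- cap
  } else {
    plan <- treatment_plan(electrodes, ratio = ratio, cap = cap)
  }

  meas <- cfg$measurements
  measured_current <- meas$measured_current_a
  if (!is.null(measured_current) && (!is.numeric(measured_current) || measured_current <= 0))
    stop("'measurements$measured_current_a' must be positive (A)")
  target_volume <- meas$target_volume_cm3
  if (is.null(target_volume) && !is.null(cfg$mask_file)) {
    mpath <- cfg$mask_file
    if (!file.exists(mpath))
      mpath <- file.path(dirname(path), cfg$mask_file)
    target_volume <- mask_volume(read_mask_nifti(mpath))
  }
  if (!is.null(target_volume) && (!is.numeric(target_volume) || target_volume <= 0))
    stop("'measurements$target_volume_cm3' must be positive (cm^3)")

  tis <- cfg$tissue
  structure(
    list(patient_id = cfg$patient_id, domain = domain, electrodes = electrodes,
         plan = plan, measured_current = measured_current,
         target_volume = target_volume,
         delta_current = meas$delta_current_a,
         psa_pre = cfg$psa_pre_ng_ml,
         sigma0 = if (!is.null(tis$sigma0_s_per_m)) tis$sigma0_s_per_m else 0.284,
         e_center = if (!is.null(tis$e_center_v_per_cm)) tis$e_center_v_per_cm else 500,
         e_width = if (!is.null(tis$e_width_v_per_cm)) tis$e_width_v_per_cm else 800,
         ground_truth = cfg$ground_truth, seed = cfg$seed),
    class = "ire_patient_config")
}

#' Write a patient treatment configuration
#'
#' Serializes a synthetic patient or materialized config to the JSON schema
#' read by [read_patient_config()]. Numbers are written at full precision
#' so export/import round-trips are lossless.
#'
#' @param patient An `ire_patient` or `ire_patient_config`.
#' @param path Output path (`.json`).
#' @param mask_file Optional path (relative to `path`) of an exported mask
#'   to reference from the config.
#' @return `path`, invisibly.
#' @export
write_patient_config <- function(patient, path, mask_file = NULL) {
  stopifnot(inherits(patient, "ire_patient") ||
            inherits(patient, "ire_patient_config"))
  electrodes <- lapply(patient$electrodes, function(e) {
    list(tip_position_cm = e$tip_position, axis = e$axis,
         exposure_length_cm = e$exposure_length, radius_cm = e$radius)
  })
  plan <- patient$plan
  cfg <- list(
    patient_id = patient$patient_id,
    domain = list(edge_length_cm = patient$domain$edge_length,
                  resolution = patient$domain$resolution),
    electrodes = electrodes,
    protocol = list(ratio_v_per_cm = attr(plan, "ratio"),
                    cap_v = attr(plan, "cap"),
                    pulses = attr(plan, "pulses"),
                    pulse_length_us = attr(plan, "pulse_length_us")),
    plan = data.frame(source = plan$source, sink = plan$sink,
                      spacing_cm = plan$spacing, voltage_v = plan$voltage),
    measurements = local({
      m <- list(
        measured_current_a = patient$measured_current,
        target_volume_cm3 = if (!is.null(patient$target_volume))
          patient$target_volume else patient$ablation_volume,
        delta_current_a = patient$delta_current)
      m[!vapply(m, is.null, logical(1))]
    }),
    psa_pre_ng_ml = patient$psa_pre,
    tissue = list(sigma0_s_per_m = patient$sigma0,
                  e_center_v_per_cm = patient$e_center,
                  e_width_v_per_cm = patient$e_width),
    seed = patient$seed)
  if (!is.null(patient$sigma_max_true) || !is.null(patient$threshold_true))
    cfg$ground_truth <- list(sigma_max_true_s_per_m = patient$sigma_max_true,
                             threshold_true_v_per_cm = patient$threshold_true)
  if (!is.null(mask_file)) cfg$mask_file <- mask_file
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Export a synthetic patient as config + mask files
#'
#' Writes `<id>.json` and, when the patient carries an ablation mask,
#' `<id>_mask.nii.gz`, into `dir`.
#'
#' @param patient An `ire_patient`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_patient <- function(patient, dir) {
  stopifnot(inherits(patient, "ire_patient"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- patient$patient_id
  paths <- c(config = file.path(dir, paste0(id, ".json")))
  mask_file <- NULL
  if (!is.null(patient$mask)) {
    paths["mask"] <- file.path(dir, paste0(id, "_mask.nii.gz"))
    write_mask_nifti(patient$mask, paths["mask"])
    mask_file <- basename(paths["mask"])
  }
  write_patient_config(patient, paths["config"], mask_file = mask_file)
  invisible(paths)
}
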