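#' Generate a synthetic patient cohort
#'
#' Emulates the study inputs so the full inference chain can be validated
#' closed-loop without clinical data. Each patient gets a four-needle
#' square geometry with spacing drawn from the clinical range, a planted
#' ground-truth conductivity ceiling and lethal threshold, a forward-model
#' "measured" current (optionally noised), and an ablation mask defined as
#' the super-level set of the forward dynamic field at the planted
#' threshold. Pre-treatment PSA is drawn through a Gaussian copula with a
#' planted (negative) correlation to the threshold, mirroring the observed
#' clinical association without asserting a mechanism.
#'
#' Sampling ranges default to the clinical cohort: spacing 1.4-2.2 cm,
#' exposure 1.5 or 2.0 cm, `sigma_max` 0.55-1.0 S/m, threshold 412-614
#' V/cm, PSA 3.8-10.03 ng/mL.
#'
#' Randomness is fully reproducible: the master `seed` spawns one substream
#' per patient, so a cohort of size n extends a cohort of size m < n
#' without reshuffling, and regeneration with the same seed is
#' bit-identical.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Master seed (integer).
#' @param resolution Grid resolution for the forward model.
#' @param edge_length Domain edge (cm).
#' @param current_noise Relative standard deviation of multiplicative
#'   Gaussian noise on the measured current (0 = noise-free, default 0.01).
#' @param rho_psa Planted latent correlation between PSA and threshold
#'   (default -0.624, the observed clinical value).
#' @param spacing_range,exposure_choices,sigma_max_range,threshold_range,psa_range
#'   Sampling ranges for the cohort.
#' @param sigma0,e_center,e_width Tissue-model constants shared by all
#'   patients.
#' @param fields How much of the forward model to run per patient:
#'   `"full"` (default) solves the whole plan and builds the ablation
#'   mask; `"current"` solves only the first-pair activation (enough for a
#'   measured current and `delta_current`, e.g. for calibration studies);
#'   `"none"` generates geometry, ground truth and PSA only — convenient
#'   for cheap cohort-level statistics of the sampler itself.
#' @param control An `ire_solver_control` for the forward solves.
#' @return List of `ire_patient` objects (class `ire_cohort`).
#' @export
generate_cohort <- function(n_patients, seed, resolution = 64,
                            edge_length = 7.5, current_noise = 0.01,
                            rho_psa = -0.624,
                            spacing_range = c(1.4, 2.2),
                            exposure_choices = c(1.5, 2.0),
                            sigma_max_range = c(0.55, 1.0),
                            threshold_range = c(412, 614),
                            psa_range = c(3.8, 10.03),
                            sigma0 = 0.284, e_center = 500, e_width = 800,
                            fields = c("full", "current", "none"),
                            control = solver_control()) {
  stopifnot(n_patients >= 1, abs(rho_psa) <= 1)
  fields <- match.arg(fields)
  set.seed(as.integer(seed))
  substreams <- sample.int(.Machine$integer.max - 1L, 2L * n_patients)
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    sub <- substreams[i]
    for (attempt in 0:4) {
      p <- tryCatch(
        generate_patient(i, sub + attempt, resolution, edge_length,
                         current_noise, rho_psa, spacing_range,
                         exposure_choices, sigma_max_range, threshold_range,
                         psa_range, sigma0, e_center, e_width, fields,
                         control),
        error = function(e) e)
      if (!inherits(p, "error")) break
      message(sprintf("patient %d: regenerating with next substream (%s)",
                      i, conditionMessage(p)))
    }
    if (inherits(p, "error")) stop(p)
    patients[[i]] <- p
  }
  structure(patients, class = "ire_cohort")
}

generate_patient <- function(i, sub_seed, resolution, edge_length,
                             current_noise, rho_psa, spacing_range,
                             exposure_choices, sigma_max_range,
                             threshold_range, psa_range, sigma0, e_center,
                             e_width, fields, control) {
  set.seed(sub_seed)
  # draw everything up front so fields = TRUE/FALSE see the same patient
  spacing <- runif(1, spacing_range[1], spacing_range[2])
  exposure <- sample(exposure_choices, 1)
  sigma_max_true <- runif(1, sigma_max_range[1], sigma_max_range[2])
  z1 <- rnorm(1)
  z2 <- rho_psa * z1 + sqrt(1 - rho_psa^2) * rnorm(1)
  noise_eps <- rnorm(1)
  threshold_true <- stats::qunif(stats::pnorm(z1), threshold_range[1],
                                 threshold_range[2])
  psa_pre <- stats::qunif(stats::pnorm(z2), psa_range[1], psa_range[2])

  domain <- make_domain(edge_length, resolution)
  electrodes <- place_electrode_grid(4, spacing, exposure, domain = domain)
  plan <- treatment_plan(electrodes)

  patient <- list(
    patient_id = sprintf("S%02d", i), seed = sub_seed,
    spacing = spacing, exposure_length = exposure,
    domain = domain, electrodes = electrodes, plan = plan,
    sigma0 = sigma0, e_center = e_center, e_width = e_width,
    sigma_max_true = sigma_max_true, threshold_true = threshold_true,
    psa_pre = psa_pre, current_noise = current_noise,
    measured_current = NULL, delta_current = NULL,
    mask = NULL, ablation_volume = NULL)

  if (fields != "none") {
    truth <- tissue_model(sigma0 = sigma0, sigma_max = sigma_max_true,
                          e_center = e_center, e_width = e_width,
                          mode = "dynamic")
    first_static <- solve_pair(domain, electrodes,
                               c(plan$source[1], plan$sink[1]),
                               plan$voltage[1],
                               tissue_model(sigma0 = sigma0, mode = "static"),
                               control = control)
    if (fields == "full") {
      fwd <- run_plan(domain, electrodes, plan, truth, control = control)
      i_first <- fwd$currents[1]
      mask <- superlevel_mask(fwd$e_max, domain, threshold_true)
      vol <- mask_volume(mask)
      if (vol <= 0) stop("degenerate geometry: empty ablation volume")
      patient$mask <- mask
      patient$ablation_volume <- vol
    } else {
      first_dyn <- solve_pair(domain, electrodes,
                              c(plan$source[1], plan$sink[1]),
                              plan$voltage[1], truth, control = control,
                              phi0 = first_static$phi)
      i_first <- first_dyn$source_current
    }
    patient$measured_current <- i_first * (1 + current_noise * noise_eps)
    patient$delta_current <- i_first - first_static$source_current
  }
  structure(patient, class = "ire_patient")
}

#' @export
print.ire_patient <- function(x, ...) {
  cat(sprintf("Synthetic IRE patient %s: spacing %.2f cm, exposure %.1f cm",
              x$patient_id, x$spacing, x$exposure_length))
  if (!is.null(x$ablation_volume))
    cat(sprintf(", ablation %.2f cm^3, I = %.1f A", x$ablation_volume,
                x$measured_current))
  cat(sprintf("\n  ground truth: sigma_max %.3f S/m, threshold %.1f V/cm; PSA %.2f ng/mL\n",
              x$sigma_max_true, x$threshold_true, x$psa_pre))
  invisible(x)
}

#' @export
print.ire_cohort <- function(x, ...) {
  cat(sprintf("Synthetic IRE cohort: %d patients\n", length(x)))
  print(cohort_table(x))
  invisible(x)
}

#' Cohort summary table
#'
#' One row per patient in the layout of the clinical treatment-
#' characteristics table: PSA, maximum voltage, maximum spacing, change in
#' current, (ground-truth) threshold, ablation volume.
#'
#' @param cohort An `ire_cohort` from [generate_cohort()].
#' @return A data frame.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "ire_cohort"))
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id,
               psa_pre = p$psa_pre,
               max_voltage = max(p$plan$voltage),
               max_spacing = max(p$plan$spacing),
               delta_current = if (!is.null(p$delta_current)) p$delta_current else NA_real_,
               threshold_true = p$threshold_true,
               sigma_max_true = p$sigma_max_true,
               ablation_volume = if (!is.null(p$ablation_volume)) p$ablation_volume else NA_real_)
  }))
}
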