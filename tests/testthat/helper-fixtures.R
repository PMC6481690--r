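# Shared fixtures for the solver tests. Everything is built in code; the
# coarse 32^3 grid keeps unit tests fast while the acceptance suite
# re-checks the oracles at higher resolution.

coarse_domain <- function(resolution = 32) make_domain(7.5, resolution)

square_setup <- function(spacing = 2.0, exposure = 2.0, resolution = 32) {
  domain <- coarse_domain(resolution)
  electrodes <- place_electrode_grid(4, spacing, exposure, domain = domain)
  list(domain = domain, electrodes = electrodes,
       plan = treatment_plan(electrodes))
}

# Parallel-plate surrogate: the first and last x-slabs of voxels are metal
# plates at V and 0; the inter-surface gap is edge - 2h.
plate_problem <- function(domain, sigma0 = 0.284, voltage = 100) {
  n <- domain$resolution
  sigma <- array(sigma0, domain$dims)
  sigma[c(1, n), , ] <- 2e6
  dirichlet <- array(FALSE, domain$dims)
  dirichlet[c(1, n), , ] <- TRUE
  values <- array(0, domain$dims)
  values[1, , ] <- voltage
  source_mask <- array(FALSE, domain$dims); source_mask[1, , ] <- TRUE
  list(sigma = sigma, dirichlet = dirichlet, values = values,
       source_mask = source_mask, gap_cm = domain$edge_length - 2 * domain$spacing,
       voltage = voltage, sigma0 = sigma0)
}

# Concentric-cylinder surrogate: metal core of radius a at V, metal beyond
# radius b grounded, z-invariant so the analytic 2*pi*sigma*L*V/ln(b/a)
# applies with L the full domain height.
cylinder_problem <- function(domain, a = 1.0, b = 3.5, sigma0 = 0.284,
                             voltage = 100) {
  cc <- axis_centers(domain)
  r2 <- outer(cc[[1]]^2, cc[[2]]^2, `+`)
  inner <- array(rep(r2 <= a^2, domain$resolution), domain$dims)
  outer_m <- array(rep(r2 >= b^2, domain$resolution), domain$dims)
  sigma <- array(sigma0, domain$dims)
  sigma[inner | outer_m] <- 2e6
  values <- array(0, domain$dims)
  values[inner] <- voltage
  i_true <- 2 * pi * sigma0 * (domain$edge_length / 100) * voltage / log(b / a)
  list(sigma = sigma, dirichlet = inner | outer_m, values = values,
       inner = inner, current_true = i_true, voltage = voltage)
}

plate_current <- function(domain, prob, phi) {
  irethreshold:::region_current(phi, prob$sigma, domain, prob$source_mask)
}

region_current_of <- function(domain, sigma, phi, region) {
  irethreshold:::region_current(phi, sigma, domain, region)
}
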