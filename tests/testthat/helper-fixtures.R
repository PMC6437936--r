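# in-code fixtures: every test input is generated at run time

write_saxs_ascii <- function(q, I, sigma = NULL, header = "# q I sigma") {
  path <- withr::local_tempfile(fileext = ".dat", .local_envir = parent.frame())
  rows <- if (is.null(sigma)) paste(q, I) else paste(q, I, sigma)
  writeLines(c(header, rows), path)
  path
}

write_dsc_csv <- function(temperature, cp) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(data.frame(temperature = temperature, cp = cp), path,
                   row.names = FALSE)
  path
}

# public-path constructor for a kelvin thermogram via the CSV reader
make_thermogram <- function(temperature, cp, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  utils::write.csv(data.frame(temperature = temperature, cp = cp), path,
                   row.names = FALSE)
  read_thermogram(path, temperature_units = "kelvin")
}

# rotate a matrix by 90 degrees (counter-clockwise)
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

default_saxs_truth <- function() {
  bilayer_model(z_H = 20.1, sigma_H = 2.5, rho_C = -1.2, sigma_C = 4,
                d = 65.8, N_layers = 5L, eta = 0.1, N_UV = 0.52,
                scale = 1, background = 1e-3)
}

# independent quadrature oracle for the form factor: numerically Fourier-
# transform the real-space three-Gaussian profile
form_factor_quadrature <- function(q, z_H, sigma_H, rho_C, sigma_C) {
  vapply(q, function(qi) {
    stats::integrate(function(z) {
      (exp(-(z - z_H)^2 / (2 * sigma_H^2)) +
         exp(-(z + z_H)^2 / (2 * sigma_H^2)) +
         rho_C * exp(-z^2 / (2 * sigma_C^2))) * cos(qi * z)
    }, lower = -60, upper = 60, rel.tol = 1e-10)$value
  }, numeric(1))
}
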