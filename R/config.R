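#' Run configuration for a membrane analysis pipeline
#'
#' Collects the unit conventions, physical constants and calibration values
#' shared by the readers and analysis stages. All analysis functions take the
#' specific values they need as arguments; a `membrane_config` is a validated
#' bundle that can be loaded from YAML and passed around a scripted pipeline.
#'
#' @param q_units Units of the scattering vector in input files, one of
#'   `"inverse_angstrom"` or `"inverse_nanometer"`. Internally q is always in
#'   inverse Angstrom.
#' @param channel_order Page order of two-channel image stacks, one of
#'   `"blue_first"` (440-nm band on odd pages) or `"red_first"`.
#' @param temperature_units Units of temperature in DSC input files, one of
#'   `"celsius"` or `"kelvin"`. Internally temperature is always kelvin.
#' @param gas_constant Gas constant R, cal mol^-1 K^-1. The default 1.9872
#'   makes the van't Hoff enthalpy come out in kcal/mol directly.
#' @param reference_gp Generalized polarization of the laurdan calibration
#'   standard (e.g. in DMSO), dimensionless in (-1, 1). No default is
#'   hardcoded; supply the value for your standard.
#' @param random_seed Integer seed used by the synthetic-data generators.
#' @param logging_level One of `"quiet"`, `"info"`, `"debug"`.
#'
#' @return An object of class `membrane_config` (a named list).
#' @examples
#' cfg <- membrane_config(q_units = "inverse_nanometer", reference_gp = 0.2)
#' cfg$gas_constant
#' @export
membrane_config <- function(q_units = c("inverse_angstrom", "inverse_nanometer"),
                            channel_order = c("blue_first", "red_first"),
                            temperature_units = c("celsius", "kelvin"),
                            gas_constant = 1.9872,
                            reference_gp = NULL,
                            random_seed = 1L,
                            logging_level = c("info", "quiet", "debug")) {
  q_units <- match.arg(q_units)
  channel_order <- match.arg(channel_order)
  temperature_units <- match.arg(temperature_units)
  logging_level <- match.arg(logging_level)
  if (!is.numeric(gas_constant) || length(gas_constant) != 1L || gas_constant <= 0) {
    stop("`gas_constant` must be a single positive number", call. = FALSE)
  }
  if (!is.null(reference_gp)) {
    if (!is.numeric(reference_gp) || length(reference_gp) != 1L ||
        reference_gp <= -1 || reference_gp >= 1) {
      stop("`reference_gp` must lie strictly inside (-1, 1)", call. = FALSE)
    }
  }
  structure(
    list(
      q_units = q_units,
      channel_order = channel_order,
      temperature_units = temperature_units,
      gas_constant = gas_constant,
      reference_gp = reference_gp,
      random_seed = as.integer(random_seed),
      logging_level = logging_level
    ),
    class = "membrane_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are an error (they are almost always typos); missing keys take
#' the [membrane_config()] defaults.
#'
#' @param path Path to a YAML file whose top-level keys match the arguments of
#'   [membrane_config()].
#' @return A `membrane_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(membrane_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(membrane_config, vals)
}

#' @export
print.membrane_config <- function(x, ...) {
  cat("<membrane_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, if (is.null(v)) "<unset>" else format(v)))
  }
  invisible(x)
}

msg_info <- function(..., level = "info") {
  if (!identical(getOption("membranalysis.quiet", FALSE), TRUE)) {
    message(...)
  }
  invisible(NULL)
}
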