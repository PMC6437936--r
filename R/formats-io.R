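#' Read a 1-D SAXS curve from a whitespace-delimited ASCII file
#'
#' Expects at least two columns (q, intensity) and optionally a third with the
#' intensity uncertainty. Lines starting with `#` are comments. q is converted
#' to inverse Angstrom on the way in (1 nm^-1 = 0.1 A^-1), the unit every
#' downstream model function assumes.
#'
#' When the uncertainty column is absent a Poisson-like counting default
#' `sqrt(max(I, 1))` is filled in, with a warning: fits weighted by a guessed
#' sigma should be interpreted accordingly. Rows containing non-finite values
#' are dropped and counted in a message.
#'
#' @param path Path to the ASCII file.
#' @param q_units Units of the q column in the file, `"inverse_angstrom"` or
#'   `"inverse_nanometer"`.
#' @return A `scattering_curve`: a tibble with columns `q` (A^-1, strictly
#'   increasing), `intensity` (arbitrary units) and `sigma` (same units).
#' @examples
#' tf <- tempfile(fileext = ".dat")
#' writeLines(c("# q I sigma", "0.5 100 10", "1.0 50 7"), tf)
#' read_scattering_curve(tf, q_units = "inverse_nanometer")
#' @export
read_scattering_curve <- function(path,
                                  q_units = c("inverse_angstrom", "inverse_nanometer")) {
  q_units <- match.arg(q_units)
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("q", "intensity", "sigma")[1:3],
                           fill = TRUE, colClasses = "numeric")
  if (nrow(raw) == 0L) stop("empty scattering file: ", path, call. = FALSE)
  if (all(is.na(raw$sigma))) {
    raw$sigma <- sqrt(pmax(raw$intensity, 1))
    warning("no uncertainty column in ", basename(path),
            "; using sqrt(max(I, 1)) counting default", call. = FALSE)
  }
  finite <- is.finite(raw$q) & is.finite(raw$intensity) & is.finite(raw$sigma)
  if (any(!finite)) {
    msg_info(sum(!finite), " non-finite row(s) dropped from ", basename(path))
    raw <- raw[finite, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("no finite rows in scattering file: ", path, call. = FALSE)
  bad_sigma <- which(raw$sigma < 0)
  if (length(bad_sigma)) {
    stop("negative sigma at data line ", bad_sigma[1], " of ", path, call. = FALSE)
  }
  nonmono <- which(diff(raw$q) <= 0)
  if (length(nonmono)) {
    stop("q not strictly increasing at data line ", nonmono[1] + 1L, " of ", path,
         call. = FALSE)
  }
  if (q_units == "inverse_nanometer") raw$q <- raw$q * 0.1
  new_scattering_curve(raw$q, raw$intensity, raw$sigma)
}

new_scattering_curve <- function(q, intensity, sigma) {
  stopifnot(length(q) == length(intensity), length(q) == length(sigma))
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  if (any(diff(q) <= 0)) stop("q must be strictly increasing", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  tibble::new_tibble(
    tibble::tibble(q = as.numeric(q), intensity = as.numeric(intensity),
                   sigma = as.numeric(sigma)),
    class = "scattering_curve"
  )
}

#' Read a DSC thermogram from CSV
#'
#' Expects a header with columns `temperature` and `cp` (apparent molar heat
#' capacity), one scan per file. Temperature is stored in kelvin internally;
#' a stable sort enforces increasing temperature and duplicate temperatures
#' are averaged.
#'
#' @param path Path to the CSV file.
#' @param temperature_units Units of the temperature column, `"celsius"` or
#'   `"kelvin"`.
#' @param scan_rate Scan rate in K/min, kept as metadata.
#' @return A `thermogram`: a tibble with columns `temperature` (K, strictly
#'   increasing) and `cp` (kcal mol^-1 K^-1), with attributes `scan_rate` and
#'   `baseline_subtracted`.
#' @export
read_thermogram <- function(path,
                            temperature_units = c("celsius", "kelvin"),
                            scan_rate = 0.5) {
  temperature_units <- match.arg(temperature_units)
  raw <- utils::read.csv(path)
  names(raw) <- tolower(names(raw))
  if (!all(c("temperature", "cp") %in% names(raw))) {
    stop("thermogram CSV must have columns `temperature` and `cp`", call. = FALSE)
  }
  if (nrow(raw) < 10L) stop("scan too short to analyze (< 10 rows)", call. = FALSE)
  tK <- if (temperature_units == "celsius") raw$temperature + 273.15 else raw$temperature
  ord <- order(tK)  # stable
  tK <- tK[ord]
  cp <- raw$cp[ord]
  if (anyDuplicated(tK)) {
    agg <- stats::aggregate(cp, by = list(temperature = tK), FUN = mean)
    tK <- agg$temperature
    cp <- agg$x
  }
  new_thermogram(tK, cp, scan_rate = scan_rate, baseline_subtracted = FALSE)
}

new_thermogram <- function(temperature, cp, scan_rate = NA_real_,
                           baseline_subtracted = FALSE) {
  stopifnot(length(temperature) == length(cp))
  if (any(diff(temperature) <= 0)) {
    stop("temperature must be strictly increasing", call. = FALSE)
  }
  tibble::new_tibble(
    tibble::tibble(temperature = as.numeric(temperature), cp = as.numeric(cp)),
    scan_rate = scan_rate,
    baseline_subtracted = baseline_subtracted,
    class = "thermogram"
  )
}

#' Read a two-channel fluorescence image stack from a multi-page TIFF
#'
#' Pages are paired into time points: with `channel_order = "blue_first"` the
#' odd pages are the blue band (I440) and the even pages the red band (I490);
#' `"red_first"` swaps them. Pixel values are kept as acquired (non-negative,
#' the `tiff` package's native [0, 1] scaling is undone to integer counts when
#' the file declares an integer bit depth).
#'
#' @param path Path to the multi-page TIFF.
#' @param channel_order `"blue_first"` or `"red_first"`.
#' @param frame_interval Minutes between successive time points, used to fill
#'   the `timestamp` of each frame (first frame at 0).
#' @return A list of `two_channel_image` objects, one per time point.
#' @export
read_image_stack <- function(path,
                             channel_order = c("blue_first", "red_first"),
                             frame_interval = 1) {
  channel_order <- match.arg(channel_order)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (n %% 2L != 0L) stop("odd page count (", n, ") in ", path, call. = FALSE)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("pages of ", path, " have mismatched dimensions", call. = FALSE)
  }
  purrr::map(seq_len(n / 2L), function(i) {
    a <- pages[[2L * i - 1L]]
    b <- pages[[2L * i]]
    if (channel_order == "blue_first") {
      new_two_channel_image(I440 = a, I490 = b, timestamp = (i - 1) * frame_interval)
    } else {
      new_two_channel_image(I440 = b, I490 = a, timestamp = (i - 1) * frame_interval)
    }
  })
}

new_two_channel_image <- function(I440, I490, timestamp = 0) {
  I440 <- as.matrix(I440); I490 <- as.matrix(I490)
  if (!identical(dim(I440), dim(I490))) {
    stop("channel images must have equal dimensions", call. = FALSE)
  }
  if (any(!is.finite(I440)) || any(!is.finite(I490))) {
    stop("channel images must be finite", call. = FALSE)
  }
  if (any(I440 < 0) || any(I490 < 0)) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  structure(list(I440 = I440, I490 = I490, timestamp = as.numeric(timestamp)),
            class = "two_channel_image")
}

#' Write an image stack as multi-page TIFF
#'
#' Inverse of [read_image_stack()]: frames are interleaved back into pages in
#' the requested channel order as 16-bit unsigned TIFF.
#'
#' @param frames List of `two_channel_image` objects.
#' @param path Output path.
#' @param channel_order `"blue_first"` or `"red_first"`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path,
                              channel_order = c("blue_first", "red_first")) {
  channel_order <- match.arg(channel_order)
  pages <- purrr::flatten(purrr::map(frames, function(fr) {
    a <- fr$I440 / 65535
    b <- fr$I490 / 65535
    if (channel_order == "blue_first") list(a, b) else list(b, a)
  }))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write analysis results to JSON
#'
#' Serializes any of the package's result records (fits, transition parameters,
#' GP tables, ground truths) to a JSON document with a schema version, input
#' checksums and a configuration echo. Numeric values are written at full
#' precision so that write-then-read round-trips are lossless.
#'
#' @param results A named list of result records (each a list, tibble or
#'   scalar), or a single record.
#' @param path Output path.
#' @param inputs Optional character vector of input file paths; their MD5
#'   checksums are recorded.
#' @param config Optional `membrane_config` echoed into the document.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, inputs = character(), config = NULL) {
  doc <- list(
    schema_version = "1.0",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_checksums = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else {
      stats::setNames(list(), character())
    },
    config = if (is.null(config)) NULL else unclass(config),
    results = strip_classes(results)
  )
  con <- tryCatch(file(path, open = "w"), error = function(e) {
    stop("cannot open `", path, "` for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  # 17 significant digits: doubles survive the round trip bit-exactly
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              null = "null", na = "null"), con)
  invisible(path)
}

#' Read back a JSON results document
#'
#' @param path Path written by [write_results()].
#' @return The parsed document as a list with elements `schema_version`,
#'   `input_checksums`, `config` and `results`.
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = TRUE)
}

# drop S3 classes (keep structure) so jsonlite serializes records plainly
strip_classes <- function(x) {
  if (is.data.frame(x)) {
    return(lapply(as.list(as.data.frame(x)), unname))
  }
  if (is.list(x)) {
    return(lapply(unclass(x), strip_classes))
  }
  x
}
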