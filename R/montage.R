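## Standard sensor montage: 31 scalp channels of the international 10/20 (10/10)
## system with an FCz reference, positioned on a sphere in RAS coordinates
## (x right, y anterior, z superior) via the conventional spherical angles
## (inclination from the vertex signed by hemisphere, azimuth).

.besa_angles <- function() {
  # name, theta (deg, signed inclination), phi (deg, azimuth)
  m <- matrix(c(
    "Fp1",  -92, -72,   "Fp2",  92,  72,
    "F7",   -92, -36,   "F3",  -60, -51,   "Fz",  46,  90,
    "F4",    60,  51,   "F8",   92,  36,
    "FC5",  -71, -25,   "FC1", -32, -45,   "FC2", 32,  45,   "FC6", 71, 25,
    "T7",   -92,   0,   "C3",  -46,   0,   "Cz",   0,   0,
    "C4",    46,   0,   "T8",   92,   0,
    "TP9", -115,  18,   "CP5", -71,  25,   "CP1", -32,  45,
    "CP2",   32, -45,   "CP6",  71, -25,   "TP10", 115, -18,
    "P7",   -92,  36,   "P3",  -60,  51,   "Pz",  46, -90,
    "P4",    60, -51,   "P8",   92, -36,
    "O1",   -92,  72,   "Oz",   92, -90,   "O2",  92, -72,
    "POz",   69, -90,
    "FCz",   23,  90
  ), ncol = 3, byrow = TRUE)
  data.frame(name = m[, 1], theta = as.numeric(m[, 2]), phi = as.numeric(m[, 3]),
             stringsAsFactors = FALSE)
}

#' Standard 31-channel sensor array
#'
#' Builds the default 31-channel 10/20 scalp montage (the 31 EEG channels of
#' a 32-channel MR-compatible cap, reference at FCz) with unit positions
#' scaled to the scalp radius.
#'
#' @param scalp_radius_mm scalp sphere radius in mm (default 92)
#' @param reference reference channel label (default `"FCz"`; not a data row)
#' @return a `sensor_array`: data.frame of `name`, `x`, `y`, `z` (mm) with
#'   attributes `scalp_radius_mm` and `reference`
#' @export
standard_montage <- function(scalp_radius_mm = 92, reference = "FCz") {
  ang <- .besa_angles()
  ang <- ang[ang$name != reference, ]
  t <- ang$theta * pi / 180
  p <- ang$phi * pi / 180
  pos <- data.frame(
    name = ang$name,
    x = sin(t) * cos(p) * scalp_radius_mm,
    y = sin(t) * sin(p) * scalp_radius_mm,
    z = cos(t) * scalp_radius_mm,
    stringsAsFactors = FALSE
  )
  structure(pos,
            scalp_radius_mm = scalp_radius_mm,
            reference = reference,
            class = c("sensor_array", "data.frame"))
}

#' Read / write a montage file
#'
#' Plain-text format: one electrode per line, `name x y z` in mm,
#' whitespace-separated, `#` comments allowed.
#'
#' @param path file path
#' @param montage a `sensor_array`
#' @param reference reference label stored in a header comment
#' @return `read_montage` returns a `sensor_array`
#' @export
read_montage <- function(path) {
  lines <- readLines(path)
  ref <- "FCz"
  refline <- grep("^#\\s*reference:", lines, value = TRUE)
  if (length(refline)) ref <- trimws(sub("^#\\s*reference:", "", refline[1]))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad)) stop("montage file: each line must be 'name x y z'")
  df <- data.frame(
    name = vapply(parts, `[`, "", 1L),
    x = as.numeric(vapply(parts, `[`, "", 2L)),
    y = as.numeric(vapply(parts, `[`, "", 3L)),
    z = as.numeric(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$name)) stop("montage file: duplicate channel names")
  r <- sqrt(df$x^2 + df$y^2 + df$z^2)
  structure(df, scalp_radius_mm = stats::median(r), reference = ref,
            class = c("sensor_array", "data.frame"))
}

#' @rdname read_montage
#' @export
write_montage <- function(montage, path, reference = attr(montage, "reference") %||% "FCz") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# electrode positions (mm, RAS)",
               paste0("# reference: ", reference)), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", montage$name, montage$x, montage$y, montage$z), con)
  invisible(path)
}
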