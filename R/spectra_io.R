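#' Read a peak list from disk
#'
#' Two dialects are supported. `"tsv"` is a tab-separated table with the
#' header `label  delta_h_ppm  delta_c_ppm  intensity` (intensity column
#' optional, defaulting to 1). `"sparky"` is a Sparky-style `.list` file:
#' a header line followed by rows of `Assignment  w1  w2 [height]`, where
#' only the assignment token is used as the label and the shifts are taken
#' positionally (`w1` = \eqn{^1}H ppm, `w2` = \eqn{^{13}}C ppm).
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"sparky"`.
#' @param spectrum_id identifier to attach; defaults to the file name
#'   without extension.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, dialect = c("tsv", "sparky"),
                          spectrum_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_peaklist: file not found: ", path)
  if (is.null(spectrum_id))
    spectrum_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("read_peaklist: ", path, " has no data rows")
  header <- lines[[1L]]
  body <- lines[-1L]
  if (dialect == "tsv") {
    cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
    if (length(cols) < 3L || cols[1L] != "label" ||
        cols[2L] != "delta_h_ppm" || cols[3L] != "delta_c_ppm")
      stop("read_peaklist: unexpected TSV header in ", path, ": ", header)
    fields <- strsplit(body, "\t", fixed = TRUE)
  } else {
    fields <- strsplit(trimws(body), "[[:space:]]+")
  }
  n <- length(fields)
  lab <- character(n); dh <- numeric(n); dc <- numeric(n); ii <- numeric(n)
  for (k in seq_len(n)) {
    f <- fields[[k]]
    line_no <- k + 1L
    if (length(f) < 3L)
      stop(sprintf("read_peaklist: line %d of %s has %d field(s), need >= 3",
                   line_no, path, length(f)))
    vh <- suppressWarnings(as.numeric(f[2L]))
    vc <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(vh) || is.na(vc))
      stop(sprintf("read_peaklist: non-numeric chemical shift on line %d of %s",
                   line_no, path))
    vi <- if (length(f) >= 4L) suppressWarnings(as.numeric(f[4L])) else 1
    if (is.na(vi))
      stop(sprintf("read_peaklist: non-numeric intensity on line %d of %s",
                   line_no, path))
    lab[k] <- f[1L]; dh[k] <- vh; dc[k] <- vc; ii[k] <- vi
  }
  peaklist(lab, dh, dc, ii, spectrum_id = spectrum_id)
}

#' Write a peak list to disk
#'
#' Lossless for label, shifts and intensity (values written with 17
#' significant digits). See [read_peaklist()] for the dialects.
#'
#' @param pl a [peaklist()].
#' @param path output file.
#' @param dialect `"tsv"` or `"sparky"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path, dialect = c("tsv", "sparky")) {
  dialect <- match.arg(dialect)
  stopifnot(is_peaklist(pl))
  num <- function(x) formatC(x, format = "g", digits = 17)
  if (dialect == "tsv") {
    lines <- c("label\tdelta_h_ppm\tdelta_c_ppm\tintensity",
               paste(pl$label, num(pl$delta_h), num(pl$delta_c),
                     num(pl$intensity), sep = "\t"))
  } else {
    lines <- c("Assignment w1 w2 Height",
               paste(pl$label, num(pl$delta_h), num(pl$delta_c),
                     num(pl$intensity)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gridded 2D spectrum from disk
#'
#' Two plain-text containers are supported. `"csv_grid"`: the first row
#' holds an empty corner cell followed by the \eqn{^1}H ppm axis; every
#' following row holds a \eqn{^{13}}C ppm value followed by that row of
#' the intensity matrix. `"json_grid"`: a JSON object with fields
#' `axis_h`, `axis_c`, `intensities` (array of rows, \eqn{^{13}}C major)
#' and optional `metadata`.
#'
#' @param path file to read.
#' @param format `"csv_grid"` or `"json_grid"`.
#' @return A [spectrum2d()]. Axis orientation is preserved as stored and
#'   then normalized by the constructor.
#' @export
read_spectrum <- function(path, format = c("csv_grid", "json_grid")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_spectrum: file not found: ", path)
  if (format == "csv_grid") {
    raw <- utils::read.csv(path, header = FALSE, colClasses = "character")
    axis_h <- as.numeric(raw[1L, -1L])
    axis_c <- as.numeric(raw[-1L, 1L])
    mat <- as.matrix(raw[-1L, -1L, drop = FALSE])
    mat <- matrix(as.numeric(mat), nrow = length(axis_c))
    if (anyNA(axis_h) || anyNA(axis_c) || anyNA(mat))
      stop("read_spectrum: non-numeric entries in ", path)
    spectrum2d(axis_h, axis_c, mat)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("axis_h", "axis_c", "intensities"))
      if (is.null(obj[[f]]))
        stop("read_spectrum: JSON grid ", path, " lacks field '", f, "'")
    mat <- obj$intensities
    if (is.list(mat)) mat <- do.call(rbind, mat)
    if (!is.matrix(mat)) mat <- matrix(mat, nrow = length(obj$axis_c), byrow = TRUE)
    md <- if (is.null(obj$metadata)) list() else as.list(obj$metadata)
    spectrum2d(obj$axis_h, obj$axis_c, mat, metadata = md)
  }
}

#' Write a gridded 2D spectrum to disk
#'
#' Full double precision in both containers; see [read_spectrum()] for
#' the layouts.
#'
#' @param s a [spectrum2d()].
#' @param path output file.
#' @param format `"csv_grid"` or `"json_grid"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("csv_grid", "json_grid")) {
  format <- match.arg(format)
  stopifnot(is_spectrum2d(s))
  if (format == "csv_grid") {
    num <- function(x) formatC(x, format = "g", digits = 17)
    header <- paste(c("", num(s$axis_h)), collapse = ",")
    rows <- vapply(seq_along(s$axis_c), function(i) {
      paste(c(num(s$axis_c[i]), num(s$intensities[i, ])), collapse = ",")
    }, character(1))
    writeLines(c(header, rows), path)
  } else {
    md <- s$metadata
    md$orientation_h <- NULL; md$orientation_c <- NULL
    obj <- list(axis_h = s$axis_h, axis_c = s$axis_c,
                intensities = lapply(seq_along(s$axis_c),
                                     function(i) s$intensities[i, ]))
    if (length(md)) obj$metadata <- md
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
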