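# Shared two-column text dialect: '#' comment/header lines, blank lines
# ignored, whitespace- or comma-separated numeric fields.
read_two_column <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no data lines in ", path, call. = FALSE)
  x <- numeric(length(idx))
  y <- numeric(length(idx))
  for (i in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[i]]), "[,[:space:]]+")[[1L]]
    if (length(fields) != 2L) {
      stop(sprintf("parse error in %s at line %d: expected 2 columns, found %d",
                   path, idx[i], length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("parse error in %s at line %d: non-numeric field",
                   path, idx[i]), call. = FALSE)
    }
    x[i] <- vals[1L]
    y[i] <- vals[2L]
  }
  comments <- lines[grepl("^\\s*#", lines)]
  list(x = x, y = y, comments = comments)
}

write_two_column <- function(path, x, y, header = character()) {
  lines <- c(paste0("# ", header),
             sprintf("%.17g %.17g", x, y))
  writeLines(lines, path)
}

comment_value <- function(comments, key) {
  pat <- paste0("^#\\s*", key, "\\s*[=:]\\s*")
  hit <- grep(pat, comments, value = TRUE)
  if (!length(hit)) return(NA_real_)
  suppressWarnings(as.numeric(sub(pat, "", hit[1L])))
}

#' Read a dipolar trace file
#'
#' Two-column text (time in µs, amplitude); `#` lines are comments. A
#' `# noise_sd = <value>` comment, as written by [write_trace()], restores
#' the noise estimate.
#'
#' @param path File path.
#' @return A [dipolar_trace()].
#' @export
read_trace <- function(path) {
  d <- read_two_column(path)
  sd <- comment_value(d$comments, "noise_sd")
  dipolar_trace(d$x, d$y, if (is.finite(sd)) sd else 0)
}

#' Write a dipolar trace file
#'
#' @param trace A [dipolar_trace()].
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dipolar_trace"))
  write_two_column(path, as.numeric(trace$time), trace$signal,
                   c("dipolar trace: time (µs), amplitude",
                     sprintf("noise_sd = %.12g", trace$noise_sd)))
  invisible(path)
}

#' Read a distance distribution file
#'
#' Two-column text (distance in nm, density in 1/nm).
#'
#' @param path File path.
#' @return A [distance_distribution()].
#' @export
read_distribution <- function(path) {
  d <- read_two_column(path)
  distance_distribution(distance_grid(d$x), d$y)
}

#' Write a distance distribution file
#'
#' @param dist A [distance_distribution()].
#' @param path File path.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "distance_distribution"))
  write_two_column(path, as.numeric(dist$grid), dist$density,
                   "distance distribution: r (nm), P(r) (1/nm)")
  invisible(path)
}

#' Read a CW spectrum file
#'
#' Two-column text (field in mT, derivative amplitude).
#'
#' @param path File path.
#' @return A [cw_spectrum()].
#' @export
read_spectrum <- function(path) {
  d <- read_two_column(path)
  cw_spectrum(d$x, d$y)
}

#' Write a CW spectrum file
#'
#' @param spectrum A [cw_spectrum()].
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "cw_spectrum"))
  write_two_column(path, spectrum$field, spectrum$amplitude,
                   "CW spectrum: field (mT), dX''/dB")
  invisible(path)
}

# simple "key = value" files for scenario truth and report metadata
write_keyvalue <- function(x, path) {
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, character(1))
  writeLines(paste(names(x), "=", vals), path)
  invisible(path)
}

read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (p in parts) {
    if (length(p) != 3L) next
    val <- p[3L]
    num <- suppressWarnings(as.numeric(val))
    out[[p[2L]]] <- if (!is.na(num)) num else val
  }
  out
}
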