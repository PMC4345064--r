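#' @include AllClasses.R
NULL

# ---- CSV ------------------------------------------------------------------

.readSpectrumCSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CSV file: ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else if (grepl(",", lines[[1L]]))
    "," else ""
  parseRow <- function(ln) {
    fields <- if (nzchar(sep)) strsplit(ln, sep, fixed = TRUE)[[1L]] else
      strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    suppressWarnings(as.numeric(trimws(fields)))
  }
  first <- parseRow(lines[[1L]])
  start <- 1L
  if (anyNA(first)) start <- 2L            # one-line header allowed
  n <- length(lines) - start + 1L
  if (n < 2L) stop("CSV needs at least 2 data rows: ", path)
  w <- numeric(n); a <- numeric(n)
  for (i in seq_len(n)) {
    vals <- parseRow(lines[[start + i - 1L]])
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop(sprintf("malformed CSV row at line %d of '%s'",
                   start + i - 1L, path))
    w[i] <- vals[1L]; a[i] <- vals[2L]
  }
  list(wavenumbers = w, absorbance = a)
}

# ---- JCAMP-DX -------------------------------------------------------------

.jcampFields <- function(lines) {
  ldr <- grepl("^##", lines)
  keys <- sub("^##([^=]*)=.*$", "\\1", lines[ldr])
  vals <- sub("^##[^=]*=", "", lines[ldr])
  names(vals) <- toupper(gsub("[- _/]", "", keys))
  vals
}

.readSpectrumJCAMP <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- .jcampFields(lines)
  num <- function(key, default = NA_real_) {
    v <- fields[key]
    if (is.na(v)) default else suppressWarnings(as.numeric(v))
  }
  xyStart <- grep("^##XYPOINTS=", lines)
  dataStart <- grep("^##XYDATA=", lines)
  endAt <- grep("^##", lines)
  blockEnd <- function(start) {
    after <- endAt[endAt > start]
    if (length(after)) min(after) - 1L else length(lines)
  }
  xf <- num("XFACTOR", 1); yf <- num("YFACTOR", 1)
  if (length(xyStart)) {
    rows <- lines[seq(xyStart[1L] + 1L, blockEnd(xyStart[1L]))]
    rows <- rows[nzchar(trimws(rows))]
    toks <- unlist(strsplit(trimws(rows), "[;,[:space:]]+"))
    vals <- suppressWarnings(as.numeric(toks[nzchar(toks)]))
    if (anyNA(vals) || length(vals) %% 2L != 0L)
      stop("malformed XYPOINTS record in '", path, "'")
    w <- vals[seq(1L, length(vals), by = 2L)] * xf
    a <- vals[seq(2L, length(vals), by = 2L)] * yf
  } else if (length(dataStart)) {
    form <- toupper(gsub("[[:space:]]", "", fields["XYDATA"]))
    if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
      stop("unsupported XYDATA form '", fields["XYDATA"], "' in '", path,
           "'; only (X++(Y..Y)) is handled")
    rows <- lines[seq(dataStart[1L] + 1L, blockEnd(dataStart[1L]))]
    rows <- rows[nzchar(trimws(rows))]
    w <- numeric(0); a <- numeric(0)
    for (ri in seq_along(rows)) {
      toks <- strsplit(trimws(rows[[ri]]), "[[:space:]]+")[[1L]]
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals) || length(vals) < 2L)
        stop(sprintf("malformed XYDATA record %d in '%s' (AFFN expected)",
                     ri, path))
      ys <- vals[-1L]
      deltax <- num("DELTAX",
                    (num("LASTX") - num("FIRSTX")) / (num("NPOINTS") - 1))
      w <- c(w, (vals[1L] + deltax * (seq_along(ys) - 1L)) * xf)
      a <- c(a, ys * yf)
    }
  } else {
    stop("no XYPOINTS or XYDATA block found in '", path, "'")
  }
  np <- num("NPOINTS")
  if (is.finite(np) && np != length(w))
    stop(sprintf("NPOINTS=%d but %d points read from '%s'", np,
                 length(w), path))
  list(wavenumbers = w, absorbance = a)
}

#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV files carry two numeric columns (wavenumber, absorbance) with an
#' optional one-line header, comma/tab/whitespace separated. JCAMP-DX
#' files may store the trace as \code{XYPOINTS} pairs or an AFFN
#' \code{XYDATA=(X++(Y..Y))} table. Either grid direction is accepted;
#' storage is normalised to descending wavenumbers.
#'
#' @param path file path.
#' @param format \code{"csv"} or \code{"jcamp"}; guessed from the file
#'   extension when missing.
#' @param label optional class label to attach.
#' @return A \linkS4class{Spectrum}.
#' @seealso \code{\link{writeSpectrum}}
#' @export
readSpectrum <- function(path, format = c("auto", "csv", "jcamp"),
                         label = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(jdx|dx|jcm|jcamp)$", tolower(path))) "jcamp"
      else "csv"
  parsed <- switch(format, csv = .readSpectrumCSV(path),
                   jcamp = .readSpectrumJCAMP(path))
  Spectrum(parsed$wavenumbers, parsed$absorbance, label = label,
           meta = list(source = path, format = format))
}

#' Write a spectrum to CSV or JCAMP-DX
#'
#' JCAMP-DX output uses an \code{XYPOINTS=(XY..XY)} block with
#' \code{XUNITS=1/CM} and \code{YUNITS=ABSORBANCE}.
#'
#' @param x a \linkS4class{Spectrum}.
#' @param path destination file path.
#' @param format \code{"csv"} or \code{"jcamp"}; guessed from the
#'   extension when missing.
#' @return \code{path}, invisibly.
#' @export
writeSpectrum <- function(x, path, format = c("auto", "csv", "jcamp")) {
  stopifnot(is(x, "Spectrum"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(jdx|dx|jcm|jcamp)$", tolower(path))) "jcamp"
      else "csv"
  w <- x@wavenumbers; a <- x@absorbance
  if (format == "csv") {
    writeLines(c("wavenumber,absorbance",
                 sprintf("%.10g,%.10g", w, a)), path)
  } else {
    title <- if (!is.na(x@label)) x@label else "spectrum"
    writeLines(c(
      sprintf("##TITLE=%s", title),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ABSORBANCE",
      sprintf("##FIRSTX=%.10g", w[1L]),
      sprintf("##LASTX=%.10g", w[length(w)]),
      sprintf("##NPOINTS=%d", length(w)),
      "##XYPOINTS=(XY..XY)",
      sprintf("%.10g, %.10g", w, a),
      "##END="), path)
  }
  invisible(path)
}

#' Write a feature table to CSV
#'
#' One row per spectrum: \code{label} followed by the feature columns.
#' Schema version 1 (recorded in a leading comment line).
#'
#' @param features matrix or data.frame of features (rows = spectra).
#' @param labels character vector of class labels.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeFeaturesCSV <- function(features, labels, path) {
  df <- data.frame(label = labels, as.data.frame(features),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ftirherb features v1", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by \code{writeFeaturesCSV}
#'
#' @param path source path.
#' @return data.frame with a \code{label} column and feature columns.
#' @export
readFeaturesCSV <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
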