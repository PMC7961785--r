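# Spectrum container and spectral-table IO.
#
# The internal axis convention is wavenumbers in cm^-1, strictly ascending;
# files written in descending order (the common instrument convention for
# FTIR) are reversed on load.

MODALITIES <- c("FTIR", "RAMAN")
STAGES <- c("RAW", "PREPROCESSED", "SECOND_DERIVATIVE")

#' Construct a spectrum
#'
#' A spectrum is the package's basic unit of data: a wavenumber axis
#' (cm\eqn{^{-1}}, strictly increasing), matching intensities (absorbance for
#' FTIR, arbitrary counts for Raman), a modality, and sample metadata.
#'
#' @param wavenumbers numeric vector of cm\eqn{^{-1}} values; may be passed in
#'   descending order and is canonicalized to ascending.
#' @param intensities numeric vector, same length as `wavenumbers`.
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @param sample_id sample identifier string.
#' @param group group label, e.g. `"control"` or `"treated"`.
#' @param stage processing stage: `"RAW"`, `"PREPROCESSED"` or
#'   `"SECOND_DERIVATIVE"`.
#' @return an object of class `rbc_spectrum`.
#' @export
spectrum <- function(wavenumbers, intensities, modality,
                     sample_id = "s1", group = "control", stage = "RAW") {
  modality <- match.arg(toupper(modality), MODALITIES)
  stage <- match.arg(toupper(stage), STAGES)
  wavenumbers <- as.double(wavenumbers)
  intensities <- as.double(intensities)
  if (length(wavenumbers) != length(intensities))
    abort("wavenumbers and intensities differ in length")
  if (length(wavenumbers) < 2L)
    abort("a spectrum needs at least 2 points")
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)) ||
      anyNA(intensities) || any(!is.finite(intensities)))
    abort("non-finite values in spectrum; missing intensities are rejected, not imputed")
  d <- diff(wavenumbers)
  if (all(d < 0)) {             # descending file: canonicalize
    wavenumbers <- rev(wavenumbers)
    intensities <- rev(intensities)
    d <- -rev(d)
  }
  if (any(d == 0)) abort("duplicate wavenumbers in spectrum")
  if (any(d < 0)) abort("wavenumbers must be monotone (ascending or descending)")
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         modality = modality, sample_id = as.character(sample_id),
         group = as.character(group), stage = stage),
    class = "rbc_spectrum")
}

#' @export
print.rbc_spectrum <- function(x, ...) {
  cat(sprintf("<rbc_spectrum> %s %s [%s] %d pts, %.1f-%.1f cm-1, stage %s\n",
              x$sample_id, x$group, x$modality, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers), x$stage))
  invisible(x)
}

# update intensities keeping axis/metadata; used by all preprocessing ops
set_intensities <- function(s, y, stage = s$stage) {
  s$intensities <- as.double(y)
  s$stage <- stage
  s
}

#' Construct a spectrum set
#'
#' A collection of spectra with a group-to-sample mapping. Sample ids must be
#' unique within a modality and every group must be non-empty.
#'
#' @param spectra list of [spectrum()] objects.
#' @return an object of class `rbc_spectrum_set`.
#' @export
spectrum_set <- function(spectra) {
  if (!length(spectra)) abort("empty spectrum set")
  ok <- vapply(spectra, inherits, logical(1), "rbc_spectrum")
  if (!all(ok)) abort("all elements must be rbc_spectrum objects")
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  mod <- vapply(spectra, `[[`, character(1), "modality")
  grp <- vapply(spectra, `[[`, character(1), "group")
  if (anyDuplicated(paste(mod, ids)))
    abort("duplicate sample_id within a modality")
  groups <- split(ids, grp)
  structure(list(spectra = spectra, groups = groups),
            class = "rbc_spectrum_set")
}

#' @export
print.rbc_spectrum_set <- function(x, ...) {
  cat(sprintf("<rbc_spectrum_set> %d spectra, groups: %s\n",
              length(x$spectra),
              paste(sprintf("%s (n=%d)", names(x$groups),
                            lengths(x$groups)), collapse = ", ")))
  invisible(x)
}

# iterate helpers
set_modalities <- function(set) vapply(set$spectra, `[[`, character(1), "modality")
set_groups <- function(set) vapply(set$spectra, `[[`, character(1), "group")
set_ids <- function(set) vapply(set$spectra, `[[`, character(1), "sample_id")

split_fields <- function(line) {
  line <- sub("^\\s+", "", sub("\\s+$", "", line))
  if (grepl(",", line, fixed = TRUE)) strsplit(line, "\\s*,\\s*")[[1]]
  else strsplit(line, "[\t ]+")[[1]]
}

parse_two_column <- function(lines, path) {
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) abort("no data rows in ", path)
  first <- TRUE
  xs <- ys <- double(length(keep))
  n <- 0L
  for (i in keep) {
    f <- split_fields(lines[i])
    if (length(f) < 2L)
      abort(sprintf("parse error in %s at line %d: expected two columns", path, i))
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(v)) {
      # a fully non-numeric first row is a tolerated header; a partially
      # numeric row is always a parse error
      if (first && all(is.na(suppressWarnings(as.numeric(f))))) {
        first <- FALSE; next
      }
      abort(sprintf("parse error in %s at line %d: non-numeric row '%s'",
                    path, i, trimws(lines[i])))
    }
    first <- FALSE
    n <- n + 1L
    xs[n] <- v[1]; ys[n] <- v[2]
  }
  if (n < 2L) abort("fewer than 2 data points in ", path)
  list(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# Minimal JCAMP-DX-like reader: ##KEY=value headers, data after ##XYDATA= up
# to ##END. Supports (XY..XY) pair lines and (X++(Y..Y)) lines where each line
# starts with its X value followed by Y values at ##DELTAX spacing (or the
# spacing implied by FIRSTX/LASTX/NPOINTS).
parse_jcamp_like <- function(lines, path) {
  hdr <- list()
  data_start <- NA_integer_
  xy_form <- "pairs"
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "##")) {
      kv <- sub("^##", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq > 0) {
        key <- toupper(trimws(substr(kv, 1, eq - 1)))
        val <- trimws(substr(kv, eq + 1, nchar(kv)))
        hdr[[key]] <- val
        if (key == "XYDATA") {
          data_start <- i + 1L
          if (grepl("\\+\\+", val)) xy_form <- "xpp"
          break
        }
      }
    }
  }
  if (is.na(data_start)) abort("no ##XYDATA= block in ", path)
  xunits <- toupper(hdr[["XUNITS"]] %||% "1/CM")
  if (!xunits %in% c("1/CM", "CM-1", "CM^-1"))
    abort("unsupported ##XUNITS '", xunits, "' in ", path)
  end <- length(lines)
  for (j in data_start:length(lines)) {
    if (startsWith(trimws(lines[j]), "##END")) { end <- j - 1L; break }
  }
  body <- lines[data_start:end]
  body <- body[nzchar(trimws(body))]
  if (xy_form == "pairs") {
    parsed <- parse_two_column(body, path)
    return(parsed)
  }
  deltax <- suppressWarnings(as.numeric(hdr[["DELTAX"]] %||% NA))
  if (is.na(deltax)) {
    fx <- as.numeric(hdr[["FIRSTX"]] %||% NA)
    lx <- as.numeric(hdr[["LASTX"]] %||% NA)
    np <- as.numeric(hdr[["NPOINTS"]] %||% NA)
    if (anyNA(c(fx, lx, np)) || np < 2)
      abort("X++(Y..Y) data in ", path, " need ##DELTAX or FIRSTX/LASTX/NPOINTS")
    deltax <- (lx - fx) / (np - 1)
  }
  xs <- ys <- list()
  for (k in seq_along(body)) {
    f <- split_fields(body[k])
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      abort(sprintf("parse error in %s: non-numeric XYDATA line %d", path, k))
    if (length(v) < 2L) next
    x0 <- v[1]; yv <- v[-1]
    xs[[k]] <- x0 + deltax * (seq_along(yv) - 1)
    ys[[k]] <- yv
  }
  list(x = unlist(xs), y = unlist(ys))
}

#' Read a spectral table
#'
#' Reads a two-column wavenumber/intensity file (comma, tab or whitespace
#' delimited, optional single header line) or a JCAMP-DX-like block
#' (`##XUNITS=1/CM`, `##XYDATA=` with `(XY..XY)` pairs or `(X++(Y..Y))`
#' lines). Descending axes are reversed so the returned spectrum is always
#' ascending with `stage = "RAW"`.
#'
#' @param path file path.
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @param dialect `"auto"` (default), `"two_column"` or `"jcampdx_like"`.
#' @param sample_id,group metadata attached to the spectrum.
#' @return an [spectrum()] object.
#' @export
read_spectrum_table <- function(path, modality,
                                dialect = c("auto", "two_column", "jcampdx_like"),
                                sample_id = basename(path), group = "control") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    nz <- lines[nzchar(trimws(lines))]
    dialect <- if (length(nz) && startsWith(trimws(nz[1]), "##"))
      "jcampdx_like" else "two_column"
  }
  parsed <- if (dialect == "two_column") parse_two_column(lines, path)
            else parse_jcamp_like(lines, path)
  spectrum(parsed$x, parsed$y, modality, sample_id = sample_id,
           group = group, stage = "RAW")
}

#' Write a results table
#'
#' Writes a data frame as CSV with full double precision so that a
#' read-back round trip reproduces the numbers to better than 1e-9 relative
#' error.
#'
#' @param rows non-empty data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    abort("rows must be a non-empty data frame")
  num <- vapply(rows, is.numeric, logical(1))
  out <- rows
  out[num] <- lapply(rows[num], function(v) {
    ifelse(is.na(v), NA_character_,
           formatC(v, digits = 17, format = "g"))
  })
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort("cannot write table to ", path)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path CSV path.
#' @return data frame.
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a cohort manifest and its spectra
#'
#' The manifest is a delimited table with columns `sample_id`, `group`,
#' `modality`, `path` (paths relative to the manifest's directory or
#' absolute).
#'
#' @param manifest_path path to the manifest CSV/TSV.
#' @return an [spectrum_set()].
#' @export
read_cohort <- function(manifest_path) {
  man <- read_table_file(manifest_path)
  need <- c("sample_id", "group", "modality", "path")
  if (!all(need %in% names(man)))
    abort("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest_path)
  spectra <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p))
      abort("manifest entry for sample '", man$sample_id[i],
            "' references missing file: ", man$path[i])
    spectra[[i]] <- read_spectrum_table(p, man$modality[i],
                                        sample_id = man$sample_id[i],
                                        group = man$group[i])
  }
  spectrum_set(spectra)
}

#' Write one spectrum as a two-column table
#' @param s spectrum.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_spectrum_table <- function(s, path) {
  stopifnot(inherits(s, "rbc_spectrum"))
  df <- data.frame(wavenumber = s$wavenumbers, intensity = s$intensities)
  utils::write.table(df, path, sep = ",", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}
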