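#' Read a spectrum from a two-column CSV file
#'
#' Expects comma-delimited `wavenumber, absorbance` rows with '.' decimals
#' and at most one header line. The axis may run in either direction; the
#' returned spectrum is normalized to ascending wavenumber and the original
#' direction is recorded in `meta$original_direction`.
#'
#' @param path file path.
#' @param label optional label; defaults to the file name.
#' @return an [ir_spectrum].
#' @export
read_spectrum_csv <- function(path, label = basename(path)) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "atmcorr_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    abort(sprintf("%s: empty file", path), "atmcorr_too_short_error")
  parse_row <- function(line) {
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) return(c(NA_real_, NA_real_))
    suppressWarnings(as.numeric(trimws(parts[1:2])))
  }
  first <- parse_row(lines[1])
  start <- if (anyNA(first)) 2L else 1L  # tolerate one header line
  if (length(lines) - start + 1L < 2L)
    abort(sprintf("%s: fewer than 2 data rows", path), "atmcorr_too_short_error")
  vals <- vapply(lines[start:length(lines)], parse_row, numeric(2), USE.NAMES = FALSE)
  bad <- which(is.na(vals[1, ]) | is.na(vals[2, ]))
  if (length(bad))
    abort(sprintf("%s: non-numeric row at line %d: '%s'",
                  path, bad[1] + start - 1L, lines[bad[1] + start - 1L]),
          "atmcorr_parse_error")
  ir_spectrum(vals[1, ], vals[2, ], label = label)
}

#' Write a spectrum to a two-column CSV file
#'
#' Values are written with 17 significant digits so that a read/write round
#' trip reproduces the spectrum to better than 1e-12 relative. The spectrum
#' is written in its stored (ascending) order.
#'
#' @param s an [ir_spectrum].
#' @param path destination path.
#' @return invisibly `path`.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "ir_spectrum"))
  con <- tryCatch(file(path, "w"), error = function(e)
    abort(sprintf("cannot open %s for writing: %s", path, conditionMessage(e)),
          "atmcorr_io_error"))
  on.exit(close(con))
  writeLines("wavenumber_cm-1,absorbance_AU", con)
  writeLines(sprintf("%.17g,%.17g", s$wavenumbers, s$absorbance), con)
  invisible(path)
}

# --- JCAMP-DX 4.24, single block, AFFN ---------------------------------------

jdx_labels <- function(lines) {
  idx <- grep("^\\s*##", lines)
  lab <- sub("^\\s*##([^=]*)=.*$", "\\1", lines[idx])
  # canonical form: drop spaces/dashes/underscores, uppercase
  lab <- toupper(gsub("[ _-]", "", lab))
  val <- sub("^\\s*##[^=]*=", "", lines[idx])
  list(idx = idx, label = lab, value = trimws(val))
}

#' Read a spectrum from a JCAMP-DX file
#'
#' Supports single-block JCAMP-DX 4.24 with AFFN numerics, in either the
#' `XYPOINTS=(XY..XY)` pair dialect or the `XYDATA=(X++(Y..Y))` dialect
#' (axis reconstructed from FIRSTX/DELTAX, honoring XFACTOR/YFACTOR).
#' Y units must be absorbance.
#'
#' @param path file path.
#' @return an [ir_spectrum].
#' @export
read_jcampdx <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "atmcorr_io_error")
  lines <- readLines(path, warn = FALSE)
  hdr <- jdx_labels(lines)
  get1 <- function(name) {
    i <- which(hdr$label == name)
    if (length(i) == 0) NULL else hdr$value[i[1]]
  }
  yunits <- toupper(get1("YUNITS") %||% "")
  if (grepl("TRANSMIT", yunits))
    abort("JCAMP-DX file is in transmittance; convert to absorbance first",
          "atmcorr_unit_error")
  data_i <- which(hdr$label %in% c("XYDATA", "XYPOINTS"))
  if (length(data_i) == 0)
    abort("no XYDATA/XYPOINTS block found", "atmcorr_parse_error")
  if (length(data_i) > 1)
    abort("multi-block JCAMP-DX files are not supported", "atmcorr_dialect_error")
  kind <- hdr$label[data_i]
  start_line <- hdr$idx[data_i]
  end_i <- hdr$idx[hdr$idx > start_line]
  end_line <- if (length(end_i)) min(end_i) - 1L else length(lines)
  body <- lines[(start_line + 1L):end_line]
  body <- body[nzchar(trimws(body))]
  xfac <- as.numeric(get1("XFACTOR") %||% "1")
  yfac <- as.numeric(get1("YFACTOR") %||% "1")
  if (kind == "XYPOINTS") {
    toks <- unlist(strsplit(paste(body, collapse = " "), "[;,[:space:]]+"))
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals) || length(vals) %% 2 != 0)
      abort("malformed XYPOINTS block (non-AFFN or odd token count)",
            "atmcorr_parse_error")
    x <- vals[seq(1, length(vals), 2)] * xfac
    y <- vals[seq(2, length(vals), 2)] * yfac
  } else {
    # (X++(Y..Y)): each line starts with an X value followed by Y ordinates
    x <- numeric(0); y <- numeric(0)
    deltax <- as.numeric(get1("DELTAX") %||% NA)
    for (ln in body) {
      toks <- unlist(strsplit(trimws(ln), "[,[:space:]]+"))
      vals <- suppressWarnings(as.numeric(toks[nzchar(toks)]))
      if (anyNA(vals) || length(vals) < 2)
        abort(sprintf("malformed XYDATA line: '%s'", ln), "atmcorr_parse_error")
      x0 <- vals[1] * xfac
      ys <- vals[-1] * yfac
      dx <- if (!is.na(deltax)) deltax * xfac else {
        fx <- as.numeric(get1("FIRSTX")); lx <- as.numeric(get1("LASTX"))
        np <- as.numeric(get1("NPOINTS"))
        if (anyNA(c(fx, lx, np)) || np < 2)
          abort("XYDATA without DELTAX needs FIRSTX/LASTX/NPOINTS",
                "atmcorr_parse_error")
        (lx - fx) / (np - 1)
      }
      x <- c(x, x0 + dx * (seq_along(ys) - 1))
      y <- c(y, ys)
    }
  }
  ir_spectrum(x, y, label = get1("TITLE") %||% basename(path))
}

#' Write a spectrum as single-block JCAMP-DX (XYPOINTS, AFFN)
#'
#' @param s an [ir_spectrum].
#' @param path destination path.
#' @return invisibly `path`.
#' @export
write_jcampdx <- function(s, path) {
  stopifnot(inherits(s, "ir_spectrum"))
  con <- tryCatch(file(path, "w"), error = function(e)
    abort(sprintf("cannot open %s for writing: %s", path, conditionMessage(e)),
          "atmcorr_io_error"))
  on.exit(close(con))
  n <- length(s$wavenumbers)
  writeLines(c(
    sprintf("##TITLE=%s", if (nzchar(s$label)) s$label else "spectrum"),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    sprintf("##FIRSTX=%.17g", s$wavenumbers[1]),
    sprintf("##LASTX=%.17g", s$wavenumbers[n]),
    sprintf("##NPOINTS=%d", n),
    "##XYPOINTS=(XY..XY)",
    sprintf("%.17g, %.17g", s$wavenumbers, s$absorbance),
    "##END="
  ), con)
  invisible(path)
}

# --- interferent configuration ----------------------------------------------

#' Read an interferent configuration file
#'
#' JSON format: an array of objects
#' `{"name": ..., "correct_region": [lo, hi], "gamma_region": [lo, hi] | null}`.
#' The list order is the processing order.
#'
#' @param path file path.
#' @return list of [interferent_spec] objects.
#' @export
read_interferent_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), "atmcorr_config_error")
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                  error = function(e)
                    abort(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                          "atmcorr_config_error"))
  lapply(raw, function(item) {
    name <- item$name %||% "<unnamed>"
    cr <- item$correct_region
    if (is.null(cr) || length(cr) != 2 || anyNA(suppressWarnings(as.numeric(cr))))
      abort(sprintf("interferent '%s': malformed correct_region", name),
            "atmcorr_config_error")
    gr <- item$gamma_region
    gspec <- if (is.null(gr) || all(is.na(unlist(gr)))) NULL else {
      if (length(gr) != 2 || anyNA(suppressWarnings(as.numeric(gr))))
        abort(sprintf("interferent '%s': malformed gamma_region", name),
              "atmcorr_config_error")
      wn_region(as.numeric(gr[[1]]), as.numeric(gr[[2]]))
    }
    interferent_spec(name, wn_region(as.numeric(cr[[1]]), as.numeric(cr[[2]])), gspec)
  })
}

#' Write an interferent configuration file
#' @param interferents list of [interferent_spec].
#' @param path destination path.
#' @return invisibly `path`.
#' @export
write_interferent_config <- function(interferents, path) {
  out <- lapply(interferents, function(sp) list(
    name = sp$name,
    correct_region = c(sp$correct_region$lo, sp$correct_region$hi),
    gamma_region = if (is.null(sp$gamma_region)) NULL
                   else c(sp$gamma_region$lo, sp$gamma_region$hi)
  ))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
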