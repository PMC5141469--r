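#' Reduced 1D scattering curve
#'
#' One radially averaged, buffer-subtracted SANS measurement on absolute
#' scale.
#'
#' @param q momentum transfer, 1/Angstrom, strictly increasing.
#' @param I intensity, 1/cm.
#' @param sigma_I intensity uncertainty, 1/cm.
#' @param dq optional q resolution column, carried through but not used.
#' @param metadata free-form list of labels (e.g. `d2o_pct`, `concentration`).
#' @return An object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, I, sigma_I, dq = NULL, metadata = list()) {
  n <- length(q)
  if (length(I) != n || length(sigma_I) != n || (!is.null(dq) && length(dq) != n))
    stop("q, I, sigma_I (and dq) must have equal length")
  if (n >= 2 && any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(q)) || any(!is.finite(I)) || any(!is.finite(sigma_I)))
    stop("non-finite values in curve")
  structure(list(q = as.numeric(q), I = as.numeric(I),
                 sigma_I = as.numeric(sigma_I),
                 dq = if (is.null(dq)) NULL else as.numeric(dq),
                 metadata = metadata),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve: %d points, q = %.4g..%.4g 1/A>\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  df <- data.frame(q = x$q, I = x$I, sigma_I = x$sigma_I)
  if (!is.null(x$dq)) df$dq <- x$dq
  df
}

#' Read a reduced SANS curve from an ASCII file
#'
#' Accepts 3 or 4 whitespace- or comma-separated numeric columns
#' (q, I, sigma\[, dq\]); lines starting with `#` and non-numeric header
#' lines are skipped. Malformed rows inside the data block are reported with
#' their line number.
#'
#' @param path file path.
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  in_data <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      if (in_data)
        stop(sprintf("malformed row at line %d of %s: '%s'", i, path, ln))
      next  # pre-data text header
    }
    if (length(vals) < 3 || length(vals) > 4) {
      if (in_data)
        stop(sprintf("row at line %d of %s has %d columns (need 3 or 4)",
                     i, path, length(vals)))
      next
    }
    in_data <- TRUE
    rows[[length(rows) + 1]] <- vals
  }
  if (length(rows) < 5)
    stop(sprintf("too few data rows in %s (%d < 5)", path, length(rows)))
  ncol <- max(lengths(rows))
  m <- t(vapply(rows, function(v) c(v, rep(NA_real_, ncol - length(v))),
                numeric(ncol)))
  if (any(diff(m[, 1]) <= 0)) stop("q column not strictly increasing in ", path)
  scattering_curve(m[, 1], m[, 2], m[, 3],
                   dq = if (ncol == 4 && !anyNA(m[, 4])) m[, 4] else NULL,
                   metadata = list(source = path))
}

#' Write a reduced SANS curve to an ASCII file
#'
#' @param curve a [scattering_curve()].
#' @param path output path.
#' @param digits significant digits (full double precision by default).
#' @export
write_curve <- function(curve, path, digits = 15) {
  df <- as.data.frame(curve)
  hdr <- c("# reduced SANS curve",
           sprintf("# columns: q[1/A] I[1/cm] sigma_I[1/cm]%s",
                   if (!is.null(curve$dq)) " dq[1/A]" else ""))
  for (nm in names(curve$metadata)) {
    v <- curve$metadata[[nm]]
    if (is.atomic(v) && length(v) == 1)
      hdr <- c(hdr, sprintf("# %s: %s", nm, format(v, digits = 15)))
  }
  body <- apply(df, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
}
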