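## Reflection containers and reflection-file IO (FCF loops, SHELX HKLF4).

#' Construct a reflection set
#'
#' @param h,k,l Integer Miller indices.
#' @param fo2 Observed intensities (F squared scale; may be negative).
#' @param sig Standard uncertainties of `fo2` (must be > 0).
#' @param fc2 Calculated intensities (optional).
#' @param phase Calculated phases in degrees (optional, for map synthesis).
#' @param merged Logical: symmetry-equivalent measurements already merged?
#' @param wavelength Radiation wavelength in Angstrom (optional).
#' @param cell Optional `ciflint_cell`, enabling resolution-dependent
#'   statistics.
#' @return data.frame-based object of class `ciflint_reflections`.
#' @export
reflection_set <- function(h, k, l, fo2, sig, fc2 = NULL, phase = NULL,
                           merged = TRUE, wavelength = NA_real_, cell = NULL) {
  n <- length(h)
  stopifnot(length(k) == n, length(l) == n, length(fo2) == n, length(sig) == n)
  if (n == 0L) stop_ciflint("zero reflections", "ciflint_refl_error")
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop_ciflint("all sigma values must be finite and > 0", "ciflint_refl_error")
  df <- data.frame(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                   fo2 = as.numeric(fo2), sig = as.numeric(sig))
  if (!is.null(fc2)) df$fc2 <- as.numeric(fc2)
  if (!is.null(phase)) df$phase <- as.numeric(phase)
  structure(df, class = c("ciflint_reflections", "data.frame"),
            merged = merged, wavelength = wavelength, cell = cell)
}

#' @export
print.ciflint_reflections <- function(x, ...) {
  cat(sprintf("Reflection set: %d reflections (%s)%s%s\n", nrow(x),
              if (isTRUE(attr(x, "merged"))) "merged" else "unmerged",
              if (!is.null(x$fc2)) ", Fc2 present" else "",
              if (is.finite(attr(x, "wavelength")))
                sprintf(", lambda = %.5f A", attr(x, "wavelength")) else ""))
  invisible(x)
}

refl_s <- function(refl, cell = NULL) {
  cell <- cell %||% attr(refl, "cell")
  if (is.null(cell)) stop_ciflint("reflection set has no cell", "ciflint_refl_error")
  s_of_hkl(cell, as.matrix(as.data.frame(refl)[, c("h", "k", "l")]))
}

#' Resolution conversions
#'
#' Converts the resolution coordinate `s = sin(theta)/lambda` (1/Angstrom)
#' to the Bragg angle theta (degrees, requires the wavelength) and the
#' real-space resolution `d = 1/(2s)` (Angstrom).  For Mo K-alpha,
#' `s = 0.65` (the copper-sphere limit `1/1.5418`) corresponds to
#' 27.5 degrees in theta and d = 0.77 Angstrom.
#'
#' @param s sin(theta)/lambda in 1/Angstrom.
#' @param lambda Wavelength in Angstrom (`NA` allowed; theta then `NA`).
#' @return List with `theta` (degrees) and `d` (Angstrom; `Inf` at s = 0).
#' @export
#' @examples
#' resolution_measures(0.65, 0.71073)
resolution_measures <- function(s, lambda = NA) {
  stopifnot(all(s >= 0))
  theta <- if (all(is.na(lambda))) rep(NA_real_, length(s)) else {
    x <- s * lambda
    if (any(x > 1 + 1e-12, na.rm = TRUE))
      stop_ciflint("s * lambda > 1: resolution not reachable at this wavelength",
                   "ciflint_refl_error")
    asin(pmin(x, 1)) * 180 / pi
  }
  d <- ifelse(s > 0, 1 / (2 * s), Inf)
  list(theta = theta, d = d)
}

## --- FCF (CIF-style _refln_ loop) ------------------------------------------

.loop_col <- function(lp, candidates) {
  for (cand in candidates) if (cand %in% lp$tags) return(lp$rows[, cand])
  NULL
}

.num_col <- function(x, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    stop_ciflint(sprintf("non-numeric value in %s column", what), "ciflint_refl_error")
  v
}

#' Read reflection data
#'
#' Two dialects: `"fcf"` (a CIF document with a `_refln_` loop; `F` or
#' `F^2` conventions auto-detected from the tags, squared values are
#' canonical internally) and `"hklf4"` (SHELX fixed-width `(3I4,2F8.2)`
#' records on the intensity scale, terminated by the all-zero record).
#'
#' @param text File content (string or lines).
#' @param dialect `"fcf"` or `"hklf4"`.
#' @param merged Merged state to record; defaults: fcf TRUE, hklf4 FALSE.
#' @return [reflection_set()] object.
#' @export
read_reflections <- function(text, dialect = c("fcf", "hklf4"), merged = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "fcf") {
    doc <- parse_cif(text)
    for (b in doc$blocks) {
      lp <- NULL
      for (l in b$loops) if (any(startsWith(l$tags, "_refln"))) { lp <- l; break }
      if (is.null(lp)) next
      h <- .loop_col(lp, c("_refln_index_h", "_refln.index_h"))
      k <- .loop_col(lp, c("_refln_index_k", "_refln.index_k"))
      l3 <- .loop_col(lp, c("_refln_index_l", "_refln.index_l"))
      if (is.null(h) || is.null(k) || is.null(l3))
        stop_ciflint("FCF _refln_ loop lacks index columns", "ciflint_refl_error")
      f2m <- .loop_col(lp, "_refln_f_squared_meas")
      f2s <- .loop_col(lp, "_refln_f_squared_sigma")
      f2c <- .loop_col(lp, "_refln_f_squared_calc")
      phase <- .loop_col(lp, "_refln_phase_calc")
      if (is.null(f2m)) {
        fm <- .loop_col(lp, "_refln_f_meas"); fs <- .loop_col(lp, "_refln_f_sigma")
        fc <- .loop_col(lp, "_refln_f_calc")
        if (is.null(fm) || is.null(fs))
          stop_ciflint("FCF loop lacks observed F or F^2 columns", "ciflint_refl_error")
        fmv <- .num_col(fm, "F_meas"); fsv <- .num_col(fs, "F_sigma")
        f2m_v <- fmv^2; f2s_v <- pmax(2 * abs(fmv) * fsv, 1e-12)
        f2c_v <- if (!is.null(fc)) .num_col(fc, "F_calc")^2 else NULL
      } else {
        if (is.null(f2s))
          stop_ciflint("FCF loop lacks F_squared_sigma column", "ciflint_refl_error")
        f2m_v <- .num_col(f2m, "F_squared_meas")
        f2s_v <- .num_col(f2s, "F_squared_sigma")
        f2c_v <- if (!is.null(f2c)) .num_col(f2c, "F_squared_calc") else NULL
      }
      cl <- NULL
      av <- block_num(b, "_cell_length_a")$value
      if (is.finite(av)) {
        cl <- cell(av, block_num(b, "_cell_length_b")$value,
                   block_num(b, "_cell_length_c")$value,
                   block_num(b, "_cell_angle_alpha")$value,
                   block_num(b, "_cell_angle_beta")$value,
                   block_num(b, "_cell_angle_gamma")$value)
      }
      wl <- block_num(b, "_diffrn_radiation_wavelength")$value
      return(reflection_set(.num_col(h, "h"), .num_col(k, "k"), .num_col(l3, "l"),
                            f2m_v, f2s_v, fc2 = f2c_v,
                            phase = if (!is.null(phase)) .num_col(phase, "phase") else NULL,
                            merged = merged %||% TRUE, wavelength = wl, cell = cl))
    }
    stop_ciflint("no _refln_ loop found in FCF", "ciflint_refl_error")
  }
  ## HKLF4 fixed width (3I4,2F8.2)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  h <- k <- l3 <- integer(0); fo2 <- sig <- numeric(0)
  parse_fw <- function(ln, from, to, what) {
    v <- suppressWarnings(as.numeric(trimws(substr(ln, from, to))))
    if (is.na(v)) stop_ciflint(sprintf("non-numeric %s field in HKLF4 record '%s'", what, ln),
                               "ciflint_refl_error")
    v
  }
  for (ln in lines) {
    hh <- parse_fw(ln, 1, 4, "h"); kk <- parse_fw(ln, 5, 8, "k"); ll <- parse_fw(ln, 9, 12, "l")
    if (hh == 0 && kk == 0 && ll == 0) break  # terminator
    h <- c(h, hh); k <- c(k, kk); l3 <- c(l3, ll)
    fo2 <- c(fo2, parse_fw(ln, 13, 20, "Fo2"))
    sig <- c(sig, parse_fw(ln, 21, 28, "sigma"))
  }
  if (!length(h)) stop_ciflint("zero reflections in HKLF4 text", "ciflint_refl_error")
  reflection_set(h, k, l3, fo2, sig, merged = merged %||% FALSE)
}

#' Write reflection data
#'
#' Bit-stable writers for both dialects.  HKLF4 uses `(3I4,2F8.2)` with
#' the all-zero terminator record; the FCF writer emits a `_refln_` loop
#' on the F-squared convention (plus calculated phases when present).
#'
#' @param refl [reflection_set()] object.
#' @param dialect `"fcf"` or `"hklf4"`.
#' @param block_name Data-block name for the FCF dialect.
#' @return Single text string.
#' @export
write_reflections <- function(refl, dialect = c("fcf", "hklf4"), block_name = "I") {
  dialect <- match.arg(dialect)
  df <- as.data.frame(refl)
  if (dialect == "hklf4") {
    recs <- sprintf("%4d%4d%4d%8.2f%8.2f", df$h, df$k, df$l, df$fo2, df$sig)
    return(paste0(paste(recs, collapse = "\n"),
                  sprintf("\n%4d%4d%4d%8.2f%8.2f\n", 0L, 0L, 0L, 0, 0)))
  }
  tags <- c("_refln_index_h", "_refln_index_k", "_refln_index_l",
            "_refln_f_squared_calc", "_refln_f_squared_meas", "_refln_f_squared_sigma")
  has_fc <- !is.null(df$fc2); has_ph <- !is.null(df$phase)
  if (!has_fc) tags <- setdiff(tags, "_refln_f_squared_calc")
  if (has_ph) tags <- c(tags, "_refln_phase_calc")
  rows <- cbind(sprintf("%d", df$h), sprintf("%d", df$k), sprintf("%d", df$l))
  if (has_fc) rows <- cbind(rows, sprintf("%.4f", df$fc2))
  rows <- cbind(rows, sprintf("%.4f", df$fo2), sprintf("%.4f", df$sig))
  if (has_ph) rows <- cbind(rows, sprintf("%.3f", df$phase))
  colnames(rows) <- tags
  items <- list()
  cl <- attr(refl, "cell")
  if (!is.null(cl)) {
    items[["_cell_length_a"]] <- format(cl$a); items[["_cell_length_b"]] <- format(cl$b)
    items[["_cell_length_c"]] <- format(cl$c); items[["_cell_angle_alpha"]] <- format(cl$alpha)
    items[["_cell_angle_beta"]] <- format(cl$beta); items[["_cell_angle_gamma"]] <- format(cl$gamma)
  }
  if (is.finite(attr(refl, "wavelength")))
    items[["_diffrn_radiation_wavelength"]] <- format(attr(refl, "wavelength"))
  doc <- structure(list(blocks = list(list(
    name = block_name, items = items,
    loops = list(list(tags = tags, rows = rows))))), class = "ciflint_cif")
  write_cif(doc)
}
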