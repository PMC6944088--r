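## Structure models and spherical-atom structure factors.

#' Bundled element tables
#'
#' Atomic weights, Bondi-style van der Waals radii, covalent radii,
#' four-Gaussian (Cromer-Mann type) scattering-factor coefficients and
#' resonant corrections f', f'' at Cu and Mo K-alpha, plus mass
#' attenuation coefficients derived from f''.
#' @return data.frame keyed by element symbol.
#' @export
element_table <- function() {
  if (is.null(.ciflint_env$elements)) {
    tab <- utils::read.delim(extdata_path("elements.tsv"), stringsAsFactors = FALSE)
    rownames(tab) <- tab$symbol
    .ciflint_env$elements <- tab
  }
  .ciflint_env$elements
}

element_row <- function(symbol) {
  tab <- element_table()
  sym <- paste0(toupper(substr(symbol, 1, 1)), tolower(substring(symbol, 2)))
  if (!sym %in% rownames(tab))
    stop_ciflint(sprintf("unknown element '%s'", symbol), "ciflint_element_error")
  tab[sym, ]
}

## spherical scattering factor f0(s) for one element, s = sin(theta)/lambda
f0_element <- function(symbol, s) {
  e <- element_row(symbol)
  a <- as.numeric(e[paste0("cm_a", 1:4)]); b <- as.numeric(e[paste0("cm_b", 1:4)])
  f <- rep(as.numeric(e$cm_c), length(s))
  for (m in 1:4) f <- f + a[m] * exp(-b[m] * s^2)
  f
}

## resonant corrections at a wavelength; zero (with attribute) off-table
fprime_element <- function(symbol, lambda) {
  e <- element_row(symbol)
  if (is.finite(lambda) && abs(lambda - 0.71073) < 0.001)
    c(fp = e$fp_mo, fpp = e$fpp_mo)
  else if (is.finite(lambda) && abs(lambda - 1.54184) < 0.001)
    c(fp = e$fp_cu, fpp = e$fpp_cu)
  else c(fp = 0, fpp = 0)
}

#' Construct a structure model
#'
#' @param cell `ciflint_cell`.
#' @param setting `ciflint_spacegroup`.
#' @param sites data.frame with columns label, element, x, y, z, occ,
#'   uiso; optional logical columns is_h, disordered, calculated and
#'   anisotropic columns u11, u22, u33, u23, u13, u12.
#' @param wavelength Radiation wavelength (Angstrom, default Mo K-alpha).
#' @return Object of class `ciflint_model`.
#' @export
structure_model <- function(cell, setting, sites, wavelength = 0.71073) {
  need <- c("label", "element", "x", "y", "z", "occ", "uiso")
  if (!all(need %in% names(sites)))
    stop_ciflint(paste("sites needs columns", paste(need, collapse = ", ")),
                 "ciflint_model_error")
  for (fl in c("is_h", "disordered", "calculated"))
    if (is.null(sites[[fl]])) sites[[fl]] <- rep(FALSE, nrow(sites))
  sites$is_h <- sites$is_h | sites$element == "H"
  structure(list(cell = cell, setting = setting, sites = sites,
                 wavelength = wavelength), class = "ciflint_model")
}

#' @export
print.ciflint_model <- function(x, ...) {
  cat(sprintf("Structure model: %d sites in %s, cell V = %.1f A^3\n",
              nrow(x$sites), x$setting$hall %||% "(ops)", x$cell$volume))
  invisible(x)
}

## all index triples (excluding 000) with s <= smax; full sphere
hkl_sphere <- function(cell, smax) {
  hmax <- ceiling(2 * smax * c(cell$a, cell$b, cell$c)) + 1L
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0L, , drop = FALSE]
  s <- s_of_hkl(cell, grid)
  grid[s <= smax, , drop = FALSE]
}

#' Spherical-atom structure factors
#'
#' `F(h) = sum_sites sof * (f0(s) + f' + i f'') * T(h) *
#' sum_ops exp(2 pi i h.(R x + t))` with the isotropic (or anisotropic)
#' Debye-Waller factor `T`.  Occupancies are interpreted as chemical
#' occupancies; the refinement-style factor `occ/sso` is applied
#' internally so special positions are not double counted.
#'
#' @param model `ciflint_model`.
#' @param hkl Integer matrix (n x 3).
#' @param anomalous Include f'/f'' (default TRUE).
#' @return Complex vector of structure factors.
#' @export
structure_factors <- function(model, hkl, anomalous = TRUE) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  cellv <- model$cell
  s <- s_of_hkl(cellv, hkl)
  astar <- sqrt(diag(cellv$Gstar))
  Fh <- complex(real = rep(0, nrow(hkl)))
  aniso_cols <- c("u11", "u22", "u33", "u23", "u13", "u12")
  has_aniso <- all(aniso_cols %in% names(model$sites))
  for (j in seq_len(nrow(model$sites))) {
    at <- model$sites[j, ]
    fj <- f0_element(at$element, s)
    if (anomalous) {
      fp <- fprime_element(at$element, model$wavelength)
      fj <- complex(real = fj + fp["fp"], imaginary = rep(fp["fpp"], length(s)))
    }
    if (has_aniso && is.finite(at$u11)) {
      U <- matrix(c(at$u11, at$u12, at$u13,
                    at$u12, at$u22, at$u23,
                    at$u13, at$u23, at$u33), 3, 3)
      Ustar <- U * outer(astar, astar)
      Tj <- exp(-2 * pi^2 * rowSums((hkl %*% Ustar) * hkl))
    } else {
      Tj <- exp(-8 * pi^2 * at$uiso * s^2)
    }
    sso <- site_symmetry(c(at$x, at$y, at$z), model$setting, cellv,
                         occupancy = at$occ)$sso
    geom <- complex(real = rep(0, nrow(hkl)))
    for (op in model$setting$ops) {
      xi <- op_apply(op, c(at$x, at$y, at$z))
      ph <- 2 * pi * as.numeric(hkl %*% xi)
      geom <- geom + complex(real = cos(ph), imaginary = sin(ph))
    }
    Fh <- Fh + (at$occ / sso) * fj * Tj * geom
  }
  Fh
}
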