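## Structural-model checks: formula and density arithmetic, occupancy
## bookkeeping, rigid-bond displacement behaviour, connectivity and
## intermolecular contacts, absorption plausibility, data-to-parameter
## ratio and resonant-scattering values.

#' Parse a chemical sum formula
#'
#' Accepts `"C10 H14 N2"` style formulas (counts may be fractional) with
#' an optional bracketed solvent annotation such as `"[+solvent]"`; the
#' bracketed part is recorded but contributes nothing to the molecular
#' weight or density.
#'
#' @param text Formula text.
#' @return List with `counts` (named numeric) and `solvent_note`
#'   (`NA` when absent).
#' @export
#' @examples
#' parse_formula("C10 H14 N2 [+solvent]")
parse_formula <- function(text) {
  s <- trimws(text)
  if (!nzchar(s)) stop_ciflint("empty formula", "ciflint_formula_error")
  note <- NA_character_
  br <- regmatches(s, regexec("\\[([^]]*)\\]", s))[[1]]
  if (length(br)) {
    note <- br[2]
    s <- trimws(gsub("\\[[^]]*\\]", "", s))
  }
  toks <- regmatches(s, gregexpr("[A-Za-z]+[0-9.]*", s))[[1]]
  if (!length(toks)) stop_ciflint("no element tokens in formula", "ciflint_formula_error")
  counts <- numeric(0)
  for (tok in toks) {
    m <- regmatches(tok, regexec("^([A-Za-z]+)([0-9.]*)$", tok))[[1]]
    el <- m[2]
    element_row(el)  # errors for unknown elements
    n <- if (nzchar(m[3])) as.numeric(m[3]) else 1
    if (!is.finite(n) || n <= 0)
      stop_ciflint(sprintf("bad count in formula token '%s'", tok), "ciflint_formula_error")
    counts[el] <- (counts[el] %||% 0) + n
    counts[is.na(counts)] <- n
  }
  counts <- tapply(counts, names(counts), sum)
  list(counts = counts[!is.na(counts)], solvent_note = note)
}

#' Molecular weight of a formula unit
#'
#' Sums bundled standard atomic weights over the non-bracketed content.
#' @param f Result of [parse_formula()].
#' @return Weight in g/mol.
#' @export
molecular_weight <- function(f) {
  sum(vapply(names(f$counts), function(e) element_row(e)$weight, numeric(1)) *
        as.numeric(f$counts))
}

#' Check reported against calculated density
#'
#' `rho_calc = Z * Mr * 1.66054 / V` in g/cm^3.
#' @param volume Cell volume in cubic Angstrom.
#' @param z Formula units per cell (`NA` yields a missing-datum finding).
#' @param mr Molecular weight (g/mol).
#' @param reported Reported density (optional).
#' @param tol Agreement tolerance (default 0.01 g/cm^3).
#' @return List with `rho_calc` and `findings`.
#' @export
density_check <- function(volume, z, mr, reported = NA, tol = 0.01) {
  stopifnot(volume > 0, mr > 0)
  if (is.na(z) || is.null(z))
    return(list(rho_calc = NA_real_,
                findings = finding("MODEL_Z_MISSING", "formula units Z not reported")))
  rho <- z * mr * 1.66054 / volume
  fx <- if (!is.na(reported) && abs(rho - reported) > tol)
    finding("MODEL_DENSITY_MISMATCH",
            sprintf("reported density %.3f vs calculated %.3f g/cm^3", reported, rho),
            abs(rho - reported))
  else finding("", "")[0, ]
  list(rho_calc = rho, findings = fx)
}

## Cartesian displacement tensor from CIF U_ij (a*-basis convention)
u_cart_from_cif <- function(ucif, cellv) {
  astar <- sqrt(diag(cellv$Gstar))
  D <- cellv$M %*% diag(astar)
  D %*% ucif %*% t(D)
}

#' Rigid-bond (Hirshfeld) displacement test
#'
#' The mean-square displacement amplitudes of two covalently bonded atoms
#' projected on the bond direction should nearly cancel.  Computes
#' `Delta = |u'Ua u - u'Ub u|` (Cartesian projection; an isotropic atom
#' contributes its Uiso directly), propagates the standard uncertainty
#' and flags the bond when `Delta/su` exceeds the threshold.
#'
#' @param ua,ub Either scalars (Uiso) or 3x3 Cartesian tensors (A^2).
#' @param unit_vec Cartesian unit vector along the bond.
#' @param su_ua,su_ub Uncertainties: scalar or symmetric 3x3 of su's.
#' @param threshold_z Flagging threshold in multiples of su (default 5;
#'   use a relaxed value, e.g. 12, for metal-ligand bonds).
#' @return List with `delta`, `su`, `z`, `flagged`.
#' @export
hirshfeld_test <- function(ua, ub, unit_vec, su_ua = 0.005, su_ub = 0.005,
                           threshold_z = 5) {
  n <- unit_vec / sqrt(sum(unit_vec^2))
  if (!all(is.finite(n))) stop_ciflint("zero-length bond", "ciflint_model_error")
  proj <- function(u) if (length(u) == 1L) as.numeric(u) else as.numeric(n %*% u %*% n)
  proj_su <- function(su) {
    if (length(su) == 1L) return(as.numeric(su))
    C <- outer(n, n); C <- C + t(C) - diag(diag(C))  # off-diagonals doubled
    sqrt(sum((C * su)^2))
  }
  delta <- abs(proj(ua) - proj(ub))
  su <- sqrt(proj_su(su_ua)^2 + proj_su(su_ub)^2)
  z <- if (su > 0) delta / su else Inf
  list(delta = delta, su = su, z = z, flagged = z > threshold_z)
}

## ---- connectivity and contacts --------------------------------------------

#' Covalent connectivity of the asymmetric unit
#'
#' Bonds where the interatomic distance is below the covalent-radius sum
#' plus `tol` (default 0.4 Angstrom).  Distances use the unwrapped
#' fractional coordinates, so molecules extending past cell bounds stay
#' connected.
#'
#' @param model `ciflint_model`.
#' @param tol Bond tolerance in Angstrom.
#' @return data.frame with columns i, j, d.
#' @export
build_connectivity <- function(model, tol = 0.4) {
  sdf <- model$sites
  n <- nrow(sdf)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), d = numeric()))
  xyz <- frac_to_cart(model$cell, t(as.matrix(sdf[, c("x", "y", "z")])))
  rcov <- vapply(sdf$element, function(e) element_row(e)$r_cov, numeric(1))
  out <- list()
  for (i in seq_len(n - 1L)) {
    d <- sqrt(colSums((xyz[, (i + 1L):n, drop = FALSE] - xyz[, i])^2))
    lim <- rcov[i] + rcov[(i + 1L):n] + tol
    hit <- which(d < lim & d > 0.4)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(i = i, j = i + hit, d = d[hit])
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(), d = numeric()))
  do.call(rbind, out)
}

## connected components from a bond list
.components <- function(n, bonds) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(bonds))) {
      a <- comp[bonds$i[r]]; b <- comp[bonds$j[r]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

.halogens <- c("F", "Cl", "Br", "I")

#' Short intermolecular contacts
#'
#' Lists pairs closer than the van der Waals sum minus `slack` between
#' different molecules (symmetry images included) and classifies each:
#' `H..H` (possibly misplaced hydrogens), `missing_H` (short O..O or
#' O..N, typically a missing hydrogen in a short hydrogen bond),
#' `halogen` (informational halogen..halogen interaction) or `other`;
#' contacts involving disordered sites are marked for inspection of the
#' disorder model.
#'
#' @param model `ciflint_model`.
#' @param slack Tolerance below the van der Waals sum (default 0.2).
#' @return data.frame of contacts.
#' @export
short_contacts <- function(model, slack = 0.2) {
  sdf <- model$sites
  n <- nrow(sdf)
  vdw <- vapply(sdf$element, function(e) element_row(e)$r_vdw, numeric(1))
  bonds <- build_connectivity(model)
  comp <- .components(n, bonds)
  frac <- t(as.matrix(sdf[, c("x", "y", "z")]))
  out <- list()
  for (oi in seq_along(model$setting$ops)) {
    op <- model$setting$ops[[oi]]
    img <- op_apply(op, frac)
    for (j in seq_len(n)) {
      dx0 <- img - frac[, j]
      for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
        ident <- oi == 1L && sx == 0L && sy == 0L && sz == 0L && all(op$t == 0L)
        d <- sqrt(colSums((model$cell$M %*% (dx0 + c(sx, sy, sz)))^2))
        lim <- vdw + vdw[j] - slack
        hit <- which(d <= lim + 1e-9)
        if (ident) hit <- hit[comp[hit] != comp[j] & hit > j]
        for (i in hit) {
          if (ident && comp[i] == comp[j]) next
          e1 <- sdf$element[i]; e2 <- sdf$element[j]
          cls <- if (e1 == "H" && e2 == "H") "H..H"
          else if (all(sort(c(e1, e2)) %in% c("N", "O")) && any(c(e1, e2) == "O")) "missing_H"
          else if (e1 %in% .halogens && e2 %in% .halogens) "halogen"
          else "other"
          key <- paste(sort(c(sdf$label[i], sdf$label[j])), collapse = "-")
          out[[length(out) + 1L]] <- data.frame(
            atom1 = sdf$label[j], atom2 = sdf$label[i], d = d[i],
            vdw_sum = vdw[i] + vdw[j], class = cls,
            symcode = encode_symmcode(oi, c(sx, sy, sz)),
            disorder = sdf$disordered[i] || sdf$disordered[j],
            key = paste(key, round(d[i], 3)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(atom1 = character(), atom2 = character(), d = numeric(),
                      vdw_sum = numeric(), class = character(), symcode = character(),
                      disorder = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res$key), setdiff(names(res), "key"), drop = FALSE]
  res[order(res$d), , drop = FALSE]
}

#' Centre-of-gravity check for connected species
#'
#' Each connected species in the asymmetric unit should have its
#' unweighted centroid within the unit-cell bounds; small species (three
#' or fewer non-H atoms, e.g. water or counter-ions best placed near
#' their interaction partners) are exempt and reported as notes only.
#'
#' @param model `ciflint_model`.
#' @return data.frame of findings with the suggested corrective
#'   translation.
#' @export
centre_of_gravity_check <- function(model) {
  sdf <- model$sites
  bonds <- build_connectivity(model)
  comp <- .components(nrow(sdf), bonds)
  out <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    cen <- colMeans(sdf[idx, c("x", "y", "z")])
    if (all(cen >= 0 & cen < 1)) next
    shift <- -floor(cen)
    small <- sum(!sdf$is_h[idx]) <= 3L
    out[[length(out) + 1L]] <- data.frame(
      component = cid, n_atoms = length(idx),
      cx = cen[1], cy = cen[2], cz = cen[3],
      shift_a = shift[1], shift_b = shift[2], shift_c = shift[3],
      exempt_small = small, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(component = integer(), n_atoms = integer(), cx = numeric(),
                      cy = numeric(), cz = numeric(), shift_a = numeric(),
                      shift_b = numeric(), shift_c = numeric(),
                      exempt_small = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## ---- absorption ------------------------------------------------------------

#' Linear absorption coefficient from cell contents
#'
#' `mu = rho * sum(mass fractions * mu/rho)` with the bundled mass
#' attenuation coefficients, returned in 1/mm.
#'
#' @param f Parsed formula (per formula unit).
#' @param z Formula units per cell.
#' @param volume Cell volume (A^3).
#' @param lambda Wavelength; only Cu and Mo K-alpha are tabulated, other
#'   wavelengths return `NA`.
#' @export
absorption_mu <- function(f, z, volume, lambda) {
  col <- if (is.finite(lambda) && abs(lambda - 1.54184) < 0.001) "mu_rho_cu"
         else if (is.finite(lambda) && abs(lambda - 0.71073) < 0.001) "mu_rho_mo"
         else return(NA_real_)
  tot <- sum(vapply(names(f$counts), function(e) {
    r <- element_row(e); r$weight * r[[col]]
  }, numeric(1)) * as.numeric(f$counts))
  ## rho * (mu/rho): 1.66054 converts amu/A^3 to g/cm^3; /10 to 1/mm
  z * tot * 1.66054 / volume / 10
}

#' Plausibility of the reported transmission range
#'
#' Compares the reported `Tmin/Tmax` with the range expected from the
#' crystal dimensions, `T = exp(-mu * t)`; the reported and expected
#' absorption effects `(1 - T)` should agree within a factor
#' `ratio_factor` (default 2).
#'
#' @param f,z,volume,lambda As in [absorption_mu()].
#' @param dim_min,dim_max Crystal dimensions in mm.
#' @param t_min,t_max Reported transmission range.
#' @param ratio_factor Allowed factor on `(1 - T)`.
#' @return List with `mu`, `t_min_exp`, `t_max_exp`, `findings`.
#' @export
absorption_range_check <- function(f, z, volume, lambda, dim_min, dim_max,
                                   t_min, t_max, ratio_factor = 2) {
  if (is.na(dim_min) || is.na(dim_max))
    return(list(mu = NA_real_, t_min_exp = NA_real_, t_max_exp = NA_real_,
                findings = finding("ABS_NO_DIMS",
                                   "crystal dimensions missing; transmission range not assessed")))
  stopifnot(dim_min > 0, dim_max >= dim_min)
  mu <- absorption_mu(f, z, volume, lambda)
  if (is.na(mu))
    return(list(mu = NA_real_, t_min_exp = NA_real_, t_max_exp = NA_real_,
                findings = finding("ABS_NO_TABLE",
                                   "wavelength outside bundled attenuation tables; not assessed")))
  te_max <- exp(-mu * dim_min)
  te_min <- exp(-mu * dim_max)
  fx <- list()
  if (!is.na(t_min) && !is.na(t_max)) {
    rep_eff <- 1 - t_min
    exp_eff <- 1 - te_min
    if (exp_eff > 1e-4 && (rep_eff < exp_eff / ratio_factor))
      fx[[1]] <- finding("ABS_RANGE_NARROW",
                         sprintf("reported transmission range %.3f-%.3f implausibly narrow for mu=%.3f /mm and %.2f-%.2f mm crystal (expected %.3f-%.3f)",
                                 t_min, t_max, mu, dim_min, dim_max, te_min, te_max),
                         rep_eff / max(exp_eff, 1e-12))
    else if (exp_eff > 1e-4 && rep_eff > exp_eff * ratio_factor)
      fx[[1]] <- finding("ABS_RANGE_WIDE",
                         sprintf("reported transmission range %.3f-%.3f implausibly wide (expected %.3f-%.3f)",
                                 t_min, t_max, te_min, te_max),
                         rep_eff / max(exp_eff, 1e-12))
  }
  list(mu = mu, t_min_exp = te_min, t_max_exp = te_max,
       findings = if (length(fx)) fx[[1]] else finding("", "")[0, ])
}

#' Data-to-parameter ratio
#'
#' Ratio of Laue-unique observed reflections to refined parameters, with
#' levelled thresholds (defaults: below 6/8/10 is A/B/C for
#' non-centrosymmetric structures, below 8/10/12 for centrosymmetric).
#'
#' @param n_reflections Laue-group-averaged observed reflection count.
#' @param n_params Refined parameter count.
#' @param centrosymmetric Logical.
#' @param thresholds Named list with `noncentro` and `centro` numeric
#'   triples (A, B, C bounds).
#' @return List with `ratio` and `level` (`"A"`, `"B"`, `"C"` or
#'   `"pass"`).
#' @export
data_parameter_ratio <- function(n_reflections, n_params, centrosymmetric = FALSE,
                                 thresholds = list(noncentro = c(6, 8, 10),
                                                   centro = c(8, 10, 12))) {
  stopifnot(n_reflections > 0, n_params > 0)
  th <- if (centrosymmetric) thresholds$centro else thresholds$noncentro
  ratio <- n_reflections / n_params
  level <- if (ratio < th[1]) "A" else if (ratio < th[2]) "B"
           else if (ratio < th[3]) "C" else "pass"
  list(ratio = ratio, level = level)
}

#' Check reported resonant scattering factors
#'
#' Reported f'/f'' values are compared with the bundled tables at Cu and
#' Mo K-alpha; other wavelengths are reported as unverified.  A value is
#' flagged when it deviates by more than `max(0.1, 10%)` from the table.
#'
#' @param reported data.frame with columns `element`, `fp`, `fpp`.
#' @param lambda Wavelength in Angstrom.
#' @return data.frame of findings.
#' @export
resonant_check <- function(reported, lambda) {
  known <- is.finite(lambda) &&
    (abs(lambda - 0.71073) < 0.001 || abs(lambda - 1.54184) < 0.001)
  if (!known)
    return(finding("RES_UNVERIFIED",
                   sprintf("no bundled resonant-scattering table at lambda = %.5f A; values unverified",
                           lambda)))
  fx <- list()
  for (r in seq_len(nrow(reported))) {
    tabv <- fprime_element(reported$element[r], lambda)
    for (comp in c("fp", "fpp")) {
      ref <- tabv[[comp]]
      val <- reported[[comp]][r]
      if (is.na(val)) next
      if (abs(val - ref) > max(0.1, 0.1 * abs(ref)))
        fx[[length(fx) + 1L]] <- finding("RES_MISMATCH",
          sprintf("%s %s = %.4f deviates from tabulated %.4f",
                  reported$element[r], if (comp == "fp") "f'" else "f''", val, ref),
          abs(val - ref))
    }
  }
  if (!length(fx)) return(finding("", "")[0, ])
  do.call(rbind, fx)
}
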