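## Space-group settings: operator lists with provenance, crystal system,
## Laue group, bundled Hall/Hermann-Mauguin table, site symmetry,
## symmetry codes and systematic absences.

.ciflint_env <- new.env(parent = emptyenv())

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "ciflint")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install use
  p
}

#' Bundled space-group table
#'
#' Standard settings of the 230 space-group types plus common alternate
#' settings (cell choices, origin choices, rhombohedral/hexagonal axes),
#' each with Hermann-Mauguin and Hall symbols.
#' @return data.frame with columns number, hm_full, hm_short, hall, ext,
#'   qualifier, crystal_system, centro, nops.
#' @export
sg_table <- function() {
  if (is.null(.ciflint_env$sg)) {
    .ciflint_env$sg <- utils::read.delim(extdata_path("spacegroups.tsv"),
                                         stringsAsFactors = FALSE, quote = "")
  }
  .ciflint_env$sg
}

## one standard setting per space-group number (origin on inversion centre
## where there is a choice; hexagonal axes for rhombohedral groups)
sg_standard_settings <- function() {
  tab <- sg_table()
  pick <- function(d) {
    if (any(d$ext == "2")) d[d$ext == "2", ][1, ]
    else if (any(d$ext == "H")) d[d$ext == "H", ][1, ]
    else d[1, ]
  }
  do.call(rbind, lapply(split(tab, tab$number), pick))
}

norm_hm <- function(hm) {
  s <- tolower(gsub("[[:space:]_]", "", hm))
  sub(":.*$", "", s)
}

norm_hall <- function(h) tolower(gsub("[[:space:]]+", " ", trimws(h)))

## --- crystal system and Laue group ----------------------------------------

rot_order <- function(R) {
  d <- round(det(R)); tr <- sum(diag(R)) * d  # proper image
  c(`3` = 1L, `-1` = 2L, `0` = 3L, `1` = 4L, `2` = 6L)[[as.character(tr)]]
}

crystal_system_of <- function(ops) {
  Rs <- unique(lapply(ops, function(o) {
    R <- o$R; if (round(det(R)) < 0) R <- -R; R
  }))
  orders <- vapply(Rs, rot_order, integer(1))
  n3 <- sum(orders == 3L)
  if (n3 >= 8L) "cubic"
  else if (any(orders == 6L)) "hexagonal"
  else if (n3 > 0L) "trigonal"
  else if (any(orders == 4L)) "tetragonal"
  else if (sum(orders == 2L) >= 3L) "orthorhombic"
  else if (sum(orders == 2L) == 1L) "monoclinic"
  else "triclinic"
}

## axis (integer vector) of the highest-order proper rotation; NULL for
## triclinic
principal_axis_of <- function(ops) {
  best <- NULL; best_ord <- 1L
  for (o in ops) {
    R <- o$R; if (round(det(R)) < 0) R <- -R
    ord <- rot_order(R)
    if (ord > best_ord) { best_ord <- ord; best <- R }
  }
  if (is.null(best)) return(NULL)
  ## integer fixed vector of R: brute force over small indices
  for (u in -2:2) for (v in -2:2) for (w in -2:2) {
    if (u == 0 && v == 0 && w == 0) next
    x <- c(u, v, w)
    if (all(best %*% x == x)) return(x)
  }
  NULL
}

laue_rotations <- function(ops) {
  Rs <- lapply(ops, `[[`, "R")
  all <- c(Rs, lapply(Rs, function(R) -R))
  keys <- vapply(all, function(R) paste(R, collapse = ","), character(1))
  all[!duplicated(keys)]
}

#' Build a space-group setting
#'
#' A setting bundles the operator list with its provenance (Hall and/or
#' Hermann-Mauguin symbol or an explicit operator loop) and derived
#' properties: operator count, centrosymmetry, crystal system and the
#' Laue-group rotations used for merging.
#'
#' @param hall Hall symbol (preferred source of operators).
#' @param hm Hermann-Mauguin symbol (looked up in the bundled table when no
#'   Hall symbol is given).
#' @param ops Optional list of operators or xyz triplet strings.
#' @return Object of class `ciflint_spacegroup`.
#' @export
#' @examples
#' sg <- spacegroup_setting(hall = "-P 2ybc")
#' sg$nsym
#' sg$crystal_system
spacegroup_setting <- function(hall = NULL, hm = NULL, ops = NULL) {
  if (!is.null(ops) && length(ops) && is.character(ops[[1]]))
    ops <- lapply(ops, parse_triplet)
  if (is.null(ops)) {
    if (!is.null(hall)) ops <- expand_hall(hall)
    else if (!is.null(hm)) {
      tab <- sg_table()
      hit <- tab[norm_hm(tab$hm_full) == norm_hm(hm) |
                 norm_hm(tab$hm_short) == norm_hm(hm), ]
      if (!nrow(hit))
        stop_ciflint(sprintf("Hermann-Mauguin symbol '%s' not in bundled table", hm),
                     "ciflint_sg_error")
      ## prefer the origin-2 / hexagonal setting, as SHELX-style archives do
      hit <- hit[order(match(hit$ext, c("2", "H", "", "1", "R"))), ]
      hall <- hit$hall[1]
      ops <- expand_hall(hall)
    } else stop_ciflint("need hall, hm or ops", "ciflint_sg_error")
  } else {
    ## canonicalize and verify closure
    ops <- group_closure(ops)
  }
  keys <- vapply(ops, op_key, character(1))
  if (anyDuplicated(keys)) ops <- ops[!duplicated(keys)]
  centro <- any(vapply(ops, function(o)
    all(o$R == -diag(3L)) && all(o$t == 0L), logical(1)))
  structure(list(hall = hall, hm = hm, ops = ops, nsym = length(ops),
                 centrosymmetric = centro,
                 crystal_system = crystal_system_of(ops),
                 laue_ops = laue_rotations(ops)),
            class = "ciflint_spacegroup")
}

#' @export
print.ciflint_spacegroup <- function(x, ...) {
  cat(sprintf("Space group: %s%s  (%d operators, %s, %scentrosymmetric)\n",
              if (!is.null(x$hm)) paste0(x$hm, "  ") else "",
              if (!is.null(x$hall)) paste0("[", x$hall, "]") else "",
              x$nsym, x$crystal_system, if (x$centrosymmetric) "" else "non-"))
  invisible(x)
}

## --- site symmetry ---------------------------------------------------------

#' Site symmetry of an atomic position
#'
#' Counts the operators that map a site onto itself (Cartesian distance
#' below `tol` modulo lattice translations).  The count is the site
#' symmetry order `sso`; the multiplicity is `ssm = nsym/sso`, and the
#' refinement-style site occupancy factor is `occupancy/sso`, so a fully
#' occupied atom on an inversion centre of a four-operator group has
#' SOF = 0.5.
#'
#' @param xyz Fractional coordinates (length 3).
#' @param setting `ciflint_spacegroup`.
#' @param cell `ciflint_cell`.
#' @param occupancy Chemical occupancy in `[0, 1]`.
#' @param tol Coincidence tolerance in Angstrom (default 0.01).
#' @return List with `sso`, `ssm`, `sof`.
#' @export
#' @examples
#' sg <- spacegroup_setting(hall = "-P 2ybc")
#' site_symmetry(c(0, 0, 0), sg, cell(10, 10, 10))$sof  # 0.5
site_symmetry <- function(xyz, setting, cell, occupancy = 1.0, tol = 0.01) {
  if (!is_number(tol) || tol <= 0) stop_ciflint("tol must be > 0", "ciflint_sg_error")
  stopifnot(length(xyz) == 3L, all(is.finite(xyz)))
  d <- vapply(setting$ops, function(op)
    frac_dist_mi(cell, op_apply(op, xyz) - xyz), numeric(1))
  sso <- sum(d < tol)
  ssm <- setting$nsym / sso
  if (abs(ssm - round(ssm)) > 1e-9)
    stop_ciflint("site symmetry order does not divide the group order; increase tol resolution",
                 "ciflint_sg_error")
  list(sso = sso, ssm = as.integer(round(ssm)), sof = occupancy / sso)
}

## --- s_uvw symmetry codes ---------------------------------------------------

#' Encode / decode ORTEP-style s_uvw symmetry codes
#'
#' The code `s_uvw` names operator `s` of the CIF operator list followed by
#' unit-cell translations, one digit each with `digit = translation + 5`;
#' `1_555` is the identity with no translation and only translations in
#' `-5..4` are representable.
#'
#' @param op_index 1-based operator index.
#' @param uvw Integer translations along a, b, c.
#' @return `encode_symmcode`: the code text. `decode_symmcode`: a list with
#'   `op_index` and `uvw`.
#' @export
#' @examples
#' encode_symmcode(1, c(2, 0, -1))  # "1_754"
encode_symmcode <- function(op_index, uvw) {
  stopifnot(length(uvw) == 3L)
  op_index <- as.integer(op_index); uvw <- as.integer(uvw)
  if (op_index < 1L) stop_ciflint("operator index must be >= 1", "ciflint_symmcode_error")
  if (any(uvw < -5L | uvw > 4L))
    stop_ciflint("translation not representable: s_uvw digits cover -5..4 only",
                 "ciflint_symmcode_error")
  sprintf("%d_%d%d%d", op_index, uvw[1] + 5L, uvw[2] + 5L, uvw[3] + 5L)
}

#' @rdname encode_symmcode
#' @param code Code text such as `"1_754"`.
#' @param setting Optional `ciflint_spacegroup` to bound the operator index.
#' @export
decode_symmcode <- function(code, setting = NULL) {
  m <- regmatches(code, regexec("^([0-9]+)_([0-9])([0-9])([0-9])$", trimws(code)))[[1]]
  if (length(m) == 0)
    stop_ciflint(sprintf("malformed symmetry code '%s' (multi-digit translations are not representable)",
                         code), "ciflint_symmcode_error")
  op_index <- as.integer(m[2])
  uvw <- as.integer(m[3:5]) - 5L
  if (op_index < 1L) stop_ciflint("operator index must be >= 1", "ciflint_symmcode_error")
  if (!is.null(setting) && op_index > setting$nsym)
    stop_ciflint(sprintf("operator index %d exceeds the %d-operator list",
                         op_index, setting$nsym), "ciflint_symmcode_error")
  list(op_index = op_index, uvw = uvw)
}

## --- systematic absences ----------------------------------------------------

## TRUE for each row of hkl that is systematically extinct: some operator
## (R, t) has hR = h with h.t not integral.
is_extinct <- function(hkl, setting) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  out <- rep(FALSE, nrow(hkl))
  for (op in setting$ops) {
    if (all(op$t == 0L)) next
    hR <- hkl %*% op$R
    fixed <- rowSums(abs(hR - hkl)) == 0L
    phase <- imod(as.integer(hkl %*% op$t), 12L)
    out <- out | (fixed & phase != 0L)
  }
  out
}

.zone_name <- function(R) {
  free <- vapply(1:3, function(i) {
    h <- integer(3); h[i] <- 1L
    all((h %*% R) == h)
  }, logical(1))
  lab <- c("h", "k", "l")
  zeros <- c("0", "0", "0")
  if (all(free)) return("hkl")
  nm <- ifelse(free, lab, zeros)
  if (!any(free)) return("(general)")
  paste(nm, collapse = "")
}

#' Systematic-absence conditions of a space-group setting
#'
#' Lists, per translation-bearing operator, the reflection zone it
#' constrains and the divisibility condition; and tests reflection sets
#' for violations.
#'
#' @param setting `ciflint_spacegroup`.
#' @return data.frame with columns `zone`, `operator`, `condition`.
#' @export
#' @examples
#' absence_conditions(spacegroup_setting(hall = "-P 2ybc"))
absence_conditions <- function(setting) {
  rows <- list()
  for (op in setting$ops) {
    if (all(op$t == 0L)) next
    zone <- .zone_name(op$R)
    if (zone == "(general)") next
    ## modulus: smallest m with m * t/12 integral on the fixed subspace
    g <- gcd2(gcd2(op$t[1], gcd2(op$t[2], op$t[3])), 12L)
    m <- 12L %/% g
    cond <- sprintf("h.t = (%d %d %d)/12 integral (period %d)",
                    op$t[1], op$t[2], op$t[3], m)
    rows[[length(rows) + 1L]] <-
      data.frame(zone = zone, operator = op_triplet(op), condition = cond,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(zone = character(), operator = character(),
                      condition = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' @rdname absence_conditions
#' @param refl A reflection set (see [reflection_set()]); merged or
#'   unmerged intensities with standard uncertainties.
#' @param nsigma Significance multiple for calling a violation (default 3).
#' @return `absence_violations`: data.frame of extinct reflections with
#'   `I > nsigma * sigma`, ranked by I/sigma.
#' @export
absence_violations <- function(refl, setting, nsigma = 3) {
  stopifnot(nsigma > 0)
  df <- as.data.frame(refl)
  if (!nrow(df)) stop_ciflint("empty reflection set", "ciflint_refl_error")
  ext <- is_extinct(as.matrix(df[, c("h", "k", "l")]), setting)
  bad <- ext & df$fo2 > nsigma * df$sig
  out <- df[bad, c("h", "k", "l", "fo2", "sig")]
  out$i_over_sig <- out$fo2 / out$sig
  out[order(-out$i_over_sig), , drop = FALSE]
}

## --- consistency of reported symmetry --------------------------------------

.metric_rules <- function(system, axis) {
  ## returns list of checks: list(kind = "len_eq"|"ang", i, j or value)
  ax <- if (is.null(axis)) 3L else which(abs(axis) == max(abs(axis)))[1]
  switch(system,
    triclinic = list(),
    monoclinic = {
      ## the two angles not about the unique axis must be 90
      idx <- setdiff(1:3, ax)
      lapply(idx, function(i) list(kind = "ang", i = i, value = 90))
    },
    orthorhombic = lapply(1:3, function(i) list(kind = "ang", i = i, value = 90)),
    tetragonal = c(lapply(1:3, function(i) list(kind = "ang", i = i, value = 90)),
                   list(list(kind = "len_eq", i = setdiff(1:3, ax)[1],
                             j = setdiff(1:3, ax)[2]))),
    trigonal = ,
    hexagonal = list(list(kind = "ang", i = 1, value = 90),
                     list(kind = "ang", i = 2, value = 90),
                     list(kind = "ang", i = 3, value = 120),
                     list(kind = "len_eq", i = 1, j = 2)),
    cubic = c(lapply(1:3, function(i) list(kind = "ang", i = i, value = 90)),
              list(list(kind = "len_eq", i = 1, j = 2),
                   list(kind = "len_eq", i = 1, j = 3))),
    list())
}

finding <- function(code, message, value = NA_real_) {
  data.frame(code = code, message = message, value = value,
             stringsAsFactors = FALSE)
}

#' Check mutual consistency of reported symmetry information
#'
#' Compares the listed operator loop against the Hall expansion, the
#' Hermann-Mauguin symbol against the Hall symbol through the bundled
#' standard-setting table (skipped, with a note, for Hall symbols not in
#' the table), and the cell metric against the constraints of the crystal
#' system implied by the operator set.  The crystal system is always taken
#' from the operators, never inferred from metric pseudo-symmetry.
#'
#' @param sym List with any of `hm`, `hall`, `ops` (triplets), plus `cell`
#'   (`ciflint_cell`).  Missing pieces yield findings, not errors.
#' @param len_floor,ang_floor Absolute tolerance floors (0.002 Angstrom,
#'   0.02 degrees); the effective tolerance is `max(3*su, floor)`.
#' @return data.frame of findings (empty when fully consistent).
#' @export
check_symmetry_consistency <- function(sym, len_floor = 0.002, ang_floor = 0.02) {
  fx <- list()
  add <- function(f) fx[[length(fx) + 1L]] <<- f
  setting <- NULL
  if (!is.null(sym$hall)) {
    setting <- tryCatch(spacegroup_setting(hall = sym$hall, hm = sym$hm),
                        error = function(e) NULL)
    if (is.null(setting))
      add(finding("SYM_HALL_INVALID", sprintf("Hall symbol '%s' cannot be expanded", sym$hall)))
  } else add(finding("SYM_HALL_MISSING", "no Hall symbol reported"))
  if (is.null(sym$hm)) add(finding("SYM_HM_MISSING", "no Hermann-Mauguin symbol reported"))
  ops_listed <- NULL
  if (!is.null(sym$ops) && length(sym$ops)) {
    ops_listed <- tryCatch(lapply(sym$ops, parse_triplet), error = function(e) NULL)
    if (is.null(ops_listed))
      add(finding("SYM_OPS_INVALID", "operator loop contains unparseable triplets"))
  } else add(finding("SYM_OPS_MISSING", "no symmetry-operator loop reported"))
  if (is.null(setting) && !is.null(ops_listed))
    setting <- spacegroup_setting(hm = sym$hm, ops = sym$ops)
  if (is.null(setting) && !is.null(sym$hm))
    setting <- tryCatch(spacegroup_setting(hm = sym$hm), error = function(e) NULL)

  ## operator loop vs Hall expansion (as sets, mod lattice)
  if (!is.null(ops_listed) && !is.null(sym$hall) && !is.null(setting) &&
      !is.null(setting$hall)) {
    hall_ops <- tryCatch(expand_hall(sym$hall), error = function(e) NULL)
    if (!is.null(hall_ops)) {
      k1 <- sort(vapply(group_closure(ops_listed), op_key, character(1)))
      k2 <- sort(vapply(hall_ops, op_key, character(1)))
      if (!identical(k1, k2))
        add(finding("SYM_OPS_HALL_MISMATCH",
                    "listed operator set differs from the Hall-symbol expansion"))
    }
  }
  ## HM vs Hall via bundled table (standard settings + common alternates)
  if (!is.null(sym$hm) && !is.null(sym$hall)) {
    tab <- sg_table()
    hit <- tab[norm_hall(tab$hall) == norm_hall(sym$hall), ]
    if (!nrow(hit)) {
      add(finding("SYM_SETTING_NONSTANDARD",
                  "Hall symbol not in bundled table; HM/Hall comparison skipped (non-standard setting)"))
    } else if (!any(norm_hm(hit$hm_full) == norm_hm(sym$hm) |
                    norm_hm(hit$hm_short) == norm_hm(sym$hm))) {
      add(finding("SYM_HM_HALL_MISMATCH",
                  sprintf("Hermann-Mauguin symbol '%s' does not match Hall symbol '%s' (table: %s)",
                          sym$hm, sym$hall, hit$hm_short[1])))
    }
  }
  ## cell metric vs crystal system from operators
  if (!is.null(setting) && !is.null(sym$cell)) {
    cl <- sym$cell
    su <- cl$su
    suv <- function(nm, deflt) {
      v <- if (!is.null(su)) su[[nm]] else NULL
      if (is.null(v) || is.na(v)) deflt else v
    }
    lens <- c(cl$a, cl$b, cl$c); angs <- c(cl$alpha, cl$beta, cl$gamma)
    len_su <- vapply(c("a", "b", "c"), suv, numeric(1), deflt = 0)
    ang_su <- vapply(c("alpha", "beta", "gamma"), suv, numeric(1), deflt = 0)
    rules <- .metric_rules(setting$crystal_system, principal_axis_of(setting$ops))
    for (r in rules) {
      if (r$kind == "ang") {
        tol <- max(3 * ang_su[r$i], ang_floor)
        dev <- abs(angs[r$i] - r$value)
        if (dev > tol)
          add(finding("SYM_CELL_SYSTEM_MISMATCH",
                      sprintf("cell angle %s = %.4f deviates from %g by %.4f deg (tol %.4f); violates %s constraint",
                              c("alpha", "beta", "gamma")[r$i], angs[r$i], r$value,
                              dev, tol, setting$crystal_system), dev))
      } else {
        tol <- max(3 * max(len_su[r$i], len_su[r$j]), len_floor)
        dev <- abs(lens[r$i] - lens[r$j])
        if (dev > tol)
          add(finding("SYM_CELL_SYSTEM_MISMATCH",
                      sprintf("cell edges %s and %s differ by %.4f A (tol %.4f); violates %s constraint",
                              c("a", "b", "c")[r$i], c("a", "b", "c")[r$j], dev, tol,
                              setting$crystal_system), dev))
      }
    }
  }
  if (!length(fx))
    return(data.frame(code = character(), message = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, fx)
}
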