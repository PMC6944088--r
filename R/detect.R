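## Missed-symmetry (coordinate-based) and twin-law (intensity-based)
## searches.

## all integer involutions with entries in {-1,0,1} compatible with the
## cell metric (candidate extra point-symmetry operations)
.lattice_involutions <- function(cellv, metric_tol = 0.02) {
  if (!is.null(.ciflint_env$invol_cache)) cands <- .ciflint_env$invol_cache
  else {
    cands <- list()
    vals <- c(-1L, 0L, 1L)
    for (i in seq_len(3^9) - 1L) {
      dig <- vals[(i %/% 3^(0:8)) %% 3 + 1L]
      R <- matrix(dig, 3, 3)
      d <- det(R)
      if (abs(abs(d) - 1) > 1e-9) next
      if (!all(R %*% R == diag(3))) next
      cands[[length(cands) + 1L]] <- R
    }
    .ciflint_env$invol_cache <- cands
  }
  keep <- vapply(cands, function(R) {
    Gp <- t(R) %*% cellv$G %*% R
    max(abs(Gp - cellv$G)) / max(abs(cellv$G)) < metric_tol
  }, logical(1))
  cands[keep]
}

## does (R, tfrac) coincide with an operator already in the group?
.op_in_group <- function(R, tfrac, setting, cellv, tol) {
  for (op in setting$ops) {
    if (!all(op$R == R)) next
    if (frac_dist_mi(cellv, tfrac - op$t / 12) < tol) return(TRUE)
  }
  FALSE
}

#' Search for missed symmetry in atomic coordinates
#'
#' Tests candidate extra operations (lattice translations, inversion
#' centres, two-fold axes and mirrors along cell axes and diagonals,
#' found as metric-compatible integer involutions) against the eligible
#' atoms.  Hydrogen and disordered atoms are excluded, and element
#' identity is ignored by default so atom-type mis-assignments are still
#' caught; a configurable percentage of atoms is allowed not to conform.
#'
#' @param model `ciflint_model`.
#' @param tol Matching tolerance in Angstrom (default 0.45).
#' @param allowed_nonfit Percentage of eligible atoms allowed not to
#'   conform (default 15).
#' @param match_elements Require equal element symbols when matching
#'   (default FALSE).
#' @return List of proposals: `op` (R and fractional t), `kind`,
#'   `fit_fraction` (percent), `max_displacement`, `implied_hall`
#'   (bundled-table Hall symbol of the closure when determinable, else
#'   `"undetermined"`), or the string `"not assessed"` when fewer than 3
#'   eligible atoms remain.
#' @export
addsym_search <- function(model, tol = 0.45, allowed_nonfit = 15,
                          match_elements = FALSE) {
  sdf <- model$sites
  elig <- which(!sdf$is_h & !sdf$disordered)
  if (length(elig) < 3L) return("not assessed")
  x <- t(as.matrix(sdf[elig, c("x", "y", "z")]))
  el <- sdf$element[elig]
  n <- ncol(x)
  cellv <- model$cell
  need <- ceiling((100 - allowed_nonfit) / 100 * n)
  proposals <- list()
  for (R in .lattice_involutions(cellv)) {
    ## candidate translations from all ordered atom pairs
    Rx <- R %*% x
    tcand <- matrix(0, 3, 0)
    for (i in seq_len(n)) tcand <- cbind(tcand, frac1(x - Rx[, i]))
    ## bin on a grid fine relative to tol to find frequent translations
    binsz <- pmax(tol / c(cellv$a, cellv$b, cellv$c), 1e-4)
    key <- paste(round(tcand[1, ] / binsz[1]), round(tcand[2, ] / binsz[2]),
                 round(tcand[3, ] / binsz[3]))
    tb <- sort(table(key), decreasing = TRUE)
    tb <- tb[tb >= max(2L, need %/% 2L)]
    tried <- 0L
    for (k in names(tb)) {
      if (tried >= 4L) break
      tried <- tried + 1L
      sel <- which(key == k)
      anchor <- tcand[, sel[1]]
      tfrac <- frac1(anchor + rowMeans(wrap_half(tcand[, sel, drop = FALSE] - anchor)))
      if (all(R == diag(3)) && frac_dist_mi(cellv, tfrac) < tol) next  # trivial identity
      if (.op_in_group(R, tfrac, model$setting, cellv, tol)) next
      ## conformity per source atom: distance from the image of atom i to
      ## the nearest (eligible) atom
      conf <- vapply(seq_len(n), function(i) {
        img_i <- as.numeric(R %*% x[, i]) + tfrac
        d <- frac_dist_mi(cellv, img_i - x)
        if (match_elements) d[el != el[i]] <- Inf
        min(d)
      }, numeric(1))
      fit <- sum(conf < tol)
      if (fit < need) next
      ## classify and derive the implied group where the translation snaps
      ## to the twelfths grid
      kind <- if (all(R == diag(3))) "centering translation"
              else if (all(R == -diag(3))) "inversion centre"
              else if (round(det(R)) > 0) "two-fold rotation" else "mirror/glide"
      t12 <- round(tfrac * 12)
      implied <- "undetermined"
      if (frac_dist_mi(cellv, tfrac - t12 / 12) < min(tol, 0.1)) {
        ext <- tryCatch(group_closure(c(model$setting$ops, list(symop(R, t12))),
                                      max_order = 192L), error = function(e) NULL)
        if (!is.null(ext)) implied <- .match_group_in_table(ext) %||%
            sprintf("undetermined (order %d)", length(ext))
      }
      proposals[[length(proposals) + 1L]] <- list(
        R = R, t = tfrac, kind = kind,
        fit_fraction = 100 * fit / n,
        max_displacement = max(conf[conf < tol]),
        implied_hall = implied,
        n_eligible = n)
    }
  }
  ## deduplicate by (R, t) proximity
  if (length(proposals) > 1L) {
    keep <- rep(TRUE, length(proposals))
    for (i in seq_along(proposals)) for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (all(proposals[[i]]$R == proposals[[j]]$R) &&
          frac_dist_mi(cellv, proposals[[i]]$t - proposals[[j]]$t) < tol)
        { keep[i] <- FALSE; break }
    }
    proposals <- proposals[keep]
  }
  proposals
}

## match an operator list against the bundled Hall table (cached keys)
.match_group_in_table <- function(ops) {
  if (is.null(.ciflint_env$table_keys)) {
    tab <- sg_table()
    keys <- vapply(tab$hall, function(h)
      paste(sort(vapply(expand_hall(h), op_key, character(1))), collapse = "|"),
      character(1))
    .ciflint_env$table_keys <- stats::setNames(tab$hall, keys)
  }
  key <- paste(sort(vapply(ops, op_key, character(1))), collapse = "|")
  hit <- .ciflint_env$table_keys[key]
  if (is.na(hit)) NULL else unname(hit)
}

#' Candidate twin laws for a cell
#'
#' Two-fold rotations about every direct row `[uvw]` and reciprocal row
#' `(hkl)` with coprime indices up to `max_index`, expressed in the
#' lattice basis.  Candidates that do not map the lattice approximately
#' onto itself (entries further than `obliquity_tol` from integers) and
#' rotations already in the Laue group are discarded; near-duplicates
#' are merged.
#'
#' @param cellv `ciflint_cell`.
#' @param setting `ciflint_spacegroup` providing the Laue group.
#' @param max_index Maximum axis index (default 2).
#' @param obliquity_tol Integrality tolerance on the index action
#'   (default 0.05).
#' @return List of candidates: `R` (action on fractional coordinates;
#'   indices transform as `h' = h R`), `axis` description.
#' @export
twin_candidates <- function(cellv, setting, max_index = 2L, obliquity_tol = 0.05) {
  stopifnot(max_index >= 1L)
  dirs <- list()
  rng <- -max_index:max_index
  for (u in rng) for (v in rng) for (w in rng) {
    if (u == 0 && v == 0 && w == 0) next
    g <- gcd2(abs(u), gcd2(abs(v), abs(w)))
    d <- c(u, v, w) / g
    ## canonical sign: first nonzero positive
    nz <- which(d != 0)[1]
    if (d[nz] < 0) d <- -d
    dirs[[paste(d, collapse = ",")]] <- d
  }
  laue <- setting$laue_ops
  out <- list()
  twofold_cart <- function(u) 2 * outer(u, u) / sum(u^2) - diag(3)
  for (space in c("direct", "reciprocal")) {
    for (d in dirs) {
      u <- if (space == "direct") as.numeric(cellv$M %*% d)
           else as.numeric(t(cellv$Minv) %*% d)
      Rf <- cellv$Minv %*% twofold_cart(u) %*% cellv$M
      if (max(abs(Rf - round(Rf))) > obliquity_tol) next
      if (any(vapply(laue, function(L) max(abs(Rf - L)) < 1e-4, logical(1)))) next
      dup <- any(vapply(out, function(o) max(abs(o$R - Rf)) < 1e-6, logical(1)))
      if (dup) next
      out[[length(out) + 1L]] <- list(
        R = Rf,
        axis = sprintf("%s [%d %d %d]", if (space == "direct") "direct" else "reciprocal",
                       d[1], d[2], d[3]))
    }
  }
  out
}

#' Search reflection data for twin laws
#'
#' Twinning leaves a population of reflections with observed intensity
#' far above the calculated one, each overlapped by a strong reflection
#' of a rotation-related lattice at (approximately) the same diffraction
#' angle.  For every candidate two-fold, the fraction of such outliers it
#' explains is computed; laws above `explained_min` are scored by
#' golden-section refinement of the twin fraction `alpha` that minimizes
#' R1 of the two-component intensity model, and the estimated R drop is
#' reported.
#'
#' @param refl Merged reflection set with `fc2` and a cell.
#' @param setting `ciflint_spacegroup`.
#' @param outlier_mult Outlier rule: `Fo2 > outlier_mult * Fc2` and
#'   `Fo2 > 10 sigma` (default 2).
#' @param min_outliers Minimum number of outliers to attempt detection
#'   (default 20; heavily pre-filtered data defeat twin detection).
#' @param delta Index-integrality tolerance for overlap (default 0.1).
#' @param theta_tol Diffraction-angle coincidence tolerance in degrees
#'   (default 0.1).
#' @param explained_min Minimum explained fraction, percent (default 60).
#' @param max_index Passed to [twin_candidates()].
#' @return List of laws (`axis`, `R`, `explained_fraction`, `alpha_hat`,
#'   `r1_before`, `r1_after`) ordered by explained fraction, or the
#'   string `"not assessed"`.
#' @export
twin_search <- function(refl, setting, outlier_mult = 2, min_outliers = 20L,
                        delta = 0.1, theta_tol = 0.1, explained_min = 60,
                        max_index = 2L) {
  df <- as.data.frame(refl)
  cellv <- attr(refl, "cell")
  if (is.null(df$fc2)) stop_ciflint("Fc2 required for twin search", "ciflint_twin_error")
  lam <- attr(refl, "wavelength")
  if (!is.finite(lam)) lam <- NA
  ## Fc2 lookup over the Laue-expanded set
  lut <- new.env(parent = emptyenv(), size = 4L * nrow(df))
  hm <- as.matrix(df[, c("h", "k", "l")])
  for (L in setting$laue_ops) {
    img <- hm %*% L
    keys <- sprintf("%d,%d,%d", img[, 1], img[, 2], img[, 3])
    for (r in seq_len(nrow(img)))
      if (is.null(lut[[keys[r]]])) lut[[keys[r]]] <- df$fc2[r]
  }
  fc2_at <- function(m) {
    vapply(seq_len(nrow(m)), function(r) {
      v <- lut[[sprintf("%d,%d,%d", m[r, 1], m[r, 2], m[r, 3])]]
      v %||% NA_real_
    }, numeric(1))
  }
  out_idx <- which(df$fo2 > outlier_mult * df$fc2 & df$fo2 > 10 * df$sig)
  if (length(out_idx) < min_outliers) return("not assessed")
  theta_of <- function(hfrac) {
    s <- s_of_hkl(cellv, hfrac)
    if (is.na(lam)) s else asin(pmin(s * lam, 1)) * 180 / pi
  }
  laws <- list()
  for (cand in twin_candidates(cellv, setting, max_index)) {
    hout <- hm[out_idx, , drop = FALSE]
    hrot <- hout %*% cand$R
    hint <- round(hrot)
    near <- apply(abs(hrot - hint), 1, max) < delta
    fc_part <- fc2_at(hint)
    th_ok <- abs(theta_of(hrot) - theta_of(hout)) < theta_tol
    explained <- near & th_ok & !is.na(fc_part) & fc_part > df$fc2[out_idx]
    frac <- 100 * mean(explained)
    if (frac < explained_min) next
    ## alpha refinement over the full data set
    hall_rot <- round(hm %*% cand$R)
    fc_p <- fc2_at(hall_rot)
    fc_p[is.na(fc_p)] <- df$fc2[is.na(fc_p)]
    r1_of <- function(alpha) {
      mod <- (1 - alpha) * df$fc2 + alpha * fc_p
      obs <- df$fo2 > 2 * df$sig
      fo <- sqrt(pmax(df$fo2[obs], 0)); fc <- sqrt(pmax(mod[obs], 0))
      sum(abs(fo - fc)) / sum(fo)
    }
    ## golden-section minimization on [0, 0.5]
    gr <- (sqrt(5) - 1) / 2
    a <- 0; b <- 0.5
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- r1_of(c1); f2 <- r1_of(c2)
    while (b - a > 1e-3) {
      if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- r1_of(c1) }
      else { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- r1_of(c2) }
    }
    alpha_hat <- (a + b) / 2
    laws[[length(laws) + 1L]] <- list(
      axis = cand$axis, R = cand$R, explained_fraction = frac,
      alpha_hat = alpha_hat, r1_before = r1_of(0), r1_after = r1_of(alpha_hat),
      n_outliers = length(out_idx))
  }
  laws[order(-vapply(laws, `[[`, numeric(1), "explained_fraction"))]
}

#' Export an HKLF5-style reflection file for a twin law
#'
#' Reflections overlapped under the law (same empirical criterion as the
#' twin search: rotated indices within `delta` of integers and matching
#' diffraction angle within `theta_tol`) are written as component pairs,
#' the non-last component carrying a negative batch number; the
#' criterion is echoed in a comment header.
#'
#' @param refl Reflection set.
#' @param law One law from [twin_search()] (or a list with `R`).
#' @param delta,theta_tol Overlap criterion.
#' @return Fixed-width `(3I4,2F8.2,I4)` text.
#' @export
export_hklf5 <- function(refl, law, delta = 0.1, theta_tol = 0.1) {
  df <- as.data.frame(refl)
  cellv <- attr(refl, "cell")
  lam <- attr(refl, "wavelength")
  hm <- as.matrix(df[, c("h", "k", "l")])
  hrot <- hm %*% law$R
  hint <- round(hrot)
  near <- apply(abs(hrot - hint), 1, max) < delta
  if (!is.null(cellv)) {
    th <- function(hh) {
      s <- s_of_hkl(cellv, hh)
      if (is.finite(lam)) asin(pmin(s * lam, 1)) * 180 / pi else s
    }
    near <- near & abs(th(hrot) - th(hm)) < theta_tol
  }
  hdr <- sprintf("! HKLF5 export: overlap criterion delta=%.3f, theta_tol=%.3f deg",
                 delta, theta_tol)
  recs <- character(0)
  for (r in seq_len(nrow(df))) {
    if (near[r]) {
      recs <- c(recs,
                sprintf("%4d%4d%4d%8.2f%8.2f%4d", hint[r, 1], hint[r, 2], hint[r, 3],
                        df$fo2[r], df$sig[r], -2L),
                sprintf("%4d%4d%4d%8.2f%8.2f%4d", df$h[r], df$k[r], df$l[r],
                        df$fo2[r], df$sig[r], 1L))
    } else {
      recs <- c(recs, sprintf("%4d%4d%4d%8.2f%8.2f%4d", df$h[r], df$k[r], df$l[r],
                              df$fo2[r], df$sig[r], 1L))
    }
  }
  paste0(paste(c(hdr, recs), collapse = "\n"),
         sprintf("\n%4d%4d%4d%8.2f%8.2f%4d\n", 0L, 0L, 0L, 0, 0, 0L))
}
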