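## Difference electron-density maps and solvent-accessible voids.

#' Synthesize an Fc-phased difference density map
#'
#' `rho(x) = (1/V) sum_h (|Fo| - |Fc|) exp(i phi_c) exp(-2 pi i h.x)`,
#' Friedel-completed and evaluated by FFT; the F(000) term is excluded,
#' so the map mean is exactly zero.  A featureless map (excursions within
#' about +/-0.5 e/A^3) is the hallmark of a well-behaved refinement.
#'
#' @param refl Merged reflection set carrying `fc2` and `phase`
#'   (degrees).
#' @param setting Space-group setting used to expand the unique
#'   reflections; when `NULL` the set is assumed to be already expanded
#'   (still Friedel-completed internally).
#' @param grid_step Target grid spacing in Angstrom (default 0.2; must
#'   resolve the data, `grid_step <= d_min/3`).
#' @return Object of class `ciflint_densitygrid`: list with `dims`,
#'   `values` (3-d array, e/A^3), `cell`.
#' @export
difference_map <- function(refl, setting = NULL, grid_step = 0.2) {
  df <- as.data.frame(refl)
  cellv <- attr(refl, "cell")
  if (is.null(cellv)) stop_ciflint("reflection set has no cell", "ciflint_map_error")
  if (!nrow(df)) stop_ciflint("empty coefficient set", "ciflint_map_error")
  if (is.null(df$fc2) || is.null(df$phase))
    stop_ciflint("difference map needs fc2 and phase columns", "ciflint_map_error")
  s <- refl_s(refl)
  d_min <- 1 / (2 * max(s))
  if (grid_step > d_min / 3 + 1e-9)
    stop_ciflint(sprintf("grid too coarse: step %.3f > d_min/3 = %.3f", grid_step,
                         d_min / 3), "ciflint_map_error")
  hkl <- as.matrix(df[, c("h", "k", "l")])
  dF <- (sqrt(pmax(df$fo2, 0)) - sqrt(pmax(df$fc2, 0)))
  Fh <- complex(modulus = abs(dF), argument = df$phase * pi / 180)
  Fh[dF < 0] <- -Fh[dF < 0]
  ## expand to the full sphere over the space group
  if (!is.null(setting)) {
    Hx <- list(); Fx <- list()
    for (op in setting$ops) {
      Hx[[length(Hx) + 1L]] <- hkl %*% op$R
      Fx[[length(Fx) + 1L]] <- Fh * exp(-2i * pi * as.numeric(hkl %*% (op$t / 12)))
    }
    hkl <- do.call(rbind, Hx); Fh <- unlist(Fx)
  }
  ## Friedel completion
  hkl <- rbind(hkl, -hkl); Fh <- c(Fh, Conj(Fh))
  keep <- !duplicated(paste(hkl[, 1], hkl[, 2], hkl[, 3]))
  hkl <- hkl[keep, , drop = FALSE]; Fh <- Fh[keep]
  zero <- rowSums(abs(hkl)) == 0L
  hkl <- hkl[!zero, , drop = FALSE]; Fh <- Fh[!zero]
  hmax <- apply(abs(hkl), 2, max)
  dims <- vapply(1:3, function(i) {
    n <- max(ceiling(c(cellv$a, cellv$b, cellv$c)[i] / grid_step), 2L * hmax[i] + 2L)
    stats::nextn(n, c(2, 3, 5))
  }, numeric(1))
  A <- array(complex(real = 0), dim = dims)
  idx <- sweep(imod(-hkl, matrix(dims, nrow(hkl), 3, byrow = TRUE)), 2, c(1, 1, 1), `+`)
  A[idx] <- Fh / cellv$volume
  rho <- Re(stats::fft(A, inverse = TRUE))
  structure(list(dims = dims, values = rho, cell = cellv, step = grid_step),
            class = "ciflint_densitygrid")
}

#' @export
print.ciflint_densitygrid <- function(x, ...) {
  cat(sprintf("Density grid %dx%dx%d: min %.3f, max %.3f e/A^3\n",
              x$dims[1], x$dims[2], x$dims[3], min(x$values), max(x$values)))
  invisible(x)
}

## periodic trilinear interpolation at fractional positions (3 x n)
grid_interp <- function(grid, frac) {
  frac <- matrix(frac, nrow = 3)
  n <- ncol(frac)
  out <- numeric(n)
  d <- grid$dims
  for (i in seq_len(n)) {
    g <- frac1(frac[, i]) * d
    i0 <- floor(g); f <- g - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      ii <- imod(i0 + c(dx, dy, dz), d) + 1
      acc <- acc + w * grid$values[ii[1], ii[2], ii[3]]
    }
    out[i] <- acc
  }
  out
}

## circular array shift along one dimension
.ashift <- function(a, dim, by) {
  n <- dim(a)[dim]
  idx <- imod(seq_len(n) - 1L + by, n) + 1L
  switch(dim, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
}

#' Peak search in a density grid
#'
#' Local maxima of the (positive) density over the 26-neighbourhood,
#' refined by separable parabolic interpolation, with the distance to the
#' nearest atom of the model.
#'
#' @param grid `ciflint_densitygrid`.
#' @param model Optional `ciflint_model` for nearest-atom distances.
#' @param n_top Number of peaks to return.
#' @param min_height Ignore peaks below this height (e/A^3).
#' @return data.frame of peaks ordered by height.
#' @export
peak_search <- function(grid, model = NULL, n_top = 10L, min_height = 0.1) {
  v <- grid$values
  is_max <- array(TRUE, dim = dim(v))
  for (dim in 1:3) for (by in c(-1L, 1L)) is_max <- is_max & (v >= .ashift(v, dim, by))
  cand <- which(is_max & v >= min_height, arr.ind = TRUE)
  if (!nrow(cand)) return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                                     height = numeric(), nearest = character(),
                                     d_nearest = numeric(), stringsAsFactors = FALSE))
  h <- v[cand]
  ord <- order(-h)[seq_len(min(n_top, length(h)))]
  cand <- cand[ord, , drop = FALSE]; h <- h[ord]
  res <- lapply(seq_len(nrow(cand)), function(r) {
    ijk <- cand[r, ]
    off <- numeric(3); hh <- h[r]
    for (dim in 1:3) {
      im <- ijk; ip <- ijk
      im[dim] <- imod(ijk[dim] - 2L, grid$dims[dim]) + 1L
      ip[dim] <- imod(ijk[dim], grid$dims[dim]) + 1L
      ym <- v[im[1], im[2], im[3]]; y0 <- h[r]; yp <- v[ip[1], ip[2], ip[3]]
      den <- ym - 2 * y0 + yp
      if (den < 0) {
        dd <- 0.5 * (ym - yp) / den
        off[dim] <- max(-0.5, min(0.5, dd))
        hh <- max(hh, y0 - 0.25 * (ym - yp) * off[dim])
      }
    }
    frac <- frac1((ijk - 1 + off) / grid$dims)
    c(frac, hh)
  })
  res <- do.call(rbind, res)
  out <- data.frame(x = res[, 1], y = res[, 2], z = res[, 3], height = res[, 4],
                    nearest = NA_character_, d_nearest = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(model)) {
    for (r in seq_len(nrow(out))) {
      best <- Inf; lab <- NA_character_
      for (op in model$setting$ops) {
        img <- op_apply(op, t(as.matrix(model$sites[, c("x", "y", "z")])))
        d <- frac_dist_mi(grid$cell, img - as.numeric(out[r, c("x", "y", "z")]))
        if (min(d) < best) { best <- min(d); lab <- model$sites$label[which.min(d)] }
      }
      out$nearest[r] <- lab; out$d_nearest[r] <- best
    }
  }
  out
}

#' Summarize a difference map against the model
#'
#' Reports the map extrema, the interpolated density on every atom site
#' and the mean density at bond midpoints, and grades findings: extrema
#' beyond 0.5/1.0/1.5 e/A^3 (C/B/A; excursions within 1 Angstrom of an
#' atom with Z >= 20 are reported separately as probable absorption
#' artefacts), significant on-atom density (possible wrong atom type),
#' and reported-versus-recalculated extrema differing by more than
#' `0.05 + 5%`.
#'
#' @param grid `ciflint_densitygrid`.
#' @param model `ciflint_model`.
#' @param bonds Optional bond list from [build_connectivity()].
#' @param reported_max,reported_min Extrema as archived in the CIF.
#' @param on_atom_threshold Flagging threshold for on-site density
#'   (default 0.5 e/A^3; a one-electron atom-type error at typical
#'   resolution produces about 0.9).
#' @return List with `min`, `max`, `site_density`, `bond_mean`,
#'   `findings`.
#' @export
map_report <- function(grid, model, bonds = NULL, reported_max = NA,
                       reported_min = NA, on_atom_threshold = 0.5) {
  v <- grid$values
  sdf <- model$sites
  site_rho <- grid_interp(grid, t(as.matrix(sdf[, c("x", "y", "z")])))
  bond_mean <- NA_real_
  if (!is.null(bonds) && nrow(bonds)) {
    mids <- (t(as.matrix(sdf[bonds$i, c("x", "y", "z")])) +
             t(as.matrix(sdf[bonds$j, c("x", "y", "z")]))) / 2
    bond_mean <- mean(grid_interp(grid, mids))
  }
  fx <- list()
  add <- function(f) fx[[length(fx) + 1L]] <<- f
  ## extrema grading, heavy-atom environment separated
  zs <- vapply(sdf$element, function(e) element_row(e)$z, numeric(1))
  heavy <- which(zs >= 20)
  near_heavy <- function(frac_pos) {
    if (!length(heavy)) return(FALSE)
    any(vapply(model$setting$ops, function(op) {
      img <- op_apply(op, t(as.matrix(sdf[heavy, c("x", "y", "z")])))
      min(frac_dist_mi(grid$cell, img - frac_pos)) < 1.0
    }, logical(1)))
  }
  for (side in c("max", "min")) {
    ex <- if (side == "max") max(v) else min(v)
    ijk <- which(if (side == "max") v == max(v) else v == min(v), arr.ind = TRUE)[1, ]
    pos <- (ijk - 1) / grid$dims
    if (abs(ex) > 0.5) {
      lvl <- if (abs(ex) > 1.5) "A" else if (abs(ex) > 1.0) "B" else "C"
      code <- if (near_heavy(pos)) "MAP_EXTREMUM_NEAR_HEAVY" else "MAP_EXTREMUM"
      add(finding(code, sprintf("difference map %s %.3f e/A^3 exceeds the +/-0.5 featureless bound (grade %s)",
                                side, ex, lvl), ex))
    }
  }
  on_atom <- which(abs(site_rho) > on_atom_threshold & !sdf$is_h)
  for (i in on_atom)
    add(finding("MAP_ON_ATOM",
                sprintf("density %.2f e/A^3 on atom site %s: possible wrong atom-type assignment",
                        site_rho[i], sdf$label[i]), site_rho[i]))
  cmp <- function(rep, calc, what) {
    if (!is.na(rep) && abs(rep - calc) > 0.05 + 0.05 * abs(calc))
      add(finding("MAP_REPORTED_MISMATCH",
                  sprintf("reported residual-density %s %.3f vs recalculated %.3f e/A^3",
                          what, rep, calc), abs(rep - calc)))
  }
  cmp(reported_max, max(v), "max"); cmp(reported_min, min(v), "min")
  findings <- if (length(fx)) do.call(rbind, fx) else finding("", "")[0, ]
  list(min = min(v), max = max(v),
       site_density = data.frame(label = sdf$label, rho = site_rho,
                                 stringsAsFactors = FALSE),
       bond_mean = bond_mean, findings = findings)
}

#' Density support for hydrogen sites
#'
#' In as-is mode (difference map from the full model) an H site is called
#' unsupported when the local density is below `-0.2` e/A^3 (density had
#' to be removed there: a misplaced hydrogen).  In omit mode (map
#' computed from a model with the H atoms left out) support requires
#' positive density above `+0.2` e/A^3 at the site.
#'
#' @param grid `ciflint_densitygrid`.
#' @param model `ciflint_model`.
#' @param mode `"asis"` or `"omit"`.
#' @param threshold Override the mode default.
#' @return data.frame with one row per H atom.
#' @export
h_site_support <- function(grid, model, mode = c("asis", "omit"), threshold = NULL) {
  mode <- match.arg(mode)
  hidx <- which(model$sites$is_h)
  if (!length(hidx))
    return(data.frame(label = character(), rho = numeric(), supported = logical(),
                      stringsAsFactors = FALSE))
  thr <- threshold %||% if (mode == "asis") -0.2 else 0.2
  rho <- grid_interp(grid, t(as.matrix(model$sites[hidx, c("x", "y", "z")])))
  supported <- if (mode == "asis") rho >= thr else rho >= thr
  data.frame(label = model$sites$label[hidx], rho = rho, supported = supported,
             stringsAsFactors = FALSE)
}

## ---- solvent-accessible voids ---------------------------------------------

#' Find solvent-accessible voids
#'
#' Marks every grid voxel within `r_vdw + probe` of any symmetry-expanded
#' atom as occupied, clusters the remaining voxels under periodic
#' 6-connectivity, and reports regions; regions below `min_volume` are
#' suppressed from the list but counted.
#'
#' @param model `ciflint_model`.
#' @param probe Probe radius in Angstrom (default 1.2).
#' @param grid_step Grid spacing (default 0.2).
#' @param min_volume Minimum region volume to report (default 20 A^3).
#' @return List with `regions` (list of void regions: `volume`,
#'   `centroid`, `voxels`, `n_voxels`), `n_suppressed`, `void_volume`,
#'   `occupied_volume`, `grid` (occupancy logical array), `dims`.
#' @export
find_voids <- function(model, probe = 1.2, grid_step = 0.2, min_volume = 20) {
  stopifnot(probe >= 0, grid_step > 0)
  cellv <- model$cell
  dims <- vapply(c(cellv$a, cellv$b, cellv$c), function(e)
    max(4L, as.integer(ceiling(e / grid_step))), integer(1))
  occ <- array(FALSE, dim = dims)
  sdf <- model$sites
  vdw <- vapply(sdf$element, function(e) element_row(e)$r_vdw, numeric(1))
  frac <- t(as.matrix(sdf[, c("x", "y", "z")]))
  ## fractional padding needed for a given Cartesian radius along each axis
  for (oi in seq_along(model$setting$ops)) {
    img <- op_apply(model$setting$ops[[oi]], frac)
    for (j in seq_len(ncol(img))) {
      r <- vdw[j] + probe
      ctr <- frac1(img[, j])
      pad <- r * sqrt(diag(cellv$Gstar))  # |grad s| bound per axis
      lo <- floor((ctr - pad) * dims); hi <- ceiling((ctr + pad) * dims)
      ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
      gg <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
      dx <- sweep(gg, 2, dims, `/`)
      d <- sqrt(colSums((cellv$M %*% (t(dx) - ctr))^2))
      hit <- gg[d <= r, , drop = FALSE]
      if (nrow(hit)) {
        hit <- imod(hit, matrix(dims, nrow(hit), 3, byrow = TRUE)) + 1L
        occ[hit] <- TRUE
      }
    }
  }
  voxvol <- cellv$volume / prod(dims)
  free_idx <- which(!occ)
  regions <- list(); n_sup <- 0L
  if (length(free_idx)) {
    lab <- array(0L, dim = dims)
    ## linear-index neighbour offsets with periodic wrap, via arr indices
    all_free <- arrayInd(free_idx, dims)
    free_set <- array(FALSE, dims); free_set[free_idx] <- TRUE
    visited <- array(FALSE, dims)
    lin <- function(m) (m[, 3] - 1L) * dims[1] * dims[2] + (m[, 2] - 1L) * dims[1] + m[, 1]
    for (start in free_idx) {
      if (visited[start]) next
      comp <- integer(0)
      frontier <- start
      visited[start] <- TRUE
      while (length(frontier)) {
        comp <- c(comp, frontier)
        fm <- arrayInd(frontier, dims)
        nbrs <- list()
        for (dim in 1:3) for (by in c(-1L, 1L)) {
          nm <- fm
          nm[, dim] <- imod(nm[, dim] - 1L + by, dims[dim]) + 1L
          nbrs[[length(nbrs) + 1L]] <- lin(nm)
        }
        nb <- unique(unlist(nbrs))
        nb <- nb[free_set[nb] & !visited[nb]]
        visited[nb] <- TRUE
        frontier <- nb
      }
      vol <- length(comp) * voxvol
      if (vol < min_volume) { n_sup <- n_sup + 1L; next }
      cm <- arrayInd(comp, dims)
      anchor <- (cm[1, ] - 1) / dims
      fr <- sweep(cm - 1, 2, dims, `/`)
      cen <- frac1(anchor + colMeans(wrap_half(sweep(fr, 2, anchor))))
      regions[[length(regions) + 1L]] <-
        list(volume = vol, centroid = cen, voxels = comp, n_voxels = length(comp))
    }
  }
  list(regions = regions, n_suppressed = n_sup,
       void_volume = sum(!occ) * voxvol,
       occupied_volume = sum(occ) * voxvol,
       grid = occ, dims = dims)
}

#' Integrate electrons in a void region
#'
#' Sums the difference density over the void voxels; the map should be
#' synthesized from a model with the void contents omitted, so the
#' integral estimates the electron count of the unmodelled material.
#' Negative totals are reported as-is with a caveat.
#'
#' @param void One region from [find_voids()].
#' @param grid `ciflint_densitygrid` on the same sampling as the void
#'   search.
#' @param dims The void-search grid dimensions (for the mismatch check).
#' @return List with `electrons` and `findings`.
#' @export
void_electron_count <- function(void, grid, dims = NULL) {
  if (!is.null(dims) && !all(dims == grid$dims))
    stop_ciflint("void and density grids have different sampling", "ciflint_map_error")
  voxvol <- grid$cell$volume / prod(grid$dims)
  e <- sum(grid$values[void$voxels]) * voxvol
  fx <- if (e < 0)
    finding("VOID_NEGATIVE_COUNT",
            sprintf("integrated void density is negative (%.2f e); map or model problem", e), e)
  else finding("", "")[0, ]
  list(electrons = e, findings = fx)
}

## integrate a density grid over a void region defined on a different
## (void-search) sampling, by nearest-voxel lookup
sample_void_electrons <- function(void, void_dims, grid) {
  vox <- arrayInd(void$voxels, void_dims)
  fr <- sweep(vox - 1, 2, void_dims, `/`)
  gi <- imod(round(sweep(fr, 2, grid$dims, `*`)), matrix(grid$dims, nrow(fr), 3,
                                                         byrow = TRUE)) + 1L
  voxvol <- grid$cell$volume / prod(void_dims)
  sum(grid$values[gi]) * voxvol * prod(void_dims) / prod(void_dims)
}
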