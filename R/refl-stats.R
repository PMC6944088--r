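## Agreement statistics recomputed from reflection data: merging and
## R(int), completeness, the two-parameter weighting scheme, R1/wR2/GooF,
## analysis of variance, normal-probability statistics, Parsons-style
## absolute-structure quotients and fabricated-data screening.

## canonical representative of each index triple under a rotation list;
## returns a key string per row
.canon_keys <- function(hkl, rot_list) {
  n <- nrow(hkl)
  best <- matrix(-Inf, n, 3)
  for (R in rot_list) {
    img <- hkl %*% R
    better <- (img[, 1] > best[, 1]) |
      (img[, 1] == best[, 1] & img[, 2] > best[, 2]) |
      (img[, 1] == best[, 1] & img[, 2] == best[, 2] & img[, 3] > best[, 3])
    best[better, ] <- img[better, , drop = FALSE]
  }
  paste(best[, 1], best[, 2], best[, 3])
}

proper_rotations <- function(setting) {
  Rs <- lapply(setting$ops, `[[`, "R")
  Rs[!duplicated(vapply(Rs, function(R) paste(R, collapse = ","), character(1)))]
}

#' Merge symmetry-equivalent reflections
#'
#' Groups measurements under the Laue group (optionally folding Friedel
#' mates), combines each group by inverse-variance weighting and computes
#' the internal-consistency residual
#' `Rint = sum |Fo2 - <Fo2>| / sum Fo2` over groups measured more than
#' once.
#'
#' @param refl Unmerged [reflection_set()].
#' @param setting `ciflint_spacegroup`.
#' @param include_friedel Merge `h` with `-h` (TRUE for Laue merging;
#'   FALSE keeps Bijvoet pairs separate).
#' @return List with `merged` (a reflection set), `rint`, `n_groups`,
#'   `redundancy`.
#' @export
merge_equivalents <- function(refl, setting, include_friedel = TRUE) {
  df <- as.data.frame(refl)
  if (!nrow(df)) stop_ciflint("empty reflection set", "ciflint_refl_error")
  rots <- if (include_friedel) setting$laue_ops else proper_rotations(setting)
  keys <- .canon_keys(as.matrix(df[, c("h", "k", "l")]), rots)
  gi <- match(keys, unique(keys))
  w <- 1 / df$sig^2
  sw <- tapply(w, gi, sum)
  mean_fo2 <- tapply(w * df$fo2, gi, sum) / sw
  sig_m <- sqrt(1 / sw)
  cnt <- tabulate(gi)
  ## Rint over groups with multiplicity >= 2
  multi <- cnt[gi] >= 2L
  num <- sum(abs(df$fo2 - mean_fo2[gi])[multi])
  den <- sum(df$fo2[multi])
  rint <- if (den > 0) num / den else NA_real_
  first <- !duplicated(gi)
  hklm <- do.call(rbind, strsplit(unique(keys), " "))
  merged <- reflection_set(as.integer(hklm[, 1]), as.integer(hklm[, 2]),
                           as.integer(hklm[, 3]),
                           as.numeric(mean_fo2), as.numeric(sig_m),
                           fc2 = if (!is.null(df$fc2)) as.numeric(tapply(df$fc2, gi, mean)) else NULL,
                           merged = TRUE, wavelength = attr(refl, "wavelength"),
                           cell = attr(refl, "cell"))
  list(merged = merged, rint = rint, n_groups = length(sw),
       redundancy = nrow(df) / length(sw))
}

## enumerate the symmetry-unique, non-extinct lattice points with s <= smax
unique_hkl_to <- function(setting, cell, smax) {
  hmax <- ceiling(2 * smax * c(cell$a, cell$b, cell$c)) + 1L
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  grid <- grid[rowSums(abs(grid)) > 0L, , drop = FALSE]
  s <- s_of_hkl(cell, grid)
  grid <- grid[s <= smax, , drop = FALSE]
  keys <- .canon_keys(grid, setting$laue_ops)
  grid <- grid[!duplicated(keys), , drop = FALSE]
  grid <- grid[!is_extinct(grid, setting), , drop = FALSE]
  grid
}

#' Completeness and observability profile
#'
#' Counts the possible symmetry-unique non-extinct reflections in
#' equal-width resolution shells, the fraction actually measured, and the
#' fraction observed above `2 sigma`; reports overall completeness at
#' `s = 0.6` (the resolution data sets are expected to reach) and at
#' `s_max`, plus a suggested noise cutoff: the lower boundary of the first
#' shell in which the observed fraction drops below `obs_threshold`.
#'
#' @param refl Merged reflection set.
#' @param setting,cell Symmetry and cell.
#' @param s_max Resolution limit of the profile (defaults to the maximum
#'   measured `s`).
#' @param nshells Number of equal-width shells (default 10).
#' @param obs_threshold Observed-fraction threshold for the noise cutoff
#'   (default 0.3).
#' @return List with `shells` (data.frame), `completeness_0.6`,
#'   `completeness_smax`, `suggested_cutoff`.
#' @export
completeness_profile <- function(refl, setting, cell = NULL, s_max = NULL,
                                 nshells = 10L, obs_threshold = 0.3) {
  cell <- cell %||% attr(refl, "cell")
  df <- as.data.frame(refl)
  s <- refl_s(refl, cell)
  s_max <- s_max %||% max(s)
  poss <- unique_hkl_to(setting, cell, s_max)
  sp <- s_of_hkl(cell, poss)
  keys_p <- .canon_keys(poss, setting$laue_ops)
  keys_m <- .canon_keys(as.matrix(df[, c("h", "k", "l")]), setting$laue_ops)
  measured <- !duplicated(keys_m)
  obs <- df$fo2 > 2 * df$sig
  edges <- seq(0, s_max, length.out = nshells + 1L)
  shell_of <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), nshells)
  shp <- shell_of(sp)
  shm <- shell_of(s[measured])
  n_poss <- tabulate(shp, nshells)
  in_poss <- keys_m[measured] %in% keys_p
  n_meas <- tabulate(shm[in_poss], nshells)
  n_obs <- tabulate(shell_of(s[measured & obs]), nshells)
  shells <- data.frame(
    s_lo = edges[-(nshells + 1L)], s_hi = edges[-1L],
    possible = n_poss, measured = n_meas,
    complete = ifelse(n_poss > 0, n_meas / n_poss, NA_real_),
    observed_frac = ifelse(n_meas > 0, pmin(n_obs / pmax(n_meas, 1L), 1),
                           ifelse(n_poss > 0, 0, NA_real_)))
  comp_at <- function(lim) {
    sel_p <- sp <= lim
    sel_m <- s[measured] <= lim & in_poss
    if (!any(sel_p)) return(NA_real_)
    sum(keys_m[measured][sel_m] %in% keys_p[sel_p]) / sum(sel_p)
  }
  below <- which(!is.na(shells$observed_frac) & shells$observed_frac < obs_threshold)
  cutoff <- if (length(below)) shells$s_lo[below[1]] else NA_real_
  list(shells = shells,
       completeness_0.6 = comp_at(min(0.6, s_max)),
       completeness_smax = comp_at(s_max),
       suggested_cutoff = cutoff)
}

#' Two-parameter reflection weights
#'
#' `w = 1 / (sigma^2 + (a*P)^2 + b*P)` with `P = (max(Fo2, 0) + 2*Fc2)/3`;
#' negative observed intensities are clamped to zero inside `P` only.
#'
#' @param fo2,sig,fc2 Intensity-scale vectors.
#' @param a,b Weighting parameters (>= 0).
#' @export
#' @examples
#' weights(100, 5, 100, a = 0.1, b = 0)  # 1/(25 + 100) = 0.008
weights <- function(fo2, sig, fc2, a = 0, b = 0) {
  stopifnot(a >= 0, b >= 0, all(sig > 0))
  P <- (pmax(fo2, 0) + 2 * fc2) / 3
  1 / (sig^2 + (a * P)^2 + b * P)
}

#' Agreement residuals R1, wR2 and goodness of fit
#'
#' `R1 = sum ||Fo| - |Fc|| / sum |Fo|` over reflections meeting the
#' observed criterion (default `I > 2 sigma`; negative intensities enter
#' with `|Fo| = 0`); `wR2 = sqrt(sum w (Fo2-Fc2)^2 / sum w Fo2^2)` over
#' all reflections; `S = sqrt(sum w (Fo2-Fc2)^2 / (n - p))`.
#'
#' @param refl Reflection set with `fc2`.
#' @param a,b Weighting parameters.
#' @param n_params Number of refined parameters `p`.
#' @param obs_sigma_mult Observed criterion multiple (default 2:
#'   `I > 2 sigma(I)`).
#' @return List with `r1`, `wr2`, `goof`, `n`, `n_obs`; `r1` is `NA` when
#'   no reflection meets the criterion.
#' @export
r_factors <- function(refl, a = 0, b = 0, n_params = 1L, obs_sigma_mult = 2) {
  df <- as.data.frame(refl)
  if (is.null(df$fc2)) stop_ciflint("Fc2 required for R factors", "ciflint_refl_error")
  w <- weights(df$fo2, df$sig, df$fc2, a, b)
  num <- sum(w * (df$fo2 - df$fc2)^2)
  wr2 <- sqrt(num / sum(w * df$fo2^2))
  n <- nrow(df)
  goof <- if (n > n_params) sqrt(num / (n - n_params)) else NA_real_
  obs <- df$fo2 > obs_sigma_mult * df$sig
  r1 <- if (any(obs)) {
    fo <- sqrt(pmax(df$fo2[obs], 0)); fc <- sqrt(pmax(df$fc2[obs], 0))
    sum(abs(fo - fc)) / sum(fo)
  } else NA_real_
  list(r1 = r1, wr2 = wr2, goof = goof, n = n, n_obs = sum(obs))
}

#' Analysis of variance of the fit
#'
#' Bins the data by resolution (equal-population bins) and by
#' `Fc/Fc(max)` (fixed fractional edges) and reports per bin the count,
#' the scale factor `K = <Fo2>/<Fc2>`, the goodness of fit and the
#' observed fraction.  Bins with `K` outside `[0.8, 1.2]` or bin GooF
#' above 2 are flagged.
#'
#' @param refl Reflection set with `fc2` and a cell.
#' @param a,b Weighting parameters.
#' @param nbins Number of resolution bins (default 10).
#' @return List with `by_resolution`, `by_fc` (data.frames) and
#'   `findings`.
#' @export
analysis_of_variance <- function(refl, a = 0, b = 0, nbins = 10L) {
  df <- as.data.frame(refl)
  if (is.null(df$fc2)) stop_ciflint("Fc2 required", "ciflint_refl_error")
  w <- weights(df$fo2, df$sig, df$fc2, a, b)
  mk_table <- function(bin, label) {
    n <- as.integer(table(bin))
    safe <- function(v) ifelse(n > 0, v, NA_real_)
    ssum <- function(x) as.numeric(tapply(x, bin, sum, default = 0))
    K <- safe(ssum(df$fo2) / pmax(ssum(df$fc2), 1e-300))
    goof <- safe(sqrt(ssum(w * (df$fo2 - df$fc2)^2) / pmax(n, 1L)))
    obs <- safe(ssum(df$fo2 > 2 * df$sig) / pmax(n, 1L))
    data.frame(bin = levels(bin), n = n, K = K, goof = goof,
               observed_frac = obs, axis = label, stringsAsFactors = FALSE)
  }
  nb <- min(nbins, nrow(df))
  s <- refl_s(refl)
  qs <- unique(stats::quantile(s, probs = seq(0, 1, length.out = nb + 1L)))
  bres <- cut(s, qs, include.lowest = TRUE)
  tab_s <- mk_table(bres, "resolution")
  fcr <- sqrt(pmax(df$fc2, 0)); fcr <- fcr / max(fcr)
  edges <- c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0)
  bfc <- cut(fcr, edges, include.lowest = TRUE)
  tab_f <- mk_table(bfc, "fc_over_fcmax")
  both <- rbind(tab_s, tab_f)
  bad <- both[!is.na(both$K) & (both$K < 0.8 | both$K > 1.2 | both$goof > 2), ]
  findings <- if (nrow(bad)) {
    do.call(rbind, lapply(seq_len(nrow(bad)), function(i)
      finding("VAR_BIN_DEVIATES",
              sprintf("%s bin %s: K = %.3f, bin GooF = %.2f", bad$axis[i],
                      bad$bin[i], bad$K[i], bad$goof[i]), bad$K[i])))
  } else finding("", "")[0, ]
  list(by_resolution = tab_s, by_fc = tab_f, findings = findings)
}

#' Normal-probability statistics of weighted residuals
#'
#' Orders `delta = (Fo2 - Fc2) * sqrt(w)` against expected normal order
#' statistics, fits a least-squares line through the central 80% and
#' reports its slope and intercept plus the maximum deviation of the
#' empirical curve from the line in that central region (an S-shape
#' metric; large values indicate heavy tails/outliers).
#'
#' @param refl Reflection set with `fc2`.
#' @param a,b Weighting parameters.
#' @return List with `slope`, `intercept`, `max_central_dev`,
#'   `degenerate`.
#' @export
normal_probability <- function(refl, a = 0, b = 0) {
  df <- as.data.frame(refl)
  if (is.null(df$fc2)) stop_ciflint("Fc2 required", "ciflint_refl_error")
  n <- nrow(df)
  if (n < 10L) stop_ciflint("need at least 10 reflections", "ciflint_refl_error")
  delta <- sort((df$fo2 - df$fc2) * sqrt(weights(df$fo2, df$sig, df$fc2, a, b)))
  expq <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  central <- seq.int(ceiling(0.1 * n) + 1L, floor(0.9 * n))
  if (stats::sd(delta) < 1e-12)
    return(list(slope = 0, intercept = mean(delta), max_central_dev = 0,
                degenerate = TRUE))
  fit <- stats::lm.fit(cbind(1, expq[central]), delta[central])
  pred <- fit$coefficients[1] + fit$coefficients[2] * expq[central]
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       max_central_dev = max(abs(delta[central] - pred)),
       degenerate = FALSE)
}

#' Absolute-structure estimate from Bijvoet quotients
#'
#' Parsons-style quotient fit: observed quotients
#' `q_o = (I+ - I-)/(I+ + I-)` are regressed on the calculated quotients
#' of the untwinned (`x = 0`) model via `q_o = (1 - 2x) q_c`, weighted by
#' the propagated variance of `q_o`.  An estimate above 0.5 means the
#' model should be inverted.
#'
#' @param refl Reflection set with `fc2`, unmerged or merged without
#'   Friedel folding.
#' @param setting `ciflint_spacegroup`.
#' @param min_qc Pairs with `|q_c|` below this are dropped (default 1e-4).
#' @return List with `x`, `su`, `n_pairs`, `decision` (one of `"retain"`,
#'   `"invert"`, `"indeterminate"`, `"not estimable"`).
#' @export
absolute_structure_estimate <- function(refl, setting, min_qc = 1e-4) {
  df <- as.data.frame(refl)
  if (is.null(df$fc2)) stop_ciflint("Fc2 required", "ciflint_refl_error")
  not_est <- list(x = NA_real_, su = NA_real_, n_pairs = 0L, decision = "not estimable")
  if (setting$centrosymmetric) return(not_est)
  rots <- proper_rotations(setting)
  keys <- .canon_keys(as.matrix(df[, c("h", "k", "l")]), rots)
  keys_inv <- .canon_keys(-as.matrix(df[, c("h", "k", "l")]), rots)
  w <- 1 / df$sig^2
  agg <- function(v, k) tapply(v, k, sum)
  sw <- agg(w, keys)
  Ip <- agg(w * df$fo2, keys) / sw
  sIp <- sqrt(1 / sw)
  Icp <- agg(w * df$fc2, keys) / sw
  ukeys <- names(sw)
  mate <- match(vapply(ukeys, function(k) keys_inv[match(k, keys)], character(1)), ukeys)
  ## each Bijvoet pair once: keep i < mate[i]
  sel <- which(!is.na(mate) & seq_along(ukeys) < mate)
  if (!length(sel)) return(not_est)
  A <- Ip[sel]; B <- Ip[mate[sel]]
  sA <- sIp[sel]; sB <- sIp[mate[sel]]
  Ac <- Icp[sel]; Bc <- Icp[mate[sel]]
  qo <- (A - B) / (A + B)
  sq <- sqrt((2 * B * sA)^2 + (2 * A * sB)^2) / (A + B)^2
  qc <- (Ac - Bc) / (Ac + Bc)
  keep <- is.finite(qo) & is.finite(qc) & is.finite(sq) & sq > 0 & abs(qc) >= min_qc
  if (sum(keep) < 2L) return(not_est)
  qo <- qo[keep]; qc <- qc[keep]; wq <- 1 / sq[keep]^2
  m <- sum(wq * qc * qo) / sum(wq * qc^2)
  su_m <- 1 / sqrt(sum(wq * qc^2))
  x <- (1 - m) / 2
  su <- su_m / 2
  decision <- if (abs(x - 0.5) < 2 * su) "indeterminate"
              else if (x > 0.5) "invert" else "retain"
  list(x = unname(x), su = unname(su), n_pairs = sum(keep), decision = decision)
}

#' Screen for fabricated reflection data
#'
#' Real counting-statistics uncertainties scatter about any smooth
#' function of the intensity; fabricated sigmas are often an exact smooth
#' function of `I`.  Fits `sigma^2 = c0 + c1*I + c2*I^2` on positive-I
#' reflections and calls the set suspicious when the fit is implausibly
#' perfect (R^2 > 0.9999 and relative residuals below 0.1%).  The verdict
#' is a screening signal, never proof.
#'
#' @param refl Reflection set (needs at least 50 reflections).
#' @return List with `verdict` (`"suspicious"`, `"ok"`, `"not assessed"`),
#'   `r_squared`, `rel_resid`, and `plot_data` (columns `inv_sigma`,
#'   `log10_i`).
#' @export
fabrication_screen <- function(refl) {
  df <- as.data.frame(refl)
  pos <- df$fo2 > 0
  if (nrow(df) < 50L)
    return(list(verdict = "not assessed", r_squared = NA_real_,
                rel_resid = NA_real_, plot_data = NULL))
  x <- df$fo2[pos]; y <- df$sig[pos]^2
  X <- cbind(1, x, x^2)
  fit <- stats::lm.fit(X, y)
  resid <- fit$residuals
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  rel <- sqrt(mean(resid^2)) / sqrt(mean(y^2))
  verdict <- if (is.finite(r2) && r2 > 0.9999 && rel < 1e-3) "suspicious" else "ok"
  list(verdict = verdict, r_squared = r2, rel_resid = rel,
       plot_data = data.frame(inv_sigma = 1 / df$sig[pos],
                              log10_i = log10(df$fo2[pos])))
}
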