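## Synthetic structures and reflection data.
##
## The generator builds internally consistent crystal structures (random
## connected molecules packed so that symmetry images keep van der Waals
## separation), computes exact spherical-atom structure factors, adds a
## declared noise model, and can inject deliberate corruptions so that
## every validation check has a positive and a negative control.  All
## outputs are reproducible from the seed.

.default_noise <- list(sigma0 = 1.0, k = 0.02)

## random unit vector
.runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

## Build a connected molecule in Cartesian coordinates: a jittered
## tetrahedral-angle random walk with clash rejection.
.build_molecule <- function(n_atoms, bond = 1.54, min_nonbond = 2.3, max_try = 400L) {
  xyz <- matrix(0, 3, n_atoms)
  parent <- integer(n_atoms)
  for (j in 2:n_atoms) {
    ok <- FALSE
    for (it in seq_len(max_try)) {
      p <- if (j == 2) 1L else sample(j - 1L, 1L)
      cand <- xyz[, p] + bond * .runit()
      d <- sqrt(colSums((xyz[, seq_len(j - 1L), drop = FALSE] - cand)^2))
      d[p] <- Inf
      if (all(d >= min_nonbond)) { xyz[, j] <- cand; parent[j] <- p; ok <- TRUE; break }
    }
    if (!ok) stop_ciflint("molecule packing failed", "ciflint_fixture_error")
  }
  list(xyz = xyz, parent = parent)
}

## smallest separation margin between the molecule and its symmetry images:
## min over pairs of (distance - vdw_i - vdw_j)
.image_margin <- function(frac, vdw, setting, cellv) {
  n <- ncol(frac)
  worst <- Inf
  for (oi in seq_along(setting$ops)) {
    op <- setting$ops[[oi]]
    img <- op_apply(op, frac)
    ident <- oi == 1L && all(op$t == 0L)
    for (j in seq_len(n)) {
      dx <- img - frac[, j]
      for (shift in seq_len(27L)) {
        sh <- c(shift - 1L) %% 3L - 1L
        sh <- c(sh, ((shift - 1L) %/% 3L) %% 3L - 1L, ((shift - 1L) %/% 9L) - 1L)
        if (ident && all(sh == 0L)) next
        d <- sqrt(colSums((cellv$M %*% (dx + sh))^2)) - vdw - vdw[j]
        if (ident) d[j] <- Inf
        worst <- min(worst, d)
      }
    }
  }
  worst
}

#' Generate a synthetic crystal structure
#'
#' Places a random connected molecule in the asymmetric unit of the
#' requested space group and scales the cell so symmetry-related images
#' keep at least `margin` beyond van der Waals contact; the result is a
#' fully consistent model (formula, Z, density all derivable).
#'
#' @param n_atoms Number of non-hydrogen atoms.
#' @param elements Element pool for the non-H atoms (recycled).
#' @param n_h Number of hydrogen atoms, attached to distinct carbons.
#' @param hall Space-group Hall symbol.
#' @param seed Integer seed; same spec yields identical output.
#' @param margin Minimum image separation relative to the van der Waals
#'   sum (Angstrom; the default -0.1 packs slightly inside it, as real
#'   crystals do, while staying above the short-contact threshold).
#' @param fill_voids Place solvent-like oxygen atoms in residual
#'   solvent-accessible voids so the packing has none above the
#'   reporting threshold (default TRUE).
#' @param angles Optional cell angles overriding the per-system defaults
#'   (e.g. `c(90, 90.3, 90)` for a pseudo-orthogonal monoclinic cell).
#' @param wavelength Radiation wavelength (default Mo K-alpha).
#' @return `ciflint_model` with an additional `bonds` attribute.
#' @export
#' @examples
#' m <- generate_structure(n_atoms = 6, seed = 7)
#' nrow(m$sites)
generate_structure <- function(n_atoms = 8L, elements = "C", n_h = 2L,
                               hall = "-P 2ybc", seed = 1L, margin = -0.1,
                               fill_voids = TRUE, angles = NULL,
                               wavelength = 0.71073) {
  setting <- spacegroup_setting(hall = hall)
  with_seed(seed, {
    mol <- .build_molecule(n_atoms)
    elems <- rep_len(elements, n_atoms)
    ## hydrogens on distinct parents (element C), roughly tetrahedral
    hxyz <- NULL; hparent <- integer(0)
    if (n_h > 0L) {
      carriers <- which(elems == "C")
      carriers <- utils::head(carriers, n_h)
      for (p in carriers) {
        for (it in 1:500) {
          cand <- mol$xyz[, p] + 0.95 * .runit()
          d <- sqrt(colSums((mol$xyz - cand)^2)); d[p] <- Inf
          dh <- if (is.null(hxyz)) Inf else sqrt(colSums((hxyz - cand)^2))
          if (all(d >= 1.6) && all(dh >= 1.5)) {
            hxyz <- cbind(hxyz, cand); hparent <- c(hparent, p); break
          }
        }
      }
    }
    all_xyz <- cbind(mol$xyz, hxyz)
    n_hh <- length(hparent)
    elems_all <- c(elems, rep("H", n_hh))
    vdw <- vapply(elems_all, function(e) element_row(e)$r_vdw, numeric(1))
    ## base cell shape for the crystal system of the group
    cs <- setting$crystal_system
    ratios <- switch(cs,
      triclinic = c(1, 1.1, 0.95), monoclinic = c(1, 1.15, 0.9),
      orthorhombic = c(1, 1.2, 0.85), c(1, 1, 1))
    if (is.null(angles))
      angles <- switch(cs,
        triclinic = c(84, 98, 94), monoclinic = c(90, 103, 90),
        trigonal = , hexagonal = c(90, 90, 120), c(90, 90, 90))
    if (cs %in% c("tetragonal")) ratios <- c(1, 1, 0.8)
    span <- apply(all_xyz, 1, function(r) diff(range(r)))
    base <- max(4, max(span))
    scale_seq <- seq(0.8, 4.0, by = 0.05)
    ## a batch of candidate molecular orientations and placements; the
    ## first (orientation, placement) that fits at the smallest feasible
    ## cell gives a reasonably dense packing
    n_trials <- 16L
    rots <- lapply(seq_len(n_trials), function(i)
      qr.Q(qr(matrix(stats::rnorm(9), 3, 3))))
    ctrs <- lapply(seq_len(n_trials), function(i) stats::runif(3, 0.1, 0.4))
    centred <- all_xyz - rowMeans(all_xyz)
    ## find any feasible placement, then shrink the cell axis by axis while
    ## the image-separation margin holds: a simple but effective packer
    best <- NULL
    for (sc in scale_seq) {
      for (tr in seq_len(n_trials)) {
        edges <- base * sc * ratios
        cl0 <- cell(edges[1], edges[2], edges[3], angles[1], angles[2], angles[3])
        cart <- rots[[tr]] %*% centred
        frac0 <- cl0$Minv %*% cart + ctrs[[tr]]
        if (.image_margin(frac0, vdw, setting, cl0) < margin) next
        repeat {
          improved <- FALSE
          for (ax in 1:3) {
            if (cs %in% c("tetragonal", "trigonal", "hexagonal") && ax == 2L) next
            if (cs == "cubic" && ax >= 2L) next
            e2 <- edges
            e2[ax] <- e2[ax] * 0.98
            if (cs %in% c("tetragonal", "trigonal", "hexagonal") && ax == 1L)
              e2[2] <- e2[1]
            if (cs == "cubic") e2[] <- e2[1]
            cl2 <- cell(e2[1], e2[2], e2[3], angles[1], angles[2], angles[3])
            fr2 <- cl2$Minv %*% cart + ctrs[[tr]]
            if (.image_margin(fr2, vdw, setting, cl2) >= margin) {
              edges <- e2; improved <- TRUE
            }
          }
          if (!improved) break
        }
        cl1 <- cell(edges[1], edges[2], edges[3], angles[1], angles[2], angles[3])
        if (is.null(best) || cl1$volume < best$cl$volume)
          best <- list(cl = cl1, frac = cl1$Minv %*% cart + ctrs[[tr]])
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) {
      cl <- best$cl; frac <- best$frac
      {
        labels <- c(sprintf("%s%d", elems, seq_len(n_atoms)),
                    if (n_hh) sprintf("H%d", seq_len(n_hh)))
        sites <- data.frame(label = labels, element = elems_all,
                            x = frac[1, ], y = frac[2, ], z = frac[3, ],
                            occ = 1.0,
                            uiso = c(stats::runif(n_atoms, 0.030, 0.045),
                                     rep(0.06, n_hh)),
                            is_h = elems_all == "H",
                            disordered = FALSE,
                            calculated = elems_all == "H",
                            stringsAsFactors = FALSE)
        model <- structure_model(cl, setting, sites, wavelength)
        attr(model, "bonds") <- cbind(
          c(2:n_atoms, if (n_hh) n_atoms + seq_len(n_hh)),
          c(mol$parent[-1L], hparent))
      }
    }
    if (is.null(model))
      stop_ciflint("could not pack molecule without image clashes", "ciflint_fixture_error")
    if (fill_voids) model <- .fill_voids(model)
    model
  })
}

## Place solvent-like oxygen atoms at the deepest points of residual
## solvent-accessible voids (as a real crystal would host solvent) until
## no region reaches the reporting threshold.
.fill_voids <- function(model, max_fill = 8L) {
  nw <- 0L
  for (round in seq_len(max_fill)) {
    vd <- find_voids(model, min_volume = 15)
    if (!length(vd$regions)) break
    placed <- FALSE
    sdfm <- model$sites
    frac_all <- t(as.matrix(sdfm[, c("x", "y", "z")]))
    vdw_all <- vapply(sdfm$element, function(e) element_row(e)$r_vdw, numeric(1))
    r_o <- element_row("O")$r_vdw
    for (reg in vd$regions) {
      vox <- arrayInd(reg$voxels, vd$dims)
      fr <- t(sweep(vox - 1, 2, vd$dims, `/`))
      ## voxel score: worst margin against all symmetry images of existing
      ## atoms and against the filler's own images
      depth <- rep(Inf, ncol(fr))
      for (oi in seq_along(model$setting$ops)) {
        op <- model$setting$ops[[oi]]
        img <- op_apply(op, frac_all)
        for (j in seq_len(ncol(img))) {
          dx <- fr - as.numeric(img[, j])
          depth <- pmin(depth, frac_dist_mi(model$cell, dx) - vdw_all[j] - r_o)
        }
        if (oi > 1L) {
          dself <- frac_dist_mi(model$cell, op_apply(op, fr) - fr)
          depth <- pmin(depth, dself - 2 * r_o)
        }
      }
      cand_i <- which.max(depth)
      if (depth[cand_i] >= -0.15) {
        pos <- fr[, cand_i]
        nw <- nw + 1L
        model$sites <- rbind(model$sites, data.frame(
          label = sprintf("O%dW", nw), element = "O",
          x = pos[1], y = pos[2], z = pos[3], occ = 1.0, uiso = 0.08,
          is_h = FALSE, disordered = FALSE, calculated = FALSE,
          stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  model
}

## ---- corrupted variants of a model ----------------------------------------

corrupt_model <- function(model, corruption, seed = 1L) {
  m <- model
  with_seed(seed + 17L, switch(corruption,
    wrong_atom_type = {
      j <- which(m$sites$element == "C")[2] %||% 1L
      m$sites$element[j] <- "N"
      m
    },
    misplace_h = {
      j <- which(m$sites$is_h)[1]
      if (is.na(j)) stop_ciflint("no H to misplace", "ciflint_fixture_error")
      shift <- m$cell$Minv %*% (0.9 * .runit())
      m$sites[j, c("x", "y", "z")] <- m$sites[j, c("x", "y", "z")] + as.numeric(shift)
      m
    },
    strip_inversion = {
      if (!m$setting$centrosymmetric)
        stop_ciflint("strip_inversion needs a centrosymmetric group", "ciflint_fixture_error")
      ## halve the group (drop improper ops), double the asymmetric unit
      keep <- vapply(m$setting$ops, function(o) round(det(o$R)) > 0, logical(1))
      sub <- spacegroup_setting(ops = m$setting$ops[keep])
      sub$hall <- .match_group_in_table(sub$ops)
      inv <- m$sites
      inv$label <- paste0(inv$label, "i")
      inv[, c("x", "y", "z")] <- -inv[, c("x", "y", "z")]
      ## translate the inverted copy so its centroid lies inside the cell
      shift <- -floor(colMeans(inv[!inv$is_h, c("x", "y", "z")]))
      inv[, c("x", "y", "z")] <- sweep(inv[, c("x", "y", "z")], 2, shift, `+`)
      m2 <- structure_model(m$cell, sub, rbind(m$sites, inv), m$wavelength)
      attr(m2, "bonds") <- attr(m, "bonds")
      m2
    },
    invert_structure = {
      m$sites[, c("x", "y", "z")] <- -m$sites[, c("x", "y", "z")]
      m
    },
    m))
}

## twin law: two-fold about the direct a axis, expressed on indices
.twin_law_a <- function(cellv) {
  G <- cellv$G
  v <- c(1, 0, 0)
  R <- 2 * outer(v, as.numeric(G %*% v)) / as.numeric(v %*% G %*% v) - diag(3)
  R  # acts on fractional coords; index action is h' = h %*% R
}

#' Generate a reflection dataset from a structure model
#'
#' Computes exact structure factors over the full sphere to `s_max`,
#' applies the declared noise model (`sigma^2 = sigma0^2 + k*I`, Gaussian
#' perturbation of the intensities, lognormal estimation scatter on the
#' reported sigmas) and optionally a corruption, then returns both the
#' unmerged sphere (natural Laue redundancy) and the merged unique set
#' with calculated intensities and phases from the reported model.
#'
#' @param model True structure (`ciflint_model`).
#' @param s_max Resolution limit in 1/Angstrom (default 0.65, the
#'   copper-sphere limit).
#' @param noise List with `sigma0` and `k`; `NULL` for noise-free data.
#' @param corruption One of "none", "twin", "invert_structure",
#'   "fabricate_sigmas", "inflate_low_order" (model-level corruptions are
#'   applied via [corrupt_model()] before calling this).
#' @param alpha Twin fraction for `corruption = "twin"`.
#' @param model_reported Model used for the calculated intensities and
#'   phases (defaults to `model`; pass a corrupted variant to emulate a
#'   wrong reported model).
#' @param seed Integer seed.
#' @return List with `unmerged`, `merged`, `rint`, `twin_law` (when
#'   twinned).
#' @export
make_dataset <- function(model, s_max = 0.65, noise = .default_noise,
                         corruption = "none", alpha = 0.3,
                         model_reported = model, seed = 1L) {
  cellv <- model$cell
  hkl <- hkl_sphere(cellv, s_max)
  ext <- is_extinct(hkl, model$setting)
  hkl <- hkl[!ext, , drop = FALSE]
  Ftrue <- structure_factors(model, hkl)
  Itrue <- Mod(Ftrue)^2
  law <- NULL
  if (corruption == "twin") {
    law <- .twin_law_a(cellv)
    hrot <- round(hkl %*% law)
    Irot <- Mod(structure_factors(model, hrot))^2
    Itrue <- (1 - alpha) * Itrue + alpha * Irot
  } else if (corruption == "invert_structure") {
    Itrue <- Mod(structure_factors(model, -hkl))^2
  } else if (corruption == "inversion_twin") {
    ## racemic twin with minority fraction alpha (the Flack-style x)
    Itrue <- (1 - alpha) * Itrue + alpha * Mod(structure_factors(model, -hkl))^2
  }
  with_seed(seed, {
    if (is.null(noise)) {
      fo2 <- Itrue
      sig <- pmax(sqrt(pmax(1e-8, 1e-6 * Itrue)), 1e-6)
    } else {
      sig_true <- sqrt(noise$sigma0^2 + noise$k * Itrue)
      fo2 <- Itrue + stats::rnorm(length(Itrue), 0, sig_true)
      sig <- sig_true * exp(stats::rnorm(length(Itrue), 0, 0.15))
    }
    if (corruption == "fabricate_sigmas") sig <- 1 + 0.02 * pmax(fo2, 0)
    if (corruption == "inflate_low_order") {
      s <- s_of_hkl(cellv, hkl)
      low <- s <= stats::quantile(s, 0.1)
      fo2[low] <- 2 * fo2[low]
    }
    Frep <- structure_factors(model_reported, hkl)
    unmerged <- reflection_set(hkl[, 1], hkl[, 2], hkl[, 3], fo2, sig,
                               fc2 = Mod(Frep)^2,
                               merged = FALSE, wavelength = model$wavelength,
                               cell = cellv)
    mg <- merge_equivalents(unmerged, model_reported$setting)
    merged <- mg$merged
    ## phases of the reported model on the merged unique set
    mh <- as.matrix(as.data.frame(merged)[, c("h", "k", "l")])
    Fm <- structure_factors(model_reported, mh)
    merged$fc2 <- Mod(Fm)^2
    merged$phase <- Arg(Fm) * 180 / pi
    list(unmerged = unmerged, merged = merged, rint = mg$rint, twin_law = law)
  })
}

## ---- CIF assembly ----------------------------------------------------------

formula_of_model <- function(model) {
  ## counts per asymmetric unit; Z = nsym (general-position molecule)
  cnt <- table(model$sites$element)
  ord <- c(intersect(c("C", "H"), names(cnt)), sort(setdiff(names(cnt), c("C", "H"))))
  paste(sprintf("%s%g", ord, as.numeric(cnt[ord])), collapse = " ")
}

#' Render a structure model (plus optional statistics) as CIF text
#'
#' The emitted CIF is mutually consistent by construction: cell, symmetry
#' (Hermann-Mauguin + Hall + operator loop), atom sites, formula, Z,
#' molecular weight and density all derive from the model.  When a
#' dataset is supplied its recomputed statistics (R factors, residual
#' density extrema, reflection counts) are written as the reported
#' values, and the reflection data and a refinement-instruction summary
#' are embedded as checksummed payloads.
#'
#' @param model `ciflint_model`.
#' @param dataset Optional result of [make_dataset()].
#' @param weighting `c(a, b)` weighting parameters reported and used.
#' @param embed Embed HKL/RES payloads with checksums (default TRUE when
#'   a dataset is given).
#' @param edit_embedded Corrupt the embedded RES payload after computing
#'   its checksum (fixture for checksum-failure alerts).
#' @param block_name CIF data-block name.
#' @return CIF text (single string).
#' @export
model_to_cif <- function(model, dataset = NULL, weighting = c(0, 0),
                         embed = !is.null(dataset), edit_embedded = FALSE,
                         block_name = "I") {
  cl <- model$cell
  st <- model$setting
  items <- list()
  it <- function(tag, val) items[[tag]] <<- as.character(val)
  fmt <- function(x, d = 4) sprintf(paste0("%.", d, "f"), x)
  it("_cell_length_a", paste0(fmt(cl$a), "(2)"))
  it("_cell_length_b", paste0(fmt(cl$b), "(2)"))
  it("_cell_length_c", paste0(fmt(cl$c), "(2)"))
  it("_cell_angle_alpha", paste0(fmt(cl$alpha), "(2)"))
  it("_cell_angle_beta", paste0(fmt(cl$beta), "(2)"))
  it("_cell_angle_gamma", paste0(fmt(cl$gamma), "(2)"))
  it("_cell_volume", fmt(cl$volume, 2))
  Z <- st$nsym
  it("_cell_formula_units_Z", Z)
  ## space-group symbols: take HM from the bundled table when known
  tab <- sg_table()
  hit <- tab[norm_hall(tab$hall) == norm_hall(st$hall %||% ""), ]
  if (nrow(hit)) it("_space_group_name_H-M_alt", hit$hm_full[1])
  if (!is.null(st$hall)) it("_space_group_name_Hall", st$hall)
  it("_chemical_formula_sum", formula_of_model(model))
  mr <- molecular_weight(parse_formula(formula_of_model(model)))
  it("_chemical_formula_weight", fmt(mr, 2))
  it("_exptl_crystal_density_diffrn", fmt(Z * mr * 1.66054 / cl$volume, 3))
  it("_diffrn_radiation_wavelength", fmt(model$wavelength, 5))
  it("_exptl_crystal_size_max", "0.40")
  it("_exptl_crystal_size_mid", "0.25")
  it("_exptl_crystal_size_min", "0.10")
  mu <- absorption_mu(parse_formula(formula_of_model(model)), Z, cl$volume,
                      model$wavelength)
  it("_exptl_absorpt_coefficient_mu", fmt(mu, 3))
  it("_exptl_absorpt_correction_T_min", fmt(exp(-mu * 0.40), 3))
  it("_exptl_absorpt_correction_T_max", fmt(exp(-mu * 0.10), 3))
  loops <- list()
  loops[[1]] <- list(
    tags = "_space_group_symop_operation_xyz",
    rows = matrix(vapply(st$ops, op_triplet, character(1)), ncol = 1,
                  dimnames = list(NULL, "_space_group_symop_operation_xyz")))
  sdf <- model$sites
  n_par <- 1L + 4L * nrow(sdf)
  loops[[2]] <- list(
    tags = c("_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             "_atom_site_u_iso_or_equiv", "_atom_site_occupancy",
             "_atom_site_site_symmetry_order", "_atom_site_calc_flag",
             "_atom_site_disorder_group"),
    rows = {
      sso <- vapply(seq_len(nrow(sdf)), function(j)
        site_symmetry(as.numeric(sdf[j, c("x", "y", "z")]), st, cl)$sso, numeric(1))
      m <- cbind(sdf$label, sdf$element,
                 sprintf("%.5f(5)", sdf$x), sprintf("%.5f(5)", sdf$y),
                 sprintf("%.5f(5)", sdf$z),
                 sprintf("%.4f(10)", sdf$uiso), sprintf("%.3f", sdf$occ),
                 sprintf("%d", as.integer(sso)),
                 ifelse(sdf$calculated, "calc", "."),
                 ifelse(sdf$disordered, "1", "."))
      colnames(m) <- c("_atom_site_label", "_atom_site_type_symbol",
                       "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
                       "_atom_site_u_iso_or_equiv", "_atom_site_occupancy",
                       "_atom_site_site_symmetry_order", "_atom_site_calc_flag",
                       "_atom_site_disorder_group")
      m
    })
  ## per-element resonant corrections, as refinement programs archive them
  els <- unique(sdf$element)
  loops[[3]] <- list(
    tags = c("_atom_type_symbol", "_atom_type_scat_dispersion_real",
             "_atom_type_scat_dispersion_imag"),
    rows = {
      m <- do.call(rbind, lapply(els, function(e) {
        fp <- fprime_element(e, model$wavelength)
        c(e, sprintf("%.4f", fp["fp"]), sprintf("%.4f", fp["fpp"]))
      }))
      colnames(m) <- c("_atom_type_symbol", "_atom_type_scat_dispersion_real",
                       "_atom_type_scat_dispersion_imag")
      m
    })
  if (!is.null(dataset)) {
    mg <- dataset$merged
    rf <- r_factors(mg, a = weighting[1], b = weighting[2], n_params = n_par)
    it("_refine_ls_number_reflns", rf$n)
    it("_refine_ls_number_parameters", n_par)
    it("_reflns_number_total", rf$n)
    it("_reflns_number_gt", rf$n_obs)
    it("_reflns_threshold_expression", "I > 2\\s(I)")
    it("_refine_ls_r_factor_gt", fmt(rf$r1, 4))
    it("_refine_ls_wr_factor_ref", fmt(rf$wr2, 4))
    it("_refine_ls_goodness_of_fit_ref", fmt(rf$goof, 3))
    it("_refine_ls_weighting_details",
       sprintf("w=1/[\\s^2^(Fo^2^)+(%.4fP)^2^+%.4fP] where P=(Fo^2^+2Fc^2^)/3",
               weighting[1], weighting[2]))
    dm <- difference_map(mg, grid_step = 0.25)
    it("_refine_diff_density_max", fmt(max(dm$values), 3))
    it("_refine_diff_density_min", fmt(min(dm$values), 3))
    s <- refl_s(mg)
    th <- resolution_measures(range(s), model$wavelength)$theta
    it("_diffrn_reflns_theta_min", fmt(th[1], 2))
    it("_diffrn_reflns_theta_max", fmt(th[2], 2))
    if (embed) {
      hkl_text <- write_reflections(dataset$unmerged, "hklf4")
      res_text <- .shelx_style_res(model, n_par)
      it("_shelx_res_file", res_text)
      it("_shelx_res_checksum", ciflint_checksum(res_text))
      if (edit_embedded) {
        res2 <- sub("TITL", "TITl", items[["_shelx_res_file"]])
        items[["_shelx_res_file"]] <- res2
      }
      it("_shelx_hkl_file", hkl_text)
      it("_shelx_hkl_checksum", ciflint_checksum(hkl_text))
    }
  }
  doc <- structure(list(blocks = list(list(name = block_name, items = items,
                                           loops = loops))),
                   class = "ciflint_cif")
  write_cif(doc)
}

## minimal SHELX-flavoured instruction summary for embedding
.shelx_style_res <- function(model, n_par) {
  cl <- model$cell
  els <- unique(model$sites$element)
  paste0(
    "TITL synthetic structure (ciflint fixture)\n",
    sprintf("CELL %.5f %.4f %.4f %.4f %.4f %.4f %.4f\n", model$wavelength,
            cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma),
    sprintf("ZERR %d 0.0002 0.0002 0.0002 0.002 0.002 0.002\n", model$setting$nsym),
    sprintf("SFAC %s\n", paste(els, collapse = " ")),
    paste(sprintf("%-5s %d %9.5f %9.5f %9.5f %7.3f %8.4f",
                  model$sites$label, match(model$sites$element, els),
                  model$sites$x, model$sites$y, model$sites$z,
                  10 + model$sites$occ, model$sites$uiso), collapse = "\n"),
    "\nHKLF 4\nEND\n")
}
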