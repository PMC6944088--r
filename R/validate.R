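## Orchestration: run every check over a CIF (+ optional FCF) and build
## the levelled alert report.

.blk_item <- function(b, ...) {
  for (tag in c(...)) if (!is.null(b$items[[tag]])) return(b$items[[tag]])
  NULL
}

.blk_loop <- function(b, tag) {
  for (lp in b$loops) if (tag %in% lp$tags) return(lp)
  NULL
}

.cell_from_block <- function(b) {
  gv <- function(tag) block_num(b, tag)
  vals <- lapply(c(a = "_cell_length_a", b = "_cell_length_b", c = "_cell_length_c",
                   alpha = "_cell_angle_alpha", beta = "_cell_angle_beta",
                   gamma = "_cell_angle_gamma"), gv)
  if (any(!vapply(vals, function(v) is.finite(v$value), logical(1)))) return(NULL)
  cell(vals$a$value, vals$b$value, vals$c$value,
       vals$alpha$value, vals$beta$value, vals$gamma$value,
       su = lapply(vals, `[[`, "su"))
}

.symmetry_from_block <- function(b) {
  hall <- .blk_item(b, "_space_group_name_hall", "_symmetry_space_group_name_hall")
  hm <- .blk_item(b, "_space_group_name_h-m_alt", "_symmetry_space_group_name_h-m")
  lp <- .blk_loop(b, "_space_group_symop_operation_xyz") %||%
        .blk_loop(b, "_symmetry_equiv_pos_as_xyz")
  ops <- if (!is.null(lp))
    as.character(lp$rows[, intersect(c("_space_group_symop_operation_xyz",
                                       "_symmetry_equiv_pos_as_xyz"), lp$tags)[1]])
  else NULL
  list(hall = hall, hm = hm, ops = ops)
}

.sites_from_block <- function(b) {
  lp <- .blk_loop(b, "_atom_site_label")
  if (is.null(lp)) return(NULL)
  col <- function(tag, default = NA) {
    if (tag %in% lp$tags) lp$rows[, tag] else rep(default, nrow(lp$rows))
  }
  numc <- function(tag, default = NA) {
    v <- col(tag, default)
    vapply(v, function(x) tryCatch(parse_uncertain(x)$value,
                                   error = function(e) NA_real_), numeric(1))
  }
  el <- col("_atom_site_type_symbol")
  lab <- col("_atom_site_label")
  if (all(is.na(el))) el <- sub("[0-9'].*$", "", lab)
  data.frame(label = lab, element = unname(el),
             x = numc("_atom_site_fract_x"), y = numc("_atom_site_fract_y"),
             z = numc("_atom_site_fract_z"),
             occ = ifelse(is.na(numc("_atom_site_occupancy")), 1,
                          numc("_atom_site_occupancy")),
             uiso = ifelse(is.na(numc("_atom_site_u_iso_or_equiv")), 0.05,
                           numc("_atom_site_u_iso_or_equiv")),
             sso_reported = suppressWarnings(
               as.numeric(col("_atom_site_site_symmetry_order"))),
             calculated = col("_atom_site_calc_flag", ".") %in% c("calc", "c"),
             disordered = !(col("_atom_site_disorder_group", ".") %in% c(".", "", "?")),
             stringsAsFactors = FALSE)
}

#' Validate a crystallographic archive
#'
#' Runs the full check battery over each structural data block of a CIF:
#' embedded-payload checksums, symmetry consistency, model checks,
#' reflection statistics (from embedded reflection payloads and/or a
#' supplied FCF; reflection-based checks degrade to missing-data alerts
#' when neither is available), difference-map analysis, void detection,
#' and missed-symmetry/twinning searches.  A failure inside one stage
#' never aborts the run; it becomes a toolkit-error alert.
#'
#' @param cif CIF text, a file path, or a parsed `ciflint_cif`.
#' @param fcf Optional FCF text or file path.
#' @param options Named list of tolerance overrides: `addsym_tol`,
#'   `addsym_nonfit`, `probe`, `grid_step`, `contact_slack`,
#'   `min_void_volume`, `nsigma_absence`.
#' @return Object of class `ciflint_report`.
#' @export
#' @examples
#' \donttest{
#' m <- generate_structure(n_atoms = 6, n_h = 1, seed = 7)
#' ds <- make_dataset(m, seed = 7)
#' rep <- run_validation(model_to_cif(m, ds))
#' print(rep)
#' }
run_validation <- function(cif, fcf = NULL, options = list()) {
  opt <- utils::modifyList(list(addsym_tol = 0.45, addsym_nonfit = 15,
                                probe = 1.2, grid_step = 0.2,
                                contact_slack = 0.2, min_void_volume = 20,
                                nsigma_absence = 3), options)
  as_text <- function(x) {
    if (inherits(x, "ciflint_cif")) return(x)
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
      x <- readChar(x, file.size(x), useBytes = TRUE)
    x
  }
  doc <- as_text(cif)
  if (!inherits(doc, "ciflint_cif")) doc <- parse_cif(doc)
  fcf_doc <- NULL
  if (!is.null(fcf)) {
    fcf_txt <- as_text(fcf)
    fcf_doc <- if (inherits(fcf_txt, "ciflint_cif")) fcf_txt else fcf_txt
  }
  structural <- Filter(function(b) !is.null(b$items[["_cell_length_a"]]), doc$blocks)
  if (!length(structural))
    stop_ciflint("no structural data block (with _cell_length_a) found",
                 "ciflint_validate_error")
  blocks <- lapply(structural, function(b)
    .validate_block(b, fcf_doc, opt))
  names(blocks) <- vapply(structural, `[[`, character(1), "name")
  structure(list(blocks = blocks, options = opt,
                 n_blocks_skipped = length(doc$blocks) - length(structural)),
            class = "ciflint_report")
}

## run one stage, converting errors to a toolkit alert
.stage <- function(alerts_env, name, expr) {
  tryCatch(expr, error = function(e) {
    alerts_env$alerts[[length(alerts_env$alerts) + 1L]] <-
      alert_row(9052, sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    NULL
  })
}

.validate_block <- function(b, fcf_doc, opt) {
  env <- new.env(parent = emptyenv())
  env$alerts <- list()
  add <- function(a) env$alerts[[length(env$alerts) + 1L]] <- a
  summary <- list(block = b$name)

  ## --- embedded payloads and checksums ------------------------------------
  embedded <- .stage(env, "embedded", {
    em <- extract_embedded(structure(list(blocks = list(b)), class = "ciflint_cif"))
    for (e in em) {
      if (e$checksum_ok == "fail")
        add(alert_row(12, sprintf("embedded %s payload (%s) fails its checksum: corrupt or edited",
                                  e$kind, e$tag)))
      else if (e$checksum_ok == "unverified")
        add(alert_row(9050, sprintf("embedded %s payload (%s) has no verifiable checksum",
                                    e$kind, e$tag)))
    }
    if (!length(em)) add(alert_row(9051, "no embedded refinement/reflection payloads"))
    em
  })

  ## --- symmetry ------------------------------------------------------------
  cellv <- .stage(env, "cell", .cell_from_block(b))
  sym <- .symmetry_from_block(b)
  setting <- .stage(env, "symmetry", {
    fx <- check_symmetry_consistency(c(sym, list(cell = cellv)))
    map <- c(SYM_HALL_MISSING = 9001, SYM_HM_MISSING = 9002, SYM_OPS_MISSING = 9003,
             SYM_HALL_INVALID = 9004, SYM_OPS_INVALID = 9005,
             SYM_OPS_HALL_MISMATCH = 9006, SYM_HM_HALL_MISMATCH = 9007,
             SYM_SETTING_NONSTANDARD = 9008, SYM_CELL_SYSTEM_MISMATCH = 9009)
    for (r in seq_len(nrow(fx))) add(alert_row(map[[fx$code[r]]], fx$message[r], fx$value[r]))
    if (!is.null(sym$ops)) spacegroup_setting(hall = sym$hall, hm = sym$hm, ops = sym$ops)
    else if (!is.null(sym$hall)) spacegroup_setting(hall = sym$hall)
    else if (!is.null(sym$hm)) spacegroup_setting(hm = sym$hm)
    else NULL
  })
  summary$cell <- if (!is.null(cellv))
    sprintf("a=%.4f b=%.4f c=%.4f alpha=%.3f beta=%.3f gamma=%.3f V=%.2f",
            cellv$a, cellv$b, cellv$c, cellv$alpha, cellv$beta, cellv$gamma,
            cellv$volume) else "(missing)"
  summary$spacegroup <- sprintf("HM: %s  Hall: %s  nsym: %s",
                                sym$hm %||% "?", sym$hall %||% "?",
                                if (!is.null(setting)) setting$nsym else "?")

  ## --- model ---------------------------------------------------------------
  wavelength <- block_num(b, "_diffrn_radiation_wavelength")$value
  sites <- .stage(env, "sites", .sites_from_block(b))
  model <- NULL
  if (is.null(sites)) add(alert_row(9053, "no _atom_site_ loop"))
  if (!is.null(sites) && !is.null(setting) && !is.null(cellv)) {
    model <- .stage(env, "model", {
      structure_model(cellv, setting,
                      data.frame(sites[c("label", "element", "x", "y", "z",
                                         "occ", "uiso", "calculated", "disordered")],
                                 is_h = sites$element == "H"),
                      wavelength = if (is.finite(wavelength)) wavelength else 0.71073)
    })
  }
  n_params <- block_num(b, "_refine_ls_number_parameters")$value
  if (!is.null(model)) {
    .stage(env, "model_checks", {
      sdf <- model$sites
      ## occupancy / site-symmetry bookkeeping
      for (j in seq_len(nrow(sdf))) {
        if (sdf$occ[j] <= 0 || sdf$occ[j] > 1 + 1e-6)
          add(alert_row(9026, sprintf("atom %s occupancy %.3f outside (0,1]",
                                      sdf$label[j], sdf$occ[j]), sdf$occ[j]))
        ss <- site_symmetry(as.numeric(sdf[j, c("x", "y", "z")]), model$setting,
                            model$cell, occupancy = sdf$occ[j])
        rep_sso <- sites$sso_reported[j]
        if (is.finite(rep_sso) && rep_sso != ss$sso)
          add(alert_row(9025, sprintf("atom %s: reported site-symmetry order %g, recomputed %d (multiplicity %d, SOF %.3f)",
                                      sdf$label[j], rep_sso, ss$sso, ss$ssm, ss$sof)))
      }
      if (any(sdf$calculated & sdf$is_h))
        add(alert_row(7, sprintf("%d hydrogen atom(s) on calculated (riding) positions",
                                 sum(sdf$calculated & sdf$is_h))))
      ## formula / weight / density
      ftxt <- .blk_item(b, "_chemical_formula_sum")
      if (!is.null(ftxt)) {
        fu <- parse_formula(ftxt)
        acc <- table(sdf$element)
        mism <- FALSE
        for (e in union(names(fu$counts), names(acc))) {
          na <- if (e %in% names(acc)) as.numeric(acc[[e]]) else 0
          nf <- if (e %in% names(fu$counts)) as.numeric(fu$counts[[e]]) else 0
          ## compare per asymmetric unit (formula given per formula unit)
          if (abs(na - nf) > 1e-6) mism <- TRUE
        }
        if (mism) add(alert_row(9012, sprintf("formula '%s' does not match the atom list", ftxt)))
        mr_rep <- block_num(b, "_chemical_formula_weight")$value
        mr <- molecular_weight(fu)
        if (is.finite(mr_rep) && abs(mr_rep - mr) > 0.5)
          add(alert_row(9013, sprintf("reported formula weight %.2f vs calculated %.2f", mr_rep, mr),
                        abs(mr_rep - mr)))
        z <- block_num(b, "_cell_formula_units_z")$value
        dc <- density_check(model$cell$volume, if (is.finite(z)) z else NA, mr,
                            block_num(b, "_exptl_crystal_density_diffrn")$value)
        for (r in seq_len(nrow(dc$findings)))
          add(alert_row(if (dc$findings$code[r] == "MODEL_Z_MISSING") 9010 else 9011,
                        dc$findings$message[r], dc$findings$value[r]))
        ## absorption plausibility
        ab <- absorption_range_check(
          fu, if (is.finite(z)) z else model$setting$nsym, model$cell$volume,
          model$wavelength,
          block_num(b, "_exptl_crystal_size_min")$value,
          block_num(b, "_exptl_crystal_size_max")$value,
          block_num(b, "_exptl_absorpt_correction_t_min")$value,
          block_num(b, "_exptl_absorpt_correction_t_max")$value)
        for (r in seq_len(nrow(ab$findings)))
          add(alert_row(if (startsWith(ab$findings$code[r], "ABS_NO")) 9021 else 9020,
                        ab$findings$message[r]))
      } else add(alert_row(9053, "missing _chemical_formula_sum"))
      ## contacts
      ct <- short_contacts(model, slack = opt$contact_slack)
      for (r in seq_len(nrow(ct))) {
        id <- switch(ct$class[r], `H..H` = 9014, missing_H = 9015,
                     halogen = 9016, 9017)
        add(alert_row(id, sprintf("%s...%s (%s) = %.2f A < vdW sum %.2f A",
                                  ct$atom1[r], ct$atom2[r], ct$symcode[r],
                                  ct$d[r], ct$vdw_sum[r]), ct$d[r]))
        if (ct$disorder[r])
          add(alert_row(9018, sprintf("contact %s...%s involves disordered sites",
                                      ct$atom1[r], ct$atom2[r])))
      }
      ## centres of gravity
      cg <- centre_of_gravity_check(model)
      for (r in seq_len(nrow(cg))) {
        msg <- sprintf("species %d (%d atoms) centroid (%.2f, %.2f, %.2f) outside cell; suggested translation (%g, %g, %g)",
                       cg$component[r], cg$n_atoms[r], cg$cx[r], cg$cy[r], cg$cz[r],
                       cg$shift_a[r], cg$shift_b[r], cg$shift_c[r])
        add(alert_row(9019, msg, level = if (cg$exempt_small[r]) "G" else "C"))
      }
      ## resonant scattering
      lp <- .blk_loop(b, "_atom_type_scat_dispersion_real")
      if (!is.null(lp)) {
        rep_df <- data.frame(
          element = lp$rows[, "_atom_type_symbol"],
          fp = suppressWarnings(as.numeric(lp$rows[, "_atom_type_scat_dispersion_real"])),
          fpp = suppressWarnings(as.numeric(lp$rows[, "_atom_type_scat_dispersion_imag"])),
          stringsAsFactors = FALSE)
        fx <- resonant_check(rep_df, model$wavelength)
        for (r in seq_len(nrow(fx)))
          add(alert_row(if (fx$code[r] == "RES_UNVERIFIED") 9024 else 9023, fx$message[r]))
      }
      NULL
    })
  }

  ## --- reflection data ------------------------------------------------------
  refl_fcf <- NULL; refl_emb <- NULL
  if (!is.null(fcf_doc))
    refl_fcf <- .stage(env, "fcf", {
      r <- read_reflections(fcf_doc, "fcf")
      if (is.null(attr(r, "cell")) && !is.null(cellv)) attr(r, "cell") <- cellv
      if (!is.finite(attr(r, "wavelength")) && is.finite(wavelength))
        attr(r, "wavelength") <- wavelength
      r
    })
  if (!is.null(embedded) && !is.null(model)) {
    hk <- Filter(function(e) e$kind == "hkl", embedded)
    if (length(hk))
      refl_emb <- .stage(env, "embedded_hkl", {
        r <- read_reflections(hk[[1]]$text, "hklf4")
        attr(r, "cell") <- cellv
        attr(r, "wavelength") <- model$wavelength
        hklm <- as.matrix(as.data.frame(r)[, c("h", "k", "l")])
        r$fc2 <- Mod(structure_factors(model, hklm))^2
        r
      })
  }
  if (is.null(refl_fcf) && is.null(refl_emb))
    add(alert_row(9030, "no FCF and no embedded reflection data: reflection checks skipped"))

  ## weighting parameters as reported
  wdet <- .blk_item(b, "_refine_ls_weighting_details") %||% ""
  wa <- regmatches(wdet, regexec("\\(([0-9.]+)P\\)", wdet))[[1]]
  wb <- regmatches(wdet, regexec("\\^2\\^?\\+([0-9.]+)P", wdet))[[1]]
  a_w <- if (length(wa)) as.numeric(wa[2]) else 0
  b_w <- if (length(wb)) as.numeric(wb[2]) else 0
  np <- if (is.finite(n_params)) n_params else
    if (!is.null(model)) 1 + 4 * nrow(model$sites) else 1

  rsets <- list()
  if (!is.null(refl_emb)) {
    .stage(env, "unmerged_checks", {
      mg <- merge_equivalents(refl_emb, model$setting)
      summary$rint <- mg$rint
      if (is.finite(mg$rint) && mg$rint > 0.10)
        add(alert_row(9034, sprintf("Rint = %.3f from %d measurements", mg$rint,
                                    nrow(refl_emb)), mg$rint,
                      level = if (mg$rint > 0.2) "B" else "C"))
      av <- absence_violations(refl_emb, model$setting, nsigma = opt$nsigma_absence)
      if (nrow(av))
        add(alert_row(9036, sprintf("%d reflection(s) violate systematic absences (strongest %d %d %d, I/sig = %.1f)",
                                    nrow(av), av$h[1], av$k[1], av$l[1],
                                    av$i_over_sig[1]), nrow(av)))
      fs <- fabrication_screen(refl_emb)
      if (identical(fs$verdict, "suspicious"))
        add(alert_row(9039, sprintf("sigma(I) is a near-exact smooth function of I (R^2 = %.6f)",
                                    fs$r_squared)))
      if (!model$setting$centrosymmetric) {
        ae <- absolute_structure_estimate(refl_emb, model$setting)
        summary$absolute_structure <- ae
        if (ae$decision != "not estimable")
          add(alert_row(9040, sprintf("Parsons-style quotient x = %.3f(su %.3f) from %d Bijvoet pairs: %s",
                                      ae$x, ae$su, ae$n_pairs, ae$decision), ae$x,
                        level = if (ae$decision == "invert") "B"
                                else if (ae$decision == "indeterminate") "C" else "G"))
      }
      rsets$embedded <- r_factors(mg$merged, a = a_w, b = b_w, n_params = np)
      NULL
    })
  }
  refl_main <- refl_fcf %||%
    (if (!is.null(refl_emb) && !is.null(model))
       .stage(env, "merge_embedded", {
         mg <- merge_equivalents(refl_emb, model$setting)$merged
         hklm <- as.matrix(as.data.frame(mg)[, c("h", "k", "l")])
         Fm <- structure_factors(model, hklm)
         mg$fc2 <- Mod(Fm)^2
         mg$phase <- Arg(Fm) * 180 / pi
         mg
       }) else NULL)

  if (!is.null(refl_main) && !is.null(refl_main$fc2)) {
    .stage(env, "refl_stats", {
      rsets$fcf <- r_factors(refl_main, a = a_w, b = b_w, n_params = np)
      rep_r1 <- block_num(b, "_refine_ls_r_factor_gt")$value
      rep_wr2 <- block_num(b, "_refine_ls_wr_factor_ref")$value
      rep_s <- block_num(b, "_refine_ls_goodness_of_fit_ref")$value
      rsets$reported <- list(r1 = rep_r1, wr2 = rep_wr2, goof = rep_s)
      if (is.finite(rep_r1) && is.finite(rsets$fcf$r1) &&
          abs(rep_r1 - rsets$fcf$r1) > 0.01)
        add(alert_row(9031, sprintf("reported R1 = %.4f vs recalculated %.4f",
                                    rep_r1, rsets$fcf$r1), abs(rep_r1 - rsets$fcf$r1)))
      if (is.finite(rep_wr2) && abs(rep_wr2 - rsets$fcf$wr2) > 0.01)
        add(alert_row(9032, sprintf("reported wR2 = %.4f vs recalculated %.4f",
                                    rep_wr2, rsets$fcf$wr2), abs(rep_wr2 - rsets$fcf$wr2)))
      if (is.finite(rep_s) && is.finite(rsets$fcf$goof) &&
          abs(rep_s - rsets$fcf$goof) > 0.1)
        add(alert_row(9033, sprintf("reported S = %.3f vs recalculated %.3f",
                                    rep_s, rsets$fcf$goof), abs(rep_s - rsets$fcf$goof)))
      ## N:p ratio on Laue-unique observed reflections
      if (!is.null(model)) {
        npr <- data_parameter_ratio(rsets$fcf$n_obs, np, model$setting$centrosymmetric)
        if (npr$level != "pass")
          add(alert_row(9022, sprintf("observed-data to parameter ratio %.1f (N=%d, p=%d)",
                                      npr$ratio, rsets$fcf$n_obs, as.integer(np)),
                        npr$ratio, level = npr$level))
      }
      ## completeness
      if (!is.null(model)) {
        cp <- completeness_profile(refl_main, model$setting, model$cell)
        summary$completeness <- cp$completeness_0.6
        if (is.finite(cp$completeness_0.6) && cp$completeness_0.6 < 0.95)
          add(alert_row(9035, sprintf("completeness %.1f%% at s = 0.6 1/A",
                                      100 * cp$completeness_0.6),
                        cp$completeness_0.6,
                        level = if (cp$completeness_0.6 < 0.85) "B" else "C"))
        if (is.finite(cp$suggested_cutoff))
          add(alert_row(9054, sprintf("observed fraction below threshold beyond s = %.2f 1/A",
                                      cp$suggested_cutoff), cp$suggested_cutoff))
      }
      ## analysis of variance + normal probability
      av <- analysis_of_variance(refl_main, a = a_w, b = b_w)
      for (r in seq_len(nrow(av$findings)))
        add(alert_row(9037, av$findings$message[r], av$findings$value[r]))
      np_stats <- normal_probability(refl_main, a = a_w, b = b_w)
      summary$npp <- np_stats
      if (!np_stats$degenerate &&
          (abs(np_stats$slope - 1) > 0.3 || np_stats$max_central_dev > 0.5))
        add(alert_row(9038, sprintf("normal-probability slope %.2f, max central deviation %.2f",
                                    np_stats$slope, np_stats$max_central_dev)))
      ## twinning
      tw <- twin_search(refl_main, model$setting)
      if (!is.character(tw) && length(tw)) {
        t1 <- tw[[1]]
        add(alert_row(9041, sprintf("two-fold about %s explains %.0f%% of outliers; alpha = %.2f, R1 %.3f -> %.3f",
                                    t1$axis, t1$explained_fraction, t1$alpha_hat,
                                    t1$r1_before, t1$r1_after), t1$alpha_hat))
      }
      NULL
    })
    ## difference map analyses
    if (!is.null(model)) .stage(env, "maps", {
      mg2 <- refl_main
      if (is.null(mg2$phase)) {
        hklm <- as.matrix(as.data.frame(mg2)[, c("h", "k", "l")])
        mg2$phase <- Arg(structure_factors(model, hklm)) * 180 / pi
      }
      dm <- difference_map(mg2, setting = NULL, grid_step = opt$grid_step)
      bonds <- build_connectivity(model)
      mr <- map_report(dm, model, bonds,
                       reported_max = block_num(b, "_refine_diff_density_max")$value,
                       reported_min = block_num(b, "_refine_diff_density_min")$value)
      summary$map_range <- c(mr$min, mr$max)
      map_ids <- c(MAP_EXTREMUM = 9042, MAP_EXTREMUM_NEAR_HEAVY = 9043,
                   MAP_ON_ATOM = 9044, MAP_REPORTED_MISMATCH = 9045)
      for (r in seq_len(nrow(mr$findings))) {
        code <- mr$findings$code[r]
        lvl <- if (code == "MAP_EXTREMUM")
          .grade_up(abs(mr$findings$value[r]), 0.5, 1.0, 1.5) else NULL
        add(alert_row(map_ids[[code]], mr$findings$message[r], mr$findings$value[r],
                      level = lvl))
      }
      if (is.finite(mr$bond_mean))
        add(alert_row(978, sprintf("mean difference density at bond midpoints %.3f e/A^3",
                                   mr$bond_mean), mr$bond_mean))
      hsup <- h_site_support(dm, model, mode = "asis")
      for (r in which(!hsup$supported))
        add(alert_row(977, sprintf("hydrogen site %s not supported by the difference density (%.2f e/A^3)",
                                   hsup$label[r], hsup$rho[r]), hsup$rho[r]))
      ## voids + electron content
      vd <- find_voids(model, probe = opt$probe, grid_step = opt$grid_step,
                       min_volume = opt$min_void_volume)
      summary$voids <- length(vd$regions)
      for (reg in vd$regions) {
        add(alert_row(9046, sprintf("solvent-accessible void of %.0f A^3 at (%.2f, %.2f, %.2f)",
                                    reg$volume, reg$centroid[1], reg$centroid[2],
                                    reg$centroid[3]), reg$volume))
        ec <- sample_void_electrons(reg, vd$dims, dm)
        add(alert_row(9047, sprintf("void at (%.2f, %.2f, %.2f) integrates to %.1f e",
                                    reg$centroid[1], reg$centroid[2],
                                    reg$centroid[3], ec), ec))
      }
      NULL
    })
  }
  summary$r_sets <- rsets

  ## --- missed symmetry -----------------------------------------------------
  if (!is.null(model)) .stage(env, "addsym", {
    pr <- addsym_search(model, tol = opt$addsym_tol,
                        allowed_nonfit = opt$addsym_nonfit)
    if (!is.character(pr)) for (p in pr) {
      lvl <- if (p$fit_fraction >= 97.5 && !startsWith(p$implied_hall, "undetermined"))
        "A" else "B"
      add(alert_row(9048, sprintf("%s at (%.3f, %.3f, %.3f) fits %.0f%% of atoms (tol %.2f A); implied group: %s",
                                  p$kind, p$t[1], p$t[2], p$t[3], p$fit_fraction,
                                  opt$addsym_tol, p$implied_hall),
                    p$fit_fraction, level = lvl))
      if (!startsWith(p$implied_hall, "undetermined") && !is.null(refl_emb)) {
        av2 <- absence_violations(refl_emb, spacegroup_setting(hall = p$implied_hall),
                                  nsigma = opt$nsigma_absence)
        add(alert_row(9049, sprintf("proposed group %s: %d extinction violation(s) in the archived data",
                                    p$implied_hall, nrow(av2)), nrow(av2)))
      }
    }
    NULL
  })

  alerts <- if (length(env$alerts)) do.call(rbind, env$alerts) else
    alert_row(9051, "")[0, ]
  alerts <- alerts[order(match(alerts$level, c("A", "B", "C", "G")), alerts$id), ,
                   drop = FALSE]
  rownames(alerts) <- NULL
  list(summary = summary, alerts = alerts)
}

#' @export
print.ciflint_report <- function(x, ...) {
  cat(render_report(x, format = "chk", explanations = FALSE))
  invisible(x)
}

#' Render a validation report
#'
#' @param report `ciflint_report`.
#' @param format `"chk"` for the human-readable text report (byte-stable
#'   for identical input) or `"json"` for a complete machine-readable
#'   serialization.
#' @param explanations Append the per-rule explanation to each alert
#'   (chk format).
#' @return A single text string.
#' @export
render_report <- function(report, format = c("chk", "json"),
                          explanations = TRUE) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(blocks = report$blocks, options = report$options,
           rules = alert_rules()),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)))
  }
  rules <- alert_rules()
  out <- c("ciflint validation report",
           sprintf("tolerances: addsym %.2f A / %g%% non-fit, probe %.2f A, grid %.2f A, contact slack %.2f A",
                   report$options$addsym_tol, report$options$addsym_nonfit,
                   report$options$probe, report$options$grid_step,
                   report$options$contact_slack), "")
  for (nm in names(report$blocks)) {
    blk <- report$blocks[[nm]]
    s <- blk$summary
    out <- c(out, sprintf("== data_%s ==", nm),
             sprintf("cell: %s", s$cell), sprintf("symmetry: %s", s$spacegroup))
    rs <- s$r_sets
    fmtset <- function(x) if (is.null(x)) "      -      -     -" else
      sprintf("%7.4f %7.4f %6.3f",
              if (is.null(x$r1) || !is.finite(x$r1)) NA else x$r1,
              if (is.null(x$wr2) || !is.finite(x$wr2)) NA else x$wr2,
              if (is.null(x$goof) || !is.finite(x$goof)) NA else x$goof)
    out <- c(out, "                 R1     wR2      S",
             sprintf("from embedded %s", fmtset(rs$embedded)),
             sprintf("from fcf      %s", fmtset(rs$fcf)),
             sprintf("reported      %s", fmtset(rs$reported)))
    if (!is.null(s$rint)) out <- c(out, sprintf("Rint (refold of archived data): %.4f", s$rint))
    if (!is.null(s$map_range))
      out <- c(out, sprintf("difference map range: %.3f to %.3f e/A^3",
                            s$map_range[1], s$map_range[2]))
    if (!is.null(s$absolute_structure) && !is.na(s$absolute_structure$x))
      out <- c(out, sprintf("absolute structure: x = %.3f (su %.3f), %s",
                            s$absolute_structure$x, s$absolute_structure$su,
                            s$absolute_structure$decision))
    al <- blk$alerts
    out <- c(out, sprintf("alerts: %d (A:%d B:%d C:%d G:%d)", nrow(al),
                          sum(al$level == "A"), sum(al$level == "B"),
                          sum(al$level == "C"), sum(al$level == "G")))
    for (r in seq_len(nrow(al))) {
      out <- c(out, sprintf("ALERT %04d %s %s", al$id[r], al$level[r], al$message[r]))
      if (explanations)
        out <- c(out, sprintf("           . %s",
                              rules$explanation[match(al$id[r], rules$id)]))
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
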