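test_that("the coordinate search recovers a stripped inversion centre", {
  m <- fx_model()
  ms <- ciflint:::corrupt_model(m, "strip_inversion")
  pr <- addsym_search(ms)
  expect_false(is.character(pr))
  kinds <- vapply(pr, `[[`, character(1), "kind")
  expect_true("inversion centre" %in% kinds)
  inv <- pr[[which(kinds == "inversion centre")[1]]]
  expect_equal(inv$fit_fraction, 100)
  expect_identical(inv$implied_hall, "-P 2ybc")
  ## the true chiral control stays silent at default tolerances
  expect_length(addsym_search(fx_chiral_model()), 0L)
  expect_length(addsym_search(m), 0L)
  ## too few atoms
  tiny <- ms; tiny$sites <- ms$sites[1:2, ]
  expect_identical(addsym_search(tiny), "not assessed")
})

test_that("proposals tolerate non-conforming atoms and rigid translations", {
  m <- fx_model()
  ms <- ciflint:::corrupt_model(m, "strip_inversion")
  ## perturb one eligible atom well beyond the tolerance
  pert <- ms
  j <- which(!pert$sites$is_h)[1]
  pert$sites$x[j] <- pert$sites$x[j] + 1.5 / pert$cell$a
  pr <- addsym_search(pert)
  kinds <- vapply(pr, `[[`, character(1), "kind")
  expect_true("inversion centre" %in% kinds)
  inv <- pr[[which(kinds == "inversion centre")[1]]]
  n_elig <- sum(!pert$sites$is_h & !pert$sites$disordered)
  ## the perturbed atom and its (now unmatched) image partner both count
  ## as non-conforming, so the fit is (n-2)/n at least
  expect_gte(inv$fit_fraction, 100 * (n_elig - 2) / n_elig - 1e-6)
  expect_lt(inv$fit_fraction, 100)
  ## rigid translation of the whole model moves the centre accordingly
  tr <- ms
  shift <- c(0.11, 0.07, 0.05)
  tr$sites[, c("x", "y", "z")] <- sweep(tr$sites[, c("x", "y", "z")], 2, shift, `+`)
  pr2 <- addsym_search(tr)
  kinds2 <- vapply(pr2, `[[`, character(1), "kind")
  inv2 <- pr2[[which(kinds2 == "inversion centre")[1]]]
  expect_equal(inv2$fit_fraction, 100)
  d <- ciflint:::frac_dist_mi(tr$cell, inv2$t - (2 * shift))
  expect_lt(d, 0.1)
})

test_that("index-2 subgroup reductions are recovered across group types", {
  for (hall in c("-P 1", "P 2yb")) {
    m <- generate_structure(n_atoms = 5, n_h = 0, hall = hall, seed = 3,
                            fill_voids = FALSE)
    if (m$setting$centrosymmetric) {
      ms <- ciflint:::corrupt_model(m, "strip_inversion")
      pr <- addsym_search(ms)
      expect_true("inversion centre" %in% vapply(pr, `[[`, character(1), "kind"),
                  label = hall)
    } else {
      ## declare a screw structure in P1: the screw must be proposed
      p1 <- spacegroup_setting(hall = "P 1")
      expanded <- m$sites
      img <- ciflint:::op_apply(m$setting$ops[[2]],
                                t(as.matrix(m$sites[, c("x", "y", "z")])))
      copy <- m$sites
      copy$label <- paste0(copy$label, "b")
      copy[, c("x", "y", "z")] <- t(ciflint:::frac1(img))
      mp <- structure_model(m$cell, p1, rbind(expanded, copy), m$wavelength)
      pr <- addsym_search(mp)
      expect_true("two-fold rotation" %in% vapply(pr, `[[`, character(1), "kind"),
                  label = hall)
    }
  }
})

test_that("twin candidates respect the metric and square to identity", {
  ## cubic metric: every metric-compatible two-fold is already in the Laue
  ## group, so the candidate list is empty
  cub <- cell(10, 10, 10)
  sgc <- spacegroup_setting(hall = "-P 4 2 3")
  expect_length(twin_candidates(cub, sgc), 0L)
  ## monoclinic cell with beta = 90.2: two-folds about a and c appear
  mono <- cell(9, 11, 8, 90, 90.2, 90)
  sgm <- spacegroup_setting(hall = "-P 2ybc")
  cands <- twin_candidates(mono, sgm)
  axes <- vapply(cands, `[[`, character(1), "axis")
  expect_true(any(grepl("\\[1 0 0\\]", axes)))
  expect_true(any(grepl("\\[0 0 1\\]", axes)))
  for (cand in cands)
    expect_lt(max(abs(cand$R %*% cand$R - diag(3))), 1e-8)
})

test_that("twin search proposes the law, estimates alpha and the R drop", {
  mt <- fx_twin_model()
  ds <- make_dataset(mt, corruption = "twin", alpha = 0.3, seed = 5)
  tw <- twin_search(ds$merged, mt$setting)
  expect_false(is.character(tw))
  expect_gt(length(tw), 0L)
  best <- tw[[1]]
  expect_gte(best$explained_fraction, 60)
  expect_gte(best$alpha_hat, 0.25)
  expect_lte(best$alpha_hat, 0.35)
  expect_lt(best$r1_after, best$r1_before)
  ## untwinned control never reaches the outlier threshold
  ds0 <- make_dataset(mt, seed = 5)
  expect_identical(twin_search(ds0$merged, mt$setting), "not assessed")
})

test_that("HKLF5 export writes overlap pairs with negative batch flags", {
  cl <- cell(9, 11, 8, 90, 90.2, 90)
  r <- reflection_set(c(1, 2, 3), c(0, 1, 0), c(0, 1, 5), c(100, 50, 80),
                      c(2, 2, 2), cell = cl)
  law <- list(R = diag(c(1, -1, -1)))  # two-fold about a for this metric
  txt <- export_hklf5(r, law, delta = 0.1, theta_tol = 10)
  lines <- strsplit(txt, "\n")[[1]]
  expect_true(startsWith(lines[1], "!"))
  body <- lines[-1]
  terminator <- body[length(body)]
  expect_match(terminator, "^   0   0   0")
  recs <- body[-length(body)]
  ## every reflection overlaps under an exact two-fold: 3 pairs = 6 records
  expect_length(recs, 6L)
  expect_match(recs[1], " -2$")
  expect_match(recs[2], "   1$")
  ## with an impossible overlap criterion all records are singles, batch 1
  txt1 <- export_hklf5(r, list(R = matrix(c(1, 0, 0, 0, 1, 0, 0.3, 0, 1), 3)),
                       delta = 0.01, theta_tol = 10)
  body1 <- strsplit(txt1, "\n")[[1]][-1]
  recs1 <- body1[-length(body1)]
  expect_length(recs1, 3L)
  expect_true(all(grepl("   1$", recs1)))
})
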