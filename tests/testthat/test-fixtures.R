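test_that("generation is byte-reproducible from the seed", {
  m1 <- generate_structure(n_atoms = 5, n_h = 1, seed = 7, fill_voids = FALSE)
  m2 <- generate_structure(n_atoms = 5, n_h = 1, seed = 7, fill_voids = FALSE)
  expect_identical(m1$sites, m2$sites)
  d1 <- make_dataset(m1, seed = 3); d2 <- make_dataset(m2, seed = 3)
  expect_identical(model_to_cif(m1, d1), model_to_cif(m2, d2))
  m3 <- generate_structure(n_atoms = 5, n_h = 1, seed = 8, fill_voids = FALSE)
  expect_false(identical(m1$sites, m3$sites))
})

test_that("structure factors obey the basic physical limits", {
  cl <- cell(10, 10, 10)
  p1 <- spacegroup_setting(hall = "P 1")
  ## single atom at the origin, U = 0: |F(h)| = f0(s) for every h
  m <- structure_model(cl, p1, data.frame(label = "C1", element = "C",
                                          x = 0, y = 0, z = 0, occ = 1, uiso = 0),
                       wavelength = NA)
  hkl <- rbind(c(1, 0, 0), c(2, 3, 1), c(0, 0, 4))
  Fh <- structure_factors(m, hkl, anomalous = FALSE)
  f0 <- ciflint:::f0_element("C", ciflint:::s_of_hkl(cl, hkl))
  expect_equal(Mod(Fh), f0, tolerance = 1e-12)
  ## centrosymmetric model without resonant terms: phases are 0 or pi
  mg <- fx_model()
  hs <- ciflint:::hkl_sphere(mg$cell, 0.3)
  hs <- hs[!ciflint:::is_extinct(hs, mg$setting), , drop = FALSE]
  Fc <- structure_factors(mg, hs, anomalous = FALSE)
  expect_lt(max(abs(Im(Fc))), 1e-9)
})

test_that("each corruption is caught by its intended check and no other fires on gold", {
  m <- fx_model()
  ds <- fx_ds_clean()
  golden_ids <- run_validation(model_to_cif(m, ds))$blocks[[1]]$alerts$id

  expect_alert <- function(cif, id, label) {
    ids <- run_validation(cif)$blocks[[1]]$alerts$id
    expect_true(id %in% ids, label = label)
    expect_false(id %in% golden_ids, label = paste("gold clean of", label))
  }
  ## corrupted archives: corruption -> alert id
  expect_alert(model_to_cif(m, ds, edit_embedded = TRUE), 12, "edit_embedded")
  mw <- ciflint:::corrupt_model(m, "wrong_atom_type")
  expect_alert(model_to_cif(mw, make_dataset(m, model_reported = mw, seed = 7)),
               9044, "wrong_atom_type")
  mh <- ciflint:::corrupt_model(m, "misplace_h")
  expect_alert(model_to_cif(mh, make_dataset(m, model_reported = mh, seed = 7)),
               977, "misplace_h")
  ms <- ciflint:::corrupt_model(m, "strip_inversion")
  expect_alert(model_to_cif(ms, make_dataset(ms, seed = 7)), 9048,
               "strip_inversion")
  expect_alert(model_to_cif(m, make_dataset(m, corruption = "fabricate_sigmas",
                                            seed = 7)), 9039, "fabricate_sigmas")
  expect_alert(model_to_cif(m, make_dataset(m, corruption = "inflate_low_order",
                                            seed = 7)), 9037, "inflate_low_order")
  mt <- fx_twin_model()
  expect_alert(model_to_cif(mt, make_dataset(mt, corruption = "twin",
                                             alpha = 0.3, seed = 5)), 9041, "twin")
})

test_that("the golden archive reports consistent reflection statistics", {
  rep <- run_validation(fx_cif_golden())
  s <- rep$blocks[[1]]$summary
  rs <- s$r_sets
  ## the three R-value sets agree on self-consistent data
  expect_equal(rs$embedded$r1, rs$fcf$r1, tolerance = 1e-6)
  expect_lt(abs(rs$fcf$r1 - rs$reported$r1), 1e-4)
  expect_lt(abs(rs$fcf$wr2 - rs$reported$wr2), 1e-4)
  expect_lt(abs(rs$fcf$goof - 1), 0.15)
  expect_lt(s$rint, 0.05)
  expect_equal(s$completeness, 1, tolerance = 1e-6)
})
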