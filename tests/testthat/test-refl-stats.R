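test_that("merging groups equivalents and reproduces the Rint definition", {
  cl <- cell(10, 12, 9, 90, 102, 90)
  sg <- spacegroup_setting(hall = "-P 2ybc")
  ## identical duplicate measurements: Rint = 0
  r0 <- reflection_set(c(1, -1), c(2, 2), c(1, -1), c(100, 100), c(5, 5), cell = cl)
  expect_equal(merge_equivalents(r0, sg)$rint, 0)
  ## two equivalents 90 and 110 with equal sigma: mean 100, Rint = 0.10
  r1 <- reflection_set(c(2, -2), c(1, 1), c(1, -1), c(90, 110), c(5, 5), cell = cl)
  mg <- merge_equivalents(r1, sg)
  expect_equal(nrow(mg$merged), 1L)
  expect_equal(mg$merged$fo2, 100)
  expect_equal(mg$rint, 0.10)
  ## Rint is invariant under reindexing the whole set by a Laue operator
  ds <- fx_ds_clean()
  m <- fx_model()
  base <- merge_equivalents(ds$unmerged, m$setting)$rint
  L <- m$setting$laue_ops[[3]]
  df <- as.data.frame(ds$unmerged)
  hr <- as.matrix(df[, c("h", "k", "l")]) %*% L
  re <- reflection_set(hr[, 1], hr[, 2], hr[, 3], df$fo2, df$sig,
                       cell = m$cell)
  expect_equal(merge_equivalents(re, m$setting)$rint, base, tolerance = 1e-12)
})

test_that("two-parameter weights follow the stated convention", {
  expect_equal(weights(100, 5, 100, 0, 0), 1 / 25)
  expect_equal(weights(100, 5, 100, a = 0.1, b = 0), 1 / (25 + 100))
  ## negative observed intensities clamp inside P only
  expect_equal(weights(-5, 2, 30, a = 0, b = 1), 1 / (4 + 20))
})

test_that("R factors and GooF match hand evaluation of the definitions", {
  cl <- cell(10, 10, 10)
  perfect <- reflection_set(1:3, 0:2, c(0, 1, 0), c(100, 81, 25), c(5, 5, 5),
                            fc2 = c(100, 81, 25), cell = cl)
  rf0 <- r_factors(perfect, n_params = 1)
  expect_equal(rf0$r1, 0); expect_equal(rf0$wr2, 0); expect_equal(rf0$goof, 0)
  ## 3-reflection hand case: Fo2 = 100, 81, 25; Fc2 = 90, 81, 30; sigma 5
  hand <- reflection_set(1:3, 0:2, c(0, 1, 0), c(100, 81, 25), c(5, 5, 5),
                         fc2 = c(90, 81, 30), cell = cl)
  w <- 1 / 25
  num <- w * ((100 - 90)^2 + 0 + (25 - 30)^2)
  wr2_hand <- sqrt(num / (w * (100^2 + 81^2 + 25^2)))
  s_hand <- sqrt(num / (3 - 1))
  r1_hand <- (abs(10 - sqrt(90)) + 0 + abs(5 - sqrt(30))) / (10 + 9 + 5)
  rf <- r_factors(hand, n_params = 1)
  expect_equal(rf$wr2, wr2_hand)
  expect_equal(rf$goof, s_hand)
  expect_equal(rf$r1, r1_hand)
  ## no observed reflections: R1 undefined
  weak <- reflection_set(1, 0, 0, 5, 10, fc2 = 5)
  expect_true(is.na(r_factors(weak, n_params = 0)$r1))
  ## recomputed values equal those archived in the fixture CIF within 1e-4
  cif <- parse_cif(fx_cif_golden())
  b <- cif$blocks[[1]]
  np <- as.numeric(b$items[["_refine_ls_number_parameters"]])
  rf2 <- r_factors(fx_ds_clean()$merged, n_params = np)
  expect_lt(abs(rf2$r1 - as.numeric(b$items[["_refine_ls_r_factor_gt"]])), 1e-4)
  expect_lt(abs(rf2$wr2 - as.numeric(b$items[["_refine_ls_wr_factor_ref"]])), 1e-4)
})

test_that("wR2 from merged data equals wR2 after merging the raw set", {
  m <- fx_model()
  ds <- fx_ds_exact()
  mg <- merge_equivalents(ds$unmerged, m$setting)$merged
  hkl <- as.matrix(as.data.frame(mg)[, c("h", "k", "l")])
  mg$fc2 <- Mod(structure_factors(m, hkl))^2
  a <- r_factors(ds$merged, n_params = 10)
  b <- r_factors(mg, n_params = 10)
  expect_equal(a$wr2, b$wr2, tolerance = 1e-6)
})

test_that("completeness counts against brute-force lattice enumeration", {
  m <- fx_model()
  ds <- fx_ds_clean()
  cp <- completeness_profile(ds$merged, m$setting, m$cell, s_max = 0.65)
  expect_true(all(cp$shells$complete > 0.999, na.rm = TRUE))
  expect_equal(cp$completeness_0.6, 1, tolerance = 1e-9)
  expect_true(is.na(cp$suggested_cutoff))
  ## truncation at s = 0.6 zeroes the outer shells and suggests the cutoff
  df <- as.data.frame(ds$merged)
  s <- ciflint:::s_of_hkl(m$cell, as.matrix(df[, c("h", "k", "l")]))
  tr <- ds$merged[s <= 0.6, ]
  attr(tr, "cell") <- m$cell
  ## 13 shells put a boundary exactly at s = 0.6
  cp2 <- completeness_profile(tr, m$setting, m$cell, s_max = 0.65, nshells = 13)
  expect_equal(cp2$completeness_0.6, 1, tolerance = 1e-9)
  outer <- cp2$shells[cp2$shells$s_lo >= 0.605, ]
  expect_true(all(outer$measured == 0))
  expect_equal(cp2$suggested_cutoff, 0.6, tolerance = 1e-9)
  ## unique-point count for a P1 cell equals brute-force enumeration
  cl <- cell(10, 10, 10)
  p1 <- spacegroup_setting(hall = "P 1")
  uh <- ciflint:::unique_hkl_to(p1, cl, 0.2)
  cnt <- 0
  for (h in -5:5) for (k in -5:5) for (l in -5:5) {
    if (h == 0 && k == 0 && l == 0) next
    if (ciflint:::s_of_hkl(cl, rbind(c(h, k, l))) <= 0.2) cnt <- cnt + 1
  }
  expect_identical(nrow(uh), as.integer(cnt / 2))  # Friedel-unique halves the sphere
})

test_that("analysis of variance partitions the data and flags distortions", {
  ds <- fx_ds_exact()
  av <- analysis_of_variance(ds$merged)
  expect_equal(sum(av$by_resolution$n), nrow(ds$merged))
  expect_equal(sum(av$by_fc$n), nrow(ds$merged))
  expect_true(all(abs(av$by_resolution$K - 1) < 1e-9))
  expect_true(all(av$by_resolution$goof < 1e-6))
  expect_identical(nrow(av$findings), 0L)
  ## doubling the low-order intensities drives the lowest-s bin K to ~2
  dsl <- make_dataset(fx_model(), corruption = "inflate_low_order", seed = 7)
  avl <- analysis_of_variance(dsl$merged)
  expect_gt(avl$by_resolution$K[1], 1.5)
  expect_true(any(avl$findings$value > 1.5))
})

test_that("normal-probability statistics behave for known generators", {
  cl <- cell(10, 10, 10)
  n <- 400
  set.seed(8)
  fc2 <- stats::runif(n, 50, 500)
  sig <- rep(4, n)
  delta <- stats::rnorm(n)
  r <- reflection_set(sample(-8:8, n, TRUE), sample(-8:8, n, TRUE),
                      sample(1:8, n, TRUE), fc2 + delta * sig, sig, fc2 = fc2,
                      cell = cl)
  np <- normal_probability(r)
  expect_equal(np$slope, 1, tolerance = 0.1)
  expect_equal(np$intercept, 0, tolerance = 0.1)
  expect_false(np$degenerate)
  ## perfect fit is degenerate
  r0 <- reflection_set(1:12, rep(0, 12), rep(1, 12), seq(10, 120, 10),
                       rep(2, 12), fc2 = seq(10, 120, 10), cell = cl)
  expect_true(normal_probability(r0)$degenerate)
  ## heavy-tailed residuals give a larger S-shape metric
  set.seed(8)
  delta_t <- stats::rt(n, df = 2)
  rt_ <- reflection_set(sample(-8:8, n, TRUE), sample(-8:8, n, TRUE),
                        sample(1:8, n, TRUE), fc2 + delta_t * sig, sig,
                        fc2 = fc2, cell = cl)
  expect_gt(normal_probability(rt_)$max_central_dev, np$max_central_dev)
  expect_error(normal_probability(r0[1:5, ]), "at least 10")
})

test_that("Parsons-style quotient estimate recovers the inversion fraction", {
  ma <- fx_chiral_model()
  ## exact limits
  d0 <- make_dataset(ma, noise = NULL, seed = 4)
  e0 <- absolute_structure_estimate(d0$unmerged, ma$setting)
  expect_equal(e0$x, 0, tolerance = 1e-8)
  di <- make_dataset(ma, noise = NULL, corruption = "invert_structure", seed = 4)
  ei <- absolute_structure_estimate(di$unmerged, ma$setting)
  expect_equal(ei$x, 1, tolerance = 1e-8)
  expect_identical(ei$decision, "invert")
  ## noisy recovery at a simulated mixing fraction of 0.3
  d3 <- make_dataset(ma, corruption = "inversion_twin", alpha = 0.3, seed = 4)
  e3 <- absolute_structure_estimate(d3$unmerged, ma$setting)
  expect_lt(abs(e3$x - 0.3), 3 * e3$su)
  ## equivariance: evaluating the same data against the inverted model
  ## (all calculated quotients negated) maps the estimate x to 1 - x
  mi <- ciflint:::corrupt_model(ma, "invert_structure")
  rinv <- d3$unmerged
  hklm <- as.matrix(as.data.frame(rinv)[, c("h", "k", "l")])
  rinv$fc2 <- Mod(structure_factors(mi, hklm))^2
  e3i <- absolute_structure_estimate(rinv, mi$setting)
  expect_equal(e3i$x, 1 - e3$x, tolerance = 1e-6)
  ## centrosymmetric data are not estimable
  ec <- absolute_structure_estimate(fx_ds_clean()$unmerged, fx_model()$setting)
  expect_identical(ec$decision, "not estimable")
})

test_that("fabrication screen fires on exact sigmas and not on noisy ones", {
  dsf <- make_dataset(fx_twin_model(), corruption = "fabricate_sigmas", seed = 5)
  expect_identical(fabrication_screen(dsf$unmerged)$verdict, "suspicious")
  ds <- fx_ds_clean()
  fs <- fabrication_screen(ds$unmerged)
  expect_identical(fs$verdict, "ok")
  expect_identical(names(fs$plot_data), c("inv_sigma", "log10_i"))
  ## small sets are not assessed
  small <- ds$unmerged[1:10, ]
  expect_identical(fabrication_screen(small)$verdict, "not assessed")
})
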