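test_that("difference synthesis: zero map, single-coefficient wave, FFT = direct sum", {
  m <- fx_model()
  ds <- fx_ds_exact()
  dm0 <- difference_map(ds$merged, grid_step = 0.2)
  expect_lt(max(abs(dm0$values)), 1e-8)
  expect_lt(abs(mean(dm0$values)), 1e-10)

  ## one coefficient h = (1,0,0) with real positive dF: cosine along a
  cl <- cell(8, 8, 8)
  r1 <- reflection_set(1, 0, 0, fo2 = 400, sig = 1, fc2 = 100, phase = 0,
                       cell = cl)
  dm1 <- difference_map(r1, grid_step = 0.3)
  dF <- 20 - 10
  nx <- dm1$dims[1]
  xs <- (seq_len(nx) - 1) / nx
  expect_equal(dm1$values[, 1, 1], 2 * dF / cl$volume * cos(2 * pi * xs),
               tolerance = 1e-10)
  expect_lt(abs(mean(dm1$values)), 1e-12)

  ## FFT equals the direct Fourier summation at every voxel
  set.seed(3)
  n <- 25
  rr <- reflection_set(sample(1:3, n, TRUE), sample(-3:3, n, TRUE),
                       sample(0:3, n, TRUE), stats::runif(n, 0, 400),
                       rep(1, n), fc2 = stats::runif(n, 0, 400),
                       phase = stats::runif(n, -180, 180), cell = cl)
  rr <- rr[!duplicated(paste(rr$h, rr$k, rr$l)), ]
  attr(rr, "cell") <- cl
  dm <- difference_map(rr, grid_step = 0.5)
  df <- as.data.frame(rr)
  Fh <- complex(modulus = abs(sqrt(df$fo2) - sqrt(df$fc2)),
                argument = df$phase * pi / 180)
  Fh[sqrt(df$fo2) - sqrt(df$fc2) < 0] <- -Fh[sqrt(df$fo2) - sqrt(df$fc2) < 0]
  for (pt in list(c(0, 0, 0), c(3, 1, 2), c(5, 7, 2))) {
    x <- pt / dm$dims
    direct <- sum(Re(Fh * exp(-2i * pi * as.matrix(df[, c("h", "k", "l")]) %*% x)) +
                    Re(Conj(Fh) * exp(2i * pi * as.matrix(df[, c("h", "k", "l")]) %*% x))) /
      cl$volume
    expect_equal(dm$values[pt[1] + 1, pt[2] + 1, pt[3] + 1], direct,
                 tolerance = 1e-8)
  }
  expect_error(difference_map(ds$merged, grid_step = 1.0), "too coarse")
})

test_that("map is symmetry-consistent under the space group", {
  m <- fx_model()
  ds <- make_dataset(m, seed = 3)
  dm <- difference_map(ds$merged, setting = m$setting, grid_step = 0.2)
  ## density at x equals density at every operator image of x
  set.seed(5)
  for (i in 1:5) {
    x <- stats::runif(3)
    v0 <- ciflint:::grid_interp(dm, x)
    for (op in m$setting$ops[2:4]) {
      vi <- ciflint:::grid_interp(dm, as.numeric(ciflint:::op_apply(op, x)))
      expect_equal(vi, v0, tolerance = 0.02)
    }
  }
})

test_that("map report flags a wrong atom type and matches reported extrema", {
  m <- fx_model()
  mw <- ciflint:::corrupt_model(m, "wrong_atom_type")
  dsw <- make_dataset(m, model_reported = mw, noise = NULL, seed = 2)
  dm <- difference_map(dsw$merged, grid_step = 0.2)
  mr <- map_report(dm, mw, build_connectivity(mw))
  wrong <- which(mw$sites$element != m$sites$element)
  expect_lt(mr$site_density$rho[wrong], -0.5)
  expect_true(any(mr$findings$code == "MAP_ON_ATOM"))
  ## clean map: everything quiet, on-bond mean ~ 0 for spherical-atom data
  dm0 <- difference_map(fx_ds_exact()$merged, grid_step = 0.2)
  mr0 <- map_report(dm0, m, build_connectivity(m))
  expect_identical(nrow(mr0$findings), 0L)
  expect_lt(abs(mr0$bond_mean), 1e-6)
  ## reported-vs-recalculated mismatch
  mr1 <- map_report(dm0, m, reported_max = 0.9, reported_min = -0.9)
  expect_identical(sort(mr1$findings$code),
                   rep("MAP_REPORTED_MISMATCH", 2))
})

test_that("hydrogen-site support distinguishes placed and misplaced H", {
  m <- fx_model()
  mh <- ciflint:::corrupt_model(m, "misplace_h")
  dsh <- make_dataset(m, model_reported = mh, noise = NULL, seed = 2)
  dmh <- difference_map(dsh$merged, grid_step = 0.2)
  hs <- h_site_support(dmh, mh, mode = "asis")
  moved <- which(mh$sites$x[mh$sites$is_h] != m$sites$x[m$sites$is_h])
  expect_false(hs$supported[moved[1]])
  ## the true H position shows as a positive peak near the misplaced one
  pk <- peak_search(dmh, mh, n_top = 5, min_height = 0.1)
  expect_gt(nrow(pk), 0L)
  expect_lt(min(pk$d_nearest), 1.2)
  ## zero map: vacuously supported
  dm0 <- difference_map(fx_ds_exact()$merged, grid_step = 0.2)
  expect_true(all(h_site_support(dm0, m, mode = "asis")$supported))
  ## omit-mode: H sites on real density are supported
  m_no_h <- m
  m_no_h$sites <- m$sites[!m$sites$is_h, ]
  ds_omit <- make_dataset(m, model_reported = m_no_h, noise = NULL, seed = 2)
  dm_omit <- difference_map(ds_omit$merged, grid_step = 0.2)
  expect_true(all(h_site_support(dm_omit, m, mode = "omit")$supported))
})

test_that("void detection matches a brute-force oracle and partitions the cell", {
  cl <- cell(10, 10, 10)
  sg <- spacegroup_setting(hall = "P 1")
  ## empty cell: one region covering the whole volume
  m0 <- structure_model(cl, sg, data.frame(label = character(), element = character(),
                                           x = numeric(), y = numeric(), z = numeric(),
                                           occ = numeric(), uiso = numeric()))
  v0 <- find_voids(m0, grid_step = 0.5)
  expect_length(v0$regions, 1L)
  expect_equal(v0$regions[[1]]$volume, cl$volume)
  ## single C atom: volume equals the brute-force grid count; probe-monotone
  m1 <- structure_model(cl, sg, data.frame(label = "C1", element = "C",
                                           x = 0.5, y = 0.5, z = 0.5, occ = 1,
                                           uiso = 0.03))
  v1 <- find_voids(m1, probe = 1.2, grid_step = 0.5)
  rC <- ciflint:::element_row("C")$r_vdw + 1.2
  cnt <- 0
  for (i in 0:19) for (j in 0:19) for (k in 0:19) {
    p <- c(i, j, k) / 20
    d <- sqrt(sum((cl$M %*% (ciflint:::wrap_half(p - 0.5)))^2))
    if (d > rC) cnt <- cnt + 1
  }
  expect_equal(v1$void_volume, cnt * cl$volume / 8000)
  expect_equal(v1$void_volume + v1$occupied_volume, cl$volume)
  v2 <- find_voids(m1, probe = 2.0, grid_step = 0.5)
  expect_lt(v2$void_volume, v1$void_volume)
  ## densely packed fixture: no reportable region
  expect_length(find_voids(fx_model())$regions, 0L)
})

test_that("void electron integration recovers an omitted solvent atom", {
  m <- fx_model()
  solvent <- grep("W$", m$sites$label)
  expect_gt(length(solvent), 0L)
  m_omit <- m
  m_omit$sites <- m$sites[-solvent, ]
  ds <- make_dataset(m, model_reported = m_omit, noise = NULL, seed = 2)
  dm <- difference_map(ds$merged, grid_step = 0.2)
  ## zero map integrates to zero electrons
  vd <- find_voids(m_omit, min_volume = 5)
  expect_gt(length(vd$regions), 0L)
  total <- sum(vapply(vd$regions, function(reg)
    ciflint:::sample_void_electrons(reg, vd$dims, dm), numeric(1)))
  ## one oxygen (8 electrons) per asymmetric unit; truncation-limited
  expect_equal(total, 8, tolerance = 0.15 * 8)
  ## additivity: region sums add to the union integral
  dm0 <- difference_map(fx_ds_exact()$merged, grid_step = 0.2)
  z <- vapply(vd$regions, function(reg)
    ciflint:::sample_void_electrons(reg, vd$dims, dm0), numeric(1))
  expect_lt(max(abs(z)), 1e-8)
})
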