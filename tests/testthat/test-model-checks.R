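test_that("formula parsing, weight and the solvent-bracket rule", {
  f <- parse_formula("C2 H6 O1")
  expect_equal(molecular_weight(f), 46.07, tolerance = 0.01)
  fb <- parse_formula("C10 H14 N2 [+solvent]")
  expect_identical(fb$solvent_note, "+solvent")
  expect_setequal(names(fb$counts), c("C", "H", "N"))
  expect_equal(molecular_weight(fb),
               10 * 12.011 + 14 * 1.008 + 2 * 14.007, tolerance = 0.05)
  expect_error(parse_formula("Xx4"), class = "ciflint_element_error")
  expect_error(parse_formula("  "), class = "ciflint_formula_error")
  ## additivity: Mr(A) + Mr(B) = Mr(concatenation)
  expect_equal(molecular_weight(parse_formula("C2 H6")) +
                 molecular_weight(parse_formula("O1 S2")),
               molecular_weight(parse_formula("C2 H6 O1 S2")))
})

test_that("density arithmetic and missing-datum handling", {
  dc <- density_check(500, 4, 46.07, reported = 0.612)
  expect_equal(dc$rho_calc, 4 * 46.07 * 1.66054 / 500, tolerance = 1e-10)
  expect_equal(dc$rho_calc, 0.612, tolerance = 5e-4)
  expect_identical(nrow(dc$findings), 0L)
  expect_identical(nrow(density_check(500, 4, 46.07, reported = 0.7)$findings), 1L)
  expect_identical(density_check(500, NA, 46.07)$findings$code, "MODEL_Z_MISSING")
})

test_that("rigid-bond differences match projections and a sampling oracle", {
  ## identical isotropic U on both atoms
  h0 <- hirshfeld_test(0.04, 0.04, c(1, 0, 0))
  expect_equal(h0$delta, 0)
  ## axis-aligned anisotropic case reduces to the U11 difference
  ua <- diag(c(0.05, 0.02, 0.02)); ub <- diag(c(0.03, 0.02, 0.02))
  h1 <- hirshfeld_test(ua, ub, c(1, 0, 0))
  expect_equal(h1$delta, 0.02)
  ## random tensors against a numeric mean-square-displacement oracle
  msda <- function(U, n) {
    ## sample the displacement quadric numerically
    ev <- eigen(U, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
    set.seed(99)
    disp <- L %*% matrix(stats::rnorm(3 * 2e5), 3)
    mean((as.numeric(n %*% disp))^2)
  }
  set.seed(31)
  for (i in 1:3) {
    A <- crossprod(matrix(stats::rnorm(9, sd = 0.15), 3))
    B <- crossprod(matrix(stats::rnorm(9, sd = 0.15), 3))
    n <- ciflint:::.runit()
    h <- hirshfeld_test(A, B, n)
    expect_equal(h$delta, abs(msda(A, n) - msda(B, n)), tolerance = 0.01)
    ## invariant under swapping the two atoms
    expect_equal(h$delta, hirshfeld_test(B, A, n)$delta)
  }
  expect_error(hirshfeld_test(0.04, 0.04, c(0, 0, 0)), "zero-length")
})

test_that("connectivity, contacts and their classification", {
  cl <- cell(10, 10, 10)
  sg <- spacegroup_setting(hall = "P 1")
  mk <- function(sites) structure_model(cl, sg, sites)
  ## two O atoms 2.45 A apart in different molecules: missing-H class
  m <- mk(data.frame(label = c("O1", "O2"), element = "O",
                     x = c(0.1, 0.1 + 2.45 / 10), y = 0.2, z = 0.2,
                     occ = 1, uiso = 0.03))
  ct <- short_contacts(m)
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$class, "missing_H")
  ## halogen...halogen at 3.30 A is informational
  mcl <- mk(data.frame(label = c("Cl1", "Cl2"), element = "Cl",
                       x = c(0.1, 0.43), y = 0.2, z = 0.2, occ = 1, uiso = 0.03))  # 3.30 A
  expect_identical(short_contacts(mcl)$class, "halogen")
  ## pair beyond the van der Waals sum: no contact
  mfar <- mk(data.frame(label = c("C1", "C2"), element = "C",
                        x = c(0.1, 0.54), y = 0.2, z = 0.2, occ = 1, uiso = 0.03))
  expect_identical(nrow(short_contacts(mfar)), 0L)
  ## golden fixture: bonds found, no spurious contacts, symmetric dedupe
  mg <- fx_model()
  bonds <- build_connectivity(mg)
  expect_gte(nrow(bonds), nrow(mg$sites) - 2)   # connected molecule + lone solvent
  expect_identical(nrow(short_contacts(mg)), 0L)
})

test_that("centre-of-gravity rule with the small-species exemption", {
  cl <- cell(10, 10, 10)
  sg <- spacegroup_setting(hall = "P 1")
  base <- data.frame(label = paste0("C", 1:5), element = "C",
                     x = 0.5 + c(0, 0.15, -0.15, 0, 0) * 0.5,
                     y = 0.5 + c(0, 0, 0, 0.15, -0.15) * 0.5,
                     z = 0.5, occ = 1, uiso = 0.03)
  m_ok <- structure_model(cl, sg, base)
  expect_identical(nrow(centre_of_gravity_check(m_ok)), 0L)
  shifted <- base; shifted$x <- shifted$x + 0.8  # centroid near 1.3
  m_out <- structure_model(cl, sg, shifted)
  cg <- centre_of_gravity_check(m_out)
  expect_identical(nrow(cg), 1L)
  expect_identical(cg$shift_a, -1)
  expect_false(cg$exempt_small)
  lone <- data.frame(label = "O1W", element = "O", x = 1.05, y = 0.5, z = 0.5,
                     occ = 1, uiso = 0.05)
  cg2 <- centre_of_gravity_check(structure_model(cl, sg, lone))
  expect_true(cg2$exempt_small)
})

test_that("absorption plausibility from composition and crystal size", {
  f <- parse_formula("C10 Br2")
  mu <- absorption_mu(f, 4, 800, 1.54184)
  expect_gt(mu, 0.3)  # bromine absorbs Cu radiation strongly
  ab <- absorption_range_check(f, 4, 800, 1.54184, 0.1, 0.4, exp(-mu * 0.4),
                               exp(-mu * 0.1))
  expect_equal(ab$t_min_exp, exp(-mu * 0.4))
  expect_equal(ab$t_max_exp, exp(-mu * 0.1))
  expect_identical(nrow(ab$findings), 0L)
  ## reported range implausibly narrow
  bad <- absorption_range_check(f, 4, 800, 1.54184, 0.1, 0.4, 0.99, 1.00)
  expect_identical(bad$findings$code, "ABS_RANGE_NARROW")
  ## missing dimensions cannot be assessed
  expect_identical(absorption_range_check(f, 4, 800, 1.54184, NA, NA, 0.9,
                                          0.95)$findings$code, "ABS_NO_DIMS")
  ## expected range is ordered and in (0, 1]; monotone in path length
  expect_lte(ab$t_min_exp, ab$t_max_exp)
  expect_gt(ab$t_min_exp, 0); expect_lte(ab$t_max_exp, 1)
})

test_that("data-to-parameter ratio thresholds are applied by symmetry class", {
  expect_identical(data_parameter_ratio(2000, 100, FALSE)$level, "pass")
  r <- data_parameter_ratio(500, 100, FALSE)
  expect_equal(r$ratio, 5); expect_identical(r$level, "A")
  r2 <- data_parameter_ratio(900, 100, TRUE)
  expect_equal(r2$ratio, 9); expect_identical(r2$level, "B")
})

test_that("resonant scattering values are checked against the tables", {
  tabv <- ciflint:::fprime_element("C", 0.71073)
  ok <- resonant_check(data.frame(element = "C", fp = tabv["fp"],
                                  fpp = tabv["fpp"]), 0.71073)
  expect_identical(nrow(ok), 0L)
  br <- ciflint:::fprime_element("Br", 0.71073)
  bad <- resonant_check(data.frame(element = "Br", fp = br["fp"],
                                   fpp = 10 * br["fpp"]), 0.71073)
  expect_identical(bad$code, "RES_MISMATCH")
  un <- resonant_check(data.frame(element = "C", fp = 0, fpp = 0), 0.9184)
  expect_identical(un$code, "RES_UNVERIFIED")
})
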