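test_that("Hall expansion decodes the documented generators", {
  ## -P 2yn: inversion plus the n-glide screw 1/2-x, 1/2+y, 1/2-z
  ops <- expand_hall("-P 2yn")
  keys <- op_keys(ops)
  expect_length(ops, 4L)
  expect_true(ciflint:::op_key(ciflint:::parse_triplet("-x,-y,-z")) %in% keys)
  expect_true(ciflint:::op_key(ciflint:::parse_triplet("1/2-x,1/2+y,1/2-z")) %in% keys)

  expect_length(expand_hall("P 1"), 1L)
  expect_identical(ciflint:::op_triplet(expand_hall("P 1")[[1]]), "x,y,z")

  ## -P 2ybc equals the brute-force closure of its generators
  oracle <- oracle_closure(c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z"))
  expect_identical(op_keys(expand_hall("-P 2ybc")), op_keys(oracle))

  expect_error(expand_hall("Q 2"), class = "ciflint_hall_error")
  expect_error(expand_hall("P 9x"), class = "ciflint_hall_error")
})

test_that("expansions satisfy the group axioms (closure, identity, inverses)", {
  halls <- c("P 1", "-P 1", "P 2yb", "-P 2ybc", "-P 2yn", "C 2y", "-C 2yc",
             "P 2 2ab", "-P 2ac 2ab", "I 4", "-P 4 2", "P 31", "R 3 -2\"",
             "-F 4 2 3", "-I 4bd 2c 3", "F 2 -2d")
  for (h in halls) {
    ops <- expand_hall(h)
    keys <- op_keys(ops)
    expect_true(ciflint:::op_key(ciflint:::op_identity()) %in% keys, label = h)
    inv_ok <- vapply(ops, function(o)
      ciflint:::op_key(ciflint:::op_inverse(o)) %in% keys, logical(1))
    expect_true(all(inv_ok), label = sprintf("%s inverses", h))
    comp_ok <- vapply(ops, function(a) all(vapply(ops, function(b)
      ciflint:::op_key(ciflint:::op_compose(a, b)) %in% keys, logical(1))),
      logical(1))
    expect_true(all(comp_ok), label = sprintf("%s closure", h))
  }
})

test_that("crystal system and operator count match the bundled table", {
  tab <- sg_table()
  set.seed(2)
  idx <- sample(nrow(tab), 40)
  for (i in idx) {
    ops <- expand_hall(tab$hall[i])
    expect_length(ops, tab$nops[i])
    expect_identical(ciflint:::crystal_system_of(ops), tab$crystal_system[i],
                     label = tab$hall[i])
  }
})

test_that("site symmetry counts coincident images and derives SOF", {
  cl <- cell(10, 12, 9, 90, 102, 90)
  sg <- spacegroup_setting(hall = "-P 2ybc")
  ## fully occupied atom on the inversion centre of a 4-operator group
  ss <- site_symmetry(c(0, 0, 0), sg, cl, occupancy = 1.0)
  expect_identical(ss$sso, 2L)
  expect_identical(ss$ssm, 2L)
  expect_equal(ss$sof, 0.5)
  expect_equal(ss$sso * ss$ssm, sg$nsym)
  ## general position
  ss2 <- site_symmetry(c(0.13, 0.27, 0.31), sg, cl, occupancy = 1.0)
  expect_identical(ss2$sso, 1L)
  expect_equal(ss2$sof, 1.0)
  ## two-fold axis in an 8-operator group (C2/c), half occupancy
  sg8 <- spacegroup_setting(hall = "-C 2yc")
  expect_identical(sg8$nsym, 8L)
  ss3 <- site_symmetry(c(0, 0.191, 0.25), sg8, cell(12, 10, 14, 90, 95, 90),
                       occupancy = 0.5)
  expect_identical(ss3$sso, 2L)
  expect_equal(ss3$sof, 0.25)
  expect_error(site_symmetry(c(0, 0, 0), sg, cl, tol = -1), "tol")
})

test_that("s_uvw symmetry codes encode and decode per the digit convention", {
  expect_identical(encode_symmcode(1, c(2, 0, -1)), "1_754")
  expect_identical(encode_symmcode(1, c(0, 0, 0)), "1_555")
  d <- decode_symmcode("1_555")
  expect_identical(d$op_index, 1L)
  expect_identical(d$uvw, c(0L, 0L, 0L))
  expect_error(encode_symmcode(1, c(5, 0, 0)), "-5..4")
  expect_error(decode_symmcode("1_5555"), "malformed")
  sg <- spacegroup_setting(hall = "-P 2ybc")
  expect_error(decode_symmcode("9_555", sg), "exceeds")
  ## decode(encode(.)) identity over a systematic sample of the code space
  for (op in 1:4) for (u in c(-5, -2, 0, 4)) for (v in c(-5, 0, 3)) for (w in c(-1, 0, 4)) {
    d <- decode_symmcode(encode_symmcode(op, c(u, v, w)), sg)
    expect_identical(d$op_index, op)
    expect_identical(d$uvw, as.integer(c(u, v, w)))
  }
})

test_that("absence conditions match the phase rule and flag violations", {
  sg <- spacegroup_setting(hall = "-P 2ybc")
  ## 0k0 with k odd and h0l with l odd are extinct; predicate agrees with
  ## the phase condition on every operator
  expect_true(all(ciflint:::is_extinct(rbind(c(0, 1, 0), c(0, 3, 0), c(1, 0, 1),
                                             c(2, 0, 3)), sg)))
  expect_false(any(ciflint:::is_extinct(rbind(c(0, 2, 0), c(1, 1, 1), c(2, 0, 2)), sg)))
  cond <- absence_conditions(sg)
  expect_setequal(cond$zone, c("0k0", "h0l"))
  expect_identical(nrow(absence_conditions(spacegroup_setting(hall = "P 1"))), 0L)

  ## extinct reflections of a real structure carry no intensity
  m <- fx_model()
  hs <- ciflint:::hkl_sphere(m$cell, 0.35)
  ext <- ciflint:::is_extinct(hs, m$setting)
  expect_gt(sum(ext), 5)
  expect_lt(max(Mod(structure_factors(m, hs[ext, , drop = FALSE]))), 1e-8)

  ## an injected strong 0 3 0 is flagged at the default 3 sigma
  r <- reflection_set(c(0, 1, 2), c(3, 1, 0), c(0, 1, 2), c(500, 100, 90),
                      c(5, 5, 5), cell = m$cell)
  v <- absence_violations(r, sg)
  expect_identical(nrow(v), 1L)
  expect_identical(c(v$h, v$k, v$l), c(0L, 3L, 0L))
})

test_that("symmetry consistency checks find exactly the planted problems", {
  sg <- spacegroup_setting(hall = "-P 2ybc")
  trip <- vapply(sg$ops, ciflint:::op_triplet, character(1))
  ok <- check_symmetry_consistency(list(
    hm = "P 21/c", hall = "-P 2ybc", ops = trip,
    cell = cell(10, 12, 9, 90, 102, 90, su = list(alpha = 0.02, beta = 0.02,
                                                  gamma = 0.02))))
  expect_identical(nrow(ok), 0L)
  ## monoclinic cell with alpha = 90.20(2): deviation is 10 su
  bad_cell <- check_symmetry_consistency(list(
    hm = "P 21/c", hall = "-P 2ybc", ops = trip,
    cell = cell(10, 12, 9, 90.20, 102, 90, su = list(alpha = 0.02))))
  expect_true("SYM_CELL_SYSTEM_MISMATCH" %in% bad_cell$code)
  ## operator loop missing the inversion listed by the Hall symbol
  part <- trip[c(1, 2)]
  mism <- check_symmetry_consistency(list(hm = "P 21/c", hall = "-P 2yn",
                                          ops = part,
                                          cell = cell(10, 12, 9, 90, 102, 90)))
  expect_true("SYM_OPS_HALL_MISMATCH" %in% mism$code)
  ## unknown non-standard Hall symbol: comparison skipped with a note
  sk <- check_symmetry_consistency(list(hm = "P 21/c", hall = "P 2yab (0 0 1)",
                                        cell = cell(10, 12, 9, 90, 102, 90)))
  expect_true("SYM_SETTING_NONSTANDARD" %in% sk$code)
  ## missing symbols are findings, not errors
  mis <- check_symmetry_consistency(list(ops = trip,
                                         cell = cell(10, 12, 9, 90, 102, 90)))
  expect_true(all(c("SYM_HALL_MISSING", "SYM_HM_MISSING") %in% mis$code))
})
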