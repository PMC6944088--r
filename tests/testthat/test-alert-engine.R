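test_that("a consistent noise-free archive raises no A/B/C alerts", {
  rep <- run_validation(fx_cif_golden())
  al <- rep$blocks[[1]]$alerts
  expect_identical(sum(al$level %in% c("A", "B", "C")), 0L)
  expect_gt(nrow(al), 0L)  # informative G notes are present
  expect_false(is.null(rep$blocks[[1]]$summary$r_sets$fcf))
})

test_that("an edited embedded payload raises the checksum alert", {
  cif <- model_to_cif(fx_model(), fx_ds_clean(), edit_embedded = TRUE)
  rep <- run_validation(cif)
  expect_true(12 %in% rep$blocks[[1]]$alerts$id)
})

test_that("absent reflection data degrades to missing-data alerts", {
  rep <- run_validation(model_to_cif(fx_model()))
  al <- rep$blocks[[1]]$alerts
  expect_true(9030 %in% al$id)
  expect_false(any(al$id %in% c(9031, 9041)))
})

test_that("reports are deterministic and every alert line is complete", {
  rep <- run_validation(fx_cif_golden())
  t1 <- render_report(rep, format = "chk")
  t2 <- render_report(run_validation(fx_cif_golden()), format = "chk")
  expect_identical(t1, t2)
  ## every alert line carries id and level; explanations toggle works
  lines <- grep("^ALERT", strsplit(t1, "\n")[[1]], value = TRUE)
  expect_true(all(grepl("^ALERT [0-9]{4} [ABCG] .+", lines)))
  t3 <- render_report(rep, format = "chk", explanations = FALSE)
  expect_lt(nchar(t3), nchar(t1))
  ## the structured form serializes every alert and the tolerances
  js <- jsonlite::fromJSON(render_report(rep, format = "json"))
  expect_identical(nrow(js$blocks$I$alerts), nrow(rep$blocks[[1]]$alerts))
  expect_identical(js$options$probe, 1.2)
})

test_that("levels grade monotonically with the measured value", {
  g <- ciflint:::.grade_up
  vals <- seq(0, 3, by = 0.1)
  lv <- vapply(vals, g, character(1), c_at = 0.5, b_at = 1, a_at = 1.5)
  rank <- match(lv, c("pass", "C", "B", "A"))
  expect_true(all(diff(rank) >= 0))
  ## registry: unique ids, valid levels, explanations present
  reg <- alert_rules()
  expect_false(anyDuplicated(reg$id) > 0)
  expect_true(all(reg$level %in% c("A", "B", "C", "G")))
  expect_true(all(nzchar(reg$explanation)))
  expect_true(all(reg$id %in% c(7, 12, 977, 978) | reg$id >= 9000))
  expect_error(ciflint:::alert_row(1234, "x"), "unknown alert id")
})

test_that("the command line validates, reports and sets exit codes", {
  dir <- withr::local_tempdir()
  golden <- file.path(dir, "golden.cif")
  writeLines(fx_cif_golden(), golden)
  out <- file.path(dir, "report.chk")
  code <- ciflint_cli(c("check", golden, "--out", out, "--no-explanations"))
  expect_identical(code, 0L)
  expect_true(any(grepl("^ALERT", readLines(out))))

  ## a missed inversion centre is an A-level issue: exit 1
  ms <- ciflint:::corrupt_model(fx_model(), "strip_inversion")
  dss <- make_dataset(ms, seed = 7)
  stripped <- file.path(dir, "stripped.cif")
  writeLines(model_to_cif(ms, dss), stripped)
  out2 <- file.path(dir, "stripped.chk")
  code2 <- ciflint_cli(c("check", stripped, "--out", out2))
  expect_identical(code2, 1L)
  expect_true(any(grepl("ALERT 9048 A", readLines(out2))))

  ## json output parses
  outj <- file.path(dir, "r.json")
  expect_identical(ciflint_cli(c("check", golden, "--format", "json",
                                 "--out", outj)), 0L)
  expect_silent(jsonlite::fromJSON(paste(readLines(outj), collapse = "\n")))

  ## failure modes: missing file and bad flags exit 2
  expect_identical(suppressMessages(ciflint_cli(c("check", "no-such.cif"))), 2L)
  expect_identical(suppressMessages(ciflint_cli(c("check", golden, "--bogus"))), 2L)
  expect_identical(suppressMessages(ciflint_cli(character(0))), 2L)
})
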