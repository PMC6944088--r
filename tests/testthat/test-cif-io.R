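test_that("minimal documents, quoting and loops parse correctly", {
  doc <- parse_cif("data_I\n_cell_length_a 5.4321(2)\n")
  expect_length(doc$blocks, 1L)
  expect_identical(doc$blocks[[1]]$items[["_cell_length_a"]], "5.4321(2)")

  txt <- paste("data_x", "_a 'two words'", "_b \"with 'quote'\"", "loop_",
               "_c1", "_c2", "1 2", "3 'four four'", sep = "\n")
  doc <- parse_cif(txt)
  b <- doc$blocks[[1]]
  expect_identical(b$items[["_a"]], "two words")
  expect_identical(b$items[["_b"]], "with 'quote'")
  expect_identical(dim(b$loops[[1]]$rows), c(2L, 2L))
  expect_identical(unname(b$loops[[1]]$rows[2, "_c2"]), "four four")
})

test_that("parse errors carry line numbers and the right condition class", {
  expect_error(parse_cif("data_I\n_x\n;\nnever closed\n"),
               class = "ciflint_cif_parse_error")
  expect_error(parse_cif("data_I\nloop_\n_a\n_b\n1 2 3\n"), "line 2")
  expect_error(parse_cif("data_I\n_a 1\n_a 2\n"), "duplicate tag")
  expect_error(parse_cif("data_I\n_a '''cif2 string'''\n"), "CIF 1.1")
  expect_error(parse_cif("data_I\nsave_frame\n_a 1\n"), "save frames")
  expect_error(parse_cif("data_I\ndata_I\n_a 1\n"), "duplicate data-block")
})

test_that("uncertain values parse and format reciprocally", {
  expect_equal(parse_uncertain("5.0"), list(value = 5.0, su = NA_real_))
  expect_equal(parse_uncertain("1.2345(6)"), list(value = 1.2345, su = 0.0006))
  expect_equal(parse_uncertain("12.34(12)"), list(value = 12.34, su = 0.12))
  expect_error(parse_uncertain("abc"), class = "ciflint_value_error")

  set.seed(11)
  for (i in 1:50) {
    v <- stats::runif(1, -50, 50)
    su <- 10^stats::runif(1, -4, 0)
    p <- parse_uncertain(format_uncertain(v, su))
    ## identity within the printed precision
    expect_lt(abs(p$value - v), su)
    expect_lt(abs(p$su - su) / su, 0.51)
  }
})

test_that("serialization round-trips: parse(write(parse(F))) == parse(F)", {
  m <- fx_model()
  txt <- model_to_cif(m, fx_ds_clean())
  d1 <- parse_cif(txt)
  d2 <- parse_cif(write_cif(d1))
  expect_identical(d2$blocks[[1]]$items, d1$blocks[[1]]$items)
  expect_identical(lapply(d2$blocks[[1]]$loops, `[[`, "rows"),
                   lapply(d1$blocks[[1]]$loops, `[[`, "rows"))
  ## writer is bit-stable
  expect_identical(write_cif(d1), write_cif(parse_cif(write_cif(d1))))
})

test_that("embedded payloads are byte-exact and checksums verify", {
  payload <- "TITL t\nCELL 0.71073 10 10 10 90 90 90\nFVAR 1\nEND"
  cs <- ciflint_checksum(payload)
  cif <- paste0("data_I\n_cell_length_a 10\n_shelx_res_file\n;\n", payload,
                "\n;\n_shelx_res_checksum ", cs, "\n_shelx_hkl_file\n;\nHKL DATA\n;\n")
  em <- extract_embedded(parse_cif(cif))
  expect_length(em, 2L)
  res <- em[[which(vapply(em, `[[`, character(1), "kind") == "res")]]
  expect_identical(res$text, payload)
  expect_identical(res$checksum_ok, "ok")
  hkl <- em[[which(vapply(em, `[[`, character(1), "kind") == "hkl")]]
  expect_identical(hkl$checksum_ok, "unverified")

  ## editing the payload after the checksum was written must fail it
  cif_bad <- sub("TITL t", "TITL x", cif, fixed = TRUE)
  em2 <- extract_embedded(parse_cif(cif_bad))
  res2 <- em2[[which(vapply(em2, `[[`, character(1), "kind") == "res")]]
  expect_identical(res2$checksum_ok, "fail")

  ## absence of embedded datanames gives an empty list
  expect_length(extract_embedded(parse_cif("data_I\n_cell_length_a 5\n")), 0L)

  ## re-serializing and re-extracting preserves the payload byte-exactly
  doc <- parse_cif(cif)
  em3 <- extract_embedded(parse_cif(write_cif(doc)))
  res3 <- em3[[which(vapply(em3, `[[`, character(1), "kind") == "res")]]
  expect_identical(res3$text, payload)
})
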