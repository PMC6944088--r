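## CIF 1.1 reading and writing.
##
## Only the subset of CIF 1.1 this toolkit consumes is implemented: data
## blocks, tag/value items, loops, quoted strings and semicolon text
## fields.  Semicolon-field payloads are preserved byte-exact because
## embedded reflection/instruction files carry checksums.  CIF2/DDLm
## syntax (triple-quoted strings) and save frames are rejected.

cif_parse_error <- function(msg, line) {
  stop_ciflint(sprintf("CIF parse error at line %d: %s", line, msg),
               "ciflint_cif_parse_error")
}

## tokenize one line (outside semicolon fields); returns character vector,
## quoted strings carry an attribute-free marker prefix "\x01" to keep
## empty strings and values starting with '_' distinguishable
.cif_tokens <- function(line, lineno) {
  toks <- list()
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch %in% c("'", "\"")) {
      if (substr(line, i, i + 2) %in% c("'''", "\"\"\""))
        cif_parse_error("CIF2 triple-quoted strings are not supported (CIF 1.1 only)", lineno)
      ## find closing quote followed by whitespace or EOL
      j <- i + 1L
      repeat {
        j2 <- regexpr(ch, substr(line, j, n), fixed = TRUE)
        if (j2 < 0) cif_parse_error("unterminated quoted string", lineno)
        j <- j + j2 - 1L
        if (j == n || substr(line, j + 1L, j + 1L) %in% c(" ", "\t")) break
        j <- j + 1L
      }
      toks[[length(toks) + 1L]] <- paste0("\x01", substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- regexpr("[ \t]", substr(line, i, n))
      j <- if (j < 0) n + 1L else i + j - 1L
      toks[[length(toks) + 1L]] <- substr(line, i, j - 1L)
      i <- j
    }
  }
  unlist(toks) %||% character(0)
}

.unmark <- function(tok) sub("^\x01", "", tok)
.is_marked <- function(tok) startsWith(tok, "\x01")

#' Parse CIF 1.1 text
#'
#' @param text CIF content as a single string or a character vector of
#'   lines.
#' @return Object of class `ciflint_cif`: a list with `blocks`, each block
#'   a list with `name`, `items` (named list of raw text values, tags
#'   lowercased) and `loops` (list of `list(tags, rows)` with `rows` a
#'   character matrix).
#' @export
#' @examples
#' doc <- parse_cif("data_I\n_cell_length_a 5.4321(2)\n")
#' doc$blocks[[1]]$items[["_cell_length_a"]]
parse_cif <- function(text) {
  stopifnot(length(text) >= 1L)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop_ciflint("empty CIF text", "ciflint_cif_parse_error")
  blocks <- list()
  cur <- NULL
  item_lines <- new.env(parent = emptyenv())

  flush_block <- function() {
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  }
  i <- 1L; n <- length(lines)
  ## token stream with lookahead across lines; semicolon fields handled here
  pending <- character(0); pending_line <- integer(0)
  next_token <- function() {
    repeat {
      if (length(pending)) {
        tok <- pending[1L]; ln <- pending_line[1L]
        pending <<- pending[-1L]; pending_line <<- pending_line[-1L]
        return(list(tok = tok, line = ln))
      }
      if (i > n) return(NULL)
      line <- lines[i]
      if (startsWith(line, ";")) {
        start <- i
        rem <- substring(line, 2L)
        body <- character(0)
        i <<- i + 1L
        repeat {
          if (i > n) cif_parse_error("unterminated semicolon text field", start)
          if (startsWith(lines[i], ";")) break
          body <- c(body, lines[i])
          i <<- i + 1L
        }
        after <- substring(lines[i], 2L)
        i <<- i + 1L
        if (nzchar(trimws(after))) {
          tk <- .cif_tokens(after, i - 1L)
          pending <<- c(pending, tk); pending_line <<- c(pending_line, rep(i - 1L, length(tk)))
        }
        val <- if (nzchar(rem)) paste(c(rem, body), collapse = "\n")
               else paste(body, collapse = "\n")
        return(list(tok = paste0("\x01", val), line = start, semi = TRUE))
      }
      tk <- .cif_tokens(line, i)
      i <<- i + 1L
      if (length(tk)) {
        pending <<- tk; pending_line <<- rep(i - 1L, length(tk))
      }
    }
  }

  tokbuf <- NULL
  peek <- function() { if (is.null(tokbuf)) tokbuf <<- next_token(); tokbuf }
  take <- function() { t <- peek(); tokbuf <<- NULL; t }

  repeat {
    t <- take()
    if (is.null(t)) break
    tok <- t$tok
    low <- tolower(tok)
    if (startsWith(low, "data_") && !.is_marked(tok)) {
      flush_block()
      cur <- list(name = substring(tok, 6L), items = list(), loops = list())
      item_lines <- new.env(parent = emptyenv())
    } else if (identical(low, "loop_") && !.is_marked(tok)) {
      if (is.null(cur)) cif_parse_error("loop_ outside any data block", t$line)
      tags <- character(0)
      repeat {
        p <- peek()
        if (!is.null(p) && !.is_marked(p$tok) && startsWith(p$tok, "_")) {
          tags <- c(tags, tolower(take()$tok))
        } else break
      }
      if (!length(tags)) cif_parse_error("loop_ without column tags", t$line)
      vals <- character(0)
      repeat {
        p <- peek()
        if (is.null(p)) break
        pl <- tolower(p$tok)
        if (!.is_marked(p$tok) &&
            (startsWith(p$tok, "_") || startsWith(pl, "data_") ||
             identical(pl, "loop_") || startsWith(pl, "save_"))) break
        vals <- c(vals, .unmark(take()$tok))
      }
      if (!length(vals) || length(vals) %% length(tags) != 0L)
        cif_parse_error(sprintf("loop body (%d values) is not a multiple of %d columns",
                                length(vals), length(tags)), t$line)
      rows <- matrix(vals, ncol = length(tags), byrow = TRUE,
                     dimnames = list(NULL, tags))
      cur$loops[[length(cur$loops) + 1L]] <- list(tags = tags, rows = rows)
    } else if (!.is_marked(tok) && startsWith(tok, "_")) {
      if (is.null(cur)) cif_parse_error("data item outside any data block", t$line)
      v <- take()
      if (is.null(v) || (!.is_marked(v$tok) &&
          (startsWith(tolower(v$tok), "data_") || identical(tolower(v$tok), "loop_") ||
           startsWith(v$tok, "_"))))
        cif_parse_error(sprintf("tag %s has no value", tok), t$line)
      tag <- tolower(tok)
      if (!is.null(cur$items[[tag]]))
        cif_parse_error(sprintf("duplicate tag %s in block '%s'", tag, cur$name), t$line)
      cur$items[[tag]] <- .unmark(v$tok)
    } else if (!.is_marked(tok) && startsWith(low, "save_")) {
      cif_parse_error("save frames are not supported (CIF 1.1 data files only)", t$line)
    } else if (!.is_marked(tok) && identical(low, "global_")) {
      flush_block()
      cur <- list(name = "global", items = list(), loops = list())
    } else {
      cif_parse_error(sprintf("unexpected value '%s'", substr(.unmark(tok), 1, 40)), t$line)
    }
  }
  flush_block()
  if (!length(blocks)) stop_ciflint("no data block found", "ciflint_cif_parse_error")
  nm <- vapply(blocks, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_ciflint(sprintf("duplicate data-block name '%s'", nm[duplicated(nm)][1]),
                 "ciflint_cif_parse_error")
  structure(list(blocks = blocks), class = "ciflint_cif")
}

#' @export
print.ciflint_cif <- function(x, ...) {
  cat(sprintf("CIF document: %d block(s)\n", length(x$blocks)))
  for (b in x$blocks)
    cat(sprintf("  data_%s: %d items, %d loops\n", b$name, length(b$items),
                length(b$loops)))
  invisible(x)
}

.cif_quote <- function(v) {
  if (grepl("\n", v, fixed = TRUE) || nchar(v) > 72)
    return(paste0("\n;", "\n", v, "\n;"))
  if (!nzchar(v)) return("''")
  if (grepl("[ \t']", v) || startsWith(v, "_") || startsWith(v, "#") ||
      grepl("^(data_|loop_|save_)", tolower(v)))
    return(if (grepl("'", v, fixed = TRUE)) paste0('"', v, '"') else paste0("'", v, "'"))
  v
}

#' Serialize a CIF document
#'
#' Deterministic writer: the same document always yields the same bytes.
#' Multi-line values are written as semicolon fields with the payload
#' verbatim.
#'
#' @param doc `ciflint_cif` object.
#' @return A single string of CIF text.
#' @export
write_cif <- function(doc) {
  out <- character(0)
  for (b in doc$blocks) {
    out <- c(out, paste0("data_", b$name))
    for (tag in names(b$items)) {
      v <- .cif_quote(b$items[[tag]])
      out <- c(out, if (startsWith(v, "\n")) paste0(tag, v) else sprintf("%-34s %s", tag, v))
    }
    for (lp in b$loops) {
      out <- c(out, "loop_", paste0(" ", lp$tags))
      rows <- apply(lp$rows, 1L, function(r)
        paste(vapply(r, .cif_quote, character(1)), collapse = " "))
      out <- c(out, rows)
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

## --- numeric values with standard uncertainties ----------------------------

#' Parse a CIF number with a parenthesized standard uncertainty
#'
#' `"1.2345(6)"` yields value 1.2345 with su 0.0006: the uncertainty
#' digits apply to the least significant printed digits.
#'
#' @param raw Text.
#' @return List with `value` and `su` (`NA` when absent).
#' @export
#' @examples
#' parse_uncertain("12.34(12)")  # value 12.34, su 0.12
parse_uncertain <- function(raw) {
  s <- trimws(raw)
  m <- regmatches(s, regexec(
    "^([+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+))(?:[eE]([+-]?[0-9]+))?(?:\\(([0-9]+)\\))?$", s))[[1]]
  if (length(m) == 0)
    stop_ciflint(sprintf("not a numeric value: '%s'", raw), "ciflint_value_error")
  mant <- m[2]
  expo <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  value <- as.numeric(mant) * 10^expo
  su <- NA_real_
  if (nzchar(m[4])) {
    dot <- regexpr(".", mant, fixed = TRUE)
    ndec <- if (dot < 0) 0L else nchar(mant) - dot
    su <- as.numeric(m[4]) * 10^(-ndec + expo)
  }
  list(value = as.numeric(value), su = as.numeric(su))
}

#' Format a value with its standard uncertainty
#'
#' Inverse of [parse_uncertain()] within printed precision; the su is
#' printed with two significant digits when its leading digit is 1, else
#' one.
#' @param value,su Numerics; `su` may be `NA`.
#' @export
format_uncertain <- function(value, su = NA) {
  if (is.na(su) || su <= 0) return(format(value, trim = TRUE, scientific = FALSE))
  e <- floor(log10(su))
  nsig <- if (su / 10^e < 2) 2L else 1L
  ndec <- max(0L, as.integer(nsig - 1L - e))
  d <- round(su * 10^ndec)
  sprintf("%.*f(%d)", ndec, round(value, ndec), d)
}

## numeric item helper: value from a block item, NA when absent/'?'/'.'
block_num <- function(block, tag) {
  v <- block$items[[tag]]
  if (is.null(v) || v %in% c("?", ".")) return(list(value = NA_real_, su = NA_real_))
  tryCatch(parse_uncertain(v), error = function(e) list(value = NA_real_, su = NA_real_))
}

## --- embedded payloads -----------------------------------------------------

.embedded_tags <- c(
  "_shelx_res_file" = "res", "_shelx_hkl_file" = "hkl", "_shelx_fab_file" = "fab",
  "_iucr_refine_instructions_details" = "res",
  "_iucr_refine_reflections_details" = "hkl",
  "_iucr_refine_fcf_details" = "fcf")

.checksum_tags <- c(
  "_shelx_res_file" = "_shelx_res_checksum",
  "_shelx_hkl_file" = "_shelx_hkl_checksum",
  "_shelx_fab_file" = "_shelx_fab_checksum")

#' Reference payload checksum
#'
#' Package-own reference convention for embedded-payload checksums: every
#' byte with code above 32 (printable, space excluded) feeds the linear
#' congruential accumulator `sum <- (1366*sum + 150889 + byte) mod 714025`.
#' Archives produced by other software may follow a different convention;
#' verification against such files is reported as unverified rather than
#' failed when no checksum is present, and mismatches are never escalated
#' beyond a C-level alert.
#'
#' @param text Payload text.
#' @return Integer checksum in `[0, 714025)`.
#' @export
ciflint_checksum <- function(text) {
  bytes <- utf8ToInt(paste(text, collapse = "\n"))
  bytes <- bytes[bytes > 32L]
  sum <- 0
  for (b in bytes) sum <- (1366 * sum + 150889 + b) %% 714025
  as.integer(sum)
}

#' Extract embedded files from a CIF document
#'
#' Recovers SHELX-style RES/HKL/FAB payloads (and their IUCr-dataname
#' equivalents) embedded as semicolon fields, byte-exact, and verifies the
#' declared checksum where one is present.
#'
#' @param doc `ciflint_cif`.
#' @return List of embedded-file records: `kind`, `tag`, `block`, `text`,
#'   `declared_checksum`, `checksum_ok` (one of `"ok"`, `"fail"`,
#'   `"unverified"`).
#' @export
extract_embedded <- function(doc) {
  out <- list()
  for (b in doc$blocks) {
    for (tag in names(.embedded_tags)) {
      v <- b$items[[tag]]
      if (is.null(v) || v %in% c("?", ".")) next
      cs_tag <- .checksum_tags[tag]
      declared <- NA_integer_
      status <- "unverified"
      if (!is.na(cs_tag) && !is.null(b$items[[cs_tag]])) {
        declared <- suppressWarnings(as.integer(b$items[[cs_tag]]))
        if (!is.na(declared))
          status <- if (identical(declared, ciflint_checksum(v))) "ok" else "fail"
      }
      out[[length(out) + 1L]] <- list(kind = unname(.embedded_tags[tag]), tag = tag,
                                      block = b$name, text = v,
                                      declared_checksum = declared,
                                      checksum_ok = status)
    }
  }
  out
}
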