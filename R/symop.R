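## Symmetry-operator algebra.
##
## An operator is a pair (R, t): R a 3x3 integer rotation part with
## det(R) = +/-1, t a translation stored exactly as integer twelfths of a
## cell edge, reduced to [0, 12).  All composition is integer arithmetic,
## so group closure is exact.

symop <- function(R, t12 = c(0L, 0L, 0L)) {
  R <- matrix(as.integer(round(R)), 3, 3)
  t12 <- imod(as.integer(round(t12)), 12L)
  d <- round(det(R))
  if (!d %in% c(-1, 1))
    stop_ciflint("rotation part must have determinant +/-1", "ciflint_symop_error")
  structure(list(R = R, t = t12), class = "ciflint_symop")
}

op_identity <- function() symop(diag(3L))

op_compose <- function(a, b) {
  ## (Ra,ta) o (Rb,tb): x -> Ra(Rb x + tb) + ta
  symop(a$R %*% b$R, a$R %*% b$t + a$t)
}

op_inverse <- function(a) {
  Ri <- matrix(as.integer(round(solve(a$R))), 3, 3)
  symop(Ri, -Ri %*% a$t)
}

op_key <- function(a) paste(c(a$R, a$t), collapse = ",")

op_apply <- function(a, x) {
  ## x: fractional column vector(s), 3 x n
  x <- matrix(x, nrow = 3)
  a$R %*% x + a$t / 12  # length-3 vector recycles down columns
}

## --- xyz triplet formatting / parsing (CIF operator loops) ---------------

fmt_frac12 <- function(n) {
  n <- imod(n, 12L)
  if (n == 0L) return("")
  g <- gcd2(n, 12L)
  sprintf("+%d/%d", n %/% g, 12L %/% g)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Format a symmetry operator as an xyz triplet
#'
#' @param op Internal operator object.
#' @return Text such as `"-x,y+1/2,-z+1/2"`.
#' @keywords internal
op_triplet <- function(op) {
  ax <- c("x", "y", "z")
  parts <- vapply(1:3, function(i) {
    s <- ""
    for (j in 1:3) {
      co <- op$R[i, j]
      if (co != 0) {
        sgn <- if (co > 0) (if (nzchar(s)) "+" else "") else "-"
        mag <- if (abs(co) == 1) "" else as.character(abs(co))
        s <- paste0(s, sgn, mag, ax[j])
      }
    }
    paste0(s, fmt_frac12(op$t[i]))
  }, character(1))
  paste(parts, collapse = ",")
}

#' Parse an xyz triplet into an operator
#'
#' Accepts the usual CIF forms: `"x, -y+1/2, 1/2+z"`, decimal translations
#' (`0.5`), and multi-character coefficients.  Translations must be
#' expressible in twelfths.
#' @param s Triplet text.
#' @keywords internal
parse_triplet <- function(s) {
  comps <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",")[[1]]
  if (length(comps) != 3L)
    stop_ciflint(sprintf("bad xyz triplet '%s'", s), "ciflint_symop_error")
  R <- matrix(0L, 3, 3); t12 <- integer(3)
  for (i in 1:3) {
    expr <- comps[i]
    ## tokenize signed terms
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tok in toks) {
      sgn <- if (startsWith(tok, "-")) -1L else 1L
      body <- sub("^[+-]", "", tok)
      if (grepl("[xyz]", body)) {
        j <- match(sub("^.*?([xyz]).*$", "\\1", body), c("x", "y", "z"))
        co <- sub("[xyz]", "", body)
        co <- sub("\\*$", "", co)
        coef <- if (co == "") 1L else as.integer(co)
        R[i, j] <- R[i, j] + sgn * coef
      } else if (grepl("/", body)) {
        nd <- as.integer(strsplit(body, "/")[[1]])
        v <- 12 * nd[1] / nd[2]
        if (abs(v - round(v)) > 1e-9)
          stop_ciflint(sprintf("translation %s not in twelfths", body), "ciflint_symop_error")
        t12[i] <- t12[i] + sgn * as.integer(round(v))
      } else {
        v <- 12 * as.numeric(body)
        if (abs(v - round(v)) > 1e-6)
          stop_ciflint(sprintf("translation %s not in twelfths", body), "ciflint_symop_error")
        t12[i] <- t12[i] + sgn * as.integer(round(v))
      }
    }
  }
  symop(R, t12)
}

## --- closure ---------------------------------------------------------------

## Closure of a generator list under composition (mod lattice translation).
## Used both by the Hall expander and as the independent oracle in tests.
group_closure <- function(gens, max_order = 192L) {
  ops <- list(op_identity())
  seen <- new.env(parent = emptyenv())
  assign(op_key(ops[[1]]), TRUE, seen)
  queue <- gens
  for (g in queue) {
    if (!exists(op_key(g), seen)) {
      ops[[length(ops) + 1L]] <- g
      assign(op_key(g), TRUE, seen)
    }
  }
  repeat {
    added <- FALSE
    n <- length(ops)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      h <- op_compose(ops[[i]], ops[[j]])
      k <- op_key(h)
      if (!exists(k, seen)) {
        ops[[length(ops) + 1L]] <- h
        assign(k, TRUE, seen)
        added <- TRUE
        if (length(ops) > max_order)
          stop_ciflint("group closure exceeds maximum order (invalid generators)",
                       "ciflint_hall_error")
      }
    }
    if (!added) break
  }
  ops
}
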