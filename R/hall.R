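## Hall-symbol expansion.
##
## Hall symbols encode a lattice letter (with optional leading "-" for a
## centre of inversion at the origin), a short list of rotation generators
## with implied-axis rules, and an optional origin shift in twelfths.
## Expansion decodes the generators and closes them under composition
## together with the centering translations.

.hall_principal <- local({
  m <- function(...) matrix(as.integer(c(...)), 3, 3, byrow = TRUE)
  rz <- list(`1` = diag(3L),
             `2` = m(-1, 0, 0, 0, -1, 0, 0, 0, 1),
             `3` = m(0, -1, 0, 1, -1, 0, 0, 0, 1),
             `4` = m(0, -1, 0, 1, 0, 0, 0, 0, 1),
             `6` = m(1, -1, 0, 1, 0, 0, 0, 0, 1))
  prz <- m(0, -1, 0, -1, 0, 0, 0, 0, -1)   # 2' relative to z: axis a-b
  drz <- m(0, 1, 0, 1, 0, 0, 0, 0, -1)     # 2" relative to z: axis a+b
  star <- m(0, 0, 1, 1, 0, 0, 0, 1, 0)     # 3-fold about [111]
  ## P maps the z context to the x context (conjugation)
  P <- m(0, 0, 1, 1, 0, 0, 0, 1, 0)
  conj <- function(A, B) {
    r <- A %*% B %*% solve(A)
    matrix(as.integer(round(r)), 3, 3)
  }
  ctx <- list(z = diag(3L), x = P, y = P %*% P)
  rot <- list(); prime <- list(); dprime <- list()
  for (ax in names(ctx)) {
    rot[[ax]] <- lapply(rz, conj, A = ctx[[ax]])
    prime[[ax]] <- conj(ctx[[ax]], prz)
    dprime[[ax]] <- conj(ctx[[ax]], drz)
  }
  list(rot = rot, prime = prime, dprime = dprime, star = star)
})

.hall_lattice <- list(
  P = list(),
  A = list(c(0L, 6L, 6L)),
  B = list(c(6L, 0L, 6L)),
  C = list(c(6L, 6L, 0L)),
  I = list(c(6L, 6L, 6L)),
  R = list(c(8L, 4L, 4L), c(4L, 8L, 8L)),
  F = list(c(0L, 6L, 6L), c(6L, 0L, 6L), c(6L, 6L, 0L))
)

.hall_trans <- list(a = c(6L, 0L, 0L), b = c(0L, 6L, 0L), c = c(0L, 0L, 6L),
                    n = c(6L, 6L, 6L), u = c(3L, 0L, 0L), v = c(0L, 3L, 0L),
                    w = c(0L, 0L, 3L), d = c(3L, 3L, 3L))

.hall_axis_vec <- list(x = c(1L, 0L, 0L), y = c(0L, 1L, 0L), z = c(0L, 0L, 1L))

## Parse one rotation field given context from the previous field.
.hall_field <- function(field, pos, prev_n, prev_axis) {
  m0 <- regmatches(field, regexec("^(-?)([1-6])([xyz'\"*]?)([abcnuvwd1-5]*)$", field))[[1]]
  if (length(m0) == 0)
    stop_ciflint(sprintf("malformed Hall rotation field '%s'", field), "ciflint_hall_error")
  improper <- m0[2] == "-"
  n <- as.integer(m0[3])
  axis <- m0[4]
  trans <- m0[5]
  if (axis == "") {
    if (n == 1L) axis <- "z"
    else if (pos == 1L) axis <- "z"
    else if (pos == 2L && n == 2L) axis <- if (prev_n %in% c(2L, 4L)) "x" else "'"
    else if (pos == 3L && n == 3L) axis <- "*"
    else if (n == 3L && pos >= 3L) axis <- "*"
    else stop_ciflint(sprintf("Hall field '%s' needs an explicit axis", field),
                      "ciflint_hall_error")
  }
  R <- if (axis %in% c("x", "y", "z")) {
    .hall_principal$rot[[axis]][[as.character(n)]]
  } else if (axis == "'") {
    if (n != 2L) stop_ciflint("' axis only valid for 2-fold", "ciflint_hall_error")
    .hall_principal$prime[[prev_axis]]
  } else if (axis == "\"") {
    if (n != 2L) stop_ciflint("\" axis only valid for 2-fold", "ciflint_hall_error")
    .hall_principal$dprime[[prev_axis]]
  } else if (axis == "*") {
    if (n != 3L) stop_ciflint("* axis only valid for 3-fold", "ciflint_hall_error")
    .hall_principal$star
  } else stop_ciflint(sprintf("unknown axis '%s'", axis), "ciflint_hall_error")
  if (improper) R <- -R
  t12 <- integer(3)
  if (nzchar(trans)) {
    for (ch in strsplit(trans, "")[[1]]) {
      if (ch %in% names(.hall_trans)) {
        t12 <- t12 + .hall_trans[[ch]]
      } else {
        d <- as.integer(ch)
        if (!(axis %in% c("x", "y", "z")))
          stop_ciflint("screw subscript requires a principal axis", "ciflint_hall_error")
        if (d >= n) stop_ciflint(sprintf("screw subscript %d invalid for %d-fold", d, n),
                                 "ciflint_hall_error")
        t12 <- t12 + .hall_axis_vec[[axis]] * (d * (12L %/% n))
      }
    }
  }
  list(op = symop(R, t12), n = n,
       axis = if (axis %in% c("x", "y", "z")) axis else prev_axis)
}

#' Expand a Hall space-group symbol to its full operator list
#'
#' Decodes the lattice letter, optional leading inversion, rotation
#' generator fields (with the implied-axis conventions) and optional
#' origin shift, then closes the generators under composition together
#' with the centering translations.
#'
#' @param hall Hall symbol, e.g. `"-P 2ybc"` for the cell-choice-1
#'   monoclinic setting with the origin on the inversion centre.
#' @return A list of symmetry operators (identity first); see
#'   [spacegroup_setting()] for the user-facing wrapper.
#' @export
#' @examples
#' length(expand_hall("-P 2ybc"))  # 4 operators
expand_hall <- function(hall) {
  stopifnot(is.character(hall), length(hall) == 1L, nzchar(hall))
  s <- trimws(hall)
  ## origin shift "(u v w)"
  shift <- c(0L, 0L, 0L)
  sh <- regmatches(s, regexec("\\(([^)]*)\\)\\s*$", s))[[1]]
  if (length(sh)) {
    shift <- as.integer(strsplit(trimws(sh[2]), "\\s+")[[1]])
    if (length(shift) != 3L || anyNA(shift))
      stop_ciflint("malformed Hall origin shift", "ciflint_hall_error")
    s <- trimws(sub("\\([^)]*\\)\\s*$", "", s))
  }
  fields <- strsplit(s, "\\s+")[[1]]
  lat <- fields[1]
  centro <- startsWith(lat, "-")
  if (centro) lat <- substring(lat, 2)
  if (!lat %in% names(.hall_lattice))
    stop_ciflint(sprintf("unknown lattice letter '%s' in Hall symbol '%s'", lat, hall),
                 "ciflint_hall_error")
  gens <- list()
  prev_n <- 0L; prev_axis <- "z"
  pos <- 0L
  for (f in fields[-1]) {
    pos <- pos + 1L
    pf <- .hall_field(f, pos, prev_n, prev_axis)
    gens[[length(gens) + 1L]] <- pf$op
    prev_n <- pf$n; prev_axis <- pf$axis
  }
  if (centro) gens[[length(gens) + 1L]] <- symop(-diag(3L))
  for (tv in .hall_lattice[[lat]]) gens[[length(gens) + 1L]] <- symop(diag(3L), tv)
  ops <- group_closure(gens)
  if (any(shift != 0L)) {
    ## conjugate by the origin shift: x' = x + v/12
    ops <- lapply(ops, function(op) symop(op$R, op$t + shift - op$R %*% shift))
  }
  ## canonical order: identity first, remainder sorted by key for stability
  keys <- vapply(ops, op_key, character(1))
  idk <- op_key(op_identity())
  ord <- order(keys != idk, keys)
  ops[ord]
}
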