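## Unit-cell metric utilities.
##
## Convention used throughout the package: fractional coordinates are
## column vectors; the orthogonalization matrix M maps fractional to
## Cartesian coordinates with a along x and b in the xy-plane.

#' Construct a unit cell
#'
#' @param a,b,c Cell edges in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @param su Optional named list/vector of standard uncertainties on the
#'   six parameters (same names).
#' @return An object of class `ciflint_cell` with the metric tensor,
#'   orthogonalization matrix and cell volume precomputed.
#' @export
#' @examples
#' cell(10, 10, 10, 90, 90, 90)$volume
cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90, su = NULL) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180, gamma > 0, gamma < 180)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop_ciflint("cell angles do not define a positive volume", "ciflint_cell_error")
  vol <- a * b * c * sqrt(vfac)
  ## fractional -> Cartesian, a along x, b in xy-plane
  M <- matrix(c(a, b * cg, c * cb,
                0, b * sg, c * (ca - cb * cg) / sg,
                0, 0, vol / (a * b * sg)), 3, 3, byrow = TRUE)
  G <- matrix(c(a * a, a * b * cg, a * c * cb,
                a * b * cg, b * b, b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
                 su = su, volume = vol, M = M, Minv = solve(M), G = G,
                 Gstar = solve(G)),
            class = "ciflint_cell")
}

#' @export
print.ciflint_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

## Cartesian coordinates (3 x n) from fractional (3 x n or length-3)
frac_to_cart <- function(cell, x) cell$M %*% matrix(x, nrow = 3)

## Cartesian length of a fractional difference vector
frac_dist <- function(cell, dx) sqrt(colSums(frac_to_cart(cell, dx)^2))

## Minimum-image Cartesian distance between fractional coordinate sets
frac_dist_mi <- function(cell, dx) {
  dx <- wrap_half(matrix(dx, nrow = 3))
  sqrt(colSums((cell$M %*% dx)^2))
}

## sin(theta)/lambda in 1/Angstrom for index triples (n x 3 matrix)
s_of_hkl <- function(cell, hkl) {
  hkl <- matrix(hkl, ncol = 3)
  ## |h*| = sqrt(h G* h'); s = |h*|/2
  0.5 * sqrt(rowSums((hkl %*% cell$Gstar) * hkl))
}
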