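## Shared fixtures, generated once per test run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

## golden centrosymmetric structure (P2_1/c), with hydrogens and a
## void-filling solvent oxygen
fx_model <- function() memo("model", generate_structure(n_atoms = 8, n_h = 2, seed = 7))

fx_ds_clean <- function() memo("ds_clean", make_dataset(fx_model(), seed = 7))
fx_ds_exact <- function() memo("ds_exact", make_dataset(fx_model(), noise = NULL, seed = 7))
fx_cif_golden <- function() memo("cif_golden", model_to_cif(fx_model(), fx_ds_clean()))

## pseudo-orthogonal monoclinic structure for twin work
fx_twin_model <- function() memo("twin_model",
  generate_structure(n_atoms = 8, n_h = 0, seed = 21, hall = "-P 2ybc",
                     angles = c(90, 90.3, 90), fill_voids = FALSE))

## chiral structure with a resonant scatterer for absolute-structure work
fx_chiral_model <- function() memo("chiral_model",
  generate_structure(n_atoms = 6, elements = c("C", "C", "C", "C", "C", "S"),
                     n_h = 0, hall = "P 2yb", seed = 9, fill_voids = FALSE))

## brute-force group closure used as the independent oracle for Hall
## expansion: compose generators exhaustively
oracle_closure <- function(triplets) {
  gens <- lapply(triplets, ciflint:::parse_triplet)
  ops <- list(ciflint:::op_identity())
  keys <- ciflint:::op_key(ops[[1]])
  repeat {
    added <- FALSE
    for (g in gens) for (o in ops) {
      h <- ciflint:::op_compose(g, o)
      k <- ciflint:::op_key(h)
      if (!k %in% keys) {
        ops <- c(ops, list(h)); keys <- c(keys, k); added <- TRUE
      }
    }
    if (!added) break
  }
  ops
}

op_keys <- function(ops) sort(vapply(ops, ciflint:::op_key, character(1)))
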