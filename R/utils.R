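## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## integer modulo that is always in [0, m)
imod <- function(x, m) ((x %% m) + m) %% m

## fractional part in [0, 1)
frac1 <- function(x) x - floor(x)

## wrap fractional differences into [-0.5, 0.5)
wrap_half <- function(x) x - round(x)

## Evaluate an expression with a temporarily seeded RNG, restoring the
## caller's RNG state afterwards.  All stochastic code in the package goes
## through this so results are reproducible from an explicit seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_ciflint <- function(msg, class, ...) {
  stop(structure(class = c(class, "ciflint_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
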