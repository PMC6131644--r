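## Avogadro constant (1/mol), CODATA 2018 exact value.
.N_A <- 6.02214076e23

#' Avogadro constant
#'
#' @return The Avogadro constant in 1/mol.
#' @export
avogadro <- function() .N_A

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards. `seed = NULL` leaves
## the global stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(structure(class = c("zincleft_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be > 0, got ", x)
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0, got ", x)
  as.numeric(x)
}
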