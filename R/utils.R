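# Internal helpers shared across modules.

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @noRd
abort <- function(msg, class) {
  stop(structure(class = c(class, "ihrc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Evaluate an expression under a temporary RNG seed.
#'
#' Restores the caller's RNG state afterwards so library code never
#' perturbs user-level random streams.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @noRd
stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    abort(sprintf("'%s' must be a single integer, got %s", name,
                  paste(deparse(x), collapse = " ")), "ihrc_config_error")
  as.integer(x)
}
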