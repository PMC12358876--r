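# Boltzmann constant, kcal mol^-1 K^-1
.kB <- 1.987204259e-3

#' Thermal energy k_B T
#'
#' @param temperature Temperature in Kelvin.
#' @return Thermal energy in kcal mol^-1 (0.596 kcal mol^-1 at 300 K).
#' @export
#' @examples
#' kBT(300)
kBT <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  .kB * temperature
}

# Run `expr` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so no global random state leaks.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Scalar positivity check with a uniform error message
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}
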