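# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded
#' generators do not disturb an enclosing simulation.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG stream untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar numeric check with informative error
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' must be supplied", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' = %g is outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# grams per mole of carbon, used for all mol -> g C conversions
.C_MOLAR_MASS <- 12.011

# unit conversion constants kept in one place so budget arithmetic cannot
# silently mix scales: areas cross module boundaries in km^2, daily rates in
# g C m^-2 d^-1, annual totals in Pg C yr^-1
.M2_PER_KM2 <- 1e6
.G_PER_PG <- 1e15
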