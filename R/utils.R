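#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded package operations never perturb a user's
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published tables here round half
#' up, so metric comparisons use this variant.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared argument checks ------------------------------------------------------

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

is_pixel_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) &&
    all(x >= 0) && all(x <= 255)
}
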