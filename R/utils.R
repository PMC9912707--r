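#' Round half away from zero
#'
#' Display rounding used throughout the package: exact halves round up
#' (0.615 -> 0.62), unlike [base::round()]'s round-half-to-even. Published
#' turn-level performance tables use this convention, so reports and print
#' methods do too; raw metric values are always retained unrounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @examples
#' round_half_up(c(0.615, 0.625), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Error helpers: validation errors exit the CLI with status 1, I/O errors
# with status 2.
stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "symtalk_validation_error")
}

stop_io <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "symtalk_io_error")
}

# Run code with a private RNG stream: the caller's .Random.seed is restored
# on exit, so seeded package operations never disturb user-level randomness.
with_private_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_validation("`seed` must be a single non-missing number.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

turn_key <- function(conversation_id, turn_index) {
  paste(conversation_id, turn_index, sep = "\r")
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)
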