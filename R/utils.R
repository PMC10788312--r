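#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# single numeric scalar, finite unless allow_inf
check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "ornacost_invalid_input")
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name),
          class = "ornacost_invalid_input")
  }
  invisible(x)
}

check_finite_vec <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || !all(is.finite(x))) {
    abort(sprintf("`%s` must be numeric and finite.", name),
          class = "ornacost_invalid_input")
  }
  invisible(x)
}

# derive a per-stage seed from a master seed, kept inside 32-bit range
derive_seed <- function(seed, stage) {
  offsets <- c(generate = 11L, gibbs = 23L, game = 37L, misc = 53L)
  off <- offsets[[stage]] %||% 97L
  as.integer((as.numeric(seed) * 101 + off) %% 2147483647)
}
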