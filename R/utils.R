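#' Derive a child seed from a parent seed and a stream label
#'
#' All randomness in the package flows from one integer seed. Stages and
#' subjects get independent streams by hashing the parent seed together with a
#' label, so that adding or reordering one stage never perturbs another.
#'
#' @param seed Integer parent seed.
#' @param ... Labels (strings or integers) identifying the stream.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "rr", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  tokens <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                   character(1))
  h <- abs(as.double(seed)) %% 2147483647
  for (tok in tokens) {
    for (code in utf8ToInt(tok)) h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate code with the session RNG seeded and restored afterwards.
local_seed_eval <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Round half away from zero
#'
#' Base [round()] rounds halves to even; printed tables in this field round
#' halves up, so 0.9295 -> 0.930 at three decimals.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  # the tiny epsilon guards against values like 818.4999999999 that are
  # exact halves in decimal but sit just below .5 in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Shared input checks -------------------------------------------------------

check_numeric_vector <- function(x, arg = "signal") {
  if (!is.numeric(x) || length(x) == 0) {
    abort(sprintf("`%s` must be a non-empty numeric vector.", arg),
          class = "bcgaf_input_error")
  }
  if (anyNA(x)) {
    abort(sprintf("`%s` contains missing values.", arg),
          class = "bcgaf_input_error")
  }
  invisible(x)
}

check_scalar <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite scalar in [%s, %s].", arg, lower, upper),
          class = "bcgaf_parameter_error")
  }
  invisible(x)
}
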