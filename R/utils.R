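# Internal helpers shared across modules.

#' Derive a named random-number substream seed from a master seed
#'
#' All randomness in the package flows from one user-supplied master seed.
#' Each stochastic stage (variant panel, genotypes, BMI noise, disease status,
#' dosage noise, ascertainment, intercept calibration) draws from its own
#' substream so that, e.g., adding variants does not perturb the BMI draws.
#' The substream seed is a deterministic hash of the master seed and the
#' stream name, kept strictly below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param name character stream name.
#' @return An integer seed usable with [set.seed()].
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629 + 1)
}

# Run `expr` under a named substream of `seed` without disturbing the
# caller's RNG state.
with_substream <- function(seed, name, expr) {
  withr::with_seed(substream_seed(seed, name), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 97.5% standard normal quantile used in all CI <-> SE conversions.
Z975 <- stats::qnorm(0.975)

# Median of the 1-df chi-square distribution (genomic-control null median).
CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)

stop_bmistrat <- function(msg, class) {
  stop(structure(
    class = c(class, "bmistrat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
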