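# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` uses banker's rounding; report tables and stratum sample
#' sizes follow the conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Draw from a normal distribution left-truncated at `lower`
# (inverse-CDF method so a single RNG stream suffices).
rtrunc_norm <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mean, sd)
}

# P(X >= threshold) for the same truncated normal.
ptrunc_norm_upper <- function(threshold, mean, sd, lower) {
  if (threshold <= lower) return(1)
  (1 - stats::pnorm(threshold, mean, sd)) / (1 - stats::pnorm(lower, mean, sd))
}

# First non-missing value, elementwise.
coalesce_num <- function(...) {
  args <- list(...)
  out <- args[[1]]
  for (v in args[-1]) {
    miss <- is.na(out)
    out[miss] <- v[miss]
  }
  out
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

stop_if_not_prob <- function(x, what) {
  if (!is_prob(x)) {
    stop(sprintf("parameterization error: `%s` must be a single probability in [0, 1]", what),
         call. = FALSE)
  }
  invisible(x)
}

# Collapse a logical reason-code matrix into semicolon-joined strings.
join_codes <- function(flags) {
  codes <- colnames(flags)
  apply(flags, 1L, function(row) paste(codes[row], collapse = ";"))
}
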