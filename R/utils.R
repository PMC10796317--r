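# Internal numerical helpers.

# Third standardized moment (no small-sample correction).
moment_skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

# Fourth standardized moment (normal -> 3, no correction).
moment_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^4) / s2^2
}

# Format doubles so that read-back with as.numeric() is bit-exact.
num_to_chr <- function(x) sprintf("%.17g", x)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_bcg <- function(..., class) {
  stop(structure(
    class = c(class, "bcgco_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
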