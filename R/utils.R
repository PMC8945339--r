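# internal helpers shared across modules

abort_input <- function(msg) stop(msg, call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

# central-difference first derivative with one-sided ends, constant step dt
finite_diff <- function(y, dt) {
  n <- length(y)
  if (n < 2L) abort_input("need at least 2 samples to differentiate")
  if (n == 2L) return(rep((y[2L] - y[1L]) / dt, 2L))
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / dt
  d[n] <- (y[n] - y[n - 1L]) / dt
  d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * dt)
  d
}

# standard error of the mean; NA for n < 2
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
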