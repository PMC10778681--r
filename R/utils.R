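# Small internal vector helpers shared across modules.

ANGSTROM_PER_NM <- 10

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Wrap angle differences into the minimal signed interval
#'
#' Maps each value into `(-pi, pi]`, the minimal signed rotation equivalent
#' modulo `2*pi`. Used for all periodic Euler-angle differences.
#'
#' @param x numeric vector of angles (rad).
#' @return numeric vector in `(-pi, pi]`.
#' @keywords internal
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

# format a numeric for deterministic text output (10 significant digits)
num10 <- function(x) formatC(x, digits = 10L, format = "g")
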