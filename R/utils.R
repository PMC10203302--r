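# Shared numerical helpers: low-discrepancy sequences, rotations, quadrature.

#' Radical-inverse (van der Corput) sequence in a given base
#' @noRd
radical_inverse <- function(i, base) {
  f <- 1
  r <- numeric(length(i))
  i <- as.integer(i)
  repeat {
    live <- i > 0L
    if (!any(live)) break
    f <- f / base
    r[live] <- r[live] + f * (i[live] %% base)
    i <- i %/% base
  }
  r
}

#' Quasi-random rotation matrices
#'
#' Generates `n` quasi-uniform rotation matrices on SO(3) by mapping a
#' Halton sequence (bases 2, 3, 5) through Shoemake's uniform-quaternion
#' construction. A seeded Cranley-Patterson shift randomises the sequence
#' while keeping its low discrepancy, so repeated calls with the same seed
#' give identical rotations.
#'
#' @param n number of rotations.
#' @param seed integer seed for the randomised shift.
#' @return a `3 x 3 x n` array of rotation matrices.
#' @export
quasi_rotations <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  shift <- with_seed(seed, runif(3))
  idx <- seq_len(n)
  u1 <- (radical_inverse(idx, 2) + shift[1]) %% 1
  u2 <- (radical_inverse(idx, 3) + shift[2]) %% 1
  u3 <- (radical_inverse(idx, 5) + shift[3]) %% 1
  # Shoemake (1992) uniform quaternions
  q <- cbind(sqrt(1 - u1) * sin(2 * pi * u2),
             sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3),
             sqrt(u1) * cos(2 * pi * u3))
  out <- array(0, dim = c(3, 3, n))
  for (k in seq_len(n)) out[, , k] <- quaternion_to_matrix(q[k, ])
  out
}

#' @noRd
quaternion_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#' @noRd
axis_angle_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               nrow = 3, byrow = TRUE)
  diag(3) * c0 + s0 * ux + (1 - c0) * tcrossprod(u)
}

#' Trapezoid rule on an (unevenly spaced) grid
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
vnorm <- function(v) sqrt(sum(v^2))
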