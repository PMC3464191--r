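# Small geometric helpers shared across modules.

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 axis vector (need not be normalized).
#' @param angle rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

# rotate row-vectors about the z axis by `angle` degrees
rotate_z <- function(xyz, angle) {
  a <- angle * pi / 180
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  xyz %*% t(R)
}

# apply f under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
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

# evenly distributed unit vectors on a sphere (deterministic Fibonacci spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
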