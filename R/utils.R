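# internal helpers shared across modules

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# sin(x)/x with the x -> 0 limit
.sinc <- function(x) {
  out <- sin(x) / x
  out[x == 0] <- 1
  out
}

# renormalize a weight vector; message if it was off by more than tol
.normalize_weights <- function(w, what = "weights", tol = 1e-6, quiet = FALSE) {
  .assert(all(is.finite(w)), "%s contain non-finite values", what)
  .assert(all(w >= 0), "%s must be non-negative", what)
  s <- sum(w)
  .assert(s > 0, "%s sum to zero", what)
  if (!quiet && abs(s - 1) > tol) {
    message(sprintf("renormalizing %s (sum was %.8g)", what, s))
  }
  w / s
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix about a unit axis
.rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotate rows of x about a point by rotation matrix R
.rotate_about <- function(x, R, origin) {
  sweep(sweep(x, 2, origin) %*% t(R), 2, origin, "+")
}

# weighted mean with normalized weights
.wmean <- function(x, w) sum(x * w) / sum(w)

.random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}
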