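# Shared fixtures, built in code.

# a small coordinate-table ensemble file: 3 frames x 5 beads
write_table_fixture <- function(path, drop_bead_in_frame = NULL) {
  set.seed(123)
  lines <- "# frame resno resname x y z"
  for (f in 1:3) {
    for (b in 1:5) {
      if (!is.null(drop_bead_in_frame) && f == drop_bead_in_frame && b == 5) next
      lines <- c(lines, sprintf("%d %d ALA %.6f %.6f %.6f", f, b,
                                b * 3.8 + f / 10, f * 0.5, 0))
    }
  }
  writeLines(lines, path)
  path
}

# exact Gaussian (Guinier) curve
gaussian_profile <- function(rg, i0 = 100, q = seq(0.005, 0.03, length.out = 25),
                             sigma_frac = 0.01) {
  I <- i0 * exp(-q^2 * rg^2 / 3)
  scattering_profile(q, I, sigma_frac * I)
}

# tiny two-frame ensemble with hand-set label distances (beads on the x axis)
two_frame_distance_ensemble <- function(d1, d2, n_beads = 4) {
  f1 <- cbind(seq(0, by = d1, length.out = n_beads), 0, 0)
  f2 <- cbind(seq(0, by = d2, length.out = n_beads), 0, 0)
  conformational_ensemble(list(f1, f2))
}

# brute-force O(n^2) Debye reference
debye_brute <- function(coords, f, q_grid) {
  n <- nrow(coords)
  f <- rep_len(f, n)
  vapply(q_grid, function(qq) {
    s <- 0
    for (a in 1:n) for (b in 1:n) {
      r <- sqrt(sum((coords[a, ] - coords[b, ])^2))
      s <- s + f[a] * f[b] * (if (r == 0) 1 else sin(qq * r) / (qq * r))
    }
    s
  }, numeric(1))
}

.normalize_runif <- function(n) {
  w <- runif(n)
  w / sum(w)
}

# exhaustive primal minimization of L = chi2/2 + theta*KL over the 2-simplex
primal_grid_min <- function(Fm, y, sig, w0, theta, step = 2e-3) {
  g <- seq(0, 1, by = step)
  grid <- expand.grid(w1 = g, w2 = g)
  grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
  W <- cbind(grid$w1, grid$w2, pmax(0, 1 - grid$w1 - grid$w2))
  calc <- W %*% t(Fm)
  chi2 <- rowSums(sweep(sweep(calc, 2, y), 2, sig, "/")^2)
  lw <- log(sweep(W, 2, w0, "/"))
  kl <- rowSums(ifelse(W > 0, W * lw, 0))
  min(0.5 * chi2 + theta * kl)
}
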