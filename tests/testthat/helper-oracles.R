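# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Two-site exchange spectrum by per-frequency 2x2 complex matrix inversion.
bm_matrix_oracle <- function(params, nu) {
  vapply(nu, function(v) {
    B <- matrix(c(
      complex(real = -params$r2_cis,
              imaginary = 2 * pi * params$nu_cis) - params$k_ct,
      params$k_tc,
      params$k_ct,
      complex(real = -params$r2_trans,
              imaginary = 2 * pi * params$nu_trans) - params$k_tc
    ), 2, 2, byrow = TRUE)
    A <- diag(2) * complex(imaginary = 2 * pi * v) - B
    2 * Re(sum(solve(A, c(params$p_cis, params$p_trans))))
  }, numeric(1))
}

# Halfspace depth by brute force over an angular grid of directions.
depth_grid_oracle <- function(point, cloud, n_dir = 3600) {
  z <- sweep(as.matrix(cloud), 2, as.numeric(point))
  phis <- seq(0, 2 * pi, length.out = n_dir + 1)[-(n_dir + 1)]
  min(vapply(phis, function(phi) {
    sum(z %*% c(cos(phi), sin(phi)) >= -1e-9)
  }, numeric(1)))
}

# Exact two-sided Spearman permutation p-value by full enumeration (n <= 7).
perm_spearman_oracle <- function(x, y) {
  n <- length(x)
  perms <- gtools_permutations(n)
  rho_obs <- stats::cor(rank(x), rank(y))
  rx <- rank(x)
  ry <- rank(y)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  p_ge <- mean(rhos >= rho_obs - 1e-12)
  p_le <- mean(rhos <= rho_obs + 1e-12)
  min(1, 2 * min(p_ge, p_le))
}

# All permutations of 1..n (recursive; fine for n <= 7).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Closed-form free ligand for a single site (quadratic mass balance).
quadratic_free_ligand <- function(x_total, m_total, kd) {
  b <- m_total + kd - x_total
  (-b + sqrt(b^2 + 4 * kd * x_total)) / 2
}

# Simple noiseless Lorentzian spectrum builder.
lorentzian_spectrum <- function(nu, nu0, r2, height = 1, base = 0) {
  new_spectrum(nu, height * r2^2 / (r2^2 + (2 * pi * (nu - nu0))^2) + base,
               noise_sigma = 0)
}

# Apply a rigid rotation (z axis, angle th) + translation to a model.
rigid_move <- function(model, th = 0.6, shift = c(4, -7, 2)) {
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% R
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  model
}
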