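# Independent brute-force implementations used as oracles. These
# deliberately use different primitives than the package code paths.

kT300 <- 0.0019872041 * 300

# --- geometry oracles -------------------------------------------------------

frame_mat <- function(frame) {
  m <- as.matrix(frame[, c("x", "y", "z")])
  rownames(m) <- frame$atom
  m
}

oracle_angle <- function(p1, p2, p3) {
  # plain law-of-cosines route
  a <- sqrt(sum((p1 - p2)^2))
  b <- sqrt(sum((p3 - p2)^2))
  c2 <- sum((p1 - p3)^2)
  acos(max(-1, min(1, (a^2 + b^2 - c2) / (2 * a * b)))) * 180 / pi
}

oracle_dihedral <- function(p1, p2, p3, p4) {
  # Gram-Schmidt projection route (praxeolitic formulation)
  b0 <- p1 - p2
  b1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x) * 180 / pi
}

oracle_fl <- function(m) {
  # 2-D coordinates of O3' in the plane perpendicular to the C->Ocarb axis,
  # basis built with prcomp for the carbonyl plane fit
  a <- m["Ocarb", ] - m["Ccarb", ]
  a <- a / sqrt(sum(a^2))
  pc <- stats::prcomp(m[c("Ccarb", "Ocarb", "Ca", "Ob"), ], center = TRUE)
  n <- pc$rotation[, 3]
  e_ob <- m["Ob", ] - m["Ccarb", ]
  e_ob <- e_ob - sum(e_ob * a) * a
  e_ob <- e_ob / sqrt(sum(e_ob^2))
  handed <- c(a[2] * e_ob[3] - a[3] * e_ob[2],
              a[3] * e_ob[1] - a[1] * e_ob[3],
              a[1] * e_ob[2] - a[2] * e_ob[1])
  if (sum(n * handed) < 0) n <- -n
  n_perp <- n - sum(n * a) * a
  n_perp <- n_perp / sqrt(sum(n_perp^2))
  v <- m["O3p", ] - m["Ccarb", ]
  v <- v - sum(v * a) * a
  ang <- atan2(sum(v * e_ob), sum(v * n_perp)) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(frame, rot, shift) {
  m <- frame_mat(frame) %*% t(rot)
  m <- sweep(m, 2, shift, `+`)
  out <- frame
  out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
  out
}

reflect_z <- function(frame) {
  out <- frame
  out$z <- -out$z
  out
}

# a well-separated random frame (resampled until non-degenerate)
random_frame <- function() {
  repeat {
    m <- matrix(stats::rnorm(24, sd = 2), ncol = 3)
    rownames(m) <- atom_labels()
    d <- as.matrix(dist(m))
    if (min(d[upper.tri(d)]) > 0.3) break
  }
  tibble::tibble(frame = 1L, atom = rownames(m),
                 x = m[, 1], y = m[, 2], z = m[, 3])
}

# --- WHAM oracles -----------------------------------------------------------

# binless MBAR-style estimator, self-consistent over individual samples;
# independent of the package's histogram WHAM path
mbar_oracle_pmf <- function(samples_by_window, windows, kT, breaks,
                            tol = 1e-9, max_iter = 20000) {
  x <- unlist(samples_by_window, use.names = FALSE)
  Ni <- lengths(samples_by_window)
  U <- vapply(seq_len(nrow(windows)), function(i) {
    0.5 * windows$force_constant[i] * (x - windows$center[i])^2
  }, numeric(length(x)))
  f <- rep(0, nrow(windows))
  ld <- function(f) {
    log(rowSums(sweep(exp(sweep(-U / kT, 2, f / kT, `+`)), 2, Ni, `*`)))
  }
  for (it in seq_len(max_iter)) {
    logdenom <- ld(f)
    fnew <- -kT * (log(colSums(exp(-U / kT - logdenom))))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  logdenom <- ld(f)
  w <- exp(-logdenom)
  bin <- findInterval(x, breaks)
  p <- vapply(seq_len(length(breaks) - 1),
              function(b) sum(w[bin == b]), numeric(1))
  pmf <- -kT * log(p)
  list(pmf = pmf, f = f)
}

# analytic stationary density of a surface + harmonic bias on a grid
biased_density_cdf <- function(surface, center, k, kT, grid) {
  u <- surface_energy(surface, grid) + 0.5 * k * (grid - center)^2
  p <- exp(-(u - min(u)) / kT)
  cdf <- cumsum(p)
  cdf / cdf[length(cdf)]
}

ks_distance <- function(samples, grid, cdf) {
  ec <- stats::ecdf(samples)
  max(abs(ec(grid) - cdf))
}

# small campaign used by several WHAM tests: 1-gaussian well, 9 windows
small_campaign <- function(n_samples = 800, seed = 5, k = 100,
                           centers = seq(-1, 1, by = 0.25)) {
  surf <- model_surface(tibble::tibble(amplitude = -5, center = 0, width = 1),
                        domain = c(-2, 2))
  w <- tibble::tibble(index = seq_along(centers) - 1L, center = centers,
                      force_constant = k, n_equil_samples = 200L,
                      n_prod_samples = as.integer(n_samples),
                      sample_interval = 5)
  camp <- generate_campaign(surf, w, langevin_params(seed = seed))
  list(surface = surf, windows = w, campaign = camp)
}
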