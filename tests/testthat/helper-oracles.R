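# Independent oracles and fixture builders used across the suite.

# A batch of random synthetic records with varied architecture.
random_records <- function(n, seed = 1000) {
  lapply(seq_len(n), function(i) {
    spec <- synthetic_protein_spec(
      n_tm_segments = 2L + (seed + i) %% 11L,
      tm_length = 17L + (seed + 3L * i) %% 8L,
      loop_length = 5L + (seed + 7L * i) %% 25L,
      livf_fraction_tm = 0.25 + 0.5 * ((seed + i) %% 10L) / 10,
      seed = seed + i)
    generate_membrane_protein(spec)
  })
}

# Random peptide sequences over the 20-letter alphabet.
random_peptides <- function(n, len = 30L, seed = 2000) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, {
    replicate(n, paste(sample(aas, len, replace = TRUE), collapse = ""))
  })
}

# Grid-scan pI oracle: evaluates the Henderson-Hasselbalch charge on a
# dense pH grid (vectorised over the grid) and returns the pH of minimal
# |charge|.  Same charge constants as the package, independent solver.
grid_pi_oracle <- function(sequence, model = charge_model(),
                           step = 1e-4) {
  chars <- strsplit(sequence, "")[[1]]
  counts <- table(factor(chars, levels = strsplit(
    "ACDEFGHIKLMNPQRSTVWYX", "")[[1]]))
  nt <- model$positive[["Nterm"]]
  if (chars[1] %in% names(model$nterm_by_residue)) {
    nt <- model$nterm_by_residue[[chars[1]]]
  }
  ct <- model$negative[["Cterm"]]
  last <- chars[length(chars)]
  if (last %in% names(model$cterm_by_residue)) {
    ct <- model$cterm_by_residue[[last]]
  }
  pks_pos <- c(nt, rep(model$positive[["K"]], counts[["K"]]),
               rep(model$positive[["R"]], counts[["R"]]),
               rep(model$positive[["H"]], counts[["H"]]))
  pks_neg <- c(ct, rep(model$negative[["D"]], counts[["D"]]),
               rep(model$negative[["E"]], counts[["E"]]),
               rep(model$negative[["C"]], counts[["C"]]),
               rep(model$negative[["Y"]], counts[["Y"]]))
  grid <- seq(0, 14, by = step)
  qpos <- rowSums(1 / (1 + 10^(outer(grid, pks_pos, `-`))))   # 10^(pH-pK)
  qneg <- rowSums(1 / (1 + 10^(-outer(grid, pks_neg, `-`))))  # 10^(pK-pH)
  grid[which.min(abs(qpos - qneg))]
}

# Quasi-uniform unit vectors (golden-spiral), for the rotation-grid oracle.
fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(x * x * C + c_, x * y * C - z * s, x * z * C + y * s,
           y * x * C + z * s, y * y * C + c_, y * z * C - x * s,
           z * x * C - y * s, z * y * C + x * s, z * z * C + c_),
         nrow = 3, byrow = TRUE)
}

# Brute-force minimum RMSD over a dense rotation grid (quasi-uniform
# rotation axes x 2-degree angle steps), translations handled exactly by
# centering.  For each axis the squared deviation is expanded by the
# Rodrigues formula into a closed quadratic in (cos, sin), so every
# (axis, angle) pair on the grid is evaluated exactly.  Independent of
# the SVD path.
grid_rmsd_oracle <- function(a, b, n_axes = 4000L, angle_step_deg = 2) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  n <- nrow(a0)
  axes <- fib_sphere(n_axes)
  ang <- seq(0, 2 * pi, by = angle_step_deg * pi / 180)
  cs <- cos(ang); sn <- sin(ang)
  best <- Inf
  for (k in seq_len(n_axes)) {
    e <- axes[k, ]
    proj <- drop(b0 %*% e)                      # (b . e) per point
    z <- outer(proj, e)                         # axial component
    x <- b0                                     # rotated: x c + y s + z(1-c)
    y <- cbind(e[2] * b0[, 3] - e[3] * b0[, 2], # e x b
               e[3] * b0[, 1] - e[1] * b0[, 3],
               e[1] * b0[, 2] - e[2] * b0[, 1])
    u <- x - z; w <- z - a0
    uu <- sum(u * u); vv <- sum(y * y); ww <- sum(w * w)
    uv <- sum(u * y); uw <- sum(u * w); vw <- sum(y * w)
    d2 <- cs^2 * uu + sn^2 * vv + ww +
      2 * (cs * sn * uv + cs * uw + sn * vw)
    m <- min(d2)
    if (m < best) best <- m
  }
  sqrt(max(best, 0) / n)
}

# Random proper rotation for invariance tests.
rand_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
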