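# Independent oracles, kept free of the package's superposition code path.

# Brute-force rotation-grid RMSD search at 1-degree final resolution.
# For a fixed rotation R the optimal translation matches centroids, and the
# residual reduces to  n * rmsd(R)^2 = ||P||^2 + ||Q||^2 - 2 tr(R C)  with
# C = P'Q on centered coordinates, so the grid search only needs tr(R C) per
# rotation. A full 6-degree ZYZ Euler scan locates the basin; a 1-degree scan
# of the surrounding (+/- 6 degree)^3 box refines it.
# `levels` are successive grid steps in degrees: the first level scans all of
# SO(3); each later level rescans a +/- 1.5-previous-step box around the
# incumbent. levels = c(6, 1) is the 1-degree-resolution search; appending
# finer steps gives the grid-refined search used for 1e-3 A comparisons.
rmsd_grid_oracle <- function(mobile, target, levels = c(6, 1)) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  C <- crossprod(P, Q)
  n <- nrow(P)
  const <- sum(P^2) + sum(Q^2)

  trace_on_grid <- function(alpha, beta, gamma) {
    g <- expand.grid(a = alpha, b = beta, g = gamma)
    ca <- cos(g$a); sa <- sin(g$a)
    cb <- cos(g$b); sb <- sin(g$b)
    cg <- cos(g$g); sg <- sin(g$g)
    # ZYZ Euler rotation R = Rz(a) %*% Ry(b) %*% Rz(g), entries expanded
    r11 <- ca * cb * cg - sa * sg; r12 <- -ca * cb * sg - sa * cg; r13 <- ca * sb
    r21 <- sa * cb * cg + ca * sg; r22 <- -sa * cb * sg + ca * cg; r23 <- sa * sb
    r31 <- -sb * cg;               r32 <- sb * sg;                 r33 <- cb
    tr <- r11 * C[1, 1] + r12 * C[2, 1] + r13 * C[3, 1] +
          r21 * C[1, 2] + r22 * C[2, 2] + r23 * C[3, 2] +
          r31 * C[1, 3] + r32 * C[2, 3] + r33 * C[3, 3]
    list(tr = tr, g = g)
  }

  deg <- pi / 180
  step <- levels[1]
  crs <- trace_on_grid(seq(0, 360 - step, by = step) * deg,
                       seq(0, 180, by = step) * deg,
                       seq(0, 360 - step, by = step) * deg)
  best <- crs$g[which.max(crs$tr), ]
  best_tr <- max(crs$tr)
  for (lev in seq_along(levels)[-1]) {
    prev <- levels[lev - 1]
    step <- levels[lev]
    fn <- trace_on_grid(best$a + seq(-1.5 * prev, 1.5 * prev, by = step) * deg,
                        best$b + seq(-1.5 * prev, 1.5 * prev, by = step) * deg,
                        best$g + seq(-1.5 * prev, 1.5 * prev, by = step) * deg)
    best <- fn$g[which.max(fn$tr), ]
    best_tr <- max(best_tr, max(fn$tr))
  }
  sqrt(max(0, (const - 2 * best_tr) / n))
}

# Adjusted Rand index by its contingency-table definition
ari_oracle <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
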