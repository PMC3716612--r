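# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately naive (double loops, dense grids, direct enumeration) and
# never reuse the code paths they check.

# Hand-written minimal 1-residue ALA PDB (5 heavy atoms).
ala_pdb_text <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.697   7.138  -4.905  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.432   7.500  -5.825  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      10.521   6.213  -4.109  1.00  0.00           C",
    "TER       6      ALA A   1",
    "END")
}

write_tmp_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# A small cached PMF table derived from ideal peptides.
test_pmf_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- suppressWarnings(derive_pmf_table(list(
        build_ideal_peptide(10, topology = "helix"),
        build_ideal_peptide(10, topology = "strand"),
        build_ideal_peptide(12, topology = "helix-loop-helix")
      )))
    }
    tab
  }
})

# Rigidly transform a model (rotation by `deg` about `axis`, then shift).
rigid_transform <- function(model, axis = c(1, 2, 3), deg = 37,
                            shift = c(5, -3, 2)) {
  R <- refine3d:::rotation_about_axis(axis, refine3d:::deg2rad(deg))
  set_coords(model, sweep(coords(model) %*% t(R), 2, shift, `+`))
}

# Central finite-difference gradient of a scalar energy functional over a
# sample of coordinates.
fd_gradient_check <- function(eval_fn, xyz, n_sample = 30, h = 1e-5,
                              seed = 11) {
  res <- eval_fn(xyz)
  set.seed(seed)
  idx <- sample(length(xyz), min(n_sample, length(xyz)))
  fd <- vapply(idx, function(k) {
    xp <- xyz; xp[k] <- xp[k] + h
    xm <- xyz; xm[k] <- xm[k] - h
    (eval_fn(xp)$E - eval_fn(xm)$E) / (2 * h)
  }, numeric(1))
  an <- res$G[idx]
  max(abs(an - fd) / pmax(1e-6, abs(an) + abs(fd)))
}

# Brute-force RMSD minimization oracle: dense rotation sampling (uniform
# random quaternions) followed by Nelder-Mead refinement of the best
# candidates.  Independent of the Kabsch code path.
quaternion_grid_rmsd <- function(P, Q, n_grid = 200000, seed = 99) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  set.seed(seed)
  qs <- matrix(stats::rnorm(4 * n_grid), ncol = 4)
  qs <- qs / sqrt(rowSums(qs^2))
  rmsd_of_q <- function(q) {
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
    sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  }
  vals <- apply(qs, 1, rmsd_of_q)
  best <- order(vals)[1:5]
  refined <- vapply(best, function(b) {
    stats::optim(qs[b, ], function(q) rmsd_of_q(q / sqrt(sum(q^2))),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$value
  }, numeric(1))
  min(refined)
}

# All 2^n signed-rank statistics, built bit by bit (independent oracle).
wilcoxon_enumeration_oracle <- function(x) {
  x <- x[x != 0]
  r <- rank(abs(x))
  n <- length(x)
  V_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.numeric(signs %*% r)
  center <- sum(r) / 2
  mean(abs(V_all - center) >= abs(V_obs - center) - 1e-9)
}
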