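# The six quality metrics against independent oracles and invariances.

test_that("identical structures give the identity metric vector", {
  m <- build_ideal_peptide(12, topology = "helix-loop-helix")
  mv <- evaluate_all(m, m)
  expect_equal(mv$gdt_ts, 1.0)
  expect_equal(mv$rmsd, 0.0, tolerance = 1e-10)
  expect_equal(mv$gdc_sc, 1.0)
  expect_equal(mv$sphere_grinder, 1.0)
  expect_equal(mv$cad_aa, 1.0)
  expect_equal(mv$aligned_length, 12)
})

test_that("superposition metrics are invariant under rigid transforms of
           either structure", {
  m <- build_ideal_peptide(10, topology = "helix")
  t1 <- rigid_transform(m, deg = 37)
  expect_equal(kabsch_rmsd(t1, m)$rmsd, 0, tolerance = 1e-10)
  expect_equal(gdt_ts(t1, m), 1.0)
  expect_equal(gdc_sc(t1, m), 1.0)
  expect_equal(sphere_grinder(t1, m), 1.0)
  mv <- evaluate_all(t1, m)
  expect_equal(mv$mp_proxy, mp_proxy(m), tolerance = 1e-9)
})

test_that("kabsch_rmsd matches the quaternion-grid oracle on an asymmetric
           4-point configuration", {
  set.seed(17)
  P <- matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0, 1, 1, 2.5), 4, 3, byrow = TRUE)
  Q <- P + matrix(rnorm(12, sd = 0.3), 4, 3)
  fit <- kabsch(P, Q)
  oracle <- quaternion_grid_rmsd(P, Q)
  expect_lt(abs(fit$rmsd - oracle), 1e-4)
  expect_lte(fit$rmsd, oracle + 1e-9)  # Kabsch is the true optimum
  # rotation must be proper (no reflection)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
})

test_that("kabsch_rmsd requires at least 3 paired atoms", {
  m <- build_ideal_peptide(4, sequence = "AAAA")
  frag <- atomic_model(m$atoms[m$atoms$resseq <= 2, ])
  expect_error(kabsch_rmsd(frag, frag, "CA"), "3 paired")
})

test_that("gdt_ts is 0.95 when 1 of 20 CA atoms is displaced far away", {
  m <- build_ideal_peptide(20, topology = "helix")
  m3 <- m
  xyz <- coords(m3)
  ca1 <- refine3d:::atom_in_residue(m, 1, "CA")
  xyz[ca1, ] <- xyz[ca1, ] + c(100, 0, 0)
  m3 <- set_coords(m3, xyz)
  expect_equal(gdt_ts(m3, m), 0.95)
})

test_that("gdt_ts is bounded below by the 8 A term alone", {
  set.seed(31)
  m <- build_ideal_peptide(14, topology = "helix-loop-helix")
  d <- set_coords(m, coords(m) + matrix(rnorm(nrow(m$atoms) * 3, sd = 1.2),
                                        ncol = 3))
  g <- gdt_ts(d, m)
  p8 <- refine3d:::max_fraction_within(
    refine3d:::pair_atoms(d, m, "CA")$P,
    refine3d:::pair_atoms(d, m, "CA")$Q, 8)
  expect_gte(g, p8 / 4 - 1e-12)
})

test_that("gdc_sc matches a direct weighted-sum evaluation", {
  set.seed(12)
  m <- build_ideal_peptide(10, topology = "helix")
  d <- set_coords(m, coords(m) + matrix(rnorm(nrow(m$atoms) * 3, sd = 0.4),
                                        ncol = 3))
  got <- gdc_sc(d, m)
  # oracle: same characteristic atoms, direct formula
  P <- list(); Q <- list()
  for (r in seq_len(10)) {
    ca <- refine3d:::CHARACTERISTIC_ATOM[m$residues$resname[r]]
    i <- refine3d:::atom_in_residue(d, r, ca)
    j <- refine3d:::atom_in_residue(m, r, ca)
    P[[r]] <- coords(d)[i, ]; Q[[r]] <- coords(m)[j, ]
  }
  P <- do.call(rbind, P); Q <- do.call(rbind, Q)
  w <- (10:1) / sum(10:1)
  oracle <- sum(w * vapply(1:10, function(k) {
    refine3d:::max_fraction_within(P, Q, 0.5 * k)
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-12)
  # fully scrambled side chains with an intact backbone score 0
  far <- d
  xyz <- coords(far)
  set.seed(40)
  for (r in seq_len(10)) {
    ca <- refine3d:::CHARACTERISTIC_ATOM[m$residues$resname[r]]
    i <- refine3d:::atom_in_residue(far, r, ca)
    # scatter characteristic atoms hundreds of Angstrom apart so no rigid
    # superposition brings any of them near its reference position
    xyz[i, ] <- 400 * rnorm(3)
  }
  expect_equal(gdc_sc(set_coords(far, xyz), m), 0)
})

test_that("per-sphere RMSDs match an independent per-sphere Kabsch
           oracle", {
  set.seed(9)
  m <- build_ideal_peptide(15, topology = "helix-loop-helix")
  d <- set_coords(m, coords(m) + matrix(rnorm(nrow(m$atoms) * 3, sd = 0.5),
                                        ncol = 3))
  pa <- refine3d:::pair_atoms(d, m, "all")
  ca_rows <- which(pa$name == "CA")
  score <- sphere_grinder(d, m)
  # oracle: explicit double loop over reference spheres
  rmsds <- c()
  for (q in ca_rows) {
    center <- pa$Q[q, ]
    sph <- which(sqrt(rowSums(sweep(pa$Q, 2, center)^2)) <= 6)
    if (length(sph) < 3) next
    # independent superposition: centered SVD from first principles
    A <- sweep(pa$P[sph, ], 2, colMeans(pa$P[sph, ]))
    B <- sweep(pa$Q[sph, ], 2, colMeans(pa$Q[sph, ]))
    sv <- svd(t(A) %*% B)
    R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    rmsds <- c(rmsds, sqrt(mean(rowSums((A %*% t(R) - B)^2))))
  }
  oracle <- mean(c(mean(rmsds < 2), mean(rmsds < 4)))
  expect_equal(score, oracle, tolerance = 1e-6)
})

test_that("contact areas agree with a dense-sampling oracle on a
           two-residue system", {
  m <- build_ideal_peptide(4, sequence = "AAAA")
  a2 <- refine3d:::contact_areas(m, n_points = 256)
  a_dense <- refine3d:::contact_areas(m, n_points = 8192)
  common <- intersect(names(a2), names(a_dense))
  expect_gt(length(common), 0)
  big <- a_dense[common] > 2   # compare areas that are not sampling noise
  expect_true(all(abs(a2[common][big] - a_dense[common][big]) /
                    a_dense[common][big] < 0.05))
})

test_that("cad_aa is 1 for identical structures and 0 for a chain pulled
           apart", {
  m <- build_ideal_peptide(8, topology = "helix")
  expect_equal(cad_aa(m, m), 1.0)
  xyz <- coords(m)
  for (r in seq_len(8)) {
    idx <- m$residues$atom_index[[r]]
    xyz[idx, 1] <- xyz[idx, 1] + 100 * r
  }
  expect_equal(cad_aa(set_coords(m, xyz), m), 0.0)
})

test_that("the clash count matches an all-pairs overlap oracle", {
  set.seed(23)
  m <- build_ideal_peptide(6, sequence = "ALVASN")
  d <- set_coords(m, coords(m) + matrix(rnorm(nrow(m$atoms) * 3, sd = 0.35),
                                        ncol = 3))
  got <- clash_count(d)
  xyz <- coords(d)
  sep <- bond_separation_sets(d, 3)
  vdw <- refine3d:::vdw_radius(d$atoms$element)
  oracle <- 0
  for (i in seq_len(nrow(xyz) - 1)) {
    for (j in (i + 1):nrow(xyz)) {
      if (j %in% sep[[i]]) next
      dd <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dd < vdw[i] + vdw[j] - 0.4) oracle <- oracle + 1
    }
  }
  expect_equal(got, oracle)
})

test_that("mp_proxy is 0.5 for a clash-free helix and increases with an
           injected clash", {
  helix <- build_ideal_peptide(12, sequence = strrep("A", 12),
                               topology = "helix")
  expect_equal(mp_proxy(helix), 0.5, tolerance = 1e-9)
  xyz <- coords(helix)
  cb <- refine3d:::atom_in_residue(helix, 6, "CB")
  o <- refine3d:::atom_in_residue(helix, 2, "O")
  xyz[cb, ] <- xyz[o, ] + c(1.0, 0, 0)   # severe overlap
  clashed <- set_coords(helix, xyz)
  expect_gt(suppressWarnings(mp_proxy(clashed)), mp_proxy(helix))
})

test_that("extra unpaired residues do not change paired-atom metrics", {
  m <- build_ideal_peptide(12, topology = "helix")
  sub <- atomic_model(m$atoms[m$atoms$resseq <= 10, ])
  set.seed(2)
  d <- set_coords(sub, coords(sub) +
                    matrix(rnorm(nrow(sub$atoms) * 3, sd = 0.3), ncol = 3))
  expect_equal(gdt_ts(d, m), gdt_ts(d, sub), tolerance = 1e-12)
  expect_equal(kabsch_rmsd(d, m)$rmsd, kabsch_rmsd(d, sub)$rmsd,
               tolerance = 1e-12)
})

test_that("sequence mismatch at a paired position is an error", {
  a <- build_ideal_peptide(6, sequence = "AAAAAA")
  g <- build_ideal_peptide(6, sequence = "AAGAAA")
  expect_error(gdt_ts(a, g), "mismatch")
})

test_that("a monotone decoy series degrades gdt_ts and grows rmsd in the
           median", {
  native <- build_ideal_peptide(10, topology = "helix")
  sds <- c(0.2, 0.6, 1.2)
  med <- sapply(sds, function(sd) {
    vals <- sapply(1:8, function(s) {
      d <- suppressWarnings(perturb(native, decoy_spec(
        backbone_noise_sd = sd, sidechain_scramble_fraction = 0,
        seed = s))$model)
      c(gdt = gdt_ts(d, native), rmsd = kabsch_rmsd(d, native)$rmsd)
    })
    apply(vals, 1, median)
  })
  expect_true(all(diff(med["gdt", ]) <= 0))
  expect_true(all(diff(med["rmsd", ]) > 0))
})
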