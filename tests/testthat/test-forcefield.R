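# Bonded, tether and hydrogen-bond terms: closed forms, analytic
# gradients, and rigid-motion invariances.

make_two_atom_model <- function(d) {
  atomic_model(data.frame(
    serial = 1:2, name = c("N", "CA"), element = c("N", "C"),
    resname = "ALA", chain = "A", resseq = 1L, icode = "",
    x = c(0, d), y = 0, z = 0, occ = 1, b = 0, is_h = FALSE,
    stringsAsFactors = FALSE))
}

test_that("bond energy has its closed form around the equilibrium length", {
  params <- ff_params()
  b0 <- refine3d:::lookup_bond_length(params, "ALA", "N", "CA")
  expect_equal(bonded_energy(make_two_atom_model(b0))$per_term[["bond"]], 0,
               tolerance = 1e-12)
  e <- bonded_energy(make_two_atom_model(b0 + 0.1))
  expect_equal(e$per_term[["bond"]], params$k_bond * 0.01, tolerance = 1e-9)
  # k_b = 300 gives exactly 3.0 for a 0.1 A stretch
  expect_equal(e$per_term[["bond"]], 3.0, tolerance = 1e-9)
})

test_that("a template bond stretched beyond 2.5 A warns but still scores", {
  m <- make_two_atom_model(3.0)
  expect_warning(e <- bonded_energy(m), "2.5")
  expect_gt(e$per_term[["bond"]], 100)
})

test_that("ideal peptides have near-zero bonded energy under the matching
           parameter table", {
  m <- build_ideal_peptide(12, sequence = strrep("A", 12), topology = "helix")
  e <- bonded_energy(m)
  expect_lt(e$total, 0.05)
  s <- build_ideal_peptide(8, sequence = strrep("A", 8), topology = "strand")
  expect_lt(bonded_energy(s)$total, 0.05)
})

test_that("tether energy is quadratic in Calpha/Cbeta displacement only", {
  m <- build_ideal_peptide(5, sequence = "ASAAA")
  params <- ff_params(tether_k = 1.0)
  expect_equal(tether_energy(m, m, params)$per_term[["tether"]], 0)
  # displace one CA by 0.5 A -> E = k * 0.25
  i_ca <- refine3d:::atom_in_residue(m, 3, "CA")
  xyz <- coords(m)
  xyz[i_ca, 1] <- xyz[i_ca, 1] + 0.5
  expect_equal(tether_energy(set_coords(m, xyz), m,
                             params)$per_term[["tether"]],
               0.25, tolerance = 1e-12)
  # displacing a side-chain OG changes nothing
  i_og <- refine3d:::atom_in_residue(m, 2, "OG")
  xyz2 <- coords(m)
  xyz2[i_og, ] <- xyz2[i_og, ] + c(1, 1, 1)
  expect_equal(tether_energy(set_coords(m, xyz2), m,
                             params)$per_term[["tether"]], 0)
  # topology mismatch errors
  other <- build_ideal_peptide(5, sequence = "AAAAA")
  expect_error(tether_energy(m, other), "topology")
})

test_that("an ideal linear hydrogen bond scores at the stated optimum and
           a 90-degree bond scores zero", {
  params <- ff_params()
  hb <- params$hb
  # constructed N-H...O=C geometry: linear DHA at d = d0
  atoms <- data.frame(
    serial = 1:5,
    name = c("N", "H", "O", "C", "CA"),
    element = c("N", "H", "O", "C", "C"),
    resname = c("ALA", "ALA", "GLY", "GLY", "GLY"),
    chain = "A", resseq = c(10L, 10L, 2L, 2L, 2L), icode = "",
    x = c(0, 0, 0, 1.231 * sin(refine3d:::deg2rad(60)), 1.4),
    y = c(hb$d0 + 1.01, hb$d0, 0, -1.231 * cos(refine3d:::deg2rad(60)), 1.2),
    z = 0, occ = 1, b = 0,
    is_h = c(FALSE, TRUE, FALSE, FALSE, FALSE), stringsAsFactors = FALSE)
  m <- atomic_model(atoms)
  e <- hbond_energy(m, NULL, params)
  # angular factor: DHA = 180 (factor 1), HAB = 120 (factor 1 at theta_off)
  expect_equal(e$per_term[["hbond"]], -hb$strength, tolerance = 1e-6)
  # bend DHA to 90 degrees: contribution clamps to zero
  atoms2 <- atoms
  atoms2$x[1] <- 1.01       # N sideways from H: D-H...A bends to 90 degrees
  atoms2$y[1] <- hb$d0
  e2 <- hbond_energy(atomic_model(atoms2), NULL, params)
  expect_equal(e2$per_term[["hbond"]], 0)
})

test_that("a model without polar hydrogens warns and scores zero", {
  m <- build_ideal_peptide(5, sequence = "AAAAA")
  expect_warning(e <- hbond_energy(m), "no polar hydrogens")
  expect_equal(e$per_term[["hbond"]], 0)
})

test_that("analytic gradients of every term match central finite
           differences", {
  set.seed(7)
  m <- build_ideal_peptide(5, sequence = "ASNQA", topology = "helix")
  ext <- add_polar_hydrogens(m)
  ext <- set_coords(ext, coords(ext) +
                      matrix(rnorm(nrow(ext$atoms) * 3, sd = 0.05), ncol = 3))
  params <- ff_params()
  ss <- assign_secondary_structure(m)
  tab <- test_pmf_table()
  topo <- ff_topology(ext, params)
  topo$hb_ss_weight <- refine3d:::hb_ss_weights(topo, ss, params)
  xyz <- coords(ext)
  ref <- xyz + 0.3
  evals <- list(
    bond = function(x) refine3d:::eval_bond_term(topo, x, params$k_bond),
    angle = function(x) refine3d:::eval_angle_term(topo, x, params$k_angle),
    torsion = function(x) refine3d:::eval_torsion_term(topo, x),
    tether = function(x) refine3d:::eval_tether_term(topo, x, ref,
                                                     params$tether_k),
    hbond = function(x) refine3d:::eval_hbond_term(topo, x, params$hb),
    pmf = function(x) refine3d:::eval_pmf_term(topo, x, tab)
  )
  for (nm in names(evals)) {
    expect_lt(fd_gradient_check(evals[[nm]], xyz), 1e-4)
  }
})

test_that("total energy is the weighted sum of terms and zero weights drop
           gradients", {
  m <- build_ideal_peptide(5, sequence = "ASNQA")
  ext <- add_polar_hydrogens(m)
  ss <- assign_secondary_structure(m)
  tab <- test_pmf_table()
  params <- ff_params()
  e <- total_energy(ext, ext, ss, params, tab)
  expect_equal(e$total,
               sum(params$term_weights[names(e$per_term)] * e$per_term),
               tolerance = 1e-9)
  # zeroing the pmf weight removes exactly its gradient contribution
  params0 <- ff_params(term_weights = c(bond = 1, angle = 1, torsion = 1,
                                        tether = 1, pmf = 0, hbond = 1))
  e0 <- total_energy(ext, ext, ss, params0, tab)
  gpmf <- pmf_energy(ext, tab, params)$gradient
  expect_equal(e0$gradient, e$gradient - gpmf, tolerance = 1e-9)
})

test_that("energies are invariant under joint rigid motion and net force
           vanishes for all terms but the tether", {
  m <- build_ideal_peptide(6, sequence = "ASNQAL")
  ext <- add_polar_hydrogens(m)
  ss <- assign_secondary_structure(m)
  tab <- test_pmf_table()
  params <- ff_params()
  ref <- set_coords(ext, coords(ext) + 0.2)
  e1 <- total_energy(ext, ref, ss, params, tab)
  R <- refine3d:::rotation_about_axis(c(2, -1, 1), 0.9)
  tr <- function(mm) set_coords(mm, sweep(coords(mm) %*% t(R), 2,
                                          c(3, 4, -1), `+`))
  e2 <- total_energy(tr(ext), tr(ref), ss, params, tab)
  expect_equal(e2$total, e1$total, tolerance = 1e-8)
  expect_equal(unclass(e2$per_term), unclass(e1$per_term), tolerance = 1e-8)
  # gradients rotate covariantly
  expect_equal(e2$gradient, e1$gradient %*% t(R), tolerance = 1e-6)
  # net force: all terms except tether sum to zero
  topo <- ff_topology(ext, params)
  xyz <- coords(ext)
  for (term in list(
    refine3d:::eval_bond_term(topo, xyz, params$k_bond),
    refine3d:::eval_angle_term(topo, xyz, params$k_angle),
    refine3d:::eval_torsion_term(topo, xyz),
    refine3d:::eval_hbond_term(topo, xyz, params$hb),
    refine3d:::eval_pmf_term(topo, xyz, tab))) {
    expect_lt(max(abs(colSums(term$G))) / nrow(xyz), 1e-8)
  }
})

test_that("parameter files round-trip through write/read", {
  params <- ff_params(tether_k = 2.5)
  params$term_weights[["pmf"]] <- 0.7
  path <- tempfile(fileext = ".txt")
  write_ff_params(params, path)
  p2 <- read_ff_params(path)
  expect_equal(p2$tether_k, 2.5)
  expect_equal(p2$term_weights[["pmf"]], 0.7)
  expect_equal(p2$k_bond, params$k_bond)
  expect_equal(p2$hb$d0, params$hb$d0)
  expect_equal(unname(p2$bond_lengths["*|N|CA"]),
               unname(params$bond_lengths["*|N|CA"]), tolerance = 1e-6)
})
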