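# The composite all-atom energy: harmonic bond/angle terms, cosine torsion
# terms, Calpha/Cbeta tethering, the knowledge-based pairwise potential of
# mean force (pmf.R) and the explicit hydrogen-bonding potential.  Every
# term returns the energy and its analytic gradient; `total_energy` forms
# the weighted sum.

# Standard chi dihedral atom names per residue type.
CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

#' Build the energy topology of a model
#'
#' Precomputes everything the energy terms need that does not depend on
#' coordinates: bond/angle/torsion lists with equilibrium values, tethered
#' atom indices, nonbonded exclusion sets, PMF atom types and
#' hydrogen-bond donor/acceptor tables.
#'
#' @param model an `atomic_model`.
#' @param params an `ff_params` object.
#' @return a list used by the energy functions (class `ff_topology`).
#' @export
ff_topology <- function(model, params = ff_params()) {
  at <- model$atoms
  res <- model$residues
  B <- bond_list(model, warn_long = TRUE)
  # residue index per atom
  resi <- integer(nrow(at))
  for (r in seq_len(nrow(res))) resi[res$atom_index[[r]]] <- r

  b0 <- vapply(seq_len(nrow(B)), function(k) {
    i <- B[k, 1]; j <- B[k, 2]
    rn <- if (at$name[j] == "N" && at$name[i] == "C") "*" else at$resname[i]
    lookup_bond_length(params, rn, at$name[i], at$name[j])
  }, numeric(1))

  # angles: all pairs of bonded neighbors around each center atom
  adj <- vector("list", nrow(at))
  if (nrow(B)) {
    for (k in seq_len(nrow(B))) {
      adj[[B[k, 1]]] <- c(adj[[B[k, 1]]], B[k, 2])
      adj[[B[k, 2]]] <- c(adj[[B[k, 2]]], B[k, 1])
    }
  }
  ang <- list()
  for (j in seq_len(nrow(at))) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (c_ in seq_len(ncol(cmb))) {
      ang[[length(ang) + 1]] <- c(cmb[1, c_], j, cmb[2, c_])
    }
  }
  A <- do.call(rbind, ang)
  if (is.null(A)) A <- matrix(integer(0), 0, 3)
  theta0 <- vapply(seq_len(nrow(A)), function(k) {
    i <- A[k, 1]; j <- A[k, 2]; l <- A[k, 3]
    lookup_angle_value(params, at$resname[j], at$name[i], at$name[j],
                       at$name[l])
  }, numeric(1))

  # torsions: peptide-bond planarity plus 3-fold sp3 chi terms
  tor <- list()   # each: c(i,j,k,l, n, k_phi, delta)
  for (r in seq_len(nrow(res) - 1)) {
    if (res$chain[r + 1] != res$chain[r]) next
    q <- c(atom_in_residue(model, r, "CA"), atom_in_residue(model, r, "C"),
           atom_in_residue(model, r + 1, "N"),
           atom_in_residue(model, r + 1, "CA"))
    if (!anyNA(q)) {
      tor[[length(tor) + 1]] <- c(q, 2, params$k_omega, pi)
    }
  }
  for (r in seq_len(nrow(res))) {
    chis <- CHI_ATOMS[[res$resname[r]]]
    if (is.null(chis)) next
    for (chain4 in chis) {
      ctr <- chain4[3]
      sp2 <- SP2_CENTERS[[res$resname[r]]]
      if (!is.null(sp2) && ctr %in% sp2) next
      q <- vapply(chain4, function(nm) atom_in_residue(model, r, nm),
                  integer(1))
      if (!anyNA(q)) {
        tor[[length(tor) + 1]] <- c(q, 3, params$k_chi, 0)
      }
    }
  }
  Tq <- do.call(rbind, tor)
  if (is.null(Tq)) Tq <- matrix(numeric(0), 0, 7)

  excl <- bond_separation_sets(model, max_sep = 3)
  n <- nrow(at)
  excl_keys <- unlist(lapply(seq_len(n), function(i) {
    js <- excl[[i]]
    js <- js[js > i]
    if (length(js)) (i - 1) * n + js else numeric(0)
  }), use.names = FALSE)

  list(
    n_atoms = n,
    resi = resi,
    is_h = at$is_h,
    bonds = B, b0 = b0,
    angles = A, theta0 = theta0,
    torsions = Tq,
    tether_idx = which(at$name %in% c("CA", "CB") & !at$is_h),
    excl = excl,
    excl_keys = excl_keys,
    pmf_types = pmf_atom_types(model),
    hb = hb_allowed_pairs(hb_topology(model, adj), excl),
    vdw = vdw_radius(at$element)
  )
}

# Precompute which donor/acceptor combinations are chemically allowed
# (acceptor is not the donor heavy atom and not covalently near the H).
hb_allowed_pairs <- function(hb, excl) {
  nd <- nrow(hb$donors)
  na_ <- nrow(hb$acceptors)
  allowed <- matrix(TRUE, nd, na_)
  for (di in seq_len(nd)) {
    D <- hb$donors[di, "D"]
    H <- hb$donors[di, "H"]
    allowed[di, ] <- hb$acceptors[, "A"] != D &
      !(hb$acceptors[, "A"] %in% excl[[H]])
  }
  hb$allowed <- allowed
  hb
}

# Hydrogen-bond donor/acceptor bookkeeping.  Donors: hydrogens bonded to
# N/O/S with their parent heavy atom.  Acceptors: carbonyl/carboxyl and
# hydroxyl oxygens, unprotonated HIS ring nitrogens, S; each with a base
# heavy atom defining the acceptor direction.
hb_topology <- function(model, adj) {
  at <- model$atoms
  donors <- list()
  for (h in which(at$is_h)) {
    parents <- adj[[h]]
    parents <- parents[!at$is_h[parents]]
    if (length(parents) && at$element[parents[1]] %in% c("N", "O", "S")) {
      donors[[length(donors) + 1]] <- c(D = parents[1], H = h)
    }
  }
  D <- do.call(rbind, donors)
  if (is.null(D)) D <- matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("D", "H")))
  acceptors <- list()
  for (a in which(!at$is_h)) {
    el <- at$element[a]
    nm <- at$name[a]
    rn <- at$resname[a]
    ok <- FALSE
    if (el == "O") ok <- TRUE
    if (el == "S") ok <- TRUE
    if (rn == "HIS" && nm %in% c("ND1", "NE2")) {
      hs <- adj[[a]]
      ok <- !any(at$is_h[hs])   # accepts only when unprotonated
    }
    if (!ok) next
    base <- adj[[a]]
    base <- base[!at$is_h[base]]
    if (length(base) == 0) next
    acceptors[[length(acceptors) + 1]] <- c(A = a, B = base[1])
  }
  A <- do.call(rbind, acceptors)
  if (is.null(A)) A <- matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("A", "B")))
  list(donors = D, acceptors = A)
}

new_energy_report <- function(per_term, gradient, weights) {
  w <- weights[names(per_term)]
  structure(list(total = sum(w * unlist(per_term)),
                 per_term = unlist(per_term),
                 gradient = gradient), class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("energy_report: total =", format(x$total, digits = 8), "\n")
  print(round(x$per_term, 6))
  invisible(x)
}

# ---- term evaluators (xyz -> list(E, G)) -----------------------------------

# Scatter-add row contributions into the gradient matrix.
acc_add <- function(G, idx, contrib) {
  rs <- rowsum(contrib, idx)
  ids <- as.integer(rownames(rs))
  G[ids, ] <- G[ids, , drop = FALSE] + rs
  G
}

eval_bond_term <- function(topo, xyz, k_bond) {
  G <- matrix(0, nrow(xyz), 3)
  B <- topo$bonds
  if (nrow(B) == 0) return(list(E = 0, G = G))
  d <- xyz[B[, 1], , drop = FALSE] - xyz[B[, 2], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  dev <- r - topo$b0
  gi <- (2 * k_bond * dev / r) * d
  G <- acc_add(G, B[, 1], gi)
  G <- acc_add(G, B[, 2], -gi)
  list(E = k_bond * sum(dev^2), G = G)
}

eval_angle_term <- function(topo, xyz, k_angle) {
  G <- matrix(0, nrow(xyz), 3)
  A <- topo$angles
  if (nrow(A) == 0) return(list(E = 0, G = G))
  u <- xyz[A[, 1], , drop = FALSE] - xyz[A[, 2], , drop = FALSE]
  v <- xyz[A[, 3], , drop = FALSE] - xyz[A[, 2], , drop = FALSE]
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  uh <- u / nu
  vh <- v / nv
  cosang <- pmax(-1, pmin(1, rowSums(uh * vh)))
  theta <- acos(cosang)
  sinang <- sqrt(pmax(1e-12, 1 - cosang^2))
  gi <- (cosang * uh - vh) / (nu * sinang)
  gk <- (cosang * vh - uh) / (nv * sinang)
  dev <- theta - topo$theta0
  coef <- 2 * k_angle * dev
  G <- acc_add(G, A[, 1], coef * gi)
  G <- acc_add(G, A[, 2], coef * (-(gi + gk)))
  G <- acc_add(G, A[, 3], coef * gk)
  list(E = k_angle * sum(dev^2), G = G)
}

eval_torsion_term <- function(topo, xyz) {
  E <- 0
  G <- matrix(0, nrow(xyz), 3)
  Tq <- topo$torsions
  for (k in seq_len(nrow(Tq))) {
    i <- Tq[k, 1]; j <- Tq[k, 2]; l <- Tq[k, 3]; m <- Tq[k, 4]
    n <- Tq[k, 5]; kphi <- Tq[k, 6]; delta <- Tq[k, 7]
    dg <- dihedral_grad(xyz[i, ], xyz[j, ], xyz[l, ], xyz[m, ])
    E <- E + kphi * (1 + cos(n * dg$value - delta))
    dEdphi <- -kphi * n * sin(n * dg$value - delta)
    G[i, ] <- G[i, ] + dEdphi * dg$gi
    G[j, ] <- G[j, ] + dEdphi * dg$gj
    G[l, ] <- G[l, ] + dEdphi * dg$gk
    G[m, ] <- G[m, ] + dEdphi * dg$gl
  }
  list(E = E, G = G)
}

eval_tether_term <- function(topo, xyz, ref_xyz, tether_k) {
  G <- matrix(0, nrow(xyz), 3)
  idx <- topo$tether_idx
  d <- xyz[idx, , drop = FALSE] - ref_xyz[idx, , drop = FALSE]
  E <- tether_k * sum(d * d)
  G[idx, ] <- 2 * tether_k * d
  list(E = E, G = G)
}

eval_hbond_term <- function(topo, xyz, hbp) {
  E <- 0
  G <- matrix(0, nrow(xyz), 3)
  don <- topo$hb$donors
  acc <- topo$hb$acceptors
  if (nrow(don) == 0 || nrow(acc) == 0) return(list(E = 0, G = G))
  ss_w <- topo$hb_ss_weight
  if (is.null(ss_w)) ss_w <- rep(1, nrow(don))
  # distance pre-filter: only allowed pairs with H..A below the cap
  Hx <- xyz[don[, "H"], , drop = FALSE]
  Ax <- xyz[acc[, "A"], , drop = FALSE]
  d2 <- outer(rowSums(Hx^2), rep(1, nrow(acc))) +
    outer(rep(1, nrow(don)), rowSums(Ax^2)) - 2 * Hx %*% t(Ax)
  cand <- which(topo$hb$allowed & d2 < hbp$cap^2, arr.ind = TRUE)
  for (q in seq_len(nrow(cand))) {
    di <- cand[q, 1]; ai <- cand[q, 2]
    {
      D <- don[di, "D"]; H <- don[di, "H"]
      A <- acc[ai, "A"]; Bb <- acc[ai, "B"]
      dg <- dist_grad(xyz[H, ], xyz[A, ])
      # linearity factor: -cos(theta_DHA) is 1 for a straight bond and
      # clamps to 0 at 90 degrees
      agD <- angle_grad(xyz[D, ], xyz[H, ], xyz[A, ])   # theta_DHA
      cD <- -cos(agD$value)
      if (cD <= 0) next
      agA <- angle_grad(xyz[H, ], xyz[A, ], xyz[Bb, ])  # theta_HAB
      cA <- cos(agA$value - hbp$theta_off)
      if (cA <= 0) next
      w <- hbp$strength * ss_w[di]
      g <- exp(-(dg$value - hbp$d0)^2 / (2 * hbp$sigma_d^2))
      fD <- cD^hbp$p
      fA <- cA^hbp$q
      E <- E - w * g * fD * fA
      # gradient: product rule over the three geometric factors
      dg_dr <- -w * g * fD * fA * (-(dg$value - hbp$d0) / hbp$sigma_d^2)
      G[H, ] <- G[H, ] + dg_dr * dg$gi
      G[A, ] <- G[A, ] + dg_dr * dg$gj
      dfD <- -w * g * fA * hbp$p * cD^(hbp$p - 1) * sin(agD$value)
      G[D, ] <- G[D, ] + dfD * agD$gi
      G[H, ] <- G[H, ] + dfD * agD$gj
      G[A, ] <- G[A, ] + dfD * agD$gk
      dfA <- -w * g * fD * hbp$q * cA^(hbp$q - 1) *
        (-sin(agA$value - hbp$theta_off))
      G[H, ] <- G[H, ] + dfA * agA$gi
      G[A, ] <- G[A, ] + dfA * agA$gj
      G[Bb, ] <- G[Bb, ] + dfA * agA$gk
    }
  }
  list(E = E, G = G)
}

# ---- public per-term operations --------------------------------------------

#' Bonded energy (bond + angle + torsion)
#'
#' Harmonic bond and angle deviations from their equilibrium values plus
#' cosine torsion terms, with analytic gradients.
#'
#' @param model an `atomic_model`.
#' @param params an `ff_params`.
#' @param topo optional precomputed [ff_topology()].
#' @return an `energy_report` with `bond`, `angle`, `torsion` terms.
#' @export
bonded_energy <- function(model, params = ff_params(), topo = NULL) {
  if (is.null(topo)) topo <- ff_topology(model, params)
  xyz <- coords(model)
  b <- eval_bond_term(topo, xyz, params$k_bond)
  a <- eval_angle_term(topo, xyz, params$k_angle)
  t <- eval_torsion_term(topo, xyz)
  new_energy_report(list(bond = b$E, angle = a$E, torsion = t$E),
                    b$G + a$G + t$G, params$term_weights)
}

#' Tethering energy of Calpha and Cbeta atoms
#'
#' Harmonic restraint of every Calpha and Cbeta atom to its position in the
#' reference model; all other atoms are unrestrained.
#'
#' @param model,reference `atomic_model`s sharing atom topology.
#' @param params an `ff_params` (field `tether_k`).
#' @param topo optional precomputed [ff_topology()].
#' @return an `energy_report` with the `tether` term.
#' @export
tether_energy <- function(model, reference, params = ff_params(),
                          topo = NULL) {
  if (nrow(model$atoms) != nrow(reference$atoms) ||
      !all(model$atoms$name == reference$atoms$name)) {
    stop("model and reference do not share atom topology")
  }
  if (is.null(topo)) topo <- ff_topology(model, params)
  t <- eval_tether_term(topo, coords(model), coords(reference),
                        params$tether_k)
  new_energy_report(list(tether = t$E), t$G, params$term_weights)
}

#' Explicit hydrogen-bond energy
#'
#' For every donor-H / acceptor pair with an H..A distance below the cap, a
#' Gaussian distance factor around the ideal H..A distance is combined with
#' clamped cosine-power angular factors at the donor (D-H..A) and acceptor
#' (H..A-base) sites.  The well depth can differ by the secondary-structure
#' state of the donor residue.
#'
#' @param model an `atomic_model` with polar hydrogens present.
#' @param ss a secondary-structure assignment (H/E/C per residue).
#' @param params an `ff_params`.
#' @param topo optional precomputed [ff_topology()].
#' @return an `energy_report` with the `hbond` term.
#' @export
hbond_energy <- function(model, ss = NULL, params = ff_params(),
                         topo = NULL) {
  if (is.null(topo)) topo <- ff_topology(model, params)
  if (nrow(topo$hb$donors) == 0) {
    warning("no polar hydrogens in model; hydrogen-bond term is 0")
  }
  topo$hb_ss_weight <- hb_ss_weights(topo, ss, params)
  h <- eval_hbond_term(topo, coords(model), params$hb)
  new_energy_report(list(hbond = h$E), h$G, params$term_weights)
}

hb_ss_weights <- function(topo, ss, params) {
  don <- topo$hb$donors
  if (nrow(don) == 0) return(numeric(0))
  if (is.null(ss)) return(rep(1, nrow(don)))
  lab <- ss[topo$resi[don[, "D"]]]
  unname(params$hb$w_ss[lab])
}

#' Total composite energy
#'
#' Weighted sum of all six terms (bond, angle, torsion, tether, pmf,
#' hbond); the gradient is the weighted sum of the per-term gradients.
#'
#' @param model an `atomic_model` (extended, i.e. with polar hydrogens, for
#'   the hydrogen-bond term to contribute).
#' @param reference tether reference model (same topology).
#' @param ss secondary-structure assignment.
#' @param params an `ff_params`.
#' @param table a `pmf_table` (NULL drops the pmf term).
#' @param topo optional precomputed [ff_topology()].
#' @return an `energy_report` with all terms.
#' @export
total_energy <- function(model, reference, ss, params = ff_params(),
                         table = NULL, topo = NULL) {
  if (is.null(topo)) topo <- ff_topology(model, params)
  topo$hb_ss_weight <- hb_ss_weights(topo, ss, params)
  xyz <- coords(model)
  ev <- total_energy_xyz(topo, xyz, coords(reference), params, table)
  new_energy_report(ev$per_term, ev$G, params$term_weights)
}

# Core evaluator on raw coordinates; used by the minimizer.
total_energy_xyz <- function(topo, xyz, ref_xyz, params, table) {
  b <- eval_bond_term(topo, xyz, params$k_bond)
  a <- eval_angle_term(topo, xyz, params$k_angle)
  t <- eval_torsion_term(topo, xyz)
  te <- eval_tether_term(topo, xyz, ref_xyz, params$tether_k)
  hb <- eval_hbond_term(topo, xyz, params$hb)
  pm <- if (is.null(table)) list(E = 0, G = matrix(0, nrow(xyz), 3)) else
    eval_pmf_term(topo, xyz, table)
  per_term <- list(bond = b$E, angle = a$E, torsion = t$E, tether = te$E,
                   pmf = pm$E, hbond = hb$E)
  w <- params$term_weights
  G <- w["bond"] * b$G + w["angle"] * a$G + w["torsion"] * t$G +
    w["tether"] * te$G + w["pmf"] * pm$G + w["hbond"] * hb$G
  list(per_term = per_term, G = G,
       total = sum(unlist(per_term) * w[names(per_term)]))
}
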