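# Model-quality metrics: single-superposition RMSD, GDT-TS, GDC-SC,
# SphereGrinder, CAD-AA, and a MolProbity-style composite proxy (labelled
# MP-proxy throughout: it follows the published score combination but
# replaces the external clash/rotamer/Ramachandran machinery with internal
# approximations).  All structure comparisons pair atoms by
# (chain, residue number, atom name); models must share the target
# sequence at paired positions.

# Residue pairing between two models; errors on sequence mismatch.
pair_residues <- function(model, reference) {
  km <- paste(model$residues$chain, model$residues$resseq,
              model$residues$icode)
  kr <- paste(reference$residues$chain, reference$residues$resseq,
              reference$residues$icode)
  common <- intersect(km, kr)
  im <- match(common, km)
  ir <- match(common, kr)
  mis <- model$residues$resname[im] != reference$residues$resname[ir]
  if (any(mis)) {
    stop("sequence mismatch at paired residue ", common[which(mis)[1]],
         ": ", model$residues$resname[im[which(mis)[1]]], " vs ",
         reference$residues$resname[ir[which(mis)[1]]])
  }
  list(model = im, reference = ir, n = length(common))
}

# Paired heavy-atom coordinate sets; atom_selection is "CA", "all" (all
# heavy atoms), or a vector of atom names.
pair_atoms <- function(model, reference, atom_selection = "CA") {
  pr <- pair_residues(model, reference)
  P <- list(); Q <- list(); resof <- integer(0); aname <- character(0)
  xm <- coords(model); xr <- coords(reference)
  for (k in seq_len(pr$n)) {
    rm_ <- pr$model[k]; rr <- pr$reference[k]
    idx_m <- model$residues$atom_index[[rm_]]
    idx_r <- reference$residues$atom_index[[rr]]
    nm_m <- model$atoms$name[idx_m]
    nm_r <- reference$atoms$name[idx_r]
    sel <- if (identical(atom_selection, "all")) {
      intersect(nm_m[!model$atoms$is_h[idx_m]],
                nm_r[!reference$atoms$is_h[idx_r]])
    } else {
      intersect(intersect(atom_selection, nm_m), nm_r)
    }
    for (nm in sel) {
      P[[length(P) + 1]] <- xm[idx_m[match(nm, nm_m)], ]
      Q[[length(Q) + 1]] <- xr[idx_r[match(nm, nm_r)], ]
      resof <- c(resof, k)
      aname <- c(aname, nm)
    }
  }
  list(P = do.call(rbind, P), Q = do.call(rbind, Q), residue = resof,
       name = aname, n_residues = pr$n, pairing = pr)
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Single least-squares superposition of the selected paired atoms with no
#' distance cutoff; reflections are excluded.
#'
#' @param model,reference `atomic_model`s sharing the target sequence.
#' @param atom_selection "CA" (default), "all", or atom names.
#' @return list with `rmsd` (A), `rotation`, `translation`, `n`.
#' @export
kabsch_rmsd <- function(model, reference, atom_selection = "CA") {
  pa <- pair_atoms(model, reference, atom_selection)
  if (is.null(pa$P) || nrow(pa$P) < 3) {
    stop("fewer than 3 paired atoms for superposition")
  }
  fit <- kabsch(pa$P, pa$Q)
  list(rmsd = fit$rmsd, rotation = fit$R, translation = fit$t,
       n = nrow(pa$P))
}

# Iteratively refit a superposition on the subset of pairs within `cutoff`,
# starting from the seed index set, until the subset is stable (<= 20
# rounds).  Returns the largest within-cutoff count seen.
iterate_fit <- function(P, Q, seed_idx, cutoff, max_rounds = 20) {
  best <- 0
  idx <- seed_idx
  for (round in seq_len(max_rounds)) {
    if (length(idx) < 3) break
    fit <- kabsch(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
    d <- sqrt(rowSums((fit$transform(P) - Q)^2))
    inside <- which(d <= cutoff)
    best <- max(best, length(inside))
    if (identical(inside, idx)) break
    idx <- inside
  }
  best
}

# Maximal fraction of pairs within `cutoff` over seeded superpositions:
# contiguous windows of 3/5/7 residues at every offset plus the global fit.
max_fraction_within <- function(P, Q, cutoff) {
  n <- nrow(P)
  best <- iterate_fit(P, Q, seq_len(n), cutoff)
  for (w in c(3, 5, 7)) {
    if (n < w) next
    for (s in seq_len(n - w + 1)) {
      best <- max(best, iterate_fit(P, Q, s:(s + w - 1), cutoff))
      if (best == n) return(1)
    }
  }
  best / n
}

#' GDT-TS score
#'
#' Mean over cutoffs 1, 2, 4 and 8 A of the maximal fraction of paired
#' Calpha atoms within the cutoff under an optimized superposition,
#' reported on \[0, 1\].
#'
#' @param model,reference `atomic_model`s.
#' @return numeric in \[0, 1\].
#' @export
gdt_ts <- function(model, reference) {
  pa <- pair_atoms(model, reference, "CA")
  if (is.null(pa$P) || nrow(pa$P) < 4) stop("fewer than 4 paired CA atoms")
  mean(vapply(c(1, 2, 4, 8), function(cut) {
    max_fraction_within(pa$P, pa$Q, cut)
  }, numeric(1)))
}

#' GDC-SC score
#'
#' Side-chain analogue of GDT: one characteristic atom near the end of each
#' side chain (GLY excluded), evaluated under 10 superpositions fit at
#' thresholds 0.5k A (k = 1..10) with linearly decreasing weights.
#'
#' @param model,reference `atomic_model`s.
#' @return numeric in \[0, 1\].
#' @export
gdc_sc <- function(model, reference) {
  pr <- pair_residues(model, reference)
  P <- list(); Q <- list()
  xm <- coords(model); xr <- coords(reference)
  for (k in seq_len(pr$n)) {
    rn <- reference$residues$resname[pr$reference[k]]
    ca <- CHARACTERISTIC_ATOM[rn]
    if (is.na(ca)) next
    i <- atom_in_residue(model, pr$model[k], ca)
    j <- atom_in_residue(reference, pr$reference[k], ca)
    if (is.na(i) || is.na(j)) next
    P[[length(P) + 1]] <- xm[i, ]
    Q[[length(Q) + 1]] <- xr[j, ]
  }
  if (length(P) < 4) stop("fewer than 4 residues with characteristic atoms")
  P <- do.call(rbind, P); Q <- do.call(rbind, Q)
  kvec <- 1:10
  w <- (10 - kvec + 1)
  w <- w / sum(w)
  sum(w * vapply(kvec, function(k) {
    max_fraction_within(P, Q, 0.5 * k)
  }, numeric(1)))
}

#' SphereGrinder score
#'
#' For each residue, the set of reference atoms within 6 A of its reference
#' Calpha defines a sphere; the all-atom RMSD of the paired model atoms of
#' that sphere (after per-sphere superposition) summarizes the local
#' environment.  The score averages the fractions of residues with sphere
#' RMSD below 2 A and below 4 A.
#'
#' @param model,reference `atomic_model`s.
#' @param radius sphere radius in A (default 6).
#' @param cutoffs RMSD cutoffs averaged over (default `c(2, 4)`).
#' @return numeric in \[0, 1\].
#' @export
sphere_grinder <- function(model, reference, radius = 6, cutoffs = c(2, 4)) {
  pa <- pair_atoms(model, reference, "all")
  if (is.null(pa$P) || pa$n_residues < 1) stop("no pairable residues")
  ca_rows <- which(pa$name == "CA")
  rmsds <- rep(NA_real_, length(ca_rows))
  for (q in seq_along(ca_rows)) {
    center <- pa$Q[ca_rows[q], ]
    d <- sqrt(rowSums(sweep(pa$Q, 2, center)^2))
    sph <- which(d <= radius)
    if (length(sph) < 3) next
    rmsds[q] <- kabsch(pa$P[sph, , drop = FALSE],
                       pa$Q[sph, , drop = FALSE])$rmsd
  }
  ok <- !is.na(rmsds)
  if (!any(ok)) stop("no sphere had at least 3 paired atoms")
  mean(vapply(cutoffs, function(cc) mean(rmsds[ok] < cc), numeric(1)))
}

# Residue-pair contact areas by quasi-uniform sphere-surface sampling:
# each atom's solvent-extended sphere (vdW + probe) is sampled at n_points
# Fibonacci points; each point is assigned to the neighboring atom whose
# extended sphere it penetrates deepest, and points claimed by another
# residue contribute area to that residue pair.
contact_areas <- function(model, n_points = 256, probe = 1.4) {
  at <- model$atoms
  heavy <- which(!at$is_h)
  xyz <- coords(model)[heavy, , drop = FALSE]
  rad <- vdw_radius(at$element[heavy]) + probe
  resk <- paste(at$chain[heavy], at$resseq[heavy], at$icode[heavy])
  resid <- match(resk, unique(resk))
  n <- length(heavy)
  dirs <- fibonacci_sphere(n_points)
  areas <- new.env(parent = emptyenv())
  maxr <- 2 * max(rad)
  prs <- cell_list_pairs(xyz, maxr)
  nb <- vector("list", n)
  for (k in seq_len(nrow(prs))) {
    i <- prs[k, 1]; j <- prs[k, 2]
    if (prs[k, 3] < rad[i] + rad[j]) {
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  for (i in seq_len(n)) {
    js <- nb[[i]]
    if (is.null(js)) next
    pts <- sweep(dirs * rad[i], 2, xyz[i, ], `+`)
    # depth of each point inside each neighbor's extended sphere
    best_depth <- rep(0, n_points)
    best_j <- rep(0L, n_points)
    for (j in js) {
      dj <- sqrt(colSums((t(pts) - xyz[j, ])^2))
      depth <- rad[j] - dj
      upd <- depth > best_depth
      best_depth[upd] <- depth[upd]
      best_j[upd] <- j
    }
    claimed <- best_j > 0L
    if (!any(claimed)) next
    pt_area <- 4 * pi * rad[i]^2 / n_points
    for (j in unique(best_j[claimed])) {
      if (resid[j] == resid[i]) next
      a <- sum(best_j == j) * pt_area
      key <- paste(min(resid[i], resid[j]), max(resid[i], resid[j]))
      prev <- if (exists(key, envir = areas, inherits = FALSE)) {
        get(key, envir = areas, inherits = FALSE)
      } else {
        0
      }
      assign(key, prev + a, envir = areas)
    }
  }
  out <- unlist(as.list(areas))
  if (is.null(out)) out <- numeric(0)
  out
}

#' CAD-AA score
#'
#' All-atom contact-area difference: residue-pair contact areas are
#' computed for reference and model by sphere-surface sampling, and the
#' score is one minus the bounded, normalized total area difference over
#' the reference's contacting residue pairs.  1 is a perfect match.
#'
#' @param model,reference `atomic_model`s.
#' @param n_points surface sample points per atom (default 256).
#' @return numeric in \[0, 1\].
#' @export
cad_aa <- function(model, reference, n_points = 256) {
  pr <- pair_residues(model, reference)
  # restrict both structures to paired residues so residue indices align
  Tm <- contact_areas(subset_residues(reference, pr$reference), n_points)
  Mm <- contact_areas(subset_residues(model, pr$model), n_points)
  Tm <- Tm[Tm > 0]
  if (length(Tm) == 0) stop("reference structure has no residue contacts")
  M <- Mm[names(Tm)]
  M[is.na(M)] <- 0
  1 - sum(pmin(abs(Tm - M), Tm)) / sum(Tm)
}

subset_residues <- function(model, res_idx) {
  idx <- unlist(model$residues$atom_index[res_idx])
  atomic_model(model$atoms[idx, , drop = FALSE],
               source_label = model$source_label)
}

# ---- MP-proxy ----------------------------------------------------------------

# Coarse favored phi/psi regions (deg): right-handed helix, extended/beta,
# and the left-handed helix region (the latter only generous for GLY).
rama_favored <- function(phi, psi, resname) {
  in_box <- function(p, s, pb, sb) {
    p > pb[1] & p < pb[2] & s > sb[1] & s < sb[2]
  }
  alpha <- in_box(phi, psi, c(-160, -40), c(-90, 40))
  beta <- in_box(phi, psi, c(-180, -45), c(85, 180)) |
    in_box(phi, psi, c(-180, -45), c(-180, -150))
  lalpha <- in_box(phi, psi, c(30, 100), c(-20, 90))
  ok <- alpha | beta | (lalpha & resname == "GLY")
  ok | resname == "GLY"  # glycine tolerated everywhere in the coarse table
}

backbone_dihedrals <- function(model) {
  nres <- n_residues(model)
  xyz <- coords(model)
  gp <- function(r, nm) {
    k <- atom_in_residue(model, r, nm)
    if (is.na(k)) NULL else xyz[k, ]
  }
  phi <- rep(NA_real_, nres)
  psi <- rep(NA_real_, nres)
  res <- model$residues
  for (r in seq_len(nres)) {
    N <- gp(r, "N"); CA <- gp(r, "CA"); C <- gp(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (r > 1 && res$chain[r - 1] == res$chain[r]) {
      Cp <- gp(r - 1, "C")
      if (!is.null(Cp)) phi[r] <- rad2deg(dihedral_at(Cp, N, CA, C))
    }
    if (r < nres && res$chain[r + 1] == res$chain[r]) {
      Nn <- gp(r + 1, "N")
      if (!is.null(Nn)) psi[r] <- rad2deg(dihedral_at(N, CA, C, Nn))
    }
  }
  list(phi = phi, psi = psi)
}

chi1_angles <- function(model) {
  nres <- n_residues(model)
  xyz <- coords(model)
  out <- rep(NA_real_, nres)
  for (r in seq_len(nres)) {
    chain4 <- CHI_ATOMS[[model$residues$resname[r]]]
    if (is.null(chain4)) next
    q <- vapply(chain4[[1]], function(nm) atom_in_residue(model, r, nm),
                integer(1))
    if (anyNA(q)) next
    out[r] <- rad2deg(dihedral_at(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ],
                                  xyz[q[4], ]))
  }
  out
}

#' Count of severe steric clashes
#'
#' Heavy-atom pairs more than 3 covalent bonds apart whose distance is more
#' than `overlap` A below the sum of their van der Waals radii.
#'
#' @param model an `atomic_model`.
#' @param overlap overlap threshold in A (default 0.4).
#' @return integer clash count.
#' @export
clash_count <- function(model, overlap = 0.4) {
  topo <- ff_topology(model)
  xyz <- coords(model)
  prs <- nonbonded_pairs(topo, xyz, 2 * max(topo$vdw))
  if (nrow(prs) == 0) return(0L)
  thr <- topo$vdw[prs[, 1]] + topo$vdw[prs[, 2]] - overlap
  sum(prs[, 3] < thr)
}

#' MolProbity-style composite proxy (MP-proxy)
#'
#' A physical-realism score combining a clash score (clashes per 1000
#' atoms), the rotamer-outlier percentage (chi1 further than 40 degrees
#' from any staggered position) and the Ramachandran-favored percentage
#' from a coarse region table, using the published MolProbity combination
#' constants.  Lower is better; a clash-free model with favored backbone
#' and rotamers scores 0.5.  This proxy is not MolProbity.
#'
#' @param model an `atomic_model`.
#' @return numeric score >= 0.
#' @export
mp_proxy <- function(model) {
  model <- strip_hydrogens(model)
  n_atoms <- nrow(model$atoms)
  clashscore <- 1000 * clash_count(model) / n_atoms
  bd <- backbone_dihedrals(model)
  scorable <- !is.na(bd$phi) & !is.na(bd$psi)
  rama_fav <- if (any(scorable)) {
    100 * mean(rama_favored(bd$phi[scorable], bd$psi[scorable],
                            model$residues$resname[scorable]))
  } else {
    100
  }
  chi1 <- chi1_angles(model)
  chi_ok <- !is.na(chi1)
  rot_out <- if (any(chi_ok)) {
    devs <- vapply(chi1[chi_ok], function(x) {
      min(abs(((x - c(-60, 60, 180) + 180) %% 360) - 180))
    }, numeric(1))
    100 * mean(devs > 40)
  } else {
    0
  }
  0.426 * log(1 + clashscore) + 0.33 * log(1 + max(0, rot_out - 1)) +
    0.25 * log(1 + max(0, 100 - rama_fav - 2)) + 0.5
}

#' Evaluate all six quality metrics
#'
#' @param model,reference `atomic_model`s; `mp_proxy` is computed on the
#'   model alone.
#' @return a `metric_vector`: named list with `gdt_ts`, `rmsd`, `gdc_sc`,
#'   `mp_proxy`, `sphere_grinder`, `cad_aa`, `aligned_length`; any failed
#'   metric is NA with the reason in attribute `failures`.
#' @export
evaluate_all <- function(model, reference) {
  failures <- list()
  run <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  out <- list(
    gdt_ts = run("gdt_ts", gdt_ts(model, reference)),
    rmsd = run("rmsd", kabsch_rmsd(model, reference, "CA")$rmsd),
    gdc_sc = run("gdc_sc", gdc_sc(model, reference)),
    mp_proxy = run("mp_proxy", mp_proxy(model)),
    sphere_grinder = run("sphere_grinder", sphere_grinder(model, reference)),
    cad_aa = run("cad_aa", cad_aa(model, reference)),
    aligned_length = run("aligned_length",
                         pair_residues(model, reference)$n)
  )
  structure(out, class = "metric_vector", failures = failures)
}

#' @export
print.metric_vector <- function(x, ...) {
  v <- unlist(x[METRIC_NAMES])
  cat("metric_vector:\n")
  print(round(v, 4))
  invisible(x)
}

METRIC_NAMES <- c("gdt_ts", "rmsd", "gdc_sc", "mp_proxy", "sphere_grinder",
                  "cad_aa")

# Metrics where a lower value means a better model.
LOWER_IS_BETTER <- c(gdt_ts = FALSE, rmsd = TRUE, gdc_sc = FALSE,
                     mp_proxy = TRUE, sphere_grinder = FALSE,
                     cad_aa = FALSE)
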