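# Synthetic fixtures and decoys: idealized peptides built from internal
# coordinates, controlled perturbations with a replayable ground-truth log,
# and multi-group assessment scenarios with a planted skill gradient.
# Everything is deterministic under the supplied seed.

#' Build an idealized all-heavy-atom peptide
#'
#' Backbone constructed from standard bond geometry at the phi/psi values
#' of the requested topology (helix: -57/-47; strand: -119/113;
#' helix-loop-helix: helix phi/psi with an extended linker), side chains
#' placed at common rotamers.  Residue types outside the builder's
#' supported set are replaced by ALA with a warning.
#'
#' @param n_residues number of residues (>= 4).
#' @param sequence optional 1-letter sequence (length `n_residues`); NULL
#'   gives a mixed default sequence.
#' @param topology "helix", "strand" or "helix-loop-helix".
#' @param chain chain identifier.
#' @return an `atomic_model`.
#' @export
build_ideal_peptide <- function(n_residues, sequence = NULL,
                                topology = c("helix", "strand",
                                             "helix-loop-helix"),
                                chain = "A") {
  topology <- match.arg(topology)
  if (n_residues < 4) stop("need at least 4 residues")
  seq3 <- resolve_sequence(n_residues, sequence)
  pp <- topology_phipsi(n_residues, topology)
  g <- BACKBONE_GEOM
  res_atoms <- vector("list", n_residues)
  N <- CA <- C <- vector("list", n_residues)
  for (r in seq_len(n_residues)) {
    if (r == 1) {
      N[[r]] <- c(0, 0, 0)
      CA[[r]] <- c(g$b_N_CA, 0, 0)
      th <- deg2rad(g$a_N_CA_C)
      C[[r]] <- CA[[r]] + g$b_CA_C * c(-cos(th), sin(th), 0)
    } else {
      N[[r]] <- place_atom(N[[r - 1]], CA[[r - 1]], C[[r - 1]], g$b_C_N,
                           deg2rad(g$a_CA_C_N), deg2rad(pp$psi[r - 1]))
      CA[[r]] <- place_atom(CA[[r - 1]], C[[r - 1]], N[[r]], g$b_N_CA,
                            deg2rad(g$a_C_N_CA), deg2rad(180))
      C[[r]] <- place_atom(C[[r - 1]], N[[r]], CA[[r]], g$b_CA_C,
                           deg2rad(g$a_N_CA_C), deg2rad(pp$phi[r]))
    }
  }
  for (r in seq_len(n_residues)) {
    atoms <- list(N = N[[r]], CA = CA[[r]], C = C[[r]])
    atoms$O <- place_atom(N[[r]], CA[[r]], C[[r]], g$b_C_O,
                          deg2rad(g$a_CA_C_O), deg2rad(pp$psi[r] + 180))
    rn <- seq3[r]
    if (rn != "GLY") {
      atoms$CB <- place_atom(C[[r]], N[[r]], CA[[r]], g$b_CA_CB,
                             deg2rad(g$a_N_CA_CB),
                             deg2rad(g$d_improper_CB))
      zmat <- SIDECHAIN_ZMAT[[rn]]
      if (!is.null(zmat)) {
        chis <- ROTAMERS[[rn]][[1]]
        atoms <- c(atoms, place_sidechain(atoms, zmat, chis))
      }
    }
    if (r == n_residues) {
      atoms$OXT <- place_atom(N[[r]], CA[[r]], C[[r]], g$b_C_OXT,
                              deg2rad(117.0), deg2rad(pp$psi[r]))
    }
    res_atoms[[r]] <- data.frame(
      serial = 0L, name = names(atoms), element = element_of(names(atoms)),
      resname = rn, chain = chain, resseq = r, icode = "",
      x = vapply(atoms, `[`, numeric(1), 1),
      y = vapply(atoms, `[`, numeric(1), 2),
      z = vapply(atoms, `[`, numeric(1), 3),
      occ = 1, b = 0, is_h = FALSE, stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, res_atoms)
  at$serial <- seq_len(nrow(at))
  atomic_model(at, source_label = sprintf("ideal_%s_%d", topology,
                                          n_residues))
}

# Side-chain placement from the z-matrix at the given chi values (deg).
place_sidechain <- function(atoms, zmat, chis) {
  out <- list()
  getpos <- function(nm) {
    if (!is.null(out[[nm]])) out[[nm]] else atoms[[nm]]
  }
  for (row in zmat) {
    refs <- row[[2]]
    dih <- eval_dihedral_spec(row[[5]], chis)
    out[[row[[1]]]] <- place_atom(getpos(refs[1]), getpos(refs[2]),
                                  getpos(refs[3]), row[[3]],
                                  deg2rad(row[[4]]), deg2rad(dih))
  }
  out
}

# "chi2+120"-style dihedral specs.
eval_dihedral_spec <- function(spec, chis) {
  if (grepl("^chi", spec)) {
    m <- regmatches(spec, regexec("^chi([0-9])([+-][0-9.]+)?$", spec))[[1]]
    base <- chis[[paste0("chi", m[2])]]
    off <- if (nzchar(m[3])) as.numeric(m[3]) else 0
    base + off
  } else {
    as.numeric(spec)
  }
}

resolve_sequence <- function(n, sequence) {
  if (is.null(sequence)) {
    pool <- c("A", "S", "L", "N", "V", "Q", "T", "A", "H", "K", "D", "E")
    sequence <- paste(rep_len(pool, n), collapse = "")
  }
  letters1 <- strsplit(sequence, "")[[1]]
  if (length(letters1) != n) {
    stop("sequence length ", length(letters1), " != n_residues ", n)
  }
  seq3 <- names(AA1)[match(letters1, AA1)]
  if (anyNA(seq3)) stop("unknown residue letter in sequence")
  unsupported <- !(seq3 %in% BUILDER_RESIDUES)
  if (any(unsupported)) {
    warning("residue type(s) outside the builder set replaced by ALA: ",
            paste(unique(seq3[unsupported]), collapse = ", "))
    seq3[unsupported] <- "ALA"
  }
  seq3
}

topology_phipsi <- function(n, topology) {
  helix <- c(-57, -47)
  strand <- c(-119, 113)
  loop <- c(-75, 145)
  if (topology == "helix") {
    list(phi = rep(helix[1], n), psi = rep(helix[2], n))
  } else if (topology == "strand") {
    list(phi = rep(strand[1], n), psi = rep(strand[2], n))
  } else {
    n1 <- max(4, floor(n * 0.4))
    nl <- max(2, floor(n * 0.2))
    n2 <- n - n1 - nl
    phi <- c(rep(helix[1], n1), rep(loop[1], nl), rep(helix[1], n2))
    psi <- c(rep(helix[2], n1), rep(loop[2], nl), rep(helix[2], n2))
    list(phi = phi, psi = psi)
  }
}

#' Decoy perturbation specification
#'
#' @param backbone_noise_sd per-atom Gaussian noise SD in A (applied to
#'   every atom).
#' @param sidechain_scramble_fraction fraction of residues whose side chain
#'   is rebuilt at a random rotamer.
#' @param segment_shift list(range = residue-window length, magnitude = A)
#'   rigid shift of one random contiguous segment; NULL disables.
#' @param clash_injection number of deliberate steric clashes introduced by
#'   displacing side-chain tips toward nearby atoms.
#' @param hb_corruption number of random ASN/GLN/HIS amide or ring flips.
#' @param seed RNG seed.
#' @return a `decoy_spec` list.
#' @export
decoy_spec <- function(backbone_noise_sd = 0.3,
                       sidechain_scramble_fraction = 0.2,
                       segment_shift = NULL, clash_injection = 0,
                       hb_corruption = 0, seed = 1) {
  stopifnot(backbone_noise_sd >= 0, sidechain_scramble_fraction >= 0,
            sidechain_scramble_fraction <= 1, clash_injection >= 0,
            hb_corruption >= 0)
  structure(list(backbone_noise_sd = backbone_noise_sd,
                 sidechain_scramble_fraction = sidechain_scramble_fraction,
                 segment_shift = segment_shift,
                 clash_injection = clash_injection,
                 hb_corruption = hb_corruption, seed = seed),
            class = "decoy_spec")
}

#' Perturb a native structure into a starting-model decoy
#'
#' Applies, in a fixed replayable order: segment rigid shift, per-atom
#' Gaussian noise, side-chain rotamer scrambling, discrete ASN/GLN/HIS
#' flips, and clash injection.  The returned log records every move.
#'
#' @param native an `atomic_model`.
#' @param spec a [decoy_spec()].
#' @return list with `model` (the decoy) and `log` (list of moves).
#' @export
perturb <- function(native, spec = decoy_spec()) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  model <- native
  xyz <- coords(model)
  log <- list(seed = spec$seed)
  if (!is.null(spec$segment_shift)) {
    len <- min(spec$segment_shift$range, n_residues(model))
    s <- sample.int(n_residues(model) - len + 1, 1)
    segment <- s:(s + len - 1)
    dir <- unit_vec(stats::rnorm(3))
    shift <- spec$segment_shift$magnitude * dir
    idx <- unlist(model$residues$atom_index[segment])
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, shift, `+`)
    log$segment_shift <- list(residues = segment, shift = shift)
  }
  if (spec$backbone_noise_sd > 0) {
    noise <- matrix(stats::rnorm(length(xyz), sd = spec$backbone_noise_sd),
                    ncol = 3)
    xyz <- xyz + noise
    log$noise_sd <- spec$backbone_noise_sd
  }
  model <- set_coords(model, xyz)
  if (spec$sidechain_scramble_fraction > 0) {
    cand <- which(model$residues$resname %in% names(SIDECHAIN_ZMAT))
    ns <- round(spec$sidechain_scramble_fraction * length(cand))
    if (ns > 0) {
      scr <- sample(cand, ns)
      for (r in scr) model <- rebuild_sidechain(model, r, random = TRUE)
      log$scrambled_residues <- scr
    }
  }
  if (spec$hb_corruption > 0) {
    cand <- which(model$residues$resname %in% c("ASN", "GLN", "HIS"))
    nf <- min(spec$hb_corruption, length(cand))
    if (nf > 0) {
      fl <- sample(cand, nf)
      xyz <- coords(model)
      for (r in fl) {
        rn <- model$residues$resname[r]
        fg <- FLIP_GROUPS[[rn]]
        ax1 <- atom_in_residue(model, r, fg$axis[1])
        ax2 <- atom_in_residue(model, r, fg$axis[2])
        if (is.na(ax1) || is.na(ax2)) next
        R <- rotation_about_axis(xyz[ax2, ] - xyz[ax1, ], pi)
        for (nm in fg$moved) {
          k <- atom_in_residue(model, r, nm)
          if (is.na(k)) next
          xyz[k, ] <- xyz[ax1, ] + as.numeric(R %*% (xyz[k, ] - xyz[ax1, ]))
        }
      }
      model <- set_coords(model, xyz)
      log$flipped_residues <- fl
    }
  }
  if (spec$clash_injection > 0) {
    xyz <- coords(model)
    topo <- ff_topology(model)
    cand <- which(model$residues$resname %in% names(SIDECHAIN_ZMAT))
    nc <- min(spec$clash_injection, length(cand))
    if (nc > 0) {
      targets <- sample(cand, nc)
      clashes <- list()
      for (r in targets) {
        zmat <- SIDECHAIN_ZMAT[[model$residues$resname[r]]]
        tip_name <- zmat[[length(zmat)]][[1]]
        tip <- atom_in_residue(model, r, tip_name)
        if (is.na(tip)) next
        d <- sqrt(rowSums(sweep(xyz, 2, xyz[tip, ])^2))
        excl <- topo$excl[[tip]]
        near <- setdiff(order(d)[-1], excl)
        near <- near[topo$resi[near] != r][1]
        if (is.na(near)) next
        u <- unit_vec(xyz[tip, ] - xyz[near, ])
        xyz[tip, ] <- xyz[near, ] + 1.8 * u
        clashes[[length(clashes) + 1]] <- c(tip = tip, against = near)
      }
      model <- set_coords(model, xyz)
      log$clashes <- clashes
    }
  }
  model$source_label <- paste0(native$source_label, "_decoy", spec$seed)
  list(model = model, log = log)
}

# Rebuild the side chain of residue r beyond CB from the z-matrix, at the
# default or a random rotamer.
rebuild_sidechain <- function(model, r, random = FALSE) {
  rn <- model$residues$resname[r]
  zmat <- SIDECHAIN_ZMAT[[rn]]
  if (is.null(zmat)) return(model)
  rots <- ROTAMERS[[rn]]
  chis <- if (random) rots[[sample.int(length(rots), 1)]] else rots[[1]]
  if (random) {
    chis <- chis + stats::rnorm(length(chis), sd = 10)
  }
  xyz <- coords(model)
  anchors <- list()
  for (nm in c("N", "CA", "CB")) {
    k <- atom_in_residue(model, r, nm)
    if (is.na(k)) return(model)
    anchors[[nm]] <- xyz[k, ]
  }
  placed <- place_sidechain(anchors, zmat, as.list(chis))
  for (nm in names(placed)) {
    k <- atom_in_residue(model, r, nm)
    if (!is.na(k)) xyz[k, ] <- placed[[nm]]
  }
  set_coords(model, xyz)
}

#' Generate a synthetic multi-group assessment scenario
#'
#' Builds `n_targets` native/start pairs and, for each group, five
#' "refined" models per target: the start moved toward (positive skill) or
#' away from (negative skill) the native by a skill-dependent fraction plus
#' small coordinate noise.  A group with skill 0 reproduces the start
#' exactly (a planted equivalent of the Void control).
#'
#' @param out_dir output directory; `targets/` and `submissions/` trees are
#'   created inside.
#' @param skills named numeric vector (one per group) in \[-1, 1\].
#' @param n_targets number of targets (>= 2).
#' @param n_models models per group per target (default 5).
#' @param seed RNG seed.
#' @return invisibly, a list with the directory paths and the ground truth.
#' @export
make_assessment_scenario <- function(out_dir, skills, n_targets = 3,
                                     n_models = 5, seed = 1) {
  if (length(skills) < 2) stop("need at least 2 groups")
  if (n_targets < 2) stop("need at least 2 targets")
  if (is.null(names(skills))) {
    names(skills) <- sprintf("group%02d", seq_along(skills))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  tdir <- file.path(out_dir, "targets")
  sdir <- file.path(out_dir, "submissions")
  topo_cycle <- c("helix", "strand", "helix-loop-helix")
  truth <- list(skills = skills, targets = list())
  for (t in seq_len(n_targets)) {
    tg <- sprintf("T%04d", t)
    dir.create(file.path(tdir, tg), recursive = TRUE, showWarnings = FALSE)
    n_res <- 10 + 2 * ((t - 1) %% 3)
    native <- build_ideal_peptide(n_res,
                                  topology = topo_cycle[1 + (t - 1) %% 3])
    dec <- perturb(native, decoy_spec(backbone_noise_sd = 0.45,
                                      sidechain_scramble_fraction = 0.3,
                                      clash_injection = 1,
                                      seed = seed * 1000 + t))
    start <- dec$model
    write_pdb(native, file.path(tdir, tg, "native.pdb"))
    write_pdb(start, file.path(tdir, tg, "start.pdb"))
    xyz_n <- coords(native)
    xyz_s <- coords(start)
    for (g in names(skills)) {
      gdir <- file.path(sdir, g, tg)
      dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
      s <- skills[[g]]
      for (k in seq_len(n_models)) {
        if (s == 0) {
          mdl <- start
        } else {
          frac <- s * (1 - 0.08 * (k - 1))
          xyz <- xyz_s + frac * (xyz_n - xyz_s) +
            matrix(stats::rnorm(length(xyz_s), sd = 0.03), ncol = 3)
          mdl <- set_coords(start, xyz)
        }
        write_pdb(mdl, file.path(gdir, sprintf("model_%d.pdb", k)))
      }
    }
    truth$targets[[tg]] <- list(n_res = n_res, log = dec$log)
  }
  jsonlite::write_json(
    list(skills = as.list(skills), seed = seed),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(list(targets_dir = tdir, submissions_dir = sdir, truth = truth))
}
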