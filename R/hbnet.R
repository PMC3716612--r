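# Step 1 of the refinement protocol: place polar hydrogens and optimize the
# hydrogen-bonding network by a discrete, clash-penalized conformational
# search over amide/imidazole flips, the HIS tautomer, and hydroxyl /
# sulfhydryl / ammonium rotor positions.  The result is the extended
# atomic model.

#' Add polar hydrogens at template geometry
#'
#' Places backbone amide hydrogens (the N-terminus is modelled as an NH3+
#' rotor), and side-chain N-H / O-H / S-H hydrogens per residue templates.
#' Rotatable hydrogens start at an arbitrary grid position; nonpolar
#' hydrogens are not added.  Heavy atoms are never moved.
#'
#' @param model an `atomic_model` (heavy atoms).
#' @return an `atomic_model` including polar hydrogens.
#' @export
add_polar_hydrogens <- function(model) {
  model <- strip_hydrogens(model)
  at <- model$atoms
  res <- model$residues
  xyz <- coords(model)
  new_rows <- vector("list", nrow(res))
  gp <- function(r, nm) {
    k <- atom_in_residue(model, r, nm)
    if (is.na(k)) NULL else xyz[k, ]
  }
  h_row <- function(r, name, pos) {
    data.frame(serial = 0L, name = name, element = "H",
               resname = res$resname[r], chain = res$chain[r],
               resseq = res$resseq[r], icode = res$icode[r],
               x = pos[1], y = pos[2], z = pos[3], occ = 1, b = 0,
               is_h = TRUE, stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(res))) {
    rn <- res$resname[r]
    rows <- list()
    N <- gp(r, "N"); CA <- gp(r, "CA"); C <- gp(r, "C")
    nterm <- r == 1 || res$chain[r] != res$chain[max(1, r - 1)]
    if (!is.null(N) && !is.null(CA) && !is.null(C)) {
      if (nterm && rn != "PRO") {
        # N-terminal NH3+ rotor, staggered start
        for (k in 0:2) {
          pos <- place_atom(C, CA, N, 1.01, deg2rad(109.5),
                            deg2rad(60 + 120 * k))
          rows[[length(rows) + 1]] <- h_row(r, paste0("H", k + 1), pos)
        }
      } else if (!nterm && rn != "PRO") {
        Cp <- gp(r - 1, "C"); Op <- gp(r - 1, "O")
        if (!is.null(Cp) && !is.null(Op)) {
          pos <- N + 1.01 * unit_vec(Cp - Op)
          rows[[length(rows) + 1]] <- h_row(r, "H", pos)
        }
      }
    }
    if (!(rn %in% AA3)) {
      if (length(rows) == 0) {
        warning("unknown residue type ", rn, "; no hydrogens added")
      }
    }
    tmpl <- POLAR_H_TEMPLATES[[rn]]
    if (!is.null(tmpl)) {
      for (tm in tmpl) {
        pos <- polar_h_position(model, xyz, r, tm, rotor_deg = 0)
        if (!is.null(pos)) rows[[length(rows) + 1]] <- h_row(r, tm[[1]], pos)
      }
    }
    if (rn == "HIS") {
      tm <- HIS_TAUTOMER_H[["NE2"]]   # default tautomer: H on NE2
      pos <- polar_h_position(model, xyz, r, tm, rotor_deg = 0)
      if (!is.null(pos)) rows[[length(rows) + 1]] <- h_row(r, tm[[1]], pos)
    }
    new_rows[[r]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  blocks <- lapply(seq_len(nrow(res)), function(r) {
    blk <- at[res$atom_index[[r]], , drop = FALSE]
    if (!is.null(new_rows[[r]])) blk <- rbind(blk, new_rows[[r]])
    blk
  })
  out <- do.call(rbind, blocks)
  out$serial <- seq_len(nrow(out))
  atomic_model(out, source_label = model$source_label)
}

# Position of a templated polar hydrogen.  tm: list(Hname, parent, refs,
# bond, angle_deg, dihedral spec).  Rotor specs resolve to rotor_deg plus
# any "+offset".
polar_h_position <- function(model, xyz, r, tm, rotor_deg = 0) {
  parent <- atom_in_residue(model, r, tm[[2]])
  a <- atom_in_residue(model, r, tm[[3]][1])
  b <- atom_in_residue(model, r, tm[[3]][2])
  if (anyNA(c(parent, a, b))) return(NULL)
  spec <- tm[[6]]
  dih <- if (grepl("^rotor", spec)) {
    off <- sub("^rotor\\+?", "", spec)
    rotor_deg + if (nzchar(off)) as.numeric(off) else 0
  } else {
    as.numeric(spec)
  }
  place_atom(xyz[a, ], xyz[b, ], xyz[parent, ], tm[[4]],
             deg2rad(tm[[5]]), deg2rad(dih))
}

# ---- discrete state space ----------------------------------------------------

FLIP_GROUPS <- list(
  ASN = list(axis = c("CB", "CG"), moved = c("OD1", "ND2", "HD21", "HD22")),
  GLN = list(axis = c("CG", "CD"), moved = c("OE1", "NE2", "HE21", "HE22")),
  HIS = list(axis = c("CB", "CG"),
             moved = c("ND1", "CD2", "CE1", "NE2", "HD1", "HE2"))
)

ROTOR_GRID <- 12L  # 30-degree steps

#' Enumerate discrete hydrogen-network states of a model
#'
#' One domain per ASN/GLN/HIS flip, HIS tautomer, and each rotatable
#' OH / SH / NH3+ group (including the N-terminal ammonium).
#'
#' @param model an `atomic_model` with polar hydrogens added.
#' @return list of `flip_state` domains, each with `residue`, `kind`,
#'   `cardinality`, and the atoms it moves.
#' @export
enumerate_states <- function(model) {
  res <- model$residues
  out <- list()
  add <- function(r, kind, card, moved) {
    out[[length(out) + 1]] <<- structure(
      list(residue = r, kind = kind, cardinality = card, moved = moved,
           state = 0L), class = "flip_state")
  }
  for (r in seq_len(nrow(res))) {
    rn <- res$resname[r]
    has <- function(nm) !is.na(atom_in_residue(model, r, nm))
    if (rn == "ASN" && has("OD1") && has("ND2")) {
      add(r, "ASN_flip", 2L, FLIP_GROUPS$ASN$moved)
    }
    if (rn == "GLN" && has("OE1") && has("NE2")) {
      add(r, "GLN_flip", 2L, FLIP_GROUPS$GLN$moved)
    }
    if (rn == "HIS" && has("ND1") && has("NE2")) {
      add(r, "HIS_flip", 2L, FLIP_GROUPS$HIS$moved)
      add(r, "HIS_tautomer", 2L, c("HD1", "HE2"))
    }
    if (rn %in% c("SER", "THR", "CYS", "TYR")) {
      hn <- POLAR_H_TEMPLATES[[rn]][[1]][[1]]
      if (has(hn)) add(r, "OH_rotation", ROTOR_GRID, hn)
      if (rn == "CYS" && has("HG")) out[[length(out)]]$kind <- "SH_rotation"
    }
    if (rn == "LYS" && has("HZ1")) {
      add(r, "NH3_rotation", ROTOR_GRID, c("HZ1", "HZ2", "HZ3"))
    }
    nterm <- r == 1 || res$chain[r] != res$chain[max(1, r - 1)]
    if (nterm && has("H1")) {
      add(r, "NH3_rotation", ROTOR_GRID, c("H1", "H2", "H3"))
    }
  }
  out
}

# Apply one domain state to coordinates; returns updated xyz and (for the
# tautomer) possibly updated atom names.
apply_state <- function(model, xyz, dom, state) {
  r <- dom$residue
  names_out <- NULL
  if (dom$kind %in% c("ASN_flip", "GLN_flip", "HIS_flip")) {
    if (state == 1) {
      rn <- model$residues$resname[r]
      fg <- FLIP_GROUPS[[rn]]
      ax1 <- atom_in_residue(model, r, fg$axis[1])
      ax2 <- atom_in_residue(model, r, fg$axis[2])
      R <- rotation_about_axis(xyz[ax2, ] - xyz[ax1, ], pi)
      for (nm in fg$moved) {
        k <- atom_in_residue(model, r, nm)
        if (is.na(k)) next
        xyz[k, ] <- xyz[ax1, ] + as.numeric(R %*% (xyz[k, ] - xyz[ax1, ]))
      }
    }
  } else if (dom$kind == "HIS_tautomer") {
    # state 0: H on NE2 (default); state 1: H on ND1
    hk <- which(model$atoms$name %in% c("HD1", "HE2") &
                  seq_len(nrow(model$atoms)) %in%
                  model$residues$atom_index[[r]])
    if (length(hk) == 1) {
      target <- if (state == 0) "NE2" else "ND1"
      tm <- HIS_TAUTOMER_H[[target]]
      pos <- polar_h_position(model, xyz, r, tm)
      if (!is.null(pos)) {
        xyz[hk, ] <- pos
        names_out <- list(index = hk, name = tm[[1]])
      }
    }
  } else {  # rotors
    tmpl <- POLAR_H_TEMPLATES[[model$residues$resname[r]]]
    deg <- 30 * state
    if (dom$kind == "NH3_rotation" && dom$moved[1] == "H1") {
      # N-terminal ammonium
      N <- atom_in_residue(model, r, "N")
      CA <- atom_in_residue(model, r, "CA")
      C <- atom_in_residue(model, r, "C")
      for (k in 0:2) {
        h <- atom_in_residue(model, r, paste0("H", k + 1))
        if (is.na(h)) next
        xyz[h, ] <- place_atom(xyz[C, ], xyz[CA, ], xyz[N, ], 1.01,
                               deg2rad(109.5), deg2rad(60 + deg + 120 * k))
      }
    } else if (!is.null(tmpl)) {
      for (tm in tmpl) {
        if (!(tm[[1]] %in% dom$moved)) next
        h <- atom_in_residue(model, r, tm[[1]])
        if (is.na(h)) next
        pos <- polar_h_position(model, xyz, r, tm, rotor_deg = deg)
        if (!is.null(pos)) xyz[h, ] <- pos
      }
    }
  }
  list(xyz = xyz, rename = names_out)
}

# Clash penalty over moved atoms: sum max(0, f * (rvdw_i + rvdw_j) - d)^2
# for moved-atom pairs against all atoms outside their exclusion sets.
clash_penalty <- function(topo, xyz, moved_idx, clash_factor) {
  pen <- 0
  n <- topo$n_atoms
  for (i in moved_idx) {
    excl <- topo$excl[[i]]
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    thr <- clash_factor * (topo$vdw[i] + topo$vdw)
    viol <- which(d < thr)
    viol <- setdiff(viol, excl)
    # avoid double-counting moved-moved pairs
    viol <- viol[!(viol %in% moved_idx & viol < i)]
    if (length(viol)) pen <- pen + sum((thr[viol] - d[viol])^2)
  }
  pen
}

#' Optimize the hydrogen-bonding network
#'
#' Discrete conformational search over the domains of [enumerate_states()]:
#' interacting domains (moved atoms within 5 A) are clustered; clusters of
#' at most `exhaustive_limit` domains are solved by exhaustive enumeration
#' of the joint state space, larger clusters by greedy descent with
#' seeded random restarts.  The objective is the hydrogen-bond energy plus
#' a local clash penalty; the input state is always a candidate, so the
#' objective never increases.
#'
#' @param model an `atomic_model` with polar hydrogens.
#' @param ss secondary-structure assignment (for the H-bond weights).
#' @param params an `ff_params`.
#' @param exhaustive_limit maximum number of variables in a cluster solved
#'   exhaustively (default 6).
#' @param max_states maximum joint state-space size enumerated exhaustively
#'   (default 2048; e.g. three 12-position rotors = 1728 states qualify,
#'   six of them do not).
#' @param restarts greedy random restarts (default 3).
#' @param seed RNG seed for the restarts (default 42).
#' @return list with `model` (the extended atomic model) and `network`
#'   (data.frame of realized hydrogen bonds; see [hb_network()]).
#' @export
optimize_network <- function(model, ss = NULL, params = ff_params(),
                             exhaustive_limit = 6, max_states = 2048,
                             restarts = 3, seed = 42) {
  doms <- enumerate_states(model)
  topo <- ff_topology(model, params)
  topo$hb_ss_weight <- hb_ss_weights(topo, ss, params)
  xyz <- coords(model)
  if (length(doms) == 0 || nrow(topo$hb$donors) == 0) {
    return(list(model = model, network = hb_network(model, params, topo)))
  }
  moved_idx <- lapply(doms, function(d) {
    idx <- vapply(d$moved, function(nm) {
      atom_in_residue(model, d$residue, nm)
    }, integer(1))
    idx[!is.na(idx)]
  })
  score_fn <- function(xz) {
    all_moved <- unlist(moved_idx)
    eval_hbond_term(topo, xz, params$hb)$E +
      clash_penalty(topo, xz, all_moved, params$clash_factor)
  }
  # interaction graph on domains
  nd <- length(doms)
  adj <- vector("list", nd)
  if (nd > 1) {
    for (i in 1:(nd - 1)) {
      for (j in (i + 1):nd) {
        di <- xyz[moved_idx[[i]], , drop = FALSE]
        dj <- xyz[moved_idx[[j]], , drop = FALSE]
        if (length(di) == 0 || length(dj) == 0) next
        dmin <- min(apply(di, 1, function(p) {
          min(sqrt(rowSums(sweep(dj, 2, p)^2)))
        }))
        if (dmin < 5) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  }
  comp <- rep(0L, nd)
  cid <- 0L
  for (i in seq_len(nd)) {
    if (comp[i] > 0) next
    cid <- cid + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- cid
      frontier <- setdiff(unlist(adj[frontier]), which(comp > 0))
    }
  }
  states <- vapply(doms, function(d) d$state, integer(1))
  apply_all <- function(st) {
    xz <- xyz
    renames <- list()
    for (k in seq_len(nd)) {
      res <- apply_state(model, xz, doms[[k]], st[k])
      xz <- res$xyz
      if (!is.null(res$rename)) renames[[length(renames) + 1]] <- res$rename
    }
    list(xyz = xz, renames = renames)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  for (cc in seq_len(cid)) {
    members <- which(comp == cc)
    cards <- vapply(doms[members], function(d) d$cardinality, integer(1))
    eval_states <- function(st_local) {
      st <- states
      st[members] <- st_local
      score_fn(apply_all(st)$xyz)
    }
    if (length(members) <= exhaustive_limit && prod(cards) <= max_states) {
      grid <- expand.grid(lapply(cards, function(cN) 0:(cN - 1)))
      sc <- apply(grid, 1, function(row) eval_states(as.integer(row)))
      states[members] <- as.integer(grid[which.min(sc), ])
    } else {
      best_local <- states[members]
      best_sc <- eval_states(best_local)
      for (rs in 0:restarts) {
        cur <- if (rs == 0) states[members] else {
          vapply(cards, function(cN) sample.int(cN, 1) - 1L, integer(1))
        }
        repeat {
          improved <- FALSE
          for (mi in seq_along(members)) {
            scs <- vapply(0:(cards[mi] - 1), function(s) {
              trial <- cur
              trial[mi] <- s
              eval_states(trial)
            }, numeric(1))
            if (min(scs) < scs[cur[mi] + 1] - 1e-12) {
              cur[mi] <- which.min(scs) - 1L
              improved <- TRUE
            }
          }
          if (!improved) break
        }
        sc <- eval_states(cur)
        if (sc < best_sc) {
          best_sc <- sc
          best_local <- cur
        }
      }
      states[members] <- best_local
    }
  }
  final <- apply_all(states)
  out <- set_coords(model, final$xyz)
  for (rn in final$renames) out$atoms$name[rn$index] <- rn$name
  out <- atomic_model(out$atoms, source_label = model$source_label)
  topo2 <- ff_topology(out, params)
  topo2$hb_ss_weight <- hb_ss_weights(topo2, ss, params)
  list(model = out, network = hb_network(out, params, topo2))
}

#' Extract the realized hydrogen-bond network
#'
#' Lists every donor-H / acceptor pair with H..A below 3.0 A and a D-H..A
#' angle above 90 degrees, with the bond's energy score.
#'
#' @param model an `atomic_model` with hydrogens.
#' @param params an `ff_params`.
#' @param topo optional precomputed topology.
#' @return data.frame with donor, hydrogen, acceptor, distance, angle and
#'   score columns, plus attribute `total_score`.
#' @export
hb_network <- function(model, params = ff_params(), topo = NULL) {
  if (is.null(topo)) topo <- ff_topology(model, params)
  xyz <- coords(model)
  at <- model$atoms
  don <- topo$hb$donors
  acc <- topo$hb$acceptors
  rows <- list()
  hbp <- params$hb
  ssw <- topo$hb_ss_weight
  if (is.null(ssw)) ssw <- rep(1, nrow(don))
  for (di in seq_len(nrow(don))) {
    D <- don[di, "D"]; H <- don[di, "H"]
    for (ai in seq_len(nrow(acc))) {
      A <- acc[ai, "A"]; Bb <- acc[ai, "B"]
      if (A == D || A %in% topo$excl[[H]]) next
      d <- vec_norm(xyz[H, ] - xyz[A, ])
      if (d >= 3.0) next
      ang <- rad2deg(angle_at(xyz[D, ], xyz[H, ], xyz[A, ]))
      if (ang <= 90) next
      cD <- cos(deg2rad(ang))
      cA <- cos(angle_at(xyz[H, ], xyz[A, ], xyz[Bb, ]) - hbp$theta_off)
      score <- -hbp$strength * ssw[di] *
        exp(-(d - hbp$d0)^2 / (2 * hbp$sigma_d^2)) *
        max(0, -cD)^hbp$p * max(0, cA)^hbp$q
      rows[[length(rows) + 1]] <- data.frame(
        donor = at$name[D], donor_res = at$resseq[D],
        hydrogen = at$name[H], acceptor = at$name[A],
        acceptor_res = at$resseq[A], distance = d, angle = ang,
        score = score, stringsAsFactors = FALSE)
    }
  }
  net <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = character(0), donor_res = integer(0),
               hydrogen = character(0), acceptor = character(0),
               acceptor_res = integer(0), distance = numeric(0),
               angle = numeric(0), score = numeric(0))
  attr(net, "total_score") <- sum(net$score)
  net
}
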