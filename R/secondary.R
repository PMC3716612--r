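# Secondary-structure assignment.
#
# The internal assigner implements the Kabsch-Sander electrostatic
# hydrogen-bond criterion on backbone geometry, so no external DSSP binary
# is required; a DSSP output file can alternatively be parsed and used
# verbatim.  Labels are the coarse 3-state alphabet H / E / C.

# Kabsch-Sander H-bond energy (kcal/mol) between the CO of residue i and
# the NH of residue j.  The amide H is reconstructed from the backbone when
# absent: 1.0 A from N, in-plane, anti to the preceding carbonyl oxygen.
ks_hbond_energy_matrix <- function(model) {
  nres <- n_residues(model)
  xyz <- coords(model)
  res <- model$residues
  gp <- function(i, nm) {
    k <- atom_in_residue(model, i, nm)
    if (is.na(k)) NULL else xyz[k, ]
  }
  # reconstruct amide H for residues 2..n (none for prolines / chain starts)
  Hpos <- vector("list", nres)
  for (j in seq_len(nres)) {
    if (res$resname[j] == "PRO") next
    hidx <- atom_in_residue(model, j, "H")
    if (!is.na(hidx)) {
      Hpos[[j]] <- xyz[hidx, ]
      next
    }
    if (j == 1 || res$chain[j - 1] != res$chain[j]) next
    N <- gp(j, "N"); Cprev <- gp(j - 1, "C"); Oprev <- gp(j - 1, "O")
    if (is.null(N) || is.null(Cprev) || is.null(Oprev)) next
    Hpos[[j]] <- N + unit_vec(Cprev - Oprev)
  }
  E <- matrix(Inf, nres, nres)
  q1q2f <- 0.084 * 332  # partial charges x electrostatic constant
  for (i in seq_len(nres)) {
    C <- gp(i, "C"); O <- gp(i, "O")
    if (is.null(C) || is.null(O)) next
    for (j in seq_len(nres)) {
      if (abs(i - j) < 2 || res$chain[i] != res$chain[j]) next
      N <- gp(j, "N"); H <- Hpos[[j]]
      if (is.null(N) || is.null(H)) next
      rON <- vec_norm(O - N); rCH <- vec_norm(C - H)
      rOH <- vec_norm(O - H); rCN <- vec_norm(C - N)
      if (min(rON, rCH, rOH, rCN) < 0.5) next
      E[i, j] <- q1q2f * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  E
}

#' Assign secondary structure from backbone geometry
#'
#' DSSP-style 3-state assignment computed internally: backbone hydrogen
#' bonds are detected with the Kabsch-Sander electrostatic criterion
#' (energy < -0.5 kcal/mol); two consecutive i -> i+4 turns make a helix,
#' bridge ladders make strands, everything else is coil.  Supplying a DSSP
#' output file via `dssp_file` overrides the internal assignment.
#'
#' @param model an `atomic_model` with backbone N, CA, C, O atoms.
#' @param dssp_file optional path to a DSSP output file.
#' @return character vector of labels in `c("H","E","C")`, one per residue,
#'   of class `ss_assignment`.
#' @export
assign_secondary_structure <- function(model, dssp_file = NULL) {
  nres <- n_residues(model)
  if (!is.null(dssp_file)) {
    ss <- parse_dssp(dssp_file)
    if (length(ss) != nres) {
      stop(sprintf("DSSP file has %d residues but the model has %d",
                   length(ss), nres))
    }
    return(structure(ss, class = "ss_assignment"))
  }
  if (nres < 4) {
    warning("fewer than 4 residues; all-coil assignment returned")
    return(structure(rep("C", nres), class = "ss_assignment"))
  }
  E <- ks_hbond_energy_matrix(model)
  hb <- E < -0.5   # hb[i, j]: CO(i) accepts from NH(j)
  ss <- rep("C", nres)
  # helices: 4-turn at i if hb(i, i+4); two consecutive turns -> H
  turn4 <- rep(FALSE, nres)
  for (i in seq_len(nres - 4)) turn4[i] <- hb[i, i + 4]
  for (i in seq_len(nres)) {
    if (i >= 2 && turn4[i - 1] && turn4[i]) ss[i:(min(i + 3, nres))] <- "H"
  }
  # bridges (parallel / antiparallel) -> E for both partners
  for (i in 2:(nres - 1)) {
    for (j in 2:(nres - 1)) {
      if (abs(i - j) < 3) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) {
        if (ss[i] != "H") ss[i] <- "E"
        if (ss[j] != "H") ss[j] <- "E"
      }
    }
  }
  structure(ss, class = "ss_assignment")
}

#' Parse a DSSP output file to 3-state labels
#'
#' Reads the per-residue summary block of a classic DSSP output file and
#' maps the 8-state alphabet onto H/E/C (H, G, I -> H; E, B -> E; else C).
#'
#' @param path DSSP output file.
#' @return character vector of 3-state labels.
#' @export
parse_dssp <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP output file: ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  body <- body[substr(body, 14, 14) != "!"]  # chain breaks
  raw <- substr(body, 17, 17)
  ss <- ifelse(raw %in% c("H", "G", "I"), "H",
               ifelse(raw %in% c("E", "B"), "E", "C"))
  ss
}
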