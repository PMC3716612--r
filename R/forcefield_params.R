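# Force-field parameter construction.
#
# The published protocol uses ENCAD-style bonded terms, a Calpha/Cbeta
# tethering restraint, a knowledge-based pairwise potential of mean force
# and an explicit hydrogen-bonding potential.  The exact constants of the
# original implementation are not public, so this package ships a
# documented parameter set built from standard equilibrium geometry
# (Engh-Huber-style bond lengths and angles, generic force constants),
# exposed through `ff_params()` and serializable to a plain-text file.

# Equilibrium bond lengths (A): specific keys first ("RES|A1|A2" or
# "*|A1|A2" for backbone), then element-pair fallbacks.
build_bond_length_table <- function() {
  g <- BACKBONE_GEOM
  tab <- c(
    "*|N|CA" = g$b_N_CA, "*|CA|C" = g$b_CA_C, "*|C|O" = g$b_C_O,
    "*|C|OXT" = g$b_C_OXT, "*|CA|CB" = g$b_CA_CB, "*|C|N" = g$b_C_N,
    "*|N|H" = 1.01, "*|N|H1" = 1.01, "*|N|H2" = 1.01, "*|N|H3" = 1.01
  )
  for (res in names(SIDECHAIN_ZMAT)) {
    for (row in SIDECHAIN_ZMAT[[res]]) {
      key <- paste(res, row[[2]][3], row[[1]], sep = "|")
      tab[key] <- row[[3]]
    }
  }
  for (res in names(POLAR_H_TEMPLATES)) {
    for (row in POLAR_H_TEMPLATES[[res]]) {
      tab[paste(res, row[[2]], row[[1]], sep = "|")] <- row[[4]]
    }
  }
  tab["HIS|ND1|HD1"] <- 1.01
  tab["HIS|NE2|HE2"] <- 1.01
  # imidazole ring-closure bond, consistent with the template construction
  tab["HIS|CD2|NE2"] <- 1.342
  tab
}

# Equilibrium angles (deg): backbone triples, z-matrix-derived side-chain
# triples, hydrogen placements; fallback by center-atom hybridization.
build_angle_table <- function() {
  g <- BACKBONE_GEOM
  tab <- c(
    "*|N|CA|C" = g$a_N_CA_C, "*|CA|C|N" = g$a_CA_C_N,
    "*|C|N|CA" = g$a_C_N_CA, "*|CA|C|O" = g$a_CA_C_O,
    "*|N|CA|CB" = g$a_N_CA_CB, "*|C|CA|CB" = g$a_C_CA_CB,
    "*|O|C|OXT" = g$a_O_C_OXT, "*|CA|C|OXT" = 117.0,
    "*|O|C|N" = 123.0, "*|C|N|H" = 119.2, "*|CA|N|H" = 119.1,
    "*|CA|N|H1" = 109.5, "*|CA|N|H2" = 109.5, "*|CA|N|H3" = 109.5,
    "*|H1|N|H2" = 109.5, "*|H1|N|H3" = 109.5, "*|H2|N|H3" = 109.5
  )
  for (res in names(SIDECHAIN_ZMAT)) {
    for (row in SIDECHAIN_ZMAT[[res]]) {
      refs <- row[[2]]
      tab[paste(res, refs[2], refs[3], row[[1]], sep = "|")] <- row[[4]]
    }
  }
  for (res in names(POLAR_H_TEMPLATES)) {
    for (row in POLAR_H_TEMPLATES[[res]]) {
      tab[paste(res, row[[3]][2], row[[2]], row[[1]], sep = "|")] <- row[[5]]
    }
  }
  tab["HIS|CG|ND1|HD1"] <- 125.5
  tab["HIS|CE1|NE2|HE2"] <- 125.5
  # planar-group completions consistent with the template construction
  tab["HIS|ND1|CG|CD2"] <- 105.6
  tab["HIS|CG|CD2|NE2"] <- 109.6
  tab["HIS|CD2|NE2|CE1"] <- 106.5
  tab["ASN|OD1|CG|ND2"] <- 122.8
  tab["GLN|OE1|CD|NE2"] <- 122.8
  tab["ASP|OD1|CG|OD2"] <- 123.2
  tab["GLU|OE1|CD|OE2"] <- 123.2
  tab
}

# sp2 side-chain centers per residue type (fallback theta0 of 120 deg).
SP2_CENTERS <- list(
  ASN = "CG", ASP = "CG", GLN = "CD", GLU = "CD", ARG = c("NE", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

#' Default force-field parameters
#'
#' Returns the parameter set for the composite energy: harmonic bond and
#' angle constants with Engh-Huber-style equilibrium values, cosine torsion
#' terms (peptide-bond planarity and 3-fold sp3 chi terms), the Calpha /
#' Cbeta tether constant, hydrogen-bond potential parameters, and the
#' per-term weights of the total energy.
#'
#' @param tether_k harmonic tether constant, kcal/mol/A^2.
#' @param term_weights named weights applied to `bond`, `angle`, `torsion`,
#'   `tether`, `pmf`, `hbond` in the total energy (all default 1).
#' @return an object of class `ff_params`.
#' @export
ff_params <- function(tether_k = 1.0,
                      term_weights = c(bond = 1, angle = 1, torsion = 1,
                                       tether = 1, pmf = 1, hbond = 1)) {
  structure(list(
    k_bond = 300,            # kcal/mol/A^2
    k_angle = 80,            # kcal/mol/rad^2
    k_omega = 10,            # peptide planarity, n = 2, delta = pi
    k_chi = 0.2,             # sp3 staggering, n = 3, delta = 0
    tether_k = tether_k,
    bond_lengths = build_bond_length_table(),
    angle_values = build_angle_table(),
    # hydrogen-bond potential: Gaussian in the H..A distance times
    # clamped-cosine angular factors at donor and acceptor
    hb = list(d0 = 2.0, sigma_d = 0.3, p = 2, q = 2,
              theta_off = deg2rad(120), cap = 3.0,
              w_ss = c(H = 1, E = 1, C = 1), strength = 2.0),
    hb_cap = 3.0,
    clash_factor = 0.8,      # discrete-search clash penalty threshold factor
    term_weights = term_weights
  ), class = "ff_params")
}

lookup_bond_length <- function(params, res, a1, a2) {
  tab <- params$bond_lengths
  for (key in c(paste(res, a1, a2, sep = "|"), paste(res, a2, a1, sep = "|"),
                paste("*", a1, a2, sep = "|"), paste("*", a2, a1, sep = "|"))) {
    if (!is.na(tab[key])) return(unname(tab[key]))
  }
  e1 <- element_of(a1); e2 <- element_of(a2)
  ek <- paste(sort(c(e1, e2)), collapse = "-")
  fallback <- c("C-C" = 1.52, "C-N" = 1.47, "C-O" = 1.42, "C-S" = 1.81,
                "H-N" = 1.01, "H-O" = 0.96, "H-S" = 1.34, "N-N" = 1.35,
                "C-H" = 1.09, "O-O" = 1.40, "H-H" = 1.0)
  v <- fallback[ek]
  if (is.na(v)) 1.5 else unname(v)
}

lookup_angle_value <- function(params, res, a1, a2, a3) {
  tab <- params$angle_values
  for (key in c(paste(res, a1, a2, a3, sep = "|"),
                paste(res, a3, a2, a1, sep = "|"),
                paste("*", a1, a2, a3, sep = "|"),
                paste("*", a3, a2, a1, sep = "|"))) {
    if (!is.na(tab[key])) return(deg2rad(unname(tab[key])))
  }
  sp2 <- SP2_CENTERS[[res]]
  if (!is.null(sp2) && a2 %in% sp2) return(deg2rad(120))
  if (a2 %in% c("C")) return(deg2rad(120))   # backbone carbonyl carbon
  deg2rad(109.47)
}

#' Write force-field parameters to a text file
#'
#' Flat `key = value` format with the bond-length and angle tables as
#' tab-separated blocks; readable back with [read_ff_params()].
#' @param params an `ff_params` object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_ff_params <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  scal <- c(k_bond = params$k_bond, k_angle = params$k_angle,
            k_omega = params$k_omega, k_chi = params$k_chi,
            tether_k = params$tether_k,
            hb_d0 = params$hb$d0, hb_sigma_d = params$hb$sigma_d,
            hb_p = params$hb$p, hb_q = params$hb$q,
            hb_theta_off_deg = rad2deg(params$hb$theta_off),
            hb_cap = params$hb$cap, hb_strength = params$hb$strength,
            clash_factor = params$clash_factor)
  writeLines("[scalars]", con)
  writeLines(sprintf("%s = %.10g", names(scal), scal), con)
  writeLines("[term_weights]", con)
  writeLines(sprintf("%s = %.10g", names(params$term_weights),
                     params$term_weights), con)
  writeLines("[bond_lengths]", con)
  writeLines(sprintf("%s\t%.6f", names(params$bond_lengths),
                     params$bond_lengths), con)
  writeLines("[angle_values_deg]", con)
  writeLines(sprintf("%s\t%.6f", names(params$angle_values),
                     params$angle_values), con)
  invisible(path)
}

#' Read force-field parameters from a text file
#' @param path file written by [write_ff_params()].
#' @return an `ff_params` object.
#' @export
read_ff_params <- function(path) {
  lines <- readLines(path)
  section <- ""
  p <- ff_params()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) { section <- gsub("\\[|\\]", "", ln); next }
    if (section %in% c("scalars", "term_weights")) {
      kv <- strsplit(ln, "\\s*=\\s*")[[1]]
      key <- kv[1]; val <- as.numeric(kv[2])
      if (section == "term_weights") {
        p$term_weights[key] <- val
      } else if (grepl("^hb_", key)) {
        hk <- sub("^hb_", "", key)
        if (hk == "theta_off_deg") p$hb$theta_off <- deg2rad(val)
        else p$hb[[hk]] <- val
      } else {
        p[[key]] <- val
      }
    } else if (section == "bond_lengths") {
      kv <- strsplit(ln, "\t")[[1]]
      p$bond_lengths[kv[1]] <- as.numeric(kv[2])
    } else if (section == "angle_values_deg") {
      kv <- strsplit(ln, "\t")[[1]]
      p$angle_values[kv[1]] <- as.numeric(kv[2])
    }
  }
  p
}
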