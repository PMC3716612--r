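# The atomic_model container and PDB input/output.
#
# An atomic_model holds an ordered atom table plus derived residue grouping.
# Coordinates are in Angstrom; residue numbering follows the source PDB
# (1-based as deposited); internal arrays are 0/1-based contiguous indices
# with the mapping kept in the residue table.

#' Construct an atomic model from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occ`, `b`,
#'   `is_h`.  Missing `element`/`is_h` are derived from `name`.
#' @param source_label free-text provenance tag (target id, group id, ...).
#' @return an object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, source_label = "") {
  need <- c("name", "resname", "chain", "resseq", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atom table must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty model: no atoms")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element)) atoms$element <- element_of(atoms$name)
  if (is.null(atoms$is_h)) atoms$is_h <- atoms$element == "H"
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite atom coordinates")
  }
  atoms$icode[is.na(atoms$icode)] <- ""
  rownames(atoms) <- NULL
  m <- structure(list(atoms = atoms, source_label = source_label),
                 class = "atomic_model")
  m$residues <- derive_residues(atoms)
  m$sequence <- model_sequence(m)
  m
}

# Residue table: one row per (chain, resseq, icode) in atom order, with the
# atom index range mapping PDB numbering onto contiguous internal indices.
derive_residues <- function(atoms) {
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, sep = "|")
  idx <- match(key, unique(key))
  first <- !duplicated(idx)
  data.frame(
    chain = atoms$chain[first],
    resseq = atoms$resseq[first],
    icode = atoms$icode[first],
    resname = atoms$resname[first],
    atom_index = I(split(seq_along(idx), idx)),
    stringsAsFactors = FALSE
  )
}

model_sequence <- function(model) {
  res <- model$residues
  vapply(split(aa_three_to_one(res$resname), res$chain), paste,
         collapse = "", FUN.VALUE = "")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms, %d residues, %d chain(s)%s\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$residues$chain)),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]")
              else ""))
  invisible(x)
}

#' Coordinates as an n x 3 matrix
#' @param model an `atomic_model`.
#' @return numeric matrix with one row per atom.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Replace coordinates of a model
#' @param model an `atomic_model`.
#' @param xyz n x 3 matrix.
#' @return the updated model.
#' @export
set_coords <- function(model, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == nrow(model$atoms), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

n_residues <- function(model) nrow(model$residues)

# Atom indices of a named atom within residue i (internal index); NA if absent.
atom_in_residue <- function(model, i, name) {
  idx <- model$residues$atom_index[[i]]
  hit <- idx[model$atoms$name[idx] == name]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Read a protein model from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records.  Only the first MODEL block
#' of a multi-model file is kept; for alternate locations the
#' highest-occupancy conformer is retained (ties broken by file order);
#' waters and hetero groups are excluded by default.
#'
#' @param path path to a PDB file.
#' @param keep_hetero keep non-water HETATM records (default FALSE).
#' @param source_label provenance tag; defaults to the file name.
#' @return an `atomic_model`.
#' @export
read_pdb <- function(path, keep_hetero = FALSE, source_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0) stop("empty model: no ATOM records in ", path)
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z))) {
    bad <- which(!(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))[1]
    stop("unparseable coordinates at atom record ", at$eleno[bad])
  }
  # altLoc policy: within each (chain, resno, icode, atom name) group keep
  # the highest-occupancy conformer, first-in-file on ties.
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ii) {
      ii[which.max(occ[ii])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  icode <- at$insert
  icode[is.na(icode)] <- ""
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     element_of(at$elety), toupper(at$elesy)),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resseq = at$resno,
    icode = icode,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
  atoms$is_h <- atoms$element == "H"
  atomic_model(atoms, source_label = source_label)
}

#' Write a model to a PDB file
#'
#' Fixed-column ATOM records, coordinates to 3 decimals, serial numbers
#' reassigned sequentially from 1, a TER record after each chain and END at
#' the end of the file.
#'
#' @param model an `atomic_model`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(model, path) {
  at <- model$atoms
  if (nrow(at) == 0) stop("refusing to write an empty model")
  if (any(nchar(at$name) > 4)) {
    stop("atom name longer than 4 characters: ",
         at$name[which(nchar(at$name) > 4)[1]])
  }
  lines <- character(0)
  serial <- 0
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1
      nm <- sub$name[i]
      # PDB convention: 1-3 char names start in column 14; 4-char in 13.
      nm_fmt <- if (nchar(nm) >= 4) nm else sprintf(" %-3s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, sub$resname[i], ch, sub$resseq[i],
        ifelse(nzchar(sub$icode[i]), sub$icode[i], " "),
        sub$x[i], sub$y[i], sub$z[i], sub$occ[i], sub$b[i], sub$element[i]))
    }
    serial <- serial + 1
    last <- sub[nrow(sub), ]
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial,
                              last$resname, ch, last$resseq))
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Remove hydrogens from a model
#' @param model an `atomic_model`.
#' @return the model restricted to heavy atoms.
#' @export
strip_hydrogens <- function(model) {
  atomic_model(model$atoms[!model$atoms$is_h, , drop = FALSE],
               source_label = model$source_label)
}

#' Covalent bond list of a model
#'
#' Bonds are derived from residue templates (backbone N-CA, CA-C, C-O,
#' CA-CB, side-chain bonds per residue type, the inter-residue peptide bond
#' C(i)-N(i+1) within a chain, and bonds to any hydrogens present, attached
#' to their nearest plausible heavy atom by name template).
#'
#' @param model an `atomic_model`.
#' @param warn_long warn about template bonds stretched beyond 2.5 A.
#' @return integer matrix, two columns of atom indices.
#' @export
bond_list <- function(model, warn_long = FALSE) {
  at <- model$atoms
  res <- model$residues
  bonds <- list()
  add_bond <- function(i, j) {
    if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1]] <<- c(i, j)
  }
  for (r in seq_len(nrow(res))) {
    idx <- res$atom_index[[r]]
    nm <- at$name[idx]
    get <- function(a) {
      hit <- idx[nm == a]
      if (length(hit)) hit[1] else NA_integer_
    }
    add_bond(get("N"), get("CA"))
    add_bond(get("CA"), get("C"))
    add_bond(get("C"), get("O"))
    add_bond(get("C"), get("OXT"))
    if (res$resname[r] != "GLY") add_bond(get("CA"), get("CB"))
    sb <- SIDECHAIN_BONDS[[res$resname[r]]]
    if (!is.null(sb)) {
      for (k in seq_len(nrow(sb))) add_bond(get(sb[k, 1]), get(sb[k, 2]))
    }
    # hydrogens: attach by name convention (H* on N; HG/HH/HD2x etc. follow
    # the heavy atom sharing the remote position code)
    hidx <- idx[at$is_h[idx]]
    for (h in hidx) add_bond(hydrogen_parent(at, idx, h), h)
    # peptide bond to the next residue in the same chain
    if (r < nrow(res) && res$chain[r + 1] == res$chain[r]) {
      nxt <- res$atom_index[[r + 1]]
      nn <- nxt[at$name[nxt] == "N"]
      if (length(nn)) add_bond(get("C"), nn[1])
    }
  }
  B <- do.call(rbind, bonds)
  if (is.null(B)) B <- matrix(integer(0), 0, 2)
  if (warn_long && nrow(B) > 0) {
    xyz <- coords(model)
    d <- sqrt(rowSums((xyz[B[, 1], , drop = FALSE] -
                         xyz[B[, 2], , drop = FALSE])^2))
    if (any(d > 2.5)) {
      warning(sum(d > 2.5), " template bond(s) stretched beyond 2.5 A")
    }
  }
  B
}

# Parent heavy atom of hydrogen h within a residue's atom indices.
hydrogen_parent <- function(at, idx, h) {
  hname <- at$name[h]
  heavy <- idx[!at$is_h[idx]]
  if (length(heavy) == 0) return(NA_integer_)
  # backbone amide / terminal NH3 hydrogens
  if (hname %in% c("H", "H1", "H2", "H3", "HN")) {
    hit <- heavy[at$name[heavy] == "N"]
    if (length(hit)) return(hit[1])
  }
  # positional code: e.g. HG -> OG/SG/CG, HD21 -> ND2, HE2 -> NE2/OE2
  code <- sub("^H", "", hname)
  for (trim in c(0, 1)) {
    cc <- if (trim > 0 && nchar(code) > trim) {
      substr(code, 1, nchar(code) - trim)
    } else {
      code
    }
    hit <- heavy[sub("^[CNOS]", "", at$name[heavy]) == cc &
                   at$name[heavy] != "CA"]
    if (length(hit)) return(hit[1])
    if (trim > 0) break
  }
  # fall back: geometrically nearest heavy atom
  hx <- c(at$x[h], at$y[h], at$z[h])
  d2 <- (at$x[heavy] - hx[1])^2 + (at$y[heavy] - hx[2])^2 +
    (at$z[heavy] - hx[3])^2
  heavy[which.min(d2)]
}

#' Bond-separation classification for nonbonded exclusions
#'
#' Breadth-first bond counting up to `max_sep` covalent bonds; used to
#' exclude 1-2, 1-3 and 1-4 pairs from the nonbonded terms.
#'
#' @param model an `atomic_model`.
#' @param max_sep maximum separation counted (default 3).
#' @return a list of integer vectors: `excluded[[i]]` contains all atoms
#'   within `max_sep` bonds of atom i (including i).
#' @export
bond_separation_sets <- function(model, max_sep = 3) {
  n <- nrow(model$atoms)
  B <- bond_list(model)
  adj <- vector("list", n)
  if (nrow(B) > 0) {
    for (k in seq_len(nrow(B))) {
      i <- B[k, 1]; j <- B[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    frontier <- i
    seen <- i
    for (s in seq_len(max_sep)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      if (length(frontier) == 0) break
      seen <- c(seen, frontier)
    }
    out[[i]] <- sort(seen)
  }
  out
}

# Check backbone completeness; refinement refuses models missing N/CA/C.
check_backbone <- function(model) {
  res <- model$residues
  for (r in seq_len(nrow(res))) {
    nm <- model$atoms$name[res$atom_index[[r]]]
    if (!all(c("N", "CA", "C") %in% nm)) {
      stop(sprintf("residue %s%d (%s) is missing backbone atoms",
                   res$chain[r], res$resseq[r], res$resname[r]))
    }
  }
  invisible(TRUE)
}
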