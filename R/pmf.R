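# Knowledge-based atomic pairwise potential of mean force (PMF).
#
# Quasi-chemical construction: observed atom-type pair counts in distance
# bins are compared against the expectation under the distance-only
# marginal (a type-independent reference state), with a pseudocount for
# sparse statistics:
#
#   e(i, j, bin) = -ln[ (N_obs(i,j,bin) + alpha) / (N_exp(i,j,bin) + alpha) ]
#
# Values are spline-smoothed per type pair so the interpolated potential is
# continuous with a continuous first derivative inside the binned range and
# vanishes at and beyond the cutoff.

pair_key <- function(t1, t2) {
  paste(pmin(t1, t2), pmax(t1, t2), sep = "~")
}

#' Derive a PMF table from a set of structures
#'
#' Counts heavy-atom type-pair distances (excluding pairs within 3 covalent
#' bonds) in `bin_width`-wide bins on \[`r_min`, `r_cut`\] and converts them
#' to energies with the quasi-chemical formula above.
#'
#' @param structures list of `atomic_model`s.
#' @param bin_width bin width in Angstrom.
#' @param r_min,r_cut binned distance range in Angstrom.
#' @param alpha pseudocount.
#' @return an object of class `pmf_table`.
#' @export
derive_pmf_table <- function(structures, bin_width = 0.5, r_min = 2.0,
                             r_cut = 10.0, alpha = 1.0) {
  if (length(structures) < 1) stop("need at least one structure")
  edges <- seq(r_min, r_cut, by = bin_width)
  if (length(edges) < 2) stop("empty bin set: check r_min/r_cut/bin_width")
  nbin <- length(edges) - 1
  counts <- list()
  types_seen <- character(0)
  for (m in structures) {
    topo <- ff_topology(m)
    xyz <- coords(m)
    ty <- topo$pmf_types
    heavy <- which(!is.na(ty))
    types_seen <- union(types_seen, ty[heavy])
    prs <- nonbonded_pairs(topo, xyz, r_cut)
    if (nrow(prs) == 0) next
    keep <- prs[, 3] >= r_min & !is.na(ty[prs[, 1]]) & !is.na(ty[prs[, 2]])
    prs <- prs[keep, , drop = FALSE]
    if (nrow(prs) == 0) next
    key <- pair_key(ty[prs[, 1]], ty[prs[, 2]])
    bin <- pmin(nbin, 1 + floor((prs[, 3] - r_min) / bin_width))
    tab <- table(key, bin)
    for (k in rownames(tab)) {
      if (is.null(counts[[k]])) counts[[k]] <- numeric(nbin)
      b <- as.integer(colnames(tab))
      counts[[k]][b] <- counts[[k]][b] + as.numeric(tab[k, ])
    }
  }
  types <- sort(types_seen)
  keys <- character(0)
  for (i in seq_along(types)) {
    for (j in i:length(types)) {
      keys <- c(keys, pair_key(types[i], types[j]))
    }
  }
  obs <- matrix(0, length(keys), nbin, dimnames = list(keys, NULL))
  for (k in names(counts)) if (k %in% keys) obs[k, ] <- counts[[k]]
  marg <- colSums(obs)
  f_bin <- if (sum(marg) > 0) marg / sum(marg) else rep(1 / nbin, nbin)
  tot_pair <- rowSums(obs)
  expd <- outer(tot_pair, f_bin)
  values <- -log((obs + alpha) / (expd + alpha))
  tab <- structure(list(
    atom_types = types, edges = edges, values = values,
    r_min = r_min, r_cut = r_cut, alpha = alpha
  ), class = "pmf_table")
  tab$splines <- build_pmf_splines(tab)
  tab
}

# One natural cubic spline per type pair through the bin midpoints, with a
# short repulsive anchor below r_min and zero anchors at/past the cutoff.
# Pairs whose values are all zero get no spline (flat zero).
build_pmf_splines <- function(tab) {
  mids <- (tab$edges[-1] + tab$edges[-length(tab$edges)]) / 2
  h <- diff(tab$edges)[1]
  out <- new.env(parent = emptyenv())
  for (k in rownames(tab$values)) {
    v <- tab$values[k, ]
    if (all(v == 0)) next
    x <- c(tab$r_min - 0.25, mids, tab$r_cut, tab$r_cut + h)
    y <- c(v[1] + 5, v, 0, 0)
    assign(k, stats::splinefun(x, y, method = "natural"), envir = out)
  }
  out
}

#' @export
print.pmf_table <- function(x, ...) {
  cat(sprintf("pmf_table: %d atom types, %d bins on [%.1f, %.1f] A, alpha = %g\n",
              length(x$atom_types), ncol(x$values), x$r_min, x$r_cut,
              x$alpha))
  invisible(x)
}

#' Interpolated PMF energy for one type pair at distances r
#' @param table a `pmf_table`.
#' @param t1,t2 atom type labels.
#' @param r distances (A).
#' @param deriv 0 for the value, 1 for d/dr.
#' @return numeric vector; 0 at and beyond the cutoff.
#' @export
pmf_interpolate <- function(table, t1, t2, r, deriv = 0) {
  key <- pair_key(t1, t2)
  out <- numeric(length(r))
  if (!exists(key, envir = table$splines, inherits = FALSE)) return(out)
  f <- get(key, envir = table$splines, inherits = FALSE)
  inside <- r < table$r_cut
  out[inside] <- f(r[inside], deriv = deriv)
  out
}

# ---- neighbor search --------------------------------------------------------

# Cell-list neighbor pairs: all atom pairs (i < j) with distance < cutoff.
# Atoms are hashed into cubic cells of edge `cutoff`; only the 27
# neighboring cells of each occupied cell are scanned, so cost scales with
# n at fixed density.  Returns a matrix with columns i, j, r.
cell_list_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  keyof <- function(cx, cy, cz) paste(cx, cy, cz, sep = ",")
  key <- keyof(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res <- list()
  for (bk in names(buckets)) {
    ii <- buckets[[bk]]
    c0 <- as.integer(strsplit(bk, ",")[[1]])
    # pairs within the cell
    jj_all <- ii
    for (s in seq_len(nrow(shifts))) {
      sh <- shifts[s, ]
      if (all(sh == 0)) next
      nk <- keyof(c0[1] + sh[1], c0[2] + sh[2], c0[3] + sh[3])
      nb <- buckets[[nk]]
      if (!is.null(nb)) jj_all <- c(jj_all, nb)
    }
    jj_all <- unique(jj_all)
    for (i in ii) {
      js <- jj_all[jj_all > i]
      if (length(js) == 0) next
      d <- sqrt((xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
                  (xyz[js, 3] - xyz[i, 3])^2)
      sel <- d < cutoff
      if (any(sel)) {
        res[[length(res) + 1]] <- cbind(i, js[sel], d[sel])
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- matrix(numeric(0), 0, 3)
  colnames(out) <- c("i", "j", "r")
  out
}

# Neighbor pairs minus covalent exclusions (<= 3 bonds) and hydrogens.
nonbonded_pairs <- function(topo, xyz, cutoff) {
  prs <- cell_list_pairs(xyz, cutoff)
  if (nrow(prs) == 0) return(prs)
  keep <- !topo$is_h[prs[, 1]] & !topo$is_h[prs[, 2]]
  prs <- prs[keep, , drop = FALSE]
  if (nrow(prs) == 0) return(prs)
  n <- topo$n_atoms
  keys <- (prs[, 1] - 1) * n + prs[, 2]
  excl <- topo$excl_keys
  prs[!(keys %in% excl), , drop = FALSE]
}

# PMF energy and gradient on raw coordinates.
eval_pmf_term <- function(topo, xyz, table) {
  G <- matrix(0, nrow(xyz), 3)
  prs <- nonbonded_pairs(topo, xyz, table$r_cut)
  if (nrow(prs) == 0) return(list(E = 0, G = G))
  ty <- topo$pmf_types
  t1 <- ty[prs[, 1]]
  t2 <- ty[prs[, 2]]
  if (anyNA(t1) || anyNA(t2)) stop("internal: hydrogen leaked into PMF pairs")
  unknown <- !(t1 %in% table$atom_types) | !(t2 %in% table$atom_types)
  if (any(unknown)) {
    k <- which(unknown)[1]
    stop(sprintf("atom type not in PMF table: atom %d (%s) / atom %d (%s)",
                 prs[k, 1], t1[k], prs[k, 2], t2[k]))
  }
  key <- pair_key(t1, t2)
  E <- 0
  dEdr <- numeric(nrow(prs))
  for (k in unique(key)) {
    if (!exists(k, envir = table$splines, inherits = FALSE)) next
    sel <- which(key == k)
    f <- get(k, envir = table$splines, inherits = FALSE)
    r <- prs[sel, 3]
    E <- E + sum(f(r))
    dEdr[sel] <- f(r, deriv = 1)
  }
  i <- prs[, 1]
  j <- prs[, 2]
  u <- (xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]) / prs[, 3]
  gi <- dEdr * u
  G <- acc_add(G, i, gi)
  G <- acc_add(G, j, -gi)
  list(E = E, G = G)
}

#' PMF energy of a model
#'
#' Sum of the interpolated pair potential over heavy-atom pairs within the
#' cutoff, excluding pairs separated by three covalent bonds or fewer.
#'
#' @param model an `atomic_model`.
#' @param table a `pmf_table`.
#' @param params an `ff_params`.
#' @param topo optional precomputed [ff_topology()].
#' @return an `energy_report` with the `pmf` term.
#' @export
pmf_energy <- function(model, table, params = ff_params(), topo = NULL) {
  if (is.null(topo)) topo <- ff_topology(model, params)
  p <- eval_pmf_term(topo, coords(model), table)
  new_energy_report(list(pmf = p$E), p$G, params$term_weights)
}

#' Write a PMF table to a tab-separated file
#'
#' Versioned tabular format: one row per (type_i, type_j, bin) with the bin
#' bounds and energy value.
#' @param table a `pmf_table`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pmf_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pmf_table v1 r_min=%g r_cut=%g alpha=%g",
                     table$r_min, table$r_cut, table$alpha), con)
  writeLines("type_i\ttype_j\tbin_lo\tbin_hi\tvalue", con)
  edges <- table$edges
  for (k in rownames(table$values)) {
    tt <- strsplit(k, "~", fixed = TRUE)[[1]]
    for (b in seq_len(ncol(table$values))) {
      writeLines(sprintf("%s\t%s\t%.4f\t%.4f\t%.10g", tt[1], tt[2],
                         edges[b], edges[b + 1], table$values[k, b]), con)
    }
  }
  invisible(path)
}

#' Read a PMF table written by [write_pmf_table()]
#' @param path input path.
#' @return a `pmf_table`.
#' @export
read_pmf_table <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.]+", hdr))[[1]]
  kv <- do.call(rbind, strsplit(meta, "="))
  getv <- function(k) as.numeric(kv[kv[, 1] == k, 2])
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE)
  keys <- unique(pair_key(df$type_i, df$type_j))
  edges <- sort(unique(c(df$bin_lo, df$bin_hi)))
  nbin <- length(edges) - 1
  values <- matrix(0, length(keys), nbin, dimnames = list(keys, NULL))
  key <- pair_key(df$type_i, df$type_j)
  bin <- match(df$bin_lo, edges[-length(edges)])
  for (r in seq_len(nrow(df))) values[key[r], bin[r]] <- df$value[r]
  tab <- structure(list(
    atom_types = sort(unique(c(df$type_i, df$type_j))),
    edges = edges, values = values,
    r_min = getv("r_min"), r_cut = getv("r_cut"), alpha = getv("alpha")
  ), class = "pmf_table")
  tab$splines <- build_pmf_splines(tab)
  tab
}
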