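# Step 2 and the iterative driver: L-BFGS minimization of the composite
# energy, and the five-round protocol in which each round re-optimizes the
# hydrogen-bond network and minimizes again from the previous round's
# output, producing one refined model per round.

#' Refinement configuration
#'
#' @param max_steps maximum L-BFGS iterations per round (default 200000).
#' @param grad_tol convergence threshold on the projected-gradient
#'   infinity norm (default 1e-8).
#' @param rel_energy_tol relative energy-change convergence threshold
#'   (default 1e-12; "machine precision" operationalized).
#' @param lbfgs_memory L-BFGS history size (default 10).
#' @param n_iterations number of refinement rounds / emitted models
#'   (default 5).
#' @param tether_reference_policy `"per_round_input"` restrains each round
#'   to its own starting coordinates (default, allows progressive drift);
#'   `"original_start"` always restrains to the original input.
#' @param keep_hydrogens keep polar hydrogens in the emitted models.
#' @param seed RNG seed for the discrete network search.
#' @return a `refinement_config` list.
#' @export
refinement_config <- function(max_steps = 200000, grad_tol = 1e-8,
                              rel_energy_tol = 1e-12, lbfgs_memory = 10,
                              n_iterations = 5,
                              tether_reference_policy = c("per_round_input",
                                                          "original_start"),
                              keep_hydrogens = FALSE, seed = 42) {
  stopifnot(max_steps >= 1, n_iterations >= 1, grad_tol > 0,
            rel_energy_tol > 0)
  structure(list(
    max_steps = max_steps, grad_tol = grad_tol,
    rel_energy_tol = rel_energy_tol, lbfgs_memory = lbfgs_memory,
    n_iterations = n_iterations,
    tether_reference_policy = match.arg(tether_reference_policy),
    keep_hydrogens = keep_hydrogens, seed = seed
  ), class = "refinement_config")
}

#' Minimize the composite energy of a model
#'
#' Limited-memory BFGS (via `stats::optim`'s L-BFGS-B implementation, which
#' uses a line search satisfying the strong Wolfe conditions) on the total
#' composite energy with its analytic gradient.  Terminates on the
#' projected-gradient norm, on relative energy change, or at `max_steps`;
#' the energy never increases across accepted iterates.
#'
#' @param model extended `atomic_model` (all coordinates finite).
#' @param reference tether reference (same topology).
#' @param ss secondary-structure assignment.
#' @param params an `ff_params`.
#' @param table a `pmf_table` or NULL.
#' @param config a [refinement_config()].
#' @return list with `model` (minimized), `energy` (an `energy_report`),
#'   `steps`, and `termination` in `c("converged", "max_steps")`.
#' @export
minimize <- function(model, reference, ss = NULL, params = ff_params(),
                     table = NULL, config = refinement_config()) {
  topo <- ff_topology(model, params)
  topo$hb_ss_weight <- hb_ss_weights(topo, ss, params)
  x0 <- as.numeric(coords(model))
  n <- length(x0) / 3
  ref_xyz <- coords(reference)
  if (!all(is.finite(x0))) stop("non-finite coordinates at start")
  as_xyz <- function(x) matrix(x, ncol = 3)
  fn <- function(x) {
    total_energy_xyz(topo, as_xyz(x), ref_xyz, params, table)$total
  }
  gr <- function(x) {
    as.numeric(total_energy_xyz(topo, as_xyz(x), ref_xyz, params, table)$G)
  }
  e0 <- fn(x0)
  if (!is.finite(e0)) stop("non-finite energy at start of minimization")
  opt <- stats::optim(
    x0, fn, gr, method = "L-BFGS-B",
    control = list(maxit = config$max_steps,
                   lmm = config$lbfgs_memory,
                   factr = config$rel_energy_tol / .Machine$double.eps,
                   pgtol = config$grad_tol)
  )
  termination <- if (opt$convergence == 1) "max_steps" else "converged"
  out <- set_coords(model, as_xyz(opt$par))
  e <- total_energy(out, reference, ss, params, table, topo = topo)
  list(model = out, energy = e, steps = unname(opt$counts["gradient"]),
       termination = termination)
}

#' One round of refinement
#'
#' The two-step protocol: assign secondary structure, build polar
#' hydrogens, optimize the hydrogen-bonding network (yielding the extended
#' atomic model), then minimize the composite all-atom energy with the
#' Calpha/Cbeta tether.  The emitted model is stripped of hydrogens unless
#' `config$keep_hydrogens`.
#'
#' @param model an `atomic_model` (heavy atoms, complete backbone).
#' @param params an `ff_params`.
#' @param table a `pmf_table` or NULL.
#' @param config a [refinement_config()].
#' @param tether_reference optional explicit reference model (used by the
#'   `original_start` policy of the iterative driver).
#' @return list with `model` and `record` (round bookkeeping: input,
#'   extended and minimized models, energies before/after, steps,
#'   termination reason).
#' @export
refine_once <- function(model, params = ff_params(), table = NULL,
                        config = refinement_config(),
                        tether_reference = NULL) {
  check_backbone(model)
  heavy <- strip_hydrogens(model)
  ss <- assign_secondary_structure(heavy)
  ext <- add_polar_hydrogens(heavy)
  opt <- optimize_network(ext, ss, params, seed = config$seed)
  ext <- opt$model
  reference <- if (is.null(tether_reference)) ext else {
    # restrain to the supplied model's Calpha/Cbeta; topologies may differ
    # in hydrogens, so map by residue
    align_tether_reference(ext, tether_reference)
  }
  e_before <- total_energy(ext, reference, ss, params, table)
  mres <- minimize(ext, reference, ss, params, table, config)
  refined <- if (config$keep_hydrogens) mres$model else
    strip_hydrogens(mres$model)
  record <- list(input = model, extended = ext, minimized = mres$model,
                 energy_before = e_before, energy_after = mres$energy,
                 steps = mres$steps, termination = mres$termination,
                 hb_network = opt$network)
  list(model = refined, record = record)
}

# Build a tether reference with the extended model's topology but the
# supplied model's Calpha/Cbeta positions (other atoms copied from ext).
align_tether_reference <- function(ext, supplied) {
  ref <- ext
  for (r in seq_len(n_residues(ext))) {
    rs <- match(paste(ext$residues$chain[r], ext$residues$resseq[r]),
                paste(supplied$residues$chain, supplied$residues$resseq))
    if (is.na(rs)) next
    for (nm in c("CA", "CB")) {
      i <- atom_in_residue(ext, r, nm)
      j <- atom_in_residue(supplied, rs, nm)
      if (!is.na(i) && !is.na(j)) {
        ref$atoms[i, c("x", "y", "z")] <- supplied$atoms[j, c("x", "y", "z")]
      }
    }
  }
  ref
}

#' The iterative refinement protocol
#'
#' Runs [refine_once()] `n_iterations` times, each round starting from the
#' previous round's minimized model, and returns one refined model per
#' round in round order (model 1 = round 1).
#'
#' @param model starting `atomic_model`.
#' @param params an `ff_params`.
#' @param table a `pmf_table` or NULL.
#' @param config a [refinement_config()].
#' @return a `refinement_trajectory`: list with `models` (length
#'   `n_iterations`) and `rounds` (per-round records).
#' @export
refine_iterative <- function(model, params = ff_params(), table = NULL,
                             config = refinement_config()) {
  start <- model
  models <- list()
  rounds <- list()
  cur <- model
  for (k in seq_len(config$n_iterations)) {
    res <- tryCatch(
      refine_once(cur, params, table, config,
                  tether_reference = if (config$tether_reference_policy ==
                                         "original_start") start else NULL),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning("round ", k, " failed: ", conditionMessage(res),
              "; returning partial trajectory")
      break
    }
    models[[k]] <- res$model
    rounds[[k]] <- res$record
    cur <- res$model
  }
  structure(list(models = models, rounds = rounds, start = start,
                 config = config), class = "refinement_trajectory")
}

#' @export
print.refinement_trajectory <- function(x, ...) {
  cat(sprintf("refinement_trajectory: %d round(s)\n", length(x$rounds)))
  for (k in seq_along(x$rounds)) {
    r <- x$rounds[[k]]
    cat(sprintf("  round %d: E %10.4f -> %10.4f (%s, %d steps)\n", k,
                r$energy_before$total, r$energy_after$total,
                r$termination, r$steps))
  }
  invisible(x)
}

#' Run-log table of a trajectory
#' @param traj a `refinement_trajectory`.
#' @return data.frame with one row per round.
#' @export
trajectory_log <- function(traj) {
  do.call(rbind, lapply(seq_along(traj$rounds), function(k) {
    r <- traj$rounds[[k]]
    data.frame(round = k, steps = r$steps,
               E_before = r$energy_before$total,
               E_after = r$energy_after$total,
               termination = r$termination, stringsAsFactors = FALSE)
  }))
}
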