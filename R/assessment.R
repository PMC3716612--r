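# Normalization and ranking framework for refinement assessment.
#
# Per target and metric, the change in quality induced by refinement
# (delta = refined - starting score) is pooled across groups, robust
# Z-scored using the median and the median absolute deviation (MAD, scaled
# by 1.486 to match a normal standard deviation), and combined into an
# overall quality score as a weighted average with GDT-TS carrying half
# the total weight.  A pseudo-group "Void" that returns the starting
# structure unchanged serves as the do-nothing control; groups summing
# below Void have on average degraded their starting structures.

#' Delta quality scores between a starting and a refined model
#'
#' @param start,refined `metric_vector`s scored against the same reference.
#' @return a `delta_record`: named list of per-metric deltas
#'   (refined - start, raw / un-oriented); metrics missing on either side
#'   are NA.
#' @export
delta_scores <- function(start, refined) {
  d <- lapply(METRIC_NAMES, function(m) {
    qs <- start[[m]]; qr <- refined[[m]]
    if (is.null(qs) || is.null(qr) || is.na(qs) || is.na(qr)) {
      NA_real_
    } else {
      qr - qs
    }
  })
  names(d) <- METRIC_NAMES
  structure(d, class = "delta_record")
}

#' Orient deltas so that positive always means improvement
#'
#' Deltas of lower-is-better metrics (RMSD and the MP-proxy) are negated.
#' @param deltas named numeric vector or `delta_record`.
#' @return named numeric vector of oriented deltas.
#' @export
orient_deltas <- function(deltas) {
  d <- unlist(deltas[METRIC_NAMES])
  sgn <- ifelse(LOWER_IS_BETTER[METRIC_NAMES], -1, 1)
  d * sgn
}

#' Robust Z-scores of one target/metric pool
#'
#' Z = (delta - median(delta)) / (1.486 * MAD) with
#' MAD = median(|delta - median(delta)|).  The 1.486 factor scales the MAD
#' to the standard deviation of a normal distribution.  A degenerate pool
#' (MAD = 0) yields all-zero Z-scores.
#'
#' @param deltas numeric vector of oriented deltas (one per group), length
#'   at least 2.
#' @return numeric vector of Z-scores, same names as `deltas`.
#' @export
robust_z <- function(deltas) {
  if (length(deltas) < 2) stop("need at least 2 delta values")
  med <- stats::median(deltas)
  mad_ <- stats::median(abs(deltas - med))
  if (mad_ == 0) {
    return(stats::setNames(rep(0, length(deltas)), names(deltas)))
  }
  (deltas - med) / (1.486 * mad_)
}

#' Default metric weights of the overall quality score
#'
#' GDT-TS carries weight 5 and each of the other five metrics weight 1, so
#' backbone accuracy makes half of the overall score.
#' @return named numeric weights.
#' @export
q_weights <- function() {
  c(gdt_ts = 5, rmsd = 1, gdc_sc = 1, mp_proxy = 1, sphere_grinder = 1,
    cad_aa = 1)
}

#' Overall quality score from six metric Z-scores
#'
#' Weighted average of the per-metric robust Z-scores; missing Z-scores are
#' treated as 0.
#'
#' @param z named numeric vector of Z-scores (names in `METRIC_NAMES`).
#' @param weights metric weights (default [q_weights()]).
#' @return scalar Q_overall.
#' @export
q_overall <- function(z, weights = q_weights()) {
  zv <- z[names(weights)]
  zv[is.na(zv)] <- 0
  sum(weights * zv) / sum(weights)
}

#' Select a group's best model by overall quality score
#'
#' @param q_values numeric Q_overall per candidate model, in rank order.
#' @return index (model rank) of the maximum; ties go to the lowest rank.
#' @export
select_best_model <- function(q_values) {
  if (length(q_values) < 1) stop("no candidates")
  which.max(q_values)  # which.max returns the first (lowest-rank) maximum
}

#' Wilcoxon signed-rank test against zero
#'
#' Two-sided test of the null hypothesis that the deltas are symmetrically
#' distributed around zero.  Zeros are dropped (classic convention; the
#' Pratt variant keeps them in the ranking).  The null distribution is
#' computed by exact enumeration of all sign assignments for n <= 20
#' (valid under ties, which are mid-ranked), and by the normal
#' approximation with tie correction otherwise.
#'
#' @param deltas numeric vector of (oriented) deltas.
#' @param zero_method "wilcox" (drop zeros, default) or "pratt".
#' @param exact_limit maximum n for exact enumeration (default 20).
#' @return list with `statistic` (V = sum of positive ranks), `p_value`,
#'   `n` (after zero handling), `method`.
#' @export
wilcoxon_signed_rank <- function(deltas, zero_method = c("wilcox", "pratt"),
                                 exact_limit = 20) {
  zero_method <- match.arg(zero_method)
  x <- deltas[!is.na(deltas)]
  nonzero <- x != 0
  if (!any(nonzero)) {
    warning("all deltas are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  if (zero_method == "wilcox") {
    x <- x[nonzero]
    ranks <- rank(abs(x))
  } else {
    ranks_all <- rank(abs(x))
    ranks <- ranks_all[nonzero]
    x <- x[nonzero]
  }
  V <- sum(ranks[x > 0])
  n <- length(x)
  if (n <= exact_limit) {
    # exact: enumerate all 2^n sign assignments of the observed |ranks|
    stats_all <- enumerate_signed_rank_sums(ranks)
    more_extreme <- mean(abs(stats_all - sum(ranks) / 2) >=
                           abs(V - sum(ranks) / 2) - 1e-9)
    p <- min(1, more_extreme)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rank(abs(x)))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n = n, method = method)
}

# All 2^n sums of positively-signed ranks (dynamic enumeration).
enumerate_signed_rank_sums <- function(ranks) {
  sums <- 0
  for (r in ranks) sums <- c(sums, sums + r)
  sums
}

#' Success/failure percentages per metric
#'
#' @param oriented_deltas data.frame or matrix with one column per metric
#'   (oriented deltas, positive = improvement) and one row per model.
#' @return data.frame with per-metric percentages improved / worsened /
#'   unchanged.
#' @export
success_failure_summary <- function(oriented_deltas) {
  od <- as.data.frame(oriented_deltas)
  if (nrow(od) < 1) stop("no records")
  do.call(rbind, lapply(names(od), function(m) {
    v <- od[[m]]
    v <- v[!is.na(v)]
    data.frame(metric = m,
               pct_improved = 100 * mean(v > 0),
               pct_worsened = 100 * mean(v < 0),
               pct_unchanged = 100 * mean(v == 0),
               stringsAsFactors = FALSE)
  }))
}

#' Rank groups by summed overall quality score
#'
#' Input: one `delta_record` (or named delta vector) per (group, target)
#' pair of the chosen model selection.  A "Void" pseudo-group with all-zero
#' deltas is injected into every target's pool before Z-scoring.  Robust
#' Z-scores are computed per target and metric across groups, combined by
#' [q_overall()], and summed over targets; a group missing a target simply
#' lacks that term.
#'
#' @param records data.frame with columns `group`, `target`, and one column
#'   per metric holding raw (un-oriented) deltas.
#' @param weights metric weights (default [q_weights()]).
#' @return a `group_ranking`: list with `table` (groups ordered by summed
#'   Q_overall, with cumulative per-metric raw delta sums) and `z` (the
#'   per-target Z-score records).
#' @export
rank_groups <- function(records, weights = q_weights()) {
  stopifnot(all(c("group", "target") %in% names(records)))
  metrics <- intersect(METRIC_NAMES, names(records))
  targets <- unique(records$target)
  # drop groups with zero targets (nothing to rank)
  groups <- unique(records$group)
  zrecs <- list()
  for (tg in targets) {
    sub <- records[records$target == tg, , drop = FALSE]
    # inject the Void control
    void <- sub[1, , drop = FALSE]
    void$group <- "Void"
    void[metrics] <- 0
    sub <- rbind(sub, void)
    zs <- matrix(NA_real_, nrow(sub), length(metrics),
                 dimnames = list(NULL, metrics))
    for (m in metrics) {
      d <- sub[[m]]
      oriented <- d * if (LOWER_IS_BETTER[m]) -1 else 1
      ok <- !is.na(oriented)
      if (sum(ok) >= 2) zs[ok, m] <- robust_z(oriented[ok])
    }
    q <- apply(zs, 1, q_overall, weights = weights)
    zrecs[[tg]] <- data.frame(group = sub$group, target = tg, zs,
                              q_overall = q, stringsAsFactors = FALSE)
  }
  zall <- do.call(rbind, zrecs)
  rownames(zall) <- NULL
  all_groups <- c(setdiff(groups, "Void"), "Void")
  tab <- do.call(rbind, lapply(all_groups, function(g) {
    zg <- zall[zall$group == g, , drop = FALSE]
    rg <- records[records$group == g, , drop = FALSE]
    sums <- if (g == "Void") {
      stats::setNames(rep(0, length(metrics)), metrics)
    } else {
      vapply(metrics, function(m) sum(rg[[m]], na.rm = TRUE), numeric(1))
    }
    out <- data.frame(group = g, targets_attempted = if (g == "Void")
      length(targets) else length(unique(rg$target)),
      sum_q_overall = sum(zg$q_overall, na.rm = TRUE),
      stringsAsFactors = FALSE)
    for (m in metrics) out[[paste0("delta_", m)]] <- sums[[m]]
    out
  }))
  tab <- tab[order(-tab$sum_q_overall), ]
  rownames(tab) <- NULL
  structure(list(table = tab, z = zall), class = "group_ranking")
}

#' @export
print.group_ranking <- function(x, ...) {
  cat("group_ranking (by summed Q_overall):\n")
  print(x$table, digits = 4)
  invisible(x)
}

# ---- directory-tree assessment ----------------------------------------------

#' Assess a directory tree of predictor submissions
#'
#' Expects `<submissions>/<group>/<target>/model_<k>.pdb` and
#' `<targets>/<target>/start.pdb` + `<targets>/<target>/native.pdb`.
#' Scores every submitted model against the native, forms delta records
#' against the starting structure, and ranks groups by summed Q_overall
#' using either each group's first model or its best model (by per-target
#' Q_overall within the group's submissions).
#'
#' @param submissions_dir,targets_dir directory roots as above.
#' @param selection "first" or "best".
#' @return list with `ranking` (a `group_ranking`), `records` (all delta
#'   records), `summary` (success/failure percentages over all models),
#'   and `wilcoxon` (per group and metric, p-values of the signed-rank
#'   test on oriented per-target deltas).
#' @export
assess_submissions <- function(submissions_dir, targets_dir,
                               selection = c("first", "best")) {
  selection <- match.arg(selection)
  targets <- list.dirs(targets_dir, recursive = FALSE, full.names = FALSE)
  groups <- list.dirs(submissions_dir, recursive = FALSE, full.names = FALSE)
  if (length(targets) == 0) stop("no targets found in ", targets_dir)
  if (length(groups) == 0) stop("no groups found in ", submissions_dir)
  ref_scores <- list()
  for (tg in targets) {
    native <- read_pdb(file.path(targets_dir, tg, "native.pdb"))
    start <- read_pdb(file.path(targets_dir, tg, "start.pdb"))
    ref_scores[[tg]] <- list(native = native,
                             start_mv = evaluate_all(start, native))
  }
  rows <- list()
  for (g in groups) {
    for (tg in targets) {
      mdir <- file.path(submissions_dir, g, tg)
      if (!dir.exists(mdir)) next
      files <- sort(list.files(mdir, pattern = "^model_[0-9]+\\.pdb$",
                               full.names = TRUE))
      if (length(files) == 0) next
      for (k in seq_along(files)) {
        mv <- evaluate_all(read_pdb(files[k]), ref_scores[[tg]]$native)
        dd <- delta_scores(ref_scores[[tg]]$start_mv, mv)
        row <- data.frame(group = g, target = tg, model_rank = k,
                          stringsAsFactors = FALSE)
        for (m in METRIC_NAMES) row[[m]] <- dd[[m]]
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  records <- do.call(rbind, rows)
  if (is.null(records)) stop("no models found under ", submissions_dir)
  selected <- select_records(records, selection)
  ranking <- rank_groups(selected)
  oriented <- selected[METRIC_NAMES]
  for (m in METRIC_NAMES) {
    if (LOWER_IS_BETTER[m]) oriented[[m]] <- -oriented[[m]]
  }
  wil <- do.call(rbind, lapply(unique(selected$group), function(g) {
    sel <- selected$group == g
    do.call(rbind, lapply(METRIC_NAMES, function(m) {
      v <- oriented[[m]][sel]
      v <- v[!is.na(v)]
      p <- if (sum(v != 0) >= 5) {
        wilcoxon_signed_rank(v)$p_value
      } else {
        NA_real_
      }
      data.frame(group = g, metric = m, p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  all_oriented <- records[METRIC_NAMES]
  for (m in METRIC_NAMES) {
    if (LOWER_IS_BETTER[m]) all_oriented[[m]] <- -all_oriented[[m]]
  }
  list(ranking = ranking, records = records,
       summary = success_failure_summary(all_oriented), wilcoxon = wil)
}

# Reduce full records to one row per (group, target): the first model or
# the best model by a within-group Q_overall pool.
select_records <- function(records, selection) {
  if (selection == "first") {
    return(records[records$model_rank == 1, , drop = FALSE])
  }
  out <- list()
  for (g in unique(records$group)) {
    for (tg in unique(records$target)) {
      sub <- records[records$group == g & records$target == tg, ,
                     drop = FALSE]
      if (nrow(sub) == 0) next
      if (nrow(sub) == 1) {
        out[[length(out) + 1]] <- sub
        next
      }
      # rank candidates by a quick oriented weighted sum of deltas
      q <- vapply(seq_len(nrow(sub)), function(i) {
        d <- orient_deltas(as.list(sub[i, METRIC_NAMES]))
        w <- q_weights()
        sum(w * ifelse(is.na(d), 0, d)) / sum(w)
      }, numeric(1))
      out[[length(out) + 1]] <- sub[select_best_model(q), , drop = FALSE]
    }
  }
  do.call(rbind, out)
}
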