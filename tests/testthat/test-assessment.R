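# Delta scores, robust Z normalization, the overall quality score, group
# ranking with the Void control, and the Wilcoxon signed-rank test.

mv_stub <- function(gdt_ts = NA, rmsd = NA, gdc_sc = NA, mp_proxy = NA,
                    sphere_grinder = NA, cad_aa = NA) {
  structure(list(gdt_ts = gdt_ts, rmsd = rmsd, gdc_sc = gdc_sc,
                 mp_proxy = mp_proxy, sphere_grinder = sphere_grinder,
                 cad_aa = cad_aa, aligned_length = 96),
            class = "metric_vector")
}

test_that("delta scores reproduce the worked refinement example", {
  start <- mv_stub(gdt_ts = 0.6458, rmsd = 4.709, gdc_sc = 0.2211,
                   mp_proxy = 3.53, sphere_grinder = 0.375, cad_aa = 0.52)
  refined <- mv_stub(gdt_ts = 0.651, rmsd = 4.698, gdc_sc = 0.2291,
                     mp_proxy = 3.52, sphere_grinder = 0.3854,
                     cad_aa = 0.53)
  d <- delta_scores(start, refined)
  expect_equal(d$gdt_ts, 0.0052, tolerance = 1e-10)
  expect_equal(d$rmsd, -0.011, tolerance = 1e-10)
  # identical vectors give all-zero deltas
  d0 <- delta_scores(start, start)
  expect_true(all(unlist(d0) == 0))
  # a missing metric propagates as NA
  dm <- delta_scores(mv_stub(gdt_ts = 0.5), mv_stub(gdt_ts = 0.6))
  expect_equal(dm$gdt_ts, 0.1)
  expect_true(is.na(dm$rmsd))
})

test_that("orientation flips the sign of lower-is-better metrics only", {
  d <- orient_deltas(list(gdt_ts = 0.1, rmsd = -0.2, gdc_sc = 0.05,
                          mp_proxy = -0.3, sphere_grinder = 0.01,
                          cad_aa = 0.02))
  expect_equal(unname(d[c("rmsd", "mp_proxy")]), c(0.2, 0.3))
  expect_equal(unname(d[c("gdt_ts", "cad_aa")]), c(0.1, 0.02))
})

test_that("robust Z follows the median/MAD form with the 1.486 factor", {
  z <- robust_z(c(-1, 0, 1))
  expect_equal(z[3], 1 / 1.486, tolerance = 1e-12)
  expect_equal(z[2], 0)
  # all-equal pool: degenerate MAD gives all-zero Z
  expect_equal(robust_z(rep(0.3, 4)), setNames(rep(0, 4), NULL))
  # the group at the median has Z exactly 0 whenever MAD > 0
  z2 <- robust_z(c(0.1, 0.4, 0.9, 1.3, 2))
  expect_equal(unname(z2[3]), 0)
  expect_error(robust_z(0.5), "at least 2")
})

test_that("Z-scores are invariant to location and positive scale of the
           pool", {
  set.seed(8)
  for (rep in 1:5) {
    d <- rnorm(7)
    z <- robust_z(d)
    expect_equal(robust_z(d + 3.7), z, tolerance = 1e-12)
    expect_equal(robust_z(d * 2.5), z, tolerance = 1e-12)
  }
})

test_that("1.486 * MAD tracks the standard deviation of normal draws", {
  set.seed(123)
  x <- rnorm(2e5)
  expect_lt(abs(1.486 * median(abs(x - median(x))) / sd(x) - 1), 0.02)
})

test_that("the overall quality score gives GDT-TS half the weight", {
  w <- q_weights()
  expect_equal(unname(w["gdt_ts"] / sum(w)), 0.5)
  z <- setNames(rep(0, 6), names(w))
  z["gdt_ts"] <- 1
  expect_equal(q_overall(z), 0.5)
  expect_equal(q_overall(setNames(rep(1, 6), names(w))), 1.0)
  z2 <- setNames(rep(0, 6), names(w))
  z2["rmsd"] <- 1
  expect_equal(q_overall(z2), 0.1)
  # missing Z treated as zero
  z3 <- setNames(c(1, rep(NA, 5)), names(w))
  expect_equal(q_overall(z3), 0.5)
})

test_that("best-model selection takes the argmax with lowest-rank ties", {
  expect_equal(select_best_model(0.7), 1)
  expect_equal(select_best_model(c(0.1, 0.4, 0.2)), 2)
  expect_equal(select_best_model(c(0.4, 0.1, 0.4)), 1)
})

test_that("exact Wilcoxon matches hand enumeration for all-positive
           deltas", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(res$p_value, 2 / 32, tolerance = 1e-12)
  expect_equal(res$statistic, 15)
  expect_equal(res$method, "exact enumeration")
})

test_that("antisymmetric deltas sit at the null center with p = 1", {
  res <- wilcoxon_signed_rank(c(-0.4, 0.4, -1.1, 1.1))
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("exact Wilcoxon equals the full sign-enumeration oracle for
           n up to 12", {
  set.seed(77)
  for (n in c(6, 9, 12)) {
    x <- round(rnorm(n), 2)
    x[x == 0] <- 0.01
    got <- wilcoxon_signed_rank(x)$p_value
    expect_equal(got, wilcoxon_enumeration_oracle(x), tolerance = 1e-12)
  }
  # tie-free case also agrees with the stats implementation
  x <- c(0.3, -0.7, 1.2, 0.5, -0.1, 0.9, 1.5, -2.0)
  expect_equal(wilcoxon_signed_rank(x)$p_value,
               stats::wilcox.test(x, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("all-zero deltas give p = 1 with a warning", {
  expect_warning(res <- wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_equal(res$p_value, 1)
})

test_that("success/failure percentages match a manual count", {
  od <- data.frame(gdt_ts = c(0.1, -0.2, 0, 0.3, 0.2, -0.1, 0, 0.5, 0.1,
                              -0.3))
  s <- success_failure_summary(od)
  expect_equal(s$pct_improved, 50)
  expect_equal(s$pct_worsened, 30)
  expect_equal(s$pct_unchanged, 20)
  # mirrored pool has equal percentages
  s2 <- success_failure_summary(rbind(od, -od))
  expect_equal(s2$pct_improved, s2$pct_worsened)
})

test_that("group ranking reproduces a hand-computed 3-group 4-target
           pool", {
  # hand-chosen raw deltas (gdt_ts only varies; other metrics zero)
  groups <- c("good", "mid", "bad")
  deltas <- list(
    good = c(0.04, 0.02, 0.05, 0.03),
    mid = c(0.01, 0.00, 0.01, -0.01),
    bad = c(-0.05, -0.03, -0.06, -0.02))
  rows <- list()
  for (g in groups) {
    for (t in 1:4) {
      row <- data.frame(group = g, target = paste0("T", t),
                        stringsAsFactors = FALSE)
      for (m in names(q_weights())) row[[m]] <- 0
      row$gdt_ts <- deltas[[g]][t]
      rows[[length(rows) + 1]] <- row
    }
  }
  records <- do.call(rbind, rows)
  rk <- rank_groups(records)
  # oracle: spreadsheet-style evaluation of the same formulas
  oracle <- sapply(c(groups, "Void"), function(g) {
    total <- 0
    for (t in 1:4) {
      pool <- c(sapply(groups, function(gg) deltas[[gg]][t]), Void = 0)
      med <- median(pool)
      mad_ <- median(abs(pool - med))
      z <- if (mad_ == 0) rep(0, 4) else (pool - med) / (1.486 * mad_)
      names(z) <- c(groups, "Void")
      total <- total + 5 * z[[g]] / 10
    }
    total
  })
  got <- setNames(rk$table$sum_q_overall, rk$table$group)
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-10)
  expect_equal(rk$table$group[1], "good")
  # the Void cumulative delta row is all zeros
  void_row <- rk$table[rk$table$group == "Void", ]
  expect_true(all(void_row[grep("^delta_", names(void_row))] == 0))
})

test_that("a do-nothing group ties with the injected Void control", {
  rows <- list()
  for (g in c("noop", "real")) {
    for (t in 1:3) {
      row <- data.frame(group = g, target = paste0("T", t),
                        stringsAsFactors = FALSE)
      for (m in names(q_weights())) {
        row[[m]] <- if (g == "noop") 0 else 0.02 * t
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  rk <- rank_groups(do.call(rbind, rows))
  tab <- rk$table
  expect_equal(tab$sum_q_overall[tab$group == "noop"],
               tab$sum_q_overall[tab$group == "Void"], tolerance = 1e-12)
})

test_that("the ranking is invariant to record ordering", {
  set.seed(14)
  rows <- list()
  for (g in c("a", "b", "c")) {
    for (t in 1:3) {
      row <- data.frame(group = g, target = paste0("T", t),
                        stringsAsFactors = FALSE)
      for (m in names(q_weights())) row[[m]] <- rnorm(1, sd = 0.05)
      rows[[length(rows) + 1]] <- row
    }
  }
  records <- do.call(rbind, rows)
  rk1 <- rank_groups(records)
  rk2 <- rank_groups(records[sample(nrow(records)), ])
  expect_equal(rk1$table, rk2$table, tolerance = 1e-12)
})
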