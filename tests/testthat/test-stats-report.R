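test_that("trajectory ratios give per-oocyte fractions summing to one", {
  pred <- tibble::tibble(
    oocyte_id = "oo1",
    label = c(rep("retracing", 3), rep("congressing", 13),
              rep("quasi-static", 4)))
  r <- trajectory_ratios(pred)
  expect_equal(r$retracing, 0.15)
  expect_equal(r$congressing, 0.65)
  expect_equal(r$quasi_static, 0.20)
  expect_equal(r$na_fraction, 0)

  all_na <- tibble::tibble(oocyte_id = "kd", label = rep(NA_character_, 20))
  rn <- trajectory_ratios(all_na)
  expect_equal(rn$na_fraction, 1)

  mixed <- dplyr::bind_rows(pred, all_na)
  rm_ <- trajectory_ratios(mixed)
  sums <- rm_$retracing + rm_$congressing + rm_$quasi_static + rm_$na_fraction
  expect_equal(sums, rep(1, 2), tolerance = 1e-9)
})

test_that("one-sided Mann-Whitney matches the worked example and edge cases", {
  r <- mann_whitney_one_sided(c(4, 5, 6), c(1, 2, 3), "a_greater")
  expect_equal(r$statistic, 9)
  expect_equal(r$p_value, 1 / 20)
  expect_equal(r$method, "exact enumeration")

  r2 <- mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6), "b_greater")
  expect_equal(r2$p_value, 1 / 20)

  same <- mann_whitney_one_sided(c(1, 2, 3, 4), c(1, 2, 3, 4), "a_greater")
  expect_gte(same$p_value, 0.5)

  tied <- mann_whitney_one_sided(c(2, 2), c(2, 2, 2), "a_greater")
  expect_equal(tied$p_value, 1)
  expect_true(tied$ties)

  expect_error(mann_whitney_one_sided(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals brute-force enumeration (n <= 10)", {
  brute <- function(a, b, direction) {
    pooled <- c(a, b); na <- length(a)
    r <- rank(pooled)
    u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
    u_obs <- u_of(seq_len(na))
    if (direction == "b_greater") u_obs <- na * length(b) - u_obs
    combos <- utils::combn(length(pooled), na)
    u_all <- apply(combos, 2, u_of)
    if (direction == "b_greater") u_all <- na * length(b) - u_all
    mean(u_all >= u_obs - 1e-9)
  }
  withr::with_seed(17, {
    for (i in 1:12) {
      na <- sample(2:5, 1); nb <- sample(2:5, 1)
      a <- sample(1:6, na, replace = TRUE)   # ties likely
      b <- sample(1:6, nb, replace = TRUE)
      dir <- sample(c("a_greater", "b_greater"), 1)
      expect_equal(mann_whitney_one_sided(a, b, dir)$p_value,
                   brute(a, b, dir), tolerance = 1e-12)
    }
  })
})

test_that("exact Mann-Whitney agrees with wilcox.test without ties", {
  withr::with_seed(23, {
    for (i in 1:8) {
      a <- rnorm(5); b <- rnorm(6)
      ours <- mann_whitney_one_sided(a, b, "a_greater")$p_value
      ref <- wilcox.test(a, b, alternative = "greater", exact = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("exact and normal-approximation branches agree at n = 8 vs 8", {
  withr::with_seed(29, {
    for (i in 1:6) {
      a <- rnorm(8); b <- rnorm(8) + 0.5
      exact <- mann_whitney_one_sided(a, b, "b_greater")$p_value
      # the tie-corrected normal approximation, as used beyond n = 25
      approx_p <- {
        pooled <- c(a, b); r <- rank(pooled)
        u_a <- sum(r[1:8]) - 8 * 9 / 2
        u <- 64 - u_a
        mu <- 32; sig2 <- 8 * 8 / 12 * 17
        pnorm((u - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
      }
      expect_lt(abs(exact - approx_p), 0.01)
    }
  })
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(adjust_pvalues(0.04), 0.04)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(3, p <- runif(20))
  adj <- adjust_pvalues(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone non-decreasing after sorting raw p ascending
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_equal(adjust_pvalues(p, "bonferroni"), pmin(p * 20, 1))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher's exact test matches enumeration and reference values", {
  even <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$p_value, 1)

  diag2 <- fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))
  expect_equal(diag2$p_value, 1 / 3, tolerance = 1e-12)

  m <- matrix(c(8, 2, 1, 9), 2)
  f <- fisher_exact_2x2(m)
  expect_equal(f$p_value, fisher_exact_2x2(m[2:1, ])$p_value)
  expect_equal(f$p_value, fisher_exact_2x2(m[, 2:1])$p_value)
  expect_equal(f$p_value, fisher_exact_2x2(t(m))$p_value)

  zero <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))
  expect_equal(zero$p_value, 1)
  expect_true(zero$degenerate)

  expect_error(fisher_exact_2x2(matrix(c(1.5, 0, 0, 2), 2)), "integer")
})

test_that("Fisher p and odds ratio agree with stats::fisher.test (total <= 40)", {
  withr::with_seed(37, {
    for (i in 1:15) {
      m <- matrix(rpois(4, 4), 2)
      if (sum(m) > 40 || any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      ours <- fisher_exact_2x2(m)
      ref <- fisher.test(m)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
      if (is.finite(ours$statistic) && ours$statistic > 0) {
        # fisher.test optimizes the conditional MLE to ~1e-4 only
        expect_equal(ours$statistic, unname(ref$estimate), tolerance = 1e-3)
      }
    }
  })
})

test_that("all-pairs comparisons carry BH-adjusted p-values", {
  withr::with_seed(41, {
    df <- tibble::tibble(
      grp = rep(c("a", "b", "c"), each = 8),
      val = c(rnorm(8, 3), rnorm(8, 1), rnorm(8, 0)))
  })
  res <- pairwise_mann_whitney(df, "val", "grp", direction = "a_greater")
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_lt(res$p_adjusted[res$comparison == "a vs c"], 0.05)
})

test_that("retracing Step III speeds dominate quasi-static ones", {
  per_traj <- purrr::map_dfr(1:5, function(s) {
    an <- control_analysis(s)
    sp <- assign_steps(an$speeds, an$segmentation)
    sp |>
      dplyr::filter(step == "III", !is.na(true_label),
                    true_label %in% c("retracing", "quasi-static")) |>
      dplyr::group_by(oocyte_id, chromosome_id, true_label) |>
      dplyr::summarise(v = mean(abs(v_axial)), .groups = "drop")
  })
  res <- mann_whitney_one_sided(
    per_traj$v[per_traj$true_label == "retracing"],
    per_traj$v[per_traj$true_label == "quasi-static"], "a_greater")
  expect_lt(res$p_value, 0.05)
})

test_that("the report bundle is deterministic and lists missing inputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  pred <- tibble::tibble(oocyte_id = rep(c("b", "a"), each = 2),
                         condition = "control",
                         label = c("retracing", "congressing",
                                   "congressing", "quasi-static"))
  ratios <- trajectory_ratios(pred)
  tests <- mann_whitney_one_sided(1:4, 2:5, "b_greater")
  for (d in c(d1, d2)) build_report(d, ratios = ratios, tests = tests)
  for (f in c("ratios.csv", "tests.csv", "report.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  js <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_true("speeds_summary.csv" %in% unlist(js$missing_inputs))
  expect_true("ratios.csv" %in% unlist(js$files))
})

test_that("KIF18A knockdown lowers the retracing share with quasi-static stable", {
  ctl <- purrr::map_dfr(control_cohort(), function(r) {
    dplyr::mutate(r$labels, condition = "control")
  })
  kd <- purrr::map_dfr(21:25, function(s) {
    dplyr::mutate(simulate_oocyte(condition = "KIF18A", seed = s)$labels,
                  condition = "KIF18A")
  })
  both <- dplyr::bind_rows(ctl, kd) |> dplyr::rename(label = true_label)
  rat <- trajectory_ratios(both)
  res <- mann_whitney_one_sided(
    rat$retracing[rat$condition == "control"],
    rat$retracing[rat$condition == "KIF18A"], "a_greater",
    comparison = "control vs KIF18A retracing")
  expect_lt(adjust_pvalues(res$p_value), 0.05)
  qs_ctl <- mean(rat$quasi_static[rat$condition == "control"])
  qs_kd <- mean(rat$quasi_static[rat$condition == "KIF18A"])
  expect_lt(abs(qs_ctl - qs_kd), 0.05 + 1e-9)
})
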