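make_sequences <- function(curves, labels, dt = 10) {
  # curves: list of numeric length-31 vectors of |z| values
  purrr::imap_dfr(curves, function(v, i) {
    tibble::tibble(oocyte_id = "toy", chromosome_id = as.integer(i),
                   slot = -15:15, t_min = dt * (-15:15) + 150,
                   value = v, mask = 1L, true_label = labels[[i]])
  })
}

test_that("sequence windows mask points outside the recording", {
  an <- control_analysis()
  t0 <- an$segmentation$boundaries[[2]]
  seqs <- build_sequences(an$aligned, t0)
  one <- dplyr::filter(seqs, chromosome_id == 1)
  expect_equal(nrow(one), 31)
  expect_equal(sum(one$mask == 0), sum(one$t_min < 0 | one$t_min > 360))
  expect_true(all(one$value[one$mask == 0] == 0))
  expect_true(all(abs(one$value[one$mask == 1]) >= 0))

  # recording that starts exactly at T0: the first 15 points are masked
  clipped <- dplyr::filter(an$aligned, t_min >= t0)
  s2 <- build_sequences(clipped, t0)
  one2 <- dplyr::filter(s2, chromosome_id == 1) |> dplyr::arrange(slot)
  expect_equal(one2$mask[1:15], rep(0L, 15))
  expect_equal(one2$mask[16:31], rep(1L, 16))

  expect_error(build_sequences(an$aligned, NA_real_), "undetermined")
})

test_that("severe knockdowns yield only NA sequences", {
  kd <- simulate_oocyte(condition = "KIF2A", seed = 4)
  an <- analyze_oocyte(kd)
  expect_equal(an$status, "no_equator")
  cs <- cohort_sequences(list(an))
  expect_null(cs$sequences)
  expect_length(cs$na_oocytes, 1)
})

test_that("stratified 9:1 split is disjoint, exhaustive and deterministic", {
  seqs <- cohort_seqs()$sequences
  sp <- split_train_test(seqs, 0.9, seed = 7)
  keys <- function(x) dplyr::distinct(x, oocyte_id, chromosome_id)
  expect_equal(nrow(keys(sp$train)), 180)
  expect_equal(nrow(keys(sp$test)), 20)
  expect_equal(nrow(dplyr::inner_join(keys(sp$train), keys(sp$test),
                                      by = c("oocyte_id", "chromosome_id"))),
               0)
  expect_equal(nrow(dplyr::bind_rows(sp$train, sp$test)), nrow(seqs))

  sp2 <- split_train_test(seqs, 0.9, seed = 7)
  expect_identical(sp$test, sp2$test)
  sp3 <- split_train_test(seqs, 0.9, seed = 8)
  expect_false(identical(sp$test, sp3$test))

  # stratification: every class appears in the test split
  tl <- dplyr::distinct(sp$test, oocyte_id, chromosome_id, true_label)
  expect_setequal(unique(tl$true_label),
                  c("retracing", "congressing", "quasi-static"))

  expect_error(split_train_test(dplyr::filter(seqs, chromosome_id == 1,
                                              oocyte_id == seqs$oocyte_id[[1]])),
               "at least 10")
})

test_that("backpropagation gradients match finite differences", {
  spec <- gru_spec(hidden_size = 4, head_size = 4, seed = 5)
  withr::with_seed(5, {
    params <- meiotrace:::init_gru_params(spec, input_dim = 2)
    xs <- lapply(1:4, function(t) matrix(rnorm(6), 3, 2))
    y <- diag(3)[sample(1:3, 3, replace = TRUE), ]
  })
  lg <- meiotrace:::gru_loss_and_grads(params, xs, y)
  eps <- 1e-5
  # probe a sample of coordinates in every parameter block
  for (blk in c("l1", "l2", "head")) {
    for (nm in names(params[[blk]])) {
      p0 <- params[[blk]][[nm]]
      idx <- unique(round(seq(1, length(p0), length.out = min(4, length(p0)))))
      for (i in idx) {
        pp <- params; pp[[blk]][[nm]][[i]] <- p0[[i]] + eps
        pm <- params; pm[[blk]][[nm]][[i]] <- p0[[i]] - eps
        num <- (meiotrace:::gru_loss_and_grads(pp, xs, y)$loss -
                  meiotrace:::gru_loss_and_grads(pm, xs, y)$loss) / (2 * eps)
        expect_equal(lg$grads[[blk]][[nm]][[i]], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and fits separable toy data perfectly", {
  withr::with_seed(31, {
    n_per <- 8
    curves <- c(
      lapply(seq_len(n_per), function(i)
        abs(c(rep(6, 10), seq(6, 12, length.out = 6),
              seq(12, 0.5, length.out = 15)) + rnorm(31, 0, 0.1))),
      lapply(seq_len(n_per), function(i)
        abs(seq(8, 0.3, length.out = 31) + rnorm(31, 0, 0.1))),
      lapply(seq_len(n_per), function(i) abs(rnorm(31, 0, 0.4))))
  })
  labels <- rep(c("retracing", "congressing", "quasi-static"), each = n_per)
  seqs <- make_sequences(curves, labels)
  fit <- train_classifier(seqs, small_gru_spec())
  expect_lt(dplyr::last(fit$loss_trace), fit$loss_trace[[1]])
  pred <- predict(fit, seqs)
  expect_equal(mean(pred$label == labels), 1)

  single <- dplyr::filter(seqs, true_label == "congressing")
  expect_error(train_classifier(single, small_gru_spec()), "single-class")
})

test_that("predictions are normalized, deterministic, and tie-stable", {
  seqs <- cohort_split()$test
  fit <- trained_full_model()
  pred <- predict(fit, seqs)
  expect_equal(pred$p_retracing + pred$p_congressing + pred$p_quasistatic,
               rep(1, nrow(pred)), tolerance = 1e-6)
  pred2 <- predict(fit, seqs)
  expect_identical(pred, pred2)

  # duplicated input rows give identical outputs
  dup <- dplyr::mutate(seqs, oocyte_id = paste0(oocyte_id, "zz"))
  both <- predict(fit, dplyr::bind_rows(seqs, dup))
  orig <- dplyr::filter(both, !grepl("zz$", oocyte_id))
  copy <- dplyr::filter(both, grepl("zz$", oocyte_id)) |>
    dplyr::mutate(oocyte_id = sub("zz$", "", oocyte_id))
  joined <- dplyr::left_join(orig, copy,
                             by = c("oocyte_id", "chromosome_id"))
  expect_equal(joined$p_congressing.x, joined$p_congressing.y)
  expect_equal(joined$label.x, joined$label.y)
})

test_that("ROC evaluation matches brute-force pairwise concordance", {
  # 4-item toy set with hand-set probabilities, including a tie
  scores <- c(0.9, 0.6, 0.6, 0.2)
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  concordance <- function(s, p) {
    pr <- s[p]; ng <- s[!p]
    tot <- 0
    for (a in pr) for (b in ng) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pr) * length(ng))
  }
  expect_equal(meiotrace:::auc_threshold_sweep(scores, pos),
               concordance(scores, pos))

  for (s in 1:20) {
    withr::with_seed(s, {
      sc <- round(runif(12), 1)          # forces ties
      p <- runif(12) > 0.5
    })
    if (any(p) && !all(p)) {
      expect_equal(meiotrace:::auc_threshold_sweep(sc, p),
                   concordance(sc, p), tolerance = 1e-12)
    }
  }
})

test_that("evaluation metrics behave at the extremes", {
  probs <- matrix(c(1, 0, 0,
                    0, 1, 0,
                    0, 0, 1), 3, byrow = TRUE)
  pred <- tibble::tibble(oocyte_id = "a", chromosome_id = 1:3,
                         p_retracing = probs[, 1],
                         p_congressing = probs[, 2],
                         p_quasistatic = probs[, 3],
                         label = c("retracing", "congressing", "quasi-static"))
  ev <- evaluate_classifier(pred, c("retracing", "congressing",
                                    "quasi-static"))
  expect_equal(ev$metrics$auc, c(1, 1, 1))
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$metrics$sensitivity, c(1, 1, 1))
  expect_equal(ev$metrics$specificity, c(1, 1, 1))

  # labels independent of scores: AUC near 1/2
  withr::with_seed(40, {
    n <- 600
    p1 <- runif(n); p2 <- runif(n) * (1 - p1); p3 <- 1 - p1 - p2
    predr <- tibble::tibble(oocyte_id = "a", chromosome_id = 1:n,
                            p_retracing = p1, p_congressing = p2,
                            p_quasistatic = p3,
                            label = sample(c("retracing", "congressing",
                                             "quasi-static"), n, TRUE))
    truth <- sample(c("retracing", "congressing", "quasi-static"), n, TRUE)
  })
  evr <- evaluate_classifier(predr, truth)
  expect_lt(abs(evr$macro_auc - 0.5), 0.07)

  # class with zero positives gets an NA AUC
  ev0 <- evaluate_classifier(pred, c("congressing", "congressing",
                                     "quasi-static"))
  expect_true(is.na(ev0$metrics$auc[ev0$metrics$class == "retracing"]))

  g <- generics::glance(ev)
  expect_equal(g$accuracy, 1)
  expect_equal(nrow(generics::tidy(ev)), 3)
})

test_that("ROC/AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  seqs <- cohort_split()$test
  pred <- predict(trained_full_model(), seqs)
  ev <- evaluate_classifier(pred)
  for (cl in c("retracing", "congressing", "quasi-static")) {
    col <- c(retracing = "p_retracing", congressing = "p_congressing",
             `quasi-static` = "p_quasistatic")[[cl]]
    ref <- suppressMessages(pROC::auc(pred$true_label == cl, pred[[col]],
                                      direction = "<"))
    expect_equal(ev$metrics$auc[ev$metrics$class == cl], as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("the rule-based baseline applies its definitional bounds", {
  curves <- list(rep(0.5, 31),
                 c(rep(6, 8), seq(6, 12, length.out = 8),
                   seq(12, 0.5, length.out = 15)),
                 seq(6, 0.2, length.out = 31))
  seqs <- make_sequences(curves, c(NA, NA, NA))
  lab <- baseline_rule_classify(seqs)
  expect_equal(lab$label, c("quasi-static", "retracing", "congressing"))

  # under 50% coverage: NA
  low <- dplyr::mutate(make_sequences(curves[1], NA),
                       mask = as.integer(slot > 3))
  expect_true(is.na(baseline_rule_classify(low)$label))
})

test_that("GRU matches or beats the baseline rule and a label shuffle breaks it", {
  seqs <- cohort_seqs()$sequences
  sp <- cohort_split()
  fit <- trained_full_model()
  pred <- predict(fit, sp$test)
  acc_gru <- mean(pred$label == pred$true_label)

  bl <- baseline_rule_classify(sp$test)
  truth <- dplyr::distinct(sp$test, oocyte_id, chromosome_id, true_label)
  acc_bl <- mean(dplyr::left_join(bl, truth,
                                  by = c("oocyte_id", "chromosome_id"))$label ==
                   truth$true_label, na.rm = TRUE)
  expect_gte(acc_gru, acc_bl - 0.05)

  # permuting the training labels drives test AUC to chance
  withr::with_seed(13, {
    keys <- dplyr::distinct(sp$train, oocyte_id, chromosome_id)
    keys$shuffled <- sample(dplyr::distinct(
      sp$train, oocyte_id, chromosome_id, true_label)$true_label)
  })
  shuffled_train <- sp$train |>
    dplyr::select(-true_label) |>
    dplyr::left_join(keys, by = c("oocyte_id", "chromosome_id")) |>
    dplyr::rename(true_label = shuffled)
  fit_sh <- train_classifier(shuffled_train, small_gru_spec())
  pred_sh <- predict(fit_sh, seqs)
  ev_sh <- evaluate_classifier(pred_sh)
  expect_lt(abs(ev_sh$macro_auc - 0.5), 0.15)
})
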