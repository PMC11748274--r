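#' Per-oocyte trajectory-class ratios
#'
#' Fractions of chromosomes classified as retracing / congressing /
#' quasi-static / NA per oocyte; fractions sum to 1.
#'
#' @param predictions Tibble with `oocyte_id`, `label` (NA allowed) and
#'   optionally `condition`.
#' @return Tibble with one row per oocyte: `n`, `retracing`, `congressing`,
#'   `quasi_static`, `na_fraction`.
#' @export
trajectory_ratios <- function(predictions) {
  has_cond <- "condition" %in% names(predictions)
  grp <- c("oocyte_id", if (has_cond) "condition")
  empty <- filter(dplyr::count(predictions, dplyr::across(all_of(grp))),
                  .data$n == 0)
  if (nrow(empty) > 0) warn("empty oocytes excluded from ratios")
  predictions %>%
    group_by(dplyr::across(all_of(grp))) %>%
    summarise(n = dplyr::n(),
              retracing = mean(!is.na(.data$label) &
                                 .data$label == "retracing"),
              congressing = mean(!is.na(.data$label) &
                                   .data$label == "congressing"),
              quasi_static = mean(!is.na(.data$label) &
                                    .data$label == "quasi-static"),
              na_fraction = mean(is.na(.data$label)),
              .groups = "drop")
}

#' One-sided Mann-Whitney U test
#'
#' The U statistic counts pairs won by the group declared larger under the
#' alternative (ties count 1/2). For small samples without prohibitive cost
#' (smaller group <= 8, combined n <= 25) the p-value is computed by exact
#' enumeration of all group labelings (valid under ties); otherwise by the
#' normal approximation with tie correction and continuity correction. The
#' direction of the alternative must be declared, never inferred from the
#' data.
#'
#' @param a,b Numeric samples.
#' @param direction `"a_greater"` (alternative: a shifted right of b) or
#'   `"b_greater"`.
#' @param comparison Label for the output row.
#' @return One-row tibble: `comparison`, `statistic` (U for the declared
#'   direction), `p_value`, `direction`, `method`, `ties`.
#' @export
mann_whitney_one_sided <- function(a, b, direction = c("a_greater",
                                                       "b_greater"),
                                   comparison = "a vs b") {
  direction <- match.arg(direction)
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_obs <- if (direction == "a_greater") u_a else na * nb - u_a
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1) {
    return(tibble(comparison = comparison, statistic = u_obs, p_value = 1,
                  direction = direction, method = "degenerate",
                  ties = TRUE))
  }
  if (min(na, nb) <= 8 && n <= 25) {
    combos <- utils::combn(n, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    if (direction == "b_greater") u_all <- na * nb - u_all
    p <- mean(u_all >= u_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    t_tab <- table(pooled)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 *
      ((n + 1) - sum(t_tab^3 - t_tab) / (n * (n - 1)))
    p <- pnorm((u_obs - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
    method <- "normal approximation"
  }
  tibble(comparison = comparison, statistic = u_obs,
         p_value = min(max(p, 0), 1), direction = direction,
         method = method, ties = ties)
}

#' Multiplicity adjustment for a set of p-values
#'
#' Benjamini-Hochberg step-up by default (configurable to Bonferroni);
#' adjusted values are monotone and bounded by 1, and never smaller than
#' the raw values.
#'
#' @param p Numeric p-values in [0, 1].
#' @param method `"BH"` or `"bonferroni"` (passed to [stats::p.adjust()]).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' All pairwise one-sided Mann-Whitney comparisons with adjustment
#'
#' @param data Tibble with a value column and a grouping column.
#' @param value,group Column names (strings).
#' @param direction Alternative for each pair: the first group of the pair
#'   (in factor order) is declared greater (`"a_greater"`) or smaller.
#' @param method Adjustment method, see [adjust_pvalues()].
#' @return Test-result tibble with raw and adjusted p-values.
#' @export
pairwise_mann_whitney <- function(data, value, group,
                                  direction = "a_greater", method = "BH") {
  gs <- unique(as.character(data[[group]]))
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  res <- bind_rows(lapply(pairs, function(pr) {
    mann_whitney_one_sided(data[[value]][data[[group]] == pr[[1]]],
                           data[[value]][data[[group]] == pr[[2]]],
                           direction = direction,
                           comparison = paste(pr, collapse = " vs "))
  }))
  res$p_adjusted <- adjust_pvalues(res$p_value, method)
  res
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one. The conditional maximum-
#' likelihood odds ratio is reported.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row tibble: `statistic` (conditional odds ratio), `p_value`,
#'   `method`, `degenerate` (TRUE when a margin is zero, giving p = 1).
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
    abort("need a 2x2 table of non-negative integer counts")
  }
  a <- m[1, 1]
  row1 <- sum(m[1, ]); col1 <- sum(m[, 1]); tot <- sum(m)
  if (row1 == 0 || col1 == 0 || row1 == tot || col1 == tot) {
    return(tibble(statistic = NA_real_, p_value = 1,
                  method = "hypergeometric", degenerate = TRUE))
  }
  support <- max(0, row1 + col1 - tot):min(row1, col1)
  probs <- dhyper(support, col1, tot - col1, row1)
  p_obs <- dhyper(a, col1, tot - col1, row1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tibble(statistic = conditional_odds_ratio(a, row1, col1, tot),
         p_value = min(p, 1), method = "hypergeometric",
         degenerate = FALSE)
}

# conditional MLE of the odds ratio: psi with E_psi[A] = a under the
# noncentral hypergeometric distribution on the observed margins
conditional_odds_ratio <- function(a, row1, col1, tot) {
  support <- max(0, row1 + col1 - tot):min(row1, col1)
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  logw <- lchoose(col1, support) + lchoose(tot - col1, row1 - support)
  e_a <- function(log_psi) {
    lp <- logw + support * log_psi
    w <- exp(lp - max(lp))
    sum(support * w) / sum(w) - a
  }
  exp(stats::uniroot(e_a, c(-35, 35), tol = 1e-10)$root)
}

#' Assemble the analysis report bundle
#'
#' Writes deterministic, machine-readable summaries of an analysis:
#' per-oocyte class ratios (`ratios.csv`), test results (`tests.csv`),
#' per-time population speed summaries (`speeds_summary.csv`),
#' spindle dimensions (`spindle.csv`) and a `report.json` index. Inputs
#' that are NULL are skipped and listed as missing in the JSON.
#'
#' @param dir Output directory.
#' @param ratios Ratio tibble from [trajectory_ratios()].
#' @param tests Test tibble (e.g. from [pairwise_mann_whitney()]).
#' @param speed_summary Tibble from [summarize_population()].
#' @param spindle_series Tibble from [fit_spindle_series()].
#' @return Invisibly, the list of files written.
#' @export
build_report <- function(dir, ratios = NULL, tests = NULL,
                         speed_summary = NULL, spindle_series = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(); missing <- character()
  emit <- function(df, name, sort_cols) {
    path <- file.path(dir, name)
    if (is.null(df)) {
      missing <<- c(missing, name)
      return()
    }
    df <- arrange(df, dplyr::across(all_of(intersect(sort_cols, names(df)))))
    if ("axes" %in% names(df)) df$axes <- NULL
    readr::write_csv(df, path)
    written <<- c(written, name)
  }
  emit(ratios, "ratios.csv", c("condition", "oocyte_id"))
  emit(tests, "tests.csv", "comparison")
  emit(speed_summary, "speeds_summary.csv", c("component", "t_mid_min"))
  emit(spindle_series, "spindle.csv", "frame")
  jsonlite::write_json(list(files = as.list(written),
                            missing_inputs = as.list(missing)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, "report.json"))
}
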