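#' Build classifier input sequences around the Step III onset
#'
#' Represents each chromosome as its distance-to-equator sequence sampled
#' every `dt` minutes in a window of +/- `half_window` around the Step III
#' onset T0 (31 points at the 10-min default). Points outside the recording
#' carry a sentinel value of 0 with `mask = 0`.
#'
#' @param aligned Aligned trajectory tibble for one oocyte.
#' @param t0 Step III onset in minutes (the II to III boundary).
#' @param dt Sampling interval, minutes.
#' @param half_window Window half-width, minutes (default 150).
#' @return Long tibble: `oocyte_id`, `chromosome_id`, `slot`
#'   (-half_window/dt .. +half_window/dt), `t_min`, `value` (|z|, um),
#'   `mask` (1 observed / 0 padded), `true_label` when present.
#' @export
build_sequences <- function(aligned, t0, dt = 10, half_window = 150) {
  if (is.na(t0)) abort("t0 is undetermined; sequence excluded (NA)")
  k <- as.integer(round(half_window / dt))
  grid <- tibble(slot = -k:k, t_min = t0 + (-k:k) * dt)
  keys <- distinct(aligned, .data$oocyte_id, .data$chromosome_id,
                   dplyr::across(dplyr::any_of("true_label")))
  obs <- aligned %>%
    mutate(value = abs(.data$z_um)) %>%
    select("oocyte_id", "chromosome_id", "t_min", "value")
  tidyr::crossing(keys, grid) %>%
    left_join(obs, by = c("oocyte_id", "chromosome_id", "t_min")) %>%
    mutate(mask = as.integer(!is.na(.data$value)),
           value = ifelse(is.na(.data$value), 0, .data$value)) %>%
    arrange(.data$oocyte_id, .data$chromosome_id, .data$slot)
}

#' Build sequences for a whole cohort of analyzed oocytes
#'
#' Applies [build_sequences()] per oocyte using each oocyte's recovered
#' Step III onset; oocytes whose equator never formed (undetermined T0,
#' severe knockdowns) are excluded and reported as NA.
#'
#' @param analyses List of [analyze_oocyte()] results.
#' @return List with `sequences` (row-bound sequence tibble) and
#'   `na_oocytes` (character vector of excluded oocyte ids).
#' @export
cohort_sequences <- function(analyses) {
  seqs <- list(); nas <- character()
  for (an in analyses) {
    if (an$status != "aligned" || an$segmentation$status != "ok") {
      oid <- if (!is.null(an$aligned)) an$aligned$oocyte_id[[1]] else
        paste0("oocyte_", length(nas) + 1)
      nas <- c(nas, oid)
      next
    }
    t0 <- an$segmentation$boundaries[[2]]
    seqs[[length(seqs) + 1]] <- build_sequences(an$aligned, t0)
  }
  list(sequences = if (length(seqs)) bind_rows(seqs) else NULL,
       na_oocytes = nas)
}

sequence_keys <- function(sequences) {
  distinct(sequences, .data$oocyte_id, .data$chromosome_id,
           dplyr::across(dplyr::any_of("true_label")))
}

# long sequence tibble -> list(x = T-length list of B x 2 matrices
# (scaled value, mask), keys tibble, y = factor labels or NULL)
sequences_to_batch <- function(sequences, input_scale = 0.1) {
  ord <- sequences %>%
    arrange(.data$oocyte_id, .data$chromosome_id, .data$slot)
  keys <- sequence_keys(ord)
  n_slot <- dplyr::n_distinct(ord$slot)
  b <- nrow(keys)
  stopifnot(nrow(ord) == b * n_slot)
  vals <- matrix(ord$value, nrow = n_slot)   # slots x B
  msk <- matrix(ord$mask, nrow = n_slot)
  x <- lapply(seq_len(n_slot), function(t) {
    cbind(vals[t, ] * input_scale, msk[t, ])
  })
  y <- if ("true_label" %in% names(keys)) {
    factor(keys$true_label, levels = TRAJECTORY_CLASSES)
  }
  list(x = x, keys = keys, y = y)
}

#' Stratified train/test split of sequences
#'
#' Splits the chromosomes (not time points) into training and test sets at
#' the given ratio, stratified by true label; deterministic for a seed,
#' disjoint and exhaustive.
#'
#' @param sequences Sequence tibble with `true_label`.
#' @param ratio Training fraction (default 0.9).
#' @param seed Integer seed.
#' @return List with `train` and `test` sequence tibbles.
#' @export
split_train_test <- function(sequences, ratio = 0.9, seed = 1) {
  keys <- sequence_keys(sequences)
  if (nrow(keys) < 10) abort("need at least 10 sequences to split")
  has_lab <- "true_label" %in% names(keys) && !anyNA(keys$true_label)
  strata <- if (has_lab) keys$true_label else rep("all", nrow(keys))
  if (has_lab && length(unique(strata)) < 2) {
    warn("only one class present: plain (unstratified) split")
    strata <- rep("all", nrow(keys))
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(unique(strata), function(s) {
      idx <- which(strata == s)
      n_test <- max(1, round(length(idx) * (1 - ratio)))
      sample(idx, n_test)
    }))
  })
  keys$.set <- "train"
  keys$.set[test_idx] <- "test"
  tagged <- left_join(sequences,
                      keys[, c("oocyte_id", "chromosome_id", ".set")],
                      by = c("oocyte_id", "chromosome_id"))
  list(train = select(filter(tagged, .data$.set == "train"), -".set"),
       test = select(filter(tagged, .data$.set == "test"), -".set"))
}

#' Specification of the GRU trajectory classifier
#'
#' Two stacked GRU (gated recurrent unit) layers encode the
#' distance-to-equator sequence; the final hidden state feeds a one-hidden-
#' layer perceptron whose softmax output gives the probabilities of the
#' three trajectory classes. Training minimizes cross-entropy between the
#' predicted and true label distributions by full-batch Adam with early
#' stopping on a loss plateau.
#'
#' @param hidden_size Hidden units per GRU layer (default 32).
#' @param head_size MLP hidden width (default 32).
#' @param learning_rate Adam step size.
#' @param epochs Maximum training epochs (default 200).
#' @param patience Early-stop patience: stop when the best loss has not
#'   improved by `tol` for this many epochs.
#' @param tol Minimum loss improvement counted as progress.
#' @param input_scale Multiplier bringing distances (um) to unit scale.
#' @param restarts Independent random weight initializations tried; the fit
#'   with the lowest final training loss is kept (recurrent nets can stall
#'   in a poor basin from an unlucky init, so a few restarts are standard).
#' @param seed Seed for weight initialization (restart k uses seed + k - 1).
#' @return A `gru_spec` list.
#' @export
gru_spec <- function(hidden_size = 32, head_size = 32, learning_rate = 0.01,
                     epochs = 200, patience = 25, tol = 1e-5,
                     input_scale = 0.1, restarts = 3, seed = 1) {
  structure(list(hidden_size = hidden_size, head_size = head_size,
                 learning_rate = learning_rate, epochs = epochs,
                 patience = patience, tol = tol, input_scale = input_scale,
                 restarts = restarts,
                 n_classes = length(TRAJECTORY_CLASSES), seed = seed),
            class = "gru_spec")
}

# ---- GRU internals --------------------------------------------------------

init_gru_params <- function(spec, input_dim = 2) {
  h <- spec$hidden_size
  rmat <- function(nr, nc, s) matrix(runif(nr * nc, -s, s), nr, nc)
  layer <- function(d) {
    s <- 1 / sqrt(h)
    list(Wr = rmat(d, h, s), Wz = rmat(d, h, s), Wn = rmat(d, h, s),
         Ur = rmat(h, h, s), Uz = rmat(h, h, s), Un = rmat(h, h, s),
         br = numeric(h), bz = numeric(h), bn = numeric(h))
  }
  s2 <- 1 / sqrt(spec$head_size)
  list(l1 = layer(input_dim), l2 = layer(h),
       head = list(W1 = rmat(h, spec$head_size, s2),
                   b1 = numeric(spec$head_size),
                   W2 = rmat(spec$head_size, spec$n_classes, s2),
                   b2 = numeric(spec$n_classes)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass of one GRU layer over a list of inputs; returns hidden states
# and gate caches needed for backpropagation through time
gru_layer_forward <- function(p, xs) {
  b <- nrow(xs[[1]]); h <- length(p$br)
  hid <- matrix(0, b, h)
  cache <- vector("list", length(xs))
  hs <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    x <- xs[[t]]
    r <- sigmoid(x %*% p$Wr + hid %*% p$Ur +
                   matrix(p$br, b, h, byrow = TRUE))
    z <- sigmoid(x %*% p$Wz + hid %*% p$Uz +
                   matrix(p$bz, b, h, byrow = TRUE))
    n <- tanh(x %*% p$Wn + (r * hid) %*% p$Un +
                matrix(p$bn, b, h, byrow = TRUE))
    h_new <- (1 - z) * n + z * hid
    cache[[t]] <- list(x = x, h_prev = hid, r = r, z = z, n = n)
    hid <- h_new
    hs[[t]] <- hid
  }
  list(hs = hs, cache = cache)
}

# backward pass of one GRU layer; dhs: list of gradients w.r.t. each hidden
# state (NULL entries allowed); returns parameter grads and input grads
gru_layer_backward <- function(p, fwd, dhs) {
  tt <- length(fwd$cache)
  b <- nrow(fwd$cache[[1]]$x)
  zero <- function(m) matrix(0, nrow(m), ncol(m))
  g <- list(Wr = zero(p$Wr), Wz = zero(p$Wz), Wn = zero(p$Wn),
            Ur = zero(p$Ur), Uz = zero(p$Uz), Un = zero(p$Un),
            br = numeric(length(p$br)), bz = numeric(length(p$bz)),
            bn = numeric(length(p$bn)))
  dxs <- vector("list", tt)
  dh <- matrix(0, b, length(p$br))
  for (t in rev(seq_len(tt))) {
    if (!is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    cc <- fwd$cache[[t]]
    dz <- dh * (cc$h_prev - cc$n)
    dn <- dh * (1 - cc$z)
    dh_prev <- dh * cc$z
    dan <- dn * (1 - cc$n^2)
    g$Wn <- g$Wn + crossprod(cc$x, dan)
    g$Un <- g$Un + crossprod(cc$r * cc$h_prev, dan)
    g$bn <- g$bn + colSums(dan)
    drh <- dan %*% t(p$Un)
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    dar <- dr * cc$r * (1 - cc$r)
    g$Wz <- g$Wz + crossprod(cc$x, daz)
    g$Uz <- g$Uz + crossprod(cc$h_prev, daz)
    g$bz <- g$bz + colSums(daz)
    g$Wr <- g$Wr + crossprod(cc$x, dar)
    g$Ur <- g$Ur + crossprod(cc$h_prev, dar)
    g$br <- g$br + colSums(dar)
    dxs[[t]] <- dan %*% t(p$Wn) + daz %*% t(p$Wz) + dar %*% t(p$Wr)
    dh_prev <- dh_prev + daz %*% t(p$Uz) + dar %*% t(p$Ur)
    dh <- dh_prev
  }
  list(grads = g, dxs = dxs)
}

softmax_rows <- function(l) {
  e <- exp(l - apply(l, 1, max))
  e / rowSums(e)
}

# full forward pass: probabilities for a batch
gru_forward <- function(params, xs) {
  f1 <- gru_layer_forward(params$l1, xs)
  f2 <- gru_layer_forward(params$l2, f1$hs)
  rep_final <- f2$hs[[length(f2$hs)]]
  u_pre <- rep_final %*% params$head$W1 +
    matrix(params$head$b1, nrow(rep_final), length(params$head$b1),
           byrow = TRUE)
  u <- pmax(u_pre, 0)
  logits <- u %*% params$head$W2 +
    matrix(params$head$b2, nrow(u), length(params$head$b2), byrow = TRUE)
  list(probs = softmax_rows(logits), f1 = f1, f2 = f2, u = u,
       rep_final = rep_final)
}

# mean cross-entropy loss and all parameter gradients for a batch
gru_loss_and_grads <- function(params, xs, y_onehot) {
  fw <- gru_forward(params, xs)
  b <- nrow(y_onehot)
  loss <- -mean(rowSums(y_onehot * log(pmax(fw$probs, 1e-12))))
  dlogits <- (fw$probs - y_onehot) / b
  gW2 <- crossprod(fw$u, dlogits)
  gb2 <- colSums(dlogits)
  du <- dlogits %*% t(params$head$W2)
  du <- du * (fw$u > 0)
  gW1 <- crossprod(fw$rep_final, du)
  gb1 <- colSums(du)
  drep <- du %*% t(params$head$W1)
  tt <- length(xs)
  dhs2 <- vector("list", tt)
  dhs2[[tt]] <- drep
  b2 <- gru_layer_backward(params$l2, fw$f2, dhs2)
  b1 <- gru_layer_backward(params$l1, fw$f1, b2$dxs)
  list(loss = loss,
       grads = list(l1 = b1$grads, l2 = b2$grads,
                    head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)),
       probs = fw$probs)
}

# elementwise recursion over the nested parameter list
map_params <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- lapply(seq_along(args[[1]]), function(i) {
      do.call(map_params, c(list(f), lapply(args, `[[`, i)))
    })
    names(out) <- names(args[[1]])
    out
  } else {
    do.call(f, args)
  }
}

#' Train the GRU trajectory classifier
#'
#' @param sequences Training sequence tibble (see [build_sequences()]) with
#'   `true_label` for every chromosome; at least two classes required.
#' @param spec A [gru_spec()].
#' @return A fitted `gru_classifier` with the weights, the per-epoch
#'   training-loss trace and the class levels.
#' @export
train_classifier <- function(sequences, spec = gru_spec()) {
  batch <- sequences_to_batch(sequences, spec$input_scale)
  if (is.null(batch$y) || anyNA(batch$y)) {
    abort("training sequences need a complete true_label")
  }
  if (length(unique(batch$y)) < 2) {
    abort("training set is single-class: nothing to discriminate")
  }
  y_onehot <- diag(spec$n_classes)[as.integer(batch$y), , drop = FALSE]
  n_restarts <- spec$restarts %||% 1
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    fits[[r]] <- with_seed(spec$seed + r - 1L,
                           gru_fit_once(spec, batch, y_onehot))
    # a well-separated basin has been found; no need for more restarts
    if (tail(fits[[r]]$loss_trace, 1) < 0.1) break
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  best <- fits[[which.min(vapply(fits, function(f) tail(f$loss_trace, 1),
                                 numeric(1)))]]
  structure(c(best, list(spec = spec, classes = TRAJECTORY_CLASSES,
                         n_train = length(batch$y))),
            class = "gru_classifier")
}

# one optimization run from a fresh initialization (full-batch Adam with
# early stopping on a loss plateau); uses the current RNG stream
gru_fit_once <- function(spec, batch, y_onehot) {
  params <- init_gru_params(spec, input_dim = ncol(batch$x[[1]]))
  m_state <- map_params(function(p) p * 0, params)
  v_state <- map_params(function(p) p * 0, params)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  trace <- numeric(0)
  best <- Inf; stall <- 0
  for (epoch in seq_len(spec$epochs)) {
    lg <- gru_loss_and_grads(params, batch$x, y_onehot)
    if (!is.finite(lg$loss)) {
      abort("training diverged (non-finite loss); lower the learning rate")
    }
    trace <- c(trace, lg$loss)
    m_state <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                          m_state, lg$grads)
    v_state <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                          v_state, lg$grads)
    bc1 <- 1 - beta1^epoch; bc2 <- 1 - beta2^epoch
    params <- map_params(function(p, m, v) {
      p - spec$learning_rate * (m / bc1) / (sqrt(v / bc2) + eps)
    }, params, m_state, v_state)
    if (lg$loss < best - spec$tol) {
      best <- lg$loss; stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= spec$patience) break
    }
  }
  list(params = params, loss_trace = trace)
}

#' @export
print.gru_classifier <- function(x, ...) {
  cat(sprintf("<gru_classifier> 2 GRU layers (H=%d) + MLP head; trained %d epochs, final loss %.4f\n",
              x$spec$hidden_size, length(x$loss_trace),
              tail(x$loss_trace, 1)))
  invisible(x)
}

#' Predict trajectory classes for sequences
#'
#' @param object A fitted `gru_classifier`.
#' @param sequences Sequence tibble (same window geometry as training).
#' @param ... Unused.
#' @return Tibble `oocyte_id`, `chromosome_id`, `p_retracing`,
#'   `p_congressing`, `p_quasistatic`, `label` (argmax; ties broken by the
#'   fixed class order retracing < congressing < quasi-static), plus
#'   `true_label` when available. Probabilities sum to 1 per row.
#' @export
predict.gru_classifier <- function(object, sequences, ...) {
  batch <- sequences_to_batch(sequences, object$spec$input_scale)
  probs <- gru_forward(object$params, batch$x)$probs
  out <- batch$keys
  out$p_retracing <- probs[, 1]
  out$p_congressing <- probs[, 2]
  out$p_quasistatic <- probs[, 3]
  out$label <- object$classes[apply(probs, 1, which.max)]
  ord <- c("oocyte_id", "chromosome_id", "p_retracing", "p_congressing",
           "p_quasistatic", "label",
           intersect("true_label", names(out)))
  out[, ord]
}

#' Rule-based baseline trajectory classifier
#'
#' Deterministic reference rule: quasi-static when the mean distance to the
#' equator stays under 1.5 um (the definitional bound); otherwise retracing
#' when the sequence peaks at >= 8 um and later returns below 3 um;
#' otherwise congressing. Sequences with less than 50% observed coverage
#' get NA.
#'
#' @param sequences Sequence tibble.
#' @return Tibble `oocyte_id`, `chromosome_id`, `label`.
#' @export
baseline_rule_classify <- function(sequences) {
  sequences %>%
    group_by(.data$oocyte_id, .data$chromosome_id) %>%
    summarise(label = {
      v <- .data$value[.data$mask == 1]
      if (mean(.data$mask) < 0.5) {
        NA_character_
      } else if (mean(v) < 1.5) {
        "quasi-static"
      } else {
        pk <- which.max(v)
        if (v[[pk]] >= 8 && pk < length(v) && min(v[pk:length(v)]) < 3) {
          "retracing"
        } else {
          "congressing"
        }
      }
    }, .groups = "drop")
}
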