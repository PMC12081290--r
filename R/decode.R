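# L2-regularized linear multiclass classifier (one-vs-rest ridge on class
# indicators with argmax aggregation), with per-feature standardization
# fitted on the training fold only. Closed form, so the repeated
# leave-trials-out loops stay cheap.
ridge_train <- function(x, y, lambda = 1) {
  classes <- sort(unique(y))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  yi <- outer(y, classes, "==") * 1
  ym <- colMeans(yi)
  g <- crossprod(xs) + lambda * diag(ncol(xs))
  w <- solve(g, crossprod(xs, sweep(yi, 2L, ym)))
  list(w = w, ym = ym, ctr = ctr, scl = scl, classes = classes)
}

ridge_predict <- function(fit, x) {
  xs <- sweep(sweep(x, 2L, fit$ctr), 2L, fit$scl, "/")
  scores <- sweep(xs %*% fit$w, 2L, fit$ym, "+")
  fit$classes[max.col(scores, ties.method = "first")]
}

check_aligned <- function(em1, em2) {
  c1 <- table(em1$labels$type)
  c2 <- table(em2$labels$type)
  if (!identical(as.vector(c1), as.vector(c2)) ||
      !identical(names(c1), names(c2)))
    stop("per-type trial counts differ between mazes; decoding requires index-matched trials")
}

#' Within- and across-maze trial-type decoding from a single unit
#'
#' On each repeat, one random trial per trial type is held out of the maze-1
#' matrix (an 8 x 9 test set), an L2-regularized linear multiclass
#' classifier is trained on the remaining trials (152 x 9 at the default
#' session size), and accuracy is measured within maze on the held-out
#' trials and across maze on the maze-2 trials with the identical
#' within-type indices. Chance is 1/8.
#'
#' @param em1,em2 The unit's per-maze `epoch_matrix` objects, with matching
#'   per-type trial counts.
#' @param n_repeats Number of repeats (default 1000).
#' @param lambda Ridge regularization strength.
#' @param seed Integer seed.
#' @return list of class `decode_result`: `unit_id`, `accuracy_within`,
#'   `accuracy_across`, `n_repeats`, `chance` (= 0.125).
#' @export
decode_single_cell <- function(em1, em2, n_repeats = 1000, lambda = 1,
                               seed = NULL) {
  stopifnot(inherits(em1, "epoch_matrix"), inherits(em2, "epoch_matrix"))
  check_aligned(em1, em2)
  types <- unique(em1$labels$type)
  key1 <- paste(em1$labels$type, em1$labels$within_type_index)
  key2 <- paste(em2$labels$type, em2$labels$within_type_index)
  row2 <- match(key1, key2) # maze-2 row with the identical trial index
  if (any(is.na(row2))) stop("within-type indices not aligned across mazes")
  y <- em1$labels$type
  idx_by_type <- split(seq_len(nrow(em1$values)), y)[types]
  acc_w <- acc_x <- numeric(n_repeats)
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      held <- vapply(idx_by_type, function(ix) ix[sample.int(length(ix), 1L)],
                     integer(1))
      fit <- ridge_train(em1$values[-held, , drop = FALSE], y[-held], lambda)
      acc_w[rep_i] <- mean(ridge_predict(fit, em1$values[held, , drop = FALSE]) ==
                             y[held])
      acc_x[rep_i] <- mean(ridge_predict(fit, em2$values[row2[held], ,
                                                         drop = FALSE]) ==
                             em2$labels$type[row2[held]])
    }
  })
  structure(list(unit_id = em1$unit_id, accuracy_within = mean(acc_w),
                 accuracy_across = mean(acc_x), n_repeats = n_repeats,
                 chance = 1 / 8),
            class = "decode_result")
}

#' Within- and across-maze trial-type decoding from a pseudo-ensemble
#'
#' Builds a pseudo-ensemble from a list of units (not necessarily recorded
#' together) by aligning trials across units on the (trial type,
#' within-type index) pair. On each repeat, `trials_per_type` trials per
#' type are drawn (a 120 x 9 matrix per maze per unit at the default 15),
#' one trial per type is left out, and a separate linear classifier is
#' trained for each epoch on the remaining maze-1 trials, with the epoch's
#' rate across units as the feature vector; accuracy is measured within
#' maze on the held-out trials and across maze on the index-matched maze-2
#' trials. Chance is 1/8.
#'
#' @param ems1,ems2 Lists of per-unit `epoch_matrix` objects for maze 1 and
#'   maze 2 (same unit order).
#' @param n_units Number of units sampled into the ensemble (default all).
#' @param trials_per_type Trials drawn per type per repeat (default 15).
#' @param n_repeats Number of repeats (default 200).
#' @param lambda Ridge regularization strength.
#' @param seed Integer seed.
#' @return list of class `decode_result` with `per_epoch` (data.frame of
#'   epoch, accuracy_within, accuracy_across), overall `accuracy_within` /
#'   `accuracy_across` (means over epochs), `n_units`, `n_repeats`,
#'   `chance`.
#' @export
decode_ensemble <- function(ems1, ems2, n_units = NULL, trials_per_type = 15,
                            n_repeats = 200, lambda = 1, seed = NULL) {
  stopifnot(length(ems1) == length(ems2), length(ems1) >= 1L)
  with_seed(seed, {
    if (!is.null(n_units)) {
      if (n_units > length(ems1)) stop("fewer units available than n_units")
      pick <- sample.int(length(ems1), n_units)
      ems1 <- ems1[pick]; ems2 <- ems2[pick]
    }
    n_units <- length(ems1)
    types <- unique(ems1[[1]]$labels$type)
    n_types <- length(types)
    avail <- min(vapply(c(ems1, ems2), function(e)
      min(table(e$labels$type)), numeric(1)))
    if (trials_per_type > avail)
      stop("not enough trials per type: have ", avail)
    epochs <- colnames(ems1[[1]]$values)
    # unit x (type, index) lookup of rates, per epoch: build aligned arrays
    rate_array <- function(ems) {
      arr <- array(NA_real_,
                   c(n_types, avail, length(epochs), n_units))
      for (u in seq_len(n_units)) {
        em <- ems[[u]]
        ti <- match(em$labels$type, types)
        wi <- em$labels$within_type_index
        keep <- wi <= avail
        arr[cbind(rep(ti[keep], length(epochs)),
                  rep(wi[keep], length(epochs)),
                  rep(seq_along(epochs), each = sum(keep)),
                  u)] <- as.vector(em$values[keep, ])
      }
      if (anyNA(arr)) stop("within-type indices not contiguous across units")
      arr
    }
    a1 <- rate_array(ems1)
    a2 <- rate_array(ems2)
    acc_w <- acc_x <- matrix(0, n_repeats, length(epochs))
    for (rep_i in seq_len(n_repeats)) {
      sel <- sample.int(avail, trials_per_type) # shared across units/types
      held_pos <- sample.int(trials_per_type, 1L)
      held <- sel[held_pos]
      train_idx <- sel[-held_pos]
      y_train <- rep(types, times = length(train_idx))
      for (e in seq_along(epochs)) {
        xtr <- matrix(aperm(a1[, train_idx, e, , drop = FALSE],
                            c(1, 2, 4, 3)),
                      nrow = n_types * length(train_idx), ncol = n_units)
        xw <- matrix(a1[, held, e, ], nrow = n_types, ncol = n_units)
        xx <- matrix(a2[, held, e, ], nrow = n_types, ncol = n_units)
        fit <- ridge_train(xtr, y_train, lambda)
        acc_w[rep_i, e] <- mean(ridge_predict(fit, xw) == types)
        acc_x[rep_i, e] <- mean(ridge_predict(fit, xx) == types)
      }
    }
    per_epoch <- data.frame(epoch = epochs,
                            accuracy_within = colMeans(acc_w),
                            accuracy_across = colMeans(acc_x))
    structure(list(per_epoch = per_epoch,
                   accuracy_within = mean(per_epoch$accuracy_within),
                   accuracy_across = mean(per_epoch$accuracy_across),
                   n_units = n_units, n_repeats = n_repeats, chance = 1 / 8),
              class = "decode_result")
  })
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: within %.3f, across %.3f (chance %.3f, %d repeats)\n",
              x$accuracy_within, x$accuracy_across, x$chance, x$n_repeats))
  invisible(x)
}

#' Label-shuffled null distribution for a decoder
#'
#' Reruns a decoding configuration with trial-type labels permuted
#' (independently per maze, by permuting rows of the rate matrices while
#' keeping the label structure fixed). The resulting accuracy distribution
#' is centered at chance (1/8) and calibrates the decoders.
#'
#' @param em1,em2 Per-maze `epoch_matrix` objects (single-unit mode).
#' @param n_null Number of null permutations (default 100).
#' @param n_repeats Decoder repeats per permutation (kept small by default;
#'   the null averages over permutations).
#' @param lambda Ridge regularization strength.
#' @param seed Integer seed.
#' @return Numeric vector of `n_null` within-maze null accuracies.
#' @export
decode_label_null <- function(em1, em2, n_null = 100, n_repeats = 20,
                              lambda = 1, seed = NULL) {
  with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      e1 <- em1; e2 <- em2
      e1$values <- e1$values[sample.int(nrow(e1$values)), , drop = FALSE]
      e2$values <- e2$values[sample.int(nrow(e2$values)), , drop = FALSE]
      decode_single_cell(e1, e2, n_repeats = n_repeats,
                         lambda = lambda)$accuracy_within
    }, numeric(1))
  })
}
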