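test_that("a noiseless unit with distinct type vectors decodes perfectly", {
  set.seed(60)
  pat <- matrix(runif(72, 1, 10), 8, 9) # 8 distinct type signatures
  rownames(pat) <- trial_types(fix$design, 1)
  fun <- function(epoch, position, subsequence, ...)
    pat[paste(subsequence, position, sep = "_"), ]
  em1 <- synthetic_em(fun, 1)
  em2 <- synthetic_em(fun, 2)
  dr <- decode_single_cell(em1, em2, n_repeats = 50, seed = 1)
  expect_equal(dr$accuracy_within, 1)
  expect_equal(dr$accuracy_across, 1)
  expect_equal(dr$chance, 0.125)
})

test_that("a generalized tuned unit decodes similarly within and across", {
  tu <- tuning_spec("g1", 8, epoch_gain = runif(9, 0.3, 3),
                    reward_gain = 2.5, position_gain = c(0.3, 1, 2, 3))
  sp <- simulate_spikes(fix$trials, tu, fix$design, seed = 61)
  e1 <- epoch_matrix(sp, fix$trials, 1, fix$design)
  e2 <- epoch_matrix(sp, fix$trials, 2, fix$design)
  dr <- decode_single_cell(e1, e2, n_repeats = 1000, seed = 62)
  expect_gt(dr$accuracy_within, 0.2) # informative unit beats chance
  expect_lt(abs(dr$accuracy_within - dr$accuracy_across), 0.06)
})

test_that("within-maze accuracy grows with tuning contrast", {
  accs <- vapply(c(0, 1, 2), function(contrast) {
    tu <- tuning_spec("c", 6, position_gain = 1 + contrast * c(-0.5, 0, 0.5, 1))
    sp <- simulate_spikes(fix$trials, tu, fix$design, seed = 70 + contrast)
    e1 <- epoch_matrix(sp, fix$trials, 1, fix$design)
    e2 <- epoch_matrix(sp, fix$trials, 2, fix$design)
    decode_single_cell(e1, e2, n_repeats = 300, seed = 71)$accuracy_within
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02)) # nondecreasing up to sampling noise
  expect_gt(accs[3], accs[1])
})

test_that("decoding requires index-aligned mazes and bounded accuracies", {
  tu <- tuning_spec("g2", 5)
  sp <- simulate_spikes(fix$trials, tu, fix$design, seed = 80)
  e1 <- epoch_matrix(sp, fix$trials, 1, fix$design)
  e2 <- epoch_matrix(sp, fix$trials, 2, fix$design)
  short <- subsample_trials(e2, 15)
  expect_error(decode_single_cell(e1, short), "counts differ")
  dr <- decode_single_cell(e1, e2, n_repeats = 100, seed = 81)
  expect_true(dr$accuracy_within >= 0 && dr$accuracy_within <= 1)
  expect_true(dr$accuracy_across >= 0 && dr$accuracy_across <= 1)
})

test_that("ridge decoding tracks an independent svm route case by case", {
  skip_if_not_installed("e1071")
  # the same leave-one-per-type protocol with a linear-kernel svm (libsvm);
  # different classifiers need not match in accuracy on noisy data, but they
  # must agree on chance, perfect separability, and direction
  svm_within <- function(em, n_repeats = 100, seed = 97) {
    y <- factor(em$labels$type)
    idx_by_type <- split(seq_along(y), y)
    set.seed(seed)
    mean(replicate(n_repeats, {
      held <- vapply(idx_by_type, function(ix) ix[sample.int(length(ix), 1L)],
                     integer(1))
      fit <- e1071::svm(em$values[-held, ], y[-held], kernel = "linear",
                        scale = TRUE)
      mean(as.character(predict(fit, em$values[held, ])) ==
             as.character(y[held]))
    }))
  }
  # flat unit: both routes at chance
  spf <- simulate_spikes(fix$trials, tuning_spec("fv", 5), fix$design,
                         seed = 94)
  f1 <- epoch_matrix(spf, fix$trials, 1, fix$design)
  f2 <- epoch_matrix(spf, fix$trials, 2, fix$design)
  ours_f <- decode_single_cell(f1, f2, n_repeats = 150, seed = 96)
  expect_lt(abs(ours_f$accuracy_within - 0.125), 0.1)
  expect_lt(abs(svm_within(f1) - 0.125), 0.1)
  # noiseless separable unit: both routes perfect
  set.seed(95)
  pat <- matrix(runif(72, 1, 10), 8, 9)
  rownames(pat) <- trial_types(fix$design, 1)
  sep1 <- synthetic_em(function(epoch, position, subsequence, ...)
    pat[paste(subsequence, position, sep = "_"), ], 1)
  sep2 <- synthetic_em(function(epoch, position, subsequence, ...)
    pat[paste(subsequence, position, sep = "_"), ], 2)
  expect_equal(decode_single_cell(sep1, sep2, n_repeats = 40,
                                  seed = 96)$accuracy_within, 1)
  expect_equal(svm_within(sep1, n_repeats = 40), 1)
  # tuned noisy unit: both routes clearly above chance
  tu <- tuning_spec("sv", 7, epoch_gain = runif(9, 0.3, 3),
                    reward_gain = 2.5, position_gain = c(0.3, 1, 2, 3))
  sp <- simulate_spikes(fix$trials, tu, fix$design, seed = 95)
  e1 <- epoch_matrix(sp, fix$trials, 1, fix$design)
  e2 <- epoch_matrix(sp, fix$trials, 2, fix$design)
  ours <- decode_single_cell(e1, e2, n_repeats = 150, seed = 96)
  expect_gt(ours$accuracy_within, 0.2)
  expect_gt(svm_within(e1), 0.2)
})

test_that("label-shuffled decoding is at chance and scale-invariant", {
  tu <- tuning_spec("n", 6, epoch_gain = runif(9, 0.5, 2))
  sp <- simulate_spikes(fix$trials, tu, fix$design, seed = 90)
  e1 <- epoch_matrix(sp, fix$trials, 1, fix$design)
  e2 <- epoch_matrix(sp, fix$trials, 2, fix$design)
  null <- decode_label_null(e1, e2, n_null = 60, n_repeats = 25, seed = 91)
  se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - 0.125), 3 * se + 0.01)
  # standardization makes the decoder invariant to feature scaling
  e1s <- e1; e1s$values <- e1$values * 7
  e2s <- e2; e2s$values <- e2$values * 7
  d0 <- decode_single_cell(e1, e2, n_repeats = 50, seed = 92)
  ds <- decode_single_cell(e1s, e2s, n_repeats = 50, seed = 92)
  expect_equal(ds$accuracy_within, d0$accuracy_within)
  expect_equal(ds$accuracy_across, d0$accuracy_across)
  null2 <- decode_label_null(e1s, e2s, n_null = 60, n_repeats = 25, seed = 91)
  expect_equal(null2, null)
})

test_that("pseudo-ensembles of noiseless tuned units decode every epoch", {
  pat <- matrix(0, 8, 9)
  rownames(pat) <- trial_types(fix$design, 1)
  mk_unit <- function(u) {
    set.seed(200 + u)
    pat[] <- runif(72, 1, 10)
    fun <- function(epoch, position, subsequence, ...)
      pat[paste(subsequence, position, sep = "_"), ]
    list(m1 = synthetic_em(fun, 1, unit_id = paste0("u", u)),
         m2 = synthetic_em(fun, 2, unit_id = paste0("u", u)))
  }
  units <- lapply(1:10, mk_unit)
  er <- decode_ensemble(lapply(units, `[[`, "m1"), lapply(units, `[[`, "m2"),
                        trials_per_type = 15, n_repeats = 30, seed = 5)
  expect_equal(er$per_epoch$accuracy_within, rep(1, 9))
  expect_equal(er$per_epoch$accuracy_across, rep(1, 9))
  expect_equal(nrow(er$per_epoch), 9L)
  expect_error(decode_ensemble(lapply(units, `[[`, "m1"),
                               lapply(units, `[[`, "m2"),
                               trials_per_type = 40), "not enough trials")
})
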