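test_that("cross-maze correlation matches the direct formula and t test", {
  set.seed(10)
  x <- rnorm(72, 5, 2); y <- 0.6 * x + rnorm(72)
  cc <- cross_maze_cor(x, y)
  # brute-force covariance formula
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc$r, r_hand, tolerance = 1e-12)
  expect_equal(cc$p, cor.test(x, y)$p.value, tolerance = 1e-12)
  expect_equal(cross_maze_cor(x, x)$r, 1)
  expect_equal(cross_maze_cor(x, -x)$r, -1)
  expect_true(cross_maze_cor(rep(2, 72), x)$degenerate)
  expect_error(cross_maze_cor(x, x[1:10]), "length")
})

test_that("units are categorized by the r and p thresholds", {
  p85 <- profiles_with_r(0.85)
  expect_equal(classify_unit(p85$x, p85$y)$category, "schema")
  p60 <- profiles_with_r(0.60)
  expect_equal(classify_unit(p60$x, p60$y)$category, "nonschema")
  p10 <- profiles_with_r(0.10)
  expect_equal(classify_unit(p10$x, p10$y)$category, "noncoding")
  # degenerate (flat) profiles are noncoding
  expect_equal(classify_unit(rep(1, 72), rep(1, 72))$category, "noncoding")
  # just below the schema threshold stays nonschema
  p79 <- profiles_with_r(0.79)
  expect_equal(classify_unit(p79$x, p79$y)$category, "nonschema")
  # invariance to a common positive affine transform
  cls <- classify_unit(3 * p85$x + 10, 0.5 * p85$y + 2)
  expect_equal(cls$r, classify_unit(p85$x, p85$y)$r, tolerance = 1e-12)
})

test_that("the schema fraction is nonincreasing across thresholds", {
  pairs <- lapply(seq(0.05, 0.95, length.out = 15), function(r) {
    pr <- profiles_with_r(r, seed = round(r * 100))
    list(pr$x, pr$y)
  })
  sw <- threshold_sweep(pairs, thresholds = seq(0, 0.95, by = 0.05))
  expect_true(all(diff(sw$fraction_schema) <= 0))
  expect_equal(sw$fraction_schema[sw$threshold == 0.95], 0)
  sw2 <- threshold_sweep(pairs, thresholds = seq(0, 0.95, by = 0.05))
  expect_identical(sw, sw2)
  expect_error(threshold_sweep(pairs, numeric(0)), "empty")
})

test_that("all three shuffles preserve stratum multisets and the grand mean", {
  em <- synthetic_em(function(...) rep(0, 9))
  lab <- em$labels
  set.seed(20)
  for (i in 1:100) {
    m <- matrix(rnorm(nrow(lab) * 9), nrow(lab), 9)
    se <- shuffle_epoch(m)
    # per-trial multisets preserved
    expect_equal(t(apply(se, 1, sort)), t(apply(m, 1, sort)))
    sr <- shuffle_reward(m, lab)
    sp <- shuffle_position(m, lab)
    for (s in list(se, sr, sp)) expect_equal(mean(s), mean(m))
    # reward shuffle: multisets per (epoch, subsequence) stratum preserved
    for (ss in c("a", "b")) {
      rows <- lab$subsequence == ss
      expect_equal(apply(sr[rows, ], 2, sort), apply(m[rows, ], 2, sort))
    }
    # position shuffle: multisets per (epoch, reward category) preserved
    for (rw in c(TRUE, FALSE)) {
      rows <- lab$rewarded == rw
      expect_equal(apply(sp[rows, ], 2, sort), apply(m[rows, ], 2, sort))
    }
  }
})

test_that("shuffles only disturb their own factor's structure", {
  lab <- synthetic_em(function(...) rep(0, 9))$labels
  # a row-constant matrix is unchanged by the epoch shuffle
  m_const <- matrix(rep(rnorm(nrow(lab)), 9), nrow(lab), 9)
  expect_equal(shuffle_epoch(m_const), m_const, ignore_attr = TRUE)
  # reward shuffle: pairs swap whole cells, so a matrix with equal values at
  # paired positions (P1==P3, P2==P4) is unchanged
  vals <- c(P1 = 1, P2 = 2, P3 = 1, P4 = 2)
  m_pos <- matrix(vals[lab$position], nrow(lab), 9)
  expect_equal(shuffle_reward(m_pos, lab), m_pos, ignore_attr = TRUE)
  # position shuffle: a reward-only matrix is unchanged
  m_rew <- matrix(ifelse(lab$rewarded, 4, 1), nrow(lab), 9)
  expect_equal(shuffle_position(m_rew, lab), m_rew, ignore_attr = TRUE)
  # epoch shuffle collapses a purely epoch-tuned unit's profile correlation
  em1 <- synthetic_em(function(epoch, ...) seq(1, 5, length.out = 9),
                      noise_sd = 0.01)
  em2 <- synthetic_em(function(epoch, ...) seq(1, 5, length.out = 9),
                      maze_id = 2, noise_sd = 0.01)
  set.seed(21)
  r_sh <- replicate(50, {
    p1 <- schemacells:::profile_from_matrix(shuffle_epoch(em1), em1$labels$type)
    p2 <- schemacells:::profile_from_matrix(shuffle_epoch(em2), em2$labels$type)
    cor(p1, p2)
  })
  expect_lt(abs(mean(r_sh)), 0.2) # collapsed toward zero
  r_act <- cross_maze_cor(type_profile(em1), type_profile(em2))$r
  expect_gt(r_act, 0.99)
})

test_that("single-factor units receive exactly their factor's flag", {
  cfg <- analysis_config(seed = 33)
  mk_pair <- function(fun) {
    list(m1 = synthetic_em(fun, maze_id = 1), m2 = synthetic_em(fun, maze_id = 2))
  }
  # epoch-only unit
  ep <- mk_pair(function(epoch, ...) c(1, 3, 2, 5, 4, 2, 6, 1, 2))
  at <- attribute_factors(ep$m1, ep$m2, cfg)
  expect_equal(unname(at$flags), c(TRUE, FALSE, FALSE))
  # reward-only unit (constant over epochs and positions within category)
  rw <- mk_pair(function(epoch, rewarded, ...) rep(if (rewarded) 6 else 2, 9))
  at <- attribute_factors(rw$m1, rw$m2, cfg)
  expect_equal(unname(at$flags), c(FALSE, TRUE, FALSE))
  # position-only unit: same pattern in both reward categories (P1=P3, P2=P4)
  vals <- c(P1 = 2, P2 = 6, P3 = 2, P4 = 6)
  po <- mk_pair(function(epoch, position, ...) rep(vals[[position]], 9))
  at <- attribute_factors(po$m1, po$m2, cfg)
  expect_equal(unname(at$flags), c(FALSE, FALSE, TRUE))
  # a fully flat unit has an undefined (degenerate) attribution
  fl <- mk_pair(function(...) rep(3, 9))
  at <- attribute_factors(fl$m1, fl$m2, cfg)
  expect_true(all(is.na(at$flags)))
})

test_that("compiled and reference shuffle engines agree", {
  set.seed(40)
  em1 <- synthetic_em(function(epoch, rewarded, ...)
    seq(2, 6, length.out = 9) * (1 + rewarded), noise_sd = 0.4)
  em2 <- synthetic_em(function(epoch, rewarded, ...)
    seq(2, 6, length.out = 9) * (1 + rewarded), maze_id = 2, noise_sd = 0.4)
  cfg <- analysis_config(n_shuffles = 400, seed = 41)
  a_cpp <- attribute_factors(em1, em2, cfg, engine = "cpp")
  a_r <- attribute_factors(em1, em2, cfg, engine = "r")
  expect_equal(a_cpp$flags, a_r$flags)
  # null distributions from the two engines agree in location and spread
  for (f in colnames(a_cpp$null)) {
    expect_equal(mean(a_cpp$null[, f]), mean(a_r$null[, f]), tolerance = 0.05)
    expect_equal(stats::sd(a_cpp$null[, f]), stats::sd(a_r$null[, f]),
                 tolerance = 0.5)
  }
})

test_that("selectivity ANOVA recovers factors and hand-computed eta squared", {
  # deterministic epoch-only unit: epoch explains everything
  em <- synthetic_em(function(epoch, ...) c(1, 3, 2, 5, 4, 2, 6, 1, 2))
  sel <- suppressWarnings(selectivity_anova(em)) # perfect fit, F unreliable
  expect_gt(sel$eta2[["epoch"]], 0.999)
  # the design is noiseless, so the other factors' shares are numerical dust
  expect_lt(sel$eta2[["reward"]] + sel$eta2[["position"]], 0.01)
  expect_equal(sel$preferred$epoch, "outcome") # argmax at the 7th epoch
  # toy balanced design: partial eta^2 against hand-computed sums of squares
  set.seed(50)
  em2 <- synthetic_em(function(epoch, rewarded, position, ...)
    5 + 2 * rewarded + (position == "P2") + seq(0, 2, length.out = 9),
    noise_sd = 1)
  sel2 <- selectivity_anova(em2)
  long_rate <- as.vector(em2$values)
  epoch_f <- rep(colnames(em2$values), each = nrow(em2$values))
  rew_f <- rep(em2$labels$rewarded, 9)
  pos_f <- rep(em2$labels$position, 9)
  grand <- mean(long_rate)
  ss_epoch <- sum(tapply(long_rate, epoch_f, length) *
                    (tapply(long_rate, epoch_f, mean) - grand)^2)
  ss_rew <- sum(tapply(long_rate, rew_f, length) *
                  (tapply(long_rate, rew_f, mean) - grand)^2)
  cat_mean <- tapply(long_rate, rew_f, mean)
  pos_mean <- tapply(long_rate, pos_f, mean)
  pos_n <- tapply(long_rate, pos_f, length)
  parent <- cat_mean[as.character(c(P1 = FALSE, P2 = FALSE, P3 = TRUE,
                                    P4 = TRUE))]
  ss_pos <- sum(pos_n * (pos_mean - parent)^2)
  fitted <- stats::ave(long_rate, epoch_f) + stats::ave(long_rate, pos_f) - grand
  ss_err <- sum((long_rate - fitted)^2)
  expect_equal(sel2$eta2[["epoch"]], ss_epoch / (ss_epoch + ss_err),
               tolerance = 1e-8)
  expect_equal(sel2$eta2[["reward"]], ss_rew / (ss_rew + ss_err),
               tolerance = 1e-8)
  expect_equal(sel2$eta2[["position"]], ss_pos / (ss_pos + ss_err),
               tolerance = 1e-8)
  expect_true(all(sel2$eta2 >= 0 & sel2$eta2 <= 1))
})
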