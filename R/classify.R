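#' Analysis configuration for unit classification
#'
#' Holds the thresholds of the cross-maze correlation classifier and the
#' structured-shuffle attribution: a unit is a schema cell if its 72-element
#' cross-maze profile correlation exceeds `r_schema` at `p < alpha_corr`,
#' a noncoding cell below `r_noncoding`, and a nonschema cell in between;
#' attribution compares the observed correlation with the
#' `shuffle_percentile`-th percentile of `n_shuffles` structured shuffles.
#'
#' @param r_schema Schema threshold on Pearson r (default 0.8).
#' @param r_noncoding Noncoding threshold (default 0.4).
#' @param alpha_corr Significance level on the correlation (default 0.01).
#' @param n_shuffles Shuffle repetitions per factor (default 1000).
#' @param shuffle_percentile Attribution percentile cut (default 99).
#' @param alpha_anova Significance level of the selectivity ANOVA.
#' @param seed Optional seed controlling the shuffles.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(r_schema = 0.8, r_noncoding = 0.4,
                            alpha_corr = 0.01, n_shuffles = 1000,
                            shuffle_percentile = 99, alpha_anova = 0.01,
                            seed = NULL) {
  if (!(r_noncoding > 0 && r_noncoding < r_schema && r_schema < 1))
    stop("need 0 < r_noncoding < r_schema < 1")
  if (n_shuffles < 100) stop("n_shuffles must be at least 100")
  structure(list(r_schema = r_schema, r_noncoding = r_noncoding,
                 alpha_corr = alpha_corr, n_shuffles = as.integer(n_shuffles),
                 shuffle_percentile = shuffle_percentile,
                 alpha_anova = alpha_anova, seed = seed),
            class = "analysis_config")
}

profile_values <- function(p) {
  if (inherits(p, "trial_type_profile")) p$values else as.numeric(p)
}

#' Cross-maze Pearson correlation of two trial-type profiles
#'
#' @param profile1,profile2 `trial_type_profile`s (or numeric vectors) of
#'   the same unit in the two mazes.
#' @return list with `r`, two-sided `p` from the exact t transform with
#'   n - 2 degrees of freedom, and `degenerate` (TRUE when either profile
#'   has zero variance, in which case r and p are NA).
#' @export
cross_maze_cor <- function(profile1, profile2) {
  x <- profile_values(profile1); y <- profile_values(profile2)
  if (length(x) != length(y)) stop("profiles differ in length")
  n <- length(x)
  if (n < 3) stop("profiles too short for a correlation test")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, degenerate = FALSE)
}

#' Classify one unit as schema, nonschema or noncoding
#'
#' Schema: r > `r_schema` and p < `alpha_corr`. Nonschema:
#' `r_noncoding` <= r <= `r_schema`. Noncoding: r < `r_noncoding`, or a
#' degenerate (zero-variance) profile.
#'
#' @param profile1,profile2 The unit's two per-maze 72-element profiles.
#' @param config An `analysis_config`.
#' @return list with `r`, `p` and `category` (character).
#' @export
classify_unit <- function(profile1, profile2, config = analysis_config()) {
  cc <- cross_maze_cor(profile1, profile2)
  category <-
    if (cc$degenerate) "noncoding"
    else if (cc$r > config$r_schema && cc$p < config$alpha_corr) "schema"
    else if (cc$r >= config$r_noncoding && cc$r <= config$r_schema) "nonschema"
    else "noncoding"
  list(r = cc$r, p = cc$p, category = category)
}

#' Fraction of schema-classified units across correlation thresholds
#'
#' Sweeps the schema threshold on r, keeping the significance requirement,
#' and reports the classified fraction at each value; the curve is
#' monotonically nonincreasing in the threshold.
#'
#' @param profile_pairs list of two-element lists (the per-maze profiles of
#'   each unit).
#' @param thresholds Numeric vector of r thresholds.
#' @param config An `analysis_config` (supplies `alpha_corr`).
#' @return data.frame with `threshold` and `fraction_schema`.
#' @export
threshold_sweep <- function(profile_pairs, thresholds,
                            config = analysis_config()) {
  if (length(thresholds) == 0) stop("empty threshold list")
  if (length(profile_pairs) == 0) stop("no units supplied")
  cc <- lapply(profile_pairs, function(pp) cross_maze_cor(pp[[1]], pp[[2]]))
  r <- vapply(cc, function(z) z$r %||% NA_real_, numeric(1))
  p <- vapply(cc, function(z) z$p %||% NA_real_, numeric(1))
  frac <- vapply(thresholds, function(th)
    mean(!is.na(r) & r > th & p < config$alpha_corr), numeric(1))
  data.frame(threshold = thresholds, fraction_schema = frac)
}

em_values <- function(m) if (inherits(m, "epoch_matrix")) m$values else m

#' Shuffle activity between epochs within each trial
#'
#' Independently permutes the nine epoch values of every row of a
#' trials-by-epochs matrix, destroying any relationship between firing and
#' epoch while leaving the trial (hence reward/position) marginals intact.
#' The per-row value multisets, and therefore the grand mean, are preserved
#' exactly.
#'
#' @param m An `epoch_matrix` or plain trials x 9 matrix.
#' @return Matrix of the same dimensions.
#' @export
shuffle_epoch <- function(m) {
  v <- em_values(m)
  t(apply(v, 1L, sample))
}

# Row pairing for the reward shuffle: each nonrewarded type (P1, P2) is
# paired with the rewarded type of the same subsequence and within-category
# ordinal (P1 <-> P3, P2 <-> P4), trial index matched.
reward_pairs <- function(labels) {
  partner <- c(P1 = "P3", P2 = "P4")
  lo <- which(labels$position %in% c("P1", "P2"))
  key_lo <- paste(labels$subsequence[lo], partner[labels$position[lo]],
                  labels$within_type_index[lo])
  key_all <- paste(labels$subsequence, labels$position,
                   labels$within_type_index)
  hi <- match(key_lo, key_all)
  if (any(is.na(hi)))
    stop("unpaired reward categories: every (subsequence, ordinal, trial) needs both a rewarded and a nonrewarded trial")
  cbind(lo = lo, hi = hi)
}

#' Shuffle activity between reward categories within epoch and subsequence
#'
#' Exchanges values between the rewarded and nonrewarded halves of each
#' subsequence while preserving the epoch, the ordinal position within the
#' reward category (P1 pairs with P3, P2 with P4) and the within-type trial
#' index: each matched cell pair is swapped with probability 1/2,
#' independently per epoch. This destroys any relationship between firing
#' and reward while keeping relationships to epoch and to position within
#' subsequence intact; per-stratum value multisets and the grand mean are
#' preserved exactly.
#'
#' @param m An `epoch_matrix`, or a plain matrix together with `labels`.
#' @param labels data.frame with `subsequence`, `position`,
#'   `within_type_index` per row (taken from `m` when it is an
#'   `epoch_matrix`).
#' @return Matrix of the same dimensions.
#' @export
shuffle_reward <- function(m, labels = NULL) {
  if (inherits(m, "epoch_matrix")) { labels <- m$labels; m <- m$values }
  if (is.null(labels)) stop("labels required for a plain matrix")
  pr <- reward_pairs(labels)
  out <- m
  sw <- matrix(stats::runif(nrow(pr) * ncol(m)) < 0.5, nrow(pr), ncol(m))
  a <- m[pr[, "lo"], , drop = FALSE]
  b <- m[pr[, "hi"], , drop = FALSE]
  out[pr[, "lo"], ] <- ifelse(sw, b, a)
  out[pr[, "hi"], ] <- ifelse(sw, a, b)
  out
}

#' Shuffle activity between positions within reward category and epoch
#'
#' Within each (epoch, reward-category) stratum, uniformly permutes the
#' values across positions (and subsequences), destroying any relationship
#' between firing and position while keeping relationships to epoch and
#' reward intact; per-stratum value multisets and the grand mean are
#' preserved exactly.
#'
#' @inheritParams shuffle_reward
#' @return Matrix of the same dimensions.
#' @export
shuffle_position <- function(m, labels = NULL) {
  if (inherits(m, "epoch_matrix")) { labels <- m$labels; m <- m$values }
  if (is.null(labels)) stop("labels required for a plain matrix")
  rew <- labels$position %in% c("P3", "P4")
  out <- m
  for (cat_rows in list(which(rew), which(!rew))) {
    for (e in seq_len(ncol(m)))
      out[cat_rows, e] <- m[sample(cat_rows), e]
  }
  out
}

# 72-profile from a plain matrix + type labels (means by type, pinned order).
profile_from_matrix <- function(m, types) {
  means <- rowsum(m, types, reorder = FALSE) /
    as.vector(table(factor(types, levels = unique(types))))
  as.vector(t(means))
}

#' Attribute a unit's cross-maze correlation to epoch, reward and position
#'
#' For each factor, both mazes' trial matrices are shuffled `n_shuffles`
#' times with the factor's structured shuffle, profiles rebuilt, and the
#' cross-maze correlation recomputed. A factor is flagged as contributing
#' when the observed correlation strictly exceeds the configured percentile
#' (default the 99th, i.e. the 990th order statistic of 1,000 shuffles) of
#' its null distribution.
#'
#' @param em1,em2 The unit's `epoch_matrix` in maze 1 and maze 2.
#' @param config An `analysis_config`; `config$seed` (or the current RNG
#'   state) determines the shuffles.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); both draw from R's RNG stream.
#' @return list with `r` (observed), `flags` (named logical for epoch,
#'   reward, position; NA when the profiles are degenerate), `cutoffs`
#'   (per-factor percentile of the null) and `null` (matrix of shuffled
#'   correlations, `n_shuffles` x 3).
#' @export
attribute_factors <- function(em1, em2, config = analysis_config(),
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(em1, "epoch_matrix"), inherits(em2, "epoch_matrix"))
  r_obs <- cross_maze_cor(type_profile(em1), type_profile(em2))
  factors <- c("epoch", "reward", "position")
  if (isTRUE(r_obs$degenerate)) {
    flags <- stats::setNames(rep(NA, 3L), factors)
    return(list(r = NA_real_, flags = flags, cutoffs = NULL, null = NULL))
  }
  n <- config$n_shuffles
  run <- function() {
    if (engine == "cpp") {
      type1 <- match(em1$labels$type, unique(em1$labels$type))
      type2 <- match(em2$labels$type, unique(em2$labels$type))
      pr1 <- reward_pairs(em1$labels); pr2 <- reward_pairs(em2$labels)
      rew1 <- em1$labels$position %in% c("P3", "P4")
      rew2 <- em2$labels$position %in% c("P3", "P4")
      cbind(
        epoch = null_r_epoch(em1$values, em2$values, type1, type2, n),
        reward = null_r_reward(em1$values, em2$values, type1, type2,
                               pr1 - 1L, pr2 - 1L, n),
        position = null_r_position(em1$values, em2$values, type1, type2,
                                   which(rew1) - 1L, which(!rew1) - 1L,
                                   which(rew2) - 1L, which(!rew2) - 1L, n)
      )
    } else {
      one <- function(fun) {
        vapply(seq_len(n), function(i) {
          s1 <- fun(em1); s2 <- fun(em2)
          p1 <- profile_from_matrix(s1, em1$labels$type)
          p2 <- profile_from_matrix(s2, em2$labels$type)
          if (stats::sd(p1) == 0 || stats::sd(p2) == 0) return(NA_real_)
          stats::cor(p1, p2)
        }, numeric(1))
      }
      cbind(epoch = one(function(m) shuffle_epoch(m)),
            reward = one(function(m) shuffle_reward(m)),
            position = one(function(m) shuffle_position(m)))
    }
  }
  null <- with_seed(config$seed, run())
  # strictly greater than the k-th order statistic, k = ceiling(q * n)
  k <- ceiling(config$shuffle_percentile / 100 * n)
  cutoffs <- apply(null, 2L, function(v) sort(v, na.last = NA)[min(k, sum(!is.na(v)))])
  # strict inequality with a rounding guard so exact-tie shuffles (a factor
  # the unit does not express at all) can never be flagged
  flags <- r_obs$r > cutoffs + 1e-12
  names(flags) <- factors
  list(r = r_obs$r, flags = flags, cutoffs = cutoffs, null = null)
}

#' Three-way selectivity ANOVA of one unit's epoch rates
#'
#' Tests whether a unit's firing is selective to trial epoch (9 levels),
#' reward (2 levels) or sequence position (P1..P4, pooled over
#' subsequences), on the trial x epoch rates of one maze. Because reward is
#' determined by position in this task (P1/P2 nonrewarded, P3/P4 rewarded),
#' the two factors are aliased in a crossed model; the decomposition here is
#' sequential -- epoch, then reward, then position within reward (2 residual
#' degrees of freedom) -- mirroring how the structured shuffles separate
#' "reward" from "position independent of reward". On the balanced task
#' design the epoch sum of squares is order-invariant.
#'
#' @param em An `epoch_matrix`.
#' @param alpha Significance level for declaring a factor selective and
#'   reporting its preferred level.
#' @return list of class `selectivity_result` with per-factor `p` values,
#'   partial eta-squared `eta2` (SS_factor / (SS_factor + SS_error)), and
#'   `preferred` level (argmax mean rate) for factors significant at
#'   `alpha` (ties broken toward the lowest-index level).
#' @export
selectivity_anova <- function(em, alpha = 0.01) {
  stopifnot(inherits(em, "epoch_matrix"))
  v <- em$values
  long <- data.frame(
    rate = as.vector(v),
    epoch = factor(rep(colnames(v), each = nrow(v)), levels = colnames(v)),
    reward = factor(rep(ifelse(em$labels$rewarded, "rewarded", "nonrewarded"),
                        ncol(v)), levels = c("nonrewarded", "rewarded")),
    position = factor(rep(em$labels$position, ncol(v)),
                      levels = paste0("P", 1:4))
  )
  fit <- stats::lm(rate ~ epoch + reward + position, data = long)
  av <- stats::anova(fit)
  ss <- av[["Sum Sq"]]; names(ss) <- rownames(av)
  ss_err <- ss[["Residuals"]]
  factors <- c("epoch", "reward", "position")
  eta2 <- vapply(factors, function(f) ss[[f]] / (ss[[f]] + ss_err), numeric(1))
  p <- vapply(factors, function(f) av[f, "Pr(>F)"], numeric(1))
  preferred <- lapply(factors, function(f) {
    if (is.na(p[[f]]) || p[[f]] >= alpha) return(NA_character_)
    mu <- tapply(long$rate, long[[f]], mean)
    names(mu)[which.max(mu)] # which.max takes the first maximum on ties
  })
  names(preferred) <- factors
  structure(list(unit_id = em$unit_id, p = p, eta2 = eta2,
                 preferred = preferred, alpha = alpha),
            class = "selectivity_result")
}

#' Classify and characterize every unit of a recorded or simulated session
#'
#' Runs the full single-unit pipeline per unit: per-maze epoch matrices and
#' 72-element profiles, cross-maze correlation classification,
#' structured-shuffle attribution (schema and nonschema cells only, since a
#' noncoding unit's correlation has nothing to attribute; controllable via
#' `attribute_all`), and the selectivity ANOVA with explained variance on
#' the maze-1 matrix.
#'
#' @param spikes Named list of spike-time vectors.
#' @param trials Session trial table.
#' @param design `session_design`.
#' @param config `analysis_config`.
#' @param attribute Run shuffle attribution (slowest stage)?
#' @param attribute_all Attribute noncoding units too?
#' @param smooth Use smoothed rates (see [epoch_rates()]).
#' @param epochs Optional character subset of epochs to restrict the whole
#'   analysis to (e.g. `c("ITIa", "light", "poke", "odor")` for the early,
#'   stimulus-uncontaminated part of the trial); thresholds are unchanged
#'   and profiles shrink to `8 * length(epochs)` elements.
#' @return data.frame, one row per unit: `unit_id`, `r`, `p_r`, `category`,
#'   attribution flags, per-factor eta-squared and ANOVA p values.
#' @export
classify_population <- function(spikes, trials, design = maze_design(),
                                config = analysis_config(), attribute = TRUE,
                                attribute_all = FALSE, smooth = TRUE,
                                epochs = NULL) {
  subset_epochs <- function(em) {
    if (is.null(epochs)) return(em)
    bad <- setdiff(epochs, colnames(em$values))
    if (length(bad) > 0) stop("unknown epoch(s): ", paste(bad, collapse = ", "))
    em$values <- em$values[, epochs, drop = FALSE]
    em
  }
  rows <- lapply(names(spikes), function(id) {
    em1 <- subset_epochs(
      epoch_matrix(spikes[[id]], trials, 1L, design, id, smooth = smooth))
    em2 <- subset_epochs(
      epoch_matrix(spikes[[id]], trials, 2L, design, id, smooth = smooth))
    cls <- classify_unit(type_profile(em1), type_profile(em2), config)
    flags <- c(epoch = NA, reward = NA, position = NA)
    if (attribute && (attribute_all || cls$category != "noncoding")) {
      at <- attribute_factors(em1, em2, config)
      flags <- at$flags
    }
    sel <- selectivity_anova(em1, alpha = config$alpha_anova)
    data.frame(unit_id = id, r = cls$r, p_r = cls$p, category = cls$category,
               epoch_flag = flags[["epoch"]], reward_flag = flags[["reward"]],
               position_flag = flags[["position"]],
               eta2_epoch = sel$eta2[["epoch"]],
               eta2_reward = sel$eta2[["reward"]],
               eta2_position = sel$eta2[["position"]],
               p_epoch = sel$p[["epoch"]], p_reward = sel$p[["reward"]],
               p_position = sel$p[["position"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
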