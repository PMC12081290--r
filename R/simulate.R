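#' Behavioral parameters for session simulation
#'
#' Captures the trial-timing statistics of the task: per-position probability
#' of a correct response, log-normal latencies between successive trial
#' events (strictly positive and right-skewed, like reaction times), the
#' 400-1,500 ms random delay between well entry and reward delivery, and the
#' intertrial interval of 4 s after correct trials and 6 s after errors.
#'
#' Latency parameters are (meanlog, sdlog) of a log-normal increment added on
#' top of the structural minimum spacing (each event window is 500 ms, so
#' e.g. the nose poke can only follow light onset by at least 500 ms here,
#' keeping the nine peri-event windows disjoint except for short reward
#' delays).
#'
#' @param p_correct Probability of a correct response at positions P1..P4.
#' @param poke_latency,unpoke_latency,well_latency Log-normal (meanlog,
#'   sdlog) pairs for the light->poke, odor-end->unpoke and
#'   unpoke->well-entry increments (seconds).
#' @param reward_delay Range (s) of the uniform delay from well entry to
#'   reward delivery.
#' @param iti_correct,iti_error Intertrial intervals (s).
#' @return list of class `behavior_spec`.
#' @export
behavior_spec <- function(p_correct = c(P1 = 0.95, P2 = 0.95, P3 = 0.98, P4 = 0.98),
                          poke_latency = c(log(0.7), 0.5),
                          unpoke_latency = c(log(0.2), 0.5),
                          well_latency = c(log(0.3), 0.5),
                          reward_delay = c(0.4, 1.5),
                          iti_correct = 4,
                          iti_error = 6) {
  if (any(p_correct < 0 | p_correct > 1)) stop("p_correct must lie in [0, 1]")
  if (iti_correct <= 0 || iti_error <= 0) stop("ITI values must be positive")
  if (any(reward_delay <= 0) || diff(reward_delay) < 0)
    stop("reward_delay must be a positive, nondecreasing range")
  structure(list(p_correct = p_correct, poke_latency = poke_latency,
                 unpoke_latency = unpoke_latency, well_latency = well_latency,
                 reward_delay = reward_delay, iti_correct = iti_correct,
                 iti_error = iti_error),
            class = "behavior_spec")
}

#' Generative tuning parameters of one synthetic unit
#'
#' A unit's expected firing rate in epoch e of trial type t (subsequence x
#' position) of maze m is the mixture
#' \deqn{\lambda_m(t, e) = \gamma\,S(t, e) + (1 - \gamma)\,M_m(t, e),}
#' where the shared profile `S` is built multiplicatively from the baseline
#' rate and per-epoch, per-position and reward gains, `M_m` is a
#' maze-specific 8 x 9 profile, and the maze-generalization parameter
#' `gamma` in \[0, 1\] interpolates between a fully generalized unit
#' (`gamma = 1`, identical expected profile in both mazes) and a fully
#' maze-specific one (`gamma = 0`). Spiking is Poisson within epoch windows,
#' optionally with trialwise log-normal rate jitter.
#'
#' @param unit_id Unit identifier.
#' @param baseline_rate Baseline firing rate (Hz), >= 0.
#' @param epoch_gain Nine nonnegative multipliers, one per epoch.
#' @param reward_gain Multiplier applied on rewarded trial types (P3, P4).
#' @param position_gain Four nonnegative multipliers for P1..P4.
#' @param gamma Maze-generalization mixing weight in \[0, 1\].
#' @param maze_profiles Optional named list of 8 x 9 nonnegative matrices
#'   (rows = trial types in pinned order, columns = epochs), one per maze;
#'   required when `gamma < 1`.
#' @param rate_jitter_sd Standard deviation of log-normal multiplicative
#'   rate jitter applied independently per trial (0 = pure Poisson).
#' @return list of class `tuning_spec`.
#' @export
tuning_spec <- function(unit_id, baseline_rate = 5, epoch_gain = rep(1, 9),
                        reward_gain = 1, position_gain = rep(1, 4),
                        gamma = 1, maze_profiles = NULL, rate_jitter_sd = 0) {
  stopifnot(length(epoch_gain) == 9L, length(position_gain) == 4L)
  if (baseline_rate < 0 || reward_gain < 0 || any(epoch_gain < 0) ||
      any(position_gain < 0))
    stop("rates and gains must be nonnegative")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (gamma < 1 && is.null(maze_profiles))
    stop("maze_profiles are required when gamma < 1")
  if (!is.null(maze_profiles)) {
    ok <- vapply(maze_profiles, function(m)
      is.matrix(m) && all(dim(m) == c(8L, 9L)) && all(m >= 0), logical(1))
    if (!all(ok)) stop("each maze profile must be a nonnegative 8 x 9 matrix")
  }
  structure(list(unit_id = unit_id, baseline_rate = baseline_rate,
                 epoch_gain = epoch_gain, reward_gain = reward_gain,
                 position_gain = position_gain, gamma = gamma,
                 maze_profiles = maze_profiles,
                 rate_jitter_sd = rate_jitter_sd),
            class = "tuning_spec")
}

#' Expected 8 x 9 rate profile of a tuning spec in one maze
#'
#' @param tuning A `tuning_spec`.
#' @param maze_id Maze identifier.
#' @param design `session_design` giving the trial-type order.
#' @return 8 x 9 matrix of expected rates (Hz), rows = trial types in pinned
#'   order, columns = epochs.
#' @export
expected_profile <- function(tuning, maze_id, design = maze_design()) {
  tt <- trial_type_table(design, maze_id)
  pos_idx <- as.integer(sub("P", "", tt$position))
  shared <- outer(
    tuning$baseline_rate * tuning$position_gain[pos_idx] *
      ifelse(tt$rewarded, tuning$reward_gain, 1),
    tuning$epoch_gain
  )
  dimnames(shared) <- list(tt$type, EPOCH_NAMES)
  if (tuning$gamma >= 1) return(shared)
  spec <- tuning$maze_profiles[[as.character(maze_id)]]
  dimnames(spec) <- dimnames(shared)
  tuning$gamma * shared + (1 - tuning$gamma) * spec
}

#' Simulate a task session
#'
#' Generates the full trial sequence of a session: alternating 80-trial
#' blocks of the two mazes in one of the two permitted orders (chosen at
#' random), trials within each block cycling deterministically through
#' subsequence a positions P1..P4 then subsequence b P1..P4, responses drawn
#' from the per-position accuracy in `behavior`, and event times drawn from
#' its latency distributions with the 4 s / 6 s intertrial interval rule.
#'
#' @param design A `session_design`.
#' @param behavior A `behavior_spec`.
#' @param seed Integer seed; the session is a pure function of
#'   (design, behavior, seed).
#' @return data.frame of trial records (one row per trial), validated.
#' @export
simulate_session <- function(design = maze_design(), behavior = behavior_spec(),
                             seed = NULL) {
  stopifnot(inherits(design, "session_design"),
            inherits(behavior, "behavior_spec"))
  with_seed(seed, {
    plan <- design$block_plan
    if (stats::runif(1) < 0.5) # maze 2 first is the other permitted order
      plan$maze_id <- c(2L, 1L)[plan$maze_id]
    cycle <- data.frame(subsequence = rep(c("a", "b"), each = 4L),
                        position = rep(paste0("P", 1:4), 2L))
    rows <- do.call(rbind, lapply(seq_len(nrow(plan)), function(b) {
      n <- plan$n_trials[b]
      idx <- ((seq_len(n) - 1L) %% 8L) + 1L
      data.frame(maze_id = plan$maze_id[b], cycle[idx, , drop = FALSE])
    }))
    rownames(rows) <- NULL
    n <- nrow(rows)
    rows$trial_index <- seq_len(n)
    for (m in unique(rows$maze_id)) {
      tt <- trial_type_table(design, m)
      sel <- rows$maze_id == m
      key <- paste(rows$subsequence[sel], rows$position[sel], sep = "_")
      rows$odor_id[sel] <- tt$odor_id[match(key, tt$type)]
      rows$rewarded[sel] <- tt$rewarded[match(key, tt$type)]
    }
    key_all <- paste(rows$maze_id, rows$subsequence, rows$position)
    rows$within_type_index <- stats::ave(rep(1L, n), key_all, FUN = cumsum)

    p_ok <- behavior$p_correct[rows$position]
    is_correct <- stats::runif(n) < p_ok
    # correct = go on rewarded, no-go on nonrewarded
    rows$response <- ifelse(rows$rewarded == is_correct, "go", "nogo")
    rows$correct <- is_correct

    rln <- function(par) stats::rlnorm(n, par[1], par[2])
    light_on <- poke <- odor_on <- unpoke <- well_entry <-
      outcome <- trial_end <- numeric(n)
    t0 <- 10
    poke_lat <- 0.5 + rln(behavior$poke_latency)
    unpoke_lat <- 0.5 + rln(behavior$unpoke_latency)
    well_lat <- 0.5 + rln(behavior$well_latency)
    rew_delay <- stats::runif(n, behavior$reward_delay[1], behavior$reward_delay[2])
    for (i in seq_len(n)) {
      light_on[i] <- t0
      poke[i] <- light_on[i] + poke_lat[i]
      odor_on[i] <- poke[i] + 0.5
      unpoke[i] <- odor_on[i] + unpoke_lat[i]
      if (rows$response[i] == "go") {
        well_entry[i] <- unpoke[i] + well_lat[i]
        if (rows$rewarded[i]) {
          outcome[i] <- well_entry[i] + rew_delay[i]
          trial_end[i] <- outcome[i] + 2
        } else { # erroneous go: lights off at response, no outcome event
          outcome[i] <- NA_real_
          trial_end[i] <- well_entry[i] + 0.5
        }
      } else { # no-go: lights extinguished after the 2 s response window
        well_entry[i] <- NA_real_
        outcome[i] <- NA_real_
        trial_end[i] <- unpoke[i] + 2
      }
      iti <- if (rows$correct[i]) behavior$iti_correct else behavior$iti_error
      t0 <- trial_end[i] + iti
    }
    rows$light_on <- light_on; rows$poke <- poke; rows$odor_on <- odor_on
    rows$unpoke <- unpoke; rows$well_entry <- well_entry
    rows$outcome <- outcome; rows$trial_end <- trial_end
    trials <- rows[TRIAL_COLS]
    validate_trials(trials, design)
    trials
  })
}

#' Simulate the spike train of one tuned unit over a session
#'
#' Within each of the nine peri-event epoch windows of every trial, spikes
#' are drawn as a Poisson count with mean `rate * 500 ms` at the unit's
#' expected rate for that (maze, trial type, epoch), placed uniformly within
#' the window; intervals between epoch windows (and short margins flanking
#' the trial) fire at the baseline rate. Where two windows overlap (possible
#' for the choice/outcome pair under reward delays shorter than 500 ms) the
#' later-starting window owns the overlap.
#'
#' @param trials Trial table from [simulate_session()].
#' @param tuning A `tuning_spec`.
#' @param design `session_design` (for trial-type ordering).
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times (seconds).
#' @export
simulate_spikes <- function(trials, tuning, design = maze_design(), seed = NULL) {
  stopifnot(inherits(tuning, "tuning_spec"))
  with_seed(seed, {
    profiles <- lapply(unique(trials$maze_id), function(m)
      expected_profile(tuning, m, design))
    names(profiles) <- unique(trials$maze_id)
    keys <- trial_types(design, 1L)
    win <- epoch_windows(trials) # n x 9 x 2
    n <- nrow(trials)
    spikes <- vector("list", n)
    for (i in seq_len(n)) {
      key <- paste(trials$subsequence[i], trials$position[i], sep = "_")
      lam <- profiles[[as.character(trials$maze_id[i])]][match(key, keys), ]
      if (tuning$rate_jitter_sd > 0)
        lam <- lam * stats::rlnorm(1, -tuning$rate_jitter_sd^2 / 2,
                                   tuning$rate_jitter_sd)
      starts <- win[i, , 1]; ends <- win[i, , 2]
      ord <- order(starts)
      seg_start <- starts[ord]; seg_end <- ends[ord]; seg_rate <- lam[ord]
      # later-starting window owns any overlap
      seg_end[-length(seg_end)] <- pmin(seg_end[-length(seg_end)],
                                        seg_start[-1L])
      # baseline segments: gaps between windows plus flanking margins
      gap_start <- c(seg_start[1L] - 0.3, seg_end)
      gap_end <- c(seg_start, seg_end[length(seg_end)] + 0.3)
      all_start <- c(seg_start, gap_start)
      all_end <- c(seg_end, gap_end)
      all_rate <- c(seg_rate, rep(tuning$baseline_rate, length(gap_start)))
      len <- pmax(all_end - all_start, 0)
      counts <- stats::rpois(length(len), all_rate * len)
      if (sum(counts) == 0) { spikes[[i]] <- numeric(0); next }
      spikes[[i]] <- stats::runif(sum(counts),
                                  rep(all_start, counts), rep(all_end, counts))
    }
    sort(unlist(spikes, use.names = FALSE))
  })
}

#' Draw a random tuning spec for a population category
#'
#' Schema-like units are strongly tuned with `gamma = 1` (identical expected
#' profiles across mazes), nonschema-like units are strongly tuned with
#' intermediate `gamma`, and noncoding-like units fire at a flat baseline.
#' Multiplicative gains are drawn from gamma distributions with unit mean so
#' that strongly tuned units have profile contrasts large relative to the
#' Poisson noise at the default trial counts.
#'
#' @param unit_id Unit identifier.
#' @param category One of "schema", "nonschema", "noncoding".
#' @param design `session_design`.
#' @param gamma_nonschema Mixing weight for nonschema-like units.
#' @return `tuning_spec`.
#' @export
draw_tuning <- function(unit_id, category = c("schema", "nonschema", "noncoding"),
                        design = maze_design(), gamma_nonschema = 0.5) {
  category <- match.arg(category)
  if (category == "noncoding")
    return(tuning_spec(unit_id, baseline_rate = stats::runif(1, 3, 8)))
  base <- stats::runif(1, 3, 8)
  eg <- stats::rgamma(9, shape = 2, rate = 2)
  pg <- stats::rgamma(4, shape = 2, rate = 2)
  rg <- stats::runif(1, 1.5, 3)
  gamma <- if (category == "schema") 1 else gamma_nonschema
  mp <- NULL
  if (gamma < 1) {
    rand_profile <- function() {
      tt <- trial_type_table(design, 1L)
      pos <- as.integer(sub("P", "", tt$position))
      outer(base * stats::rgamma(4, 2, 2)[pos] *
              ifelse(tt$rewarded, stats::runif(1, 1.5, 3), 1),
            stats::rgamma(9, 2, 2))
    }
    mp <- list("1" = rand_profile(), "2" = rand_profile())
  }
  tuning_spec(unit_id, baseline_rate = base, epoch_gain = eg,
              reward_gain = rg, position_gain = pg, gamma = gamma,
              maze_profiles = mp)
}

#' Simulate a labeled population with known ground truth
#'
#' Generates one session and `n_units` spike trains whose intended category
#' (schema-like, nonschema-like, noncoding-like) is drawn from
#' `category_mix`, returning the ground-truth tuning specs alongside the data
#' so that classifier recovery can be measured.
#'
#' @param design A `session_design`.
#' @param n_units Number of units.
#' @param category_mix Named numeric vector of fractions
#'   (schema, nonschema, noncoding); must sum to 1.
#' @param behavior A `behavior_spec`.
#' @param gamma_nonschema Mixing weight used for nonschema-like units.
#' @param seed Integer seed.
#' @return list with `trials`, `spikes` (named list of spike vectors),
#'   `tuning` (list of `tuning_spec`s) and `category` (intended label per
#'   unit).
#' @export
simulate_population <- function(design = maze_design(), n_units = 50,
                                category_mix = c(schema = 1/3, nonschema = 1/3,
                                                 noncoding = 1/3),
                                behavior = behavior_spec(),
                                gamma_nonschema = 0.5, seed = NULL) {
  if (abs(sum(category_mix) - 1) > 1e-8)
    stop("category_mix fractions must sum to 1")
  if (!all(names(category_mix) %in% c("schema", "nonschema", "noncoding")))
    stop("category_mix names must be schema/nonschema/noncoding")
  with_seed(seed, {
    trials <- simulate_session(design, behavior)
    counts <- floor(category_mix * n_units)
    while (sum(counts) < n_units)
      counts[which.max(category_mix * n_units - counts)] <-
        counts[which.max(category_mix * n_units - counts)] + 1L
    category <- rep(names(counts), counts)
    ids <- sprintf("u%03d", seq_len(n_units))
    tuning <- lapply(seq_len(n_units), function(i)
      draw_tuning(ids[i], category[i], design, gamma_nonschema))
    spikes <- lapply(tuning, function(tu) simulate_spikes(trials, tu, design))
    names(spikes) <- ids
    names(category) <- ids
    list(trials = trials, spikes = spikes, tuning = tuning,
         category = category)
  })
}

#' Write ground-truth tuning specs as structured text
#'
#' @param tuning list of `tuning_spec`s.
#' @param path Output JSON path.
#' @export
write_tuning <- function(tuning, path) {
  jsonlite::write_json(lapply(tuning, unclass), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
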