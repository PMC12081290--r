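#' Canonical dual figure-of-eight odor-sequence task design
#'
#' Builds the session design for the two-maze odor-sequence task: ten odors
#' arranged into two virtual figure-of-eight mazes, each composed of two
#' four-position subsequences (a, b). Within every subsequence the first two
#' positions (P1, P2) are nonrewarded and the last two (P3, P4) rewarded, and
#' one rewarded odor repeats within subsequence a (e.g. maze 1, subsequence a
#' runs odors 0-, 1-, 2+, 2+). A session consists of alternating 80-trial
#' blocks of the two mazes; at the default 20 trials per trial type this is
#' 4 blocks and 320 trials.
#'
#' @param trials_per_type Number of trials of each of the 8 trial types per
#'   maze. Must make the per-maze trial count a multiple of the 80-trial
#'   block size (i.e. a multiple of 10).
#' @return An object of class `session_design`: a list with elements
#'   `mazes` (per maze, per subsequence, a data.frame of `odor_id` and
#'   `rewarded`), `block_plan` (data.frame of `maze_id`, `n_trials`; the
#'   realized maze order of the two permitted alternations is chosen at
#'   simulation time), `trials_per_type`, and `n_trials`.
#' @examples
#' d <- maze_design()
#' trial_types(d, 1)
#' @export
maze_design <- function(trials_per_type = 20) {
  if (trials_per_type < 1 || trials_per_type %% 10 != 0)
    stop("`trials_per_type` must be a positive multiple of 10 so that sessions divide into 80-trial blocks")
  subseq <- function(odors) data.frame(
    position = paste0("P", 1:4),
    odor_id  = odors,
    rewarded = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  mazes <- list(
    "1" = list(a = subseq(c(0L, 1L, 2L, 2L)), b = subseq(c(0L, 1L, 3L, 4L))),
    "2" = list(a = subseq(c(5L, 6L, 7L, 7L)), b = subseq(c(5L, 6L, 8L, 9L)))
  )
  n_per_maze <- 8L * trials_per_type
  n_blocks_per_maze <- n_per_maze %/% 80L
  block_plan <- data.frame(
    maze_id  = rep(c(1L, 2L), times = n_blocks_per_maze),
    n_trials = 80L
  )
  structure(
    list(
      mazes = mazes,
      block_plan = block_plan,
      trials_per_type = as.integer(trials_per_type),
      n_trials = 2L * n_per_maze
    ),
    class = "session_design"
  )
}

#' @export
print.session_design <- function(x, ...) {
  cat("Dual figure-of-eight session design\n")
  cat(sprintf("  %d mazes x 8 trial types x %d trials/type = %d trials\n",
              length(x$mazes), x$trials_per_type, x$n_trials))
  for (m in names(x$mazes)) {
    for (s in names(x$mazes[[m]])) {
      ss <- x$mazes[[m]][[s]]
      cat(sprintf("  maze %s, subsequence %s: %s\n", m, s,
                  paste0(ss$odor_id, ifelse(ss$rewarded, "+", "-"), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Enumerate the 8 trial types of one maze in the pinned order
#'
#' The ordering (subsequence a P1..P4, then subsequence b P1..P4) is fixed
#' and used everywhere downstream, in particular for the 72-element
#' trial-type-by-epoch profiles; cross-maze correlations are invariant to the
#' choice as long as both mazes use the same order.
#'
#' @param design A `session_design`.
#' @param maze_id Maze identifier (1 or 2).
#' @return Character vector of 8 trial-type keys, e.g. `"a_P1"`.
#' @export
trial_types <- function(design, maze_id) {
  stopifnot(inherits(design, "session_design"))
  if (!as.character(maze_id) %in% names(design$mazes))
    stop("unknown maze_id: ", maze_id)
  as.vector(t(outer(c("a", "b"), paste0("P", 1:4), paste, sep = "_")))
}

#' Trial-type lookup table for one maze
#'
#' @inheritParams trial_types
#' @return data.frame with one row per trial type in pinned order:
#'   `type`, `subsequence`, `position`, `odor_id`, `rewarded`.
#' @export
trial_type_table <- function(design, maze_id) {
  keys <- trial_types(design, maze_id)
  maze <- design$mazes[[as.character(maze_id)]]
  out <- do.call(rbind, lapply(c("a", "b"), function(s) {
    ss <- maze[[s]]
    data.frame(type = paste(s, ss$position, sep = "_"), subsequence = s,
               position = ss$position, odor_id = ss$odor_id,
               rewarded = ss$rewarded, stringsAsFactors = FALSE)
  }))
  out[match(keys, out$type), , drop = FALSE]
}

# Event columns of a trial table, in their within-trial temporal order.
EVENT_COLS <- c("light_on", "poke", "odor_on", "unpoke", "well_entry",
                "outcome", "trial_end")

TRIAL_COLS <- c("trial_index", "maze_id", "subsequence", "position",
                "odor_id", "rewarded", "response", "correct",
                EVENT_COLS, "within_type_index")

#' Validate a trial table against the session design
#'
#' Checks that event times present on each trial are strictly increasing in
#' the canonical order (light_on, poke, odor_on, unpoke, well_entry, outcome,
#' trial_end), that the rewarded flag matches the design for each
#' (maze, subsequence, position), and that `within_type_index` lies in
#' `[1, trials_per_type]`. Violations raise an error naming the offending
#' rows.
#'
#' @param trials data.frame of trial records.
#' @param design Optional `session_design` to check reward structure against.
#' @return `trials`, invisibly, if valid.
#' @export
validate_trials <- function(trials, design = NULL) {
  missing_cols <- setdiff(TRIAL_COLS, names(trials))
  if (length(missing_cols) > 0)
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  ev <- as.matrix(trials[EVENT_COLS])
  bad <- which(apply(ev, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 1L && any(diff(r) <= 0)
  }))
  if (length(bad) > 0)
    stop("event times out of order on trial row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (!is.null(design)) {
    for (m in unique(trials$maze_id)) {
      tt <- trial_type_table(design, m)
      sel <- trials$maze_id == m
      key <- paste(trials$subsequence[sel], trials$position[sel], sep = "_")
      expect_rew <- tt$rewarded[match(key, tt$type)]
      mism <- which(expect_rew != trials$rewarded[sel])
      if (length(mism) > 0)
        stop("rewarded flag inconsistent with design on trial row(s): ",
             paste(utils::head(which(sel)[mism], 10L), collapse = ", "))
    }
    wti <- trials$within_type_index
    if (any(wti < 1L | wti > design$trials_per_type))
      stop("within_type_index outside [1, trials_per_type]")
  }
  invisible(trials)
}

#' Read a session from columnar text files
#'
#' The trials file is a CSV with one row per trial (columns `trial_index`,
#' `maze_id`, `subsequence`, `position`, `odor_id`, `rewarded`, `response`,
#' `correct`, the seven event-time columns, `within_type_index`); an empty
#' event cell marks an absent event (e.g. no well entry on a no-go trial).
#' The spikes file is a CSV with columns `unit_id`, `timestamp` (seconds).
#'
#' @param trials_path,spikes_path Paths to the two CSV files.
#' @param design Optional `session_design` for validation.
#' @return list with `trials` (validated data.frame) and `spikes` (named list
#'   of sorted numeric timestamp vectors, one per unit).
#' @export
read_session <- function(trials_path, spikes_path, design = NULL) {
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLS, names(trials))
  if (length(missing_cols) > 0)
    stop("malformed trials file, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in EVENT_COLS) trials[[col]] <- as.numeric(trials[[col]])
  validate_trials(trials, design)
  sp <- utils::read.csv(spikes_path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "timestamp") %in% names(sp)))
    stop("malformed spikes file: need columns unit_id, timestamp")
  if (any(is.na(sp$timestamp)) || any(sp$timestamp < 0))
    stop("spike timestamps must be nonnegative numbers")
  spikes <- lapply(split(sp$timestamp, sp$unit_id), sort)
  list(trials = trials, spikes = spikes)
}

#' Write a session to columnar text files
#'
#' Inverse of [read_session()]; the round trip is lossless.
#'
#' @param trials data.frame of trial records.
#' @param spikes Named list of numeric spike-timestamp vectors.
#' @param trials_path,spikes_path Output CSV paths.
#' @export
write_session <- function(trials, spikes, trials_path, spikes_path) {
  utils::write.csv(trials[TRIAL_COLS], trials_path, row.names = FALSE, na = "")
  sp <- data.frame(
    unit_id = rep(names(spikes), lengths(spikes)),
    timestamp = unlist(spikes, use.names = FALSE)
  )
  utils::write.csv(sp, spikes_path, row.names = FALSE)
  invisible(list(trials = trials_path, spikes = spikes_path))
}
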