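# The nine peri-event epochs, in within-trial order.
EPOCH_NAMES <- c("ITIa", "light", "poke", "odor", "unpoke", "choice",
                 "outcome", "postout", "ITIb")

#' Peri-event epoch definitions
#'
#' Each trial is divided into nine 500-ms epochs anchored to trial events:
#' ITIa covers the 500 ms before light onset; light, poke, odor, unpoke,
#' choice and outcome cover the 500 ms from the corresponding event; postout
#' and ITIb cover the two consecutive 500-ms windows after the end of the
#' outcome period. On no-go trials, where well entry is absent, the choice
#' epoch anchors to trial termination and the outcome epoch to 500 ms after
#' trial termination.
#'
#' @return data.frame with columns `name`, `anchor`, `offset` (s),
#'   `duration` (s) and `fallback` anchor used when the event is absent.
#' @export
epoch_definitions <- function() {
  data.frame(
    name = EPOCH_NAMES,
    anchor = c("light_on", "light_on", "poke", "odor_on", "unpoke",
               "well_entry", "outcome", "outcome", "outcome"),
    offset = c(-0.5, 0, 0, 0, 0, 0, 0, 0.5, 1.0),
    duration = 0.5,
    fallback = c(NA, NA, NA, NA, NA, "trial_end", "trial_end_500",
                 "trial_end_500", "trial_end_500"),
    stringsAsFactors = FALSE
  )
}

# Epoch windows for every trial: n x 9 x 2 array of [start, end) in seconds.
# The outcome anchor falls back to 500 ms after trial termination, so on
# no-go trials choice/outcome/postout/ITIb tile the 2 s after termination.
epoch_windows <- function(trials) {
  n <- nrow(trials)
  choice_anchor <- ifelse(is.na(trials$well_entry), trials$trial_end,
                          trials$well_entry)
  outcome_anchor <- ifelse(is.na(trials$outcome), trials$trial_end + 0.5,
                           trials$outcome)
  if (any(is.na(choice_anchor)) || any(is.na(outcome_anchor)))
    stop("trial(s) lack both anchor and fallback for choice/outcome epochs")
  starts <- cbind(
    ITIa = trials$light_on - 0.5,
    light = trials$light_on,
    poke = trials$poke,
    odor = trials$odor_on,
    unpoke = trials$unpoke,
    choice = choice_anchor,
    outcome = outcome_anchor,
    postout = outcome_anchor + 0.5,
    ITIb = outcome_anchor + 1.0
  )
  if (any(is.na(starts))) {
    bad <- which(apply(is.na(starts), 1L, any))
    stop("missing epoch anchor(s) on trial row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  out <- array(NA_real_, c(n, 9L, 2L),
               dimnames = list(NULL, EPOCH_NAMES, c("start", "end")))
  out[, , 1L] <- starts
  out[, , 2L] <- starts + 0.5
  out
}

#' Smoothed, binned firing-rate trace over a time window
#'
#' Counts spikes in fixed-width bins and smooths with a Gaussian kernel.
#' Kernel mass falling outside the analysis window is handled by truncation
#' with renormalization: each spike contributes total mass 1 within the
#' window, so the trace integrates to the raw spike count.
#'
#' @param spikes Numeric vector of spike times (s).
#' @param window Length-2 numeric, the analysis window `[t0, t1)`.
#' @param bin_ms Bin width in ms (default 100).
#' @param kernel_sd_ms Gaussian kernel s.d. in ms (default 50).
#' @return data.frame with bin `time` (center, s) and `rate` (Hz).
#' @export
smooth_binned_rate <- function(spikes, window, bin_ms = 100, kernel_sd_ms = 50) {
  if (bin_ms <= 0 || kernel_sd_ms <= 0)
    stop("bin and kernel widths must be positive")
  stopifnot(length(window) == 2L, window[2] > window[1])
  bw <- bin_ms / 1000; sd <- kernel_sd_ms / 1000
  edges <- seq(window[1], window[2], by = bw)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  widths <- diff(edges)
  sp <- spikes[spikes >= window[1] & spikes < window[2]]
  if (length(sp) == 0)
    return(data.frame(time = centers, rate = 0))
  # per-spike kernel mass in each bin, renormalized to the window
  upper <- stats::pnorm(outer(edges[-1], sp, "-") / sd)
  lower <- stats::pnorm(outer(edges[-length(edges)], sp, "-") / sd)
  mass <- upper - lower
  tot <- stats::pnorm((window[2] - sp) / sd) - stats::pnorm((window[1] - sp) / sd)
  mass <- sweep(mass, 2L, tot, "/")
  data.frame(time = centers, rate = rowSums(mass) / widths)
}

# Smoothed spike mass inside arbitrary windows (no renormalization: mass can
# leak across window edges symmetrically, as the per-trial smoothing does).
# starts/ends are parallel vectors; spikes must be sorted.
window_mass <- function(spikes, starts, ends, kernel_sd = 0.05) {
  nw <- length(starts)
  if (length(spikes) == 0) return(numeric(nw))
  pad <- 5 * kernel_sd
  lo <- findInterval(starts - pad, spikes)
  hi <- findInterval(ends + pad, spikes)
  k <- hi - lo
  if (sum(k) == 0) return(numeric(nw))
  widx <- rep.int(seq_len(nw), k)
  sidx <- sequence(k, from = lo + 1L)
  contrib <- stats::pnorm((ends[widx] - spikes[sidx]) / kernel_sd) -
    stats::pnorm((starts[widx] - spikes[sidx]) / kernel_sd)
  out <- numeric(nw)
  agg <- rowsum(contrib, widx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

window_counts <- function(spikes, starts, ends) {
  if (length(spikes) == 0) return(numeric(length(starts)))
  # half-open windows [start, end)
  findInterval(ends, spikes, left.open = TRUE) -
    findInterval(starts, spikes, left.open = TRUE)
}

#' Firing rate of one unit in the nine epochs of one trial
#'
#' @param spikes Sorted numeric spike times (s).
#' @param trial One-row data.frame of a trial record.
#' @param smooth If TRUE (default), rates are Gaussian-smoothed spike mass in
#'   the window divided by the 500-ms duration; if FALSE, raw counts divided
#'   by duration.
#' @param kernel_sd Gaussian kernel s.d. in seconds (default 0.05).
#' @return Named numeric vector of nine rates (Hz).
#' @export
epoch_rates <- function(spikes, trial, smooth = TRUE, kernel_sd = 0.05) {
  win <- epoch_windows(trial)
  starts <- win[1L, , 1L]; ends <- win[1L, , 2L]
  mass <- if (smooth) window_mass(sort(spikes), starts, ends, kernel_sd)
          else window_counts(sort(spikes), starts, ends)
  stats::setNames(mass / 0.5, EPOCH_NAMES)
}

#' Trials-by-epochs firing-rate matrix for one unit in one maze
#'
#' Builds the per-maze rate matrix used throughout the analysis: one row per
#' completed trial of the given maze, grouped by trial type in the pinned
#' order (subsequence a P1..P4, then b P1..P4) and, within type, by
#' within-type trial index; one column per epoch. A full default session
#' yields a 160 x 9 matrix (8 trial types x 20 trials).
#'
#' @param spikes Sorted numeric spike times of the unit.
#' @param trials Session trial table.
#' @param maze_id Which maze to extract.
#' @param design `session_design` used for the trial-type order.
#' @param unit_id Identifier stored with the matrix.
#' @param smooth,kernel_sd Passed to the rate computation, see
#'   [epoch_rates()].
#' @return Object of class `epoch_matrix`: list with `unit_id`, `maze_id`,
#'   `values` (trials x 9 matrix, Hz), and `labels` (data.frame of `type`,
#'   `subsequence`, `position`, `rewarded`, `within_type_index` per row).
#' @export
epoch_matrix <- function(spikes, trials, maze_id, design = maze_design(),
                         unit_id = "unit", smooth = TRUE, kernel_sd = 0.05) {
  sel <- trials$maze_id == maze_id & !is.na(trials$poke)
  tr <- trials[sel, , drop = FALSE]
  if (nrow(tr) == 0) stop("no completed trials for maze ", maze_id)
  keys <- trial_types(design, maze_id)
  key <- paste(tr$subsequence, tr$position, sep = "_")
  missing_types <- setdiff(keys, key)
  if (length(missing_types) > 0)
    stop("missing trial type(s) in maze ", maze_id, ": ",
         paste(missing_types, collapse = ", "))
  ord <- order(match(key, keys), tr$within_type_index)
  tr <- tr[ord, , drop = FALSE]
  key <- key[ord]
  win <- epoch_windows(tr)
  starts <- as.vector(win[, , 1L]); ends <- as.vector(win[, , 2L])
  spikes <- sort(spikes)
  mass <- if (smooth) window_mass(spikes, starts, ends, kernel_sd)
          else window_counts(spikes, starts, ends)
  values <- matrix(mass / 0.5, nrow = nrow(tr), ncol = 9L,
                   dimnames = list(NULL, EPOCH_NAMES))
  tt <- trial_type_table(design, maze_id)
  labels <- data.frame(
    type = key,
    subsequence = tr$subsequence,
    position = tr$position,
    rewarded = tt$rewarded[match(key, tt$type)],
    within_type_index = tr$within_type_index,
    stringsAsFactors = FALSE
  )
  structure(list(unit_id = unit_id, maze_id = maze_id, values = values,
                 labels = labels),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("epoch_matrix: unit %s, maze %s, %d trials x %d epochs\n",
              x$unit_id, x$maze_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Subsample an epoch matrix to a fixed number of trials per type
#'
#' Used by the ensemble decoder, which works on 15 randomly selected trials
#' per trial type (a 120 x 9 matrix per maze).
#'
#' @param em An `epoch_matrix`.
#' @param trials_per_type Trials retained per type.
#' @param indices Optional explicit within-type indices (shared across units
#'   so pseudo-ensemble trials stay aligned); sampled at random when NULL.
#' @return A reduced `epoch_matrix`.
#' @export
subsample_trials <- function(em, trials_per_type = 15, indices = NULL) {
  stopifnot(inherits(em, "epoch_matrix"))
  keep <- logical(nrow(em$values))
  for (ty in unique(em$labels$type)) {
    rows <- which(em$labels$type == ty)
    avail <- em$labels$within_type_index[rows]
    idx <- if (is.null(indices)) sample(avail, trials_per_type)
           else indices
    if (!all(idx %in% avail))
      stop("requested within-type indices absent for type ", ty)
    keep[rows[avail %in% idx]] <- TRUE
  }
  em$values <- em$values[keep, , drop = FALSE]
  em$labels <- em$labels[keep, , drop = FALSE]
  rownames(em$labels) <- NULL
  em
}

#' Mean trial-type-by-epoch profile of one unit in one maze
#'
#' Averages the epoch rate matrix within each of the 8 trial types, yielding
#' the 72-element profile (trial-type-major, epoch-minor in the pinned
#' order) whose cross-maze Pearson correlation defines schema cells.
#'
#' @param em An `epoch_matrix`.
#' @return Object of class `trial_type_profile`: list with `unit_id`,
#'   `maze_id` and `values`, a named numeric vector of length 72.
#' @export
type_profile <- function(em) {
  stopifnot(inherits(em, "epoch_matrix"))
  types <- unique(em$labels$type)
  if (length(types) != 8L)
    stop("profile requires all 8 trial types; found ", length(types))
  means <- rowsum(em$values, em$labels$type, reorder = FALSE) /
    as.vector(table(factor(em$labels$type, levels = unique(em$labels$type))))
  values <- as.vector(t(means))
  names(values) <- as.vector(t(outer(rownames(means), colnames(em$values),
                                     paste, sep = ".")))
  structure(list(unit_id = em$unit_id, maze_id = em$maze_id, values = values),
            class = "trial_type_profile")
}

#' Write epoch matrices or profiles to labeled CSV
#'
#' @param x An `epoch_matrix` or `trial_type_profile`.
#' @param path Output path.
#' @export
write_rates <- function(x, path) {
  if (inherits(x, "epoch_matrix")) {
    out <- cbind(unit_id = x$unit_id, maze_id = x$maze_id, x$labels,
                 as.data.frame(x$values))
  } else if (inherits(x, "trial_type_profile")) {
    parts <- strsplit(names(x$values), ".", fixed = TRUE)
    out <- data.frame(unit_id = x$unit_id, maze_id = x$maze_id,
                      type = vapply(parts, `[`, "", 1L),
                      epoch = vapply(parts, `[`, "", 2L),
                      rate = unname(x$values))
  } else stop("unsupported object")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
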