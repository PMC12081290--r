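#' Embed population responses into a shared 3-D space
#'
#' Points (trial or condition responses, one per column of `x`) living in
#' the N-unit state space are projected to `n_components` dimensions with
#' either PCA (linear) or Isomap (nonlinear, geodesic-preserving,
#' `n_neighbors` nearest neighbors -- 19 by default, one less than the 20
#' repetitions of each condition). Both mazes' points are embedded jointly
#' into the same subspace and returned separately, ready for Procrustes
#' comparison.
#'
#' @param x Numeric matrix, units x points (columns are per-maze condition
#'   or trial responses, e.g. 8 types x 9 epochs per maze).
#' @param maze_labels Vector of maze ids, one per column of `x`.
#' @param method "linear" (PCA) or "nonlinear" (Isomap).
#' @param n_components Embedding dimension (default 3).
#' @param n_neighbors Isomap neighborhood size (default 19).
#' @return Named list of point matrices (points x `n_components`), one per
#'   maze.
#' @export
embed_population <- function(x, maze_labels, method = c("linear", "nonlinear"),
                             n_components = 3, n_neighbors = 19) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), length(maze_labels) == ncol(x))
  pts <- t(x)
  if (nrow(pts) <= n_components)
    stop("need more points than embedding dimensions")
  if (method == "linear") {
    pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
    emb <- pc$x[, seq_len(n_components), drop = FALSE]
  } else {
    k <- min(n_neighbors, nrow(pts) - 1L)
    iso <- tryCatch(
      vegan::isomap(stats::dist(pts), ndim = n_components, k = k),
      error = function(e)
        stop("isomap embedding failed (disconnected neighbor graph?): ",
             conditionMessage(e))
    )
    emb <- iso$points[, seq_len(n_components), drop = FALSE]
  }
  split.data.frame(emb, maze_labels)
}

#' Procrustes dissimilarity between two corresponded point sets
#'
#' Residual sum of squared distances between corresponding points after the
#' optimal translation, uniform scaling and rotation of one configuration
#' onto the other. Both configurations are centered and scaled to unit
#' total scatter before alignment (symmetric Procrustes), so the statistic
#' is symmetric in its arguments, zero exactly on the
#' similarity-transform orbit, and comparable across populations. Smaller
#' values mean more similar geometries.
#'
#' @param points1,points2 Point matrices with equal dimensions; rows
#'   correspond.
#' @return Nonnegative scalar dissimilarity.
#' @export
procrustes_dissimilarity <- function(points1, points2) {
  points1 <- as.matrix(points1); points2 <- as.matrix(points2)
  if (!all(dim(points1) == dim(points2)))
    stop("point sets must have equal dimensions with row correspondence")
  scatter <- function(p) sum(scale(p, scale = FALSE)^2)
  if (scatter(points1) == 0 || scatter(points2) == 0)
    stop("degenerate (all-coincident) point set")
  max(vegan::procrustes(points1, points2, symmetric = TRUE)$ss, 0)
}

#' Canonical-variable clustering of trials with silhouette evaluation
#'
#' Reduces a trials-by-features matrix to its first `n_pcs` principal
#' component scores, extracts canonical discriminant variables for the
#' given trial labels (the axes a MANOVA on the PC scores separates groups
#' along), and scores the clustering by per-trial silhouette widths on the
#' first two canonical dimensions.
#'
#' @param x Numeric matrix, trials x features (e.g. K trials x (units *
#'   epochs)).
#' @param labels Grouping labels, one per trial (e.g. maze x position).
#' @param n_pcs Number of principal components fed to the discriminant
#'   analysis (default 30).
#' @return list with `silhouette` (per-trial widths), `mean_by_type` (named
#'   mean silhouette per label), `scores` (trials x 2 canonical scores).
#' @export
lda_cluster_silhouette <- function(x, labels, n_pcs = 30) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two distinct labels")
  if (nrow(x) <= n_pcs)
    stop("need more trials than principal components (", n_pcs, ")")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > max(pc$sdev) * 1e-8)
  scores <- pc$x[, utils::head(keep, n_pcs), drop = FALSE]
  fit <- MASS::lda(scores, grouping = labels)
  cv <- stats::predict(fit)$x
  cv <- cv[, seq_len(min(2L, ncol(cv))), drop = FALSE]
  sil <- cluster::silhouette(as.integer(labels), stats::dist(cv))
  widths <- sil[, "sil_width"]
  mean_by_type <- tapply(widths, labels, mean)
  list(silhouette = widths, mean_by_type = mean_by_type, scores = cv)
}

#' Assemble a units x epochs x trials population tensor
#'
#' @param ems list of per-unit `epoch_matrix` objects built from the same
#'   trials (identical label rows).
#' @return list of class `population_tensor`: `values` (N x 9 x K
#'   nonnegative array) and `labels` (per-trial data.frame with maze and
#'   type).
#' @export
population_tensor <- function(ems) {
  stopifnot(length(ems) >= 1L)
  lab <- ems[[1]]$labels
  for (em in ems)
    if (!identical(em$labels$type, lab$type) ||
        !identical(em$labels$within_type_index, lab$within_type_index))
      stop("all units must share the same trial rows")
  vals <- vapply(ems, function(em) t(em$values),
                 matrix(0, ncol(ems[[1]]$values), nrow(ems[[1]]$values)))
  # vapply gives epochs x trials x units; reorder to units x epochs x trials
  vals <- aperm(vals, c(3L, 1L, 2L))
  dimnames(vals) <- list(vapply(ems, `[[`, "", "unit_id"),
                         colnames(ems[[1]]$values), NULL)
  structure(list(values = vals,
                 labels = data.frame(maze_id = rep(ems[[1]]$maze_id, nrow(lab)),
                                     lab[c("type", "within_type_index")])),
            class = "population_tensor")
}

# Khatri-Rao (columnwise Kronecker) product.
khatri_rao <- function(a, b) {
  out <- matrix(0, nrow(a) * nrow(b), ncol(a))
  for (r in seq_len(ncol(a))) out[, r] <- kronecker(a[, r], b[, r])
  out
}

# mode-n unfolding of a 3-way array
unfold <- function(x, mode) {
  d <- dim(x)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  matrix(aperm(x, perm), d[mode])
}

#' Non-negative canonical polyadic (tensor component) decomposition
#'
#' Fits a rank-`rank` non-negative CP model to a units x epochs x trials
#' tensor by multiplicative-update alternating optimization, returning the
#' best of `n_restarts` random restarts (the nonconvex objective needs
#' restarts for the error-vs-rank nesting property to hold in practice).
#' Each component is a triple of nonnegative unit, epoch and trial factors
#' whose outer products sum to the reconstruction.
#'
#' @param tensor A `population_tensor` or nonnegative 3-way array.
#' @param rank Number of components (6 and 8 are the sizes used for
#'   across-trial learning dynamics).
#' @param n_restarts Random restarts (default 10).
#' @param n_iter Maximum update sweeps per restart.
#' @param tol Relative-error improvement tolerance for early stopping.
#' @param seed Integer seed.
#' @return list of class `tca_fit`: `factors` (list `unit`, `epoch`,
#'   `trial`, columns normalized so unit and epoch factors have unit
#'   Euclidean norm), `error` (relative reconstruction error
#'   ||X - Xhat||_F / ||X||_F), `rank`, `restart_errors`.
#' @export
tca_decompose <- function(tensor, rank, n_restarts = 10, n_iter = 250,
                          tol = 1e-7, seed = NULL) {
  x <- if (inherits(tensor, "population_tensor")) tensor$values else tensor
  stopifnot(length(dim(x)) == 3L)
  if (any(x < 0)) stop("tensor must be nonnegative")
  d <- dim(x)
  if (rank >= min(d))
    warning("rank >= smallest tensor dimension; components may be redundant")
  xn <- sqrt(sum(x^2))
  if (xn == 0) stop("all-zero tensor")
  xu <- lapply(1:3, function(m) unfold(x, m))
  eps <- 1e-12
  fit_one <- function() {
    f <- lapply(d, function(n) matrix(stats::runif(n * rank, 0.1, 1), n, rank))
    err_prev <- Inf
    for (it in seq_len(n_iter)) {
      for (m in 1:3) {
        others <- setdiff(3:1, m)
        # unfolding pairs mode m against (last mode, ..., first mode)
        kr <- khatri_rao(f[[others[1]]], f[[others[2]]])
        gram <- (crossprod(f[[others[1]]]) * crossprod(f[[others[2]]]))
        num <- xu[[m]] %*% kr
        den <- f[[m]] %*% gram + eps
        f[[m]] <- f[[m]] * num / den
      }
      if (it %% 10L == 0L || it == n_iter) {
        rec <- f[[1]] %*% t(khatri_rao(f[[3]], f[[2]]))
        err <- sqrt(max(sum(xu[[1]]^2) - 2 * sum(xu[[1]] * rec) + sum(rec^2),
                        0)) / xn
        if (err_prev - err < tol) { err_prev <- err; break }
        err_prev <- err
      }
    }
    list(f = f, err = err_prev)
  }
  with_seed(seed, {
    fits <- lapply(seq_len(n_restarts), function(i) fit_one())
    errs <- vapply(fits, `[[`, numeric(1), "err")
    best <- fits[[which.min(errs)]]
    f <- best$f
    # push scale into the trial factors
    for (m in 1:2) {
      nrm <- sqrt(colSums(f[[m]]^2))
      nrm[nrm == 0] <- 1
      f[[m]] <- sweep(f[[m]], 2L, nrm, "/")
      f[[3]] <- sweep(f[[3]], 2L, nrm, "*")
    }
    structure(list(factors = list(unit = f[[1]], epoch = f[[2]],
                                  trial = f[[3]]),
                   error = min(errs), rank = rank, restart_errors = errs),
              class = "tca_fit")
  })
}

#' @export
print.tca_fit <- function(x, ...) {
  cat(sprintf("tca_fit: rank %d, relative error %.4f (best of %d restarts)\n",
              x$rank, x$error, length(x$restart_errors)))
  invisible(x)
}
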