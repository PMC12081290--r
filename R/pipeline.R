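#' Run the full schema-cell analysis pipeline from a config file
#'
#' Orchestrates simulate -> rates -> classify -> decode -> geometry ->
#' report. The configuration is a YAML (or JSON) file with optional
#' sections `simulate`, `classify`, `decode`, `geometry`, a `stages` list,
#' a global `seed` and an optional `epoch_subset`; unknown keys fail fast.
#' The global seed fans out deterministically into independent per-stage
#' seeds, so any stage can be re-run in isolation from the manifest and a
#' re-run of the same config and seed reproduces identical tables.
#'
#' Stage outputs are written as CSV/JSON under `out_dir`:
#' `trials.csv`/`spikes.csv`/`tuning.json` (simulate),
#' `classification.csv`, `decoding.csv`, `geometry.json` plus TCA factor
#' CSVs, `summary.json` and `manifest.json`.
#'
#' @param config Path to a config file, or a config list.
#' @param out_dir Output directory (default from config, else
#'   `"schemacells_run"`).
#' @param seed Overrides the config seed when given.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("seed", "out_dir", "stages", "epoch_subset", "simulate",
             "classify", "decode", "geometry")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("invalid config key(s): ", paste(bad, collapse = ", "))
  check_keys <- function(section, allowed) {
    extra <- setdiff(names(cfg[[section]] %||% list()), allowed)
    if (length(extra) > 0)
      stop("invalid config key(s) in ", section, ": ",
           paste(extra, collapse = ", "))
  }
  check_keys("simulate", c("n_units", "trials_per_type", "category_mix",
                           "gamma_nonschema"))
  check_keys("classify", c("r_schema", "r_noncoding", "alpha_corr",
                           "n_shuffles", "shuffle_percentile", "alpha_anova",
                           "attribute"))
  check_keys("decode", c("single_repeats", "ensemble_repeats",
                         "ensemble_trials_per_type", "max_single_units",
                         "lambda"))
  check_keys("geometry", c("tca_rank", "tca_restarts", "embed_method"))

  seed <- seed %||% cfg$seed %||% 1L
  out_dir <- out_dir %||% cfg$out_dir %||% "schemacells_run"
  stages <- cfg$stages %||% c("simulate", "rates", "classify", "decode",
                              "geometry", "report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log <- function(...) message(sprintf(...))

  sim <- cfg$simulate %||% list()
  design <- maze_design(trials_per_type = sim$trials_per_type %||% 20)
  mix <- unlist(sim$category_mix %||%
                  c(schema = 1/3, nonschema = 1/3, noncoding = 1/3))

  pop <- NULL
  if ("simulate" %in% stages) {
    log("simulate: %d units, %d trials", sim$n_units %||% 40, design$n_trials)
    pop <- simulate_population(design, n_units = sim$n_units %||% 40,
                               category_mix = mix,
                               gamma_nonschema = sim$gamma_nonschema %||% 0.5,
                               seed = stage_seed(seed, 1L))
    paths$trials <- file.path(out_dir, "trials.csv")
    paths$spikes <- file.path(out_dir, "spikes.csv")
    paths$tuning <- file.path(out_dir, "tuning.json")
    write_session(pop$trials, pop$spikes, paths$trials, paths$spikes)
    write_tuning(pop$tuning, paths$tuning)
  } else {
    sess <- read_session(file.path(out_dir, "trials.csv"),
                         file.path(out_dir, "spikes.csv"), design)
    pop <- list(trials = sess$trials, spikes = sess$spikes)
  }

  cls_cfg <- cfg$classify %||% list()
  config_obj <- analysis_config(
    r_schema = cls_cfg$r_schema %||% 0.8,
    r_noncoding = cls_cfg$r_noncoding %||% 0.4,
    alpha_corr = cls_cfg$alpha_corr %||% 0.01,
    n_shuffles = cls_cfg$n_shuffles %||% 1000,
    shuffle_percentile = cls_cfg$shuffle_percentile %||% 99,
    alpha_anova = cls_cfg$alpha_anova %||% 0.01,
    seed = stage_seed(seed, 2L)
  )

  # per-unit epoch matrices feed every later stage
  ems1 <- ems2 <- NULL
  if (any(c("rates", "classify", "decode", "geometry") %in% stages)) {
    log("rates: building epoch matrices")
    ems1 <- lapply(names(pop$spikes), function(id)
      epoch_matrix(pop$spikes[[id]], pop$trials, 1L, design, id))
    ems2 <- lapply(names(pop$spikes), function(id)
      epoch_matrix(pop$spikes[[id]], pop$trials, 2L, design, id))
    names(ems1) <- names(ems2) <- names(pop$spikes)
  }

  classification <- NULL
  if ("classify" %in% stages) {
    log("classify: %d units, %d shuffles/factor", length(pop$spikes),
        config_obj$n_shuffles)
    classification <- classify_population(
      pop$spikes, pop$trials, design, config_obj,
      attribute = cls_cfg$attribute %||% TRUE,
      epochs = unlist(cfg$epoch_subset))
    paths$classification <- file.path(out_dir, "classification.csv")
    utils::write.csv(classification, paths$classification, row.names = FALSE)
    log("classify: %s", paste(names(table(classification$category)),
                              table(classification$category),
                              sep = "=", collapse = ", "))
  }

  if ("decode" %in% stages) {
    dec <- cfg$decode %||% list()
    schema_ids <- if (!is.null(classification))
      classification$unit_id[classification$category == "schema"]
    else names(pop$spikes)
    n_single <- min(length(schema_ids), dec$max_single_units %||% 25)
    log("decode: %d single units + ensemble of %d", n_single,
        length(schema_ids))
    dseed <- stage_seed(seed, 3L)
    single_rows <- list()
    if (n_single > 0) {
      ids <- with_seed(dseed, sample(schema_ids, n_single))
      single_rows <- lapply(ids, function(id) {
        dr <- decode_single_cell(ems1[[id]], ems2[[id]],
                                 n_repeats = dec$single_repeats %||% 200,
                                 lambda = dec$lambda %||% 1,
                                 seed = stage_seed(dseed, match(id, ids)))
        data.frame(id = id, mode = "single", epoch = "all",
                   within_acc = dr$accuracy_within,
                   across_acc = dr$accuracy_across,
                   n_repeats = dr$n_repeats)
      })
    }
    ens_rows <- NULL
    if (length(schema_ids) >= 2) {
      er <- decode_ensemble(ems1[schema_ids], ems2[schema_ids],
                            trials_per_type = dec$ensemble_trials_per_type %||% 15,
                            n_repeats = dec$ensemble_repeats %||% 200,
                            lambda = dec$lambda %||% 1,
                            seed = stage_seed(dseed, 7777L))
      ens_rows <- data.frame(id = "ensemble", mode = "ensemble",
                             epoch = er$per_epoch$epoch,
                             within_acc = er$per_epoch$accuracy_within,
                             across_acc = er$per_epoch$accuracy_across,
                             n_repeats = er$n_repeats)
    }
    decoding <- rbind(do.call(rbind, single_rows), ens_rows)
    paths$decoding <- file.path(out_dir, "decoding.csv")
    utils::write.csv(decoding, paths$decoding, row.names = FALSE)
  }

  if ("geometry" %in% stages) {
    geo <- cfg$geometry %||% list()
    log("geometry: embeddings, silhouettes, TCA")
    gseed <- stage_seed(seed, 4L)
    profs1 <- vapply(ems1, function(e) type_profile(e)$values,
                     numeric(8L * ncol(ems1[[1]]$values)))
    profs2 <- vapply(ems2, function(e) type_profile(e)$values,
                     numeric(8L * ncol(ems2[[1]]$values)))
    x <- cbind(t(profs1), t(profs2)) # units x (72 per maze)
    mlab <- rep(c(1L, 2L), each = ncol(t(profs1)))
    proc <- list()
    for (meth in (geo$embed_method %||% c("linear", "nonlinear"))) {
      emb <- embed_population(x, mlab, method = meth)
      proc[[meth]] <- procrustes_dissimilarity(emb[[1]], emb[[2]])
    }
    # trials x (units * epochs) matrix for canonical-variable clustering
    xt <- rbind(do.call(cbind, lapply(ems1, `[[`, "values")),
                do.call(cbind, lapply(ems2, `[[`, "values")))
    lab <- c(paste0("m1_", ems1[[1]]$labels$position),
             paste0("m2_", ems2[[1]]$labels$position))
    sil <- lda_cluster_silhouette(xt, lab,
                                  n_pcs = min(30L, nrow(xt) - 2L))
    tens <- population_tensor(ems1)
    tca <- tca_decompose(tens, rank = geo$tca_rank %||% 6,
                         n_restarts = geo$tca_restarts %||% 5, seed = gseed)
    paths$geometry <- file.path(out_dir, "geometry.json")
    jsonlite::write_json(
      list(procrustes = proc,
           silhouette_by_type = as.list(sil$mean_by_type),
           tca = list(rank = tca$rank, error = tca$error)),
      paths$geometry, auto_unbox = TRUE, digits = NA)
    for (f in names(tca$factors)) {
      p <- file.path(out_dir, sprintf("tca_factor_%s.csv", f))
      utils::write.csv(as.data.frame(tca$factors[[f]]), p, row.names = FALSE)
      paths[[paste0("tca_", f)]] <- p
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("schemacells")),
    seed = seed,
    config = cfg,
    stages = stages,
    outputs = paths,
    digests = as.list(tools::md5sum(unlist(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if ("report" %in% stages) summarize_run(out_dir)
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Builds a machine-readable summary from the stage outputs in `out_dir`:
#' category counts, the attribution Venn partition of flagged units (each
#' unit counted in exactly the region of its flag set), and mean decoding
#' accuracies; written to `summary.json`. Missing stage outputs are
#' reported as gaps rather than errors.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return The summary list, invisibly.
#' @export
summarize_run <- function(out_dir) {
  summary <- list(gaps = character(0))
  cls_path <- file.path(out_dir, "classification.csv")
  if (file.exists(cls_path)) {
    cls <- utils::read.csv(cls_path, stringsAsFactors = FALSE)
    summary$n_units <- nrow(cls)
    summary$category_counts <- as.list(table(cls$category))
    flagged <- cls[!is.na(cls$epoch_flag), , drop = FALSE]
    if (nrow(flagged) > 0) {
      region <- paste0(ifelse(flagged$epoch_flag, "E", ""),
                       ifelse(flagged$reward_flag, "R", ""),
                       ifelse(flagged$position_flag, "P", ""))
      region[region == ""] <- "none"
      summary$attribution_venn <- as.list(table(region))
    }
    summary$mean_eta2 <- lapply(
      split(cls[c("eta2_epoch", "eta2_reward", "eta2_position")],
            cls$category), colMeans)
  } else summary$gaps <- c(summary$gaps, "classification")
  dec_path <- file.path(out_dir, "decoding.csv")
  if (file.exists(dec_path)) {
    dec <- utils::read.csv(dec_path, stringsAsFactors = FALSE)
    summary$decoding <- lapply(split(dec, dec$mode), function(d)
      list(within = mean(d$within_acc), across = mean(d$across_acc),
           chance = 0.125))
  } else summary$gaps <- c(summary$gaps, "decoding")
  geo_path <- file.path(out_dir, "geometry.json")
  if (file.exists(geo_path)) {
    summary$geometry <- jsonlite::read_json(geo_path)
  } else summary$gaps <- c(summary$gaps, "geometry")
  if (length(summary$gaps) == 0) summary$gaps <- NULL
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
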