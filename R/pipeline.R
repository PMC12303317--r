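# End-to-end orchestration: simulate -> hrv -> vitals -> assemble ->
# network -> embed -> rank, with per-stage CSV artifacts, a JSON manifest
# of checksums, and full determinism given the config seed.

#' Default pipeline configuration
#'
#' All analysis constants are surfaced here rather than hard-coded:
#' the \[2 h, 14 h) observation window (12 hourly segments starting at the
#' 2nd hour), the 12 h minimum recording length, k = 5 imputation
#' neighbours, the 0.5 correlation threshold, and the embedding grid
#' (hidden 32/64/128/256, learning rates 0.001/0.01/0.1, 1000 search
#' epochs, 10000 final epochs). Override any entry via [run_pipeline()]'s
#' `config` argument or a YAML file read with [read_run_config()].
#'
#' @param seed Master seed for every stage.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_patients = 34L, n_short_patients = 5L, duration_h = 14,
                  short_duration_h = 8, ecg_fs = 240, ecg_mode = "rr"),
    window = c(start = 2, end = 14),
    min_hours = 12,
    knn_k = 5L,
    rqa = list(embedding_dim = 10L, delay = 1L, radius = 0.1, l_min = 2L,
               max_beats = 1500L),
    corr_threshold = 0.5,
    gcn = list(hidden_grid = c(32L, 64L, 128L, 256L),
               lr_grid = c(0.001, 0.01, 0.1),
               search_epochs = 1000L, final_epochs = 10000L,
               val_fraction = 0.2, grid_search = TRUE, weighted = TRUE,
               hidden = 64L, lr = 0.01)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override the defaults of
#' [default_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @param seed Fallback seed if the file sets none.
#' @export
read_run_config <- function(path, seed = 1L) {
  if (!file.exists(path)) {
    hrvnet_error("hrvnet_validation_error", paste("config file not found:", path))
  }
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(seed), user)
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  if (config$corr_threshold <= 0 || config$corr_threshold > 1) {
    stop_invalid("corr_threshold must be in (0, 1]")
  }
  if (config$window[["end"]] <= config$window[["start"]]) {
    stop_invalid("window end must exceed window start")
  }
  if (config$min_hours < 0) stop_invalid("min_hours must be non-negative")
  if (config$knn_k < 1) stop_invalid("knn_k must be >= 1")
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes `simulate -> hrv -> vitals -> assemble -> network -> embed ->
#' rank`, writing each stage's artifacts under `output_dir` and a
#' `manifest.json` with the config hash, seed and per-file MD5 checksums.
#' Re-running with an identical config reproduces byte-identical
#' artifacts. A stage failure aborts with an error naming the stage.
#'
#' @param config Configuration list (see [default_config()]).
#' @param output_dir Writable output directory.
#' @param stages Subset of stages to run (consuming earlier artifacts
#'   already in `output_dir`).
#' @param quiet Suppress per-stage log lines.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), output_dir,
                         stages = c("simulate", "hrv", "vitals", "assemble",
                                    "network", "embed", "rank"),
                         quiet = FALSE) {
  validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    hrvnet_error("hrvnet_runtime_error", paste("cannot create output dir:", output_dir))
  }
  all_stages <- c("simulate", "hrv", "vitals", "assemble", "network", "embed", "rank")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  fns <- list(simulate = stage_simulate, hrv = stage_hrv, vitals = stage_vitals,
              assemble = stage_assemble, network = stage_network,
              embed = stage_embed, rank = stage_rank)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  for (st in all_stages[all_stages %in% stages]) {
    if (!quiet) message(sprintf("[%s] seed=%d ...", st, config$seed))
    files <- tryCatch(
      fns[[st]](output_dir, config),
      hrvnet_error = function(e) {
        hrvnet_error("hrvnet_runtime_error",
                     sprintf("stage '%s' failed: %s", st, conditionMessage(e)))
      })
    sums <- tools::md5sum(files)
    names(sums) <- basename(names(sums))
    manifest$stages[[st]] <- as.list(sums)
    if (!quiet) message(sprintf("[%s] wrote %d artifact(s)", st, length(files)))
  }
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    hrvnet_error("hrvnet_runtime_error",
                 sprintf("stage '%s' requires missing upstream artifact: %s", stage, path))
  }
  path
}

#' Pipeline stages
#'
#' Each stage consumes the previous stage's files under `dir` and writes
#' its own artifact(s), returning the paths written. They can be invoked
#' independently; a missing upstream artifact raises an error naming the
#' required file.
#'
#' @param dir Pipeline output directory.
#' @param config Configuration list (see [default_config()]).
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(dir, config) {
  cc <- do.call(cohort_config, c(config$cohort, list(seed = config$seed)))
  cohort <- generate_cohort(cc)
  write_cohort(cohort, file.path(dir, "cohort"))
  list.files(file.path(dir, "cohort"), recursive = TRUE, full.names = TRUE)
}

#' @rdname pipeline_stages
#' @export
stage_hrv <- function(dir, config) {
  cdir <- file.path(dir, "cohort")
  rq <- do.call(rqa_params, config$rqa)
  rr_dir <- file.path(cdir, "rr")
  ecg_dir <- file.path(cdir, "ecg")
  use_ecg <- dir.exists(ecg_dir)
  if (!use_ecg) require_artifact(rr_dir, "hrv")
  src <- if (use_ecg) ecg_dir else rr_dir
  files <- sort(list.files(src, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) {
    hrvnet_error("hrvnet_runtime_error", paste("stage 'hrv': no signal files in", src))
  }
  rows <- lapply(files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    d <- utils::read.csv(f)
    rr <- if (use_ecg) {
      fs <- 1 / stats::median(diff(d$time_s))
      detect_r_peaks(ecg_trace(d$mv, fs = round(fs)))
    } else {
      rr_series(d$rr_ms, times = d$time_s)
    }
    rr <- clean_rr(rr)
    feats <- hourly_hrv(rr, window_start = config$window[["start"]],
                        window_end = config$window[["end"]], rqa = rq)
    data.frame(patient = id, t(unclass(feats)), check.names = FALSE)
  })
  out <- file.path(dir, "hrv_features.csv")
  utils::write.csv(do.call(rbind, rows), out, row.names = FALSE, na = "")
  out
}

#' @rdname pipeline_stages
#' @export
stage_vitals <- function(dir, config) {
  cdir <- file.path(dir, "cohort")
  require_artifact(file.path(cdir, "clinical.csv"), "vitals")
  clin <- utils::read.csv(file.path(cdir, "clinical.csv"), check.names = FALSE)
  vdir <- require_artifact(file.path(cdir, "vitals"), "vitals")
  files <- sort(list.files(vdir, pattern = "\\.csv$", full.names = TRUE))
  vrows <- lapply(files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    v <- utils::read.csv(f)
    temp <- clin$temperature[clin$patient == id]
    # window is clamped to the patient's recording so short (later
    # excluded) patients still get defined features
    h_end <- min(config$window[["end"]], max(v$time_min + 1) / 60)
    feats <- vital_features(v, temperature = temp,
                            h_start = min(config$window[["start"]], h_end - 1 / 60),
                            h_end = h_end, k = config$knn_k)
    data.frame(patient = id, t(feats), check.names = FALSE)
  })
  crows <- lapply(seq_len(nrow(clin)), function(i) {
    rec <- validate_clinical(clin[i, setdiff(names(clin), "patient")])
    data.frame(patient = clin$patient[i], t(clinical_features(rec)), check.names = FALSE)
  })
  out1 <- file.path(dir, "vitals_features.csv")
  out2 <- file.path(dir, "clinical_features.csv")
  utils::write.csv(do.call(rbind, vrows), out1, row.names = FALSE, na = "")
  utils::write.csv(do.call(rbind, crows), out2, row.names = FALSE, na = "")
  c(out1, out2)
}

#' @rdname pipeline_stages
#' @export
stage_assemble <- function(dir, config) {
  for (f in c("hrv_features.csv", "vitals_features.csv", "clinical_features.csv",
              file.path("cohort", "durations.csv"))) {
    require_artifact(file.path(dir, f), "assemble")
  }
  durs <- utils::read.csv(file.path(dir, "cohort", "durations.csv"))
  retained <- apply_exclusions(durs, min_hours = config$min_hours)
  fm <- assemble_features(
    utils::read.csv(file.path(dir, "hrv_features.csv"), check.names = FALSE),
    utils::read.csv(file.path(dir, "vitals_features.csv"), check.names = FALSE),
    utils::read.csv(file.path(dir, "clinical_features.csv"), check.names = FALSE),
    patients = sort(retained)
  )
  write_feature_matrix(fm, dir)
  log <- attr(retained, "exclusion_log")
  out <- file.path(dir, "exclusions.csv")
  utils::write.csv(data.frame(step = names(log), n = as.integer(log)), out,
                   row.names = FALSE)
  c(file.path(dir, "feature_matrix.csv"), file.path(dir, "schema.csv"), out)
}

#' @rdname pipeline_stages
#' @export
stage_network <- function(dir, config) {
  require_artifact(file.path(dir, "feature_matrix.csv"), "network")
  fm <- read_feature_matrix(dir)
  net <- feature_network(fm, threshold = config$corr_threshold)
  write_network(net, dir)
  file.path(dir, c("correlation_matrix.csv", "edges.csv", "centrality.csv",
                   "group_density.csv", "network.graphml"))
}

#' @rdname pipeline_stages
#' @export
stage_embed <- function(dir, config) {
  require_artifact(file.path(dir, "correlation_matrix.csv"), "embed")
  require_artifact(file.path(dir, "network.graphml"), "embed")
  rdf <- utils::read.csv(file.path(dir, "correlation_matrix.csv"), check.names = FALSE)
  r <- as.matrix(rdf[, -1, drop = FALSE])
  rownames(r) <- rdf$feature
  cm <- structure(list(r = r), class = "correlation_matrix")
  g <- igraph::read_graph(file.path(dir, "network.graphml"), format = "graphml")
  A_hat <- normalize_adjacency(g, weighted = isTRUE(config$gcn$weighted) &&
                                 igraph::ecount(g) > 0)
  X <- node_feature_profile(cm, threshold = config$corr_threshold)
  X <- X[rownames(A_hat), rownames(A_hat)]
  gc <- config$gcn
  if (igraph::ecount(g) == 0L) {
    message("embed: graph has no edges; embedding reflects isolated node features only")
  }
  if (isTRUE(gc$grid_search)) {
    gs <- gcn_grid_search(X, A_hat, hidden_grid = gc$hidden_grid,
                          lr_grid = gc$lr_grid, search_epochs = gc$search_epochs,
                          val_fraction = gc$val_fraction, seed = config$seed)
    best <- gs$best
    utils::write.csv(gs$results, file.path(dir, "grid_search.csv"), row.names = FALSE)
  } else {
    best <- list(hidden = gc$hidden, lr = gc$lr)
    utils::write.csv(data.frame(hidden = best$hidden, lr = best$lr,
                                train_mse = NA, val_mse = NA, diverged = FALSE),
                     file.path(dir, "grid_search.csv"), row.names = FALSE)
  }
  fit <- gcn_fit(X, A_hat, hidden = best$hidden, lr = best$lr,
                 epochs = gc$final_epochs, seed = config$seed)
  utils::write.csv(data.frame(epoch = seq_along(fit$loss_trace),
                              train_mse = fit$loss_trace),
                   file.path(dir, "loss_trace.csv"), row.names = FALSE)
  emb <- data.frame(feature = rownames(fit$H), fit$H, check.names = FALSE)
  names(emb)[-1] <- paste0("h", seq_len(ncol(fit$H)))
  utils::write.csv(emb, file.path(dir, "embedding.csv"), row.names = FALSE)
  file.path(dir, c("grid_search.csv", "loss_trace.csv", "embedding.csv"))
}

#' @rdname pipeline_stages
#' @export
stage_rank <- function(dir, config) {
  require_artifact(file.path(dir, "embedding.csv"), "rank")
  require_artifact(file.path(dir, "schema.csv"), "rank")
  emb <- utils::read.csv(file.path(dir, "embedding.csv"), check.names = FALSE)
  schema <- utils::read.csv(file.path(dir, "schema.csv"), stringsAsFactors = FALSE)
  H <- as.matrix(emb[, -1, drop = FALSE])
  rownames(H) <- emb$feature
  imp <- node_importance(H, groups = stats::setNames(schema$group, schema$feature))
  out <- file.path(dir, "importance.csv")
  utils::write.csv(as.data.frame(imp), out, row.names = FALSE)
  out
}
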