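# End-to-end orchestration: simulate / features / train / translate /
# evaluate, each writing its outputs plus a JSON run manifest so every
# report is reproducible from its manifest.

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  config
}

require_keys <- function(config, keys, where) {
  missing <- setdiff(keys, names(config))
  if (length(missing)) {
    abort("missing config key(s) for %s: %s", where,
          paste(missing, collapse = ", "))
  }
}

write_manifest <- function(dir, command, config, inputs, outputs, seed) {
  digest <- function(paths) {
    paths <- as.character(unlist(paths))
    paths <- as.character(unlist(lapply(paths, function(p) {
      if (dir.exists(p)) list.files(p, recursive = TRUE, full.names = TRUE)
      else p
    })))
    if (!length(paths)) return(stats::setNames(list(), character(0)))
    paths <- paths[file.exists(paths) & !dir.exists(paths)]
    if (!length(paths)) return(stats::setNames(list(), character(0)))
    as.list(tools::md5sum(paths))
  }
  manifest <- list(
    command = command,
    package = "xmodal",
    version = as.character(utils::packageVersion("xmodal")),
    seed = seed,
    config = config,
    input_digests = digest(unlist(inputs)),
    outputs = unname(unlist(outputs)),
    wall_clock = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a coupled benchmark and write it to disk
#'
#' @param config list or YAML path with keys `n` (required),
#'   `anchor_fraction` (default 0), `seed` (default 1), `n_features`
#'   (default 50), `volume_shape` (default 32^3), and optional noise
#'   settings `vector_noise_sd`, `volume_noise_sd`.
#' @param out output directory.
#' @return invisibly, the benchmark object.
#' @export
cmd_simulate <- function(config, out) {
  config <- read_config(config)
  require_keys(config, "n", "simulate")
  seed <- config$seed %||% 1L
  specs <- list(
    default_vector_spec(n_features = config$n_features %||% 50L,
                        noise_sd = config$vector_noise_sd %||% 0.05),
    default_volume_spec(shape = config$volume_shape %||% c(32L, 32L, 32L),
                        noise_sd = config$volume_noise_sd %||% 0.02)
  )
  bench <- make_benchmark(default_latent_config(), specs, config$n,
                          config$anchor_fraction %||% 0, seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_benchmark(bench, out)
  outputs <- list.files(out, recursive = TRUE, full.names = TRUE)
  write_manifest(out, "simulate", config, inputs = list(), outputs = outputs,
                 seed = seed)
  invisible(bench)
}

#' Extract radial profiles for a directory of nucleus TIFF stacks
#'
#' @param config list or YAML path; optional keys `step_um` (0.5),
#'   `min_volume_um3` (10), `n_clusters` (2), `background_offset` (0,
#'   subtracted from intensities inside the mask before profiling).
#' @param volumes_dir directory of `nucleus*.tif` stems written by
#'   [write_volume_tiff()].
#' @param out output directory; writes `profiles.tsv` with columns
#'   `bin01..bin10` (outermost bin first) and `cluster`.
#' @return invisibly, the profile matrix.
#' @export
cmd_features <- function(config, volumes_dir, out) {
  config <- read_config(config)
  stems <- sub("\\.tif$", "",
               list.files(volumes_dir, pattern = "^nucleus[0-9]+\\.tif$",
                          full.names = TRUE))
  if (!length(stems)) abort("no nucleus TIFF stacks found in '%s'", volumes_dir)
  offset <- config$background_offset %||% 0
  profiles <- lapply(stems, function(s) {
    v <- read_volume_tiff(s)
    intens <- v$volume
    if (offset > 0) intens <- pmax(intens - offset, 0) * (v$mask != 0)
    extract_profile(voxel_volume(intens, v$mask, v$spacing_um),
                    config$step_um %||% 0.5,
                    config$min_volume_um3 %||% 10)
  })
  B <- do.call(rbind, lapply(profiles, function(p) p$binned10))
  colnames(B) <- sprintf("bin%02d", 1:10)
  cl <- cluster_profiles(profiles, config$n_clusters %||% 2)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(nucleus = basename(stems), B, cluster = cl)
  utils::write.table(df, file.path(out, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out, "features", config,
                 inputs = paste0(stems, ".tif"),
                 outputs = file.path(out, "profiles.tsv"),
                 seed = config$seed %||% 1L)
  invisible(df)
}

load_domain <- function(path) {
  if (dir.exists(path)) {
    stems <- sub("\\.tif$", "",
                 list.files(path, pattern = "^nucleus[0-9]+\\.tif$",
                            full.names = TRUE))
    lapply(stems, read_volume_tiff)
  } else {
    read_matrix_tsv(path)
  }
}

config_to_training <- function(config) {
  keep <- intersect(names(config), names(formals(training_config)))
  do.call(training_config, config[keep])
}

#' Train a cross-modal model from files on disk
#'
#' @param config list or YAML path holding [training_config()] fields plus
#'   optional `anchors` (path), `labels` (vector of per-domain label paths)
#'   and `resume` (checkpoint path to continue from; the loss table then
#'   continues from the stored epoch counter).
#' @param data_paths character vector of >= 2 domain inputs: a `.tsv` matrix
#'   path or a directory of nucleus TIFF stacks.
#' @param out output directory; writes `checkpoint.rds`, `loss.tsv` and a
#'   manifest.
#' @return invisibly, the fitted model.
#' @export
cmd_train <- function(config, data_paths, out) {
  config <- read_config(config)
  domains <- lapply(data_paths, load_domain)
  cfg <- config_to_training(config)
  priors <- list()
  if (!is.null(config$anchors)) priors$anchors <- read_anchors_tsv(config$anchors)
  if (!is.null(config$labels)) priors$labels <- lapply(config$labels, read_index_tsv)
  if (!length(priors)) priors <- NULL
  epoch_offset <- 0L
  autoencoders <- NULL
  if (!is.null(config$resume)) {
    prev <- load_checkpoint(config$resume)
    autoencoders <- prev$autoencoders
    epoch_offset <- max(prev$log$epoch)
  }
  model <- fit_crossmodal(domains, cfg, priors, autoencoders)
  if (epoch_offset > 0) model$log$epoch <- model$log$epoch + epoch_offset
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ckpt <- file.path(out, "checkpoint.rds")
  save_checkpoint(model, ckpt)
  utils::write.table(model$log, file.path(out, "loss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(config, file.path(out, "resolved-config.yaml"))
  write_manifest(out, "train", config, inputs = data_paths,
                 outputs = c(ckpt, file.path(out, c("loss.tsv",
                                                    "resolved-config.yaml"))),
                 seed = cfg$seed)
  invisible(model)
}

#' Translate a dataset between modalities using a checkpoint
#'
#' @param config list or YAML path with keys `source` and `target`
#'   (modality indices, 1-based).
#' @param checkpoint checkpoint path.
#' @param data_path source-domain input (matrix `.tsv` or volume directory).
#' @param out output directory; vector targets are written as
#'   `translated.tsv`, volume targets as per-nucleus TIFF stacks.
#' @return invisibly, the `translation_result`.
#' @export
cmd_translate <- function(config, checkpoint, data_path, out) {
  config <- read_config(config)
  require_keys(config, c("source", "target"), "translate")
  model <- load_checkpoint(checkpoint)
  x <- load_domain(data_path)
  tr <- translate(x, model, config$source, config$target)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (model$kinds[config$target] == "vector") {
    outputs <- write_matrix_tsv(tr$translated, file.path(out, "translated.tsv"))
  } else {
    shape <- attr(tr$translated, "vol_shape")
    vdir <- file.path(out, "translated")
    dir.create(vdir, showWarnings = FALSE)
    spacing <- model$autoencoders[[config$target]]$spacing_um %||% c(0.5, 0.5, 0.5)
    for (i in seq_len(nrow(tr$translated))) {
      v <- array(pmin(pmax(tr$translated[i, ], 0), 1), shape)
      write_volume_tiff(list(volume = v, mask = array(1L, shape),
                             spacing_um = spacing),
                        file.path(vdir, sprintf("nucleus%04d", i)))
    }
    outputs <- vdir
  }
  write_manifest(out, "translate", config, inputs = c(checkpoint, data_path),
                 outputs = outputs, seed = model$seed)
  invisible(tr)
}

#' Evaluate a trained model on data with known labels/pairing
#'
#' @param config list or YAML path; keys `metrics` (subset of
#'   `"cluster_accuracy"`, `"knn"`, `"roc"`, `"fold_change"`, `"markers"`;
#'   default all), `k_grid` (default c(1, 5, 10, 50)), `pairing` (path;
#'   required for knn), `labels` (per-domain label paths; required for
#'   cluster accuracy, roc, fold_change, markers), `source`/`target` for
#'   translation-based metrics (defaults 2 -> 1).
#' @param checkpoint checkpoint path.
#' @param data_paths per-domain inputs as in [cmd_train()].
#' @param out output directory for the report files.
#' @return invisibly, a list of computed metrics.
#' @export
cmd_evaluate <- function(config, checkpoint, data_paths, out) {
  config <- read_config(config)
  model <- load_checkpoint(checkpoint)
  domains <- lapply(data_paths, load_domain)
  metrics <- config$metrics %||%
    c("cluster_accuracy", "knn", "roc", "fold_change", "markers")
  n <- nrow(as_domain_matrix(domains[[1]]))
  labels <- if (!is.null(config$labels)) lapply(config$labels, read_index_tsv)
  pairing <- if (!is.null(config$pairing)) read_index_tsv(config$pairing)
  if (!is.null(pairing) && length(pairing) != n) {
    abort("pairing has %d entries but data has %d rows", length(pairing), n)
  }
  if (("knn" %in% metrics) && is.null(pairing)) {
    abort("metric 'knn' requires a pairing file")
  }
  need_labels <- intersect(metrics,
                           c("cluster_accuracy", "roc", "fold_change", "markers"))
  if (length(need_labels) && is.null(labels)) {
    abort("metric(s) %s require label files", paste(need_labels, collapse = ", "))
  }
  Z <- lapply(seq_along(domains),
              function(i) encode_modality(model, domains[[i]], i))
  res <- list()
  rows <- list()
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  src <- config$source %||% 2L
  tgt <- config$target %||% 1L
  if ("cluster_accuracy" %in% metrics) {
    acc <- cluster_assignment_accuracy(do.call(rbind, Z), unlist(labels),
                                       length(unique(unlist(labels))),
                                       seed = model$seed)
    res$cluster_accuracy <- acc
    rows[[length(rows) + 1L]] <- data.frame(metric = "cluster_accuracy",
                                            value = acc, parameter = "")
  }
  if ("knn" %in% metrics) {
    kg <- config$k_grid %||% c(1, 5, 10, 50)
    kacc <- vapply(kg, function(k) {
      knn_matching_accuracy(Z[[1]], Z[[2]], pairing, k)$accuracy
    }, numeric(1))
    res$knn <- data.frame(k = kg, accuracy = kacc)
    utils::write.table(res$knn, file.path(out, "knn.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(metric = "knn_accuracy", value = kacc,
                 parameter = paste0("k=", kg))
  }
  needs_translation <- any(c("roc", "fold_change", "markers") %in% metrics)
  if (needs_translation) {
    tr <- translate(domains[[src]], model, src, tgt)
    trX <- tr$translated
    obsX <- as_domain_matrix(domains[[tgt]])
    if ("roc" %in% metrics) {
      roc <- transfer_roc(obsX, labels[[tgt]], trX, labels[[src]],
                          list(ntree = 100, maxnodes = 4, seed = model$seed))
      res$roc <- roc
      utils::write.table(data.frame(fpr = roc$fpr, tpr = roc$tpr),
                         file.path(out, "roc.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(metric = "transfer_auc",
                                              value = roc$auc, parameter = "")
    }
    if ("fold_change" %in% metrics) {
      fc <- fold_change_concordance(trX, labels[[src]], obsX, labels[[tgt]])
      res$fold_change <- fc
      rows[[length(rows) + 1L]] <- data.frame(metric = "fold_change_pearson_r",
                                              value = fc$pearson_r,
                                              parameter = "")
    }
    if ("markers" %in% metrics) {
      mt <- marker_genes(trX, labels[[src]])
      res$markers <- mt
      utils::write.table(mt, file.path(out, "markers.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  summary$seed <- model$seed
  utils::write.table(summary, file.path(out, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out, "evaluate", config,
                 inputs = c(checkpoint, data_paths,
                            unlist(config[c("pairing", "labels")])),
                 outputs = list.files(out, full.names = TRUE),
                 seed = model$seed)
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `features`, `train`, `translate`, `evaluate`.
#' Every flag `--key value` overrides the corresponding config key; `--config`
#' names a YAML file; positional arguments give the data paths and the
#' output directory is taken from `--out`.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    cat("usage: xmodal <simulate|features|train|translate|evaluate> [--config file.yaml] [--key value ...] [paths...] --out DIR\n")
    return(invisible(1L))
  }
  cmd <- argv[1]
  rest <- argv[-1]
  opts <- list()
  pos <- character(0)
  i <- 1
  while (i <= length(rest)) {
    a <- rest[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(rest)) abort("flag --%s needs a value", key)
      val <- rest[i + 1]
      num <- suppressWarnings(as.numeric(val))
      opts[[key]] <- if (!is.na(num)) num else val
      i <- i + 2
    } else {
      pos <- c(pos, a)
      i <- i + 1
    }
  }
  out <- opts$out
  if (is.null(out)) abort("--out is required")
  opts$out <- NULL
  config <- if (!is.null(opts$config)) read_config(opts$config) else list()
  opts$config <- NULL
  config[names(opts)] <- opts  # flags take precedence
  status <- tryCatch({
    switch(cmd,
      simulate = cmd_simulate(config, out),
      features = cmd_features(config, pos[1], out),
      train = cmd_train(config, pos, out),
      translate = cmd_translate(config, pos[1], pos[2], out),
      evaluate = cmd_evaluate(config, pos[1], pos[-1], out),
      abort("unknown command '%s'", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
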