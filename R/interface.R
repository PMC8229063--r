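# Manifest and configuration I/O plus a thin command-line front end
# chaining the pipeline modules.

#' Load and validate a dataset manifest
#'
#' @param path CSV with header `path,label,split` (extra columns such as
#'   `seed` are kept). Relative image paths are resolved against the
#'   manifest's directory.
#' @param labels known label set (class ids `C1`..`C4` and the manufacturer
#'   names are both accepted by default).
#' @param requireFiles check that every referenced image exists.
#' @return validated manifest data.frame.
#' @export
loadManifest <- function(path, labels = c(.CLASS_IDS, .CLASS_LABELS),
                         requireFiles = TRUE) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "split")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  for (i in seq_len(nrow(man))) {
    if (!man$label[i] %in% labels)
      stop("row ", i, ": unknown label '", man$label[i], "'")
    if (!man$split[i] %in% c("train", "test"))
      stop("row ", i, ": split must be 'train' or 'test'")
    if (requireFiles && !file.exists(man$path[i]))
      stop("row ", i, ": missing image file ", man$path[i])
  }
  man
}

#' @rdname loadManifest
#' @param manifest manifest data.frame.
#' @return `writeManifest`: the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration round-tripping
#'
#' Reads or writes a nested run configuration as YAML (JSON also accepted
#' when reading). Keys mirror the training-parameter table (epochs,
#' mini-batch size, learning rate, momentum term, L2 regularization,
#' learning-rate drop factor) plus synthesis/evaluation blocks and the
#' root seed every stochastic component derives from.
#'
#' @param path file path.
#' @return named list.
#' @export
loadRunConfig <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                   simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' @rdname loadRunConfig
#' @param config named list.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default run configuration
#' @param rootSeed integer seed from which all component seeds derive.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(rootSeed = 1L) {
  list(rootSeed = as.integer(rootSeed),
       synthesis = list(countsPerClass = list(C1 = 30L, C2 = 30L, C3 = 30L,
                                              C4 = 30L),
                        difficulty = "easy"),
       augmentation = list(angleStepDeg = 10, nAngles = 36L),
       training = unclass(trainConfig(seed = rootSeed + 1L)),
       evaluation = list(kClosed = 10L, ria = TRUE))
}

#' Command-line entry point
#'
#' A thin dispatcher over the package's exported functions. Sub-commands:
#' `synth`, `augment`, `extract`, `train`, `eval-closed`, `eval-open`,
#' `pca-knn`, `maps`. Flags: `--seed`, `--out`, `--manifest`, `--counts`,
#' `--k`, plus sub-command specifics. Intended to be called from the
#' installed `drenet` script; returns the exit status.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
drenetCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: drenet <command> [options]",
    "commands: synth augment extract train eval-closed eval-open pca-knn",
    "          maps",
    "common options: --seed INT --out DIR --manifest FILE", sep = "\n")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- .parseFlags(args[-1L])
  seed <- as.integer(opt$seed %||% 1L)
  out <- opt$out %||% "."
  status <- tryCatch({
    switch(cmd,
      synth = {
        counts <- as.integer(strsplit(opt$counts %||% "30,30,30,30",
                                      ",")[[1L]])
        man <- generateDataset(stats::setNames(counts, .CLASS_IDS), out,
                               masterSeed = seed,
                               difficulty = opt$difficulty %||% "easy")
        message(nrow(man), " images written under ", out)
        0L
      },
      augment = {
        man <- loadManifest(opt$manifest)
        aug <- riaExpandManifest(man, outDir = opt$out %||% NULL)
        writeManifest(aug, file.path(dirname(opt$manifest),
                                     "manifest_augmented.csv"))
        message(nrow(aug), " rows in augmented manifest")
        0L
      },
      extract = {
        man <- loadManifest(opt$manifest)
        model <- buildDRENet(
          buildExtractor("resnet50_modified", seed = seed),
          buildExtractor("densenet201_modified", seed = seed + 1L))
        f <- extractConcatFeatures(model, .loadImages(man))
        utils::write.csv(cbind(man["label"], as.data.frame(f)),
                         file.path(out, "features.csv"), row.names = FALSE)
        message("features: ", nrow(f), " x ", ncol(f))
        0L
      },
      train = {
        man <- loadManifest(opt$manifest)
        cfg <- trainConfig(regime = opt$regime %||% "sequential",
                           seed = seed)
        fit <- if (cfg$regime == "end_to_end")
          trainEndToEnd(man, cfg) else trainSequential(man, cfg)
        saveDRENet(fit$model, file.path(out, "model"))
        message("model bundle written under ", file.path(out, "model"))
        0L
      },
      `eval-closed` = {
        man <- loadManifest(opt$manifest)
        cfg <- trainConfig(epochsBackbone = as.integer(opt$backboneEpochs
                                                       %||% 0L),
                           seed = seed + 1L)
        res <- runClosedWorld(man, cfg, k = as.integer(opt$k %||% 10L),
                              seed = seed,
                              resnet = buildExtractor("resnet50_modified",
                                                      seed = seed),
                              densenet = buildExtractor(
                                "densenet201_modified", seed = seed + 1L),
                              ria = !isTRUE(opt$`no-ria`))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(
          c(lapply(res$folds, function(r) as.list(metricsVector(r))),
            list(mean = as.list(res$mean))),
          file.path(out, "metrics_closed.json"), auto_unbox = TRUE,
          digits = NA)
        utils::write.csv(counts(res$confusion),
                         file.path(out, "confusion_closed.csv"))
        message(sprintf("closed-world mean accuracy %.2f%%",
                        res$mean[["accuracy"]]))
        0L
      },
      `eval-open` = {
        man <- loadManifest(opt$manifest)
        cfg <- trainConfig(epochsBackbone = 0L, seed = seed + 1L)
        res <- runOpenWorld(man, config = cfg, seed = seed,
                            resnet = buildExtractor("resnet50_modified",
                                                    seed = seed),
                            densenet = buildExtractor(
                              "densenet201_modified", seed = seed + 1L),
                            ria = !isTRUE(opt$`no-ria`))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(as.list(res$mean),
                             file.path(out, "metrics_open.json"),
                             auto_unbox = TRUE, digits = NA)
        message(sprintf("open-world mean accuracy %.2f%%",
                        res$mean[["accuracy"]]))
        0L
      },
      `pca-knn` = {
        f <- utils::read.csv(opt$features)
        labels <- f$label
        X <- as.matrix(f[, setdiff(names(f), "label")])
        sw <- lambdaSweep(X, labels,
                          lambdas = seq_len(as.integer(opt$maxLambda %||%
                                                         20L)),
                          seed = seed)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(sw$curve, file.path(out, "lambda_sweep.csv"),
                         row.names = FALSE)
        message("best lambda: ", sw$bestLambda)
        0L
      },
      maps = {
        man <- loadManifest(opt$manifest)
        fx <- buildExtractor(opt$arch %||% "densenet201_modified",
                             seed = seed)
        img <- readImageFile(man$path[1L])
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        for (st in activationStages(fx)) {
          m <- blockActivationMap(fx, img, st)
          writeImageFile(array(m * 255, c(dim(m), 3L)),
                         file.path(out, sprintf("map_%s.png",
                                                gsub("[^A-Za-z0-9]", "_",
                                                     st))))
        }
        message("activation maps written under ", out)
        0L
      },
      {
        message("unknown command '", cmd, "'\n", usage)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parseFlags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        out[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  out
}
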