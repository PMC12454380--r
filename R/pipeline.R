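# Pipeline orchestration: synth -> augment -> train -> segment -> cluster ->
# evaluate -> phenotype, each stage writing its outputs plus a JSON receipt
# (seed, config hash, input/output file hashes) into an append-only run
# directory, so that a rerun with the same configuration is auditable as
# bit-identical.

#' Default run configuration
#'
#' Every published default is the config default: Table-of-hyperparameters
#' training values (100 epochs, batch 24, Adam at 5e-4, decay 1e-4, npoint
#' 4096 in the full preset), clustering k = 55 and minpts = 3, 0.1 cm
#' voxels, 0.2 cm pivot ball, 25 cm tray reference. The demo profile scales
#' the scene count and network preset down to desk size.
#'
#' @param seed global integer seed.
#' @param outDir run directory.
#' @param demo use the small network preset and a 10-scene dataset.
#' @param nScenes number of synthetic scenes.
#' @param epochs training epochs.
#' @param stopValAcc early-stop validation accuracy (NULL to disable).
#' @return A classed list of class `"RunConfig"`.
#' @export
runConfig <- function(seed = 1L, outDir = "corncloud_run", demo = TRUE,
                      nScenes = if (demo) 10L else 106L,
                      epochs = if (demo) 12L else 100L,
                      stopValAcc = if (demo) 0.995 else NULL) {
  net <- netConfig(preset = if (demo) "small" else "full",
                   epochs = epochs, seed = seed)
  structure(list(seed = as.integer(seed), outDir = outDir, demo = demo,
                 nScenes = as.integer(nScenes), net = net,
                 augment = augmentConfig(seed = seed),
                 clusterK = 55L, minPts = 3L, voxelSideCm = 0.1,
                 ballRadiusCm = 0.2, trayCm = 25,
                 stopValAcc = stopValAcc),
            class = "RunConfig")
}

#' Load a run configuration from YAML
#'
#' Scalar fields of the YAML override [runConfig()] defaults.
#'
#' @param path YAML file.
#' @return A `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("seed", "outDir", "demo", "nScenes",
                                  "epochs", "stopValAcc"))]
  do.call(runConfig, args)
}

.hashFiles <- function(files) {
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}

.writeReceipt <- function(runDir, stage, seed, inputs, outputs, extra = list()) {
  rec <- c(list(stage = stage, seed = seed,
                inputs = .hashFiles(inputs), outputs = .hashFiles(outputs)),
           extra)
  dir.create(file.path(runDir, "receipts"), showWarnings = FALSE,
             recursive = TRUE)
  jsonlite::write_json(rec, file.path(runDir, "receipts",
                                      paste0(stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}

#' Run the pipeline
#'
#' Executes the requested stages in order. Stages read only earlier stages'
#' outputs; each writes a receipt under `<outDir>/receipts/`. Rerunning with
#' the same configuration and seed reproduces all output hashes.
#'
#' @param config a [runConfig()].
#' @param stages character subset of
#'   `c("synth", "augment", "train", "segment", "cluster", "evaluate",
#'   "phenotype")`.
#' @return Invisibly, a list with the run directory and per-stage summaries.
#' @export
runPipeline <- function(config = runConfig(),
                        stages = c("synth", "augment", "train", "segment",
                                   "cluster", "evaluate", "phenotype")) {
  runDir <- config$outDir
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  res <- list(runDir = runDir)
  rawDir <- file.path(runDir, "raw")
  augDir <- file.path(runDir, "augmented")
  ckptFile <- file.path(runDir, "checkpoint.rds.txt")  # base64 text payload

  stageFail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  if ("synth" %in% stages) {
    tryCatch({
      manifest <- generateDataset(config$nScenes, rawDir, seed = config$seed)
      res$synth <- list(nScenes = config$nScenes, nPlants = nrow(manifest))
      .writeReceipt(runDir, "synth", config$seed, character(0),
                    list.files(rawDir, full.names = TRUE),
                    list(n_scenes = config$nScenes))
    }, error = function(e) stageFail("synth", e))
  }

  if ("augment" %in% stages) {
    tryCatch({
      man <- buildAugmentedDataset(rawDir, augDir, config$augment)
      res$augment <- list(nFiles = nrow(man))
      .writeReceipt(runDir, "augment", config$seed,
                    list.files(rawDir, full.names = TRUE),
                    file.path(augDir, c("train.csv", "test.csv", "val.csv")),
                    list(n_files = nrow(man)))
    }, error = function(e) stageFail("augment", e))
  }

  readSplit <- function(split) {
    man <- utils::read.csv(file.path(augDir, paste0(split, ".csv")))
    lapply(file.path(augDir, man$file), readLabeledTxt)
  }

  if ("train" %in% stages) {
    tryCatch({
      train <- readSplit("train")
      val <- readSplit("val")
      if (!length(val)) val <- NULL
      state <- trainNet(train, val, config$net,
                        stopValAcc = config$stopValAcc)
      saveNetState(state, ckptFile)
      res$train <- list(epochs = nrow(state$log),
                        finalValAcc = utils::tail(state$log$val_acc, 1))
      utils::write.csv(state$log, file.path(runDir, "training_log.csv"),
                       row.names = FALSE)
      .writeReceipt(runDir, "train", config$seed,
                    file.path(augDir, "train.csv"),
                    c(ckptFile, file.path(runDir, "training_log.csv")),
                    list(epochs = nrow(state$log)))
    }, error = function(e) stageFail("train", e))
  }

  if (any(c("segment", "cluster", "evaluate") %in% stages)) {
    if (!file.exists(ckptFile))
      stop("pipeline: no checkpoint; run the train stage first")
    state <- loadNetState(ckptFile)
    man <- utils::read.csv(file.path(augDir, "test.csv"))
    segDir <- file.path(runDir, "segmented")
    dir.create(segDir, showWarnings = FALSE)
    semAcc <- c(); semMiou <- c(); iious <- c()
    for (f in man$file) {
      cl <- readLabeledTxt(file.path(augDir, f))
      pred <- predictCloud(cl, state, seed = config$seed)
      if ("segment" %in% stages) {
        out <- labeledCloud(cl@points, cl@normals, pred,
                            ifelse(pred == 1L, 1L, 0L))
        writeLabeledTxt(out, file.path(segDir, f))
      }
      if ("evaluate" %in% stages) {
        sm <- semanticMetrics(pred, cl@semantic)
        semAcc <- c(semAcc, sm$acc); semMiou <- c(semMiou, sm$miou)
      }
      if ("cluster" %in% stages) {
        sel <- which(pred == 1L)
        if (length(sel) >= config$minPts) {
          asn <- cornDBSCAN(cl@points[sel, , drop = FALSE],
                            k = config$clusterK, minPts = config$minPts)
          if ("evaluate" %in% stages)
            iious <- c(iious,
                       instanceMetrics(asn@labels, cl@instance[sel])$iiou)
        }
      }
    }
    if ("evaluate" %in% stages) {
      metrics <- list(
        semantic_acc = if (length(semAcc)) mean(semAcc) else NA,
        semantic_miou = if (length(semMiou)) mean(semMiou) else NA,
        instance_iiou = if (length(iious)) mean(iious) else NA)
      jsonlite::write_json(metrics, file.path(runDir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      res$evaluate <- metrics
      .writeReceipt(runDir, "evaluate", config$seed, ckptFile,
                    file.path(runDir, "metrics.json"), metrics)
    }
    if ("segment" %in% stages)
      .writeReceipt(runDir, "segment", config$seed, ckptFile,
                    list.files(segDir, full.names = TRUE))
  }

  if ("phenotype" %in% stages) {
    tryCatch({
      files <- list.files(rawDir, pattern = "^scene_.*\\.txt$",
                          full.names = TRUE)
      recs <- lapply(files, function(f) {
        ph <- phenotypeScene(readLabeledTxt(f), computeArea = !config$demo,
                             referenceLengthReal = config$trayCm,
                             voxelSideCm = config$voxelSideCm,
                             ballRadiusCm = config$ballRadiusCm,
                             seed = config$seed)
        if (nrow(ph$records))
          cbind(scene = basename(f), ph$records)
      })
      traits <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
      utils::write.csv(traits, file.path(runDir, "traits.csv"),
                       row.names = FALSE)
      res$phenotype <- list(nPlants = nrow(traits))
      .writeReceipt(runDir, "phenotype", config$seed, files,
                    file.path(runDir, "traits.csv"),
                    list(n_plants = nrow(traits)))
    }, error = function(e) stageFail("phenotype", e))
  }

  invisible(res)
}

#' Save / load a trained network state as text
#'
#' The checkpoint is serialized and base64-encoded so that run directories
#' remain plain text.
#'
#' @param state a `"NetState"`.
#' @param path checkpoint file.
#' @return `path` (save) or the restored state (load).
#' @export
saveNetState <- function(state, path) {
  raw <- serialize(state, NULL, version = 2)
  writeLines(jsonlite::base64_enc(raw), path)
  invisible(path)
}

#' @rdname saveNetState
#' @export
loadNetState <- function(path) {
  unserialize(jsonlite::base64_dec(paste(readLines(path), collapse = "")))
}
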