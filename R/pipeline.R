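# Pipeline orchestration: simulate -> train -> predict -> reconstruct ->
# measure -> evaluate, with per-stage artifacts, resolved-config snapshots
# and JSON-lines logging.  One global seed fans out to per-stage seeds.

#' Full pipeline configuration
#'
#' @param outputDir artifact root; each stage writes under
#'   `outputDir/<stage>/`.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param phantom a [phantomConfig()].
#' @param detector a [detectorConfig()] (tiny by default).
#' @param segmenter a [segmenterConfig()].
#' @param er an [erNetConfig()].
#' @param reconstruct list(tau, contain, gap, L).
#' @param training list of per-network step counts.
#' @return a `RunConfig` list (YAML-serialisable).
#' @export
runConfig <- function(outputDir = tempfile("organelleEM_run_"),
                      seed = 1L,
                      phantom = phantomConfig(),
                      detector = tinyDetectorConfig(),
                      segmenter = segmenterConfig(),
                      er = erNetConfig(),
                      reconstruct = list(tau = 0.3, contain = 0.5,
                                         gap = 1L, L = 15L),
                      training = list(detSteps = 250L, segSteps = 300L,
                                      erSteps = 150L)) {
  cfg <- list(outputDir = outputDir, seed = as.integer(seed),
              phantom = phantom, detector = detector,
              segmenter = segmenter, er = er,
              reconstruct = reconstruct, training = training)
  class(cfg) <- "RunConfig"
  cfg
}

.stageDir <- function(cfg, stage) {
  d <- file.path(cfg$outputDir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

.cfgHash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

.logLine <- function(dir, stage, msg, extra = list()) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, msg = msg), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file.path(dir, "log.jsonl"), append = TRUE, sep = "")
}

.needArtifact <- function(path, producer) {
  if (!file.exists(path))
    stop(sprintf("missing artifact '%s'; run stage '%s' first",
                 path, producer), call. = FALSE)
  path
}

# ground-truth boxes (k x 4) for one instance slice map
#' @keywords internal
gtBoxesFromInstances <- function(instMap) {
  ids <- setdiff(unique(as.vector(instMap)), 0L)
  if (length(ids) == 0L) return(matrix(0, 0L, 4L))
  t(vapply(ids, function(id) {
    w <- which(instMap == id, arr.ind = TRUE)
    c(min(w[, 2]) - 1, min(w[, 1]) - 1, max(w[, 2]), max(w[, 1]))
  }, numeric(4)))
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `train-mito-detect`, `train-mito-seg`, `train-er`,
#' `predict`, `reconstruct`, `measure`, `evaluate`.  Each stage reads its
#' upstream artifacts from `cfg$outputDir`, writes its own under
#' `outputDir/<stage>/` together with the resolved config, and appends to
#' the run log.  A missing upstream artifact raises an error naming the
#' stage that produces it.
#'
#' @param stage stage name.
#' @param cfg a [runConfig()].
#' @return invisible list of produced artifact paths.
#' @export
runStage <- function(stage = c("simulate", "train-mito-detect",
                               "train-mito-seg", "train-er", "predict",
                               "reconstruct", "measure", "evaluate"),
                     cfg = runConfig()) {
  stage <- match.arg(stage)
  dir <- .stageDir(cfg, stage)
  seed <- .deriveSeed(cfg$seed, stage)
  yaml::write_yaml(list(stage = stage, seed = seed,
                        configHash = .cfgHash(cfg)),
                   file.path(dir, "resolved_config.yaml"))
  .logLine(dir, stage, "start", list(seed = seed, hash = .cfgHash(cfg)))
  t0 <- Sys.time()
  simDir <- file.path(cfg$outputDir, "simulate")
  arts <- list()

  if (stage == "simulate") {
    ph <- cfg$phantom; ph$seed <- seed
    r <- generatePhantom(ph)
    writeStack(r$stack, file.path(dir, "image.tif"))
    writeStack(r$truth@mito, file.path(dir, "mito_truth.tif"))
    saveRDS(r$truth, file.path(dir, "truth.rds"))
    arts <- list(image = file.path(dir, "image.tif"),
                 truth = file.path(dir, "truth.rds"))
  } else if (stage == "train-mito-detect") {
    truth <- readRDS(.needArtifact(file.path(simDir, "truth.rds"),
                                   "simulate"))
    stack <- readStack(file.path(simDir, "image.tif"))
    v <- voxels(stack); lab <- labels3d(truth@mito)
    samples <- lapply(seq_len(dim(v)[1]), function(z)
      list(image = v[z, , ], boxes = gtBoxesFromInstances(lab[z, , ])))
    samples <- Filter(function(s) nrow(s$boxes) > 0L, samples)
    tr <- trainMitoDetector(samples, cfg$detector,
                            cfg$training$detSteps, seed)
    saveRDS(tr$weights, file.path(dir, "det_weights.rds"))
    .logLine(dir, stage, "trained",
             list(finalLoss = mean(tail(tr$lossTrace, 20))))
    arts <- list(weights = file.path(dir, "det_weights.rds"))
  } else if (stage == "train-mito-seg") {
    truth <- readRDS(.needArtifact(file.path(simDir, "truth.rds"),
                                   "simulate"))
    detW <- readRDS(.needArtifact(
      file.path(cfg$outputDir, "train-mito-detect", "det_weights.rds"),
      "train-mito-detect"))
    stack <- readStack(file.path(simDir, "image.tif"))
    v <- voxels(stack); lab <- labels3d(truth@mito)
    slices <- lapply(seq_len(dim(v)[1]), function(z)
      list(image = v[z, , ], instances = lab[z, , ]))
    slices <- Filter(function(s) any(s$instances > 0L), slices)
    tr <- trainMitoSegmenter(slices, detW, cfg$segmenter,
                             cfg$training$segSteps, seed,
                             featCh = cfg$detector$channels$fpn)
    saveRDS(tr$weights, file.path(dir, "seg_weights.rds"))
    .logLine(dir, stage, "trained",
             list(finalLoss = mean(tail(tr$lossTrace, 20))))
    arts <- list(weights = file.path(dir, "seg_weights.rds"))
  } else if (stage == "train-er") {
    truth <- readRDS(.needArtifact(file.path(simDir, "truth.rds"),
                                   "simulate"))
    stack <- readStack(file.path(simDir, "image.tif"))
    v <- voxels(stack)
    cls <- array(0L, dim(v))
    cls[truth@er] <- 1L; cls[truth@nucMembrane] <- 2L
    samples <- lapply(seq_len(dim(v)[1]), function(z)
      list(image = v[z, , ], classes = cls[z, , ]))
    tr <- trainErNet(samples, cfg$er, cfg$training$erSteps, seed)
    saveRDS(tr$weights, file.path(dir, "er_weights.rds"))
    .logLine(dir, stage, "trained",
             list(finalLoss = mean(tail(tr$lossTrace, 20))))
    arts <- list(weights = file.path(dir, "er_weights.rds"))
  } else if (stage == "predict") {
    detW <- readRDS(.needArtifact(
      file.path(cfg$outputDir, "train-mito-detect", "det_weights.rds"),
      "train-mito-detect"))
    segW <- readRDS(.needArtifact(
      file.path(cfg$outputDir, "train-mito-seg", "seg_weights.rds"),
      "train-mito-seg"))
    stack <- readStack(.needArtifact(file.path(simDir, "image.tif"),
                                     "simulate"))
    pm <- predictMito(stack, detW, segW, cfg$detector, cfg$segmenter)
    saveRDS(pm, file.path(dir, "mito_pred.rds"))
    writeStack(LabelVolume(pm$instances), file.path(dir, "mito_instances.tif"))
    erWPath <- file.path(cfg$outputDir, "train-er", "er_weights.rds")
    if (file.exists(erWPath)) {
      erW <- readRDS(erWPath)
      cm <- predictEr(stack, erW)
      saveRDS(cm, file.path(dir, "er_classes.rds"))
    }
    arts <- list(mito = file.path(dir, "mito_pred.rds"))
  } else if (stage == "reconstruct") {
    predPath <- file.path(cfg$outputDir, "predict", "mito_pred.rds")
    if (file.exists(predPath)) {
      inst <- readRDS(predPath)$instances
    } else {
      # ground-truth shortcut: reconstruct directly from simulated truth
      truth <- readRDS(.needArtifact(file.path(simDir, "truth.rds"),
                                     "simulate"))
      inst <- labels3d(truth@mito)
    }
    rc <- cfg$reconstruct
    objs <- linkSlices(inst, rc$tau, rc$contain, rc$gap,
                       cfg$phantom$spacingNm)
    objs <- rectifyObjects(objs, dim(inst)[2:3])
    objs <- filterByLength(objs, rc$L)
    saveRDS(objs, file.path(dir, "objects.rds"))
    writeStack(objectsToLabelVolume(objs, dim(inst)),
               file.path(dir, "instances3d.tif"))
    jsonlite::write_json(summarizeObjects(objs),
                         file.path(dir, "objects.json"))
    arts <- list(objects = file.path(dir, "objects.rds"))
  } else if (stage == "measure") {
    objs <- readRDS(.needArtifact(
      file.path(cfg$outputDir, "reconstruct", "objects.rds"),
      "reconstruct"))
    truth <- readRDS(.needArtifact(file.path(simDir, "truth.rds"),
                                   "simulate"))
    dims <- dim(labels3d(truth@mito))
    tab <- measureObjects(objs, dims)
    utils::write.csv(tab, file.path(dir, "morphometry.csv"),
                     row.names = FALSE)
    erPath <- file.path(cfg$outputDir, "predict", "er_classes.rds")
    erMask <- if (file.exists(erPath)) readRDS(erPath) == 1L else truth@er
    recs <- list()
    if (any(erMask)) for (obj in objs) {
      recs[[length(recs) + 1L]] <- minDistance(
        objectMask(obj, dims), erMask, cfg$phantom$spacingNm,
        mitoId = obj@id)
    }
    if (length(recs) > 0L) {
      cs <- contactStats(recs)
      jsonlite::write_json(cs, file.path(dir, "contacts.json"),
                           auto_unbox = TRUE)
    }
    arts <- list(morphometry = file.path(dir, "morphometry.csv"))
  } else if (stage == "evaluate") {
    truth <- readRDS(.needArtifact(file.path(simDir, "truth.rds"),
                                   "simulate"))
    pm <- readRDS(.needArtifact(
      file.path(cfg$outputDir, "predict", "mito_pred.rds"), "predict"))
    rep <- evaluateSegmentation(pm$prob, labels3d(truth@mito) > 0L)
    jsonlite::write_json(rep[names(rep) != "undefined"],
                         file.path(dir, "metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    arts <- list(metrics = file.path(dir, "metrics.json"))
  }

  .logLine(dir, stage, "done",
           list(seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(arts)
}

#' Run several stages in order
#' @param stages character vector of stage names.
#' @param cfg a [runConfig()].
#' @export
runPipeline <- function(stages = c("simulate", "train-mito-detect",
                                   "train-mito-seg", "predict",
                                   "reconstruct", "measure", "evaluate"),
                        cfg = runConfig()) {
  for (s in stages) runStage(s, cfg)
  invisible(cfg$outputDir)
}
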