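# Batch orchestration: centralized configuration, per-frame processing
# chain, manifest-driven batch runs with incremental result writing.

#' Centralized pipeline configuration
#'
#' Every tunable parameter of every stage in one place. Unknown keys are
#' rejected (arguments are matched exactly), so a config file cannot
#' silently misspell a parameter.
#'
#' @param pixelSizeUm um per pixel edge of the input frames.
#' @param channelOrder TIFF page order, permutation of
#'   `c("nuclear", "neurite")`.
#' @param preprocess a [preprocessParams()] list.
#' @param plausibilityNuclear,plausibilityNeurite apply the area filter to
#'   the respective channel.
#' @param minPeakSeparationPx,hDepth watershed marker parameters.
#' @param upscaleFactor neurite-mask upscale factor before skeletonization.
#' @param epsilonPx skeleton pruning precision, in upscaled px.
#' @param somaRadiusPx soma distance-transform threshold (source px).
#' @param denominator per-cell denominator: `"nuclei"` or `"neurons"`.
#' @param controlCondition solvent-control compound label.
#' @param outputDir directory for result tables (`NULL`: don't write).
#' @param workerCount frames processed concurrently; results are merged in
#'   manifest order, so outputs are identical for any worker count.
#' @return named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(pixelSizeUm = DEFAULT_PIXEL_SIZE_UM,
                           channelOrder = c("nuclear", "neurite"),
                           preprocess = preprocessParams(),
                           plausibilityNuclear = TRUE,
                           plausibilityNeurite = TRUE,
                           minPeakSeparationPx = 10,
                           hDepth = 0.2,
                           upscaleFactor = 3L,
                           epsilonPx = 10,
                           somaRadiusPx = 8,
                           denominator = c("nuclei", "neurons"),
                           controlCondition = "DMSO",
                           outputDir = NULL,
                           workerCount = 1L) {
  denominator <- match.arg(denominator)
  structure(list(pixelSizeUm = pixelSizeUm, channelOrder = channelOrder,
                 preprocess = preprocess,
                 plausibilityNuclear = plausibilityNuclear,
                 plausibilityNeurite = plausibilityNeurite,
                 minPeakSeparationPx = minPeakSeparationPx, hDepth = hDepth,
                 upscaleFactor = as.integer(upscaleFactor),
                 epsilonPx = epsilonPx, somaRadiusPx = somaRadiusPx,
                 denominator = denominator,
                 controlCondition = controlCondition,
                 outputDir = outputDir,
                 workerCount = as.integer(workerCount)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [pipelineConfig()] arguments (with `preprocess` as a nested
#' map of [preprocessParams()] arguments). Unknown keys raise an error.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$preprocess)) {
    badp <- setdiff(names(y$preprocess), names(formals(preprocessParams)))
    if (length(badp))
      stop("unknown preprocess key(s): ", paste(badp, collapse = ", "))
    y$preprocess <- do.call(preprocessParams, y$preprocess)
  }
  if (!is.null(y$channelOrder)) y$channelOrder <- unlist(y$channelOrder)
  do.call(pipelineConfig, y)
}

#' Process one frame through the full analysis chain
#'
#' Preprocess both channels, split nuclei, identify neurons, drop orphan
#' neurite components, detect somata, upscale + skeletonize, clip the
#' skeleton at somata, and assemble the metrics row.
#'
#' @param frame a [MicrographFrame-class].
#' @param config a [pipelineConfig()].
#' @param keepIntermediates also return masks/skeleton (for QC overlays).
#' @return one-row metrics data.frame, or (with `keepIntermediates`) a
#'   list with `metrics` plus the intermediate objects.
#' @export
processFrame <- function(frame, config = pipelineConfig(),
                         keepIntermediates = FALSE) {
  cal <- frame@calibration
  nucMask <- preprocessChannel(frame@nuclearChannel, cal, config$preprocess,
                               config$plausibilityNuclear)
  neuMask <- preprocessChannel(frame@neuriteChannel, cal, config$preprocess,
                               config$plausibilityNeurite)
  nuclei <- splitTouchingNuclei(nucMask, config$minPeakSeparationPx,
                                config$hDepth)
  assignment <- identifyNeurons(nuclei, neuMask)
  neuMask <- removeOrphanComponents(neuMask, assignment, nuclei)
  somaMask <- detectSomata(neuMask, nuclei, config$somaRadiusPx)
  up <- upscaleMask(neuMask, config$upscaleFactor)
  skeleton <- skeletonizePropagated(up, config$epsilonPx)
  skeleton <- pruneSomaOverlap(skeleton, somaMask)
  metrics <- computeImageMetrics(frame, nuclei, assignment, somaMask,
                                 neuMask, skeleton, config$denominator)
  if (!keepIntermediates) return(metrics)
  list(metrics = metrics, nucleusMask = nucMask, neuriteMask = neuMask,
       nuclei = nuclei, assignment = assignment, somaMask = somaMask,
       skeleton = skeleton)
}

.excludedRow <- function(frameId, cond, reason) {
  out <- data.frame(frame_id = frameId,
                    experiment_id = as.character(cond$experimentId),
                    compound = as.character(cond$compound),
                    concentration_nM = as.numeric(cond$concentrationNM),
                    is_control = isTRUE(cond$isControl),
                    nuclei_count = NA_integer_, neuron_count = NA_integer_,
                    mean_nucleus_area_um2 = NA_real_,
                    total_soma_area_um2 = NA_real_,
                    soma_area_per_cell_um2 = NA_real_,
                    neurite_area_um2 = NA_real_,
                    total_neurite_length_um = NA_real_,
                    neurite_length_per_cell_um = NA_real_,
                    branch_point_count = NA_integer_,
                    endpoint_count = NA_integer_,
                    branch_segment_count = NA_integer_,
                    branches_per_cell = NA_real_,
                    excluded = TRUE, exclusion_reason = reason,
                    stringsAsFactors = FALSE)
  out[, METRIC_COLUMNS]
}

#' Run the pipeline over an experiment manifest
#'
#' Processes every manifest row independently (so results are identical
#' for any worker count and any row order), appending per-image rows to
#' `metrics.csv` as they complete when `outputDir` is set. A failing frame
#' is logged, flagged excluded and does not abort the batch. Afterwards
#' the metrics are normalized to the solvent control per experiment and
#' summarized per condition.
#'
#' @param config a [pipelineConfig()].
#' @param manifest data.frame (or CSV path) with columns `path`,
#'   `experiment_id`, `condition`, `concentration_nM`, `is_control`; a
#'   `compound` column is optional (derived from `condition` otherwise).
#' @param verbose log per-frame progress and wall time.
#' @return list with `metrics`, `normalized`, `summary` data.frames.
#' @export
runBatch <- function(config, manifest, verbose = FALSE) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest")
  need <- c("path", "experiment_id", "condition", "concentration_nM",
            "is_control")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(manifest$compound))
    manifest$compound <- sub("_[0-9.]+$", "", manifest$condition)
  manifest <- manifest[order(manifest$path), , drop = FALSE]  # order-independent
  cal <- NULL
  doOne <- function(i) {
    row <- manifest[i, ]
    cond <- list(compound = row$compound,
                 concentrationNM = row$concentration_nM,
                 isControl = isTRUE(as.logical(row$is_control)),
                 experimentId = row$experiment_id)
    t0 <- proc.time()[3]
    res <- tryCatch({
      pages <- tiff::readTIFF(row$path, as.is = TRUE)
      d <- dim(pages)
      frameCal <- Calibration(frameWidthPx = d[2], frameHeightPx = d[1],
                              pixelSizeUm = config$pixelSizeUm)
      frame <- readFrame(row$path, frameCal, cond,
                         channelOrder = config$channelOrder)
      processFrame(frame, config)
    }, error = function(e) {
      .excludedRow(sub("\\.[^.]*$", "", basename(row$path)), cond,
                   paste("processing failed:", conditionMessage(e)))
    })
    if (verbose)
      message(sprintf("[%d/%d] %s (%.2f s)%s", i, nrow(manifest),
                      res$frame_id, proc.time()[3] - t0,
                      if (res$excluded) " EXCLUDED" else ""))
    res
  }
  idx <- seq_len(nrow(manifest))
  outPath <- NULL
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    outPath <- file.path(config$outputDir, "metrics.csv")
    if (file.exists(outPath)) file.remove(outPath)
  }
  if (config$workerCount > 1L &&
      .Platform$OS.type == "unix") {
    rows <- parallel::mclapply(idx, doOne, mc.cores = config$workerCount)
    if (!is.null(outPath))
      for (r in rows) .appendMetricsRow(r, outPath)
  } else {
    rows <- vector("list", length(idx))
    for (i in idx) {
      rows[[i]] <- doOne(i)
      if (!is.null(outPath)) .appendMetricsRow(rows[[i]], outPath)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  normalized <- normalizeToControl(metrics, config$controlCondition)
  summary <- summarizeConditions(normalized)
  if (!is.null(config$outputDir)) {
    utils::write.csv(normalized,
                     file.path(config$outputDir, "normalized.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$outputDir, "summary.csv"),
                     row.names = FALSE)
  }
  list(metrics = metrics, normalized = normalized, summary = summary)
}

.appendMetricsRow <- function(row, path) {
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
}

#' Fit dose-response curves from a metrics table
#'
#' One constrained 4PL fit per compound, on the control-normalized
#' per-cell neurite length. Controls define the fixed top (their
#' normalized mean, 100% by construction) and are excluded from the fit.
#'
#' @param normalized normalized metrics (from [runBatch()] or
#'   [normalizeToControl()]).
#' @param metric normalized column to fit.
#' @return data.frame with one row per compound (LD50, hill, bottom, rss,
#'   converged).
#' @export
fitDoseResponse <- function(normalized,
                            metric = "neurite_length_per_cell_um_pct_control") {
  m <- normalized[!normalized$excluded & !normalized$is_control, ,
                  drop = FALSE]
  ctrl <- normalized[!normalized$excluded & normalized$is_control, ,
                     drop = FALSE]
  topValue <- mean(ctrl[[metric]])
  do.call(rbind, lapply(split(m, m$compound), function(g) {
    fit <- tryCatch(
      fitFourParamLogistic(g$concentration_nM, g[[metric]], topValue),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(compound = g$compound[1], ld50_nM = NA_real_,
                        hill = NA_real_, bottom = NA_real_, top = topValue,
                        rss = NA_real_, converged = FALSE))
    data.frame(compound = g$compound[1], ld50_nM = fit@ld50,
               hill = fit@hillSlope, bottom = fit@bottom, top = fit@top,
               rss = fit@rss, converged = fit@converged)
  }))
}
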