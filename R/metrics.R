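# Per-image morphological metrics and normalization to solvent control.

#' Column order of the per-image metrics table
#' @export
METRIC_COLUMNS <- c(
  "frame_id", "experiment_id", "compound", "concentration_nM", "is_control",
  "nuclei_count", "neuron_count", "mean_nucleus_area_um2",
  "total_soma_area_um2", "soma_area_per_cell_um2", "neurite_area_um2",
  "total_neurite_length_um", "neurite_length_per_cell_um",
  "branch_point_count", "endpoint_count", "branch_segment_count",
  "branches_per_cell", "excluded", "exclusion_reason")

#' Assemble all per-frame morphological readouts
#'
#' Combines the outputs of the preprocessing, nuclei, skeleton and soma
#' stages into one metrics row. Per-cell quantities divide by
#' `nuclei_count` (`denominator = "nuclei"`, the default, suited to
#' cultures where every cell is a neuron candidate) or by `neuron_count`
#' (`denominator = "neurons"`, the TH+ mode for mixed cultures). A zero
#' denominator sets `excluded` with a reason instead of erroring.
#'
#' @param frame the source [MicrographFrame-class] (identity + condition).
#' @param nucleiRegions [LabeledRegions-class].
#' @param assignment [NeuronAssignment-class].
#' @param somaMask soma [BinaryMask-class] at source scale.
#' @param neuriteMask cleaned neurite [BinaryMask-class] at source scale.
#' @param skeleton soma-pruned [NeuriteSkeleton-class].
#' @param denominator `"nuclei"` or `"neurons"`.
#' @return one-row data.frame with columns [METRIC_COLUMNS].
#' @export
computeImageMetrics <- function(frame, nucleiRegions, assignment, somaMask,
                                neuriteMask, skeleton,
                                denominator = c("nuclei", "neurons")) {
  denominator <- match.arg(denominator)
  cal <- frame@calibration
  meas <- measureRegions(nucleiRegions)
  st <- branchStatistics(skeleton)
  totalLen <- totalLengthUm(skeleton) + .tipExtensionUm(skeleton, somaMask)
  somaPx <- sum(somaMask@raster)
  effPx <- cal@pixelSizeUm / somaMask@scaleFactor
  somaArea <- somaPx * effPx^2
  denom <- if (denominator == "nuclei") meas$count else assignment@neuronCount
  excluded <- denom == 0L
  reason <- if (excluded) sprintf("zero denominator (%s)", denominator) else ""
  perCell <- function(x) if (excluded) NA_real_ else x / denom
  out <- data.frame(
    frame_id = frame@frameId,
    experiment_id = as.character(frame@condition$experimentId),
    compound = as.character(frame@condition$compound),
    concentration_nM = as.numeric(frame@condition$concentrationNM),
    is_control = isTRUE(frame@condition$isControl),
    nuclei_count = meas$count,
    neuron_count = assignment@neuronCount,
    mean_nucleus_area_um2 = meas$mean_area_um2,
    total_soma_area_um2 = somaArea,
    soma_area_per_cell_um2 = perCell(somaArea),
    neurite_area_um2 = neuriteAreaUm2(neuriteMask, somaMask, cal),
    total_neurite_length_um = totalLen,
    neurite_length_per_cell_um = perCell(totalLen),
    branch_point_count = st$branch_point_count,
    endpoint_count = st$endpoint_count,
    branch_segment_count = st$branch_segment_count,
    branches_per_cell = perCell(st$branch_point_count),
    excluded = excluded,
    exclusion_reason = reason,
    stringsAsFactors = FALSE)
  out[, METRIC_COLUMNS]
}

# The medial axis of a round-capped tube ends one cap radius short of the
# tube tip; reported neurite length therefore extends every free terminal
# (degree-1 endpoint away from the soma mask) by its endpoint's
# maximal-disk radius, bounded by twice the skeleton's median radius so
# wide structures cannot over-extend. Endpoints at the soma boundary are
# not extended: the length there is truncated deliberately.
.tipExtensionUm <- function(skeleton, somaMask) {
  bs <- skeleton@branches[lengths(skeleton@branches) >= 2L]
  if (length(bs) == 0L) return(0)
  ends <- unlist(lapply(bs, function(b) c(b[1], b[length(b)])),
                 use.names = FALSE)
  tab <- table(ends)
  tips <- as.integer(names(tab)[tab == 1L])
  if (length(tips) == 0L) return(0)
  f <- skeleton@scaleFactor / somaMask@scaleFactor
  soma <- somaMask@raster
  rows <- pmax(1L, pmin(nrow(soma),
                        as.integer(floor(skeleton@points$y[tips] / f)) + 1L))
  cols <- pmax(1L, pmin(ncol(soma),
                        as.integer(floor(skeleton@points$x[tips] / f)) + 1L))
  nearSoma <- vapply(seq_along(tips), function(i) {
    r0 <- max(1L, rows[i] - 2L); r1 <- min(nrow(soma), rows[i] + 2L)
    c0 <- max(1L, cols[i] - 2L); c1 <- min(ncol(soma), cols[i] + 2L)
    any(soma[r0:r1, c0:c1])
  }, logical(1))
  tips <- tips[!nearSoma]
  if (length(tips) == 0L) return(0)
  cap <- 2 * stats::median(skeleton@points$r)
  extPx <- pmin(skeleton@points$r[tips], cap)
  sum(extPx) / skeleton@scaleFactor * skeleton@calibration@pixelSizeUm
}

#' Normalize per-cell metrics to the solvent control
#'
#' Within each experiment, each chosen metric is divided by the mean of
#' that metric over the non-excluded control images and expressed as a
#' percentage, so the control-group mean maps to 100%. Excluded frames do
#' not contribute to control means and their normalized values are `NA`.
#'
#' @param metrics metrics table (rows as from [computeImageMetrics()]).
#' @param controlCondition control rows are those with `is_control`, or —
#'   if a label is given here — those whose `compound` equals it.
#' @param metricCols columns to normalize.
#' @return `metrics` with added `<col>_pct_control` columns.
#' @export
normalizeToControl <- function(metrics, controlCondition = NULL,
                               metricCols = c("neurite_length_per_cell_um",
                                              "branches_per_cell",
                                              "soma_area_per_cell_um2",
                                              "mean_nucleus_area_um2")) {
  metricCols <- intersect(metricCols, names(metrics))
  isCtrl <- if (is.null(controlCondition)) metrics$is_control
            else metrics$compound == controlCondition
  out <- metrics
  for (col in metricCols) out[[paste0(col, "_pct_control")]] <- NA_real_
  for (ex in unique(metrics$experiment_id)) {
    inEx <- metrics$experiment_id == ex
    ctrl <- inEx & isCtrl & !metrics$excluded
    if (!any(ctrl))
      stop("no usable control images in experiment '", ex, "'")
    for (col in metricCols) {
      ref <- mean(metrics[[col]][ctrl])
      sel <- inEx & !metrics$excluded
      out[[paste0(col, "_pct_control")]][sel] <-
        100 * metrics[[col]][sel] / ref
    }
  }
  out
}

#' Per-condition summary (mean, SEM, n)
#'
#' @param metrics (possibly normalized) metrics table.
#' @param cols columns to summarize.
#' @return data.frame with one row per compound x concentration per column.
#' @export
summarizeConditions <- function(metrics,
                                cols = grep("_pct_control$", names(metrics),
                                            value = TRUE)) {
  m <- metrics[!metrics$excluded, , drop = FALSE]
  key <- interaction(m$compound, m$concentration_nM, drop = TRUE)
  do.call(rbind, lapply(split(m, key), function(g) {
    do.call(rbind, lapply(cols, function(col) {
      v <- g[[col]][is.finite(g[[col]])]
      data.frame(compound = g$compound[1],
                 concentration_nM = g$concentration_nM[1],
                 metric = col, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                       else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
}
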