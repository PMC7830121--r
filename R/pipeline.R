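#' @include AllClasses.R
NULL

#' Build a pipeline configuration
#'
#' Collects the settings of a batch run into a validated
#' [RunConfig-class]. `maxLag`, `guessA` and `guessC` accept the string
#' `"auto"` (or `NA`) for the automatic per-file choices described in
#' [autoMaxLag()] and [fitExponential()].
#'
#' @param inputPaths character vector of input volumes, processed in the
#'   given order. An Analyze pair listed by both its `.hdr` and `.img`
#'   member is deduplicated (first occurrence kept).
#' @param varPath output `.var` parameter table.
#' @param ldpPath output discrimination-plot PNG.
#' @param componentLdpPath output component-plot PNG.
#' @param imageThreshold binarization threshold in \[0, 1\].
#' @param maxLag `"auto"` or a positive integer number of lags.
#' @param guessA,guessC `"auto"` or numeric starting estimates for the
#'   model fit.
#' @param plotWidth,plotHeight PNG pixel dimensions.
#' @param varioPostfix postfix for per-file variogram plot names.
#' @param varioDir directory for per-file variogram plots (default: the
#'   directory of `varPath`).
#' @return a [RunConfig-class].
#' @seealso [runPipeline()]
#' @export
ldpConfig <- function(inputPaths, varPath, ldpPath, componentLdpPath,
                      imageThreshold = 0.5, maxLag = "auto",
                      guessA = "auto", guessC = "auto",
                      plotWidth = 1200, plotHeight = 900,
                      varioPostfix = "_variograms.png",
                      varioDir = NA_character_) {
  asAuto <- function(x) {
    if (is.character(x)) {
      if (!identical(tolower(x), "auto"))
        stop("expected a number or \"auto\", got \"", x, "\"")
      return(NA_real_)
    }
    as.numeric(x)
  }
  inputPaths <- .dedupeAnalyzePairs(as.character(inputPaths))
  new("RunConfig",
      inputPaths = inputPaths,
      varPath = varPath, ldpPath = ldpPath,
      componentLdpPath = componentLdpPath,
      imageThreshold = as.numeric(imageThreshold),
      maxLag = asAuto(maxLag),
      guessA = asAuto(guessA), guessC = asAuto(guessC),
      plotWidth = as.numeric(plotWidth),
      plotHeight = as.numeric(plotHeight),
      varioPostfix = varioPostfix,
      varioDir = varioDir)
}

.dedupeAnalyzePairs <- function(paths) {
  stem <- ifelse(grepl("\\.(hdr|img)$", paths, ignore.case = TRUE),
                 sub("\\.(hdr|img)$", "", paths, ignore.case = TRUE),
                 paths)
  paths[!duplicated(stem)]
}

#' Run the full discrimination-plot pipeline
#'
#' Reproduces the batch flow over a list of lesion masks: each input
#' file is loaded, binarized, its three directional empirical
#' variograms are computed, an exponential model is fitted per
#' direction, the log-scale summary is appended to the `.var` container
#' file and a per-file variogram plot is written. Files that fail
#' (unreadable or non-3D volume, empty mask, non-converged fit) are
#' logged and skipped without aborting the batch. After the loop the
#' discrimination plot and its component plot are rendered from the
#' `.var` file on disk, not from in-memory state, so they reflect
#' exactly what was persisted.
#'
#' Processing is fully deterministic: the same inputs and configuration
#' produce byte-identical `.var` files.
#'
#' @param config a [RunConfig-class] from [ldpConfig()].
#' @param quiet suppress per-file progress messages.
#' @return invisibly, a data frame summarizing the run: one row per
#'   input with its assigned ID (`NA` when skipped), status
#'   (`"ok"`/`"skipped"`), reason and the variogram-plot path written.
#' @examples
#' td <- tempdir()
#' ins <- vapply(1:2, function(i) {
#'   m <- ellipsoidScene(c(24, 24, 24), 4, c(2, 2, 4), seed = i)
#'   writeMask(m, file.path(td, sprintf("scene%d.nii", i)))
#'   file.path(td, sprintf("scene%d.nii", i))
#' }, "")
#' cfg <- ldpConfig(ins, file.path(td, "demo.var"),
#'                  file.path(td, "demo_LDP.png"),
#'                  file.path(td, "demo_LDP_xyz.png"))
#' rep <- runPipeline(cfg, quiet = TRUE)
#' readVarFile(file.path(td, "demo.var"))
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  missing <- !file.exists(config@inputPaths)
  if (any(missing))
    stop("input file(s) not found: ",
         paste(config@inputPaths[missing], collapse = ", "))
  if (file.exists(config@varPath))
    file.remove(config@varPath)
  varioDir <- if (is.na(config@varioDir)) dirname(config@varPath)
              else config@varioDir

  say <- function(...) if (!quiet) message(...)
  n <- length(config@inputPaths)
  status <- character(n); reason <- character(n)
  ids <- rep(NA_integer_, n); plots <- rep(NA_character_, n)
  nextId <- 1L

  for (i in seq_len(n)) {
    path <- config@inputPaths[i]
    say(sprintf("[%d/%d] %s", i, n, basename(path)))
    res <- tryCatch({
      vol <- loadVolume(path)
      mask <- binarize(vol, config@imageThreshold)
      if (mask@lesionVoxelCount == 0L)
        stop("mask is empty after thresholding (no lesion voxels)")
      maxLag <- if (is.na(config@maxLag)) autoMaxLag(mask@spacing)
                else as.integer(config@maxLag)
      emps <- variogramsXYZ(mask, maxLag)
      gA <- if (is.na(config@guessA)) NULL else config@guessA
      gC <- if (is.na(config@guessC)) NULL else config@guessC
      fits <- lapply(emps, fitExponential, guessA = gA, guessC = gC)
      rec <- ldpSummary(fits, id = nextId, filename = basename(path))
      appendVarRecord(config@varPath, rec)
      pPath <- file.path(varioDir,
                         paste0(basename(path), config@varioPostfix))
      plotVariograms(emps, fits, pPath,
                     width = config@plotWidth,
                     height = config@plotHeight)
      say(sprintf("    a(x,y,z) = %s mm; c(x,y,z) = %s",
                  paste(sprintf("%.3f", vapply(fits, modelRange,
                                               numeric(1))),
                        collapse = "/"),
                  paste(sprintf("%.3g", vapply(fits, modelSill,
                                               numeric(1))),
                        collapse = "/")))
      list(ok = TRUE, plot = pPath)
    }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    if (res$ok) {
      status[i] <- "ok"; reason[i] <- ""
      ids[i] <- nextId; plots[i] <- res$plot
      nextId <- nextId + 1L
    } else {
      status[i] <- "skipped"; reason[i] <- res$msg
      say("    skipped: ", res$msg)
    }
  }

  if (!file.exists(config@varPath))
    stop("no processable inputs: every file was skipped (",
         paste(unique(reason[nzchar(reason)]), collapse = "; "), ")")
  tab <- readVarFile(config@varPath)
  plotLDP(tab, config@ldpPath,
          width = config@plotWidth, height = config@plotHeight)
  plotComponentLDP(tab, config@componentLdpPath,
                   width = config@plotWidth, height = config@plotHeight)
  say(sprintf("wrote %s (%d record(s)), %s, %s", config@varPath,
              nrow(tab), config@ldpPath, config@componentLdpPath))
  invisible(data.frame(input = config@inputPaths, id = ids,
                       status = status, reason = reason,
                       varioPlot = plots, stringsAsFactors = FALSE))
}
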