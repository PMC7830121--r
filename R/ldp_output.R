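#' @include AllClasses.R
NULL

.VAR_HEADER <- c("ID", "ln(avg(a[xyz]))", "ln(avg(C[xyz]))",
                 "ln(aX)", "ln(CX)", "ln(aY)", "ln(CY)",
                 "ln(az)", "ln(CZ)", "File")

.DIR_COLS <- c(x = "red", y = "green", z = "blue")

.recordToRow <- function(record) {
  paste(c(record@id,
          sprintf("%.5f", c(record@lnMeanA, record@lnMeanC,
                            record@lnA[["x"]], record@lnC[["x"]],
                            record@lnA[["y"]], record@lnC[["y"]],
                            record@lnA[["z"]], record@lnC[["z"]])),
          record@filename),
        collapse = "\t")
}

#' Append one LDP record to a `.var` container file
#'
#' The `.var` container is a tab-delimited ASCII table, one header line
#' plus one row per processed mask, numeric fields serialized with 5
#' decimal places (ASCII hyphen-minus for negatives). If the file does
#' not exist the header is written first.
#'
#' @param path path of the `.var` file.
#' @param record an [LDPRecord-class].
#' @return `path`, invisibly.
#' @seealso [readVarFile()]
#' @export
appendVarRecord <- function(path, record) {
  stopifnot(is(record, "LDPRecord"))
  newFile <- !file.exists(path)
  con <- tryCatch(file(path, open = "at"),
                  error = function(e) stop("cannot write to ", path,
                                           ": ", conditionMessage(e)))
  on.exit(close(con))
  if (newFile)
    writeLines(paste(.VAR_HEADER, collapse = "\t"), con)
  writeLines(.recordToRow(record), con)
  invisible(path)
}

#' Read a `.var` container file
#'
#' Parses a container file written by [appendVarRecord()] (or
#' hand-edited in the same dialect) into a data frame with one row per
#' lesion pattern and columns `ID`, `lnMeanA`, `lnMeanC`, `lnAX`,
#' `lnCX`, `lnAY`, `lnCY`, `lnAZ`, `lnCZ`, `File`. Malformed rows are
#' reported with their line numbers; IDs must run 1..n in file order.
#'
#' @param path path of the `.var` file.
#' @return a data frame (the variogram-parameter table).
#' @export
readVarFile <- function(path) {
  if (!file.exists(path))
    stop("no such .var file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !identical(strsplit(lines[1], "\t",
                                            fixed = TRUE)[[1]],
                                   .VAR_HEADER))
    stop("missing header in ", path,
         " (expected the 10-column .var header line)")
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L))
    stop("malformed row(s) in ", path, " at line(s) ",
         paste(which(nf != 10L) + 1L, collapse = ", "),
         ": expected 10 tab-separated columns, got ",
         paste(unique(nf[nf != 10L]), collapse = "/"))
  tab <- data.frame(
    ID = as.integer(vapply(fields, `[`, "", 1L)),
    do.call(rbind, lapply(fields, function(f) as.numeric(f[2:9]))),
    File = vapply(fields, `[`, "", 10L),
    stringsAsFactors = FALSE)
  names(tab)[2:9] <- c("lnMeanA", "lnMeanC", "lnAX", "lnCX",
                       "lnAY", "lnCY", "lnAZ", "lnCZ")
  badNum <- which(!stats::complete.cases(tab[2:9]) | is.na(tab$ID))
  if (length(badNum))
    stop("non-numeric field(s) in ", path, " at line(s) ",
         paste(badNum + 1L, collapse = ", "))
  if (nrow(tab) && !identical(tab$ID, seq_len(nrow(tab))))
    stop("IDs in ", path, " are not consecutive 1..n in file order")
  tab
}

.openPng <- function(path, width, height) {
  grDevices::png(path, width = width, height = height)
}

#' Per-mask variogram plot
#'
#' Renders the three directional empirical variograms (dots) with their
#' fitted exponential models (curves) into one PNG. Red/green/blue
#' encode the x/y/z directions; a square marks the (range, sill) point
#' of each fitted model and an annotation box lists the parameters.
#'
#' @param emps named list of three [EmpiricalVariogram-class] objects
#'   (x, y, z), as from [variogramsXYZ()].
#' @param fits list of the three matching [ExpModelFit-class] objects.
#' @param outPath output PNG path.
#' @param width,height image size in pixels.
#' @return `outPath`, invisibly.
#' @export
plotVariograms <- function(emps, fits, outPath, width = 1200,
                           height = 900) {
  if (length(emps) != 3L || length(fits) != 3L)
    stop("need three empirical variograms and three fits (x, y, z)")
  dirs <- vapply(emps, lagDirection, character(1))
  names(emps) <- dirs
  names(fits) <- vapply(fits, lagDirection, character(1))
  if (!setequal(dirs, c("x", "y", "z")))
    stop("variograms must cover the x, y and z directions")
  xmax <- max(vapply(emps, function(e) max(e@distances), numeric(1)))
  ymax <- max(c(vapply(emps, function(e) max(e@gamma), numeric(1)),
                vapply(fits, function(f)
                  if (isTRUE(f@converged)) f@c else 0, numeric(1))))
  if (ymax <= 0) ymax <- 1e-6
  .openPng(outPath, width, height)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1.05 * ymax),
                 xlab = "Distance [mm]", ylab = expression(gamma),
                 main = "Directional empirical variograms and fitted exponential models")
  hh <- seq(0, xmax, length.out = 200)
  ann <- character(0)
  for (d in c("x", "y", "z")) {
    e <- emps[[d]]; f <- fits[[d]]
    graphics::points(e@distances, e@gamma, pch = 16,
                     col = .DIR_COLS[[d]])
    if (isTRUE(f@converged)) {
      graphics::lines(hh, exponentialModel(hh, f@a, f@c),
                      col = .DIR_COLS[[d]], lwd = 2)
      graphics::points(f@a, f@c, pch = 0, cex = 1.6,
                       col = .DIR_COLS[[d]])
      ann <- c(ann, sprintf("%s: a = %.3f mm, c = %.3g", d, f@a, f@c))
    } else {
      ann <- c(ann, sprintf("%s: fit not converged", d))
    }
  }
  graphics::legend("bottomright", legend = ann, text.col = .DIR_COLS,
                   bty = "o", title = "Exponential model")
  invisible(outPath)
}

.checkSpan <- function(xs, ys, xlim, ylim, what) {
  out <- xs < min(xlim) | xs > max(xlim) | ys < min(ylim) | ys > max(ylim)
  if (any(out))
    warning(sum(out), " ", what,
            " point(s) fall outside the configured axis span; drawn anyway")
  invisible(NULL)
}

#' Component discrimination plot (per-direction parameters)
#'
#' For each lesion pattern in the table, draws three squares — red,
#' green, blue for the x, y, z directions — at (ln a_dir, ln c_dir),
#' labelled with the pattern ID. Axes default to the standardized spans
#' ln(a) in \[0, 3\] and ln(c) in \[-12, -4\]; points outside the span
#' are drawn anyway with a warning.
#'
#' @param table data frame from [readVarFile()].
#' @param outPath output PNG path.
#' @param width,height image size in pixels.
#' @param xlim,ylim axis spans on the ln scale.
#' @param symbolSize,textSize relative symbol and label sizes.
#' @return `outPath`, invisibly.
#' @export
plotComponentLDP <- function(table, outPath, width = 1200, height = 900,
                             xlim = c(0, 3), ylim = c(-12, -4),
                             symbolSize = 1.4, textSize = 1.0) {
  if (!nrow(table))
    stop("empty variogram-parameter table: nothing to plot")
  aCols <- c(x = "lnAX", y = "lnAY", z = "lnAZ")
  cCols <- c(x = "lnCX", y = "lnCY", z = "lnCZ")
  .checkSpan(unlist(table[aCols]), unlist(table[cCols]), xlim, ylim,
             "component")
  .openPng(outPath, width, height)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "ln(a)  [spatial continuity]",
                 ylab = "ln(c)  [lesion-load proxy]",
                 main = "Component lesion pattern discrimination plot")
  graphics::par(xpd = NA)  # out-of-span points stay visible
  for (d in c("x", "y", "z")) {
    graphics::points(table[[aCols[[d]]]], table[[cCols[[d]]]],
                     pch = 15, cex = symbolSize, col = .DIR_COLS[[d]])
    graphics::text(table[[aCols[[d]]]], table[[cCols[[d]]]],
                   labels = table$ID, pos = 4, cex = textSize)
  }
  graphics::legend("topright", legend = c("x", "y", "z"), pch = 15,
                   col = .DIR_COLS, title = "Direction")
  invisible(outPath)
}

#' Lesion pattern discrimination plot
#'
#' One labelled point per lesion pattern at (ln(mean a), ln(mean c)) —
#' the log of the arithmetic mean over the three directions, as stored
#' in the table. Same standardized axes as [plotComponentLDP()].
#'
#' @inheritParams plotComponentLDP
#' @return `outPath`, invisibly.
#' @export
plotLDP <- function(table, outPath, width = 1200, height = 900,
                    xlim = c(0, 3), ylim = c(-12, -4),
                    symbolSize = 1.6, textSize = 1.1) {
  if (!nrow(table))
    stop("empty variogram-parameter table: nothing to plot")
  .checkSpan(table$lnMeanA, table$lnMeanC, xlim, ylim, "LDP")
  .openPng(outPath, width, height)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "ln(mean a)  [spatial continuity]",
                 ylab = "ln(mean c)  [lesion-load proxy]",
                 main = "Lesion pattern discrimination plot")
  graphics::par(xpd = NA)
  graphics::points(table$lnMeanA, table$lnMeanC, pch = 16,
                   cex = symbolSize, col = "black")
  graphics::text(table$lnMeanA, table$lnMeanC, labels = table$ID,
                 pos = 4, cex = textSize)
  invisible(outPath)
}
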