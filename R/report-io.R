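#' Write a report bundle to disk
#'
#' Emits one JSON summary (`summary.json`: config echo with seeds,
#' per-threshold token counts and vocabulary sizes, fitted exponents,
#' collapse overlap scores, log) plus tidy CSVs: `events_theta<t>.csv` per
#' threshold and `curves.csv` with all law curves in long format
#' (`lawId`, `theta`, `x`, `y`, `xRescaled`, `yRescaled`).
#'
#' @param bundle a `ReportBundle` from [runPipeline()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeReportBundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ReportBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  summary <- list(
    config = bundle$config,
    perTheta = lapply(bundle$perTheta, function(p) {
      if (isTRUE(p$empty))
        list(theta = p$theta, empty = TRUE, reason = p$reason)
      else list(theta = p$theta, empty = FALSE,
                nTokens = nrow(p$events@tokens),
                nSilences = nrow(p$events@silences),
                resolvedEnergy = p$events@threshold@resolvedEnergy,
                V = p$V, L = p$L, typeTokenRatio = p$typeTokenRatio)
    }),
    exponents = bundle$exponents,
    overlapScores = lapply(bundle$collapse, function(cl) cl$overlapScore),
    log = bundle$log)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  paths <- c(paths, p)
  curveRows <- list()
  for (law in names(bundle$collapse)) {
    for (cv in bundle$collapse[[law]]$curves)
      curveRows[[length(curveRows) + 1]] <- curveData(cv)
  }
  if (length(curveRows)) {
    p <- file.path(dir, "curves.csv")
    write.csv(do.call(rbind, curveRows), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (pt in bundle$perTheta) {
    if (isTRUE(pt$empty) || is.null(pt$events)) next
    p <- file.path(dir, sprintf("events_theta%g.csv", pt$theta))
    write.csv(eventTable(pt$events), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
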