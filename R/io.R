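# Readers/writers for the standard on-disk formats: multi-frame TIFF
# movies, CSV trial tables, and CSV trace/response tables.

#' Read a multi-frame TIFF movie
#'
#' @param path TIFF file path.
#' @param frameRate acquisition rate in Hz (TIFFs rarely store it).
#' @return A [CalciumMovie-class].
#' @export
readMovieTiff <- function(path, frameRate = 15) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF movies")
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  frames <- array(0, c(length(imgs), dim(imgs[[1]])[1], dim(imgs[[1]])[2]))
  for (i in seq_along(imgs)) frames[i, , ] <- imgs[[i]]
  calciumMovie(frames, frameRate)
}

#' Write a movie as multi-frame TIFF
#'
#' Intensities are rescaled to [0, 1] over the whole stack (the TIFF
#' writer's expected range); QC flags are not stored.
#'
#' @param movie a [CalciumMovie-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeMovieTiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF movies")
  rng <- range(movie@frames)
  den <- if (diff(rng) > 0) diff(rng) else 1
  imgs <- lapply(seq_len(nFrames(movie)), function(i)
    (movie@frames[i, , ] - rng[1]) / den)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  invisible(path)
}

#' Read / write a trial table as CSV
#'
#' Columns: onset_s, stimulus, block, shutter_close_s, shutter_open_s and
#' any extra light-timing columns.
#'
#' @param path CSV file path.
#' @return A [TrialTable-class].
#' @export
readTrialTable <- function(path) {
  new("TrialTable", trials = utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readTrialTable
#' @param x a [TrialTable-class].
#' @export
writeTrialTable <- function(x, path) {
  stopifnot(is(x, "TrialTable"))
  utils::write.csv(x@trials, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a trace set as CSV
#'
#' Cells as rows; the sampling rate is stored in a leading comment line.
#'
#' @param path CSV file path.
#' @return A [TraceSet-class].
#' @export
readTraceSet <- function(path) {
  first <- readLines(path, n = 1)
  rate <- as.numeric(sub("^# frameRate=", "", first))
  m <- as.matrix(utils::read.csv(path, comment.char = "#", header = FALSE))
  dimnames(m) <- NULL
  traceSet(m, rate)
}

#' @rdname readTraceSet
#' @param x a [TraceSet-class].
#' @export
writeTraceSet <- function(x, path) {
  stopifnot(is(x, "TraceSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frameRate=%g", x@frameRate), con)
  utils::write.table(x@traces, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
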