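#' @include methods.R
NULL

#' Read fluorescence traces from delimited text
#'
#' Reads CSV/TSV files with one column per trace (optional header).  The
#' frame rate must be supplied (or a frame interval).  Raw-count traces can
#' be baseline-normalized to relative units with \code{normalize = TRUE},
#' which divides by the per-trace 10th percentile:
#' \eqn{F/F_0} with \eqn{F_0} = percentile 10 (so the model's resting
#' baseline is about 1).
#'
#' @param path file path (delimiter inferred from the extension: .tsv/.txt
#'   = tab, otherwise comma).
#' @param rate frame rate (Hz); alternatively \code{dt}.
#' @param dt frame interval (s).
#' @param header does the file carry a header row? Auto-detected by
#'   default.
#' @param normalize divide each trace by its 10th percentile.
#' @return a list of [FluoTrace-class] objects, one per column.
#' @export
readTrace <- function(path, rate = NULL, dt = NULL, header = NA,
                      normalize = FALSE) {
  if (is.null(rate) && is.null(dt))
    stop("a frame rate (or frame interval) is required")
  if (is.null(dt)) dt <- 1 / rate
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1)
  if (is.na(header)) {
    cells <- strsplit(first, sep, fixed = TRUE)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(cells))))
  }
  d <- utils::read.table(path, sep = sep, header = header,
                         stringsAsFactors = FALSE)
  lapply(seq_len(ncol(d)), function(j) {
    v <- d[[j]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (any(is.na(v2) & !is.na(v)))
        stop("non-numeric cells in column ", j)
      v <- v2
    }
    if (any(is.na(v))) stop("missing values in column ", j)
    if (normalize) {
      f0 <- as.numeric(stats::quantile(v, 0.10))
      if (f0 <= 0) stop("non-positive baseline percentile in column ", j)
      v <- v / f0
    }
    fluoTrace(v, dt = dt)
  })
}

#' Write traces to delimited text
#'
#' @param traces a [FluoTrace-class] or list of them (equal lengths).
#' @param path output file (.tsv/.txt for tab, else comma).
#' @return the path, invisibly.
#' @export
writeTrace <- function(traces, path) {
  if (is(traces, "FluoTrace")) traces <- list(traces)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  m <- do.call(cbind, lapply(traces, function(tr) tr@values))
  colnames(m) <- paste0("trace", seq_len(ncol(m)))
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write spike times as plain text
#'
#' One spike time (seconds, 6 decimal places) per line.
#'
#' @param spikes a [SpikeTrain-class], [MapResult-class] or numeric times.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSpikes <- function(spikes, path) {
  writeLines(sprintf("%.6f", spikeTimes(spikes)), path)
  invisible(path)
}

#' Read spike times from plain text
#'
#' @param path file with one spike time (s) per line.
#' @return a [SpikeTrain-class].
#' @export
readSpikes <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  v <- suppressWarnings(as.numeric(lines))
  if (any(is.na(v))) stop("non-numeric spike times in ", path)
  spikeTrain(v)
}

#' Serialize model parameters to a list / JSON
#'
#' @param params a [ModelParams-class].
#' @return a named list of parameter values.
#' @export
paramsToList <- function(params) {
  nm <- slotNames(params)
  out <- lapply(nm, function(s) slot(params, s))
  names(out) <- nm
  out
}

#' Model parameters from a list (inverse of [paramsToList()])
#'
#' @param x a named list; unknown names are an error.
#' @return a [ModelParams-class].
#' @export
paramsFromList <- function(x) {
  bad <- setdiff(names(x), slotNames("ModelParams"))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  do.call(modelParams, x)
}

#' Read a JSON run configuration
#'
#' A configuration holds a \code{mode}, optional \code{params} (see
#' [paramsFromList()]), optional \code{control} overrides (see
#' [spikeControl()]), and free fields such as \code{seed}, \code{rate},
#' \code{duration}.
#'
#' @param path JSON file path.
#' @return a list with \code{params} and \code{control} materialized.
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(cfg$params)) cfg$params <- paramsFromList(cfg$params)
  if (!is.null(cfg$control)) cfg$control <- do.call(spikeControl, cfg$control)
  cfg
}

#' Write a run manifest
#'
#' Records everything needed to replay a run: mode, parameters, control
#' settings, seed and package version, as JSON.
#'
#' @param path output file.
#' @param mode run mode string.
#' @param params optional [ModelParams-class].
#' @param control optional control list.
#' @param seed optional seed.
#' @param extra extra named fields.
#' @return the path, invisibly.
#' @export
writeManifest <- function(path, mode, params = NULL, control = NULL,
                          seed = NULL, extra = list()) {
  man <- c(list(mode = mode,
                package = "spikegrid",
                version = as.character(utils::packageVersion("spikegrid"))),
           if (!is.null(params)) list(params = paramsToList(params)),
           if (!is.null(control)) list(control = control[
             !vapply(control, is.null, TRUE)]),
           if (!is.null(seed)) list(seed = seed),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write inference results to files
#'
#' Spike times go to \code{<stem>_spikes.txt} (plain text, seconds); the
#' latent path and fit to \code{<stem>_path.csv}; spike-probability
#' matrices to \code{<stem>_proba.csv}; a JSON manifest to
#' \code{<stem>_manifest.json}.
#'
#' @param result a [MapResult-class], [SpikePosterior-class] or list of
#'   sample trains from [samplePosterior()].
#' @param stem output path stem.
#' @param params,control,seed recorded in the manifest.
#' @return character vector of written paths, invisibly.
#' @export
writeResults <- function(result, stem, params = NULL, control = NULL,
                         seed = NULL) {
  paths <- character(0)
  if (is(result, "MapResult")) {
    p <- paste0(stem, "_spikes.txt")
    writeSpikes(result, p); paths <- c(paths, p)
    path <- latentPath(result)
    d <- data.frame(time = (seq_along(result@fit) - 1) * result@dt,
                    fit = result@fit, calcium = path@calcium,
                    baseline = path@baseline)
    p <- paste0(stem, "_path.csv")
    utils::write.csv(d, p, row.names = FALSE); paths <- c(paths, p)
    mode <- "map"
  } else if (is(result, "SpikePosterior")) {
    d <- data.frame(time = (seq_len(nrow(result@spikeMarginals)) - 1) *
                      result@dt,
                    expected = result@expected, result@spikeMarginals)
    p <- paste0(stem, "_proba.csv")
    utils::write.csv(d, p, row.names = FALSE); paths <- c(paths, p)
    mode <- "proba"
  } else if (is.list(result) && !is.null(result$trains)) {
    for (r in seq_along(result$trains)) {
      p <- sprintf("%s_sample%03d.txt", stem, r)
      writeSpikes(result$trains[[r]], p); paths <- c(paths, p)
    }
    mode <- "samples"
  } else stop("unsupported result type")
  p <- paste0(stem, "_manifest.json")
  writeManifest(p, mode, params, control, seed)
  invisible(c(paths, p))
}
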