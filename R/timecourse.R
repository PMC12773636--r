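#' Construct a replicated time course
#'
#' Container for replicated growth/fermentation series: an optical-density
#' channel (\code{od600}) plus metabolite concentration channels in mM, all on
#' one shared, strictly increasing time grid (hours).
#'
#' @param time Numeric vector of hours, strictly increasing.
#' @param channels Named list of numeric matrices, one per channel
#'   (\code{od600} or a registered compound name), each with
#'   \code{length(time)} rows and one column per replicate. Vectors are
#'   accepted for single-replicate data. \code{NA} marks unmeasured points.
#' @param condition Free-text condition label (substrate, inhibitor, ...).
#' @param registry Compound registry used to validate channel names.
#' @return An object of class \code{timecourse}.
#' @seealso [read_timecourse()], [summarize_timecourse()]
#' @export
timecourse <- function(time, channels, condition = "", registry = compounds()) {
  stopifnot(is.numeric(time), length(time) >= 1L)
  if (any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (length(channels) == 0L) stop("at least one channel required", call. = FALSE)
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("channels must be named", call. = FALSE)
  }
  channels <- lapply(channels, function(x) {
    if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
    storage.mode(x) <- "double"
    x
  })
  nrep <- unique(vapply(channels, ncol, integer(1)))
  if (length(nrep) != 1L) {
    stop("all channels must have the same replicate count", call. = FALSE)
  }
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (nrow(ch) != length(time)) {
      stop("channel '", nm, "' does not match the time grid", call. = FALSE)
    }
    if (any(ch < 0, na.rm = TRUE)) {
      bad <- which(ch < 0, arr.ind = TRUE)[1, ]
      stop("negative value in channel '", nm, "' at row ", bad[1],
           ", replicate ", bad[2], call. = FALSE)
    }
    if (nm != "od600" && !nm %in% registry$name) {
      stop("channel '", nm, "' is not a registered compound", call. = FALSE)
    }
  }
  structure(list(time = as.numeric(time), channels = channels,
                 replicate_count = nrep, condition = condition),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("Time course", if (nzchar(x$condition)) paste0(" [", x$condition, "]"),
      ": ", length(x$time), " timepoints, ", x$replicate_count,
      " replicate(s)\n", sep = "")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Read a replicated time-course table
#'
#' Reads the package's wide layout: a \code{time} column followed by
#' \code{<channel>_rep<k>} columns (a bare \code{<channel>} column is taken as
#' a single replicate). Decimal separator is a dot; encoding UTF-8.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator, \code{","} (default) or \code{"\t"}.
#' @param condition Condition label to attach; defaults to the file name.
#' @param registry Compound registry for channel validation.
#' @return A [timecourse()] object.
#' @export
read_timecourse <- function(path, sep = ",", condition = NULL,
                            registry = compounds()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!"time" %in% names(df)) {
    stop("missing 'time' column in ", path, call. = FALSE)
  }
  time <- df$time
  if (any(diff(time) <= 0)) {
    stop("non-monotone time in ", path, " (row ",
         which(diff(time) <= 0)[1] + 1L, ")", call. = FALSE)
  }
  cols <- setdiff(names(df), "time")
  base <- sub("_rep[0-9]+$", "", cols)
  channels <- list()
  for (ch in unique(base)) {
    sub <- cols[base == ch]
    reps <- suppressWarnings(as.integer(sub("^.*_rep", "", sub)))
    sub <- sub[order(ifelse(is.na(reps), 1L, reps))]
    m <- as.matrix(df[sub])
    for (j in seq_along(sub)) {
      neg <- which(m[, j] < 0)
      if (length(neg)) {
        stop("negative concentration in column '", sub[j], "', row ", neg[1],
             call. = FALSE)
      }
    }
    dimnames(m) <- NULL
    channels[[ch]] <- m
  }
  timecourse(time, channels,
             condition = if (is.null(condition)) basename(path) else condition,
             registry = registry)
}

#' Write a time course in the wide CSV layout
#'
#' Inverse of [read_timecourse()]: \code{time} column plus
#' \code{<channel>_rep<k>} columns.
#'
#' @param tc A [timecourse()] object.
#' @param path Output path.
#' @param sep Field separator.
#' @param digits Significant digits written (round-trip is exact to this
#'   precision).
#' @return \code{path}, invisibly.
#' @export
write_timecourse <- function(tc, path, sep = ",", digits = 10) {
  stopifnot(inherits(tc, "timecourse"))
  out <- data.frame(time = tc$time, check.names = FALSE)
  for (nm in names(tc$channels)) {
    ch <- tc$channels[[nm]]
    for (j in seq_len(ncol(ch))) {
      out[[paste0(nm, "_rep", j)]] <- signif(ch[, j], digits)
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-timepoint mean and standard error of a channel
#'
#' Summarizes replicates as mean +/- SEM, the presentation convention for
#' N = 3 biological replicates. SEM uses the sample (n-1) standard deviation
#' divided by the square root of the number of non-missing replicates; with a
#' single replicate the SEM is reported as 0. Missing values are dropped
#' per timepoint (gas channels are often sparsely sampled).
#'
#' @param tc A [timecourse()] object.
#' @param channel Channel name (\code{"od600"} or a metabolite).
#' @return A data frame of class \code{summary_series} with columns
#'   \code{time}, \code{mean}, \code{sem}.
#' @examples
#' tc <- timecourse(0:2, list(od600 = cbind(c(1, 2, 4), c(1, 2, 4))))
#' summarize_timecourse(tc, "od600")
#' @export
summarize_timecourse <- function(tc, channel) {
  stopifnot(inherits(tc, "timecourse"))
  if (!channel %in% names(tc$channels)) {
    stop("unknown channel '", channel, "'", call. = FALSE)
  }
  m <- tc$channels[[channel]]
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  sdv <- apply(m, 1L, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 1, sdv / sqrt(n), 0)
  sem[n == 0] <- NA_real_
  structure(data.frame(time = tc$time, mean = mu, sem = sem),
            class = c("summary_series", "data.frame"), channel = channel)
}
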