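#' Read and write the package's plain-text interchange formats
#'
#' Hypnograms travel as TSV (`epoch_index`, `zt_seconds`, `state`,
#' `artifact`), spectra as TSV with a bin-frequency header row, activity
#' as CSV (`timestamp_min`, `counts`, `condition`, `intensity`) and
#' expression as gene-by-sample TSV whose second line is a `#group`
#' comment carrying the sample group labels.
#'
#' @param hyp,frames,series,matrix objects to serialize.
#' @param path file path.
#' @name somnostat-io
NULL

#' @rdname somnostat-io
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch_index = hyp$epoch, zt_seconds = hyp$zt_sec,
                   state = as.character(hyp$state),
                   artifact = as.integer(hyp$artifact))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname somnostat-io
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  hyp <- data.frame(epoch = df$epoch_index, zt_sec = df$zt_seconds,
                    state = factor(df$state, levels = c("W", "N", "R")),
                    artifact = as.logical(df$artifact))
  if (any(is.na(hyp$state))) stop("invalid states in ", path,
                                  call. = FALSE)
  if (nrow(hyp) > 1 && !all(diff(hyp$zt_sec) == 4)) {
    stop("hypnogram epochs must be contiguous 4-s epochs", call. = FALSE)
  }
  structure(hyp, epoch_s = 4L, class = c("hypnogram", "data.frame"))
}

#' @rdname somnostat-io
#' @export
write_spectra <- function(frames, path) {
  stopifnot(inherits(frames, "spectral_frame"))
  m <- cbind(epoch = seq_len(nrow(frames$power)), frames$power)
  colnames(m) <- c("epoch", format(frames$freq_hz, digits = 10))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname somnostat-io
#' @export
read_spectra <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  freq <- as.numeric(colnames(df)[-1])
  structure(list(power = as.matrix(df[, -1, drop = FALSE]),
                 freq_hz = freq, epoch_s = 4L, sample_hz = 250L),
            class = "spectral_frame")
}

#' @rdname somnostat-io
#' @export
write_activity <- function(series, path) {
  df <- data.frame(timestamp_min = series$minute, counts = series$counts,
                   condition = series$condition,
                   intensity = series$intensity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname somnostat-io
#' @export
read_activity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(data.frame(minute = df$timestamp_min, counts = df$counts,
                       condition = df$condition,
                       intensity = df$intensity),
            class = c("activity_series", "data.frame"))
}

#' @rdname somnostat-io
#' @export
write_expression <- function(matrix, path) {
  groups <- attr(matrix, "groups")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  if (!is.null(groups)) {
    writeLines(paste(c("#group", as.character(groups)), collapse = "\t"),
               con)
  }
  utils::write.table(cbind(gene_id = rownames(matrix), matrix), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname somnostat-io
#' @export
read_expression <- function(path) {
  lines <- readLines(path, n = 2L)
  header <- strsplit(lines[1], "\t")[[1]]
  has_groups <- startsWith(lines[2], "#group")
  df <- utils::read.table(path, sep = "\t", skip = if (has_groups) 2L else
    1L, header = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- header[-1]
  if (has_groups) {
    attr(m, "groups") <- factor(strsplit(lines[2], "\t")[[1]][-1])
  }
  m
}
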