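#' Write / read a trace matrix as CSV
#'
#' Rows are cells, columns are frames; the header row holds the frame times
#' in seconds and the first column the cell ids.
#'
#' @param traces Matrix (cells x frames) with frame-time column names.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  df <- data.frame(cell_id = rownames(traces), traces, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @return `read_trace_csv()`: the trace matrix.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (anyNA(as.numeric(colnames(m)))) {
    stop("trace CSV header must hold frame times in seconds", call. = FALSE)
  }
  m
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Reading delegates to [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(s) {
    paste(c(s, s, gene_sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a stimulation protocol as YAML
#'
#' @param protocol A [stimulation_protocol()].
#' @param path YAML file path.
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  obj <- list(stimuli = as.list(protocol$stimuli),
              duration = protocol$duration,
              baseline_window = protocol$baseline_window,
              rebaseline_length = protocol$rebaseline_length)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  stimuli <- unlist(obj$stimuli)
  stimulation_protocol(stimuli, duration = obj$duration,
                       baseline_window = unlist(obj$baseline_window),
                       rebaseline_length = obj$rebaseline_length)
}
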