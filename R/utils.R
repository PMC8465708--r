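# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hdc <- function(..., class = "hdcminer_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_hdc(what, " is missing required column(s): ",
             paste(missing, collapse = ", "),
             class = "hdcminer_validation_error")
  }
  invisible(df)
}

#' Write a tab-separated report
#'
#' Thin wrapper around [utils::write.table()] using the conventions every
#' report in this package follows: tab separator, header line, no quoting,
#' no row names.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_strict <- function(path, what) {
  if (!file.exists(path)) {
    stop_hdc(what, " file not found: ", path,
             class = "hdcminer_validation_error")
  }
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "", check.names = FALSE)
}
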