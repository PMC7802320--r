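#' Write a carrier matrix to TSV
#' @param carriers A `carrier_matrix`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_carrier_matrix <- function(carriers, path) {
  df <- data.frame(sample_id = rownames(carriers$carriers),
                   carriers$carriers, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a carrier matrix from TSV
#' @param path TSV written by [write_carrier_matrix()].
#' @param dsv_info Optional deletion metadata table to attach.
#' @return A `carrier_matrix`.
#' @export
read_carrier_matrix <- function(path, dsv_info = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  storage.mode(x) <- "integer"
  structure(list(carriers = x,
                 dsv = dsv_info %||% data.frame(dsv_id = colnames(x))),
            class = "carrier_matrix")
}

#' Write a JSON filter report
#' @param filtered Output of [filter_deletions()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(filtered, path) {
  rep <- list(n_kept = nrow(filtered$dsvs$info),
              rejections = as.list(filtered$tally),
              params = unclass(filtered$params))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write an association result table to TSV
#' @param res An `association_result` data.frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_association_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
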