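# Chemical-shift tables and cross-peak lists: light data-frame wrappers with
# validation and TSV I/O.

#' Construct a chemical-shift table
#'
#' One row per assigned atom: `resid`, `restype`, `atom`, `element`, `shift`
#' (ppm).  Exactly one shift per atom is enforced.
#'
#' @param df data frame with the columns above (`element` inferred if absent).
#' @param keep_attrs keep extra attributes of `df` (internal use).
#' @return an object of class `shift_table` (a data frame).
#' @export
shift_table <- function(df, keep_attrs = FALSE) {
  need <- c("resid", "atom", "shift")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("shift table missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$element)) df$element <- infer_element(df$atom)
  if (is.null(df$restype)) df$restype <- "UNK"
  if (any(!is.finite(df$shift))) stop("shifts must be finite")
  if (anyDuplicated(paste(df$resid, df$atom)))
    stop("duplicate shift entries: one shift per atom required")
  out <- df[, c("resid", "restype", "atom", "element", "shift")]
  if (keep_attrs)
    attr(out, "degenerate_pairs") <- attr(df, "degenerate_pairs")
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Read / write shift tables as TSV
#' @param path file path.
#' @return [shift_table()] for the reader; `path` invisibly for the writer.
#' @export
read_shift_table <- function(path) {
  shift_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_shift_table
#' @param shifts a `shift_table`.
#' @export
write_shift_table <- function(shifts, path) {
  utils::write.table(as.data.frame(shifts), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct a cross-peak list
#'
#' One row per observed cross peak: `peak_id`, observed shifts `w1`, `w2`
#' (ppm; dimension 1 and 2), `experiment` tag (CORD, PAIN-CP, NCACX, NCOCX),
#' `mixing_ms`, optional `intensity`.
#'
#' @param df data frame with the columns above.
#' @return an object of class `peak_list` (a data frame).
#' @export
peak_list <- function(df) {
  need <- c("peak_id", "w1", "w2", "experiment")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak list missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$mixing_ms)) df$mixing_ms <- NA_real_
  if (is.null(df$intensity)) df$intensity <- NA_real_
  out <- df[, c("peak_id", "w1", "w2", "experiment", "mixing_ms", "intensity")]
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Read / write peak lists as TSV
#' @param path file path.
#' @return [peak_list()] for the reader; `path` invisibly for the writer.
#' @export
read_peak_list <- function(path) {
  peak_list(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_peak_list
#' @param peaks a `peak_list`.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
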