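#' Ordinal response matrices
#'
#' A response matrix holds respondent-by-item ordinal codes aligned to an
#' [item_bank].  Codes are 0-based internally: an item with k options takes
#' values 0 ... k-1.  Missing responses are `NA` and are preserved; all
#' downstream pairwise statistics use pairwise deletion.
#'
#' @param values integer matrix (respondents x items) with `NA` for missing;
#'   column names must match `bank$id`.
#' @param bank the [item_bank] the columns refer to.
#' @param respondent_ids optional respondent identifiers.
#' @return An object of class `response_matrix`: a list with elements
#'   `values`, `bank`, `respondent_ids`.
#' @export
response_matrix <- function(values, bank, respondent_ids = NULL) {
  bank <- validate_item_bank(bank)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    if (ncol(values) != nrow(bank))
      stop("unnamed response columns must match the bank item count")
    colnames(values) <- bank$id
  }
  unknown <- setdiff(colnames(values), bank$id)
  if (length(unknown)) stop("unknown item id(s) in responses: ",
                            paste(unknown, collapse = ", "))
  values <- values[, bank$id[bank$id %in% colnames(values)], drop = FALSE]
  storage.mode(values) <- "integer"
  for (j in seq_len(ncol(values))) {
    k <- bank$n_options[match(colnames(values)[j], bank$id)]
    v <- values[, j]
    bad <- which(!is.na(v) & (v < 0L | v >= k))
    if (length(bad)) {
      stop(sprintf(
        "response code %d out of range [0, %d] for item '%s' (row %d)",
        v[bad[1L]], k - 1L, colnames(values)[j], bad[1L]))
    }
  }
  if (is.null(respondent_ids)) respondent_ids <- as.character(seq_len(nrow(values)))
  rownames(values) <- respondent_ids
  structure(list(values = values,
                 bank = bank[match(colnames(values), bank$id), , drop = FALSE],
                 respondent_ids = respondent_ids),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix:", nrow(x$values), "respondents x",
      ncol(x$values), "items;",
      sum(is.na(x$values)), "missing cells\n")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Read and write ordinal responses as CSV
#'
#' The CSV has a header row of item ids and one row per respondent.  Codes
#' may be stored 0-based or 1-based in the file (`index_base`); internally
#' they are always 0-based.  Empty cells and the token `"NA"` are missing.
#'
#' @param path CSV file path.
#' @param bank [item_bank] used to validate ids and category ranges.
#' @param index_base 0 or 1: the lowest category code used in the file.
#' @return A [response_matrix].
#' @export
read_responses <- function(path, bank, index_base = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(index_base %in% c(0L, 1L))
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA"),
                        colClasses = "integer")
  vals <- as.matrix(df) - as.integer(index_base)
  response_matrix(vals, bank)
}

#' @rdname read_responses
#' @param rm a [response_matrix].
#' @export
write_responses <- function(rm, path, index_base = 0L) {
  stopifnot(inherits(rm, "response_matrix"), index_base %in% c(0L, 1L))
  out <- as.data.frame(rm$values + as.integer(index_base))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Flag items that cannot be fitted
#'
#' An item is degenerate when fewer than 2 distinct categories are observed
#' (after dropping missing values): it then has no estimable threshold.
#'
#' @param rm a [response_matrix].
#' @return Named logical vector, `TRUE` for degenerate items.
#' @export
degenerate_items <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  apply(rm$values, 2L, function(v) length(unique(v[!is.na(v)])) < 2L)
}

#' Subset a response matrix by item id
#' @param rm a [response_matrix].
#' @param items item ids to keep, in order.
#' @return A [response_matrix] on the selected items.
#' @export
subset_items <- function(rm, items) {
  stopifnot(inherits(rm, "response_matrix"))
  missing_it <- setdiff(items, colnames(rm$values))
  if (length(missing_it)) stop("item(s) not in responses: ",
                               paste(missing_it, collapse = ", "))
  response_matrix(rm$values[, items, drop = FALSE],
                  rm$bank[match(items, rm$bank$id), , drop = FALSE],
                  rm$respondent_ids)
}
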