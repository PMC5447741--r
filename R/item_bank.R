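#' Item banks
#'
#' An item bank is the metadata table behind every analysis: one row per
#' item with its identifier, display label, source scale, RRE domain, number
#' of response options, and whether the item belongs to the reference (base)
#' scale whose thresholds define the gap-detection baseline.
#'
#' @param id character vector of unique item identifiers.
#' @param label display labels; defaults to `id`.
#' @param source source scale, one of [red_sources()].
#' @param domain construct domain, one of [red_domains()].
#' @param n_options number of response options per item (k >= 2); an item
#'   with k options has k - 1 thresholds.
#' @param is_reference logical; `TRUE` for the items of the base scale.
#' @return An object of class `item_bank`: a data frame with the columns
#'   above, one row per item.
#' @examples
#' bank <- item_bank(id = c("red1", "red2"), n_options = 5,
#'                   is_reference = c(TRUE, FALSE))
#' bank
#' @export
item_bank <- function(id, label = id, source = "OTHER",
                      domain = "OUT_OF_DOMAIN", n_options = 5L,
                      is_reference = FALSE) {
  id <- as.character(id)
  if (length(id) == 0L) stop("item bank must contain at least one item")
  if (anyDuplicated(id)) {
    stop("duplicate item id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  n <- length(id)
  bank <- data.frame(
    id = id,
    label = rep_len(as.character(label), n),
    source = rep_len(as.character(source), n),
    domain = rep_len(as.character(domain), n),
    n_options = rep_len(as.integer(n_options), n),
    is_reference = rep_len(as.logical(is_reference), n),
    stringsAsFactors = FALSE
  )
  validate_item_bank(bank)
}

#' @rdname item_bank
#' @export
red_sources <- function() {
  c("RED9", "BES", "TFEQ", "DEBQ", "YFAS", "PFS", "FCQTR", "PEMS", "EI",
    "OTHER")
}

#' @rdname item_bank
#' @export
red_domains <- function() {
  c("LOSS_OF_CONTROL", "LACK_OF_SATIETY", "PREOCCUPATION", "OUT_OF_DOMAIN")
}

validate_item_bank <- function(bank) {
  stopifnot(is.data.frame(bank))
  need <- c("id", "label", "source", "domain", "n_options", "is_reference")
  miss <- setdiff(need, names(bank))
  if (length(miss)) stop("item bank lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(bank) == 0L) stop("item bank must contain at least one item")
  if (anyDuplicated(bank$id)) {
    stop("duplicate item id(s): ",
         paste(unique(bank$id[duplicated(bank$id)]), collapse = ", "))
  }
  bad <- !bank$source %in% red_sources()
  if (any(bad)) stop("unknown source for item ", bank$id[bad][1L], ": ",
                     bank$source[bad][1L])
  bad <- !bank$domain %in% red_domains()
  if (any(bad)) stop("unknown domain for item ", bank$id[bad][1L], ": ",
                     bank$domain[bad][1L])
  bad <- is.na(bank$n_options) | bank$n_options < 2L
  if (any(bad)) stop("item ", bank$id[bad][1L],
                     " has fewer than 2 response options")
  if (anyNA(bank$is_reference)) stop("is_reference must be TRUE/FALSE")
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank:", nrow(x), "items (",
      sum(x$is_reference), "reference,",
      sum(!x$is_reference), "candidate )\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read and write item banks
#'
#' Item banks are stored as JSON or YAML: an array of objects, each with
#' fields `id`, `label`, `source`, `domain`, `n_options`, `is_reference`.
#' The format is chosen from the file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path file path.
#' @return `read_item_bank()` returns a validated [item_bank];
#'   `write_item_bank()` returns `path` invisibly.
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  if (length(raw) == 0L) stop("item bank file is empty: ", path)
  rows <- lapply(raw, function(it) {
    if (is.null(it$id)) stop("item bank entry lacks an id in ", path)
    data.frame(
      id = as.character(it$id),
      label = as.character(it$label %||% it$id),
      source = as.character(it$source %||% "OTHER"),
      domain = as.character(it$domain %||% "OUT_OF_DOMAIN"),
      n_options = as.integer(it$n_options %||% 5L),
      is_reference = isTRUE(it$is_reference),
      stringsAsFactors = FALSE
    )
  })
  validate_item_bank(do.call(rbind, rows))
}

#' @rdname read_item_bank
#' @param bank an [item_bank].
#' @export
write_item_bank <- function(bank, path) {
  bank <- validate_item_bank(bank)
  items <- lapply(seq_len(nrow(bank)), function(i) {
    list(id = bank$id[i], label = bank$label[i], source = bank$source[i],
         domain = bank$domain[i], n_options = bank$n_options[i],
         is_reference = bank$is_reference[i])
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(items, path)
  } else {
    jsonlite::write_json(items, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
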