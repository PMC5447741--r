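#' Write a threshold/gap report as TSV
#'
#' One row per estimated threshold (item id, source, domain, reference flag,
#' threshold index, location), items ordered by the average of their
#' thresholds' values, followed by a gap section (one row per gap interval:
#' lower, upper, width).  The two sections are separated by a line starting
#' with `# gaps`.
#'
#' @param map a [threshold_map].
#' @param gaps a `gap_set` on the same metric.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(map, gaps, path) {
  stopifnot(inherits(map, "threshold_map"), inherits(gaps, "gap_set"))
  items <- map$items[order(map$items$mean_threshold), , drop = FALSE]
  rows <- do.call(rbind, lapply(items$id, function(id) {
    th <- map$thresholds[[id]]
    info <- items[items$id == id, ]
    data.frame(item = id, source = info$source, domain = info$domain,
               is_reference = info$is_reference,
               threshold_index = seq_along(th), location = th,
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("# gaps", con)
  utils::write.table(
    data.frame(lower = gaps$lower, upper = gaps$upper, width = gaps$width),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back the threshold section of a report
#' @param path report path from [write_threshold_report()].
#' @return List with data frames `thresholds` and `gaps`.
#' @export
read_threshold_report <- function(path) {
  lines <- readLines(path)
  cut <- grep("^# gaps", lines)
  th <- utils::read.delim(text = lines[seq_len(cut - 1L)])
  gp <- utils::read.delim(text = lines[(cut + 1L):length(lines)])
  list(thresholds = th, gaps = gp)
}

#' Render a person-item (Wright) map
#'
#' Draws the joint display of person locations and item severities: a
#' histogram of person locations on top, one row per item below with a
#' circle at each threshold, items ordered by mean threshold, and shaded
#' rectangles over the coverage gaps left by the reference scale.  A
#' machine-readable JSON sidecar (`<out_path>.json`) records the plotted
#' thresholds and gap bounds so downstream checks never parse the image.
#'
#' @param map a [threshold_map] with at least one item and person locations.
#' @param gaps a `gap_set`.
#' @param out_path PNG output path.
#' @param width,height device size in pixels.
#' @return `out_path`, invisibly.
#' @export
render_person_item_map <- function(map, gaps, out_path, width = 900,
                                   height = 700) {
  stopifnot(inherits(map, "threshold_map"))
  if (!nrow(map$items)) stop("empty threshold map")
  grDevices::png(out_path, width = width, height = height)
  on.exit(grDevices::dev.off())
  draw_person_item_map(map, gaps)
  sidecar <- list(
    items = lapply(stats::setNames(map$items$id, map$items$id), function(id)
      list(thresholds = map$thresholds[[id]],
           is_reference = map$items$is_reference[map$items$id == id])),
    gaps = if (nrow(gaps)) {
      lapply(seq_len(nrow(gaps)), function(g)
        list(lower = gaps$lower[g], upper = gaps$upper[g],
             type = gaps$type[g]))
    } else list(),
    n_persons = length(map$persons)
  )
  jsonlite::write_json(sidecar, paste0(out_path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_path)
}

draw_person_item_map <- function(map, gaps) {
  items <- map$items[order(map$items$mean_threshold), , drop = FALSE]
  all_th <- unlist(map$thresholds)
  xlim <- range(c(all_th, map$persons,
                  if (nrow(gaps)) c(gaps$lower, gaps$upper)))
  xlim <- xlim + c(-0.2, 0.2) * diff(xlim)
  old <- graphics::par(mfrow = c(2, 1), mar = c(0.5, 9, 2, 1))
  on.exit(graphics::par(old))
  if (length(map$persons)) {
    graphics::hist(map$persons, breaks = 30, xlim = xlim, main = "",
                   xlab = "", col = "gray80", border = "white")
    graphics::title("Person locations on the latent trait")
  } else {
    graphics::plot.new()
  }
  graphics::par(mar = c(4, 9, 0.5, 1))
  n <- nrow(items)
  graphics::plot.new()
  graphics::plot.window(xlim = xlim, ylim = c(0.5, n + 0.5))
  if (nrow(gaps))
    graphics::rect(gaps$lower, 0.5, gaps$upper, n + 0.5,
                   col = grDevices::gray(0.85), border = NA)
  for (q in seq_len(n)) {
    id <- items$id[q]
    th <- map$thresholds[[id]]
    graphics::segments(min(th), q, max(th), q, col = "gray60")
    graphics::points(th, rep(q, length(th)), pch = 21,
                     bg = if (items$is_reference[q]) "black" else "white")
  }
  graphics::axis(1)
  graphics::axis(2, at = seq_len(n), labels = items$id, las = 2,
                 cex.axis = 0.7)
  graphics::mtext("Latent trait (normal units)", side = 1, line = 2.5)
  graphics::box()
}

#' @describeIn render_person_item_map `plot()` method for fitted models:
#'   builds the threshold map and gap set from the fit and draws the map on
#'   the active device.
#' @param x a `red_cfa`.
#' @param criterion a [gap_criterion]; trait range defaults to the person
#'   range padded by 0.25.
#' @param ... unused.
#' @export
plot.red_cfa <- function(x, criterion = NULL, ...) {
  map <- threshold_map(x)
  if (is.null(criterion)) {
    rng <- if (length(map$persons)) default_trait_range(map) else c(-3, 3)
    criterion <- gap_criterion(trait_range = rng)
  }
  ref <- sort(unlist(map$thresholds[map$items$id[map$items$is_reference]]))
  if (!length(ref)) ref <- sort(unlist(map$thresholds))
  gaps <- find_gaps(ref, criterion)
  draw_person_item_map(map, gaps)
  invisible(list(map = map, gaps = gaps))
}
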