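# Tabular file formats.
#
# Quantification tables use an IRIS-like dialect: tab-separated, metadata
# lines prefixed with '#', required columns row, column, size, opacity. One
# file per (plate, timepoint); the timepoint is carried both in the filename
# and in a '#time_h=' header. Halo scores are plain CSV. Layout sets are
# serialized as JSON.

parse_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- sub("=.*$", "", body)
      meta[[key]] <- sub("^[^=]*=", "", body)
    }
  }
  meta
}

#' Read an IRIS-style colony quantification table
#'
#' One row per detected spot. Spots missing at a timepoint (not detected by
#' the image analysis) are simply absent from the file; they stay absent from
#' the joined time series.
#'
#' @param path Path to a tab-delimited quantification file.
#' @param time_h Imaging time in hours; if `NULL`, taken from the `#time_h=`
#'   header (an error if neither is available).
#' @return data.frame with columns `plate_id`, `position`, `row`, `column`,
#'   `time_h`, `size`, `opacity`, plus an `array_format` attribute.
#' @export
read_quant_table <- function(path, time_h = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- parse_meta(lines[is_meta])
  if (is.null(time_h)) {
    if (is.null(meta$time_h)) stop(path, ": no time_h argument and no #time_h= header")
    time_h <- as.numeric(meta$time_h)
  }
  array_format <- if (!is.null(meta$array_format)) as.integer(meta$array_format) else NA_integer_
  plate_id <- if (!is.null(meta$plate_id)) meta$plate_id else NA_character_

  body_idx <- which(!is_meta & nzchar(lines))
  if (length(body_idx) == 0L) stop(path, ": no header line")
  header <- strsplit(lines[body_idx[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("row", "column", "size", "opacity")
  if (!all(need %in% header)) {
    stop(path, ": header must declare columns ", paste(need, collapse = ", "))
  }
  data_idx <- body_idx[-1L]
  n <- length(data_idx)
  out <- data.frame(plate_id = rep(plate_id, n), position = character(n),
                    row = integer(n), column = integer(n),
                    time_h = rep(time_h, n), size = numeric(n),
                    opacity = numeric(n))
  col_of <- match(need, header)
  for (i in seq_len(n)) {
    lineno <- data_idx[i]
    fields <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < length(header)) {
      stop(path, ": line ", lineno, ": expected ", length(header),
           " fields, got ", length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields[col_of]))
    if (anyNA(vals)) {
      stop(path, ": line ", lineno, ": non-numeric value in ",
           paste(need[is.na(vals)], collapse = ", "))
    }
    if (vals[1L] != round(vals[1L]) || vals[2L] != round(vals[2L])) {
      stop(path, ": line ", lineno, ": row/column must be integers")
    }
    out$row[i] <- as.integer(vals[1L])
    out$column[i] <- as.integer(vals[2L])
    out$size[i] <- vals[3L]
    out$opacity[i] <- vals[4L]
  }
  dup <- duplicated(out[c("row", "column")])
  if (any(dup)) {
    stop(path, ": duplicate (row, column) entries: ",
         paste(pos_label(out$row[dup], out$column[dup]), collapse = ", "))
  }
  out$position <- pos_label(out$row, out$column)
  attr(out, "array_format") <- array_format
  out
}

#' Write an IRIS-style colony quantification table
#'
#' @param x data.frame with columns `row`, `column`, `size`, `opacity`.
#' @param path Output path.
#' @param plate_id,array_format,time_h Metadata written as '#key=value'
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path, plate_id, array_format, time_h) {
  stopifnot(all(c("row", "column", "size", "opacity") %in% names(x)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# IRIS-like colony quantification table",
               paste0("#plate_id=", plate_id),
               paste0("#array_format=", as.integer(array_format)),
               paste0("#time_h=", format(time_h, digits = 10)),
               "row\tcolumn\tsize\topacity"), con)
  writeLines(sprintf("%d\t%d\t%.10g\t%.10g", as.integer(x$row),
                     as.integer(x$column), x$size, x$opacity), con)
  invisible(path)
}

#' Read or write qualitative inhibition-halo scores
#'
#' Halo scores are qualitative (presence/absence of a visible inhibition zone
#' around a spot on the yeast lawn): one record per (plate, position, target),
#' `antifungal` coded 0/1.
#'
#' @param path CSV path with columns `plate_id`, `position`, `target`,
#'   `antifungal`.
#' @return data.frame with `antifungal` as logical.
#' @export
read_halo_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "position", "target", "antifungal")
  if (!all(need %in% names(x))) {
    stop(path, ": halo table must have columns ", paste(need, collapse = ", "))
  }
  if (!all(x$antifungal %in% c(0L, 1L))) {
    stop(path, ": 'antifungal' must be 0/1")
  }
  if (anyDuplicated(x[c("plate_id", "position", "target")])) {
    stop(path, ": duplicate (plate_id, position, target) records")
  }
  x$antifungal <- as.logical(x$antifungal)
  x[need]
}

#' @rdname read_halo_table
#' @param x data.frame with columns `plate_id`, `position`, `target`,
#'   `antifungal` (logical or 0/1).
#' @export
write_halo_table <- function(x, path) {
  need <- c("plate_id", "position", "target", "antifungal")
  stopifnot(all(need %in% names(x)))
  x <- x[need]
  x$antifungal <- as.integer(x$antifungal)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize plate layouts to and from JSON
#'
#' @param layouts Named list of [plate_layout()] objects.
#' @param path JSON path.
#' @return `read_layouts()` returns a named list of `plate_layout` objects;
#'   the write/read round trip is exact.
#' @export
write_layouts <- function(layouts, path) {
  payload <- lapply(layouts, function(l) {
    list(plate_id = l$plate_id, array_format = l$array_format,
         medium = l$medium, role = l$role, occupants = l$occupants,
         quadrant_of = as.list(l$quadrant_of), target_yeast = l$target_yeast)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_layouts
#' @export
read_layouts <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  layouts <- lapply(payload, function(p) {
    quad <- if (length(p$quadrant_of)) unlist(p$quadrant_of) else NULL
    plate_layout(p$plate_id, p$array_format, p$medium, p$role,
                 occupants = lapply(p$occupants, function(o) unlist(o)),
                 quadrant_of = quad, target_yeast = p$target_yeast)
  })
  names(layouts) <- vapply(layouts, `[[`, "", "plate_id")
  layouts
}
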