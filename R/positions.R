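# Array geometry helpers shared by every module.
#
# Positions are labelled letter-row / number-column ("B7"); internally we use
# 1-based (row, col) integer indices. Supported formats are the robotic
# standards: 96 (8 x 12) and 384 (16 x 24).

array_dims <- function(array_format) {
  switch(as.character(as.integer(array_format)),
    "96"  = c(rows = 8L,  cols = 12L),
    "384" = c(rows = 16L, cols = 24L),
    stop("unsupported array format: ", array_format, " (expected 96 or 384)")
  )
}

#' Position labels of a colony array
#'
#' @param array_format Array density, 96 or 384.
#' @return Character vector of position labels in row-major order
#'   ("A1", "A2", ...).
#' @export
all_positions <- function(array_format) {
  d <- array_dims(array_format)
  as.vector(t(outer(LETTERS[seq_len(d[["rows"]])], seq_len(d[["cols"]]), paste0)))
}

#' Convert between position labels and (row, col) indices
#'
#' @param row,col 1-based integer indices.
#' @return `pos_label()` returns labels such as "B7"; `pos_parse()` returns a
#'   data.frame with integer columns `row` and `col`.
#' @export
pos_label <- function(row, col) {
  stopifnot(all(row >= 1L), all(col >= 1L))
  paste0(LETTERS[row], col)
}

#' @rdname pos_label
#' @param label Character vector of position labels.
#' @export
pos_parse <- function(label) {
  m <- regmatches(label, regexec("^([A-P])([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed position label(s): ", paste(label[bad], collapse = ", "))
  }
  data.frame(
    row = match(vapply(m, `[`, "", 2L), LETTERS),
    col = as.integer(vapply(m, `[`, "", 3L))
  )
}

#' Border flag for array positions
#'
#' A position is a border position iff it lies in the outermost row or column
#' of the array. Border spots grow atypically (more nutrient access) and are
#' excluded from replicate-noise (MSD) estimation.
#'
#' @param row,col 1-based indices, or `row` may be a character vector of
#'   position labels (then `col` is ignored).
#' @param array_format Array density, 96 or 384.
#' @return Logical vector.
#' @export
is_border_position <- function(row, col = NULL, array_format) {
  if (is.character(row)) {
    p <- pos_parse(row)
    row <- p$row
    col <- p$col
  }
  d <- array_dims(array_format)
  row == 1L | row == d[["rows"]] | col == 1L | col == d[["cols"]]
}

# Quadrant offsets for 96 -> 384 condensation (interleaved): quadrant q of a
# 96-array well (r, c) lands on 384-array position (2(r-1) + dr + 1,
# 2(c-1) + dc + 1).
quadrant_offset <- function(q) {
  stopifnot(q %in% 1:4)
  list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))[[q]]
}

# 384-array labels of quadrant q, one entry per 96-array well, row-major.
quadrant_positions <- function(q) {
  off <- quadrant_offset(q)
  d <- array_dims(96)
  idx <- expand.grid(col = seq_len(d[["cols"]]), row = seq_len(d[["rows"]]))
  pos_label(2L * (idx$row - 1L) + off[1L] + 1L, 2L * (idx$col - 1L) + off[2L] + 1L)
}
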