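# Plate layouts and the MSP/RSP position-pairing model.
#
# The screening design condenses four distinct 96-array preculture plates into
# one 384-array Main Source Plate (MSP), and replicates each single 96-array
# plate into the four quadrants of a 384-array Replicate Source Plate (RSP,
# four replicate spots per isolate). Replicating an RSP on top of the MSP
# yields an interaction plate whose every position carries two isolates; the
# individual reference values for a pair are read from the *same* position of
# the MSP and the RSP, which cancels positional bias.

PLATE_ROLES <- c("preculture", "main_source", "replicate_source",
                 "interaction", "antifungal_lawn", "growth_control")
TARGET_YEASTS <- c("K_lactis", "C_boidinii", "S_cerevisiae")

#' Construct a plate layout
#'
#' @param plate_id Plate identifier.
#' @param array_format Array density, 96 or 384.
#' @param medium Culture medium identifier (e.g. "LM17", "PCA", "SALN").
#' @param role One of "preculture", "main_source", "replicate_source",
#'   "interaction", "antifungal_lawn", "growth_control".
#' @param occupants Named list mapping position labels to a character vector
#'   of isolate ids: length 1 on single-isolate plates, exactly 2 on
#'   interaction plates (a self pair repeats the same id). Positions without
#'   an entry are unoccupied.
#' @param quadrant_of Optional named character vector mapping positions to the
#'   source 96-array plate id they were condensed from.
#' @param target_yeast Optional target yeast, only meaningful for
#'   antifungal-lawn plates.
#' @return An object of class `plate_layout`. `is_border` is precomputed for
#'   every occupied position.
#' @export
plate_layout <- function(plate_id, array_format, medium, role, occupants,
                         quadrant_of = NULL, target_yeast = NULL) {
  array_format <- as.integer(array_format)
  role <- match.arg(role, PLATE_ROLES)
  if (!is.null(target_yeast)) target_yeast <- match.arg(target_yeast, TARGET_YEASTS)
  if (!is.list(occupants) || is.null(names(occupants)) || any(names(occupants) == "")) {
    stop("'occupants' must be a named list keyed by position label")
  }
  valid <- all_positions(array_format)
  unknown <- setdiff(names(occupants), valid)
  if (length(unknown) > 0L) {
    stop("plate ", plate_id, ": positions outside the ", array_format,
         "-array grid: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(names(occupants))) {
    stop("plate ", plate_id, ": duplicated occupant positions")
  }
  expected_n <- if (role == "interaction") 2L else 1L
  n_occ <- vapply(occupants, length, 1L)
  if (any(n_occ != expected_n)) {
    stop("plate ", plate_id, " (role ", role, "): every occupied position must",
         " hold exactly ", expected_n, " isolate id(s)")
  }
  border <- is_border_position(names(occupants), array_format = array_format)
  names(border) <- names(occupants)
  structure(
    list(plate_id = plate_id, array_format = array_format, medium = medium,
         role = role, occupants = occupants, quadrant_of = quadrant_of,
         is_border = border, target_yeast = target_yeast),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout %s: %d-array, medium %s, role %s, %d occupied%s>\n",
              x$plate_id, x$array_format, x$medium, x$role, length(x$occupants),
              if (is.null(x$target_yeast)) "" else paste0(", target ", x$target_yeast)))
  invisible(x)
}

#' Tidy view of a layout's occupancy
#'
#' @param layout A [plate_layout()].
#' @return data.frame with one row per occupied position: `plate_id`,
#'   `position`, `isolate_1`, `isolate_2` (NA on single plates), `border`.
#' @export
layout_table <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  pos <- names(layout$occupants)
  occ1 <- vapply(layout$occupants, `[`, "", 1L)
  occ2 <- if (layout$role == "interaction") {
    vapply(layout$occupants, `[`, "", 2L)
  } else {
    rep(NA_character_, length(pos))
  }
  data.frame(plate_id = layout$plate_id, medium = layout$medium,
             role = layout$role, position = pos,
             isolate_1 = unname(occ1), isolate_2 = unname(occ2),
             border = unname(layout$is_border), row.names = NULL)
}

#' Assemble the source and interaction layouts of one screening medium
#'
#' Builds, from four 96-array preculture plates: one 384-array main source
#' plate (MSP, the four plates interleaved quadrant-wise), four 384-array
#' replicate source plates (RSP1-4, each a single 96-plate replicated into
#' all four quadrants, i.e. four replicate spots per isolate), and four
#' interaction layouts (the MSP occupant paired with the corresponding RSP
#' occupant at the same position). With this design every isolate is paired
#' with three other isolates and itself, and every unordered pair occurs
#' twice at different positions.
#'
#' @param source_plates Named list of exactly four 96-array preculture plates.
#'   Each element is a character vector of isolate ids, either named by
#'   96-array position label or unnamed (then filled row-major from A1).
#' @param medium Culture medium identifier.
#' @param plate_prefix Prefix for generated 384-plate ids (default the medium).
#' @return Named list of nine `plate_layout` objects: `<prefix>-MSP`,
#'   `<prefix>-RSP1` .. `-RSP4`, `<prefix>-INT1` .. `-INT4`.
#' @export
assemble_layouts <- function(source_plates, medium, plate_prefix = medium) {
  if (!is.list(source_plates) || length(source_plates) != 4L) {
    stop("exactly four 96-array preculture plates are required (got ",
         length(source_plates), ")")
  }
  if (is.null(names(source_plates))) {
    names(source_plates) <- paste0("P", 1:4)
  }
  pos96 <- all_positions(96)
  wells <- lapply(names(source_plates), function(pid) {
    occ <- source_plates[[pid]]
    if (!is.character(occ) || length(occ) < 1L || length(occ) > 96L) {
      stop("preculture plate ", pid, ": expected 1-96 isolate ids")
    }
    if (is.null(names(occ))) names(occ) <- pos96[seq_along(occ)]
    if (!all(names(occ) %in% pos96)) {
      stop("preculture plate ", pid, ": invalid 96-array positions")
    }
    occ
  })
  names(wells) <- names(source_plates)
  all_ids <- unlist(wells, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("occupant collision: isolate id(s) occur on more than one preculture",
         " plate: ", paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }

  # map 96-well label -> 384 label for quadrant q
  well_to_384 <- function(q, labels96) {
    idx <- pos_parse(labels96)
    off <- quadrant_offset(q)
    pos_label(2L * (idx$row - 1L) + off[1L] + 1L, 2L * (idx$col - 1L) + off[2L] + 1L)
  }

  msp_occ <- list()
  msp_quad <- character(0)
  for (q in 1:4) {
    pid <- names(wells)[q]
    p384 <- well_to_384(q, names(wells[[q]]))
    msp_occ[p384] <- as.list(unname(wells[[q]]))
    msp_quad[p384] <- pid
  }
  msp <- plate_layout(paste0(plate_prefix, "-MSP"), 384, medium, "main_source",
                      msp_occ, quadrant_of = msp_quad)

  layouts <- list()
  layouts[[msp$plate_id]] <- msp
  for (r in 1:4) {
    pid <- names(wells)[r]
    rsp_occ <- list()
    rsp_quad <- character(0)
    for (q in 1:4) {
      p384 <- well_to_384(q, names(wells[[r]]))
      rsp_occ[p384] <- as.list(unname(wells[[r]]))
      rsp_quad[p384] <- pid
    }
    rsp <- plate_layout(paste0(plate_prefix, "-RSP", r), 384, medium,
                        "replicate_source", rsp_occ, quadrant_of = rsp_quad)
    layouts[[rsp$plate_id]] <- rsp

    shared <- intersect(names(msp$occupants), names(rsp$occupants))
    int_occ <- lapply(shared, function(p) {
      c(msp$occupants[[p]], rsp$occupants[[p]])
    })
    names(int_occ) <- shared
    int <- plate_layout(paste0(plate_prefix, "-INT", r), 384, medium,
                        "interaction", int_occ)
    layouts[[int$plate_id]] <- int
  }
  layouts
}

#' Map pair positions to their individual reference positions
#'
#' The individual reference values of a pair are read from the same position
#' of the MSP and RSP layouts (identity mapping on positions); each pair
#' instance keeps its own record even when the same unordered pair occurs at
#' another position.
#'
#' @param interaction_layout,msp_layout,rsp_layout `plate_layout` objects
#'   sharing the same array geometry.
#' @return data.frame with one row per pair position: `position`,
#'   `msp_position`, `rsp_position`, `isolate_msp`, `isolate_rsp`,
#'   `self_pair`.
#' @export
match_pair_to_individuals <- function(interaction_layout, msp_layout, rsp_layout) {
  stopifnot(inherits(interaction_layout, "plate_layout"),
            inherits(msp_layout, "plate_layout"),
            inherits(rsp_layout, "plate_layout"))
  if (interaction_layout$role != "interaction") {
    stop("first layout must have role 'interaction'")
  }
  fmts <- c(interaction_layout$array_format, msp_layout$array_format,
            rsp_layout$array_format)
  if (length(unique(fmts)) != 1L) {
    stop("geometry mismatch: array formats ", paste(fmts, collapse = "/"))
  }
  pos <- names(interaction_layout$occupants)
  missing_msp <- setdiff(pos, names(msp_layout$occupants))
  missing_rsp <- setdiff(pos, names(rsp_layout$occupants))
  if (length(missing_msp) || length(missing_rsp)) {
    stop("geometry mismatch: pair positions absent from source layouts: ",
         paste(unique(c(missing_msp, missing_rsp)), collapse = ", "))
  }
  iso_m <- vapply(pos, function(p) msp_layout$occupants[[p]][1L], "")
  iso_r <- vapply(pos, function(p) rsp_layout$occupants[[p]][1L], "")
  pair <- interaction_layout$occupants[pos]
  consistent <- mapply(function(pr, m, r) setequal(pr, c(m, r)), pair, iso_m, iso_r)
  if (!all(consistent)) {
    stop("interaction occupants disagree with MSP/RSP occupants at: ",
         paste(pos[!consistent], collapse = ", "))
  }
  data.frame(position = pos, msp_position = pos, rsp_position = pos,
             isolate_msp = unname(iso_m), isolate_rsp = unname(iso_r),
             self_pair = unname(iso_m == iso_r), row.names = NULL)
}
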