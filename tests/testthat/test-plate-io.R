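# plate_io: quantification-table dialect, halo tables, layout assembly and
# position pairing.

test_that("quant table round trip is exact, including absent spots", {
  x <- make_quant_df(12L)
  x <- x[-5L, ]  # spot not detected at this timepoint: simply absent
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(x, path, plate_id = "LM17-MSP", array_format = 384,
                    time_h = 14)
  y <- read_quant_table(path)
  expect_equal(nrow(y), 11L)
  expect_equal(y$row, x$row)
  expect_equal(y$column, x$column)
  expect_identical(y$size, x$size)
  expect_identical(y$opacity, x$opacity)
  expect_equal(unique(y$time_h), 14)
  expect_equal(unique(y$plate_id), "LM17-MSP")
  expect_equal(attr(y, "array_format"), 384L)
  expect_false("A5" %in% y$position)
})

test_that("malformed quant rows error with their line number", {
  x <- make_quant_df(4L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(x, path, "P", 384, 2)
  lines <- readLines(path)
  lines[7L] <- "1\t3\tnot_a_number\t9"  # line 7 = second data row
  writeLines(lines, path)
  expect_error(read_quant_table(path), "line 7")

  write_quant_table(rbind(x, x[1L, ]), path, "P", 384, 2)
  expect_error(read_quant_table(path), "duplicate")
})

test_that("halo tables round trip and validate", {
  h <- data.frame(plate_id = "LM17-INT1",
                  position = c("A1", "A2", "B1"),
                  target = "S_cerevisiae",
                  antifungal = c(TRUE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_halo_table(h, path)
  y <- read_halo_table(path)
  expect_identical(y$antifungal, h$antifungal)
  expect_identical(y$position, h$position)

  write_halo_table(rbind(h, h[1L, ]), path)
  expect_error(read_halo_table(path), "duplicate")
})

test_that("assemble_layouts builds the MSP/RSP/interaction set", {
  plates <- make_source_plates(96L)
  layouts <- assemble_layouts(plates, medium = "LM17")
  expect_named(layouts, c("LM17-MSP", paste0("LM17-RSP", 1:4),
                          paste0("LM17-INT", 1:4)), ignore.order = TRUE)

  msp <- layouts[["LM17-MSP"]]
  expect_equal(length(msp$occupants), 384L)
  expect_equal(length(unique(unlist(msp$occupants))), 384L)

  # every RSP holds 4 copies of its source plate's occupants
  for (r in 1:4) {
    rsp <- layouts[[paste0("LM17-RSP", r)]]
    occ <- unlist(rsp$occupants)
    expect_equal(sort(unname(table(occ))), rep(4L, 96L), ignore_attr = TRUE)
    expect_setequal(unique(occ), unname(plates[[r]]))
  }

  # interaction occupants are (MSP occupant, RSP occupant) at each position
  int2 <- layouts[["LM17-INT2"]]
  expect_true(all(vapply(int2$occupants, length, 1L) == 2L))
  p <- "B7"
  expect_equal(int2$occupants[[p]],
               c(msp$occupants[[p]], layouts[["LM17-RSP2"]]$occupants[[p]]))
})

test_that("quadrant condensation is the interleaved SGA pattern", {
  plates <- make_source_plates(96L)
  layouts <- assemble_layouts(plates, medium = "M")
  msp <- layouts[["M-MSP"]]
  # quadrant 1 (plate P1) well B3 -> rows 2*(2-1)+1 = 3 (C), col 2*(3-1)+1 = 5
  expect_equal(msp$occupants[["C5"]], unname(plates$P1[["B3"]]))
  # quadrant 4 (plate P4) well B3 -> row 4 (D), col 6
  expect_equal(msp$occupants[["D6"]], unname(plates$P4[["B3"]]))
  expect_equal(msp$quadrant_of[["C5"]], "P1")
})

test_that("assemble_layouts validates its inputs", {
  plates <- make_source_plates(96L)
  expect_error(assemble_layouts(plates[1:3], "LM17"), "four")
  collide <- plates
  collide$P2[1L] <- collide$P1[[1L]]
  expect_error(assemble_layouts(collide, "LM17"), "collision")
})

test_that("match_pair_to_individuals is the identity on positions", {
  layouts <- assemble_layouts(make_source_plates(96L), "LM17")
  pairing <- match_pair_to_individuals(layouts[["LM17-INT3"]],
                                       layouts[["LM17-MSP"]],
                                       layouts[["LM17-RSP3"]])
  expect_equal(pairing$msp_position, pairing$position)
  expect_equal(pairing$rsp_position, pairing$position)
  # self pairs exactly where the MSP quadrant equals the RSP source plate
  expect_equal(sum(pairing$self_pair), 96L)

  # the same unordered pair occurs twice across the interaction plates
  all_pairs <- do.call(rbind, lapply(1:4, function(r) {
    match_pair_to_individuals(layouts[[paste0("LM17-INT", r)]],
                              layouts[["LM17-MSP"]],
                              layouts[[paste0("LM17-RSP", r)]])
  }))
  non_self <- all_pairs[!all_pairs$self_pair, ]
  unordered <- apply(cbind(non_self$isolate_msp, non_self$isolate_rsp), 1L,
                     function(x) paste(sort(x), collapse = "|"))
  expect_true(all(table(unordered) == 2L))

  # geometry mismatch
  small <- plate_layout("X", 96, "LM17", "main_source",
                        occupants = list(A1 = "ISO001"))
  expect_error(match_pair_to_individuals(layouts[["LM17-INT1"]], small,
                                         layouts[["LM17-RSP1"]]),
               "geometry mismatch")
})

test_that("border flags mark exactly the outermost ring", {
  expect_equal(sum(is_border_position(all_positions(384), array_format = 384)), 76L)
  expect_equal(sum(is_border_position(all_positions(96), array_format = 96)), 36L)
  expect_true(is_border_position("A5", array_format = 384))
  expect_true(is_border_position("P24", array_format = 384))
  expect_false(is_border_position("B2", array_format = 384))
})

test_that("layout JSON round trip reproduces every field", {
  layouts <- assemble_layouts(make_source_plates(8L), "SALN")
  path <- withr::local_tempfile(fileext = ".json")
  write_layouts(layouts, path)
  back <- read_layouts(path)
  expect_named(back, names(layouts))
  for (nm in names(layouts)) {
    expect_equal(back[[nm]]$occupants, layouts[[nm]]$occupants)
    expect_equal(back[[nm]]$medium, layouts[[nm]]$medium)
    expect_equal(back[[nm]]$role, layouts[[nm]]$role)
    expect_equal(back[[nm]]$is_border, layouts[[nm]]$is_border)
  }
})

test_that("plate_layout enforces occupancy invariants", {
  expect_error(plate_layout("X", 384, "LM17", "main_source",
                            occupants = list(Z99 = "a")), "grid")
  expect_error(plate_layout("X", 384, "LM17", "main_source",
                            occupants = list(A1 = c("a", "b"))), "exactly 1")
  expect_error(plate_layout("X", 384, "LM17", "interaction",
                            occupants = list(A1 = "a")), "exactly 2")
  # self pair: identical ids allowed on interaction plates
  l <- plate_layout("X", 384, "LM17", "interaction",
                    occupants = list(B2 = c("a", "a")))
  expect_equal(l$occupants$B2, c("a", "a"))
})
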