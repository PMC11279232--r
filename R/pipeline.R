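# End-to-end orchestration: io -> fit -> fitness -> scoring -> report.
#
# Every stage persists a tidy CSV when an output directory is given, and a
# manifest records the configuration plus exact attrition accounting
# (records_in = records_out + records_rejected at every stage).

#' Run the full screening analysis pipeline
#'
#' Stages: (1) join quantification tables into per-spot time series;
#' (2) QC + Gompertz fitting + significance screen; (3) integrated fitness,
#' robust per-plate centering, MSD estimation from RSP replicates;
#' (4) ecological and functional classification of every pair instance,
#' behavior profiles and spectrum classes; (5) summary report tables.
#'
#' @param input A bundle directory (as written by [write_bundle()]), or an
#'   in-memory list/`sim_bundle` with elements `layouts`, `quant`, `halos`.
#' @param output_dir Optional directory for stage CSVs, report tables and
#'   `manifest.json`.
#' @param alpha Per-parameter significance level for fit acceptance
#'   (default 0.05).
#' @param t_max Integration horizon for IF in hours (default 72).
#' @param center_method `"huber"` (default) or `"median"` plate centering.
#' @param strict_one_sided Passed to [classify_functional()].
#' @param include_self_pairs Classify self pairs ecologically (default FALSE:
#'   a self pair has a degenerate two-sided rule and stays `"unscored"`).
#' @param msd_scope Label recorded with the MSD estimate.
#' @return List with `series`, `fits`, `fitness`, `msd`, `interactions`,
#'   `profiles`, `spectrum`, `report`, `manifest`.
#' @export
run_pipeline <- function(input, output_dir = NULL, alpha = 0.05, t_max = 72,
                         center_method = c("huber", "median"),
                         strict_one_sided = FALSE,
                         include_self_pairs = FALSE,
                         msd_scope = "dataset") {
  center_method <- match.arg(center_method)
  bundle <- if (is.character(input)) read_bundle(input) else input
  if (!all(c("layouts", "quant", "halos") %in% names(bundle))) {
    stop("input must provide layouts, quant and halos")
  }
  layouts <- bundle$layouts
  lay_tab <- do.call(rbind, lapply(layouts, layout_table))
  rownames(lay_tab) <- NULL

  # stage 1: series ----------------------------------------------------
  quant <- bundle$quant
  key_q <- paste(quant$plate_id, quant$position)
  key_l <- paste(lay_tab$plate_id, lay_tab$position)
  known <- key_q %in% key_l
  series <- quant[known, ]
  series$biomass <- compute_biomass(series$size, series$opacity)
  n_spots_dropped <- sum(!known)

  # stage 2: growth fits ------------------------------------------------
  fits <- fit_growth_table(series, alpha = alpha)
  m <- match(paste(fits$plate_id, fits$position), key_l)
  fits$medium <- lay_tab$medium[m]
  fits$role <- lay_tab$role[m]
  fits$isolate_1 <- lay_tab$isolate_1[m]
  fits$isolate_2 <- lay_tab$isolate_2[m]
  fits$border <- lay_tab$border[m]

  # stage 3: fitness ----------------------------------------------------
  fitness <- fits
  fitness$IF_raw <- NA_real_
  acc <- fitness$status == "accepted"
  fitness$IF_raw[acc] <- integrated_fitness(fitness$A[acc], fitness$k[acc],
                                            fitness$t_i[acc], t_max = t_max)
  fitness$IF_centered <- center_by_design(fitness, layouts,
                                          method = center_method)

  rsp <- fitness[fitness$role == "replicate_source", ]
  msd <- compute_msd(rsp$IF_centered, rsp$isolate_1, rsp$border,
                     scope = msd_scope)

  # stage 4: interaction scoring ----------------------------------------
  interactions <- score_interactions(fitness, bundle$halos, layouts, msd$msd,
                                     strict_one_sided = strict_one_sided,
                                     include_self_pairs = include_self_pairs)
  targets <- sort(unique(bundle$halos$target))
  profiles <- profile_isolates(interactions, bundle$halos, layouts, targets)
  spectrum <- spectrum_isolates(bundle$halos, layouts)

  # stage 5: report ------------------------------------------------------
  report <- screen_report(interactions, bundle$halos, layouts, profiles,
                          spectrum, targets)

  manifest <- list(
    package = "colonyscreen",
    version = as.character(utils::packageVersion("colonyscreen")),
    parameters = list(alpha = alpha, t_max = t_max,
                      center_method = center_method,
                      strict_one_sided = strict_one_sided,
                      include_self_pairs = include_self_pairs,
                      msd_scope = msd_scope),
    msd = msd,
    counts = list(
      quant_records_in = nrow(quant),
      quant_records_unmapped = n_spots_dropped,
      series_spots = length(unique(paste(series$plate_id, series$position))),
      fits_total = nrow(fits),
      fits_by_status = as.list(table(fits$status)),
      fits_accepted = sum(fits$status == "accepted"),
      fits_rejected = sum(fits$status != "accepted"),
      pair_instances = nrow(interactions),
      pair_instances_eco_scored = sum(interactions$eco_class %in% ECO_CLASSES)
    )
  )

  out <- list(series = series, fits = fits, fitness = fitness, msd = msd,
              interactions = interactions, profiles = profiles,
              spectrum = spectrum, report = report, manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(series, file.path(output_dir, "series.csv"), row.names = FALSE)
    utils::write.csv(fits, file.path(output_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(fitness, file.path(output_dir, "fitness.csv"), row.names = FALSE)
    utils::write.csv(interactions, file.path(output_dir, "interactions.csv"),
                     row.names = FALSE)
    utils::write.csv(profiles, file.path(output_dir, "profiles.csv"), row.names = FALSE)
    utils::write.csv(spectrum, file.path(output_dir, "spectrum.csv"), row.names = FALSE)
    for (nm in names(report$tables)) {
      utils::write.csv(report$tables[[nm]],
                       file.path(output_dir, paste0("report_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' Design-aware plate centering onto a common per-medium scale
#'
#' Robust per-plate centering removes each plate's location, but a plate's
#' location mixes the technical offset with the plate's *population*: an
#' interaction plate populated by pairs, or an RSP carrying a quarter of the
#' isolates, does not share the MSP's population location, so plain per-plate
#' centering biases every cross-plate comparison by the population-median
#' difference. This routine instead chains technical offsets onto the MSP
#' scale using the design's internal anchors: RSP offsets are the robust
#' location of same-isolate IF differences vs the MSP, and interaction-plate
#' offsets come from self pairs — spots biologically identical to the RSP
#' individual at the very same position (position effects cancel exactly).
#' Plates without usable anchors fall back to plain [center_plate()].
#'
#' @param fitness data.frame with `plate_id`, `position`, `role`, `medium`,
#'   `isolate_1`, `IF_raw`.
#' @param layouts Named list of [plate_layout()] objects.
#' @param method Robust location: `"huber"` or `"median"`.
#' @param min_anchors Minimum finite anchor differences per plate (default 4).
#' @return Numeric vector of centered IF values aligned with `fitness` rows.
#' @export
center_by_design <- function(fitness, layouts, method = c("huber", "median"),
                             min_anchors = 4L) {
  method <- match.arg(method)
  loc <- function(v) {
    v <- v[is.finite(v)]
    if (method == "huber") huber_location(v) else stats::median(v)
  }
  raw <- fitness$IF_raw
  names(raw) <- paste(fitness$plate_id, fitness$position)
  centered <- rep(NA_real_, nrow(fitness))

  fallback <- function(plate_id, sel) {
    vals <- fitness$IF_raw[sel]
    if (sum(is.finite(vals)) >= 8L) {
      center_plate(vals, method = method)
    } else {
      if (any(is.finite(vals))) {
        warning("plate ", plate_id, ": fewer than 8 accepted fits; left uncentered")
      }
      rep(NA_real_, sum(sel))
    }
  }

  media <- unique(vapply(layouts, `[[`, "", "medium"))
  for (medium in media) {
    med_plates <- names(layouts)[vapply(layouts, function(l) l$medium == medium, TRUE)]
    roles <- vapply(layouts[med_plates], `[[`, "", "role")
    msp_id <- med_plates[roles == "main_source"]
    shift <- rep(NA_real_, length(med_plates))
    names(shift) <- med_plates

    if (length(msp_id) == 1L) {
      msp <- layouts[[msp_id]]
      msp_vals <- raw[paste(msp_id, names(msp$occupants))]
      if (sum(is.finite(msp_vals)) >= 8L) {
        shift[msp_id] <- loc(msp_vals)
        # isolate -> its MSP position
        msp_pos <- names(msp$occupants)
        names(msp_pos) <- vapply(msp$occupants, `[`, "", 1L)
        for (rsp_id in med_plates[roles == "replicate_source"]) {
          rsp <- layouts[[rsp_id]]
          pos <- names(rsp$occupants)
          iso <- vapply(rsp$occupants, `[`, "", 1L)
          d <- raw[paste(rsp_id, pos)] - raw[paste(msp_id, msp_pos[iso])]
          if (sum(is.finite(d)) >= min_anchors) {
            shift[rsp_id] <- shift[msp_id] + loc(d)
          }
        }
        for (int_id in med_plates[roles == "interaction"]) {
          int <- layouts[[int_id]]
          r <- sub("^.*-INT", "", int_id)
          rsp_id <- paste0(sub("-INT.*$", "", int_id), "-RSP", r)
          if (!rsp_id %in% med_plates || !is.finite(shift[rsp_id])) next
          self_pos <- names(int$occupants)[vapply(int$occupants, function(o) {
            o[1L] == o[2L]
          }, TRUE)]
          d <- raw[paste(int_id, self_pos)] - raw[paste(rsp_id, self_pos)]
          if (sum(is.finite(d)) >= min_anchors) {
            shift[int_id] <- shift[rsp_id] + loc(d)
          }
        }
      }
    }

    for (plate_id in med_plates) {
      sel <- fitness$plate_id == plate_id
      if (!any(sel)) next
      if (is.finite(shift[plate_id])) {
        centered[sel] <- fitness$IF_raw[sel] - shift[plate_id]
      } else {
        centered[sel] <- fallback(plate_id, sel)
      }
    }
  }

  # plates outside any layout medium (defensive): plain per-plate centering
  done <- fitness$plate_id %in% unlist(lapply(media, function(m) {
    names(layouts)[vapply(layouts, function(l) l$medium == m, TRUE)]
  }))
  for (plate_id in unique(fitness$plate_id[!done])) {
    sel <- fitness$plate_id == plate_id
    centered[sel] <- fallback(plate_id, sel)
  }
  centered
}

# One row per pair instance; halo flags and functional class per target.
score_interactions <- function(fitness, halos, layouts, msd,
                               strict_one_sided = FALSE,
                               include_self_pairs = FALSE) {
  targets <- sort(unique(halos$target))
  key_fit <- paste(fitness$plate_id, fitness$position)
  if_of <- fitness$IF_centered
  names(if_of) <- key_fit
  halo_of <- list()
  for (tg in targets) {
    h <- halos[halos$target == tg, ]
    v <- h$antifungal
    names(v) <- paste(h$plate_id, h$position)
    halo_of[[tg]] <- v
  }

  rows <- list()
  int_layouts <- Filter(function(l) l$role == "interaction", layouts)
  for (int in int_layouts) {
    medium <- int$medium
    msp_id <- grep("-MSP$", names(layouts), value = TRUE)
    msp_id <- msp_id[vapply(layouts[msp_id], function(l) l$medium == medium, TRUE)]
    if (length(msp_id) != 1L) {
      stop("expected exactly one main source plate for medium ", medium,
           " (found ", length(msp_id), ")")
    }
    r <- sub("^.*-INT", "", int$plate_id)
    rsp_id <- paste0(sub("-INT.*$", "", int$plate_id), "-RSP", r)
    pairing <- match_pair_to_individuals(int, layouts[[msp_id]], layouts[[rsp_id]])

    key_int <- paste(int$plate_id, pairing$position)
    key_msp <- paste(msp_id, pairing$position)
    key_rsp <- paste(rsp_id, pairing$position)
    if_pair <- unname(if_of[key_int])
    if_ind1 <- unname(if_of[key_msp])
    if_ind2 <- unname(if_of[key_rsp])
    eco <- classify_ecological(if_pair, if_ind1, if_ind2, msd)
    if (!include_self_pairs) eco[pairing$self_pair] <- "unscored"

    df <- data.frame(pair_id = paste0(int$plate_id, ":", pairing$position),
                     medium = medium, plate_id = int$plate_id,
                     position = pairing$position,
                     isolate_1 = pairing$isolate_msp,
                     isolate_2 = pairing$isolate_rsp,
                     self_pair = pairing$self_pair,
                     IF_pair = if_pair, IF_ind1 = if_ind1, IF_ind2 = if_ind2,
                     eco_class = eco)
    for (tg in targets) {
      hp <- unname(halo_of[[tg]][key_int])
      h1 <- unname(halo_of[[tg]][key_msp])
      h2 <- unname(halo_of[[tg]][key_rsp])
      df[[paste0("halo_pair_", tg)]] <- hp
      df[[paste0("halo_ind1_", tg)]] <- h1
      df[[paste0("halo_ind2_", tg)]] <- h2
      fc <- classify_functional(hp, h1, h2, strict_one_sided = strict_one_sided)
      fc[pairing$self_pair] <- "unscored"
      df[[paste0("func_", tg)]] <- fc
    }
    rows[[int$plate_id]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Behavior profile per isolate: ecological outcomes of its three MSP-side
# partner pairs, plus its own antifungal flag (any target, individual assay).
profile_isolates <- function(interactions, halos, layouts, targets) {
  ind_flags <- individual_halo_flags(halos, layouts)
  non_self <- interactions[!interactions$self_pair, ]
  rows <- lapply(split(non_self, list(non_self$isolate_1, non_self$medium),
                       drop = TRUE), function(d) {
    iso <- d$isolate_1[1L]
    medium <- d$medium[1L]
    af <- ind_flags$antifungal_any[ind_flags$isolate == iso &
                                     ind_flags$medium == medium]
    prof <- behavior_profile(d$eco_class, antifungal = any(af))
    data.frame(isolate = iso, medium = medium,
               n_interactions = prof$n_interactions,
               n_cooperative = prof$n_cooperative,
               n_competitive = prof$n_competitive,
               antifungal = prof$antifungal, incomplete = prof$incomplete)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Individual antifungal flags per isolate x medium x target, read from the
# main source plate's halo scores.
individual_halo_flags <- function(halos, layouts) {
  msp_layouts <- Filter(function(l) l$role == "main_source", layouts)
  rows <- list()
  for (msp in msp_layouts) {
    pos <- names(msp$occupants)
    iso <- vapply(msp$occupants, `[`, "", 1L)
    h <- halos[halos$plate_id == msp$plate_id, ]
    wide <- data.frame(isolate = unname(iso), medium = msp$medium,
                       position = pos)
    for (tg in sort(unique(h$target))) {
      v <- h$antifungal[h$target == tg]
      names(v) <- h$position[h$target == tg]
      wide[[tg]] <- unname(v[pos])
    }
    tg_cols <- setdiff(names(wide), c("isolate", "medium", "position"))
    wide$antifungal_any <- rowSums(as.data.frame(wide[tg_cols]), na.rm = TRUE) > 0
    rows[[msp$plate_id]] <- wide
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Spectrum class per isolate x medium from individual three-target activity.
spectrum_isolates <- function(halos, layouts) {
  flags <- individual_halo_flags(halos, layouts)
  need <- c("K_lactis", "S_cerevisiae", "C_boidinii")
  if (!all(need %in% names(flags))) {
    return(data.frame(isolate = character(0), medium = character(0),
                      class = character(0)))
  }
  data.frame(isolate = flags$isolate, medium = flags$medium,
             class = spectrum_class(flags$K_lactis, flags$S_cerevisiae,
                                    flags$C_boidinii))
}

# Summary tables in the shape of the screening results: per-medium antifungal
# rates (individual and paired), functional- and ecological-class
# proportions, behavior-profile counts, spectrum tables, stability matrices
# (when exactly two media were screened), and the association tests.
screen_report <- function(interactions, halos, layouts, profiles, spectrum,
                          targets) {
  tables <- list()
  tests <- list()
  flags <- individual_halo_flags(halos, layouts)

  # individual antifungal rate per medium x target (2 decimals, isolate level)
  ind <- list()
  for (tg in targets) {
    if (!tg %in% names(flags)) next
    s <- proportion_summary(ifelse(flags[[tg]], "antifungal", "not_antifungal"),
                            by = flags$medium, decimals = 2)
    s$target <- tg
    ind[[tg]] <- s
  }
  tables$individual_antifungal <- do.call(rbind, ind)

  # paired antifungal rate per medium x target (1 decimal)
  paired <- list()
  for (tg in targets) {
    col <- paste0("halo_pair_", tg)
    ok <- !is.na(interactions[[col]])
    if (!any(ok)) next
    s <- proportion_summary(ifelse(interactions[[col]][ok], "antifungal",
                                   "not_antifungal"),
                            by = interactions$medium[ok], decimals = 1)
    s$target <- tg
    paired[[tg]] <- s
  }
  tables$paired_antifungal <- do.call(rbind, paired)

  # functional classes per medium x target
  fun <- list()
  for (tg in targets) {
    col <- paste0("func_", tg)
    scored <- interactions[[col]] %in% FUNC_CLASSES
    if (!any(scored)) next
    s <- proportion_summary(interactions[[col]][scored],
                            by = interactions$medium[scored], decimals = 1)
    s$target <- tg
    fun[[tg]] <- s
  }
  tables$functional_classes <- do.call(rbind, fun)

  # ecological classes, overall and per medium
  scored <- interactions$eco_class %in% ECO_CLASSES
  if (any(scored)) {
    tables$ecological_overall <- proportion_summary(
      interactions$eco_class[scored], decimals = 1)
    tables$ecological_by_medium <- proportion_summary(
      interactions$eco_class[scored], by = interactions$medium[scored],
      decimals = 1)
  }

  # behavior profiles: occurrence counts of cooperative/competitive outcomes
  if (nrow(profiles) > 0L) {
    complete <- profiles[!profiles$incomplete, ]
    if (nrow(complete) > 0L) {
      tables$behavior_profiles <- do.call(rbind, lapply(
        split(complete, complete$antifungal), function(d) {
          data.frame(antifungal = d$antifungal[1L],
                     n_isolates = nrow(d),
                     coop_0 = sum(d$n_cooperative == 0L),
                     coop_1 = sum(d$n_cooperative == 1L),
                     coop_2 = sum(d$n_cooperative == 2L),
                     coop_3 = sum(d$n_cooperative == 3L),
                     comp_0 = sum(d$n_competitive == 0L),
                     comp_1 = sum(d$n_competitive == 1L),
                     comp_2 = sum(d$n_competitive == 2L),
                     comp_3 = sum(d$n_competitive == 3L))
        }))
      rownames(tables$behavior_profiles) <- NULL
      # consistently competitive (all three interactions) vs antifungal
      tab <- table(factor(complete$n_competitive == 3L, c(FALSE, TRUE)),
                   factor(complete$antifungal, c(FALSE, TRUE)))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        tests$competitive3_vs_antifungal <- g_test(unclass(tab))
      }
    }
  }

  if (nrow(spectrum) > 0L) {
    tables$spectrum_classes <- proportion_summary(spectrum$class,
                                                  by = spectrum$medium,
                                                  decimals = 1)
  }

  # suppression vs competition association (right-sided Fisher), per target
  for (tg in targets) {
    col <- paste0("func_", tg)
    ok <- interactions$eco_class %in% ECO_CLASSES &
      interactions[[col]] %in% FUNC_CLASSES
    if (sum(ok) == 0L) next
    supp <- interactions[[col]][ok] == "suppression"
    comp <- interactions$eco_class[ok] == "competition"
    tab <- matrix(c(sum(supp & comp), sum(supp & !comp),
                    sum(!supp & comp), sum(!supp & !comp)), 2, byrow = TRUE,
                  dimnames = list(c("suppression", "no_suppression"),
                                  c("competition", "no_competition")))
    tab <- t(tab)  # orient so [1,1] = competitive & suppressed
    p <- tryCatch(fisher_exact(matrix(c(sum(comp & supp), sum(comp & !supp),
                                        sum(!comp & supp), sum(!comp & !supp)),
                                      2, byrow = TRUE), side = "right"),
                  error = function(e) NA_real_)
    tests[[paste0("suppression_vs_competition_", tg)]] <-
      list(table = tab, p_right = p)
  }

  # antifungal rate across media (G-test), individual assay, per target
  for (tg in targets) {
    if (!tg %in% names(flags)) next
    tab <- table(flags$medium, factor(flags[[tg]], c(FALSE, TRUE)))
    if (nrow(tab) >= 2L && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      tests[[paste0("antifungal_rate_by_medium_", tg)]] <- g_test(unclass(tab))
    }
  }

  # venn regions: which targets each antifungal isolate hits, per medium
  tg_cols <- intersect(targets, names(flags))
  if (length(tg_cols) %in% c(2L, 3L)) {
    venns <- lapply(split(flags, flags$medium), function(d) {
      venn_counts(d[tg_cols])
    })
    tables$venn_by_medium <- do.call(rbind, lapply(names(venns), function(m) {
      data.frame(medium = m, region = names(venns[[m]]),
                 count = as.integer(venns[[m]]))
    }))
  }

  # stability across media (exactly two media screened)
  media <- sort(unique(interactions$medium))
  if (length(media) == 2L) {
    key <- function(d) paste(d$isolate_1, d$isolate_2, d$position, d$plate_suffix)
    a <- interactions[interactions$medium == media[1L], ]
    b <- interactions[interactions$medium == media[2L], ]
    a$plate_suffix <- sub("^.*-INT", "INT", a$plate_id)
    b$plate_suffix <- sub("^.*-INT", "INT", b$plate_id)
    ka <- key(a); kb <- key(b)
    shared <- intersect(ka, kb)
    a <- a[match(shared, ka), ]
    b <- b[match(shared, kb), ]
    ok <- a$eco_class %in% ECO_CLASSES & b$eco_class %in% ECO_CLASSES
    if (sum(ok) > 0L) {
      sm <- stability_matrix(a$eco_class[ok], b$eco_class[ok],
                             levels = ECO_CLASSES)
      tables$eco_stability <- as.data.frame(as.table(sm$counts))
      names(tables$eco_stability) <- c(media[1L], media[2L], "count")
      tests$eco_stability_diagonal_pct <- sm$diagonal_pct
    }
  }

  list(tables = tables, tests = tests)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed S --out DIR [--n-isolates N] [--media A,B]`
#' generates a synthetic bundle; `run --in DIR --out DIR [--alpha A]
#' [--t-max H] [--center huber|median]` analyzes a bundle; `run-all` does
#' both in one go. Installed as the `colonyscreen` script under
#' `inst/exec/`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code: 0 ok, 2 usage/validation error, 3 stage
#'   failure.
#' @export
cs_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: colonyscreen <simulate|run|run-all> [options]",
    "  simulate --seed S --out DIR [--n-isolates N] [--media A,B]",
    "  run      --in DIR --out DIR [--alpha A] [--t-max H] [--center M]",
    "  run-all  --seed S --out DIR [--n-isolates N] [--alpha A]",
    sep = "\n")
  if (length(args) < 1L) {
    message(usage)
    return(2L)
  }
  cmd <- args[1L]
  opts <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      message("malformed option: ", rest[i], "\n", usage)
      return(2L)
    }
    opts[[sub("^--", "", rest[i])]] <- rest[i + 1L]
    i <- i + 2L
  }
  get_opt <- function(name, default = NULL) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }

  run_stage <- function(expr) {
    tryCatch({ expr; 0L }, error = function(e) {
      message("stage failure: ", conditionMessage(e))
      3L
    })
  }

  if (cmd == "simulate" || cmd == "run-all") {
    seed <- suppressWarnings(as.integer(get_opt("seed", "1")))
    out <- get_opt("out")
    if (is.na(seed) || is.null(out)) {
      message("simulate requires --seed and --out\n", usage)
      return(2L)
    }
    n <- suppressWarnings(as.integer(get_opt("n-isolates", "64")))
    media <- strsplit(get_opt("media", "LM17"), ",", fixed = TRUE)[[1L]]
    code <- run_stage({
      cfg <- simulation_config(seed = seed, n_isolates = n, media = media)
      bundle <- simulate_experiment(cfg)
      write_bundle(bundle, file.path(out, "bundle"))
      message("bundle written to ", file.path(out, "bundle"))
    })
    if (code != 0L || cmd == "simulate") return(code)
    opts[["in"]] <- file.path(out, "bundle")
  }

  if (cmd == "run" || cmd == "run-all") {
    indir <- get_opt("in")
    out <- get_opt("out")
    if (is.null(indir) || is.null(out)) {
      message("run requires --in and --out\n", usage)
      return(2L)
    }
    if (!dir.exists(indir)) {
      message("input directory does not exist: ", indir)
      return(2L)
    }
    return(run_stage({
      res <- run_pipeline(indir, output_dir = file.path(out, "analysis"),
                          alpha = as.numeric(get_opt("alpha", "0.05")),
                          t_max = as.numeric(get_opt("t-max", "72")),
                          center_method = get_opt("center", "huber"))
      message("analysis written to ", file.path(out, "analysis"),
              " (", res$manifest$counts$fits_accepted, " accepted fits, MSD ",
              format(res$msd$msd, digits = 4), ")")
    }))
  }

  if (!cmd %in% c("simulate", "run", "run-all")) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(2L)
  }
  0L
}
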