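# Ground-truth synthetic plate experiments.
#
# Emulates the screening design end to end: four 96-array preculture plates
# per medium condensed into an MSP, four RSPs (four replicates per isolate),
# four interaction plates, time-lapse quantification tables (imaged every
# two hours during the day over four days, <= 20 usable points per spot),
# and qualitative halo scores per target yeast. Every generated observation
# is annotated with its ground truth so recovery can be measured.
#
# Noise model for an observed log2 biomass at time t on plate P, position x:
#
#   b = y_spot(t) + plate_offset(P) + position_effect(medium, x) + N(0, sigma)
#
# The position effect is shared by ALL plates of a medium at the same
# position: it emulates positional bias (edge effects, local nutrient
# gradients), inflates replicate-to-replicate variation (replicates sit at
# different positions, so the MSD absorbs it) and cancels exactly in the
# pair-vs-individual comparison at the same position -- the reason the
# screening design pairs positions in the first place.

#' Imaging schedule: every two hours during the day for four days
#'
#' Five images per day at 2-h spacing (hours 8-16 of each of four days),
#' giving the 20 usable timepoints per spot that the fitting contract
#' assumes.
#'
#' @return Numeric vector of 20 hours.
#' @export
daytime_hours <- function() {
  as.vector(vapply(0:3, function(d) d * 24 + c(8, 10, 12, 14, 16), numeric(5)))
}

#' Configuration of a synthetic plate experiment
#'
#' Defaults state the emulated experimental world: 384 isolates per medium
#' (four 96-array preculture plates), log2-biomass Gompertz growth with
#' uniform parameter ranges, replicate noise sigma = 0.05 log2 units per
#' timepoint, positional bias of the same magnitude, plate offsets of 0.25,
#' 5% spot-timepoint dropout (spots not consistently detected), pair effects
#' injected at 6 expected MSD, and per-medium antifungal prevalences taken
#' from typical screening rates on rich vs minimal media.
#'
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   config (including the seed).
#' @param n_isolates Isolates per medium; divisible by 4, at most 384.
#' @param media Character vector of media.
#' @param targets Target yeasts for the halo assay.
#' @param timepoints Imaging hours (default [daytime_hours()]).
#' @param A_range,k_range,ti_range Uniform ranges of the true Gompertz
#'   parameters (asymptote in log2 units, rate in 1/h, inflection in h).
#' @param sigma Replicate noise SD per timepoint (log2-biomass units).
#' @param position_sigma SD of the per-(medium, position) bias shared across
#'   plates (log2-biomass units).
#' @param plate_sigma SD of per-plate offsets (log2-biomass units).
#' @param p_cooperation,p_competition Fractions of non-self pair instances
#'   with an injected positive / negative effect.
#' @param delta_msd Magnitude of injected pair effects, in multiples of the
#'   expected MSD; must exceed 2 (the classification threshold) whenever a
#'   non-neutral fraction is positive.
#' @param antifungal_prevalence Named per-medium probability that an isolate
#'   is antifungal against a given target.
#' @param p_suppression Probability that a pair with at least one antifungal
#'   member loses the halo (suppression).
#' @param p_induction Probability that a pair with no antifungal member
#'   gains a halo (induction).
#' @param dropout Per-(spot, timepoint) probability that the spot is not
#'   detected in that image.
#' @param msd_draws Monte-Carlo replicate-spot fits used by [expected_msd()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_isolates = 384L, media = "LM17",
                              targets = c("K_lactis", "C_boidinii", "S_cerevisiae"),
                              timepoints = daytime_hours(),
                              A_range = c(8, 12), k_range = c(0.15, 0.35),
                              ti_range = c(8, 20),
                              sigma = 0.05, position_sigma = 0.05,
                              plate_sigma = 0.25,
                              p_cooperation = 0.15, p_competition = 0.12,
                              delta_msd = 6,
                              antifungal_prevalence = c(LM17 = 0.111,
                                                        PCA = 0.019,
                                                        SALN = 0.007),
                              p_suppression = 0.6, p_induction = 0.006,
                              dropout = 0.05, msd_draws = 1000L) {
  cfg <- list(seed = as.integer(seed), n_isolates = as.integer(n_isolates),
              media = media, targets = targets, timepoints = sort(timepoints),
              A_range = A_range, k_range = k_range, ti_range = ti_range,
              sigma = sigma, position_sigma = position_sigma,
              plate_sigma = plate_sigma, p_cooperation = p_cooperation,
              p_competition = p_competition, delta_msd = delta_msd,
              antifungal_prevalence = antifungal_prevalence,
              p_suppression = p_suppression, p_induction = p_induction,
              dropout = dropout, msd_draws = as.integer(msd_draws))
  probs <- c(cfg$p_cooperation, cfg$p_competition, cfg$p_suppression,
             cfg$p_induction, cfg$dropout, cfg$antifungal_prevalence)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$p_cooperation + cfg$p_competition > 1) {
    stop("p_cooperation + p_competition must not exceed 1")
  }
  if (cfg$n_isolates < 4L || cfg$n_isolates %% 4L != 0L || cfg$n_isolates > 384L) {
    stop("n_isolates must be a multiple of 4 between 4 and 384")
  }
  if (!all(cfg$media %in% names(cfg$antifungal_prevalence))) {
    stop("antifungal_prevalence must name every medium")
  }
  if (cfg$sigma < 0 || cfg$position_sigma < 0 || cfg$plate_sigma < 0) {
    stop("noise scales must be non-negative")
  }
  if ((cfg$p_cooperation > 0 || cfg$p_competition > 0) && cfg$delta_msd <= 2) {
    stop("impossible config: injected effect delta (", cfg$delta_msd,
         " MSD) must exceed the 2 MSD classification threshold")
  }
  structure(cfg, class = "simulation_config")
}

# Evaluate a function with a local, restorable RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Observed size/opacity from log2 biomass: the product must reproduce the
# biomass, the split is even in log space (only the product matters).
biomass_to_size_opacity <- function(b) {
  s <- 2^(b / 2)
  list(size = s, opacity = s)
}

#' Expected replicate-IF noise scale implied by a configuration
#'
#' Monte-Carlo estimate (deterministic given the config seed) of the median
#' replicate-IF standard deviation: simulated isolates with four replicate
#' spots at random positions are pushed through the actual QC + Gompertz
#' fitting + integration path, and the median per-isolate SD is returned.
#' Used to calibrate injected pair effects (`delta_msd` multiples).
#'
#' @param config A [simulation_config()].
#' @param n_draws Number of replicate-spot fits (default `config$msd_draws`,
#'   at least 1000 by default; four spots per isolate).
#' @return Length-1 numeric, the expected MSD (log2-biomass x hours).
#' @export
expected_msd <- function(config, n_draws = config$msd_draws) {
  stopifnot(inherits(config, "simulation_config"))
  n_sets <- max(1L, ceiling(n_draws / 4))
  tp <- config$timepoints
  with_local_seed(config$seed + 104729L, {
    sds <- vapply(seq_len(n_sets), function(i) {
      A <- stats::runif(1, config$A_range[1], config$A_range[2])
      k <- stats::runif(1, config$k_range[1], config$k_range[2])
      ti <- stats::runif(1, config$ti_range[1], config$ti_range[2])
      y <- gompertz(tp, A, k, ti)
      ifs <- vapply(1:4, function(r) {
        pos_eff <- stats::rnorm(1, 0, config$position_sigma)
        b <- y + pos_eff + stats::rnorm(length(tp), 0, config$sigma)
        b <- pmax(b, 0)  # the biomass floor applied on re-read
        keep <- stats::runif(length(tp)) >= config$dropout
        qc <- qc_filter(tp[keep], b[keep])
        if (!qc$pass) return(NA_real_)
        f <- fit_gompertz(qc$times, qc$biomass)
        if (f$status != "accepted") return(NA_real_)
        integrated_fitness(f$A, f$k, f$t_i)
      }, numeric(1))
      ifs <- ifs[is.finite(ifs)]
      if (length(ifs) >= 2L) stats::sd(ifs) else NA_real_
    }, numeric(1))
    sds <- sds[is.finite(sds)]
    if (length(sds) == 0L) stop("no usable replicate sets in MSD calibration")
    stats::median(sds)
  })
}

#' Simulate a complete plate experiment with ground truth
#'
#' Deterministic given the config. Generates, per medium: the nine layouts
#' (MSP, RSP1-4, INT1-4), per-timepoint quantification tables for every
#' plate (size and opacity back-computed from noisy log2 biomass, with
#' dropout), halo score tables for every plate and target, and ground-truth
#' tables (true Gompertz parameters and antifungal flags per isolate, true
#' ecological and functional class per pair instance).
#'
#' Pair growth follows the dominant partner's Gompertz curve (the one with
#' the larger individual IF) with its asymptote rescaled so the pair's true
#' IF matches the intended class: cooperative pairs at max(IF1, IF2) + delta,
#' competitive at min(IF1, IF2) - delta (delta = `delta_msd` expected MSD),
#' neutral within half an expected MSD of the dominant individual
#' (comfortably inside the ±2 MSD neutral band, so the generator's null is
#' recoverable under comparison noise). The IF is
#' exactly linear in the asymptote, so the injected effect is exact, and the
#' pair observable stays inside the model family the analysis fits. Self
#' pairs grow exactly like the isolate alone.
#'
#' @param config A [simulation_config()].
#' @return A `sim_bundle` list: `config`, `layouts`, `quant` (one tidy
#'   data.frame), `halos`, `truth` (list of `isolates`, `pairs`,
#'   `msd_expected`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  msd_exp <- expected_msd(config)
  delta <- config$delta_msd * msd_exp
  tp <- config$timepoints
  n_per_plate <- config$n_isolates / 4L
  # partial source plates are filled interior-first: border positions of the
  # condensed 384 array are known growth artifacts, so a partial layout
  # keeps all four replicates of an isolate usable for MSD estimation
  p96 <- all_positions(96)
  idx96 <- pos_parse(p96)
  ring <- pmin(idx96$row - 1L, 8L - idx96$row, idx96$col - 1L, 12L - idx96$col)
  pos96 <- p96[order(-ring, idx96$row, idx96$col)][seq_len(n_per_plate)]

  with_local_seed(config$seed, {
    layouts <- list()
    quant <- list()
    halos <- list()
    iso_truth <- list()
    pair_truth <- list()

    for (medium in config$media) {
      ids <- sprintf("%s-I%03d", medium, seq_len(config$n_isolates))
      params <- data.frame(
        isolate = ids, medium = medium,
        A = stats::runif(config$n_isolates, config$A_range[1], config$A_range[2]),
        k = stats::runif(config$n_isolates, config$k_range[1], config$k_range[2]),
        t_i = stats::runif(config$n_isolates, config$ti_range[1], config$ti_range[2])
      )
      params$IF_true <- integrated_fitness(params$A, params$k, params$t_i)
      af <- matrix(FALSE, config$n_isolates, length(config$targets),
                   dimnames = list(ids, config$targets))
      prev <- config$antifungal_prevalence[[medium]]
      for (tg in config$targets) {
        af[, tg] <- stats::runif(config$n_isolates) < prev
      }
      iso_truth[[medium]] <- cbind(params,
                                   as.data.frame(af)[
                                     , , drop = FALSE])

      source_plates <- lapply(1:4, function(q) {
        occ <- ids[(q - 1L) * n_per_plate + seq_len(n_per_plate)]
        names(occ) <- pos96
        occ
      })
      names(source_plates) <- paste0(medium, "-P", 1:4)
      med_layouts <- assemble_layouts(source_plates, medium)
      layouts <- c(layouts, med_layouts)

      pos384 <- all_positions(384)
      pos_eff <- stats::rnorm(length(pos384), 0, config$position_sigma)
      names(pos_eff) <- pos384

      coarse_curves <- lapply(seq_len(nrow(params)), function(i) {
        gompertz(tp, params$A[i], params$k[i], params$t_i[i])
      })
      names(coarse_curves) <- params$isolate
      curve_of <- function(iso) coarse_curves[[iso]]

      # per-plate true curves per occupied position
      plate_curves <- list()
      for (lname in names(med_layouts)) {
        l <- med_layouts[[lname]]
        if (l$role != "interaction") {
          occ <- vapply(l$occupants, `[`, "", 1L)
          plate_curves[[lname]] <- lapply(occ, curve_of)
        }
      }

      # pair instances: class assignment and rescaled curves
      msp <- med_layouts[[paste0(medium, "-MSP")]]
      for (r in 1:4) {
        int <- med_layouts[[paste0(medium, "-INT", r)]]
        rsp <- med_layouts[[paste0(medium, "-RSP", r)]]
        pairing <- match_pair_to_individuals(int, msp, rsp)
        n_pairs <- nrow(pairing)
        cls <- rep("neutral", n_pairs)
        non_self <- !pairing$self_pair
        u <- stats::runif(n_pairs)
        cls[non_self & u < config$p_cooperation] <- "cooperation"
        cls[non_self & u >= config$p_cooperation &
              u < config$p_cooperation + config$p_competition] <- "competition"
        shift_u <- stats::runif(n_pairs, -0.5, 0.5)

        curves <- vector("list", n_pairs)
        if_pair_true <- numeric(n_pairs)
        for (i in seq_len(n_pairs)) {
          i1 <- pairing$isolate_msp[i]
          i2 <- pairing$isolate_rsp[i]
          p1 <- params[match(i1, params$isolate), ]
          p2 <- params[match(i2, params$isolate), ]
          if (pairing$self_pair[i]) {
            curves[[i]] <- curve_of(i1)
            if_pair_true[i] <- p1$IF_true
            next
          }
          # the pair spot grows like its dominant partner (larger IF), with
          # the asymptote rescaled to place the pair IF at the class target
          # (IF is exactly linear in A)
          dom <- if (p1$IF_true >= p2$IF_true) i1 else i2
          if_dom <- max(p1$IF_true, p2$IF_true)
          target_if <- switch(cls[i],
            cooperation = if_dom + delta,
            competition = min(p1$IF_true, p2$IF_true) - delta,
            neutral = if_dom + shift_u[i] * msd_exp)
          if (target_if <= 0) {
            stop("impossible config: injected pair effect drives IF below zero")
          }
          curves[[i]] <- (target_if / if_dom) * curve_of(dom)
          if_pair_true[i] <- target_if
        }
        names(curves) <- pairing$position
        plate_curves[[int$plate_id]] <- curves

        pair_truth[[int$plate_id]] <- data.frame(
          pair_id = paste0(int$plate_id, ":", pairing$position),
          medium = medium, plate_id = int$plate_id,
          position = pairing$position,
          isolate_1 = pairing$isolate_msp, isolate_2 = pairing$isolate_rsp,
          self_pair = pairing$self_pair, eco_class_true = cls,
          IF_pair_true = if_pair_true,
          IF_ind1_true = params$IF_true[match(pairing$isolate_msp, params$isolate)],
          IF_ind2_true = params$IF_true[match(pairing$isolate_rsp, params$isolate)]
        )
      }

      # observations: quant tables per plate x timepoint
      for (lname in names(med_layouts)) {
        l <- med_layouts[[lname]]
        curves <- plate_curves[[lname]]
        pos <- names(curves)
        idx <- pos_parse(pos)
        offset <- stats::rnorm(1, 0, config$plate_sigma)
        cm <- do.call(rbind, curves)  # n_pos x n_timepoints
        noise <- matrix(stats::rnorm(length(cm), 0, config$sigma), nrow(cm))
        b <- cm + offset + pos_eff[pos] + noise
        detected <- matrix(stats::runif(length(cm)) >= config$dropout, nrow(cm))
        for (j in seq_along(tp)) {
          keep <- detected[, j]
          if (!any(keep)) next
          so <- biomass_to_size_opacity(b[keep, j])
          quant[[paste0(lname, "_t", tp[j])]] <- data.frame(
            plate_id = lname, position = pos[keep],
            row = idx$row[keep], column = idx$col[keep], time_h = tp[j],
            size = so$size, opacity = so$opacity)
        }
      }

      # halo scores: individual plates carry the isolate's flags; pair
      # plates apply suppression / induction
      for (tg in config$targets) {
        for (lname in names(med_layouts)) {
          l <- med_layouts[[lname]]
          pos <- names(l$occupants)
          if (l$role != "interaction") {
            iso <- vapply(l$occupants, `[`, "", 1L)
            flag <- af[iso, tg]
          } else {
            i1 <- vapply(l$occupants, `[`, "", 1L)
            i2 <- vapply(l$occupants, `[`, "", 2L)
            base <- af[i1, tg] | af[i2, tg]
            udraw <- stats::runif(length(pos))
            flag <- ifelse(base, udraw >= config$p_suppression,
                           udraw < config$p_induction)
          }
          halos[[paste0(lname, "_", tg)]] <- data.frame(
            plate_id = lname, position = pos, target = tg,
            antifungal = unname(flag))
        }
      }
    }

    quant <- do.call(rbind, quant)
    halos <- do.call(rbind, halos)
    rownames(quant) <- rownames(halos) <- NULL
    iso_truth <- do.call(rbind, iso_truth)
    rownames(iso_truth) <- NULL
    pairs <- do.call(rbind, pair_truth)
    rownames(pairs) <- NULL

    # true functional class per pair instance x target, from the halo draws
    func <- list()
    for (tg in config$targets) {
      h <- halos[halos$target == tg, ]
      key <- paste(h$plate_id, h$position)
      hflag <- h$antifungal
      names(hflag) <- key
      pair_flag <- hflag[paste(pairs$plate_id, pairs$position)]
      i1_flag <- iso_truth[match(pairs$isolate_1, iso_truth$isolate), tg]
      i2_flag <- iso_truth[match(pairs$isolate_2, iso_truth$isolate), tg]
      func[[tg]] <- classify_functional(pair_flag, i1_flag, i2_flag)
    }
    for (tg in config$targets) {
      pairs[[paste0("func_true_", tg)]] <- func[[tg]]
    }

    structure(list(config = config, layouts = layouts, quant = quant,
                   halos = halos,
                   truth = list(isolates = iso_truth, pairs = pairs,
                                msd_expected = msd_exp)),
              class = "sim_bundle")
  })
}

#' Write or read a simulated bundle as plain-text files
#'
#' The on-disk bundle uses exactly the formats the IO layer reads:
#' `layouts.json`, `quant/<plate>_t<hour>.tsv` (IRIS dialect),
#' `halos.csv`, plus ground truth (`truth_isolates.csv`,
#' `truth_pairs.csv`) and the config (`config.json`).
#'
#' @param bundle A `sim_bundle` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()` returns
#'   a list with `layouts`, `quant`, `halos`, and (when present) `truth` and
#'   `config`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(file.path(dir, "quant"), recursive = TRUE, showWarnings = FALSE)
  write_layouts(bundle$layouts, file.path(dir, "layouts.json"))
  for (key in unique(paste(bundle$quant$plate_id, bundle$quant$time_h))) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1L]]
    plate <- parts[1L]
    th <- as.numeric(parts[2L])
    x <- bundle$quant[bundle$quant$plate_id == plate & bundle$quant$time_h == th, ]
    write_quant_table(x, file.path(dir, "quant", sprintf("%s_t%04d.tsv", plate, as.integer(round(th)))),
                      plate_id = plate,
                      array_format = bundle$layouts[[plate]]$array_format,
                      time_h = th)
  }
  write_halo_table(bundle$halos, file.path(dir, "halos.csv"))
  utils::write.csv(bundle$truth$isolates, file.path(dir, "truth_isolates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$truth$pairs, file.path(dir, "truth_pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- unclass(bundle$config)
  jsonlite::write_json(c(cfg, list(msd_expected = bundle$truth$msd_expected)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  layouts <- read_layouts(file.path(dir, "layouts.json"))
  files <- list.files(file.path(dir, "quant"), pattern = "\\.tsv$",
                      full.names = TRUE)
  quant <- do.call(rbind, lapply(files, read_quant_table))
  rownames(quant) <- NULL
  halos <- read_halo_table(file.path(dir, "halos.csv"))
  out <- list(layouts = layouts, quant = quant, halos = halos)
  tiso <- file.path(dir, "truth_isolates.csv")
  tpair <- file.path(dir, "truth_pairs.csv")
  if (file.exists(tiso) && file.exists(tpair)) {
    out$truth <- list(isolates = utils::read.csv(tiso),
                      pairs = utils::read.csv(tpair))
  }
  cfgp <- file.path(dir, "config.json")
  if (file.exists(cfgp)) out$config <- jsonlite::fromJSON(cfgp)
  out
}
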