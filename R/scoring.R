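# Classification of pairwise interaction outcomes.
#
# Ecological outcome (from integrated fitness): a pair is cooperative iff its
# IF exceeds BOTH individual IFs by more than twice the MSD; competitive iff
# its IF falls below both individual IFs by more than twice the MSD; neutral
# otherwise. Inequalities are strict, so a value sitting exactly on the
# +/- 2 MSD boundary is neutral.
#
# Functional outcome (from qualitative halo flags): induction iff the pair is
# antifungal while neither individual is; suppression iff the pair is not
# antifungal while at least one individual is (the `strict_one_sided` flag
# restricts this to exactly one active individual); neutral otherwise.

ECO_CLASSES <- c("cooperation", "competition", "neutral")
FUNC_CLASSES <- c("induction", "suppression", "neutral")

#' Classify the ecological outcome of pair instances
#'
#' @param if_pair IF of the pair spot.
#' @param if_ind1,if_ind2 IF of the two individual reference spots (same
#'   position, separate plates). The rule is symmetric in the two.
#' @param msd Replicate-noise scale (median standard deviation), `>= 0`.
#' @return Character vector: `"cooperation"`, `"competition"`, `"neutral"`,
#'   or `"unscored"` when any input is missing.
#' @export
classify_ecological <- function(if_pair, if_ind1, if_ind2, msd) {
  if (any(is.finite(msd) & msd < 0)) stop("msd must be non-negative")
  n <- max(length(if_pair), length(if_ind1), length(if_ind2))
  if_pair <- rep_len(if_pair, n)
  hi <- pmax(rep_len(if_ind1, n), rep_len(if_ind2, n))
  lo <- pmin(rep_len(if_ind1, n), rep_len(if_ind2, n))
  msd <- rep_len(msd, n)
  out <- rep("neutral", n)
  out[if_pair > hi + 2 * msd] <- "cooperation"
  out[if_pair < lo - 2 * msd] <- "competition"
  out[!is.finite(if_pair) | !is.finite(hi) | !is.finite(lo) | !is.finite(msd)] <- "unscored"
  out
}

#' Classify the functional (antifungal) outcome of pair instances
#'
#' @param halo_pair,halo_ind1,halo_ind2 Logical halo flags (pair spot and the
#'   two individual spots) for one target yeast.
#' @param strict_one_sided If `TRUE`, suppression requires exactly one active
#'   individual; by default both-active with an inactive pair also counts as
#'   suppression (the functional loss is the same).
#' @return Character vector: `"induction"`, `"suppression"`, `"neutral"`, or
#'   `"unscored"` when any flag is missing.
#' @export
classify_functional <- function(halo_pair, halo_ind1, halo_ind2,
                                strict_one_sided = FALSE) {
  n <- max(length(halo_pair), length(halo_ind1), length(halo_ind2))
  p <- rep_len(as.logical(halo_pair), n)
  i1 <- rep_len(as.logical(halo_ind1), n)
  i2 <- rep_len(as.logical(halo_ind2), n)
  ind_active <- if (strict_one_sided) xor(i1, i2) else (i1 | i2)
  out <- rep("neutral", n)
  out[p & !i1 & !i2] <- "induction"
  out[!p & ind_active] <- "suppression"
  out[is.na(p) | is.na(i1) | is.na(i2)] <- "unscored"
  out
}

#' Ecological behavior profile of one isolate
#'
#' Summarizes an isolate's outcomes over its three partner pairs (the
#' screening design pairs every isolate with three other isolates and
#' itself; self pairs are not part of the profile).
#'
#' @param eco_classes Character vector of ecological classes of the isolate's
#'   non-self pair instances (expected length 3; `"unscored"` entries allowed).
#' @param antifungal Logical: does the isolate show antifungal activity on
#'   its own?
#' @return List with `n_interactions`, `n_cooperative`, `n_competitive`,
#'   `antifungal`, and `incomplete` (TRUE when fewer than 3 scored outcomes).
#' @export
behavior_profile <- function(eco_classes, antifungal = FALSE) {
  scored <- eco_classes[eco_classes %in% ECO_CLASSES]
  list(n_interactions = length(scored),
       n_cooperative = sum(scored == "cooperation"),
       n_competitive = sum(scored == "competition"),
       antifungal = isTRUE(antifungal),
       incomplete = length(scored) < 3L)
}

#' Antifungal spectrum class of an isolate
#'
#' K. lactis and S. cerevisiae belong to the same phylogenetic family;
#' C. boidinii to a different one. Activity against both K. lactis and
#' S. cerevisiae (but not C. boidinii) is an intrafamily spectrum; activity
#' against C. boidinii together with at least one of the other two (which
#' includes all three) crosses families (interfamily). Single-target or no
#' activity is "none".
#'
#' @param kl,sc,cb Logical activity flags against K. lactis, S. cerevisiae,
#'   and C. boidinii (vectorized).
#' @return Character vector: `"interfamily"`, `"intrafamily"`, or `"none"`.
#' @export
spectrum_class <- function(kl, sc, cb) {
  n <- max(length(kl), length(sc), length(cb))
  kl <- rep_len(as.logical(kl), n)
  sc <- rep_len(as.logical(sc), n)
  cb <- rep_len(as.logical(cb), n)
  out <- rep("none", n)
  out[kl & sc & !cb] <- "intrafamily"
  out[cb & (kl | sc)] <- "interfamily"
  out[is.na(kl) | is.na(sc) | is.na(cb)] <- NA_character_
  out
}

#' Cross-condition stability of interaction outcomes
#'
#' Square transition table of per-pair class labels scored under two
#' conditions (e.g. two culture media). The diagonal sum is the percentage
#' of outcomes scored the same in both.
#'
#' @param classes_a,classes_b Class labels of the same pair set under
#'   condition A and B. If both are named, names must match as sets and are
#'   used to align the pairs.
#' @param levels Label universe (default: the union of observed labels).
#' @return List with `counts` (square matrix A x B), `n`, `diagonal_pct`
#'   (half-up, 1 decimal), and `percentages` (counts / n * 100).
#' @export
stability_matrix <- function(classes_a, classes_b, levels = NULL) {
  if (!is.null(names(classes_a)) && !is.null(names(classes_b))) {
    if (!setequal(names(classes_a), names(classes_b))) {
      stop("pair-set mismatch between the two conditions")
    }
    classes_b <- classes_b[names(classes_a)]
  } else if (length(classes_a) != length(classes_b)) {
    stop("pair-set mismatch: label vectors differ in length")
  }
  if (is.null(levels)) levels <- sort(unique(c(classes_a, classes_b)))
  a <- factor(classes_a, levels = levels)
  b <- factor(classes_b, levels = levels)
  if (anyNA(a) || anyNA(b)) stop("labels outside the declared levels")
  counts <- table(A = a, B = b)
  counts <- matrix(as.integer(counts), nrow = length(levels),
                   dimnames = list(A = levels, B = levels))
  n <- sum(counts)
  if (n == 0L) stop("no pairs to compare")
  list(counts = counts, n = n,
       diagonal_pct = round_half_up(100 * sum(diag(counts)) / n, 1),
       percentages = 100 * counts / n)
}
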