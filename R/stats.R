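# Contingency-table statistics and tally helpers for the report layer.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed summary percentages use
#' conventional half-up rounding at the reported precision.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Likelihood-ratio (G) test of independence
#'
#' G = 2 * sum(observed * ln(observed / expected)) over non-zero cells, with
#' (r - 1)(c - 1) degrees of freedom and an upper-tail chi-square p-value.
#' This is the likelihood-ratio chi-square reported as "Log likelihood,
#' Chi-square Prob" by common statistical packages.
#'
#' @param x Matrix of non-negative counts (at least 2 x 2); zero rows or
#'   columns are an error.
#' @return An object of class `htest` with `statistic` (G), `parameter`
#'   (df), `p.value`, `observed`, `expected`.
#' @export
g_test <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0) || any(!is.finite(x))) stop("counts must be finite and non-negative")
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least a 2 x 2 table")
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero marginal total: every row and column must contain counts")
  }
  E <- outer(rs, cs) / sum(x)
  G <- 2 * sum(ifelse(x > 0, x * log(x / E), 0))
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  structure(list(statistic = c(G = G), parameter = c(df = df),
                 p.value = stats::pchisq(G, df, lower.tail = FALSE),
                 method = "Likelihood-ratio (G) test of independence",
                 data.name = deparse(substitute(x)),
                 observed = x, expected = E),
            class = "htest")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact hypergeometric p-value with margins fixed. The right-sided p-value
#' sums the probabilities of tables at least as extreme in the [1,1] cell;
#' the two-sided p-value sums the probabilities of all tables no more
#' probable than the observed one.
#'
#' @param x 2 x 2 matrix of non-negative integer counts; a zero row or
#'   column margin is an error.
#' @param side `"two_sided"` (default) or `"right"`.
#' @return The p-value (length-1 numeric).
#' @export
fisher_exact <- function(x, side = c("two_sided", "right")) {
  side <- match.arg(side)
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) stop("fisher_exact requires a 2 x 2 table")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) stop("degenerate margin: zero row or column total")
  a <- x[1L, 1L]
  support <- max(0L, cs[1L] - rs[2L]):min(rs[1L], cs[1L])
  # P(a) with margins fixed: hypergeometric(white = row1 total, black = row2
  # total, drawn = col1 total)
  probs <- stats::dhyper(support, rs[1L], rs[2L], cs[1L])
  p_obs <- probs[match(a, support)]
  p <- if (side == "right") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  min(1, unname(p))
}

#' Counts and percentages of class labels
#'
#' The tally layer behind every reported proportion: per (group, class), the
#' count, the group denominator, and the percentage rounded half-up to the
#' requested number of decimals.
#'
#' @param x Vector of class labels (character, factor, or logical).
#' @param by Optional grouping vector (same length as `x`).
#' @param decimals Decimal places for the percentage (printed summaries use
#'   2 for isolate-level rates, 1 elsewhere).
#' @return data.frame with columns `group` (absent when `by` is NULL),
#'   `class`, `count`, `denominator`, `pct`.
#' @export
proportion_summary <- function(x, by = NULL, decimals = 1) {
  if (length(x) == 0L) stop("empty denominator: no records to summarize")
  x <- as.character(x)
  if (is.null(by)) {
    tab <- table(x)
    out <- data.frame(class = names(tab), count = as.integer(tab),
                      denominator = length(x))
  } else {
    stopifnot(length(by) == length(x))
    tab <- table(group = as.character(by), class = x)
    denom <- rowSums(tab)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("group", "class", "count")
    out$count <- as.integer(out$count)
    out$denominator <- as.integer(denom[out$group])
  }
  out$pct <- round_half_up(100 * out$count / out$denominator, decimals)
  rownames(out) <- NULL
  out
}

#' Venn region counts over 2 or 3 flag sets
#'
#' @param flags Logical matrix or data.frame (one column per set, one row
#'   per item, e.g. per isolate) with 2 or 3 columns.
#' @return Named integer vector of exclusive region counts (names like
#'   `"A"`, `"A&B"`); the regions partition the set of items with at least
#'   one flag.
#' @export
venn_counts <- function(flags) {
  flags <- as.matrix(flags)
  if (!ncol(flags) %in% c(2L, 3L)) stop("venn_counts supports 2 or 3 sets")
  if (is.null(colnames(flags))) colnames(flags) <- LETTERS[seq_len(ncol(flags))]
  mode(flags) <- "logical"
  if (anyNA(flags)) stop("flags must not contain NA")
  sets <- colnames(flags)
  regions <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  regions <- regions[rowSums(regions) > 0L, , drop = FALSE]
  names(regions) <- sets
  counts <- apply(regions, 1L, function(r) {
    sum(apply(flags, 1L, function(f) all(f == r)))
  })
  names(counts) <- apply(regions, 1L, function(r) paste(sets[as.logical(r)], collapse = "&"))
  counts[order(nchar(names(counts)), names(counts))]
}
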