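# interaction_scoring: ecological and functional classification, behavior
# profiles, spectrum classes, cross-media stability.

test_that("classify_ecological applies the strict +/- 2 MSD rule", {
  expect_equal(classify_ecological(10, 5, 6, 1), "cooperation")  # 10 > 6 + 2
  expect_equal(classify_ecological(8, 5, 6, 1), "neutral")       # tie, strict
  expect_equal(classify_ecological(2, 5, 6, 1), "competition")   # 2 < 5 - 2
  expect_equal(classify_ecological(3, 5, 6, 1), "neutral")       # tie below
  expect_equal(classify_ecological(NA, 5, 6, 1), "unscored")
  expect_equal(classify_ecological(10, NA, 6, 1), "unscored")
  expect_error(classify_ecological(1, 1, 1, -0.5), "non-negative")
})

test_that("classify_functional matches its definition on all 8 inputs", {
  expect_equal(classify_functional(TRUE, FALSE, FALSE), "induction")
  expect_equal(classify_functional(FALSE, TRUE, FALSE), "suppression")
  expect_equal(classify_functional(TRUE, TRUE, FALSE), "neutral")
  expect_equal(classify_functional(NA, TRUE, FALSE), "unscored")
  # both-active + inactive pair: suppression by default, neutral when strict
  expect_equal(classify_functional(FALSE, TRUE, TRUE), "suppression")
  expect_equal(classify_functional(FALSE, TRUE, TRUE, strict_one_sided = TRUE),
               "neutral")
})

test_that("behavior_profile counts outcomes and flags incompleteness", {
  p <- behavior_profile(c("competition", "competition", "competition"), TRUE)
  expect_equal(p$n_competitive, 3L)
  expect_equal(p$n_cooperative, 0L)
  expect_false(p$incomplete)
  expect_true(p$antifungal)
  p <- behavior_profile(c("cooperation", "neutral", "competition"))
  expect_equal(c(p$n_cooperative, p$n_competitive), c(1L, 1L))
  expect_true(p$n_cooperative + p$n_competitive <= p$n_interactions)
  p <- behavior_profile(c("cooperation", "neutral", "unscored"))
  expect_true(p$incomplete)
  expect_equal(p$n_interactions, 2L)
})

test_that("spectrum_class separates intra- and interfamily activity", {
  expect_equal(spectrum_class(TRUE, TRUE, FALSE), "intrafamily")
  expect_equal(spectrum_class(TRUE, TRUE, TRUE), "interfamily")
  expect_equal(spectrum_class(FALSE, FALSE, FALSE), "none")
  # full truth table: interfamily iff cb & (kl | sc); intra iff kl & sc & !cb
  g <- expand.grid(kl = c(FALSE, TRUE), sc = c(FALSE, TRUE), cb = c(FALSE, TRUE))
  got <- spectrum_class(g$kl, g$sc, g$cb)
  want <- ifelse(g$cb & (g$kl | g$sc), "interfamily",
                 ifelse(g$kl & g$sc & !g$cb, "intrafamily", "none"))
  expect_equal(got, want)
})

test_that("stability_matrix tabulates transitions and the stable fraction", {
  lv <- c("cooperation", "competition", "neutral")
  a <- rep(lv, times = c(3, 4, 5))
  expect_equal(stability_matrix(a, a, lv)$diagonal_pct, 100)
  # printed-style case: 86 matching labels out of 166 -> 51.8%
  a2 <- rep(c("neutral", "competition", "cooperation"), c(100, 40, 26))
  b2 <- a2
  b2[1:50] <- "competition"  # 50 neutrals flip
  b2[101:130] <- "neutral"   # 30 competitions flip
  expect_equal(sum(a2 == b2), 86L)
  expect_equal(stability_matrix(a2, b2, lv)$diagonal_pct, 51.8)
  # fully discordant vectors
  expect_equal(stability_matrix(rep("neutral", 5), rep("competition", 5),
                                lv)$diagonal_pct, 0)
  # pair-set mismatch
  expect_error(stability_matrix(c(x = "neutral"), c(y = "neutral")),
               "mismatch")
  expect_error(stability_matrix(rep("neutral", 3), rep("neutral", 4)),
               "mismatch")
})

test_that("ecological classification properties hold on random cases", {
  set.seed(123)
  n <- 10000L
  if_pair <- runif(n, -50, 650)
  i1 <- runif(n, 0, 600)
  i2 <- runif(n, 0, 600)
  msd <- runif(n, 0, 30)
  # invariant under swapping the two individuals
  expect_identical(classify_ecological(if_pair, i1, i2, msd),
                   classify_ecological(if_pair, i2, i1, msd))
  # msd -> infinity: everything neutral
  expect_true(all(classify_ecological(if_pair, i1, i2, 1e9) == "neutral"))
  # msd = 0 reduces to strict dominance over both individuals
  cls0 <- classify_ecological(if_pair, i1, i2, 0)
  dom <- ifelse(if_pair > pmax(i1, i2), "cooperation",
                ifelse(if_pair < pmin(i1, i2), "competition", "neutral"))
  expect_identical(cls0, dom)
  # exact boundary ties are neutral
  expect_true(all(classify_ecological(pmax(i1, i2) + 2 * msd, i1, i2, msd)
                  == "neutral"))
  expect_true(all(classify_ecological(pmin(i1, i2) - 2 * msd, i1, i2, msd)
                  == "neutral"))
})
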