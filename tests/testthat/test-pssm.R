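test_that("per-position frequencies count letters correctly", {
  p1 <- compute_frequencies("SHL")
  expect_equal(unname(p1$freq["S", 1]), 1)
  expect_equal(unname(p1$freq["H", 2]), 1)
  expect_equal(unname(colSums(p1$freq)), rep(1, 3))
  p4 <- compute_frequencies(c("S", "S", "H", "L"))
  expect_equal(unname(p4$freq[c("S", "H", "L"), 1]), c(0.5, 0.25, 0.25))
  expect_error(compute_frequencies(c("SS", "S")), "ragged")
  expect_error(compute_frequencies("SX"), "alphabet")
})

test_that("delta between dominant and dominant+suboptimal sets behaves algebraically", {
  a <- compute_frequencies(c("SH", "SH"))
  expect_equal(delta_sse(a, a), matrix(0, 7, 2, dimnames = list(SSE_KINDS, NULL)))
  dom <- compute_frequencies(c("S", "S"))
  dsub <- compute_frequencies(c("S", "H"))
  d <- delta_sse(dom, dsub)
  expect_equal(unname(d["S", 1]), 50)
  expect_equal(unname(d["H", 1]), -50)
  # column sums are identically zero
  set.seed(5)
  for (rep in 1:20) {
    x <- compute_frequencies(replicate(6, random_ss_string(9, SSE_KINDS)))
    y <- compute_frequencies(replicate(9, random_ss_string(9, SSE_KINDS)))
    expect_equal(unname(colSums(delta_sse(x, y))), rep(0, 9))
  }
  expect_error(delta_sse(dom, a), "different lengths")
})

test_that("PSSM matches the hand-computed smoothing example", {
  p <- compute_pssm(c("S", "S", "S", "H"),
                    c("S", "H", "L", "I", "G", "D", "M"), alpha = 1)
  expect_equal(unname(p$theta["S", 1]), 4 / 11)
  expect_equal(unname(p$W["S", 1]), 0.75 * log2((4 / 11) / (1 / 7)))
  expect_equal(unname(colSums(p$theta)), 1)
  expect_equal(unname(colSums(p$mu)), 1)
  expect_error(compute_pssm("S", "S", alpha = 0), "alpha")
  expect_error(compute_pssm("SS", "S"), "different lengths")
})

test_that("a foreground matching the background scores exactly zero", {
  set.seed(11)
  bg <- replicate(49, random_ss_string(8, SSE_KINDS))
  p <- compute_pssm(bg, bg, alpha = 1e-9)
  expect_lt(max(abs(p$S)), 1e-6)
})

test_that("enrichment sign and absence behaviour follow the score definitions", {
  set.seed(12)
  bg <- replicate(70, random_ss_string(5, SSE_KINDS))
  fg <- replicate(20, random_ss_string(5, c("S", "H")))
  p <- compute_pssm(fg, bg, alpha = 1)
  # enriched letters score positive wherever f > mu and H > 0
  sel <- p$f > p$mu & matrix(p$H > 0, 7, 5, byrow = TRUE)
  expect_true(all(p$S[sel] >= 0))
  # absent letters: S is 0 but the display score is negative
  absent <- p$counts == 0
  expect_true(any(absent))
  expect_true(all(p$S[absent] == 0))
  expect_true(all(p$Dsp[absent & matrix(p$H > 0, 7, 5, byrow = TRUE)] < 0))
})

test_that("the score is invariant to duplicating the foreground", {
  set.seed(13)
  bg <- replicate(30, random_ss_string(6, SSE_KINDS))
  fg <- replicate(10, random_ss_string(6, SSE_KINDS))
  p1 <- compute_pssm(fg, bg, alpha = 1)
  # theta changes with N, so invariance holds in the alpha -> 0 limit
  p1 <- compute_pssm(fg, bg, alpha = 1e-12)
  p2 <- compute_pssm(c(fg, fg), bg, alpha = 1e-12)
  expect_equal(p1$S, p2$S, tolerance = 1e-6)
})

test_that("adding one matching string raises the cell's smoothed estimate", {
  # theta = (7*alpha*mu + c) / (7*alpha + N) strictly increases when the
  # cell's count is incremented (the full score S = H * W need not: the
  # entropy and frequency factors can shrink elsewhere)
  set.seed(14)
  bg <- replicate(40, random_ss_string(4, SSE_KINDS))
  fg <- replicate(12, random_ss_string(4, SSE_KINDS))
  p0 <- compute_pssm(fg, bg, alpha = 1)
  extra <- random_ss_string(4, SSE_KINDS)
  p1 <- compute_pssm(c(fg, extra), bg, alpha = 1)
  k <- match(strsplit(extra, "")[[1]], SSE_KINDS)
  for (j in 1:4) {
    expect_gt(p1$theta[k[j], j], p0$theta[k[j], j])
  }
})

test_that("string scoring and best match follow the matrix", {
  set.seed(15)
  bg <- replicate(30, random_ss_string(3, SSE_KINDS))
  fg <- replicate(10, random_ss_string(3, c("S", "H", "L")))
  p <- compute_pssm(fg, bg, alpha = 1)
  # the per-position argmax string scores at least as high as any other
  arg <- paste(SSE_KINDS[apply(p$S, 2, which.max)], collapse = "")
  all3 <- expand.grid(SSE_KINDS, SSE_KINDS, SSE_KINDS)
  others <- apply(all3, 1, paste, collapse = "")
  top <- score_string(p, arg)
  expect_true(all(vapply(others, function(s) score_string(p, s), 0) <= top + 1e-12))
  pool <- c(a = others[1], b = arg, c = others[2])
  expect_equal(as.character(best_match(p, pool)), "b")
  expect_error(score_string(p, "SXH"), "alphabet")
  expect_error(score_string(p, "SSSS"), "length")
  # an all-zero matrix scores every string 0
  pz <- p; pz$S[] <- 0
  expect_equal(score_string(pz, "SHL"), 0)
})
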