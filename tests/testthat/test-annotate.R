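test_that("simple structures are decomposed as expected", {
  # all unpaired
  a0 <- annotate_structure(base_pair_set(NULL, 10))
  expect_equal(a0$ss_string, strrep("S", 10))
  expect_equal(unname(a0$count_vector), c(1L, rep(0L, 6)))
  # single hairpin with 3' tail
  a1 <- annotate_structure(base_pair_set(cbind(1:5, 13:9), 15))
  expect_equal(a1$ss_string, "HHHHHLLLHHHHHSS")
  expect_equal(a1$count_vector[c("S", "H", "L")], c(S = 1L, H = 1L, L = 1L))
  expect_equal(to_ss_string(a1), a1$ss_string)
  # hairpin at 55-67 plus a long-range helix enclosing an interior hairpin:
  # the enclosing helix does not close a hairpin loop, so it is a duplex
  pr <- rbind(cbind(55:59, 67:63), c(5, 45), c(6, 44), cbind(20:22, 30:28))
  a2 <- annotate_structure(base_pair_set(pr, 69))
  expect_equal(substr(a2$ss_string, 55, 67), "HHHHHLLLHHHHH")
  expect_equal(substr(a2$ss_string, 5, 6), "DD")
  expect_equal(substr(a2$ss_string, 44, 45), "DD")
  expect_equal(a2$count_vector[["D"]], 1L)
  expect_equal(a2$count_vector[["H"]], 2L)
  expect_equal(a2$count_vector[["I"]], 1L)
  # bulge-interrupted stem: only the loop-closing helix is H
  prb <- rbind(c(1, 12), c(3, 11), c(4, 10))  # bulge at 2
  a3 <- annotate_structure(base_pair_set(prb, 12))
  expect_equal(a3$ss_string, "DGHHLLLLLHHD")
  expect_equal(a3$count_vector[c("H", "D", "G", "L")],
               c(H = 1L, D = 1L, G = 1L, L = 1L))
  expect_error(annotate_structure(base_pair_set(rbind(c(1, 8), c(4, 12)), 12)),
               "pseudoknot")
})

test_that("annotation matches the independent nesting-tree oracle on planted structures", {
  for (rep in 1:1000) {
    spec <- random_planted_spec(rep, max_len = 40L)
    bp <- plant_structure(spec)$pairs
    got <- annotate_structure(bp)
    want <- oracle_annotate(bp)
    expect_equal(got$ss_string, want$ss_string,
                 info = write_dotbracket(bp))
    expect_equal(unname(got$count_vector), unname(want$count_vector),
                 info = write_dotbracket(bp))
  }
})

test_that("plant then annotate recovers the requested element counts", {
  for (rep in 1:1000) {
    spec <- random_planted_spec(rep + 20000, max_len = 48L)
    out <- plant_structure(spec)
    got <- annotate_structure(out$pairs)$count_vector
    expect_equal(unname(got), unname(spec$element_counts),
                 info = write_dotbracket(out$pairs))
    expect_equal(nchar(out$record$sequence), spec$length)
  }
})

test_that("planted sequences are Watson-Crick compatible with their pairs", {
  spec <- planted_spec(40, c(S = 2, H = 2, L = 2, I = 1, D = 1), seed = 5)
  out <- plant_structure(spec)
  ch <- strsplit(out$record$sequence, "")[[1]]
  for (r in seq_len(NROW(out$pairs$pairs))) {
    pp <- paste0(ch[out$pairs$pairs[r, 1]], ch[out$pairs$pairs[r, 2]])
    expect_true(pp %in% c("AT", "TA", "GC", "CG"))
  }
})

test_that("unrealizable planted specs are rejected with a reason", {
  expect_error(planted_spec(20, c(G = 1)), "duplex count")
  expect_error(planted_spec(20, c(S = 2)), "single-stranded segment")
  expect_error(planted_spec(20, c(S = 1, H = 1, L = 2)), "H == L")
  expect_error(planted_spec(20, c(H = 1, L = 1, M = 1, D = 1)), "branches")
  expect_error(planted_spec(4, c(S = 1, H = 1, L = 1)), "minimum")
  expect_error(planted_spec(20, c(S = 3, H = 1, L = 1)), "exterior runs")
})

test_that("letters partition the strand between paired and unpaired classes", {
  for (rep in 1:200) {
    spec <- random_planted_spec(rep + 40000)
    bp <- plant_structure(spec)$pairs
    ann <- annotate_structure(bp)
    ch <- strsplit(ann$ss_string, "")[[1]]
    expect_length(ch, bp$length)
    paired <- rep(FALSE, bp$length)
    if (NROW(bp$pairs)) paired[c(bp$pairs)] <- TRUE
    expect_true(all(ch[paired] %in% c("H", "D")))
    expect_true(all(ch[!paired] %in% c("S", "L", "I", "G", "M")))
    # span lengths cover the strand
    el <- ann$elements[!is.na(ann$elements$start), ]
    expect_equal(sum(el$end - el$start + 1), bp$length)
  }
})

test_that("families group by exact element counts only, order-invariantly", {
  a <- annotate_structure(base_pair_set(NULL, 10))
  b <- annotate_structure(base_pair_set(NULL, 25))  # different length, same counts
  c3 <- annotate_structure(base_pair_set(cbind(1:3, 12:10), 12))
  cat1 <- assign_families(list(x = a, y = b, z = c3))
  expect_length(cat1$families, 1)
  expect_setequal(cat1$families[[1]], c("x", "y"))
  expect_equal(cat1$unassigned, "z")
  cat2 <- assign_families(list(z = c3, y = b, x = a))
  expect_setequal(cat2$families[[1]], c("x", "y"))
  expect_identical(names(cat1$families), names(cat2$families))
})

test_that("a planted all-but-multibranch structure lands in the matching family", {
  # counts with every element except multi-branched loops
  cv <- c(S = 2, H = 1, L = 1, I = 1, G = 1, D = 2, M = 0)
  out1 <- plant_structure(planted_spec(50, cv, seed = 1))
  out2 <- plant_structure(planted_spec(60, cv, seed = 2))
  ann <- list(p1 = annotate_structure(out1$pairs),
              p2 = annotate_structure(out2$pairs))
  expect_true(all(ann$p1$count_vector == cv))
  expect_true(!"M" %in% strsplit(ann$p1$ss_string, "")[[1]])
  expect_true(all(c("S", "H", "L", "I", "G", "D") %in%
                    strsplit(ann$p1$ss_string, "")[[1]]))
  cat <- assign_families(ann)
  expect_length(cat$families, 1)
  expect_setequal(cat$families[[1]], c("p1", "p2"))
})
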