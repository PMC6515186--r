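test_that("base_pair_set enforces its invariants", {
  expect_error(base_pair_set(rbind(c(1, 9), c(1, 8)), 10), "more than one pair")
  expect_error(base_pair_set(rbind(c(1, 4)), 10), "loop shorter")
  expect_error(base_pair_set(rbind(c(1, 8), c(4, 12)), 12), "pseudoknot")
  bps <- base_pair_set(rbind(c(2, 10), c(3, 9)), 12)
  expect_equal(NROW(bps$pairs), 2)
})

test_that("baseline folder reproduces forced small cases", {
  expect_equal(unname(baseline_fold("GGGAAACCC")$pairs$pairs),
               cbind(1:3, 9:7))
  expect_equal(unname(baseline_fold("ATATAT")$pairs$pairs),
               matrix(c(1L, 6L), 1))
  expect_equal(NROW(baseline_fold("GCGC")$pairs$pairs), 0)
  fs <- baseline_fold("AAAAAAAAAA")
  expect_equal(NROW(fs$pairs$pairs), 0)
  expect_equal(fs$dG, 0)
  expect_true(fs$pseudo)
})

test_that("baseline folder attains the exhaustive-search optimum on random short sequences", {
  set.seed(202)
  for (rep in 1:300) {
    len <- sample(5:12, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    got <- NROW(baseline_fold(s)$pairs$pairs)
    expect_equal(got, oracle_max_pairs(s), info = s)
  }
})

test_that("suboptimal window arithmetic, idempotence and monotonicity hold", {
  mk <- function(dg, id = "x") folded_structure(id, base_pair_set(NULL, 10), dg)
  st <- list(mk(-10.0), mk(-9.6), mk(-9.4))
  kept <- select_suboptimal(st, 0.05)
  expect_equal(vapply(kept, `[[`, 0, "dG"), c(-10.0, -9.6))
  expect_equal(vapply(kept, `[[`, "", "rank_label"), c("S1", "S2"))
  # single structure
  expect_length(select_suboptimal(list(mk(-3)), 0.05), 1)
  # unfolded dominant: zero-width window keeps ties only
  st0 <- list(mk(0), mk(0.3))
  expect_length(select_suboptimal(st0, 0.5), 1)
  expect_length(select_suboptimal(list(mk(0), mk(0)), 0.5), 2)
  # idempotent
  expect_equal(vapply(select_suboptimal(kept, 0.05), `[[`, 0, "dG"),
               vapply(kept, `[[`, 0, "dG"))
  # monotone in window
  for (w in c(0, 0.02, 0.05, 0.1, 0.5)) {
    small <- vapply(select_suboptimal(st, w), `[[`, 0, "dG")
    big <- vapply(select_suboptimal(st, w + 0.1), `[[`, 0, "dG")
    expect_true(all(small %in% big))
  }
  expect_error(select_suboptimal(st, -0.1), ">= 0")
})

test_that("dot-bracket parsing, writing and round trips work", {
  bps <- parse_dotbracket("((((...))))")
  expect_equal(unname(bps$pairs), cbind(1:4, 11:8))
  expect_equal(write_dotbracket(bps), "((((...))))")
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("..x.."), "position 3")
  set.seed(31)
  for (rep in 1:100) {
    spec <- random_planted_spec(rep + 5000)
    bp <- plant_structure(spec)$pairs
    expect_equal(unname(parse_dotbracket(write_dotbracket(bp))$pairs),
                 unname(bp$pairs))
  }
})

test_that("CT files round-trip and inconsistent pairing is rejected", {
  seqs <- "GGGAAACCCAA"
  fs <- baseline_fold(seqs)
  fs$dG <- -5.2
  f <- tempfile(fileext = ".ct")
  write_ct(seqs, fs, f)
  back <- parse_ct(f)
  expect_equal(back$sequence, seqs)
  expect_equal(back$structure$dG, -5.2)
  expect_equal(unname(back$structure$pairs$pairs), unname(fs$pairs$pairs))
  # corrupt reciprocity
  lines <- readLines(f)
  lines[2] <- sub(" 9 ", " 8 ", lines[2])  # row 1 now names 8, row 8 names 2
  writeLines(lines, f)
  expect_error(parse_ct(f), "reciprocal")
})

test_that("fold() with the baseline engine returns a ranked, validated structure", {
  rec <- sequence_record("t1", "GGGAAACCCAAAA", origin = "planted")
  out <- fold(rec, folding_conditions(), baseline_engine())
  expect_equal(out[[1]]$rank_label, "S1")
  expect_equal(out[[1]]$sequence_id, "t1")
  expect_true(all(diff(vapply(out, `[[`, 0, "dG")) >= 0))
})

test_that("ct_dir_engine serves dominant and suboptimal structures from disk", {
  dir <- tempfile(); dir.create(dir)
  s <- "GGGAAACCCAA"
  f1 <- baseline_fold(s); f1$dG <- -8
  f2 <- baseline_fold(s); f2$dG <- -7.8; f2$pairs <- base_pair_set(rbind(c(2, 9), c(3, 8)), 11)
  write_ct(s, f1, file.path(dir, "q_1.ct"))
  write_ct(s, f2, file.path(dir, "q_2.ct"))
  rec <- sequence_record("q", s, origin = "planted")
  out <- fold(rec, folding_conditions(), ct_dir_engine(dir))
  expect_length(out, 2)
  expect_equal(vapply(out, `[[`, 0, "dG"), c(-8, -7.8))
  expect_equal(vapply(out, `[[`, "", "rank_label"), c("S1", "S2"))
})

test_that("the standard-flank hairpin appears at bases 55-67 with a thermodynamic engine", {
  skip_if_not(vienna_available())
  rec <- sequence_record("allA",
                         paste0("GGGACAGGGCTAGC", strrep("A", 40),
                                "GAGGCAAAGCTTCCG"),
                         design = equibase_design())
  out <- fold(rec, folding_conditions(), vienna_engine())
  pr <- out[[1]]$pairs$pairs
  expect_true(all(apply(cbind(55:59, 67:63), 1, function(q)
    any(pr[, 1] == q[1] & pr[, 2] == q[2]))))
  ann <- annotate_structure(out[[1]]$pairs)
  expect_equal(substr(ann$ss_string, 55, 67), "HHHHHLLLHHHHH")
})
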