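test_that("column classification applies gap, consensus, nongap in order", {
  aln <- multiple_alignment(c(a = "S-SH", b = "S-HS", c = "SSHL", d = "S-LD"))
  cc <- classify_columns(aln)
  # column 1: all S -> consensus
  expect_equal(cc$class[1], "consensus")
  expect_equal(cc$consensus_letter[1], "S")
  # column 2: 3/4 gaps -> gap, even though all residues agree
  expect_equal(cc$class[2], "gap")
  expect_true(is.na(cc$consensus_letter[2]))
  # column 3: top letter at 2/4 = exactly 0.5 -> consensus (threshold inclusive)
  expect_equal(cc$class[3], "consensus")
  # column 4: four distinct letters -> nongap
  expect_equal(cc$class[4], "nongap")
  # gap fraction exactly 0.5 classifies as gap before consensus is considered
  aln2 <- multiple_alignment(c(a = "S", b = "S", c = "-", d = "-"))
  expect_equal(classify_columns(aln2)$class, "gap")
  # gaps stay in the consensus denominator: 2 S of 4 rows with 1 gap is 0.5
  aln3 <- multiple_alignment(c(a = "S", b = "S", c = "H", d = "-"))
  cc3 <- classify_columns(aln3)
  expect_equal(cc3$class, "consensus")
  expect_equal(cc3$consensus_fraction, 0.5)
})

test_that("segmentation numbers maximal runs independently per kind", {
  cc <- data.frame(
    class = c("consensus", "consensus", "gap", "gap", "nongap", "consensus"),
    consensus_letter = c("S", "H", NA, NA, NA, "L"),
    consensus_fraction = c(1, 1, 0, 0, 0.4, 0.9),
    gap_fraction = c(0, 0, 1, 1, 0, 0),
    column = 1:6)
  reg <- segment_regions(cc)
  expect_equal(reg$kind, c("consensus", "gap", "nongap", "consensus"))
  expect_equal(reg$start, c(1L, 3L, 5L, 6L))
  expect_equal(reg$end, c(2L, 4L, 5L, 6L))
  expect_equal(reg$index[reg$kind == "consensus"], c(1, 2))
  expect_equal(reg$ss_identity[c(1, 4)], c("SH", "L"))
  expect_true(all(is.na(reg$ss_identity[2:3])))
})

test_that("identical rows collapse to one fully conserved domain", {
  ss <- stats::setNames(rep("SSHHHLLLHHHSS", 6), sprintf("r%d", 1:6))
  aln <- progressive_align(ss)
  cc <- classify_columns(aln)
  reg <- segment_regions(cc)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$kind, "consensus")
  expect_equal(reg$ss_identity, "SSHHHLLLHHHSS")
  st <- domain_stats(aln, reg, cc)
  expect_equal(st$regions$conserved, 1)
  expect_equal(st$regions$frequency, 1)
  expect_equal(st$regions$mean_length, 13)
  expect_equal(st$regions$sd_length, 0)
  expect_equal(st$domains_per_sequence, 1)
  expect_equal(st$pct_in_domains, 100)
})

test_that("rows matching fewer than half the domain columns are not members", {
  # columns are all consensus-S (3 of 4 rows agree everywhere); row d matches
  # the consensus letter in only 2 of 5 columns (40%) so it lacks the domain
  aln <- multiple_alignment(c(a = "SSSSS", b = "SSSSS", c = "SSSSS",
                              d = "SSHHH"))
  cc <- classify_columns(aln)
  expect_true(all(cc$class == "consensus"))
  reg <- segment_regions(cc)
  st <- domain_stats(aln, reg, cc)
  expect_equal(st$row_domain_counts[["d"]], 0)
  expect_equal(st$regions$frequency, 0.75)
  expect_equal(st$domains_per_sequence, 0.75)
  # but the percentage of characters in domain columns counts row d fully
  expect_equal(st$pct_in_domains, 100)
  # at exactly half matching, membership is granted
  aln2 <- multiple_alignment(c(a = "SSSS", b = "SSSS", c = "SSSS",
                               d = "SSHH"))
  st2 <- domain_stats(aln2, segment_regions(classify_columns(aln2)))
  expect_equal(st2$row_domain_counts[["d"]], 1)
})

test_that("fraction of fixed bases follows the projected base coordinates", {
  # 16-character rows; with fixed positions 1:4 and 13:16, the single domain
  # covering all columns has fixed fraction 8/16
  ss <- stats::setNames(rep(strrep("S", 16), 4), sprintf("r%d", 1:4))
  aln <- progressive_align(ss)
  reg <- segment_regions(classify_columns(aln))
  st <- domain_stats(aln, reg, fixed_positions = c(1:4, 13:16))
  expect_equal(st$regions$fraction_fixed_base, 0.5)
  st0 <- domain_stats(aln, reg, fixed_positions = integer(0))
  expect_equal(st0$regions$fraction_fixed_base, 0)
})

test_that("gapless projections recover exact base spans and distances", {
  # two consensus domains separated by a two-column non-gap region
  aln2 <- multiple_alignment(c(a = "SSSHLSSS", b = "SSSLHSSS",
                               c = "SSSGDSSS", d = "SSSMISSS"))
  cc2 <- classify_columns(aln2)
  reg2 <- segment_regions(cc2)
  expect_equal(reg2$kind, c("consensus", "nongap", "consensus"))
  pr <- project_domains(aln2, reg2, cc2)
  expect_equal(pr$n_missing, 0)
  expect_equal(pr$spans$start[pr$spans$domain == 1], rep(1L, 4))
  expect_equal(pr$spans$end[pr$spans$domain == 1], rep(3L, 4))
  expect_equal(pr$spans$start[pr$spans$domain == 2], rep(6L, 4))
  expect_equal(pr$d_between, 2)
  expect_equal(pr$d_prior, c(0, 2))
  expect_equal(pr$d_next, c(2, 0))
  expect_equal(pr$domain_loss, c(0, 0))
  expect_equal(unname(pr$inclusion[1, ]), c(1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(pr$inclusion[2, ]), c(0, 0, 0, 0, 0, 1, 1, 1))
})

test_that("a gap inside a domain column is counted as domain loss", {
  aln <- multiple_alignment(c(a = "SSS", b = "SSS", c = "SSS", d = "S-S"))
  cc <- classify_columns(aln)
  reg <- segment_regions(cc)
  expect_equal(reg$kind, "consensus")
  pr <- project_domains(aln, reg, cc)
  expect_equal(pr$domain_loss, 0.25)
  expect_equal(pr$spans$loss[pr$spans$row == "d"], 1)
  expect_equal(pr$spans$end[pr$spans$row == "d"], 2L)
  # a row with no character in any domain column is reported as missing
  alnm <- multiple_alignment(c(a = "SSH", b = "SSL", c = "SSD", d = "--G"))
  ccm <- classify_columns(alnm)
  regm <- segment_regions(ccm)
  expect_equal(regm$kind, c("consensus", "nongap"))
  expect_message(prm <- project_domains(alnm, regm, ccm), "empty")
  expect_equal(prm$n_missing, 1)
  expect_true(is.na(prm$spans$start[prm$spans$row == "d"]))
})

test_that("a planted shared hairpin yields a domain with full inclusion", {
  # every sequence carries the same fold; the single consensus domain must
  # cover each base of every row
  ss <- stats::setNames(rep("SSSHHHHLLLHHHHSSS", 8), sprintf("p%d", 1:8))
  aln <- progressive_align(ss)
  reg <- segment_regions(classify_columns(aln))
  pr <- project_domains(aln, reg)
  expect_equal(max(pr$inclusion), 1)
  expect_true(all(pr$inclusion[1, 1:17] == 1))
})
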