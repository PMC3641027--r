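test_that("tabular parsing groups HSPs per query-subject pair", {
  lines <- c(
    paste("T1", "P1", "100.0", "50", "0", "0", "10", "159", "1", "50",
          "1e-30", "120", "90.0", "100", sep = "\t"),
    paste("T1", "P1", "100.0", "40", "0", "0", "200", "319", "60", "99",
          "1e-20", "90", "85.0", "100", sep = "\t"))
  f <- withr::local_tempfile()
  writeLines(lines, f)
  hits <- parse_blast_tabular(f, c(T1 = 400L))
  expect_length(hits, 1L)
  expect_length(hits$T1, 1L)
  expect_equal(nrow(hits$T1[[1]]$hsps), 2L)
  expect_equal(hits$T1[[1]]$best_bitscore, 120)
  expect_equal(hits$T1[[1]]$best_evalue, 1e-30)

  # empty file -> empty map
  f2 <- withr::local_tempfile()
  writeLines(character(0), f2)
  expect_length(parse_blast_tabular(f2, c(T1 = 400L)), 0L)

  # wrong column count -> parse error naming the line
  f3 <- withr::local_tempfile()
  writeLines("T1\tP1\t100.0", f3)
  expect_error(parse_blast_tabular(f3, c(T1 = 400L)), "line 1")
})

test_that("synthetic BLASTX records round-trip through the parser", {
  w <- make_world(n_proteins = 12, n_transcripts = 24, seed = 61)
  tab <- emit_blastx_tabular(w)
  f <- withr::local_tempfile()
  write_blast_tabular(tab, f)
  qlen <- setNames(w$transcripts$length, w$transcripts$id)
  hits <- parse_blast_tabular(f, qlen)
  expect_setequal(names(hits), names(w$hsps))
  for (tx in names(w$hsps)) {
    h <- hits[[tx]][[1]]$hsps
    expect_equal(h$s_start, w$hsps[[tx]]$s_start)
    expect_equal(h$s_end, w$hsps[[tx]]$s_end)
    expect_equal(h$align_len, w$hsps[[tx]]$align_len)
    expect_equal(h$positives, w$hsps[[tx]]$positives)
  }
})

test_that("top_hit prefers bitscore, then E-value, then subject id", {
  h1 <- make_hit(subject_id = "S2", query_len = 400L, subject_len = 100L,
                 s_starts = 1, s_ends = 50, positives = 50,
                 align_lens = 50, bitscores = 200, evalues = 1e-50)
  h2 <- make_hit(subject_id = "S1", query_len = 400L, subject_len = 100L,
                 s_starts = 1, s_ends = 50, positives = 50,
                 align_lens = 50, bitscores = 150, evalues = 1e-60)
  expect_equal(top_hit(list(h1, h2))$subject_id, "S2")

  h3 <- make_hit(subject_id = "S3", query_len = 400L, subject_len = 100L,
                 s_starts = 1, s_ends = 50, positives = 50,
                 align_lens = 50, bitscores = 200, evalues = 1e-40)
  expect_equal(top_hit(list(h3, h1))$subject_id, "S2")  # lower E wins

  h4 <- make_hit(subject_id = "S0", query_len = 400L, subject_len = 100L,
                 s_starts = 1, s_ends = 50, positives = 50,
                 align_lens = 50, bitscores = 200, evalues = 1e-50)
  expect_equal(top_hit(list(h1, h4))$subject_id, "S0")  # full tie
  expect_error(top_hit(list()), "empty")
})

test_that("tier assignment follows the gold/silver/bronze cascade", {
  # all gold criteria met: 350 nt PUT, 1 HSP, 120 aa subject,
  # positives 90/100, span 110 -> coverage 0.917
  gold <- make_hit(query_len = 350L, subject_len = 120L,
                   s_starts = 5, s_ends = 114, positives = 99,
                   align_lens = 110)
  expect_equal(assign_tier("T", 350L, gold)$tier, "gold")

  # identical geometry but a 250 nt PUT drops to silver
  expect_equal(assign_tier("T", 250L, gold)$tier, "silver")

  # two HSPs jointly covering 40/120 -> bronze
  bronze <- make_hit(query_len = 400L, subject_len = 120L,
                     s_starts = c(1, 30), s_ends = c(20, 49),
                     positives = c(20, 20), align_lens = c(20, 20))
  expect_equal(assign_tier("T", 400L, bronze)$tier, "bronze")

  # no hit -> none
  expect_equal(assign_tier("T", 400L, NULL)$tier, "none")
})

test_that("merged subject coverage counts overlaps once", {
  h <- make_hit(query_len = 400L, subject_len = 100L,
                s_starts = c(1, 40, 45), s_ends = c(50, 60, 80),
                positives = c(50, 21, 36), align_lens = c(50, 21, 36))
  expect_equal(subject_coverage(h), 0.80)
})

test_that("increasing merged coverage never demotes a PUT", {
  tier_rank <- c(none = 0, bronze = 1, silver = 2, gold = 3)
  set.seed(71)
  for (i in 1:200) {
    subject_len <- sample(100:300, 1)
    put_len <- sample(c(150L, 400L), 1)
    span1 <- sample(10:(subject_len - 10), 1)
    h_small <- make_hit(query_len = put_len, subject_len = subject_len,
                        s_starts = 1, s_ends = span1,
                        positives = span1, align_lens = span1)
    span2 <- sample(span1:subject_len, 1)
    h_big <- make_hit(query_len = put_len, subject_len = subject_len,
                      s_starts = 1, s_ends = span2,
                      positives = span2, align_lens = span2)
    r1 <- tier_rank[assign_tier("T", put_len, h_small)$tier]
    r2 <- tier_rank[assign_tier("T", put_len, h_big)$tier]
    expect_gte(r2, r1)
  }
})

test_that("tiers are mutually disjoint and exhaustive", {
  w <- make_world(n_proteins = 20, n_transcripts = 40, seed = 81)
  tab <- emit_blastx_tabular(w)
  f <- withr::local_tempfile()
  write_blast_tabular(tab, f)
  qlen <- setNames(w$transcripts$length, w$transcripts$id)
  tiers <- classify_tiers(parse_blast_tabular(f, qlen), qlen)
  expect_equal(nrow(tiers), nrow(w$transcripts))
  expect_equal(anyDuplicated(tiers$put_id), 0L)
  expect_equal(sum(table(tiers$tier)), nrow(w$transcripts))
})

test_that("trim_and_translate trims to the HSP and translates it", {
  # 72 nt PUT, HSP on q 10..69, frame +1 -> 60 nt CDS, 20 aa protein
  put <- paste0(strrep("G", 9), back_translate(strrep("M", 20)),
                strrep("G", 3))
  hit <- make_hit(query_len = 72L, subject_len = 20L,
                  s_starts = 1, s_ends = 20, positives = 20,
                  align_lens = 20, q_starts = 10L, q_ends = 69L)
  tg <- trim_and_translate(put, hit)
  expect_equal(nchar(tg$cds), 60L)
  expect_equal(tg$protein, strrep("M", 20))

  # the standard genetic code
  hit2 <- make_hit(query_len = 6L, subject_len = 2L, s_starts = 1,
                   s_ends = 2, positives = 2, align_lens = 2,
                   q_starts = 1L, q_ends = 6L)
  expect_equal(trim_and_translate("ATGAAA", hit2)$protein, "MK")

  # out-of-range coordinates are rejected
  hit3 <- make_hit(query_len = 10L, subject_len = 10L, s_starts = 1,
                   s_ends = 10, positives = 10, align_lens = 10,
                   q_starts = 1L, q_ends = 30L)
  expect_error(trim_and_translate("ATGAAA", hit3), "outside")
})

test_that("minus-frame gold PUTs translate back to their source protein", {
  w <- make_world(n_proteins = 15, n_transcripts = 30,
                  tier_mix = c(gold = 1, silver = 0, bronze = 0,
                               none = 0), seed = 91)
  qlen <- setNames(w$transcripts$length, w$transcripts$id)
  f <- withr::local_tempfile()
  emit_blastx_tabular(w, f)
  hits <- parse_blast_tabular(f, qlen)
  frames <- integer(0)
  for (tx in names(hits)) {
    h <- top_hit(hits[[tx]])
    tg <- trim_and_translate(
      w$transcripts$seq[w$transcripts$id == tx], h)
    pid <- w$put_to_protein[[tx]]
    expected <- substr(w$proteins$seq[w$proteins$id == pid],
                       h$hsps$s_start, h$hsps$s_end)
    expect_equal(tg$protein, expected)
    frames <- c(frames, h$hsps$frame)
  }
  # both strands are exercised
  expect_true(any(frames < 0) && any(frames > 0))
})
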