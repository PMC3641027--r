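test_that("six-frame translation covers both strands with stops as *", {
  fr <- six_frame_translate("ATGTAA")
  expect_equal(fr[["+1"]], "M*")
  # reverse-complement symmetry
  s <- "ATGCCGTTAGGACTA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(six_frame_translate(s)[["-1"]],
               six_frame_translate(rc)[["+1"]])
  # frame lengths
  L <- nchar(s)
  lens <- nchar(six_frame_translate(s))
  expect_equal(unname(lens), rep((L - c(0, 1, 2)) %/% 3, 2))
  # degenerate input
  expect_equal(unname(six_frame_translate("AT")), rep("", 6))
})

test_that("longest_orf takes the maximal stop-free run, ties by frame order", {
  frames <- setNames(c("MKL*A", "MK*LLLL", "", "", "", ""),
                     c("+1", "+2", "+3", "-1", "-2", "-3"))
  res <- longest_orf(frames)
  expect_equal(res$orf, "LLLL")
  expect_equal(res$frame, "+2")

  tie <- setNames(c("AAAA*", "", "", "", "CCCC*", ""),
                  c("+1", "+2", "+3", "-1", "-2", "-3"))
  expect_equal(longest_orf(tie)$frame, "+1")

  allstop <- setNames(rep("***", 6), c("+1", "+2", "+3", "-1", "-2", "-3"))
  expect_equal(longest_orf(allstop)$length, 0L)
})

test_that("domtblout top-hit selection honors the E-value cutoff", {
  rows <- data.frame(
    family_name = c("famA", "famB", "famC", "famD"),
    family_acc = c("PF00001.5", "PF00002.3", "PF00003.1", "PF00004.2"),
    query_id = c("G1", "G1", "G2", "G3"),
    evalue = c(1e-5, 1e-3, 0.5, 1e-8),
    score = c(50, 30, 10, 80))
  f <- withr::local_tempfile()
  write_domtbl_fixture(f, rows)
  hits <- parse_domtbl_top_hit(f)
  expect_equal(nrow(hits), 2L)  # G2's only hit fails the 1e-2 cutoff
  expect_equal(hits$family_acc[hits$query_id == "G1"], "PF00001.5")
  expect_equal(hits$family_acc[hits$query_id == "G3"], "PF00004.2")

  # tie on E-value resolved by higher bitscore
  rows2 <- data.frame(
    family_name = c("famA", "famB"), family_acc = c("PF10.1", "PF11.1"),
    query_id = c("G1", "G1"), evalue = c(1e-4, 1e-4), score = c(20, 90))
  f2 <- withr::local_tempfile()
  write_domtbl_fixture(f2, rows2)
  expect_equal(parse_domtbl_top_hit(f2)$family_acc, "PF11.1")

  # empty table
  f3 <- withr::local_tempfile()
  writeLines("# comment only", f3)
  expect_equal(nrow(parse_domtbl_top_hit(f3)), 0L)

  # malformed line
  f4 <- withr::local_tempfile()
  writeLines("too few fields", f4)
  expect_error(parse_domtbl_top_hit(f4), "line 1")
})

test_that("pfam_to_go tallies every mapped GO term per hit, by domain", {
  graph <- make_toy_ontology(depth = 2, branching = 3, seed = 5)
  terms <- graph$terms$id[!graph$terms$id %in% graph$roots]
  bp <- graph$terms$id[graph$terms$namespace == "biological_process" &
                       !graph$terms$id %in% graph$roots]
  mf <- graph$terms$id[graph$terms$namespace == "molecular_function" &
                       !graph$terms$id %in% graph$roots]
  p2g <- data.frame(
    pfam_acc = c("PF00001", "PF00001", "PF00002"),
    pfam_name = c("famA", "famA", "famB"),
    go_name = c("x", "y", "z"),
    go_id = c(bp[1], mf[1], bp[2]))
  f <- withr::local_tempfile()
  write_pfam2go_fixture(f, p2g)
  p2g_tab <- read_external2go(f)

  # two proteins hitting the same 2-term family: total 4, unique 2
  hits <- tibble::tibble(
    query_id = c("G1", "G2"), family_acc = c("PF00001.9", "PF00001.9"),
    family_name = "famA", full_seq_evalue = 1e-6, bitscore = 50)
  tally <- pfam_to_go(hits, p2g_tab, graph)
  expect_equal(tally$all$total, 4L)
  expect_equal(tally$all$unique, 2L)
  expect_equal(tally$biological_process$total, 2L)
  expect_equal(tally$molecular_function$total, 2L)

  # a family with no GO terms contributes nothing
  hits2 <- tibble::tibble(
    query_id = "G3", family_acc = "PF09999.1", family_name = "famZ",
    full_seq_evalue = 1e-6, bitscore = 50)
  expect_equal(pfam_to_go(hits2, p2g_tab, graph)$all$total, 0L)

  # hand-computed five-record fixture
  hits3 <- tibble::tibble(
    query_id = paste0("G", 1:5),
    family_acc = c("PF00001.1", "PF00001.2", "PF00002.1", "PF00002.1",
                   "PF09999.1"),
    family_name = "f", full_seq_evalue = 1e-6, bitscore = 50)
  t3 <- pfam_to_go(hits3, p2g_tab, graph)
  expect_equal(t3$all$total, 6L)   # 2+2 from PF00001, 1+1 from PF00002
  expect_equal(t3$all$unique, 3L)
  expect_equal(unname(t3$all$counts[bp[1]]), 2L)

  # unknown GO term warns and lands in unmapped
  p2g_bad <- rbind(p2g, data.frame(pfam_acc = "PF00003",
                                   pfam_name = "famC", go_name = "w",
                                   go_id = "GO:9999999"))
  f2 <- withr::local_tempfile()
  write_pfam2go_fixture(f2, p2g_bad)
  hits4 <- tibble::tibble(
    query_id = "G9", family_acc = "PF00003.1", family_name = "famC",
    full_seq_evalue = 1e-6, bitscore = 50)
  expect_warning(t4 <- pfam_to_go(hits4, read_external2go(f2), graph),
                 "unmapped")
  expect_equal(t4$unmapped$total, 1L)
})

test_that("go_slim returns penultimate ancestors on chains and diamonds", {
  ch <- chain_ontology()
  expect_equal(go_slim("GO:0000003", ch), "GO:0000001")  # chain -> {A}
  expect_equal(go_slim("GO:0000001", ch), "GO:0000001")  # slim of itself
  expect_equal(go_slim("GO:0008150", ch), character(0))  # root -> empty

  dm <- diamond_ontology()
  expect_equal(go_slim("GO:0000020", dm),
               c("GO:0000011", "GO:0000012"))             # both paths

  expect_error(go_slim("GO:7777777", ch), "unknown term")
})

test_that("go_slim terms are direct root children of the term's own domain", {
  graph <- make_toy_ontology(depth = 4, branching = 4, seed = 17)
  root_children <- lapply(graph$roots, function(r) graph$children[[r]])
  names(root_children) <- graph$roots
  non_roots <- setdiff(graph$terms$id, graph$roots)
  for (term in non_roots) {
    slims <- go_slim(term, graph)
    expect_gt(length(slims), 0L)
    ns <- graph$terms$namespace[match(term, graph$terms$id)]
    root <- graph$roots[match(ns, graph$terms$namespace[
      match(graph$roots, graph$terms$id)])]
    expect_true(all(slims %in% root_children[[root]]))
  }
})

test_that("go_slim_tally supports set and multiset modes", {
  ch <- chain_ontology()
  terms <- c("GO:0000003", "GO:0000003", "GO:0000002")
  multi <- go_slim_tally(terms, ch, mode = "multiset")
  expect_equal(multi$count, 3L)
  set <- go_slim_tally(terms, ch, mode = "set")
  expect_equal(set$count, 2L)
})

test_that("toy ontologies are acyclic and OBO round-trips isomorphically", {
  graph <- make_toy_ontology(depth = 3, branching = 3, seed = 9)
  # Kahn's algorithm: a DAG empties completely
  indeg <- lengths(graph$parents)
  names(indeg) <- graph$terms$id
  frontier <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(frontier) > 0L) {
    x <- frontier[1]; frontier <- frontier[-1]; seen <- seen + 1L
    for (ch in graph$children[[x]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) frontier <- c(frontier, ch)
    }
  }
  expect_equal(seen, nrow(graph$terms))

  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(graph, f)
  back <- read_obo(f)
  expect_setequal(back$terms$id, graph$terms$id)
  for (id in graph$terms$id) {
    expect_setequal(back$parents[[id]], graph$parents[[id]])
  }
  expect_setequal(back$roots, graph$roots)
  # generated worlds are reproducible
  expect_identical(make_toy_ontology(depth = 3, branching = 3, seed = 9),
                   graph)
})

test_that("go_to_kegg reports the mapped fraction of unique GO terms", {
  # fixture built with 148 unique terms of which 7 map, mirroring a
  # molecular-function panel
  gos <- sprintf("GO:%07d", 1:148)
  k2g <- data.frame(kegg_id = sprintf("R%05d", 1:7),
                    go_name = "r", go_id = gos[1:7])
  f <- withr::local_tempfile()
  write_kegg2go_fixture(f, k2g)
  k2g_tab <- read_external2go(f)
  res <- go_to_kegg(gos, k2g_tab)
  expect_equal(res$mapped_fraction, 7 / 148)
  expect_true(all(res$tally$counts >= 1L))
  expect_true(all(names(res$tally$counts) %in% k2g_tab$external_id))

  # no mapped terms -> fraction 0
  expect_equal(go_to_kegg("GO:7654321", k2g_tab)$mapped_fraction, 0)
})
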