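test_that("structurally identical transcripts merge to the lowest file index", {
  a <- mk_tx("1.t1", c(100, 300), c(200, 400), file_index = 1L)
  b <- mk_tx("2.t9", c(100, 300), c(200, 400), file_index = 2L)
  c2 <- mk_tx("2.t2", c(100, 300), c(200, 401), file_index = 2L) # 1 nt off
  merged <- merge_identical(list(b, a, c2))
  expect_named(merged, c("1.t1", "2.t2"), ignore.order = TRUE)
  expect_equal(attr(merged, "n_merged"), 1L)
  expect_equal(attr(merged, "merged")$dropped, "2.t9")
  # idempotent
  again <- merge_identical(merged)
  expect_identical(names(again), names(merged))
  expect_equal(attr(again, "n_merged"), 0L)
})

test_that("coding overlap needs >= 3 shared in-frame coding nucleotides", {
  a <- mk_tx("a", 100, 400)
  expect_true(coding_overlap(a, mk_tx("b", 100, 400)))
  expect_false(coding_overlap(a, mk_tx("b", 100, 400, strand = "-")))
  # 2 nt of shared sequence: too short; 3 nt in frame: enough
  expect_false(coding_overlap(a, mk_tx("b", 399, 700)))
  expect_true(coding_overlap(a, mk_tx("b", 397, 700))) # offset 297 = 0 mod 3
  # same interval, translation start shifted by 1: never in frame
  expect_false(coding_overlap(a, mk_tx("b", 101, 401)))
  expect_true(coding_overlap(a, mk_tx("b", 103, 403)))
  # different sequences never overlap
  expect_false(coding_overlap(a, mk_tx("b", 100, 400, seqname = "chr2")))
})

test_that("interval-based overlap equals per-nucleotide frame labeling", {
  # independent brute force: label every coding nucleotide with its codon
  # offset and look for >= 3 consecutive shared positions with equal labels
  brute <- function(t1, t2) {
    if (t1$seqname != t2$seqname || t1$strand != t2$strand) {
      return(FALSE)
    }
    lab <- function(t) {
      pos <- unlist(mapply(seq, t$cds$start, t$cds$end, SIMPLIFY = FALSE))
      if (t$strand == "-") pos <- rev(pos)
      stats::setNames((seq_along(pos) - 1) %% 3, pos)
    }
    l1 <- lab(t1)
    l2 <- lab(t2)
    shared <- intersect(names(l1), names(l2))
    ok <- sort(as.integer(shared[l1[shared] == l2[shared]]))
    if (length(ok) < 3) {
      return(FALSE)
    }
    d <- diff(ok)
    any(d[-length(d)] == 1 & d[-1] == 1)
  }
  set.seed(31)
  hits <- 0
  for (rep in 1:60) {
    strand <- sample(c("+", "-"), 1)
    mk_rand <- function() {
      n <- sample(1:4, 1)
      lens <- sample(5:40, n, replace = TRUE)
      gaps <- if (n > 1) sample(5:30, n - 1, replace = TRUE) else integer(0)
      starts <- cumsum(c(sample(1:50, 1), utils::head(lens, -1) + gaps + 1L))
      mk_tx("r", starts, starts + lens - 1, strand = strand)
    }
    t1 <- mk_rand()
    t2 <- mk_rand()
    got <- coding_overlap(t1, t2)
    expect_identical(got, brute(t1, t2))
    hits <- hits + got
  }
  expect_gt(hits, 0) # the case mix exercised both outcomes
})

test_that("comparison rule follows the ordered threshold procedure", {
  hp <- default_hyperparameters()
  r <- compare_pair(c(1.0, 1.0, 40, 12), c(0.5, 1.0, 40, 12), hp)
  expect_equal(r$outcome, "second")
  expect_equal(r$decisive, 1)

  expect_equal(compare_pair(c(0.8, 1, 100, 5), c(0.8, 1, 100, 5), hp)$outcome, "none")

  r3 <- compare_pair(c(0.8, 1.0, 100, 5), c(0.8, 0.6, 50, 5), hp)
  expect_equal(r3$outcome, "second")
  expect_equal(r3$decisive, 3) # s2 diff 0.4 <= 0.5, s3 diff 50 > 25

  mirror <- compare_pair(c(0.8, 0.6, 50, 5), c(0.8, 1.0, 100, 5), hp)
  expect_equal(mirror$outcome, "first")
  expect_equal(mirror$decisive, 3)

  # equality at a threshold does not trigger: all diffs == epsilon -> none
  expect_equal(
    compare_pair(c(0.5, 1.0, 50, 20), c(0.5, 0.5, 25, 10), hp)$outcome,
    "none"
  )
})

test_that("comparison rule is antisymmetric on random score pairs", {
  set.seed(17)
  hp <- default_hyperparameters()
  for (rep in 1:200) {
    v1 <- c(sample(0:4, 1) / 4, sample(0:2, 1) / 2, sample(0:80, 1), sample(0:20, 1))
    v2 <- c(sample(0:4, 1) / 4, sample(0:2, 1) / 2, sample(0:80, 1), sample(0:20, 1))
    a <- compare_pair(v1, v2, hp)
    b <- compare_pair(v2, v1, hp)
    expect_identical(a$decisive, b$decisive)
    expect_identical(
      a$outcome,
      switch(b$outcome, first = "second", second = "first", none = "none")
    )
  }
})

test_that("low-support removal requires both fractions below threshold", {
  hp <- default_hyperparameters()
  expect_false(low_support(c(0.5, 1.0, 0, 0), hp)) # codons fully supported
  expect_true(low_support(c(0.5, 0.5, 99, 99), hp)) # both below
  expect_false(low_support(c(1.0, 0.0, 0, 0), hp)) # introns pass
  expect_false(low_support(c(0.75, 0.0, 0, 0), hp)) # at threshold = not below
})

test_that("selection keeps the supported transcript of an overlapping pair", {
  good <- mk_tx("1.good", c(100, 300), c(200, 400), gene_id = "ga")
  bad <- mk_tx("1.bad", c(103, 300), c(200, 403), gene_id = "gb")
  hints <- mk_hints(hints_on(good, src = "E", mult = 2))
  sel <- run_selection(list(good, bad), hints)
  expect_named(selected_transcripts(sel), "1.good")
  st <- attr(sel, "stats")
  expect_equal(st$n_marked, 1)
})

test_that("single-linkage chains of overlaps form one gene", {
  # A overlaps B, B overlaps C, A does not overlap C
  # (starts 3k apart so the shared segments are in frame)
  a <- mk_tx("1.a", 100, 250)
  b <- mk_tx("1.b", 202, 400)
  c3 <- mk_tx("1.c", 352, 500)
  expect_true(coding_overlap(a, b))
  expect_true(coding_overlap(b, c3))
  expect_false(coding_overlap(a, c3))
  hints <- mk_hints(
    hints_on(a, src = "E"), hints_on(b, src = "E"), hints_on(c3, src = "E")
  )
  sel <- run_selection(list(a, b, c3), hints)
  expect_length(sel, 1)
  expect_named(selected_transcripts(sel), c("1.a", "1.b", "1.c"),
    ignore.order = TRUE
  )
  expect_equal(sel[[1]]$gene_id, "g1")
})

test_that("empty input selects to an empty gene set", {
  sel <- run_selection(list(), mk_hints(hint_row("c", 1, 9, "intron", "+", "E")))
  expect_length(sel, 0)
  expect_length(selected_transcripts(sel), 0)
})

test_that("every output transcript appears structurally in the input", {
  for (s in c(41, 42)) {
    fx <- generate_fixture(fixture_spec(seed = s, n_loci = 6))
    sel <- run_selection(fx$transcripts, fx$hints)
    expect_true(all(
      surviving_chains(sel) %in% surviving_chains(fx$transcripts)
    ))
  }
})

test_that("selection result is a fixed point of re-selection", {
  fx <- generate_fixture(fixture_spec(seed = 43, n_loci = 6))
  sel <- run_selection(fx$transcripts, fx$hints)
  survivors <- selected_transcripts(sel)
  again <- run_selection(survivors, fx$hints)
  expect_identical(
    names(selected_transcripts(again)),
    names(survivors)
  )
})

test_that("marks accumulate over the original union, not incrementally", {
  # Single-CDS chain a-b-c with disjoint codon features: B beats A on s4,
  # C beats B on s4, A and C do not overlap. B is marked by C but must
  # still mark A, leaving only C; incremental removal would keep A too.
  a <- mk_tx("1.a", 100, 250)
  b <- mk_tx("1.b", 202, 400)
  c3 <- mk_tx("1.c", 352, 500)
  expect_true(coding_overlap(a, b))
  expect_true(coding_overlap(b, c3))
  expect_false(coding_overlap(a, c3))
  hints <- mk_hints(
    hints_on(a, src = "E", mult = 1), # s4 = 20
    hints_on(b, src = "E", mult = 3), # s4 = 60
    hints_on(c3, src = "E", mult = 10) # s4 = 200
  )
  sel <- run_selection(list(a, b, c3), hints)
  scores <- attr(sel, "scores")
  hp <- default_hyperparameters()
  expect_equal(compare_pair(scores["1.a", ], scores["1.b", ], hp)$outcome, "first")
  expect_equal(compare_pair(scores["1.b", ], scores["1.c", ], hp)$outcome, "first")
  expect_named(selected_transcripts(sel), "1.c")
  expect_equal(attr(sel, "stats")$n_marked, 2)
})
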