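test_that("prediction GTF parsing builds sorted per-transcript CDS chains", {
  path <- write_tmp(c(
    gtf_line("chr1", "CDS", 300, 400, "+", "0", "t1"),
    gtf_line("chr1", "CDS", 100, 200, "+", "0", "t1"),
    gtf_line("chr1", "CDS", 500, 600, "+", "2", "t1"),
    gtf_line("chr1", "CDS", 1100, 1200, "-", "0", "t2", gid = "g2"),
    gtf_line("chr1", "CDS", 1300, 1400, "-", "1", "t2", gid = "g2"),
    gtf_line("chr1", "CDS", 1500, 1600, "-", "2", "t2", gid = "g2")
  ))
  txs <- read_predictions(path, file_index = 1L)
  expect_length(txs, 2)
  expect_named(txs, c("1.t1", "1.t2"), ignore.order = TRUE)
  t1 <- txs[["1.t1"]]
  expect_equal(t1$cds$start, c(100, 300, 500))
  expect_equal(t1$cds$end, c(200, 400, 600))
  expect_equal(t1$gene_id, "g1")
  expect_equal(t1$strand, "+")
  expect_equal(txs[["1.t2"]]$strand, "-")
})

test_that("identifiers from different files stay distinct after prefixing", {
  mk <- function() {
    write_tmp(gtf_line("chr1", "CDS", 100, 200, "+", "0", "t1"))
  }
  txs <- c(
    unclass(read_predictions(mk(), file_index = 1L)),
    unclass(read_predictions(mk(), file_index = 2L))
  )
  ids <- vapply(txs, `[[`, "", "id")
  expect_setequal(ids, c("1.t1", "2.t1"))
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("empty prediction file parses to an empty set without error", {
  expect_length(read_predictions(write_tmp(character(0))), 0)
})

test_that("transcripts without CDS rows are skipped with a warning", {
  path <- write_tmp(c(
    gtf_line("chr1", "exon", 100, 200, "+", ".", "t1"),
    gtf_line("chr1", "CDS", 500, 700, "+", "0", "t2")
  ))
  expect_warning(txs <- read_predictions(path), "without CDS")
  expect_named(txs, "1.t2")
})

test_that("malformed prediction rows are rejected with file and line", {
  bad_cols <- write_tmp(c(
    gtf_line("chr1", "CDS", 100, 200, "+", "0", "t1"),
    "chr1\tonly\tthree"
  ))
  expect_error(read_predictions(bad_cols), ":2:")
  dotted <- write_tmp(gtf_line("chr1", "CDS", 100, 200, ".", "0", "t1"))
  expect_error(read_predictions(dotted), "strand")
  mixed <- write_tmp(c(
    gtf_line("chr1", "CDS", 100, 200, "+", "0", "t1"),
    gtf_line("chr1", "CDS", 300, 400, "-", "0", "t1")
  ))
  expect_error(read_predictions(mixed), "t1")
  mixed_seq <- write_tmp(c(
    gtf_line("chr1", "CDS", 100, 200, "+", "0", "t1"),
    gtf_line("chr2", "CDS", 300, 400, "+", "0", "t1")
  ))
  expect_error(read_predictions(mixed_seq), "t1")
})

test_that("explicit stop_codon rows are kept and are authoritative", {
  path <- write_tmp(c(
    gtf_line("chr1", "CDS", 100, 200, "+", "0", "t1"),
    gtf_line("chr1", "stop_codon", 201, 203, "+", "0", "t1")
  ))
  tx <- read_predictions(path)[["1.t1"]]
  expect_equal(tx$stop_codon, c(201, 203))
  expect_equal(derive_features(tx)$stop_codon, c(201, 203))
})

test_that("hint parsing reads mult and src and sums duplicates", {
  path <- write_tmp(c(
    gff_hint_line("chr1", "intron", 201, 299, "+", "mult=5;src=P"),
    gff_hint_line("chr1", "intron", 500, 599, "+", "src=E"),
    gff_hint_line("chr1", "intron", 201, 299, "+", "mult=2;src=E"),
    gff_hint_line("chr1", "intron", 201, 299, "+", "mult=3;src=E")
  ), ext = ".gff")
  h <- read_hints(path)
  expect_equal(nrow(h), 3)
  p <- h[h$src == "P", ]
  expect_equal(p$mult, 5L)
  e_dup <- h[h$src == "E" & h$start == 201, ]
  expect_equal(e_dup$mult, 5L) # 2 + 3 merged
  e_single <- h[h$src == "E" & h$start == 500, ]
  expect_equal(e_single$mult, 1L) # absent mult= means 1
  expect_setequal(attr(h, "sources"), c("E", "P"))
})

test_that("hint rows with missing src or bad codon span are rejected", {
  no_src <- write_tmp(
    gff_hint_line("chr1", "intron", 201, 299, "+", "mult=5"),
    ext = ".gff"
  )
  expect_error(read_hints(no_src), "src")
  bad_codon <- write_tmp(
    gff_hint_line("chr1", "start", 100, 104, "+", "src=P"),
    ext = ".gff"
  )
  expect_error(read_hints(bad_codon), "3 nucleotides")
})

test_that("unknown hint feature types are skipped with a warning", {
  path <- write_tmp(c(
    gff_hint_line("chr1", "exonpart", 100, 200, "+", "src=E"),
    gff_hint_line("chr1", "intron", 201, 299, "+", "src=E")
  ), ext = ".gff")
  expect_warning(h <- read_hints(path), "unsupported feature")
  expect_equal(nrow(h), 1)
})

test_that("hint multiplicity is conserved from rows to parsed set", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    rows <- data.frame(
      seqname = sample(c("c1", "c2"), n, replace = TRUE),
      start = sample(seq(101, 1001, by = 100), n, replace = TRUE),
      type = "intron",
      strand = sample(c("+", "-"), n, replace = TRUE),
      src = sample(c("E", "P"), n, replace = TRUE),
      mult = sample(1:20, n, replace = TRUE)
    )
    rows$end <- rows$start + 50L
    paths <- vapply(split(rows, rep(1:2, length.out = n)), function(part) {
      write_tmp(gff_hint_line(
        part$seqname, part$type, part$start, part$end, part$strand,
        sprintf("mult=%d;src=%s", part$mult, part$src)
      ), ext = ".gff")
    }, "")
    h <- read_hints(paths)
    expect_equal(sum(h$mult), sum(rows$mult))
  }
})

test_that("configuration parsing applies defaults and overrides", {
  hp <- read_config(write_tmp(character(0), ext = ".cfg"))
  expect_equal(hp$weights, c(P = 0.1, E = 10, C = 5, M = 1))
  expect_equal(hp$epsilon, c(0, 0.5, 25, 10))
  expect_equal(hp$intron_support, 0.75)
  expect_equal(hp$stasto_support, 1.0)

  hp2 <- read_config(write_tmp(c("e_3 50", "w_R 2.5"), ext = ".cfg"))
  expect_equal(hp2$epsilon, c(0, 0.5, 50, 10))
  expect_equal(hp2$weights[["R"]], 2.5)
  expect_equal(hp2$weights[["E"]], 10)

  expect_error(read_config(write_tmp("w_P abc", ext = ".cfg")), "non-numeric")
  expect_error(read_config(write_tmp("nonsense 3", ext = ".cfg")), "unknown")
})

test_that("write/parse round-trip preserves CDS coordinates, strand, frame", {
  fx <- generate_fixture(fixture_spec(seed = 11, n_loci = 5))
  sel <- run_selection(fx$transcripts, fx$hints)
  out <- tempfile(fileext = ".gtf")
  write_annotation(sel, out)
  reread <- read_predictions(out, prefix = FALSE)
  orig <- selected_transcripts(sel)
  expect_setequal(names(reread), names(orig))
  for (id in names(orig)) {
    expect_equal(reread[[id]]$cds, orig[[id]]$cds, info = id)
    expect_equal(reread[[id]]$strand, orig[[id]]$strand)
    expect_equal(reread[[id]]$seqname, orig[[id]]$seqname)
  }
})

test_that("output ordering is a function of content, not input order", {
  fx <- generate_fixture(fixture_spec(seed = 12, n_loci = 6))
  sel1 <- run_selection(fx$transcripts, fx$hints)
  set.seed(99)
  shuffled <- fx$transcripts[sample(length(fx$transcripts))]
  sel2 <- run_selection(shuffled, fx$hints)
  f1 <- tempfile()
  f2 <- tempfile()
  write_annotation(sel1, f1)
  write_annotation(sel2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empty selection writes a valid header-only file", {
  sel <- run_selection(list(), mk_hints(
    hint_row("chr1", 201, 299, "intron", "+", "E")
  ))
  out <- tempfile(fileext = ".gtf")
  write_annotation(sel, out)
  lines <- readLines(out)
  expect_true(startsWith(lines[1], "#"))
  expect_length(read_predictions(out, prefix = FALSE), 0)
})
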