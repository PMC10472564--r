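test_that("FASTA reading preserves records, folds soft-masking, rejects bad input", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1 description", "ACGT"), f)
  a <- read_genome_fasta(f)
  expect_identical(names(a$seq), "s1")
  expect_identical(unname(a$seq[["s1"]]), "ACGT")
  expect_identical(seq_lengths(a), c(s1 = 4L))

  writeLines(c(">s1", "acgT"), f)
  a <- read_genome_fasta(f)
  expect_identical(unname(a$seq[["s1"]]), "ACGT")
  expect_identical(a$mask[["s1"]], c(TRUE, TRUE, TRUE, FALSE))

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_genome_fasta(f), "duplicate seq_id a")
  writeLines(c(">a", "ACGT", ">b", ""), f)
  expect_error(read_genome_fasta(f), "empty sequence.*b")
})

test_that("FASTA writing restores lowercase masking (round trip)", {
  f <- tempfile(fileext = ".fa")
  a <- genome_assembly(c(s1 = "ACGTacgtNN", s2 = "ttttAAAA"))
  write_genome_fasta(a, f)
  b <- read_genome_fasta(f)
  expect_identical(a$seq, b$seq)
  expect_identical(a$mask, b$mask)
})

test_that("gene model reading converts coordinates and groups CDS by transcript", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\tx\tCDS\t101\t200\t.\t+\t0\tgene_id \"g1\"; transcript_id \"t1\";",
    "chr1\tx\tCDS\t401\t500\t.\t+\t0\tgene_id \"g1\"; transcript_id \"t1\";",
    "chr1\tx\tCDS\t281\t300\t.\t+\t0\tgene_id \"g1\"; transcript_id \"t1\";"), f)
  m <- read_gene_models(f, "gtf")
  expect_equal(nrow(m), 3L)
  # 1-based inclusive 101..200 becomes [100, 200)
  expect_identical(m$start, c(100L, 280L, 400L))
  expect_identical(m$end, c(200L, 300L, 500L))
  expect_identical(unique(m$transcript_id), "t1")
})

test_that("mixed strands within one transcript are rejected", {
  df <- data.frame(gene_id = "g", transcript_id = "t", seq_id = "s",
                   strand = c("+", "-"), start = c(0L, 100L), end = c(50L, 150L),
                   completeness = "complete")
  expect_error(gene_models(df), "both strands")
})

test_that("GTF and GFF3 writers round-trip all completeness states", {
  set.seed(42)
  m <- random_gene_set(10L)
  m$completeness[m$gene_id %in% c("g1")] <- "missing_start"
  m$completeness[m$gene_id %in% c("g2")] <- "missing_stop"
  m$completeness[m$gene_id %in% c("g3")] <- "missing_both"
  m <- gene_models(m)
  for (dia in c("gtf", "gff3")) {
    f <- tempfile(fileext = paste0(".", dia))
    write_gene_models(m, f, dia)
    back <- read_gene_models(f, dia)
    expect_identical(as.data.frame(back), as.data.frame(m), label = dia)
  }
})

test_that("compact dialect: run-length classes, introns and event tokens", {
  f <- tempfile(fileext = ".aln")
  writeLines(c("## prohintr-compact 1",
               "C\tp1\ts1\t+\t120\tcovers_start,covers_stop",
               "B\t940\t1000\tM10S2M8\t.",
               "B\t1100\t1160\tM20\t*@1234"), f)
  chains <- parse_alignments(f, "compact")
  expect_length(chains, 1L)
  ch <- chains[[1L]]
  # M10S2M8 decodes to 18 identical + 2 substitution columns
  cls <- strsplit(ch$blocks$classes[[1L]], "")[[1L]]
  expect_equal(sum(cls == "M"), 18L)
  expect_equal(sum(cls == "S"), 2L)
  # gap between the blocks is one candidate intron [1000, 1100)
  iv <- prohintr:::chain_introns(ch)
  expect_equal(iv, data.frame(start = 1000L, end = 1100L))
  # event recorded at genomic position 1234
  expect_equal(ch$events$type, "stop")
  expect_equal(ch$events$pos, 1234L)
  expect_true(ch$covers_start && ch$covers_stop)
})

test_that("compact writer and parser are mutually inverse on fixtures", {
  fx <- make_fixture(fixture_config(seed = 21, n_genes = 6L, sequence_length = 60000L,
                                    frameshift_rate = 0.3, stop_rate = 0.3))
  f <- tempfile(fileext = ".aln")
  write_alignments_compact(fx$chains, f)
  back <- parse_alignments(f, "compact")
  expect_length(back, length(fx$chains))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$blocks, fx$chains[[i]]$blocks)
    expect_identical(back[[i]]$protein_id, fx$chains[[i]]$protein_id)
    expect_equal(back[[i]]$score, fx$chains[[i]]$score)
    ev_a <- back[[i]]$events[order(back[[i]]$events$pos), ]
    ev_b <- fx$chains[[i]]$events[order(fx$chains[[i]]$events$pos), ]
    expect_equal(ev_a$pos, ev_b$pos)
  }
})

test_that("out-of-order blocks reject the chain with a warning, parsing continues", {
  f <- tempfile(fileext = ".aln")
  writeLines(c("C\tbad\ts1\t+\t10\t.",
               "B\t1100\t1160\tM20\t.",
               "B\t940\t1000\tM20\t.",
               "C\tgood\ts1\t+\t10\t.",
               "B\t940\t1000\tM20\t."), f)
  expect_warning(chains <- parse_alignments(f, "compact"), "rejecting chain bad")
  expect_length(chains, 1L)
  expect_identical(chains[[1L]]$protein_id, "good")
})

test_that("miniprot GFF chains lack residue detail but keep block structure", {
  fx <- make_fixture(fixture_config(seed = 22, n_genes = 4L, sequence_length = 40000L))
  f <- tempfile(fileext = ".gff3")
  write_alignments_gff(fx$chains, f)
  back <- parse_alignments(f, "miniprot_gff")
  expect_length(back, length(fx$chains))
  for (i in seq_along(back)) {
    expect_false(back[[i]]$has_detail)
    expect_true(back[[i]]$covers_start)
    expect_identical(back[[i]]$blocks$start, fx$chains[[i]]$blocks$start)
    expect_identical(back[[i]]$blocks$end, fx$chains[[i]]$blocks$end)
  }
})

test_that("hints GFF writer emits the exact column-9 contract and round-trips", {
  h <- hints(data.frame(seq_id = "s1", feature = c("intron", "CDSpart"),
                        start = c(1000L, 1009L), end = c(1100L, 1091L),
                        strand = "+", score = c(0.91, 0.5), mult = c(3L, 1L),
                        confidence = c("high", "low")))
  f <- tempfile(fileext = ".gff")
  write_hints_gff(h, f)
  lines <- readLines(f)
  expect_identical(lines[[2L]], "s1\tminiprothint\tintron\t1001\t1100\t0.91\t+\t.\tsrc=M;mult=3;pri=4")
  expect_match(lines[[3L]], "src=P;mult=1;pri=4$")
  back <- read_hints_gff(f)
  expect_identical(as.data.frame(back), as.data.frame(h))
  # empty set: header comment only
  write_hints_gff(empty <- h[0, ], f)
  expect_identical(readLines(f), "# prohintr hints")
  expect_equal(nrow(read_hints_gff(f)), 0L)
})

test_that("GenBank training records: excision arithmetic, strand, clamping", {
  a <- genome_assembly(c(s1 = paste(rep("ACGTTGCA", 125), collapse = "")))  # 1 kb
  m <- gene_models(data.frame(gene_id = "tg1", transcript_id = "tg1.t1", seq_id = "s1",
                              strand = "+", start = c(100L, 250L), end = c(160L, 400L),
                              completeness = "complete"))
  tg <- structure(list(models = m,
                       info = data.frame(transcript_id = "tg1.t1", source = "alignment",
                                         protein_id = "p", score = 1, n_exons = 2L,
                                         flank = 50L, window_start = 50L, window_end = 450L)),
                  class = "training_gene_set")
  f <- tempfile(fileext = ".gb")
  write_training_genbank(tg, a, f)
  rec <- read_training_genbank(f)[[1L]]
  expect_equal(rec$length, 400L)                       # window [50,450) on a gene [100,400)
  expect_equal(rec$cds, data.frame(start = c(50L, 200L), end = c(110L, 350L)))
  expect_match(readLines(f)[5L], "join\\(51\\.\\.110,201\\.\\.350\\)")
  expect_identical(rec$seq, subseq_window(a, "s1", 50L, 450L))

  # minus strand uses complement(join(...))
  m2 <- gene_models(transform(as.data.frame(m), strand = "-"))
  tg$models <- m2
  write_training_genbank(tg, a, f)
  expect_match(paste(readLines(f), collapse = "\n"), "complement\\(join\\(")

  # window exceeding the sequence start is clamped (and reported)
  tg$info$window_start <- -40L
  expect_message(write_training_genbank(tg, a, f), "clamped")
  expect_equal(read_training_genbank(f)[[1L]]$length, 450L)
})

test_that("fixture alignments reproduce the planted intron intervals exactly", {
  fx <- make_fixture(fixture_config(seed = 23, n_genes = 8L, sequence_length = 80000L))
  truth_introns <- do.call(rbind, lapply(split(fx$truth, fx$truth$transcript_id), function(tr) {
    tr <- tr[order(tr$start), ]
    n <- nrow(tr)
    if (n < 2L) return(NULL)
    data.frame(seq_id = tr$seq_id[[1L]], strand = tr$strand[[1L]],
               start = tr$end[-n], end = tr$start[-1L])
  }))
  want <- sort(paste(truth_introns$seq_id, truth_introns$strand,
                     truth_introns$start, truth_introns$end))
  got <- sort(unique(unlist(lapply(fx$chains, function(ch) {
    iv <- prohintr:::chain_introns(ch)
    paste(ch$seq_id, ch$strand, iv$start, iv$end)
  }))))
  expect_identical(got, unique(want))
})
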