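high_evidence_for <- function(chains) classify_evidence(chains, scoring_config())$evidence

test_that("one training gene per locus: max score, then CDS length, then protein id", {
  # two overlapping candidates, scores 120 vs 90 -> keep the 120 one
  a <- chain2("pA", b1 = c(1000L, 1099L), b2 = c(1300L, 1399L), score = 120)
  b <- chain2("pB", b1 = c(1050L, 1149L), b2 = c(1300L, 1399L), score = 90)
  tg <- select_training_genes(list(a, b), high_evidence_for(list(a, b)))
  expect_equal(nrow(tg$info), 1L)
  expect_identical(tg$info$protein_id, "pA")
  # equal scores: the longer CDS wins
  c1 <- chain2("pC", b1 = c(1000L, 1099L), b2 = c(1300L, 1501L), score = 100)  # 300 bp
  c2 <- chain2("pD", b1 = c(1000L, 1099L), b2 = c(1300L, 1471L), score = 100)  # 270 bp
  tg <- select_training_genes(list(c1, c2), high_evidence_for(list(c1, c2)))
  expect_identical(tg$info$protein_id, "pC")
  # equal score and CDS length: lexicographically smaller protein id
  c3 <- chain2("pE", b1 = c(1000L, 1099L), b2 = c(1300L, 1501L), score = 100)
  tg <- select_training_genes(list(c3, c1), high_evidence_for(list(c3, c1)))
  expect_identical(tg$info$protein_id, "pC")
})

test_that("overlapping candidates on opposite strands form distinct loci", {
  a <- chain2("pA", strand = "+", score = 100)
  b <- chain2("pB", strand = "-", score = 50)
  tg <- select_training_genes(list(a, b), high_evidence_for(list(a, b)))
  expect_equal(nrow(tg$info), 2L)
})

test_that("candidate filters: high-confidence introns, clean ORF, terminal coverage", {
  ok <- chain2("ok")
  # an in-frame stop event disqualifies the chain
  ev <- data.frame(type = "stop", pos = 950L)
  bad_ev <- chain2("bad_ev", events = ev)
  # CDS length not a multiple of 3
  bad_len <- chain2("bad_len", b2 = c(1100L, 1201L))
  # does not reach the protein terminus
  bad_cov <- chain2("bad_cov", covers = FALSE)
  chains <- list(ok, bad_ev, bad_len, bad_cov)
  tg <- select_training_genes(chains, high_evidence_for(chains))
  expect_identical(tg$info$protein_id, "ok")
  # selected genes' introns are all high-confidence, spans non-overlapping per strand
  expect_error(select_training_genes(list(bad_cov), high_evidence_for(list(bad_cov))),
               "no training genes")
})

test_that("selected training genes include the downstream stop codon and are locus-exclusive", {
  fx <- make_fixture(fixture_config(seed = 41, n_genes = 12L, sequence_length = 100000L,
                                    n_donor_proteomes = 2L))
  cls <- classify_evidence(fx$chains, scoring_config())
  tg <- select_training_genes(fx$chains, cls$evidence)
  expect_equal(nrow(tg$info), 12L)
  # exact CDS structures of the planted genes are recovered (stop codon included)
  expect_setequal(unname(transcript_keys(tg$models)),
                  unname(transcript_keys(fx$truth)))
  # pairwise non-overlap on the same strand
  sp <- transcript_spans(tg$models)
  for (key in unique(paste(sp$seq_id, sp$strand))) {
    s <- sp[paste(sp$seq_id, sp$strand) == key, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1L) expect_true(all(s$start[-1L] >= s$end[-nrow(s)]))
  }
})

test_that("flank rule: half the mean span, clamped to [floor, cap]", {
  mk_tg <- function(spans) {
    rows <- do.call(rbind, lapply(seq_along(spans), function(i)
      data.frame(gene_id = sprintf("t%d", i), transcript_id = sprintf("t%d.t1", i),
                 seq_id = "s1", strand = "+", start = (i - 1L) * 100000L,
                 end = (i - 1L) * 100000L + spans[[i]], completeness = "complete")))
    structure(list(models = gene_models(rows),
                   info = data.frame(transcript_id = rows$transcript_id, flank = NA)),
              class = "training_gene_set")
  }
  expect_equal(compute_flank(mk_tg(c(2000L, 4000L))), 1500L)   # mean 3000 -> 1500
  expect_equal(compute_flank(mk_tg(c(100L, 100L))), 500L)      # floor
  expect_equal(compute_flank(mk_tg(c(50000L, 50000L))), 10000L) # cap
})

test_that("support evaluation: intron exactness and CDS coverage threshold", {
  m <- gene_models(data.frame(
    gene_id = c("g1", "g1", "g1", "g2"), transcript_id = c("t1", "t1", "t1", "t2"),
    seq_id = "s1", strand = "+",
    start = c(0L, 200L, 400L, 5000L), end = c(100L, 300L, 500L, 5400L),
    completeness = "complete"))
  h <- hints(data.frame(seq_id = "s1",
                        feature = c("intron", "intron", "CDSpart", "CDSpart", "CDSpart", "CDSpart"),
                        start = c(100L, 300L, 0L, 200L, 400L, 5000L),
                        end = c(200L, 400L, 95L, 300L, 500L, 5200L),
                        strand = "+", score = 1, mult = 1L, confidence = "low"))
  rep <- evaluate_support(m, h, coverage_threshold = 0.8)
  t1 <- rep[rep$transcript_id == "t1", ]
  expect_equal(t1$n_introns, 2L); expect_equal(t1$n_introns_supported, 2L)
  expect_equal(t1$cds_coverage_fraction, 295 / 300)
  expect_true(t1$fully_supported)
  # single-exon transcript at coverage 0.5: below threshold
  t2 <- rep[rep$transcript_id == "t2", ]
  expect_equal(t2$cds_coverage_fraction, 0.5)
  expect_false(t2$fully_supported)
  # one intron hint removed -> not fully supported
  h2 <- h[-1L, ]
  rep2 <- evaluate_support(m, h2, coverage_threshold = 0.8)
  expect_false(rep2$fully_supported[rep2$transcript_id == "t1"])
  # incomplete models are never fully supported
  m3 <- m; m3$completeness <- "missing_start"
  rep3 <- evaluate_support(gene_models(m3), h, coverage_threshold = 0.8)
  expect_false(any(rep3$fully_supported))
})

test_that("flank refinement removes neighboring predictions from windows", {
  tg_model <- data.frame(gene_id = "tg1", transcript_id = "tg1.t1", seq_id = "s1",
                         strand = "+", start = 5000L, end = 5600L, completeness = "complete")
  tg <- structure(list(models = gene_models(tg_model),
                       info = data.frame(transcript_id = "tg1.t1", source = "alignment",
                                         protein_id = "p", score = 1, n_exons = 1L,
                                         flank = 1500L, window_start = 3500L,
                                         window_end = 7100L)),
                  class = "training_gene_set")
  # neighbor ending 200 bp left of the gene: left flank shrinks to its boundary
  nb <- data.frame(gene_id = "n1", transcript_id = "n1.t1", seq_id = "s1", strand = "+",
                   start = 4300L, end = 4800L, completeness = "complete")
  preds <- gene_models(rbind(nb, tg_model))  # the gene's own prediction is exempt
  out <- refine_flanks(tg, preds)
  expect_equal(out$info$window_start, 4800L)
  expect_equal(out$info$window_end, 7100L)
  # no neighbors: window unchanged
  out2 <- refine_flanks(tg, gene_models(tg_model))
  expect_equal(out2$info$window_start, 3500L)
  # neighbor overlapping the gene itself: window collapses to the gene span
  ov <- data.frame(gene_id = "n2", transcript_id = "n2.t1", seq_id = "s1", strand = "-",
                   start = 5400L, end = 5900L, completeness = "complete")
  expect_message(out3 <- refine_flanks(tg, gene_models(rbind(ov, tg_model))), "collapsed")
  expect_equal(out3$info$window_start, 5000L)
  expect_equal(out3$info$window_end, 5600L)
  # invariant: refined windows contain zero bp of other predictions
  w <- IRanges::IRanges(out$info$window_start + 1L, out$info$window_end)
  others <- IRanges::IRanges(nb$start + 1L, nb$end)
  expect_equal(sum(IRanges::width(IRanges::intersect(w, others))), 0L)
})

test_that("training-gene recovery is monotone in donor divergence", {
  counts <- vapply(c(0, 0.3, 0.7), function(div) {
    fx <- make_fixture(fixture_config(seed = 47, n_genes = 15L, sequence_length = 60000L,
                                      protein_divergence = div))
    cls <- classify_evidence(fx$chains, scoring_config())
    n <- tryCatch(nrow(select_training_genes(fx$chains, cls$evidence)$info),
                  error = function(e) 0L)
    n
  }, integer(1L))
  expect_true(all(diff(counts) <= 0L))
  expect_equal(counts[[1L]], 15L)
})
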