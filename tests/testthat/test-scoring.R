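test_that("IBA score: closed-form hand-computed cases", {
  cfg <- scoring_config()
  # fully conserved flanks, no events
  j <- list(left = rep("identical", 20L), right = rep("identical", 20L), n_events = 0L)
  expect_equal(score_iba(j, cfg), 1.0)
  # fully diverged flanks
  j <- list(left = rep("mismatch", 20L), right = rep("mismatch", 20L))
  expect_equal(score_iba(j, cfg), 0.0)
  # W = 2, q = 0.8: left (identical, mismatch) -> 1/1.8, right all identical -> 1
  cfg2 <- scoring_config(window = 2L, decay = 0.8)
  j <- list(left = c("identical", "mismatch"), right = c("identical", "identical"),
            n_events = 0L)
  expect_equal(score_iba(j, cfg2), mean(c(1 / 1.8, 1)), tolerance = 1e-12)
  expect_equal(round(score_iba(j, cfg2), 4), 0.7778)
  # one frameshift in the window halves the score multiplicatively
  j$n_events <- 1L
  expect_equal(round(score_iba(j, cfg2), 4), 0.3889)
  # a side with zero aligned columns scores 0
  j0 <- list(left = character(), right = rep("identical", 5L))
  expect_equal(score_iba(j0, cfg), 0.5)
  # unknown column class is an error
  expect_error(score_iba(list(left = "weird", right = "identical"), cfg), "unknown column class")
})

test_that("IBA is bounded, monotone under mismatch upgrades, decay-invariant on uniform flanks", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(1:25, 1L)
    left <- sample(c("identical", "substitution", "mismatch"), n, replace = TRUE)
    right <- sample(c("identical", "substitution", "mismatch"), n, replace = TRUE)
    j <- list(left = left, right = right, n_events = sample(0:2, 1L))
    s <- score_iba(j)
    expect_gte(s, 0); expect_lte(s, 1)
    # upgrading any mismatch column to identical never lowers the score
    mm <- which(left == "mismatch")
    if (length(mm)) {
      left2 <- left; left2[[sample(mm, 1L)]] <- "identical"
      expect_gte(score_iba(list(left = left2, right = right, n_events = j$n_events)), s)
    }
    # uniform-class flanks are invariant to the decay parameter
    u <- sample(c("identical", "substitution", "mismatch"), 1L)
    ju <- list(left = rep(u, n), right = rep(u, n), n_events = 0L)
    expect_equal(score_iba(ju, scoring_config(decay = 0.5)),
                 score_iba(ju, scoring_config(decay = 0.999)), tolerance = 1e-9)
  }
})

test_that("IMC counts distinct proteins per identical intron", {
  mk <- function(p, strand = "+") chain2(protein_id = p, strand = strand)
  imc <- compute_imc(list(mk("p1"), mk("p2"), mk("p3")))
  expect_equal(nrow(imc), 1L)
  expect_equal(imc$imc, 3L)
  expect_equal(imc$start, 1000L); expect_equal(imc$end, 1100L)
  # the same protein aligned twice counts once
  imc <- compute_imc(list(mk("p1"), mk("p1")))
  expect_equal(imc$imc, 1L)
  # identical interval on opposite strands: two separate keys
  imc <- compute_imc(list(mk("p1", "+"), mk("p2", "-")))
  expect_equal(nrow(imc), 2L)
  expect_equal(imc$imc, c(1L, 1L))
})

test_that("IMC equals a brute-force (protein x intron) double loop on random instances", {
  set.seed(202)
  for (rep in 1:200) {
    chains <- random_chains(n_proteins = sample(3:8, 1L), n_loci = sample(2:4, 1L))
    imc <- compute_imc(chains)
    oracle <- brute_imc(chains)
    got <- stats::setNames(imc$imc, paste(imc$seq_id, imc$strand, imc$start, imc$end, sep = "|"))
    expect_identical(sort(names(got)), sort(names(oracle)))
    expect_identical(unname(got[names(oracle)]), unname(oracle))
  }
})

test_that("classification thresholds: keep/high logic under the defaults", {
  cfg <- scoring_config()
  mkchain <- function(p, cls) chain2(protein_id = p, cls1 = cls, cls2 = cls)
  # iba 1.0, imc 1 -> high via the IBA branch
  cls <- classify_evidence(list(mkchain("p1", NULL)), cfg)
  expect_identical(cls$evidence$confidence, "high")
  # all-mismatch flanks, imc 1 -> iba 0 -> discarded
  cls <- classify_evidence(list(mkchain("p1", strrep("X", 33L))), cfg)
  expect_identical(cls$evidence$confidence, "discarded")
  expect_false(any(cls$hints$feature == "intron"))
  # weak iba but imc 3 -> kept and high via the IMC branch
  chains <- lapply(c("p1", "p2", "p3"), function(p) mkchain(p, strrep("X", 33L)))
  cls <- classify_evidence(chains, cfg)
  expect_identical(cls$evidence$confidence, "high")
  expect_equal(cls$evidence$imc, 3L)
  # intermediate iba (>= keep, < high), imc 1 -> low
  cls15 <- paste0(strrep("S", 8L), strrep("X", 25L))  # decayed weighted credit in (0.1, 0.25)
  cls <- classify_evidence(list(mkchain("p1", cls15)), cfg)
  expect_identical(cls$evidence$confidence, "low")
})

test_that("chains without residue detail contribute to IMC only", {
  plain <- alignment_chain("p9", "s1", "+",
                           data.frame(start = c(900L, 1100L), end = c(1000L, 1200L)),
                           score = 5)
  cls <- classify_evidence(list(plain), scoring_config())
  expect_equal(cls$evidence$iba, 0)
  expect_identical(cls$evidence$confidence, "discarded")  # imc 1 < 2, iba 0
  # with a second distinct protein the IMC branch keeps it
  plain2 <- alignment_chain("p10", "s1", "+",
                            data.frame(start = c(900L, 1100L), end = c(1000L, 1200L)),
                            score = 5)
  cls <- classify_evidence(list(plain, plain2), scoring_config())
  expect_identical(cls$evidence$confidence, "high")
})

test_that("hint derivation: CDSpart shrink, start/stop placement, mult semantics", {
  ch <- chain2(b1 = c(1000L, 1100L), b2 = c(1300L, 1400L))
  cls <- classify_evidence(list(ch), scoring_config())
  h <- cls$hints
  cp <- h[h$feature == "CDSpart", ]
  # block [1000,1100) shrinks by 9 bp per side to [1009,1091)
  expect_true(any(cp$start == 1009L & cp$end == 1091L))
  intron <- h[h$feature == "intron", ]
  expect_equal(intron$mult, 1L)
  expect_identical(intron$confidence, "high")
  expect_identical(intron$source_tag, "M")
  expect_true(all(h$mult[h$feature != "intron"] == 1L))
  # plus strand: start hint at the first codon, stop hint just beyond the chain
  expect_true(any(h$feature == "start" & h$start == 1000L & h$end == 1003L))
  expect_true(any(h$feature == "stop" & h$start == 1400L & h$end == 1403L))
  # confidence high <=> src M over the whole hint set
  expect_identical(h$source_tag == "M", h$confidence == "high")
})

test_that("evidence partition is exhaustive and exclusive", {
  set.seed(303)
  for (rep in 1:25) {
    chains <- random_chains(n_proteins = sample(4:8, 1L))
    ev <- classify_evidence(chains, scoring_config())$evidence
    expect_true(all(ev$confidence %in% c("discarded", "low", "high")))
    keys <- paste(ev$seq_id, ev$strand, ev$start, ev$end)
    expect_identical(anyDuplicated(keys), 0L)
    # every distinct intron of the input appears exactly once
    expect_equal(nrow(ev), length(brute_imc(chains)))
  }
})

test_that("zero divergence, no corruption: every planted intron is high, none is false", {
  fx <- make_fixture(fixture_config(seed = 31, n_genes = 10L, sequence_length = 80000L,
                                    protein_divergence = 0))
  ev <- classify_evidence(fx$chains, scoring_config())$evidence
  expect_identical(unique(ev$confidence), "high")
  truth_iv <- unlist(lapply(split(fx$truth, fx$truth$transcript_id), function(tr) {
    tr <- tr[order(tr$start), ]
    n <- nrow(tr)
    if (n < 2L) return(character())
    paste(tr$seq_id[[1L]], tr$strand[[1L]], tr$end[-n], tr$start[-1L])
  }))
  expect_setequal(paste(ev$seq_id, ev$strand, ev$start, ev$end), truth_iv)
})
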