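# shared fixture builders for the test suite (everything generated in code)

# a minimal hand-built chain: two blocks with given class strings
chain2 <- function(protein_id = "p1", seq_id = "s1", strand = "+",
                   b1 = c(901L, 1000L), b2 = c(1100L, 1199L),
                   cls1 = NULL, cls2 = NULL, score = 100, events = NULL,
                   covers = TRUE) {
  n1 <- (b1[[2L]] - b1[[1L]]) %/% 3L; n2 <- (b2[[2L]] - b2[[1L]]) %/% 3L
  blocks <- data.frame(start = c(b1[[1L]], b2[[1L]]), end = c(b1[[2L]], b2[[2L]]),
                       classes = c(cls1 %||% strrep("M", n1), cls2 %||% strrep("M", n2)))
  alignment_chain(protein_id, seq_id, strand, blocks, score = score, events = events,
                  covers_start = covers, covers_stop = covers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random chain set over a small coordinate universe, for oracle tests
random_chains <- function(n_proteins = 6L, n_loci = 3L) {
  chains <- list()
  for (p in seq_len(n_proteins)) {
    locus <- sample.int(n_loci, 1L)
    base <- locus * 10000L
    n_blocks <- sample(2:4, 1L)
    # shared intron grid per locus so distinct proteins can hit identical introns
    bstart <- base + cumsum(c(0L, rep(300L, n_blocks - 1L)))
    blen <- 90L
    blocks <- data.frame(start = bstart, end = bstart + blen,
                         classes = strrep("M", blen %/% 3L))
    # sometimes drop the last block so intron sets differ between proteins
    if (stats::runif(1L) < 0.3 && n_blocks > 2L) blocks <- blocks[-n_blocks, ]
    chains[[p]] <- alignment_chain(sprintf("p%d", sample.int(n_proteins %/% 2L + 1L, 1L)),
                                   sprintf("s%d", sample.int(2L, 1L)),
                                   sample(c("+", "-"), 1L), blocks, score = 10)
  }
  chains
}

# independent brute-force IMC: double loop over (protein, intron) pairs
brute_imc <- function(chains) {
  seen <- list()
  for (ch in chains) {
    b <- ch$blocks
    if (nrow(b) < 2L) next
    for (i in seq_len(nrow(b) - 1L)) {
      key <- paste(ch$seq_id, ch$strand, b$end[[i]], b$start[[i + 1L]], sep = "|")
      seen[[key]] <- union(seen[[key]], ch$protein_id)
    }
  }
  sapply(seen, length)
}

# random valid gene-model table for evaluation property tests
random_gene_set <- function(n_genes = 8L, seq_ids = c("s1", "s2"), prefix = "g") {
  rows <- list()
  pos <- stats::setNames(rep(0L, length(seq_ids)), seq_ids)
  for (g in seq_len(n_genes)) {
    sid <- sample(seq_ids, 1L)
    n_ex <- sample(1:4, 1L)
    start <- pos[[sid]] + sample(50:200, 1L)
    ex <- list()
    for (e in seq_len(n_ex)) {
      len <- 3L * sample(10:40, 1L)
      ex[[e]] <- c(start, start + len)
      start <- start + len + sample(60:200, 1L)
    }
    pos[[sid]] <- start
    gid <- sprintf("%s%d", prefix, g)
    rows[[g]] <- data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                            seq_id = sid, strand = sample(c("+", "-"), 1L),
                            start = vapply(ex, `[[`, numeric(1L), 1L),
                            end = vapply(ex, `[[`, numeric(1L), 2L),
                            completeness = "complete")
  }
  gene_models(do.call(rbind, rows))
}
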