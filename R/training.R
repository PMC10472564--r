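#' Select training genes from high-confidence alignments
#'
#' Builds the gene-finder training set from spliced alignments: candidate
#' chains are those whose every candidate intron is high-confidence, that
#' carry no frameshift or in-frame-stop event, whose implied CDS length is a
#' multiple of 3, that cover the protein's start and end, and that have at
#' least `min_exons` blocks. Candidates are grouped into loci (connected
#' components of same-strand span overlap) and exactly one chain per locus
#' is kept: the one with maximal alignment score, ties broken by longer CDS,
#' then lexicographically smaller protein id.
#'
#' @param chains list of [alignment_chain()]
#' @param evidence classified intron evidence from [classify_evidence()]
#' @param min_exons minimum number of CDS blocks (default 1; single-exon
#'   candidates are admitted but reported)
#' @return a `training_gene_set`: list with `models` (a [gene_models()]
#'   table, one transcript per selected gene, ids `tg1`, `tg2`, ... in
#'   genomic order) and `info` (per-gene data.frame: transcript_id, source,
#'   protein_id, score, n_exons, flank, window_start, window_end)
#' @export
select_training_genes <- function(chains, evidence, min_exons = 1L) {
  high <- evidence[evidence$confidence == "high", , drop = FALSE]
  high_keys <- paste(high$seq_id, high$strand, high$start, high$end, sep = "\r")
  is_candidate <- vapply(chains, function(ch) {
    if (nrow(ch$blocks) < min_exons) return(FALSE)
    if (nrow(ch$events) > 0L) return(FALSE)
    if (!ch$covers_start || !ch$covers_stop) return(FALSE)
    if (sum(ch$blocks$end - ch$blocks$start) %% 3L != 0L) return(FALSE)
    iv <- chain_introns(ch)
    if (nrow(iv) == 0L) return(TRUE)
    all(paste(ch$seq_id, ch$strand, iv$start, iv$end, sep = "\r") %in% high_keys)
  }, logical(1L))
  cand <- chains[is_candidate]
  if (!length(cand)) stopf("no training genes")
  spans <- data.frame(
    idx = seq_along(cand),
    seq_id = vapply(cand, `[[`, character(1L), "seq_id"),
    strand = vapply(cand, `[[`, character(1L), "strand"),
    start = vapply(cand, function(ch) min(ch$blocks$start), integer(1L)),
    end = vapply(cand, function(ch) max(ch$blocks$end), integer(1L)),
    score = vapply(cand, function(ch) as.numeric(ch$score), numeric(1L)),
    cds_len = vapply(cand, function(ch) sum(ch$blocks$end - ch$blocks$start), integer(1L)),
    protein_id = vapply(cand, `[[`, character(1L), "protein_id"))
  gr <- GenomicRanges::GRanges(spans$seq_id,
                               IRanges::IRanges(spans$start + 1L, spans$end),
                               strand = spans$strand)
  # connected components of same-strand overlap = membership in reduced ranges
  red <- GenomicRanges::reduce(gr)
  locus <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, red))
  winners <- vapply(split(seq_len(nrow(spans)), locus), function(ii) {
    s <- spans[ii, , drop = FALSE]
    o <- order(-s$score, -s$cds_len, s$protein_id, method = "radix")
    s$idx[o[[1L]]]
  }, integer(1L))
  sel <- spans[spans$idx %in% winners, , drop = FALSE]
  sel <- sel[order_by(sel, c("seq_id", "start", "end", "strand")), , drop = FALSE]
  rows <- list(); info <- list()
  for (j in seq_len(nrow(sel))) {
    ch <- cand[[sel$idx[[j]]]]
    gid <- sprintf("tg%d", j); tid <- sprintf("tg%d.t1", j)
    b <- ch$blocks
    # implied gene structure includes the stop codon downstream of the
    # aligned protein: extend the biological last block by 3 bp
    if (ch$strand == "+") b$end[[nrow(b)]] <- b$end[[nrow(b)]] + 3L
    else b$start[[1L]] <- b$start[[1L]] - 3L
    rows[[j]] <- data.frame(gene_id = gid, transcript_id = tid, seq_id = ch$seq_id,
                            strand = ch$strand, start = b$start, end = b$end,
                            completeness = "complete")
    info[[j]] <- data.frame(transcript_id = tid, source = "alignment",
                            protein_id = ch$protein_id, score = ch$score,
                            n_exons = nrow(b), flank = NA_integer_,
                            window_start = NA_integer_, window_end = NA_integer_)
  }
  structure(list(models = gene_models(do.call(rbind, rows)),
                 info = do.call(rbind, info)),
            class = "training_gene_set")
}

#' @export
print.training_gene_set <- function(x, ...) {
  cat(sprintf("training_gene_set: %d gene(s), %d single-exon\n",
              nrow(x$info), sum(x$info$n_exons == 1L)))
  invisible(x)
}

#' Flank size for training-gene excision
#'
#' The flank added on both sides of every training gene before excision:
#' half the mean genomic span of the training genes, clamped to
#' [`floor`, `cap`]. One value is used for all genes.
#'
#' @param training a `training_gene_set`
#' @param cap maximum flank (bp, default 10000)
#' @param floor minimum flank (bp, default 500)
#' @return flank size in bp (integer)
#' @export
compute_flank <- function(training, cap = 10000L, floor = 500L) {
  sp <- transcript_spans(training$models)
  if (nrow(sp) == 0L) stopf("no training genes")
  as.integer(clamp(round(0.5 * mean(sp$end - sp$start)), floor, cap))
}

#' Apply a flank to a training-gene set
#'
#' Sets each gene's excision window to its span extended by `flank` on both
#' sides, clamped to the sequence bounds.
#'
#' @param training a `training_gene_set`
#' @param flank flank size in bp (e.g. from [compute_flank()])
#' @param lengths named vector of sequence lengths (see [seq_lengths()])
#' @return the updated `training_gene_set`
#' @export
apply_flank <- function(training, flank, lengths) {
  sp <- transcript_spans(training$models)
  m <- match(training$info$transcript_id, sp$transcript_id)
  training$info$flank <- as.integer(flank)
  training$info$window_start <- pmax(sp$start[m] - as.integer(flank), 0L)
  training$info$window_end <- pmin(sp$end[m] + as.integer(flank),
                                   as.integer(lengths[sp$seq_id[m]]))
  training
}

#' Evidence support of predicted transcripts
#'
#' Operationalizes "full evidence support": a transcript is fully supported
#' iff every one of its introns matches an intron hint exactly (sequence,
#' strand and interval), the fraction of its CDS covered by the union of
#' CDSpart hints is at least `coverage_threshold`, and the model is
#' complete.
#'
#' @param predictions a [gene_models()] table
#' @param h a [hints()] table with intron and CDSpart features
#' @param coverage_threshold minimum CDS coverage fraction (default 0.8)
#' @return data.frame: transcript_id, n_introns, n_introns_supported,
#'   cds_coverage_fraction, fully_supported
#' @export
evaluate_support <- function(predictions, h, coverage_threshold = 0.8) {
  ih <- h[h$feature == "intron", , drop = FALSE]
  ikeys <- paste(ih$seq_id, ih$strand, ih$start, ih$end, sep = "\r")
  ch <- h[h$feature == "CDSpart", , drop = FALSE]
  out <- lapply(split(predictions, predictions$transcript_id), function(tr) {
    tr <- tr[order(tr$start), , drop = FALSE]
    n <- nrow(tr)
    introns <- if (n > 1L) data.frame(start = tr$end[-n], end = tr$start[-1L])
               else data.frame(start = integer(), end = integer())
    supported <- if (nrow(introns))
      sum(paste(tr$seq_id[[1L]], tr$strand[[1L]], introns$start, introns$end, sep = "\r") %in% ikeys)
    else 0L
    cov_h <- ch[ch$seq_id == tr$seq_id[[1L]] & ch$strand == tr$strand[[1L]], , drop = FALSE]
    cds_ir <- IRanges::IRanges(tr$start + 1L, tr$end)
    cov <- if (nrow(cov_h)) {
      hit <- IRanges::intersect(IRanges::reduce(IRanges::IRanges(cov_h$start + 1L, cov_h$end)), cds_ir)
      sum(IRanges::width(hit)) / sum(IRanges::width(cds_ir))
    } else 0
    data.frame(transcript_id = tr$transcript_id[[1L]], n_introns = nrow(introns),
               n_introns_supported = supported, cds_coverage_fraction = cov,
               fully_supported = supported == nrow(introns) &&
                 cov >= coverage_threshold &&
                 tr$completeness[[1L]] == "complete")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove neighboring predicted genes from training-gene flanks
#'
#' Shrinks every training gene's excision window so it contains no part of
#' any other predicted gene (predictions whose CDS structure equals the
#' training gene itself do not count). If a neighbor overlaps the training
#' gene's own span, the window on that side collapses to the gene boundary
#' and the conflict is reported; windows are never smaller than the gene
#' span.
#'
#' @param training a `training_gene_set` with windows set (see
#'   [apply_flank()])
#' @param all_predictions a [gene_models()] table of predicted genes
#' @return the `training_gene_set` with shrunk windows
#' @export
refine_flanks <- function(training, all_predictions) {
  psp <- transcript_spans(all_predictions)
  pkeys <- transcript_keys(all_predictions)
  tkeys <- transcript_keys(training$models)
  tsp <- transcript_spans(training$models)
  for (i in seq_len(nrow(training$info))) {
    tid <- training$info$transcript_id[[i]]
    g <- tsp[tsp$transcript_id == tid, , drop = FALSE]
    self_key <- tkeys[[tid]]
    others <- psp[psp$seq_id == g$seq_id & pkeys[psp$transcript_id] != self_key, , drop = FALSE]
    w0 <- training$info$window_start[[i]]; w1 <- training$info$window_end[[i]]
    if (!nrow(others)) next
    ov_gene <- others$start < g$end & others$end > g$start
    if (any(ov_gene)) {
      message(sprintf("training gene %s overlaps prediction(s) %s; window collapsed to gene span",
                      tid, paste(others$transcript_id[ov_gene], collapse = ",")))
    }
    left <- others$end[others$end <= g$start & others$end > w0]
    right <- others$start[others$start >= g$end & others$start < w1]
    if (any(ov_gene)) { w0 <- g$start; w1 <- g$end }
    else {
      if (length(left)) w0 <- max(left)
      if (length(right)) w1 <- min(right)
    }
    training$info$window_start[[i]] <- w0
    training$info$window_end[[i]] <- w1
  }
  training
}

#' Build a training-gene set from predicted gene models
#'
#' Wraps fully-supported predictions (see [evaluate_support()]) as the
#' second-round training set, scored by their CDS coverage fraction.
#'
#' @param predictions a [gene_models()] table
#' @param support the report from [evaluate_support()]
#' @return a `training_gene_set` (windows unset; see [apply_flank()])
#' @export
training_set_from_predictions <- function(predictions, support) {
  keep <- support$transcript_id[support$fully_supported]
  if (!length(keep)) stopf("no training genes")
  models <- predictions[predictions$transcript_id %in% keep, , drop = FALSE]
  models <- gene_models(models)
  sp <- transcript_spans(models)
  info <- data.frame(transcript_id = sp$transcript_id, source = "prediction",
                     protein_id = NA_character_,
                     score = support$cds_coverage_fraction[match(sp$transcript_id, support$transcript_id)],
                     n_exons = sp$n_exons, flank = NA_integer_,
                     window_start = NA_integer_, window_end = NA_integer_)
  structure(list(models = models, info = info), class = "training_gene_set")
}

#' Write the training-gene selection report
#' @param training a `training_gene_set`
#' @param path output TSV
#' @export
write_training_tsv <- function(training, path) {
  sp <- transcript_spans(training$models)
  m <- match(training$info$transcript_id, sp$transcript_id)
  out <- cbind(training$info,
               sp[m, c("seq_id", "strand", "start", "end")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
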