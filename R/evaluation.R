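#' F1 score from sensitivity and specificity
#'
#' `2 * Sn * Sp / (Sn + Sp)`, defined as 0 when both are 0.
#'
#' @param sn sensitivity in [0, 1]
#' @param sp specificity in [0, 1]
#' @return F1 in [0, 1]
#' @export
f1 <- function(sn, sp) {
  if (any(sn < 0 | sn > 1 | sp < 0 | sp > 1, na.rm = TRUE))
    stopf("sensitivity and specificity must be in [0, 1]")
  ifelse(sn + sp == 0, 0, 2 * sn * sp / (sn + sp))
}

#' Compare predicted and reference gene sets
#'
#' Coordinate-exact, CDS-only matching at three structural levels. Exon
#' true positives are exact (seq, strand, start, end) matches counted over
#' distinct exons; a transcript matches when its ordered CDS exon list is
#' identical to a reference transcript's; a gene matches (sensitivity side)
#' when at least one of its transcripts matches, and symmetrically on the
#' prediction side for specificity. One reference item matches at most one
#' predicted item. Both inputs are stop-codon-included by construction (see
#' [read_gene_models()]).
#'
#' @param pred,ref [gene_models()] tables on the same assembly
#' @return data.frame of class `accuracy_report`: one row per level
#'   (`gene`, `transcript`, `exon`) with `tp_ref`, `tp_pred`,
#'   `n_reference`, `n_predicted`, `sensitivity`, `specificity`, `f1`
#' @export
compare_gene_sets <- function(pred, ref) {
  if (nrow(ref) == 0L) stopf("empty reference gene set")
  exon_key <- function(m) unique(paste(m$seq_id, m$strand, m$start, m$end, sep = "\r"))
  pe <- exon_key(pred); re <- exon_key(ref)
  exon_tp <- length(intersect(pe, re))
  pk <- transcript_keys(pred); rk <- transcript_keys(ref)
  # dedup: matched pairs limited by multiplicity on both sides
  ptab <- table(pk); rtab <- table(rk)
  shared <- intersect(names(ptab), names(rtab))
  tx_tp <- sum(pmin(as.integer(ptab[shared]), as.integer(rtab[shared])))
  p_sp <- transcript_spans(pred); r_sp <- transcript_spans(ref)
  r_gene_tp <- sum(vapply(split(rk[r_sp$transcript_id], r_sp$gene_id),
                          function(k) any(k %in% pk), logical(1L)))
  p_gene_tp <- if (nrow(p_sp)) sum(vapply(split(pk[p_sp$transcript_id], p_sp$gene_id),
                                          function(k) any(k %in% rk), logical(1L))) else 0L
  lev <- function(level, tp_ref, tp_pred, n_ref, n_pred) {
    sn <- if (n_ref > 0) tp_ref / n_ref else 0
    sp <- if (n_pred > 0) tp_pred / n_pred else 0
    data.frame(level = level, tp_ref = tp_ref, tp_pred = tp_pred,
               n_reference = n_ref, n_predicted = n_pred,
               sensitivity = sn, specificity = sp, f1 = f1(sn, sp))
  }
  out <- rbind(
    lev("gene", r_gene_tp, p_gene_tp, length(unique(ref$gene_id)), length(unique(pred$gene_id))),
    lev("transcript", tx_tp, tx_tp, nrow(r_sp), nrow(p_sp)),
    lev("exon", exon_tp, exon_tp, length(re), length(pe)))
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Summary metrics of one gene set
#'
#' The mono:mult ratio considers only the first isoform of each gene (the
#' transcript with the lexicographically smallest id): single-CDS-exon
#' first isoforms divided by multi-exon ones (`Inf` when there are none of
#' the latter). `max_exons` is the maximum CDS exon count of any
#' transcript; `n_incomplete` counts transcripts lacking a start and/or
#' stop codon.
#'
#' @param models a [gene_models()] table
#' @return data.frame with `n_genes`, `n_transcripts`, `mono_mult_ratio`,
#'   `max_exons`, `n_incomplete`
#' @export
summarize_gene_set <- function(models) {
  sp <- transcript_spans(models)
  if (nrow(sp) == 0L)
    return(data.frame(n_genes = 0L, n_transcripts = 0L, mono_mult_ratio = NA_real_,
                      max_exons = 0L, n_incomplete = 0L))
  first <- do.call(rbind, lapply(split(sp, sp$gene_id), function(g)
    g[order(g$transcript_id, method = "radix")[1L], , drop = FALSE]))
  mono <- sum(first$n_exons == 1L)
  multi <- sum(first$n_exons > 1L)
  data.frame(n_genes = length(unique(sp$gene_id)), n_transcripts = nrow(sp),
             mono_mult_ratio = if (multi == 0L) Inf else mono / multi,
             max_exons = max(sp$n_exons),
             n_incomplete = sum(sp$completeness != "complete"))
}

#' Transcripts reported identically by two annotations
#'
#' The reliable subset of two reference annotations: transcripts whose
#' ordered CDS exon lists are identical in both. Rows are taken from the
#' first input.
#'
#' @param ref_a,ref_b [gene_models()] tables on the same assembly
#' @return a [gene_models()] table (subset of `ref_a`)
#' @export
reliable_subset <- function(ref_a, ref_b) {
  ka <- transcript_keys(ref_a); kb <- transcript_keys(ref_b)
  keep <- names(ka)[ka %in% kb]
  out <- ref_a[ref_a$transcript_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_gene_models())
  gene_models(out)
}

#' Average a per-species F1 column
#'
#' Unweighted arithmetic mean, rounded half-up to two decimals — the
#' summary used for cross-species benchmark tables.
#'
#' @param per_species_f1 non-empty numeric vector of F1 values (percent)
#' @return mean rounded to 2 decimals
#' @export
summarize_f1_table <- function(per_species_f1) {
  if (!length(per_species_f1)) stopf("empty F1 list")
  round_half_up(mean(per_species_f1), 2)
}

#' Bundled cross-species benchmark F1 table
#'
#' Published per-species F1 scores (percent) of a protein-evidence
#' annotation pipeline evaluated against reference annotations of 14
#' species, at gene, transcript and exon level, for two donor settings:
#' `multi_donor` (several reference proteomes) and `single_donor` (one
#' reference proteome). Used by the worked examples and the acceptance
#' script to exercise [summarize_f1_table()].
#'
#' @return data.frame with columns `species`, `donor_mode`, `gene`,
#'   `transcript`, `exon`
#' @export
benchmark_f1 <- function() {
  path <- system.file("extdata", "benchmark_f1.csv", package = "prohintr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an accuracy report
#' @param report an `accuracy_report` from [compare_gene_sets()]
#' @param path output path (TSV or JSON by extension)
#' @export
write_accuracy_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
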