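#' Gene model table
#'
#' Gene models are kept in a plain data.frame with one row per CDS exon and
#' columns `gene_id`, `transcript_id`, `seq_id`, `strand`, `start`, `end`,
#' `completeness`. Coordinates are 0-based half-open; the terminal stop codon
#' is part of the CDS (models read from GTF, where the stop codon is a
#' separate feature, are canonicalized on input). `completeness` is one of
#' `complete`, `missing_start`, `missing_stop`, `missing_both` and is
#' constant within a transcript.
#'
#' @param df data.frame with the columns above
#' @return the validated data.frame with class `gene_models`
#' @export
gene_models <- function(df) {
  req <- c("gene_id", "transcript_id", "seq_id", "strand", "start", "end", "completeness")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("gene_models: missing column(s) %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start >= df$end)) stopf("gene_models: empty or inverted exon interval")
  if (!all(df$strand %in% c("+", "-"))) stopf("gene_models: strand must be + or -")
  if (!all(df$completeness %in% c("complete", "missing_start", "missing_stop", "missing_both")))
    stopf("gene_models: invalid completeness value")
  for (tid in unique(df$transcript_id)) {
    rows <- df[df$transcript_id == tid, ]
    if (length(unique(rows$strand)) > 1L)
      stopf("transcript %s has CDS on both strands", tid)
    if (length(unique(rows$seq_id)) > 1L)
      stopf("transcript %s spans multiple sequences", tid)
    o <- order(rows$start)
    if (any(rows$end[o][-nrow(rows)] > rows$start[o][-1L]))
      stopf("transcript %s has overlapping CDS exons", tid)
  }
  df <- df[order_by(df, c("seq_id", "start", "end", "transcript_id")), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

empty_gene_models <- function() {
  gene_models(data.frame(gene_id = character(), transcript_id = character(),
                         seq_id = character(), strand = character(),
                         start = integer(), end = integer(),
                         completeness = character()))
}

#' Per-transcript summary of a gene model table
#'
#' @param models a [gene_models()] table
#' @return data.frame with one row per transcript: ids, location span,
#'   exon count and completeness
#' @export
transcript_spans <- function(models) {
  if (nrow(models) == 0L)
    return(data.frame(transcript_id = character(), gene_id = character(),
                      seq_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_exons = integer(), completeness = character()))
  sp <- do.call(rbind, lapply(split(models, models$transcript_id), function(tr) {
    data.frame(transcript_id = tr$transcript_id[[1L]], gene_id = tr$gene_id[[1L]],
               seq_id = tr$seq_id[[1L]], strand = tr$strand[[1L]],
               start = min(tr$start), end = max(tr$end),
               n_exons = nrow(tr), completeness = tr$completeness[[1L]])
  }))
  sp <- sp[order_by(sp, c("seq_id", "start", "end", "transcript_id")), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

#' Canonical CDS-structure keys
#'
#' One string per transcript encoding sequence, strand and the ordered CDS
#' exon intervals; two transcripts have equal keys iff their CDS structures
#' are coordinate-identical. This is the equality notion used by
#' [compare_gene_sets()], [reliable_subset()] and the duplicate removal in
#' [merge_chunk_predictions()].
#'
#' @param models a [gene_models()] table
#' @return named character vector (names are transcript ids)
#' @export
transcript_keys <- function(models) {
  if (nrow(models) == 0L) return(character())
  vapply(split(models, models$transcript_id), function(tr) {
    tr <- tr[order(tr$start), ]
    paste0(tr$seq_id[[1L]], ":", tr$strand[[1L]], ":",
           paste(tr$start, tr$end, sep = "-", collapse = ","))
  }, character(1L))
}

#' Read gene models from GFF3 or GTF
#'
#' File coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention. For GTF, `stop_codon` features are merged back into
#' the terminal CDS interval so that comparisons are always stop-included.
#' Completeness is inferred from `start_codon`/`stop_codon` features when the
#' transcript has any, else from a `completeness` attribute, else the model
#' is assumed complete.
#'
#' @param path GFF3 or GTF file
#' @param dialect `"gff3"` or `"gtf"`
#' @return a [gene_models()] table
#' @export
read_gene_models <- function(path, dialect = c("gtf", "gff3")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  df <- as.data.frame(gr)
  if (nrow(df) == 0L) return(empty_gene_models())
  if (dialect == "gtf") {
    if (!"transcript_id" %in% names(df)) stopf("GTF lacks transcript_id attributes")
    df$tid <- df$transcript_id
    df$gid <- if ("gene_id" %in% names(df)) df$gene_id else df$transcript_id
  } else {
    par <- vapply(df$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, character(1L))
    df$tid <- par
    # map transcript feature ID -> its gene Parent
    tr_rows <- df$type %in% c("mRNA", "transcript")
    t2g <- stats::setNames(par[tr_rows], df$ID[tr_rows])
    df$gid <- ifelse(is.na(t2g[df$tid]), df$tid, t2g[df$tid])
    comp_attr <- if ("completeness" %in% names(df))
      stats::setNames(df$completeness[tr_rows], df$ID[tr_rows]) else NULL
  }
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(empty_gene_models())
  if (anyNA(cds$tid)) stopf("CDS feature without a transcript identifier")
  out <- data.frame(gene_id = cds$gid, transcript_id = cds$tid,
                    seq_id = as.character(cds$seqnames),
                    strand = as.character(cds$strand),
                    start = cds$start - 1L, end = cds$end,
                    stringsAsFactors = FALSE)
  has_start <- df$type == "start_codon"
  has_stop <- df$type == "stop_codon"
  start_tids <- unique(df$tid[has_start])
  stop_tids <- unique(df$tid[has_stop])
  # merge GTF stop_codon intervals into the terminal CDS exon (stop-included)
  if (dialect == "gtf" && any(has_stop)) {
    for (i in which(has_stop)) {
      tid <- df$tid[[i]]; s0 <- df$start[[i]] - 1L; e0 <- df$end[[i]]
      rows <- which(out$transcript_id == tid)
      adj <- rows[out$end[rows] == s0 | out$start[rows] == e0]
      if (length(adj)) {
        j <- adj[[1L]]
        out$start[[j]] <- min(out$start[[j]], s0)
        out$end[[j]] <- max(out$end[[j]], e0)
      } else {
        out <- rbind(out, data.frame(gene_id = out$gene_id[rows][[1L]], transcript_id = tid,
                                     seq_id = as.character(df$seqnames[[i]]),
                                     strand = as.character(df$strand[[i]]),
                                     start = s0, end = e0))
      }
    }
  }
  comp_for <- function(tid) {
    if (tid %in% start_tids || tid %in% stop_tids) {
      if (tid %in% start_tids && tid %in% stop_tids) "complete"
      else if (tid %in% start_tids) "missing_stop"
      else "missing_start"
    } else if (dialect == "gtf" && "completeness" %in% names(df)) {
      v <- df$completeness[df$tid == tid & df$type == "CDS"]
      v <- v[!is.na(v)]
      if (length(v)) v[[1L]] else "complete"
    } else if (dialect == "gff3" && exists("comp_attr") && !is.null(comp_attr) &&
               !is.na(comp_attr[tid])) {
      unname(comp_attr[tid])
    } else "complete"
  }
  out$completeness <- vapply(out$transcript_id, comp_for, character(1L))
  gene_models(out)
}

gff_escape <- function(x) x  # ids in this package are plain tokens

#' Write gene models to GFF3 or GTF
#'
#' The GTF writer emits the Ensembl-style layout (stop codon excluded from
#' the terminal CDS, separate `start_codon`/`stop_codon` features for
#' complete ends); the GFF3 writer emits gene/mRNA/CDS with the stop codon
#' inside the CDS and a `completeness` attribute. Both round-trip through
#' [read_gene_models()].
#'
#' @param models a [gene_models()] table
#' @param path output file
#' @param dialect `"gtf"` or `"gff3"`
#' @param source source column token
#' @export
write_gene_models <- function(models, path, dialect = c("gtf", "gff3"), source = "prohintr") {
  dialect <- match.arg(dialect)
  lines <- character()
  sp <- transcript_spans(models)
  if (dialect == "gff3") {
    lines <- "##gff-version 3"
    for (g in unique(sp$gene_id)) {
      gsp <- sp[sp$gene_id == g, , drop = FALSE]
      lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                                gsp$seq_id[[1L]], source, min(gsp$start) + 1L, max(gsp$end),
                                gsp$strand[[1L]], g))
      for (i in seq_len(nrow(gsp))) {
        tid <- gsp$transcript_id[[i]]
        lines <- c(lines, sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;completeness=%s",
                                  gsp$seq_id[[i]], source, gsp$start[[i]] + 1L, gsp$end[[i]],
                                  gsp$strand[[i]], tid, g, gsp$completeness[[i]]))
        tr <- models[models$transcript_id == tid, , drop = FALSE]
        lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t.\tID=%s.cds;Parent=%s",
                                  tr$seq_id, source, tr$start + 1L, tr$end, tr$strand, tid, tid))
      }
    }
  } else {
    for (i in seq_len(nrow(sp))) {
      tid <- sp$transcript_id[[i]]
      tr <- models[models$transcript_id == tid, , drop = FALSE]
      tr <- tr[order(tr$start), , drop = FALSE]
      comp <- sp$completeness[[i]]
      strand <- sp$strand[[i]]
      attr9 <- sprintf("gene_id \"%s\"; transcript_id \"%s\";", sp$gene_id[[i]], tid)
      if (comp %in% c("missing_start", "missing_both"))
        attr9 <- paste0(attr9, sprintf(" completeness \"%s\";", comp))
      has_stop <- comp %in% c("complete", "missing_start")
      has_start <- comp %in% c("complete", "missing_stop")
      stop_iv <- NULL
      if (has_stop) {
        if (strand == "+") {
          j <- nrow(tr)
          stop_iv <- c(tr$end[[j]] - 3L, tr$end[[j]])
          tr$end[[j]] <- tr$end[[j]] - 3L
        } else {
          stop_iv <- c(tr$start[[1L]], tr$start[[1L]] + 3L)
          tr$start[[1L]] <- tr$start[[1L]] + 3L
        }
        tr <- tr[tr$end > tr$start, , drop = FALSE]
      }
      lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                tr$seq_id, source, tr$start + 1L, tr$end, tr$strand, attr9))
      if (has_start) {
        si <- if (strand == "+") c(min(tr$start), min(tr$start) + 3L)
              else c(max(tr$end) - 3L, max(tr$end))
        lines <- c(lines, sprintf("%s\t%s\tstart_codon\t%d\t%d\t.\t%s\t0\t%s",
                                  sp$seq_id[[i]], source, si[[1L]] + 1L, si[[2L]], strand, attr9))
      }
      if (has_stop)
        lines <- c(lines, sprintf("%s\t%s\tstop_codon\t%d\t%d\t.\t%s\t0\t%s",
                                  sp$seq_id[[i]], source, stop_iv[[1L]] + 1L, stop_iv[[2L]], strand, attr9))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
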