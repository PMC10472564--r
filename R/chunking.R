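#' Intron size cap from genome size
#'
#' The maximal intron size used when aligning proteins to a genome:
#' `floor(3.6 * sqrt(genome_size))` bp. The square-root scaling keeps the
#' cap generous for large genomes while pruning implausibly long introns in
#' small ones.
#'
#' @param genome_size total genome size in bp (> 0)
#' @return intron cap in bp (integer-valued numeric)
#' @export
max_intron_size <- function(genome_size) {
  if (!is.numeric(genome_size) || length(genome_size) != 1L || is.na(genome_size) ||
      genome_size <= 0)
    stopf("genome_size must be a positive number")
  floor(3.6 * sqrt(genome_size))
}

#' Plan overlapping chunks and batches for parallel prediction
#'
#' Sequences longer than `chunk_size` are tiled into windows of exactly
#' `chunk_size` bp with consecutive windows overlapping by `overlap` bp; the
#' final window is clamped to the sequence end and its start pulled back so
#' it keeps the full chunk size when possible. Sequences not longer than
#' `chunk_size` are greedily packed (in seq_id order) into batches whose
#' total length does not exceed `batch_target`; each batch is one chunk and
#' its member sequences are whole. Responsibility intervals partition every
#' sequence: within a split sequence, each overlap is divided at its
#' midpoint between the two adjacent windows.
#'
#' @param assembly a [genome_assembly()] or a named vector of sequence
#'   lengths
#' @param chunk_size window size in bp (default 5e6)
#' @param overlap overlap between consecutive windows in bp (default 1e6);
#'   a warning is issued when it is below twice [max_intron_size()] of the
#'   genome
#' @param batch_target total bp per batch of small sequences (default 5e6)
#' @return a `chunk_plan`: list with `entries` (data.frame: chunk_id,
#'   seq_id, win_start, win_end, resp_start, resp_end, kind) and the three
#'   parameters
#' @export
plan_chunks <- function(assembly, chunk_size = 5e6, overlap = 1e6, batch_target = 5e6) {
  lens <- if (inherits(assembly, "genome_assembly")) seq_lengths(assembly)
          else { stopifnot(!is.null(names(assembly))); assembly }
  chunk_size <- as.numeric(chunk_size); overlap <- as.numeric(overlap)
  if (overlap < 0 || chunk_size <= 0) stopf("chunk_size must be > 0 and overlap >= 0")
  if (overlap >= chunk_size) stopf("overlap must be smaller than chunk_size")
  cap <- max_intron_size(sum(lens))
  if (overlap < 2 * cap)
    warnf("overlap (%d bp) is below twice the intron cap (2 x %d bp); boundary genes may be truncated",
          as.integer(overlap), as.integer(cap))
  ids <- sort(names(lens), method = "radix")
  entries <- list()
  small <- character()
  for (sid in ids) {
    L <- as.numeric(lens[[sid]])
    if (L <= chunk_size) { small <- c(small, sid); next }
    stride <- chunk_size - overlap
    starts <- seq(0, L, by = stride)
    starts <- starts[starts + chunk_size < L]
    starts <- c(starts, max(0, L - chunk_size))  # clamped final window, pulled back
    wins <- data.frame(win_start = starts, win_end = pmin(starts + chunk_size, L))
    n <- nrow(wins)
    # responsibility boundaries: midpoints of consecutive-window overlaps
    bnd <- if (n > 1L) floor((wins$win_start[-1L] + wins$win_end[-n]) / 2) else numeric()
    resp_start <- c(0, bnd); resp_end <- c(bnd, L)
    for (w in seq_len(n))
      entries[[length(entries) + 1L]] <-
        data.frame(seq_id = sid, win_start = wins$win_start[[w]], win_end = wins$win_end[[w]],
                   resp_start = resp_start[[w]], resp_end = resp_end[[w]], kind = "split")
  }
  # greedy batch packing of small sequences in seq_id order
  batch <- character(); total <- 0
  flush_batch <- function(entries, batch) {
    if (!length(batch)) return(entries)
    entries[[length(entries) + 1L]] <-
      data.frame(seq_id = batch, win_start = 0, win_end = as.numeric(lens[batch]),
                 resp_start = 0, resp_end = as.numeric(lens[batch]), kind = "batch")
    entries
  }
  for (sid in small) {
    L <- as.numeric(lens[[sid]])
    if (length(batch) && total + L > batch_target) {
      entries <- flush_batch(entries, batch); batch <- character(); total <- 0
    }
    batch <- c(batch, sid); total <- total + L
  }
  entries <- flush_batch(entries, batch)
  dfs <- list(); cid <- 0L
  for (e in entries) {
    cid <- cid + 1L
    e$chunk_id <- cid
    dfs[[length(dfs) + 1L]] <- e
  }
  ent <- if (length(dfs)) do.call(rbind, dfs)
         else data.frame(seq_id = character(), win_start = numeric(), win_end = numeric(),
                         resp_start = numeric(), resp_end = numeric(), kind = character(),
                         chunk_id = integer())
  ent <- ent[c("chunk_id", "seq_id", "win_start", "win_end", "resp_start", "resp_end", "kind")]
  rownames(ent) <- NULL
  structure(list(entries = ent, chunk_size = chunk_size, overlap = overlap,
                 batch_target = batch_target, lengths = lens),
            class = "chunk_plan")
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("chunk_plan: %d chunk(s) over %d sequence(s) (chunk %s bp, overlap %s bp)\n",
              length(unique(x$entries$chunk_id)), length(unique(x$entries$seq_id)),
              format(x$chunk_size, big.mark = ","), format(x$overlap, big.mark = ",")))
  invisible(x)
}

#' Serialize / read a chunk plan as TSV
#' @param plan a `chunk_plan`
#' @param path file path
#' @export
write_chunk_plan <- function(plan, path) {
  utils::write.table(plan$entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit per-chunk FASTA files
#'
#' Writes `chunk_<id>.fa` files into `dir`: split chunks hold one window
#' (record named after the source sequence), batch chunks hold their member
#' sequences in full.
#'
#' @param plan a `chunk_plan`
#' @param assembly the [genome_assembly()]
#' @param dir output directory
#' @return character vector of written paths, named by chunk id
#' @export
write_chunk_fasta <- function(plan, assembly, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cid in unique(plan$entries$chunk_id)) {
    e <- plan$entries[plan$entries$chunk_id == cid, , drop = FALSE]
    seqs <- stats::setNames(vapply(seq_len(nrow(e)), function(i)
      subseq_window(assembly, e$seq_id[[i]], e$win_start[[i]], e$win_end[[i]]),
      character(1L)), e$seq_id)
    p <- file.path(dir, sprintf("chunk_%d.fa", cid))
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), p)
    paths[[as.character(cid)]] <- p
  }
  paths
}

chunk_entries <- function(plan, chunk_id) {
  e <- plan$entries[plan$entries$chunk_id == chunk_id, , drop = FALSE]
  if (!nrow(e)) stopf("unknown chunk_id %s", chunk_id)
  e
}

#' Chunk-local sequences and hints for one chunk
#'
#' Returns the window sequences of a chunk and the hints that fall entirely
#' inside its windows, shifted to window-local coordinates.
#'
#' @param plan a `chunk_plan`
#' @param chunk_id chunk id
#' @param assembly the [genome_assembly()]
#' @param h a [hints()] table in genome coordinates (optional)
#' @return list with `sequences` (named character) and `hints`
#' @export
chunk_input <- function(plan, chunk_id, assembly, h = NULL) {
  e <- chunk_entries(plan, chunk_id)
  seqs <- stats::setNames(vapply(seq_len(nrow(e)), function(i)
    subseq_window(assembly, e$seq_id[[i]], e$win_start[[i]], e$win_end[[i]]),
    character(1L)), e$seq_id)
  lh <- NULL
  if (!is.null(h)) {
    rows <- list()
    for (i in seq_len(nrow(e))) {
      hi <- h[h$seq_id == e$seq_id[[i]] & h$start >= e$win_start[[i]] &
                h$end <= e$win_end[[i]], , drop = FALSE]
      if (nrow(hi)) {
        hi$start <- hi$start - as.integer(e$win_start[[i]])
        hi$end <- hi$end - as.integer(e$win_start[[i]])
        rows[[length(rows) + 1L]] <- hi
      }
    }
    lh <- if (length(rows)) hints(do.call(rbind, rows)) else empty_hints()
  }
  list(sequences = seqs, hints = lh)
}

#' Remap chunk-local predictions to genome coordinates
#'
#' @param chunk_id the emitting chunk
#' @param models a [gene_models()] table in chunk-local coordinates (for a
#'   split chunk, coordinates relative to the window start; for a batch
#'   chunk, coordinates on the member sequences)
#' @param plan the `chunk_plan`
#' @return the models shifted to genome coordinates
#' @export
remap_predictions <- function(chunk_id, models, plan) {
  e <- chunk_entries(plan, chunk_id)
  if (nrow(models) == 0L) return(models)
  out <- models
  for (i in seq_len(nrow(models))) {
    row <- e[e$seq_id == models$seq_id[[i]], , drop = FALSE]
    if (!nrow(row)) stopf("chunk %s: prediction on sequence %s not in this chunk",
                          chunk_id, models$seq_id[[i]])
    wlen <- row$win_end[[1L]] - row$win_start[[1L]]
    if (models$start[[i]] < 0L || models$end[[i]] > wlen)
      stopf("chunk %s: prediction exceeds window bounds on %s", chunk_id, models$seq_id[[i]])
    out$start[[i]] <- models$start[[i]] + as.integer(row$win_start[[1L]])
    out$end[[i]] <- models$end[[i]] + as.integer(row$win_start[[1L]])
  }
  gene_models(out)
}

#' Merge per-chunk predictions with duplicate removal
#'
#' Deterministic resolution of the redundancy introduced by overlapping
#' windows: a transcript is kept from the chunk whose responsibility
#' interval contains its midpoint, provided that chunk's window fully
#' contains it; otherwise from the lowest-indexed emitting chunk that fully
#' contains it; transcripts fully contained in no window are kept once
#' (lowest emitting chunk) and flagged truncated. Exact-duplicate
#' structures collapse to one. Gene and transcript ids are renumbered in
#' genomic order (`g1`, `g1.t1`, ...).
#'
#' @param per_chunk named list: chunk id -> [gene_models()] in genome
#'   coordinates (from [remap_predictions()])
#' @param plan the `chunk_plan`
#' @return a [gene_models()] table with an extra logical `truncated` column
#' @export
merge_chunk_predictions <- function(per_chunk, plan) {
  recs <- list()
  for (cid in names(per_chunk)) {
    m <- per_chunk[[cid]]
    if (is.null(m) || nrow(m) == 0L) next
    keys <- transcript_keys(m)
    for (tid in unique(m$transcript_id)) {
      recs[[length(recs) + 1L]] <-
        list(chunk = as.integer(cid), key = keys[[tid]],
             rows = m[m$transcript_id == tid, , drop = FALSE])
    }
  }
  if (!length(recs)) {
    out <- empty_gene_models(); out$truncated <- logical(); return(out)
  }
  e <- plan$entries
  kept <- list()
  ki <- 0L
  for (key in unique(vapply(recs, `[[`, character(1L), "key"))) {
    cand <- recs[vapply(recs, function(r) r$key == key, logical(1L))]
    rows <- cand[[1L]]$rows
    sid <- rows$seq_id[[1L]]
    span <- c(min(rows$start), max(rows$end))
    mid <- floor((span[[1L]] + span[[2L]]) / 2)
    emitters <- sort(vapply(cand, `[[`, integer(1L), "chunk"))
    contains <- function(cid) {
      w <- e[e$chunk_id == cid & e$seq_id == sid, , drop = FALSE]
      nrow(w) > 0L && span[[1L]] >= w$win_start[[1L]] && span[[2L]] <= w$win_end[[1L]]
    }
    owns <- function(cid) {
      w <- e[e$chunk_id == cid & e$seq_id == sid, , drop = FALSE]
      nrow(w) > 0L && mid >= w$resp_start[[1L]] && mid < w$resp_end[[1L]]
    }
    owner <- emitters[vapply(emitters, function(c) owns(c) && contains(c), logical(1L))]
    full <- emitters[vapply(emitters, contains, logical(1L))]
    pick <- if (length(owner)) owner[[1L]]
            else if (length(full)) full[[1L]]
            else emitters[[1L]]
    truncated <- !length(owner) && !length(full)
    rows <- cand[[which(vapply(cand, `[[`, integer(1L), "chunk") == pick)[[1L]]]]$rows
    # chunk-local ids can collide across chunks; use interim unique ids
    ki <- ki + 1L
    rows$gene_id <- sprintf("k%d", ki)
    rows$transcript_id <- sprintf("k%d.t1", ki)
    rows$truncated <- truncated
    kept[[length(kept) + 1L]] <- rows
  }
  out <- do.call(rbind, kept)
  # renumber deterministically in genomic order
  sp <- transcript_spans(gene_models(out[setdiff(names(out), "truncated")]))
  newg <- stats::setNames(sprintf("g%d", seq_len(nrow(sp))), sp$transcript_id)
  newt <- stats::setNames(sprintf("g%d.t1", seq_len(nrow(sp))), sp$transcript_id)
  out$gene_id <- unname(newg[out$transcript_id])
  trunc <- out$truncated
  out$transcript_id <- unname(newt[out$transcript_id])
  res <- gene_models(out[setdiff(names(out), "truncated")])
  tr_map <- stats::setNames(trunc, out$transcript_id)[res$transcript_id]
  res$truncated <- unname(tr_map)
  res
}
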