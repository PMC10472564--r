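#' Spliced protein-to-genome alignment chains
#'
#' An `alignment_chain` describes one protein's spliced alignment to one
#' genomic locus: ordered CDS blocks, per-block residue-alignment column
#' classes, frameshift / in-frame-stop events, and an alignment score.
#' Consecutive blocks define exactly one candidate intron each.
#'
#' Column classes are single characters per aligned residue column:
#' `M` identical, `S` positive (conservative) substitution, `X` mismatch.
#' Block class strings are stored in genomic order.
#'
#' @param protein_id,seq_id,strand identifiers and strand (`+`/`-`)
#' @param blocks data.frame with integer `start`,`end` (0-based half-open,
#'   sorted, non-overlapping) and optionally a character `classes` column
#'   (one class letter per residue column of the block)
#' @param score alignment score
#' @param events data.frame with `type` (`frameshift` or `stop`) and integer
#'   genomic `pos`; may be empty
#' @param covers_start,covers_stop does the alignment reach the protein's
#'   first residue / last residue (so that start/stop hints can be derived)?
#' @return object of class `alignment_chain`
#' @export
alignment_chain <- function(protein_id, seq_id, strand, blocks, score = 0,
                            events = NULL, covers_start = FALSE, covers_stop = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  blocks <- as.data.frame(blocks)
  blocks$start <- as.integer(blocks$start); blocks$end <- as.integer(blocks$end)
  o <- order(blocks$start)
  if (!identical(o, seq_len(nrow(blocks)))) stopf("chain %s: blocks out of order", protein_id)
  if (nrow(blocks) > 1L && any(blocks$end[-nrow(blocks)] > blocks$start[-1L]))
    stopf("chain %s: overlapping blocks", protein_id)
  has_detail <- "classes" %in% names(blocks) && !anyNA(blocks$classes)
  if (has_detail) {
    bad <- grepl("[^MSX]", blocks$classes)
    if (any(bad)) stopf("chain %s: unknown column class in block %d", protein_id, which(bad)[[1L]])
  } else blocks$classes <- NA_character_
  if (is.null(events))
    events <- data.frame(type = character(), pos = integer())
  events <- as.data.frame(events)
  if (nrow(events) && !all(events$type %in% c("frameshift", "stop")))
    stopf("chain %s: unknown event type", protein_id)
  ncol_tot <- if (has_detail) sum(nchar(blocks$classes)) else NA_integer_
  ident <- if (has_detail && ncol_tot > 0L)
    sum(vapply(strsplit(blocks$classes, ""), function(ch) sum(ch == "M"), integer(1L))) / ncol_tot
  else NA_real_
  structure(list(protein_id = protein_id, seq_id = seq_id, strand = strand,
                 blocks = blocks, score = score, identity = ident,
                 events = events, covers_start = isTRUE(covers_start),
                 covers_stop = isTRUE(covers_stop), has_detail = has_detail),
            class = "alignment_chain")
}

#' @export
print.alignment_chain <- function(x, ...) {
  cat(sprintf("alignment_chain %s on %s(%s): %d block(s), score %.1f%s\n",
              x$protein_id, x$seq_id, x$strand, nrow(x$blocks), x$score,
              if (x$has_detail) sprintf(", identity %.3f", x$identity) else ", no residue detail"))
  invisible(x)
}

# candidate introns of one chain: gaps between consecutive blocks
chain_introns <- function(chain) {
  b <- chain$blocks
  n <- nrow(b)
  if (n < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = b$end[-n], end = b$start[-1L])
}

# junction descriptors for scoring: per internal boundary, the column classes
# adjacent to the intron on both sides (index 1 = adjacent column), plus the
# number of frameshift/stop events within `window` residue columns (3*window
# bp inside the two flanking blocks)
chain_junctions <- function(chain, window = 15L) {
  b <- chain$blocks
  n <- nrow(b)
  if (n < 2L) return(list())
  class_name <- c(M = "identical", S = "substitution", X = "mismatch")
  lapply(seq_len(n - 1L), function(i) {
    if (!chain$has_detail) return(list(available = FALSE))
    left_ch <- rev(strsplit(b$classes[[i]], "")[[1L]])
    right_ch <- strsplit(b$classes[[i + 1L]], "")[[1L]]
    istart <- b$end[[i]]; iend <- b$start[[i + 1L]]
    w_bp <- 3L * window
    ev <- chain$events
    n_ev <- if (nrow(ev)) {
      sum((ev$pos >= max(b$start[[i]], istart - w_bp) & ev$pos < istart) |
          (ev$pos >= iend & ev$pos < min(b$end[[i + 1L]], iend + w_bp)))
    } else 0L
    list(available = TRUE,
         left = unname(class_name[left_ch]),
         right = unname(class_name[right_ch]),
         n_events = n_ev)
  })
}

rle_encode_classes <- function(classes) {
  r <- rle(strsplit(classes, "")[[1L]])
  paste0(r$values, r$lengths, collapse = "")
}

rle_decode_classes <- function(token) {
  m <- gregexpr("([MSX])([0-9]+)", token)[[1L]]
  if (m[[1L]] == -1L || sum(attr(m, "match.length")) != nchar(token))
    stopf("malformed class run-length string: %s", token)
  parts <- regmatches(token, gregexpr("([MSX])([0-9]+)", token))[[1L]]
  paste0(unlist(lapply(parts, function(p) {
    strrep(substr(p, 1L, 1L), as.integer(substr(p, 2L, nchar(p))))
  })), collapse = "")
}

#' Write alignment chains in the compact dialect
#'
#' The compact dialect is this package's residue-level alignment exchange
#' format (one `C` header line per chain, one `B` line per block). Unlike
#' the GFF formats it uses 0-based half-open coordinates. Block residue
#' columns are run-length encoded over classes `M` (identical), `S`
#' (positive substitution) and `X` (mismatch); frameshift and in-frame-stop
#' events are appended as `F@pos` / `*@pos` tokens at genomic positions.
#'
#' @param chains list of [alignment_chain()]
#' @param path output file
#' @export
write_alignments_compact <- function(chains, path) {
  lines <- "## prohintr-compact 1"
  for (ch in chains) {
    flags <- c(if (ch$covers_start) "covers_start", if (ch$covers_stop) "covers_stop")
    lines <- c(lines, sprintf("C\t%s\t%s\t%s\t%s\t%s", ch$protein_id, ch$seq_id, ch$strand,
                              format(ch$score, trim = TRUE, scientific = FALSE),
                              if (length(flags)) paste(flags, collapse = ",") else "."))
    for (i in seq_len(nrow(ch$blocks))) {
      b <- ch$blocks[i, ]
      ev <- ch$events
      ev <- ev[ev$pos >= b$start & ev$pos < b$end, , drop = FALSE]
      ev_tok <- if (nrow(ev))
        paste(sprintf("%s@%d", ifelse(ev$type == "frameshift", "F", "*"), ev$pos), collapse = ",")
      else "."
      cls <- if (ch$has_detail) rle_encode_classes(b$classes) else "."
      lines <- c(lines, sprintf("B\t%d\t%d\t%s\t%s", b$start, b$end, cls, ev_tok))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

parse_compact <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  chains <- list()
  cur <- NULL
  flush <- function(cur, chains) {
    if (is.null(cur)) return(chains)
    blocks <- do.call(rbind, cur$blocks)
    events <- if (length(cur$events)) do.call(rbind, cur$events)
              else data.frame(type = character(), pos = integer())
    ch <- tryCatch(
      alignment_chain(cur$protein_id, cur$seq_id, cur$strand,
                      blocks, cur$score, events,
                      cur$covers_start, cur$covers_stop),
      error = function(e) { warnf("rejecting chain %s: %s", cur$protein_id, conditionMessage(e)); NULL })
    if (!is.null(ch)) chains[[length(chains) + 1L]] <- ch
    chains
  }
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (f[[1L]] == "C") {
      chains <- flush(cur, chains)
      flags <- if (f[[6L]] == ".") character() else strsplit(f[[6L]], ",")[[1L]]
      cur <- list(protein_id = f[[2L]], seq_id = f[[3L]], strand = f[[4L]],
                  score = as.numeric(f[[5L]]),
                  covers_start = "covers_start" %in% flags,
                  covers_stop = "covers_stop" %in% flags,
                  blocks = list(), events = list())
    } else if (f[[1L]] == "B") {
      if (is.null(cur)) stopf("compact dialect: B line before any C line")
      cls <- if (f[[4L]] == ".") NA_character_ else rle_decode_classes(f[[4L]])
      cur$blocks[[length(cur$blocks) + 1L]] <-
        data.frame(start = as.integer(f[[2L]]), end = as.integer(f[[3L]]), classes = cls)
      if (f[[5L]] != ".") {
        for (tok in strsplit(f[[5L]], ",")[[1L]]) {
          type <- if (startsWith(tok, "F@")) "frameshift"
                  else if (startsWith(tok, "*@")) "stop"
                  else stopf("compact dialect: bad event token %s", tok)
          cur$events[[length(cur$events) + 1L]] <-
            data.frame(type = type, pos = as.integer(sub("^..", "", tok)))
        }
      }
    } else stopf("compact dialect: unexpected line type %s", f[[1L]])
  }
  flush(cur, chains)
}

parse_miniprot_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  chains <- list()
  for (i in seq_len(nrow(mrna))) {
    id <- mrna$ID[[i]]
    par <- vapply(cds$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, character(1L))
    b <- cds[!is.na(par) & par == id, , drop = FALSE]
    if (nrow(b) == 0L) next
    b <- b[order(b$start), , drop = FALSE]
    tgt <- if ("Target" %in% names(mrna)) mrna$Target[[i]] else NA_character_
    prot <- if (!is.na(tgt)) strsplit(tgt, " ")[[1L]][[1L]] else id
    covers_start <- !is.na(tgt) && length(strsplit(tgt, " ")[[1L]]) >= 2L &&
      strsplit(tgt, " ")[[1L]][[2L]] == "1"
    blocks <- data.frame(start = b$start - 1L, end = b$end, classes = NA_character_)
    ch <- tryCatch(
      alignment_chain(prot, as.character(mrna$seqnames[[i]]), as.character(mrna$strand[[i]]),
                      blocks, score = if (is.na(mrna$score[[i]])) 0 else mrna$score[[i]],
                      covers_start = covers_start, covers_stop = FALSE),
      error = function(e) { warnf("rejecting chain %s: %s", prot, conditionMessage(e)); NULL })
    if (!is.null(ch)) chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Parse spliced alignments
#'
#' Reads either miniprot-style `--gff` output (`dialect = "miniprot_gff"`;
#' chains from it carry no residue detail, so their junction descriptors are
#' marked unavailable and they contribute to intron mapping coverage only)
#' or the package's compact residue-level dialect (`dialect = "compact"`,
#' see [write_alignments_compact()]). Chains whose blocks are out of order
#' are rejected with a warning and parsing continues.
#'
#' @param path alignment file
#' @param dialect `"compact"` or `"miniprot_gff"`
#' @return list of [alignment_chain()]
#' @export
parse_alignments <- function(path, dialect = c("compact", "miniprot_gff")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (dialect == "compact") parse_compact(path) else parse_miniprot_gff(path)
}

#' Write alignment chains as miniprot-style GFF
#'
#' Emits mRNA + CDS features with `Target` attributes, 1-based inclusive.
#' Residue detail is not representable in this dialect.
#'
#' @param chains list of [alignment_chain()]
#' @param path output file
#' @export
write_alignments_gff <- function(chains, path) {
  lines <- "##gff-version 3"
  k <- 0L
  for (ch in chains) {
    k <- k + 1L
    id <- sprintf("MP%06d", k)
    span <- c(min(ch$blocks$start), max(ch$blocks$end))
    ncol_tot <- sum(ch$blocks$end - ch$blocks$start) %/% 3L
    lines <- c(lines, sprintf("%s\tminiprot\tmRNA\t%d\t%d\t%s\t%s\t.\tID=%s;Target=%s 1 %d;Identity=%s",
                              ch$seq_id, span[[1L]] + 1L, span[[2L]],
                              format(ch$score, trim = TRUE, scientific = FALSE),
                              ch$strand, id, ch$protein_id, ncol_tot,
                              if (is.na(ch$identity)) "." else sprintf("%.4f", ch$identity)))
    lines <- c(lines, sprintf("%s\tminiprot\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s;Target=%s",
                              ch$seq_id, ch$blocks$start + 1L, ch$blocks$end,
                              ch$strand, id, ch$protein_id))
  }
  writeLines(lines, path)
  invisible(path)
}
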