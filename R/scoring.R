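#' Scoring configuration for intron evidence
#'
#' Parameters of the intron border alignment (IBA) score, the penalty model
#' and the two-tier classification thresholds.
#'
#' IBA looks at up to `window` aligned residue columns on each side of a
#' candidate intron. Column k (k = 1 adjacent to the junction) carries
#' weight `decay^(k-1)`; identical columns credit 1, positive substitutions
#' `substitution_credit`, mismatches 0. The two side scores (weighted means)
#' are averaged and the result is multiplied by `event_penalty` once per
#' frameshift or in-frame-stop event inside the window, then clamped to
#' [0, 1]. Evidence is kept when IBA >= `iba_min_keep` OR the intron mapping
#' coverage (IMC) >= `imc_min_keep`, and classified high-confidence when
#' IBA >= `iba_min_high` OR IMC >= `imc_min_high`.
#'
#' @param window columns considered per side (default 15)
#' @param decay geometric weight decay per column, in (0, 1] (default 0.8)
#' @param substitution_credit credit of a positive substitution (default 0.5)
#' @param event_penalty multiplicative penalty per frameshift / in-frame
#'   stop within the window (default 0.5)
#' @param iba_min_keep,imc_min_keep discard thresholds (keep if either holds)
#' @param iba_min_high,imc_min_high high-confidence thresholds (high if
#'   either holds)
#' @param cdspart_shrink bp trimmed from each side of an alignment block
#'   when emitting CDSpart hints (default 9)
#' @return a list of class `scoring_config`
#' @export
scoring_config <- function(window = 15L, decay = 0.8, substitution_credit = 0.5,
                           event_penalty = 0.5, iba_min_keep = 0.1, imc_min_keep = 2L,
                           iba_min_high = 0.25, imc_min_high = 2L, cdspart_shrink = 9L) {
  stopifnot(is_count(window), window >= 1,
            decay > 0, decay <= 1,
            substitution_credit >= 0, substitution_credit <= 1,
            event_penalty > 0, event_penalty <= 1,
            iba_min_keep >= 0, iba_min_keep <= 1,
            iba_min_high >= 0, iba_min_high <= 1,
            is_count(imc_min_keep), imc_min_keep >= 1,
            is_count(imc_min_high), imc_min_high >= 1)
  if (iba_min_high < iba_min_keep) stopf("iba_min_high must be >= iba_min_keep")
  structure(list(window = as.integer(window), decay = decay,
                 substitution_credit = substitution_credit,
                 event_penalty = event_penalty,
                 iba_min_keep = iba_min_keep, imc_min_keep = as.integer(imc_min_keep),
                 iba_min_high = iba_min_high, imc_min_high = as.integer(imc_min_high),
                 cdspart_shrink = as.integer(cdspart_shrink)),
            class = "scoring_config")
}

#' Intron border alignment (IBA) score of one junction
#'
#' Measures the conservation of the aligned exonic columns flanking a
#' candidate intron, weighted toward the splice junction; see
#' [scoring_config()] for the formula. A side with zero aligned columns
#' scores 0.
#'
#' @param junction list with `left` and `right` character vectors of column
#'   classes (`identical` / `substitution` / `mismatch`), ordered with the
#'   junction-adjacent column first, and optionally `n_events` (frameshift
#'   plus in-frame-stop events within the window, default 0)
#' @param cfg a [scoring_config()]
#' @return IBA score in [0, 1]
#' @export
score_iba <- function(junction, cfg = scoring_config()) {
  credit <- c(identical = 1, substitution = cfg$substitution_credit, mismatch = 0)
  side_score <- function(classes) {
    if (length(classes) == 0L) return(0)
    bad <- setdiff(classes, names(credit))
    if (length(bad)) stopf("unknown column class: %s", bad[[1L]])
    k <- seq_len(min(length(classes), cfg$window))
    w <- cfg$decay^(k - 1L)
    sum(w * credit[classes[k]]) / sum(w)
  }
  iba <- mean(c(side_score(junction$left), side_score(junction$right)))
  n_ev <- junction$n_events %||% 0L
  iba <- iba * cfg$event_penalty^n_ev
  clamp(iba, 0, 1)
}

#' Intron mapping coverage (IMC)
#'
#' Counts, per distinct intron (same sequence, strand and interval), how
#' many distinct donor proteins map that exact intron in their spliced
#' alignments. A protein aligned twice to the same locus counts once.
#'
#' @param chains list of [alignment_chain()]
#' @return data.frame with `seq_id`, `strand`, `start`, `end`, `imc` and a
#'   `proteins` list-column of supporting protein ids, sorted by position
#' @export
compute_imc <- function(chains) {
  rows <- list()
  for (ch in chains) {
    iv <- chain_introns(ch)
    if (!nrow(iv)) next
    rows[[length(rows) + 1L]] <-
      data.frame(seq_id = ch$seq_id, strand = ch$strand,
                 start = iv$start, end = iv$end, protein = ch$protein_id)
  }
  if (!length(rows))
    return(data.frame(seq_id = character(), strand = character(), start = integer(),
                      end = integer(), imc = integer(), proteins = I(list())))
  all <- do.call(rbind, rows)
  key <- paste(all$seq_id, all$strand, all$start, all$end, sep = "\r")
  sp <- split(all$protein, key)
  parts <- strsplit(names(sp), "\r", fixed = TRUE)
  out <- data.frame(seq_id = vapply(parts, `[[`, character(1L), 1L),
                    strand = vapply(parts, `[[`, character(1L), 2L),
                    start = as.integer(vapply(parts, `[[`, character(1L), 3L)),
                    end = as.integer(vapply(parts, `[[`, character(1L), 4L)))
  prots <- lapply(sp, function(p) sort(unique(p)))
  out$imc <- vapply(prots, length, integer(1L))
  out$proteins <- I(unname(prots))
  out <- out[order_by(out, c("seq_id", "start", "end", "strand")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score, filter and classify intron evidence; derive hints
#'
#' The evidence-classification stage: every distinct candidate intron gets
#' an IBA score (maximum over its supporting junctions; chains without
#' residue detail contribute to IMC only) and an IMC count, unreliable
#' evidence is discarded, and the remainder is split into high- and
#' low-confidence classes (thresholds in [scoring_config()]). Hints are
#' derived for the kept introns (`mult` = IMC, high-confidence introns get
#' source tag `M`), plus low-confidence CDSpart hints (one per distinct
#' alignment block, shrunk by `cdspart_shrink` bp per side with a 1 bp
#' floor) and start/stop hints where a chain covers the protein's terminal
#' codons.
#'
#' @param chains list of [alignment_chain()]
#' @param cfg a [scoring_config()]
#' @return list with `evidence` (data.frame: seq_id, strand, start, end,
#'   iba, imc, n_frameshift_near, n_stop_near, confidence, proteins) and
#'   `hints` (a [hints()] table)
#' @export
classify_evidence <- function(chains, cfg = scoring_config()) {
  imc <- compute_imc(chains)
  key_of <- function(seq_id, strand, start, end) paste(seq_id, strand, start, end, sep = "\r")
  iba_best <- new.env(parent = emptyenv())
  ev_near <- new.env(parent = emptyenv())
  for (ch in chains) {
    iv <- chain_introns(ch)
    if (!nrow(iv)) next
    jx <- chain_junctions(ch, cfg$window)
    for (i in seq_len(nrow(iv))) {
      k <- key_of(ch$seq_id, ch$strand, iv$start[[i]], iv$end[[i]])
      j <- jx[[i]]
      if (isTRUE(j$available)) {
        s <- score_iba(j, cfg)
        if (is.null(iba_best[[k]]) || s > iba_best[[k]]) iba_best[[k]] <- s
        # track frameshift/stop events near the junction (max over junctions)
        w_bp <- 3L * cfg$window
        e <- ch$events
        nf <- ns <- 0L
        if (nrow(e)) {
          near <- (e$pos >= iv$start[[i]] - w_bp & e$pos < iv$start[[i]]) |
                  (e$pos >= iv$end[[i]] & e$pos < iv$end[[i]] + w_bp)
          nf <- sum(near & e$type == "frameshift"); ns <- sum(near & e$type == "stop")
        }
        prev <- ev_near[[k]] %||% c(0L, 0L)
        ev_near[[k]] <- pmax(prev, c(nf, ns))
      }
    }
  }
  ev <- imc
  if (nrow(ev)) {
    keys <- key_of(ev$seq_id, ev$strand, ev$start, ev$end)
    ev$iba <- vapply(keys, function(k) iba_best[[k]] %||% 0, numeric(1L))
    near <- lapply(keys, function(k) ev_near[[k]] %||% c(0L, 0L))
    ev$n_frameshift_near <- vapply(near, `[[`, integer(1L), 1L)
    ev$n_stop_near <- vapply(near, `[[`, integer(1L), 2L)
    keep <- ev$iba >= cfg$iba_min_keep | ev$imc >= cfg$imc_min_keep
    high <- ev$iba >= cfg$iba_min_high | ev$imc >= cfg$imc_min_high
    ev$confidence <- ifelse(!keep, "discarded", ifelse(high, "high", "low"))
    ev <- ev[c("seq_id", "strand", "start", "end", "iba", "imc",
               "n_frameshift_near", "n_stop_near", "confidence", "proteins")]
  } else {
    ev <- data.frame(seq_id = character(), strand = character(), start = integer(),
                     end = integer(), iba = numeric(), imc = integer(),
                     n_frameshift_near = integer(), n_stop_near = integer(),
                     confidence = character(), proteins = I(list()))
  }
  # intron hints for kept evidence
  kept <- ev[nrow(ev) > 0 & ev$confidence != "discarded", , drop = FALSE]
  hint_rows <- list()
  if (nrow(kept))
    hint_rows[[1L]] <- data.frame(seq_id = kept$seq_id, feature = "intron",
                                  start = kept$start, end = kept$end,
                                  strand = kept$strand, score = round(kept$iba, 2),
                                  mult = kept$imc,
                                  confidence = ifelse(kept$confidence == "high", "high", "low"))
  # CDSpart hints: one per distinct alignment block, shrunk, floor 1 bp
  blocks <- list(); terms <- list()
  for (ch in chains) {
    b <- ch$blocks
    s <- pmin(b$start + cfg$cdspart_shrink, b$end - 1L)
    e <- pmax(b$end - cfg$cdspart_shrink, s + 1L)
    sc <- if (is.na(ch$identity)) 0.5 else round(ch$identity, 2)
    blocks[[length(blocks) + 1L]] <-
      data.frame(seq_id = ch$seq_id, feature = "CDSpart", start = s, end = e,
                 strand = ch$strand, score = sc, mult = 1L, confidence = "low")
    span <- c(min(b$start), max(b$end))
    if (ch$covers_start) {
      si <- if (ch$strand == "+") c(span[[1L]], span[[1L]] + 3L) else c(span[[2L]] - 3L, span[[2L]])
      terms[[length(terms) + 1L]] <-
        data.frame(seq_id = ch$seq_id, feature = "start", start = si[[1L]], end = si[[2L]],
                   strand = ch$strand, score = sc, mult = 1L, confidence = "low")
    }
    if (ch$covers_stop) {
      si <- if (ch$strand == "+") c(span[[2L]], span[[2L]] + 3L) else c(span[[1L]] - 3L, span[[1L]])
      terms[[length(terms) + 1L]] <-
        data.frame(seq_id = ch$seq_id, feature = "stop", start = si[[1L]], end = si[[2L]],
                   strand = ch$strand, score = sc, mult = 1L, confidence = "low")
    }
  }
  extra <- do.call(rbind, c(blocks, terms))
  if (!is.null(extra) && nrow(extra)) {
    k <- paste(extra$seq_id, extra$feature, extra$start, extra$end, extra$strand, sep = "\r")
    extra <- extra[order(k, -extra$score), , drop = FALSE]
    extra <- extra[!duplicated(paste(extra$seq_id, extra$feature, extra$start,
                                     extra$end, extra$strand, sep = "\r")), , drop = FALSE]
    hint_rows[[length(hint_rows) + 1L]] <- extra
  }
  h <- if (length(hint_rows)) hints(do.call(rbind, hint_rows)) else empty_hints()
  list(evidence = ev, hints = h)
}

#' Write the evidence score table
#'
#' @param evidence the `evidence` component of [classify_evidence()]
#' @param path output TSV
#' @export
write_scores_tsv <- function(evidence, path) {
  out <- evidence
  out$proteins <- vapply(out$proteins, paste, character(1L), collapse = ",")
  out$iba <- sprintf("%.4f", out$iba)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
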