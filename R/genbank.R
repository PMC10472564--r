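#' Write training genes as GenBank flat-file records
#'
#' Each training gene is excised from the assembly with its flanking window
#' and written as one GenBank-style record of the kind gene-finder training
#' tools consume: a LOCUS line with the excised length, a `CDS join(...)`
#' feature in window-local 1-based coordinates (`complement(join(...))` on
#' the minus strand) and an ORIGIN sequence block. Windows reaching outside
#' the sequence are clamped to its bounds with a message.
#'
#' @param training a `training_gene_set` (see [select_training_genes()])
#' @param assembly the [genome_assembly()] the genes live on
#' @param path output file
#' @export
write_training_genbank <- function(training, assembly, path) {
  stopifnot(inherits(training, "training_gene_set"), inherits(assembly, "genome_assembly"))
  lens <- seq_lengths(assembly)
  con <- file(path, "w")
  on.exit(close(con))
  info <- training$info
  for (i in seq_len(nrow(info))) {
    tid <- info$transcript_id[[i]]
    tr <- training$models[training$models$transcript_id == tid, , drop = FALSE]
    sid <- tr$seq_id[[1L]]
    w0 <- info$window_start[[i]]; w1 <- info$window_end[[i]]
    if (w0 < 0L || w1 > lens[[sid]]) {
      w0c <- max(w0, 0L); w1c <- min(w1, lens[[sid]])
      message(sprintf("training window of %s clamped from [%d,%d) to [%d,%d) on %s",
                      tid, w0, w1, w0c, w1c, sid))
      w0 <- w0c; w1 <- w1c
    }
    seq <- subseq_window(assembly, sid, w0, w1)
    loc_start <- tr$start - w0 + 1L
    loc_end <- tr$end - w0
    join <- paste(sprintf("%d..%d", loc_start, loc_end), collapse = ",")
    loc <- if (nrow(tr) > 1L) sprintf("join(%s)", join) else join
    if (tr$strand[[1L]] == "-") loc <- sprintf("complement(%s)", loc)
    name <- sprintf("%s_%s_%d_%d", tid, sid, w0, w1)
    writeLines(sprintf("LOCUS       %s %d bp  DNA     linear   UNK", name, w1 - w0), con)
    writeLines(sprintf("DEFINITION  training gene %s excised from %s:%d-%d (%s).",
                       tid, sid, w0, w1, tr$strand[[1L]]), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", w1 - w0), con)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", tr$gene_id[[1L]]), con)
    writeLines("ORIGIN", con)
    s <- tolower(seq)
    pos <- seq(1L, nchar(s), by = 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      grp <- substring(chunk, seq(1L, nchar(chunk), 10L),
                       pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(grp, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Read GenBank training records written by this package
#'
#' Minimal flat-file reader for the records emitted by
#' [write_training_genbank()] (no general GenBank support is attempted).
#'
#' @param path GenBank flat file
#' @return list of records, each a list with `name`, `gene_id`, `strand`,
#'   `length`, `cds` (data.frame of 0-based half-open window-local
#'   intervals) and `seq` (uppercase window sequence)
#' @export
read_training_genbank <- function(path) {
  lines <- readLines(path)
  recs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[[i]], "LOCUS")) { i <- i + 1L; next }
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    name <- f[[2L]]; len <- as.integer(f[[3L]])
    strand <- "+"; cds <- NULL; gene <- NA_character_; seq <- character()
    i <- i + 1L
    while (i <= length(lines) && lines[[i]] != "//") {
      ln <- lines[[i]]
      if (grepl("^\\s+CDS\\s", ln)) {
        loc <- trimws(sub("^\\s+CDS\\s+", "", ln))
        if (startsWith(loc, "complement(")) {
          strand <- "-"
          loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        loc <- sub("^join\\((.*)\\)$", "\\1", loc)
        iv <- do.call(rbind, lapply(strsplit(loc, ",")[[1L]], function(p) {
          se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
          data.frame(start = se[[1L]] - 1L, end = se[[2L]])
        }))
        cds <- iv
      } else if (grepl("^\\s+/gene=", ln)) {
        gene <- sub("^\\s+/gene=\"(.*)\"$", "\\1", ln)
      } else if (grepl("^\\s*[0-9]+ [acgtn ]+$", ln)) {
        seq <- c(seq, gsub("[ 0-9]", "", ln))
      }
      i <- i + 1L
    }
    recs[[length(recs) + 1L]] <-
      list(name = name, gene_id = gene, strand = strand, length = len,
           cds = cds, seq = toupper(paste(seq, collapse = "")))
    i <- i + 1L
  }
  recs
}
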