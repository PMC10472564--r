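#' Extrinsic-evidence hints
#'
#' Hints are the features handed to the gene predictor: `intron`, `start`,
#' `stop` and `CDSpart` intervals with a score, a multiplicity (`mult`, the
#' number of distinct supporting proteins for introns, 1 otherwise) and a
#' two-tier confidence. High-confidence hints carry source tag `M`
#' (enforced evidence), low-confidence hints carry `P`; the two encodings
#' are equivalent by construction.
#'
#' @param df data.frame with columns `seq_id`, `feature`, `start`, `end`
#'   (0-based half-open), `strand`, `score`, `mult`, `confidence`
#' @return validated data.frame of class `hints`
#' @export
hints <- function(df) {
  req <- c("seq_id", "feature", "start", "end", "strand", "score", "mult", "confidence")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("hints: missing column(s) %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$mult <- as.integer(df$mult)
  if (!all(df$feature %in% c("intron", "start", "stop", "CDSpart")))
    stopf("hints: invalid feature")
  if (!all(df$confidence %in% c("high", "low"))) stopf("hints: invalid confidence")
  if (any(df$mult < 1L)) stopf("hints: mult must be >= 1")
  if (any(df$start >= df$end)) stopf("hints: empty interval")
  df$source_tag <- ifelse(df$confidence == "high", "M", "P")
  df <- df[order_by(df, c("seq_id", "start", "end", "feature")), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hints", "data.frame")
  df
}

empty_hints <- function() {
  hints(data.frame(seq_id = character(), feature = character(), start = integer(),
                   end = integer(), strand = character(), score = numeric(),
                   mult = integer(), confidence = character()))
}

#' Write hints to predictor-ready GFF
#'
#' One tab-separated line per hint, 1-based inclusive, with column 9 exactly
#' `src=<M|P>;mult=<n>;pri=4`. Lines are sorted by (seq_id, start, end,
#' feature). An empty hint set produces a file holding only the header
#' comment.
#'
#' @param h a [hints()] table
#' @param path output file
#' @export
write_hints_gff <- function(h, path) {
  h <- hints(h)
  header <- "# prohintr hints"
  if (nrow(h) == 0L) { writeLines(header, path); return(invisible(path)) }
  lines <- sprintf("%s\tminiprothint\t%s\t%d\t%d\t%.2f\t%s\t.\tsrc=%s;mult=%d;pri=4",
                   h$seq_id, h$feature, h$start + 1L, h$end, h$score, h$strand,
                   h$source_tag, h$mult)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read hints back from GFF
#'
#' Inverse of [write_hints_gff()].
#'
#' @param path hints GFF file
#' @return a [hints()] table
#' @export
read_hints_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(empty_hints())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  attrs <- f[, 9L]
  m <- regmatches(attrs, regexec("^src=([MP]);mult=([0-9]+);pri=4$", attrs))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad)) stopf("malformed hint attributes: %s", attrs[bad][[1L]])
  hints(data.frame(seq_id = f[, 1L], feature = f[, 3L],
                   start = as.integer(f[, 4L]) - 1L, end = as.integer(f[, 5L]),
                   strand = f[, 7L], score = as.numeric(f[, 6L]),
                   mult = vapply(m, function(x) as.integer(x[[3L]]), integer(1L)),
                   confidence = ifelse(vapply(m, `[[`, character(1L), 2L) == "M", "high", "low")))
}
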