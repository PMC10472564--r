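# Synthetic data with known ground truth: toy genomes with planted
# multi-exon genes, donor proteins at controlled divergence, the spliced
# alignments these would induce, and a deterministic window-local mock
# predictor.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
                              c("A", "C", "G", "T"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

AA_GROUPS <- list(c("A", "G", "S", "T"), c("I", "L", "V", "M"), c("F", "Y", "W"),
                  c("K", "R", "H"), c("D", "E", "N", "Q"), "C", "P")
AA_ALPHABET <- unlist(AA_GROUPS)

aa_group_of <- function(aa) {
  for (g in AA_GROUPS) if (aa %in% g) return(g)
  AA_ALPHABET
}

# conservative substitution <=> same similarity group
same_group <- function(a, b) {
  vapply(seq_along(a), function(i) a[[i]] != b[[i]] && b[[i]] %in% aa_group_of(a[[i]]),
         logical(1L))
}

#' Configuration of the synthetic-fixture generator
#'
#' @param seed RNG seed; identical seeds give byte-identical fixtures
#' @param n_sequences,sequence_length assembly geometry
#' @param n_genes genes planted (distributed round-robin over sequences)
#' @param exons_per_gene integer range `c(lo, hi)` of CDS exons per gene
#' @param intron_length integer range of intron lengths (bp); keep it below
#'   [max_intron_size()] of the genome for realistic alignments
#' @param protein_divergence per-residue substitution probability of donor
#'   proteins in [0, 1]
#' @param frameshift_rate,stop_rate per-block probabilities of injecting a
#'   frameshift / in-frame-stop corruption event into induced alignments
#' @param n_donor_proteomes number of donor proteomes
#' @return list of class `fixture_config`
#' @export
fixture_config <- function(seed = 1L, n_sequences = 2L, sequence_length = 100000L,
                           n_genes = 20L, exons_per_gene = c(2L, 5L),
                           intron_length = c(60L, 300L), protein_divergence = 0,
                           frameshift_rate = 0, stop_rate = 0, n_donor_proteomes = 1L) {
  stopifnot(protein_divergence >= 0, protein_divergence <= 1,
            frameshift_rate >= 0, frameshift_rate <= 1,
            stop_rate >= 0, stop_rate <= 1,
            n_donor_proteomes >= 1, exons_per_gene[[1L]] >= 1,
            intron_length[[1L]] >= 10)
  structure(list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
                 sequence_length = as.integer(sequence_length), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 intron_length = as.integer(intron_length),
                 protein_divergence = protein_divergence,
                 frameshift_rate = frameshift_rate, stop_rate = stop_rate,
                 n_donor_proteomes = as.integer(n_donor_proteomes)),
            class = "fixture_config")
}

#' Preset fixture configurations
#' @param preset `"tiny"`, `"default"` or `"stress"`
#' @param seed RNG seed
#' @return a [fixture_config()]
#' @export
fixture_preset <- function(preset = c("default", "tiny", "stress"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         tiny = fixture_config(seed = seed, n_sequences = 1L, sequence_length = 30000L,
                               n_genes = 5L, exons_per_gene = c(2L, 3L),
                               intron_length = c(60L, 150L)),
         default = fixture_config(seed = seed),
         stress = fixture_config(seed = seed, n_sequences = 4L, sequence_length = 500000L,
                                 n_genes = 100L))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Generate a toy genome with planted protein-coding genes
#'
#' Plants `n_genes` multi-exon genes with canonical structure: ATG start, a
#' single in-frame stop at the end (included in the CDS), GT..AG introns,
#' exon lengths multiples of 3 (codons never span introns). Genes are
#' placed non-overlapping with intergenic gaps, on random strands. The
#' emitted proteins are the exact translations of the planted CDSs (stop
#' excluded).
#'
#' @param cfg a [fixture_config()]
#' @return list with `assembly` (a [genome_assembly()]), `truth` (a
#'   [gene_models()] table) and `proteins` (named character vector, one
#'   exact translation per gene)
#' @export
make_genome_with_genes <- function(cfg) {
  with_seed(cfg$seed, {
    per_seq <- split(seq_len(cfg$n_genes),
                     rep_len(seq_len(cfg$n_sequences), cfg$n_genes))
    seqs <- character(); masks <- list()
    truth_rows <- list(); proteins <- character()
    for (si in seq_len(cfg$n_sequences)) {
      sid <- sprintf("s%d", si)
      parts <- character(); pos <- 0L
      genes_here <- per_seq[[as.character(si)]] %||% integer()
      # spread genes over the whole sequence: gap budget from the mean stride
      stride <- cfg$sequence_length %/% (length(genes_here) + 1L)
      gap_max <- max(800L, stride - 2500L)
      for (gi in genes_here) {
        gid <- sprintf("g%d", gi)
        n_ex <- sample(seq(cfg$exons_per_gene[[1L]], cfg$exons_per_gene[[2L]]), 1L)
        codons_per_exon <- sample(10:60, n_ex, replace = TRUE)
        total <- sum(codons_per_exon)
        codons <- c("ATG", sample(SENSE_CODONS, total - 2L, replace = TRUE), "TAA")
        intron_seqs <- if (n_ex > 1L)
          vapply(seq_len(n_ex - 1L), function(i) {
            len <- sample(seq(cfg$intron_length[[1L]], cfg$intron_length[[2L]]), 1L)
            paste0("GT", random_dna(len - 4L), "AG")
          }, character(1L))
        else character()
        exon_seqs <- vapply(seq_len(n_ex), function(i) {
          off <- c(0L, cumsum(codons_per_exon))[[i]]
          paste(codons[(off + 1L):(off + codons_per_exon[[i]])], collapse = "")
        }, character(1L))
        gene_fwd <- paste0(exon_seqs, c(intron_seqs, ""), collapse = "")
        glen <- nchar(gene_fwd)
        strand <- sample(c("+", "-"), 1L)
        gap <- sample(200:gap_max, 1L)
        gstart <- pos + gap
        if (gstart + glen > cfg$sequence_length)
          stopf("infeasible geometry: gene %s does not fit on %s", gid, sid)
        # exon offsets within the forward-oriented gene
        ex_w <- nchar(exon_seqs); in_w <- nchar(intron_seqs)
        off_start <- cumsum(c(0L, utils::head(ex_w, -1L) + in_w))
        off_end <- off_start + ex_w
        if (strand == "+") {
          ex_g <- data.frame(start = gstart + off_start, end = gstart + off_end)
          region <- gene_fwd
        } else {
          ex_g <- data.frame(start = gstart + glen - off_end, end = gstart + glen - off_start)
          ex_g <- ex_g[order(ex_g$start), , drop = FALSE]
          region <- revcomp(gene_fwd)
        }
        parts <- c(parts, random_dna(gap), region)
        pos <- gstart + glen
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"), seq_id = sid,
                     strand = strand, start = ex_g$start, end = ex_g$end,
                     completeness = "complete")
        cds <- paste(codons, collapse = "")
        prot <- sub("\\*$", "", translate_dna(cds))
        proteins[[gid]] <- prot
      }
      tail_len <- cfg$sequence_length - pos
      parts <- c(parts, random_dna(tail_len))
      seqs[[sid]] <- paste(parts, collapse = "")
    }
    list(assembly = genome_assembly(seqs),
         truth = gene_models(do.call(rbind, truth_rows)),
         proteins = proteins)
  })
}

#' Diverge donor proteins from the reference translations
#'
#' Substitutes each residue independently with probability `divergence`;
#' replacements are drawn half the time from the residue's conservative
#' similarity group, half the time from the full alphabet, and never equal
#' the original (expected identity is exactly `1 - divergence`).
#'
#' @param proteins named character vector of protein sequences
#' @param divergence per-residue substitution probability in [0, 1]
#' @param seed RNG seed
#' @return named character vector of diverged proteins
#' @export
diverge_proteins <- function(proteins, divergence, seed) {
  stopifnot(divergence >= 0, divergence <= 1)
  with_seed(seed, {
    vapply(proteins, function(p) {
      aa <- strsplit(p, "")[[1L]]
      hit <- stats::runif(length(aa)) < divergence
      if (any(hit)) {
        aa[hit] <- vapply(aa[hit], function(r) {
          grp <- setdiff(aa_group_of(r), r)
          pool <- if (length(grp) && stats::runif(1L) < 0.5) grp else setdiff(AA_ALPHABET, r)
          sample(pool, 1L)
        }, character(1L))
      }
      paste(aa, collapse = "")
    }, character(1L))
  })
}

#' Induce the spliced alignments a set of donor proteins would produce
#'
#' Deterministically reconstructs, per donor protein and planted gene, the
#' alignment chain a spliced aligner would report: blocks are the true CDS
#' exons (stop codon excluded), column classes reflect the realized
#' per-residue divergence (identical / conservative substitution /
#' mismatch), and frameshift / in-frame-stop corruption events are injected
#' per block at the configured rates.
#'
#' @param fixture result of [make_genome_with_genes()]
#' @param donors list of donor proteomes (each a named character vector as
#'   from [diverge_proteins()]); names become donor prefixes
#' @param cfg the [fixture_config()]
#' @param seed RNG seed for event injection (default `cfg$seed + 1`)
#' @return list of [alignment_chain()]
#' @export
induce_alignments <- function(fixture, donors, cfg, seed = cfg$seed + 1L) {
  if (!is.list(donors)) donors <- list(d1 = donors)
  if (is.null(names(donors))) names(donors) <- sprintf("d%d", seq_along(donors))
  truth <- fixture$truth
  refs <- fixture$proteins
  with_seed(seed, {
    chains <- list()
    for (dn in names(donors)) {
      donor <- donors[[dn]]
      for (gid in names(refs)) {
        tr <- truth[truth$gene_id == gid, , drop = FALSE]
        tr <- tr[order(tr$start), , drop = FALSE]
        strand <- tr$strand[[1L]]
        b <- data.frame(start = tr$start, end = tr$end)
        if (strand == "+") b$end[[nrow(b)]] <- b$end[[nrow(b)]] - 3L  # drop stop codon
        else b$start[[1L]] <- b$start[[1L]] + 3L
        ra <- strsplit(refs[[gid]], "")[[1L]]
        da <- strsplit(donor[[gid]], "")[[1L]]
        cls <- ifelse(da == ra, "M", ifelse(same_group(ra, da), "S", "X"))
        cod_per_block <- (b$end - b$start) %/% 3L
        bio_order <- if (strand == "+") seq_len(nrow(b)) else rev(seq_len(nrow(b)))
        classes <- character(nrow(b))
        off <- 0L
        for (bi in bio_order) {
          v <- cls[(off + 1L):(off + cod_per_block[[bi]])]
          off <- off + cod_per_block[[bi]]
          if (strand == "-") v <- rev(v)  # store in genomic order
          classes[[bi]] <- paste(v, collapse = "")
        }
        b$classes <- classes
        ev <- list()
        for (bi in seq_len(nrow(b))) {
          if (stats::runif(1L) < cfg$frameshift_rate)
            ev[[length(ev) + 1L]] <- data.frame(type = "frameshift",
                                                pos = sample(b$start[[bi]]:(b$end[[bi]] - 1L), 1L))
          if (stats::runif(1L) < cfg$stop_rate)
            ev[[length(ev) + 1L]] <- data.frame(type = "stop",
                                                pos = sample(b$start[[bi]]:(b$end[[bi]] - 1L), 1L))
        }
        events <- if (length(ev)) do.call(rbind, ev)
                  else data.frame(type = character(), pos = integer())
        nM <- sum(cls == "M"); nS <- sum(cls == "S"); nX <- sum(cls == "X")
        score <- 3 * nM + 1 * nS - 2 * nX - 20 * nrow(events)
        chains[[length(chains) + 1L]] <-
          alignment_chain(sprintf("%s_%s", dn, gid), tr$seq_id[[1L]], strand, b,
                          score = score, events = events,
                          covers_start = TRUE, covers_stop = TRUE)
      }
    }
    chains
  })
}

#' Build a complete fixture: genome, donors, alignments
#'
#' Convenience wrapper chaining [make_genome_with_genes()],
#' [diverge_proteins()] (one donor proteome per `n_donor_proteomes`, each
#' with its own sub-seed) and [induce_alignments()].
#'
#' @param cfg a [fixture_config()]
#' @return list with `assembly`, `truth`, `proteins`, `donors`, `chains`
#' @export
make_fixture <- function(cfg = fixture_config()) {
  fx <- make_genome_with_genes(cfg)
  donors <- lapply(seq_len(cfg$n_donor_proteomes), function(d)
    diverge_proteins(fx$proteins, cfg$protein_divergence, seed = cfg$seed + 100L * d))
  names(donors) <- sprintf("d%d", seq_len(cfg$n_donor_proteomes))
  fx$donors <- donors
  fx$chains <- induce_alignments(fx, donors, cfg)
  fx
}

#' Write a fixture to files
#'
#' Emits the assembly FASTA, truth annotation (GFF3) and the induced
#' alignments in both supported dialects.
#'
#' @param fixture result of [make_fixture()]
#' @param dir output directory
#' @return named character vector of paths
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             truth = file.path(dir, "truth.gff3"),
             compact = file.path(dir, "alignments.aln"),
             gff = file.path(dir, "alignments.gff3"))
  write_genome_fasta(fixture$assembly, paths[["genome"]])
  write_gene_models(fixture$truth, paths[["truth"]], dialect = "gff3")
  write_alignments_compact(fixture$chains, paths[["compact"]])
  write_alignments_gff(fixture$chains, paths[["gff"]])
  paths
}

valid_orf <- function(cds) {
  if (nchar(cds) %% 3L != 0L || nchar(cds) < 6L) return(FALSE)
  if (substr(cds, 1L, 3L) != "ATG") return(FALSE)
  aa <- translate_dna(cds)
  substr(aa, nchar(aa), nchar(aa)) == "*" &&
    !grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))
}

#' Deterministic hint-driven mock gene predictor
#'
#' A stand-in for an external gene predictor, used to test chunked
#' execution: it reconstructs gene models from start/stop/intron hints that
#' fall inside its window and validates them against the window sequence
#' (ATG start, GT..AG introns, single terminal in-frame stop). Its output
#' depends only on the window content — genes not fully contained in the
#' window are not reported — which is exactly the property that makes
#' chunked-versus-unchunked equality a valid oracle.
#'
#' @param sequences named character vector of window sequences
#'   (window-local coordinates)
#' @param h a [hints()] table in the same window-local coordinates
#' @return a [gene_models()] table in window-local coordinates, genes
#'   numbered in positional order
#' @export
mock_predictor <- function(sequences, h) {
  rows <- list()
  for (sid in sort(names(sequences))) {
    L <- nchar(sequences[[sid]])
    s <- sequences[[sid]]
    for (strand in c("+", "-")) {
      hs <- h[h$seq_id == sid & h$strand == strand, , drop = FALSE]
      starts <- hs[hs$feature == "start", , drop = FALSE]
      stops <- hs[hs$feature == "stop", , drop = FALSE]
      intr <- hs[hs$feature == "intron", , drop = FALSE]
      for (i in seq_len(nrow(starts))) {
        if (strand == "+") {
          ok <- stops$start >= starts$end[[i]]
          if (!any(ok)) next
          sp <- c(starts$start[[i]], min(stops$end[ok]))
        } else {
          ok <- stops$end <= starts$start[[i]]
          if (!any(ok)) next
          sp <- c(max(stops$start[ok]), starts$end[[i]])
        }
        if (sp[[1L]] < 0L || sp[[2L]] > L) next
        iv <- intr[intr$start >= sp[[1L]] & intr$end <= sp[[2L]], , drop = FALSE]
        iv <- iv[order(iv$start), , drop = FALSE]
        bnd <- c(sp[[1L]], rbind(iv$start, iv$end), sp[[2L]])
        ex <- data.frame(start = bnd[seq(1L, length(bnd), 2L)],
                         end = bnd[seq(2L, length(bnd), 2L)])
        if (any(ex$end <= ex$start)) next
        cds <- paste(vapply(seq_len(nrow(ex)), function(j)
          substr(s, ex$start[[j]] + 1L, ex$end[[j]]), character(1L)), collapse = "")
        if (strand == "-") cds <- revcomp(cds)
        if (!valid_orf(cds)) next
        splice_ok <- all(vapply(seq_len(nrow(iv)), function(j) {
          din5 <- substr(s, iv$start[[j]] + 1L, iv$start[[j]] + 2L)
          din3 <- substr(s, iv$end[[j]] - 1L, iv$end[[j]])
          if (strand == "+") din5 == "GT" && din3 == "AG"
          else din5 == "CT" && din3 == "AC"
        }, logical(1L)))
        if (!splice_ok) next
        rows[[length(rows) + 1L]] <-
          data.frame(seq_id = sid, strand = strand, start = ex$start, end = ex$end)
      }
    }
  }
  if (!length(rows)) return(empty_gene_models())
  # dedup (the same gene can be reachable from duplicate hints) and number
  uniq <- unique(do.call(rbind, lapply(rows, function(r)
    data.frame(seq_id = r$seq_id[[1L]], strand = r$strand[[1L]],
               start = min(r$start), end = max(r$end),
               key = paste(r$seq_id[[1L]], r$strand[[1L]],
                           paste(r$start, r$end, sep = "-", collapse = ","))))))
  uniq <- uniq[order_by(uniq, c("seq_id", "start", "end", "strand")), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(uniq))) {
    r <- rows[[match(uniq$key[[i]], vapply(rows, function(r)
      paste(r$seq_id[[1L]], r$strand[[1L]], paste(r$start, r$end, sep = "-", collapse = ",")),
      character(1L)))]]
    out[[i]] <- data.frame(gene_id = sprintf("g%d", i),
                           transcript_id = sprintf("g%d.t1", i),
                           seq_id = r$seq_id, strand = r$strand,
                           start = r$start, end = r$end, completeness = "complete")
  }
  gene_models(do.call(rbind, out))
}
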