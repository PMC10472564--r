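#' Pipeline configuration
#'
#' Wires the stages together: spliced alignment (external aligner or a
#' precomputed alignment file), evidence scoring and classification,
#' training-gene construction, chunked prediction, support-based iterative
#' refinement, and final merge. External tools are reached through
#' adapters: R functions for the predictor (`function(sequences, hints)`
#' returning chunk-local gene models, e.g. [mock_predictor()]) and
#' trainer/optimizer hooks (`function(genbank_path)`); when an adapter is
#' `NULL` the corresponding stage is a recorded no-op (dry run).
#'
#' @param genome path to the assembly FASTA
#' @param alignments path to a precomputed alignment file, or `NULL` to
#'   call the aligner adapter
#' @param alignment_dialect `"compact"` or `"miniprot_gff"`
#' @param workdir working directory (created; stage checkpoints live here
#'   and make reruns resumable)
#' @param aligner optional adapter `function(genome_path, protein_paths)`
#'   returning an alignment file path
#' @param proteins protein FASTA paths handed to the aligner adapter
#' @param predictor predictor adapter (default [mock_predictor()])
#' @param trainer,optimizer optional training hooks
#' @param scoring a [scoring_config()]
#' @param chunk_size,overlap,batch_target chunking parameters (see
#'   [plan_chunks()])
#' @param flank_floor,flank_cap flank clamp (see [compute_flank()])
#' @param coverage_threshold full-support CDS coverage threshold (see
#'   [evaluate_support()])
#' @param min_exons minimum blocks for training-gene candidates
#' @param skip_optimize skip the optimizer hook
#' @param reference optional reference annotation path (GTF) for a final
#'   accuracy report
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(genome, alignments = NULL, alignment_dialect = "compact",
                            workdir = tempfile("prohintr_run_"), aligner = NULL,
                            proteins = character(), predictor = mock_predictor,
                            trainer = NULL, optimizer = NULL,
                            scoring = scoring_config(),
                            chunk_size = 5e6, overlap = 1e6, batch_target = 5e6,
                            flank_floor = 500L, flank_cap = 10000L,
                            coverage_threshold = 0.8, min_exons = 1L,
                            skip_optimize = FALSE, reference = NULL) {
  if (is.null(alignments) && is.null(aligner))
    stopf("either a precomputed alignment file or an aligner adapter is required")
  structure(list(genome = genome, alignments = alignments,
                 alignment_dialect = alignment_dialect, workdir = workdir,
                 aligner = aligner, proteins = proteins, predictor = predictor,
                 trainer = trainer, optimizer = optimizer, scoring = scoring,
                 chunk_size = chunk_size, overlap = overlap, batch_target = batch_target,
                 flank_floor = as.integer(flank_floor), flank_cap = as.integer(flank_cap),
                 coverage_threshold = coverage_threshold, min_exons = as.integer(min_exons),
                 skip_optimize = isTRUE(skip_optimize), reference = reference),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Reads key-value pairs (keys matching the arguments of
#' [pipeline_config()]) from a YAML file; arguments passed directly
#' override file values.
#'
#' @param path YAML config file
#' @param ... overrides forwarded to [pipeline_config()]
#' @return a `pipeline_config`
#' @export
pipeline_config_yaml <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, vals[keep])
}

stage_log <- function(workdir, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  cat(line, "\n", sep = "", file = file.path(workdir, "pipeline.log"), append = TRUE)
}

predict_chunked <- function(cfg, assembly, h, plan) {
  per_chunk <- list()
  for (cid in unique(plan$entries$chunk_id)) {
    inp <- chunk_input(plan, cid, assembly, h)
    local <- cfg$predictor(inp$sequences, inp$hints)
    per_chunk[[as.character(cid)]] <- remap_predictions(cid, local, plan)
  }
  merge_chunk_predictions(per_chunk, plan)
}

#' Run the annotation pipeline
#'
#' Executes, in order: alignment loading (or the aligner adapter), evidence
#' scoring/classification, round-1 training-gene selection and excision,
#' the trainer hook, chunk planning, chunked prediction with hints, merge,
#' evidence-support evaluation, round-2 training-set construction with
#' flank refinement, the trainer/optimizer hooks, the final chunked
#' prediction and merge, and a gene-set summary. Every stage writes its
#' checkpoint file(s) into the work directory; a rerun resumes after the
#' last complete stage (a stage is complete when its checkpoint files
#' exist). With the same inputs and configuration the written outputs are
#' byte-identical across runs.
#'
#' @param cfg a [pipeline_config()]
#' @return list with `final` (merged [gene_models()]), `summary`
#'   (see [summarize_gene_set()]), `support`, `training`, `paths`
#'   (checkpoint files) and optionally `accuracy`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!file.exists(cfg$genome)) stopf("missing genome file: %s", cfg$genome)
  wd <- cfg$workdir
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(wd, sprintf(...))
  paths <- c(alignments = p("01_alignments.%s", if (cfg$alignment_dialect == "compact") "aln" else "gff3"),
             hints = p("02_hints.gff"), scores = p("02_scores.tsv"),
             training1_gb = p("03_training.gb"), training1 = p("03_training.tsv"),
             train1_done = p("03_train.done"),
             plan = p("04_plan.tsv"), predictions = p("05_predictions.gtf"),
             support = p("06_support.tsv"), training2_gb = p("06_training2.gb"),
             training2 = p("06_training2.tsv"), train2_done = p("06_train.done"),
             final = p("07_final.gtf"), summary = p("07_summary.json"))
  assembly <- read_genome_fasta(cfg$genome)

  # stage 1: alignments
  if (!file.exists(paths[["alignments"]])) {
    src <- cfg$alignments
    if (is.null(src)) {
      stage_log(wd, "align", "running aligner adapter")
      src <- cfg$aligner(cfg$genome, cfg$proteins)
    }
    if (!file.exists(src)) stopf("alignment file not found: %s", src)
    file.copy(src, paths[["alignments"]], overwrite = TRUE)
    stage_log(wd, "align", sprintf("alignments staged from %s", src))
  } else stage_log(wd, "align", "checkpoint present, skipping")
  chains <- parse_alignments(paths[["alignments"]], cfg$alignment_dialect)

  # stage 2: evidence scoring and classification
  if (!all(file.exists(paths[c("hints", "scores")]))) {
    cls <- classify_evidence(chains, cfg$scoring)
    write_hints_gff(cls$hints, paths[["hints"]])
    write_scores_tsv(cls$evidence, paths[["scores"]])
    stage_log(wd, "hints", sprintf("%d evidence intron(s), %d hint(s)",
                                   nrow(cls$evidence), nrow(cls$hints)))
    evidence <- cls$evidence; h <- cls$hints
  } else {
    stage_log(wd, "hints", "checkpoint present, skipping")
    cls <- classify_evidence(chains, cfg$scoring)  # evidence table is cheap to rebuild
    evidence <- cls$evidence
    h <- read_hints_gff(paths[["hints"]])
  }

  # stage 3: round-1 training genes + trainer hook
  if (!all(file.exists(paths[c("training1_gb", "training1", "train1_done")]))) {
    training <- select_training_genes(chains, evidence, min_exons = cfg$min_exons)
    flank <- compute_flank(training, cap = cfg$flank_cap, floor = cfg$flank_floor)
    training <- apply_flank(training, flank, seq_lengths(assembly))
    write_training_genbank(training, assembly, paths[["training1_gb"]])
    write_training_tsv(training, paths[["training1"]])
    if (!is.null(cfg$trainer)) cfg$trainer(paths[["training1_gb"]])
    writeLines(sprintf("trained on %d gene(s), flank %d bp", nrow(training$info), flank),
               paths[["train1_done"]])
    stage_log(wd, "train1", sprintf("%d training gene(s), flank %d bp",
                                    nrow(training$info), flank))
  } else stage_log(wd, "train1", "checkpoint present, skipping")

  # stage 4: chunk plan
  if (!file.exists(paths[["plan"]])) {
    plan <- suppressWarnings(plan_chunks(assembly, cfg$chunk_size, cfg$overlap, cfg$batch_target))
    write_chunk_plan(plan, paths[["plan"]])
    stage_log(wd, "chunks", sprintf("%d chunk(s)", length(unique(plan$entries$chunk_id))))
  } else {
    stage_log(wd, "chunks", "checkpoint present, skipping")
    plan <- suppressWarnings(plan_chunks(assembly, cfg$chunk_size, cfg$overlap, cfg$batch_target))
  }

  # stage 5: chunked prediction round 1
  if (!file.exists(paths[["predictions"]])) {
    merged <- predict_chunked(cfg, assembly, h, plan)
    write_gene_models(gene_models(merged[setdiff(names(merged), "truncated")]),
                      paths[["predictions"]], dialect = "gtf")
    stage_log(wd, "predict1", sprintf("%d transcript(s) after merge",
                                      length(unique(merged$transcript_id))))
  } else stage_log(wd, "predict1", "checkpoint present, skipping")
  predictions <- read_gene_models(paths[["predictions"]], dialect = "gtf")

  # stage 6: support evaluation, refined round-2 training set
  if (!all(file.exists(paths[c("support", "training2_gb", "training2", "train2_done")]))) {
    support <- evaluate_support(predictions, h, cfg$coverage_threshold)
    utils::write.table(support, paths[["support"]], sep = "\t", quote = FALSE, row.names = FALSE)
    training2 <- training_set_from_predictions(predictions, support)
    flank2 <- compute_flank(training2, cap = cfg$flank_cap, floor = cfg$flank_floor)
    training2 <- apply_flank(training2, flank2, seq_lengths(assembly))
    training2 <- refine_flanks(training2, predictions)
    write_training_genbank(training2, assembly, paths[["training2_gb"]])
    write_training_tsv(training2, paths[["training2"]])
    if (!is.null(cfg$trainer)) cfg$trainer(paths[["training2_gb"]])
    if (!cfg$skip_optimize && !is.null(cfg$optimizer)) cfg$optimizer(paths[["training2_gb"]])
    writeLines(sprintf("retrained on %d gene(s), flank %d bp", nrow(training2$info), flank2),
               paths[["train2_done"]])
    stage_log(wd, "refine", sprintf("%d fully supported gene(s)", nrow(training2$info)))
  } else stage_log(wd, "refine", "checkpoint present, skipping")
  support <- utils::read.delim(paths[["support"]])

  # stage 7: final prediction and summary
  if (!all(file.exists(paths[c("final", "summary")]))) {
    final <- predict_chunked(cfg, assembly, h, plan)
    write_gene_models(gene_models(final[setdiff(names(final), "truncated")]),
                      paths[["final"]], dialect = "gtf")
    summ <- summarize_gene_set(final)
    jsonlite::write_json(as.list(summ), paths[["summary"]], auto_unbox = TRUE, digits = NA)
    stage_log(wd, "final", sprintf("%d gene(s) in final set", summ$n_genes))
  } else stage_log(wd, "final", "checkpoint present, skipping")
  final <- read_gene_models(paths[["final"]], dialect = "gtf")
  summ <- as.data.frame(jsonlite::read_json(paths[["summary"]], simplifyVector = TRUE))

  out <- list(final = final, summary = summ, support = support, paths = paths)
  if (!is.null(cfg$reference)) {
    ref <- read_gene_models(cfg$reference, dialect = "gtf")
    out$accuracy <- compare_gene_sets(final, ref)
  }
  out
}
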