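# End-to-end pipeline: preprocess -> align -> junction calling ->
# classification -> deduplication -> quantification -> hotspots, driven
# by a single YAML config, with per-stage accounting and deterministic
# outputs.

#' Load and validate a run configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' entries: `fastq1`, `fastq2`, `genome_fasta`, `out_dir`, `sample_id`,
#' a `bait` block (chrom, strand, primer_start, primer_end, cut_pos,
#' guide, pam), an `adapters` block (sequencing_adapter, bridge_template,
#' bait_primer, quality_floor, min_len), optional `control`
#' (`fastq1`/`fastq2` of the uncut library), `te` (transfection
#' efficiency in (0,1]), optional `peak`, `dedup` and `classify`
#' parameter blocks, an optional `replicates` list of junction BEDPE
#' paths for hotspot recurrence, and `seed`.
#'
#' @param x path to a YAML file or a named list.
#' @return A validated list of class `pem_config`.
#' @export
pem_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  req <- c("fastq1", "fastq2", "genome_fasta", "out_dir", "bait",
           "adapters")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stopf("config error: missing fields: %s", paste(miss, collapse = ", "))
  for (f in c("fastq1", "fastq2", "genome_fasta"))
    if (!file.exists(cfg[[f]]))
      stopf("config error: %s does not exist: %s", f, cfg[[f]])
  cfg$te <- cfg$te %||% 1
  if (cfg$te <= 0 || cfg$te > 1)
    stopf("config error: te must be in (0, 1]")
  cfg$sample_id <- cfg$sample_id %||% "sample"
  cfg$seed <- cfg$seed %||% 1L
  if (!is.null(cfg$control)) {
    for (f in c("fastq1", "fastq2"))
      if (!file.exists(cfg$control[[f]]))
        stopf("config error: control %s does not exist", f)
  }
  if (!is.null(cfg$replicates))
    for (p in cfg$replicates)
      if (!file.exists(p)) stopf("config error: replicate BEDPE missing: %s", p)
  class(cfg) <- c("pem_config", "list")
  cfg
}

#' Write a configuration back to YAML
#' @param cfg a `pem_config` (or plain list).
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Analyse cleaned molecules against a genome
#'
#' The in-memory core shared by [run_pipeline()] and the tests: aligns
#' cleaned molecules, calls and classifies junctions, removes PCR
#' duplicates, and tabulates library statistics.
#'
#' @param molecules cleaned molecule table (`id`, `rmb`, `insert_seq`).
#' @param genome named character vector of chromosome sequences.
#' @param bait a [bait_config()].
#' @param align_par an [align_params()] list.
#' @param dedup_par list with `max_edit`, `pos_tol`, `metric`.
#' @param indel_window,proximal_span classification windows, see
#'   [classify_junctions()].
#' @return A list with `calls` (all classified calls), `unique`
#'   (deduplicated calls), `stats` (`library_stats`), `dedup_report`,
#'   and `dropped` (data.table `reason`, `n`).
#' @export
analyze_molecules <- function(molecules, genome, bait,
                              align_par = align_params(),
                              dedup_par = list(max_edit = 2L, pos_tol = 2L,
                                               metric = "levenshtein"),
                              indel_window = 5L,
                              proximal_span = 250000L) {
  aln <- toy_align(molecules, genome, bait, align_par)
  grp <- group_alignments(aln$segments)
  jn <- call_junctions(grp$segments, bait)
  cls <- classify_junctions(jn$calls, aln$edits, bait,
                            indel_window = indel_window,
                            proximal_span = proximal_span)
  dd <- dedup_junctions(cls, max_edit = dedup_par$max_edit %||% 2L,
                        pos_tol = dedup_par$pos_tol %||% 2L,
                        metric = dedup_par$metric %||% "levenshtein")
  dropped <- rbindlist(list(aln$dropped, grp$dropped, jn$dropped))
  drop_counts <- if (nrow(dropped))
    dropped[, .(n = .N), by = reason] else
    data.table(reason = character(0), n = integer(0))
  list(calls = cls, unique = dd$unique,
       stats = tabulate_junctions(dd$unique),
       dedup_report = dd$report, dropped = drop_counts)
}

#' Run the full PEM-seq analysis pipeline
#'
#' Executes preprocessing, alignment with the bundled toy aligner,
#' junction calling, classification, deduplication, quantification and
#' (when possible) hotspot identification, and writes the output bundle:
#' `counts.tsv` (per-stage dispositions), `stats.tsv`, `junctions.bedpe`,
#' `hotspots.tsv`/`hotspots.bed`, and `summary.json`. Reruns on identical
#' inputs produce byte-identical outputs.
#'
#' @param config a `pem_config`, a path to one, or a named list.
#' @return Invisibly, a list with `stats`, `efficiency`, `hotspots`,
#'   `unique` calls and per-stage `counts`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pem_config")) config else pem_config(config)
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- read_genome_fasta(cfg$genome_fasta)
  b <- cfg$bait
  bait <- bait_config(b$chrom, b$strand, b$primer_start, b$primer_end,
                      b$cut_pos, b$guide, b$pam %||% "NGG")
  a <- cfg$adapters
  adapters <- adapter_spec(
    sequencing_adapter = a$sequencing_adapter %||% "AGATCGGAAGAGC",
    bridge_template = a$bridge_template %||%
      paste0("ACCGTAGT", strrep("N", 14), "TGCAGGTA"),
    bait_primer = a$bait_primer,
    quality_floor = a$quality_floor %||% 30L,
    min_len = a$min_len %||% 25L)
  pp_args <- cfg$peak %||% list()
  params <- do.call(peak_params, pp_args)

  process_one <- function(fq1, fq2, label) {
    reads <- read_fastq_pairs(fq1, fq2)
    pre <- preprocess_reads(reads, adapters)
    res <- analyze_molecules(pre$molecules, genome, bait,
                             dedup_par = cfg$dedup %||% list(),
                             indel_window = cfg$classify$indel_window %||% 5L,
                             proximal_span =
                               cfg$classify$proximal_span %||% 250000L)
    res$stats$label <- label
    res$pre_counts <- pre$counts
    res
  }

  smp <- process_one(cfg$fastq1, cfg$fastq2, cfg$sample_id)
  ctl <- if (!is.null(cfg$control))
    process_one(cfg$control$fastq1, cfg$control$fastq2, "control")
  else NULL
  ctl_stats <- if (is.null(ctl)) library_stats(1L, 0L, 0L,
                                               label = "control_assumed")
  else ctl$stats

  # hotspots: replicate junction files when provided, otherwise this
  # library alone with recurrence requirement relaxed
  jx_self <- junctions_from_calls(smp$unique)
  if (!is.null(cfg$replicates)) {
    jreps <- lapply(cfg$replicates, function(p)
      junctions_from_calls(read_junctions_bedpe(p)))
  } else {
    jreps <- list(jx_self)
    params$min_replicates <- 1L
  }
  hs <- call_hotspots(jreps, genome, bait, params)
  if (nrow(hs)) {
    hs[, intensity := hotspot_intensity(junction_count, smp$stats,
                                        if (is.null(ctl)) NULL
                                        else ctl$stats)]
  }

  smp$unique <- split_translocations(smp$unique, hs, params$count_window)
  smp$stats <- tabulate_junctions(smp$unique, cfg$sample_id)
  eff <- editing_efficiency(smp$stats, ctl_stats, cfg$te)

  # output bundle
  od <- cfg$out_dir
  counts <- copy(smp$pre_counts)
  counts <- rbind(counts,
                  data.table(stage = paste0("dropped_", smp$dropped$reason),
                             n = smp$dropped$n),
                  data.table(stage = c("unique_molecules", "duplicates"),
                             n = c(smp$stats$total,
                                   nrow(smp$calls) - smp$stats$total)))
  fwrite(counts, file.path(od, "counts.tsv"), sep = "\t")
  write_stats_tsv(c(list(smp$stats),
                    if (!is.null(ctl)) list(ctl$stats)),
                  file.path(od, "stats.tsv"))
  write_junctions_bedpe(smp$unique, bait, file.path(od, "junctions.bedpe"))
  write_hotspots(hs, bed_path = file.path(od, "hotspots.bed"),
                 tsv_path = file.path(od, "hotspots.tsv"))
  summary <- list(
    sample = cfg$sample_id,
    stats = list(G = smp$stats$G, I = smp$stats$I, T = smp$stats$T,
                 total = smp$stats$total,
                 subcounts = as.list(smp$stats$subcounts)),
    control = list(G = ctl_stats$G, I = ctl_stats$I, T = ctl_stats$T),
    efficiency = eff$efficiency,
    raw_sample_fraction = eff$raw_sample_fraction,
    raw_control_fraction = eff$raw_control_fraction,
    te = cfg$te,
    n_hotspots = nrow(hs),
    config = list(seed = cfg$seed, sample_id = cfg$sample_id))
  jsonlite::write_json(summary, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(stats = smp$stats, control_stats = ctl_stats,
                 efficiency = eff, hotspots = hs, unique = smp$unique,
                 counts = counts))
}

#' Write a simulated library to disk with its matching run config
#'
#' Emits the genome FASTA, gzipped paired FASTQ, the truth table TSV and
#' a ready-to-run YAML config; with `control = TRUE` an uncut (100%
#' germline) library is written alongside and referenced by the config.
#'
#' @param lib a [simulate_library()] result.
#' @param dir output directory.
#' @param control optionally a second library (from [control_spec()]) to
#'   write as the uncut control.
#' @return The path of the written YAML config.
#' @export
write_simulated_library <- function(lib, dir, control = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(lib$genome, file.path(dir, "genome.fa"))
  write_fastq_pairs(lib$reads, file.path(dir, "reads_R1.fastq.gz"),
                    file.path(dir, "reads_R2.fastq.gz"))
  fwrite(lib$truth, file.path(dir, "truth.tsv"), sep = "\t")
  if (nrow(lib$offtargets))
    fwrite(lib$offtargets, file.path(dir, "offtargets.tsv"), sep = "\t")
  cfg <- list(
    fastq1 = file.path(dir, "reads_R1.fastq.gz"),
    fastq2 = file.path(dir, "reads_R2.fastq.gz"),
    genome_fasta = file.path(dir, "genome.fa"),
    out_dir = file.path(dir, "out"),
    sample_id = "simulated",
    bait = list(chrom = lib$bait$chrom, strand = lib$bait$strand,
                primer_start = lib$bait$primer_start,
                primer_end = lib$bait$primer_end,
                cut_pos = lib$bait$cut_pos, guide = lib$bait$guide,
                pam = lib$bait$pam),
    adapters = list(
      sequencing_adapter = lib$adapters$sequencing_adapter,
      bridge_template = lib$adapters$bridge_template,
      bait_primer = lib$adapters$bait_primer),
    te = 1, seed = lib$spec$seed)
  if (!is.null(control)) {
    write_fastq_pairs(control$reads,
                      file.path(dir, "control_R1.fastq.gz"),
                      file.path(dir, "control_R2.fastq.gz"))
    cfg$control <- list(fastq1 = file.path(dir, "control_R1.fastq.gz"),
                        fastq2 = file.path(dir, "control_R2.fastq.gz"))
  }
  path <- file.path(dir, "config.yaml")
  write_config(cfg, path)
  path
}
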