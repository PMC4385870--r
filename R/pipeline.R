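#' Pipeline run configuration
#'
#' Collects the file paths and tolerances for one end-to-end run over a
#' pooled sequencing run. Round-trips through JSON via [save_run_config()] /
#' [load_run_config()].
#'
#' @param panel_tsv,panel_fasta,panel_spans panel files ([load_panel()]).
#' @param fastq_r1,fastq_r2 pooled paired FASTQ files (gzip ok).
#' @param manifest_tsv sample manifest TSV: `sample_id`, `barcode`, and per
#'   sample either `input_genomes` or `dna_mass_ng`, plus `plasma_ml` and
#'   `ipc_copies` (spiked IPC molecules per mutation).
#' @param lod_tsv optional LOD table TSV (from a previous [estimate_lod()]);
#'   when present, calls are emitted.
#' @param out_dir output directory.
#' @param min_overlap,max_mismatch_frac,barcode_max_mismatch,max_edit_frac,flank_match
#'   tolerances, see [process_reads()].
#' @param genome_mass_pg pg per haploid genome.
#' @param correct_yield see [estimate_yield()].
#' @return object of class `run_config`.
#' @export
run_config <- function(panel_tsv, panel_fasta, panel_spans,
                       fastq_r1, fastq_r2, manifest_tsv,
                       lod_tsv = NULL, out_dir = "panelcall_out",
                       min_overlap = 20L, max_mismatch_frac = 0.1,
                       barcode_max_mismatch = 1L, max_edit_frac = 0.3,
                       flank_match = 10L, genome_mass_pg = 3.3,
                       correct_yield = TRUE) {
  stopifnot(min_overlap >= 1, max_mismatch_frac >= 0, max_mismatch_frac <= 1,
            barcode_max_mismatch >= 0, max_edit_frac >= 0, max_edit_frac <= 1,
            flank_match >= 0)
  structure(list(
    panel_tsv = panel_tsv, panel_fasta = panel_fasta,
    panel_spans = panel_spans, fastq_r1 = fastq_r1, fastq_r2 = fastq_r2,
    manifest_tsv = manifest_tsv, lod_tsv = lod_tsv, out_dir = out_dir,
    min_overlap = as.integer(min_overlap),
    max_mismatch_frac = max_mismatch_frac,
    barcode_max_mismatch = as.integer(barcode_max_mismatch),
    max_edit_frac = max_edit_frac, flank_match = as.integer(flank_match),
    genome_mass_pg = genome_mass_pg, correct_yield = correct_yield
  ), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) config_error("config does not exist: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Run the full pipeline on a pooled sequencing run
#'
#' Loads the panel, reads the pooled FASTQ pair, merges/demultiplexes/
#' classifies all reads, quantifies every manifest sample, and (when an LOD
#' table is supplied) calls mutations. All stage outputs are written under
#' `config$out_dir`: per-sample classified-cluster TSVs, quantitation TSVs,
#' call TSVs, and a QC JSON with full read-fate accounting. Deterministic
#' given identical inputs.
#'
#' @param config a `run_config` (or path to its JSON).
#' @return (invisibly) list: `quants`, `calls` (or `NULL`), `qc`,
#'   `clusters`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$fastq_r1, config$fastq_r2, config$manifest_tsv))
    if (!file.exists(p)) config_error("input does not exist: ", p)
  panel <- load_panel(config$panel_tsv, config$panel_fasta,
                      config$panel_spans,
                      genome_mass_pg = config$genome_mass_pg)
  manifest <- read.delim(config$manifest_tsv, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "barcode")
  if (length(setdiff(need, names(manifest))))
    config_error("manifest lacks columns: ",
                 paste(setdiff(need, names(manifest)), collapse = ", "))
  barcodes <- setNames(manifest$barcode, manifest$sample_id)

  r1 <- read_fastq(config$fastq_r1)
  r2 <- read_fastq(config$fastq_r2)
  pr <- tryCatch(
    process_reads(r1, r2, panel, barcodes,
                  min_overlap = config$min_overlap,
                  max_mismatch_frac = config$max_mismatch_frac,
                  barcode_max_mismatch = config$barcode_max_mismatch,
                  max_edit_frac = config$max_edit_frac,
                  flank_match = config$flank_match),
    error = function(e) config_error("readproc stage failed: ",
                                     conditionMessage(e)))

  lods <- NULL
  if (!is.null(config$lod_tsv)) {
    if (!file.exists(config$lod_tsv))
      config_error("LOD table does not exist: ", config$lod_tsv)
    lods <- read.delim(config$lod_tsv, stringsAsFactors = FALSE)
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  quants <- list(); calls <- list()
  for (k in seq_len(nrow(manifest))) {
    m <- manifest[k, ]
    q <- tryCatch(
      quantify_sample(
        pr$clusters, panel,
        spiked_ipc_copies = if (!is.null(m$ipc_copies)) m$ipc_copies else 100L,
        input_genomes = if (!is.null(m$input_genomes) && !is.na(m$input_genomes))
          m$input_genomes else NULL,
        dna_mass_ng = if (!is.null(m$dna_mass_ng) && !is.na(m$dna_mass_ng))
          m$dna_mass_ng else NULL,
        plasma_ml = if (!is.null(m$plasma_ml)) m$plasma_ml else 5,
        sample = m$sample_id, correct_yield = config$correct_yield),
      error = function(e) config_error("quant stage failed for sample ",
                                       m$sample_id, ": ",
                                       conditionMessage(e)))
    quants[[m$sample_id]] <- q
    write.table(q, file.path(config$out_dir,
                             paste0(m$sample_id, "_quant.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sub <- pr$clusters[!is.na(pr$clusters$sample) &
                         pr$clusters$sample == m$sample_id, , drop = FALSE]
    write.table(sub, file.path(config$out_dir,
                               paste0(m$sample_id, "_clusters.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(lods)) {
      cl <- tryCatch(call_mutations(q, lods),
                     error = function(e) config_error(
                       "calling stage failed for sample ", m$sample_id, ": ",
                       conditionMessage(e)))
      calls[[m$sample_id]] <- cl
      write.table(cl, file.path(config$out_dir,
                                paste0(m$sample_id, "_calls.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  qc <- pr$qc
  qc$labels <- as.list(qc$labels)
  jsonlite::write_json(qc, file.path(config$out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(quants = quants,
                 calls = if (length(calls)) calls else NULL,
                 qc = pr$qc, clusters = pr$clusters))
}
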