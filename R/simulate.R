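#' Simulation configuration for one assay sample
#'
#' Describes the wet-lab front end of the assay for one plasma sample:
#' genomic wild-type molecules (one per amplicon per input genome
#' equivalent), titrated mutant molecules, and randomly barcoded internal
#' positive control (IPC) molecules, taken through limited-cycle error-prone
#' multiplex PCR, a differential mutant-enrichment step, and paired-end
#' sequencing with an inline sample barcode on read 1.
#'
#' PCR is modelled as per-cycle doubling with independent per-base
#' substitution errors (applied per emitted read with probability
#' `1 - (1 - per_base_error_per_cycle)^pcr_cycles_pre` per base, the
#' accumulated per-lineage rate). Enrichment is phenomenological: each
#' amplified molecule survives each of `enrich_cycles` cycles independently
#' with probability `retain_mut` (mutant and IPC molecules) or `retain_wt`
#' (wild-type), so the expected mutant:wild-type enrichment factor is
#' `(retain_mut / retain_wt)^enrich_cycles`. The defaults give a factor of
#' 1e4, consistent with a single-copy limit of detection at an input of
#' 1e5 genome equivalents.
#'
#' @param input_genomes haploid genome equivalents of plasma DNA; overridden
#'   by `dna_mass_ng` when supplied.
#' @param dna_mass_ng input DNA mass; converted at `genome_mass_pg` pg per
#'   haploid genome.
#' @param mutant_copies named integer vector, mutation_id -> spiked mutant
#'   molecule count (default none).
#' @param ipc_copies IPC molecules spiked per mutation: a single count or a
#'   named vector by mutation_id (default 100).
#' @param pcr_cycles_pre pre-enrichment PCR cycles (limited to minimise
#'   pre-enrichment errors; default 10).
#' @param per_base_error_per_cycle substitution probability per base per
#'   cycle (default 1e-4, lumping polymerase and readout error).
#' @param enrich_cycles enrichment cycles (default 20).
#' @param retain_mut per-cycle retention probability for mutant/IPC molecules
#'   (default 0.9).
#' @param retain_wt per-cycle retention probability for wild-type molecules
#'   (default `0.9 * 10^(-4/enrich_cycles)`, i.e. 1e4-fold enrichment).
#' @param reads_per_sample sequenced read pairs (default 1e5).
#' @param read_len read length (default 110); read 1 is
#'   `barcode + first (read_len - nchar(barcode)) bases` of the molecule,
#'   read 2 the reverse complement of its last `read_len` bases.
#' @param barcode inline sample barcode (default first packaged barcode).
#' @param plasma_ml plasma volume the sample represents (default 5).
#' @param genome_mass_pg pg per haploid genome for the mass conversion.
#' @param seed integer RNG seed; identical seeds give byte-identical output.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(input_genomes = 1e5, dna_mass_ng = NULL,
                       mutant_copies = NULL, ipc_copies = 100L,
                       pcr_cycles_pre = 10L, per_base_error_per_cycle = 1e-4,
                       enrich_cycles = 20L, retain_mut = 0.9,
                       retain_wt = 0.9 * 10^(-4 / 20),
                       reads_per_sample = 1e5, read_len = 110L,
                       barcode = "ACGTAGCA", plasma_ml = 5,
                       genome_mass_pg = 3.3, seed = 1L) {
  if (!is.null(dna_mass_ng))
    input_genomes <- dna_mass_ng * 1000 / genome_mass_pg
  probs <- c(per_base_error_per_cycle, retain_mut, retain_wt)
  if (any(probs < 0) || any(probs > 1))
    config_error("probabilities must lie in [0, 1]")
  if (retain_mut < retain_wt)
    config_error("retain_mut must be >= retain_wt (enrichment enriches mutants)")
  if (input_genomes < 0 || reads_per_sample < 0)
    config_error("counts must be >= 0")
  if (!is.null(mutant_copies)) {
    if (is.null(names(mutant_copies)) || any(!nzchar(names(mutant_copies))))
      config_error("mutant_copies must be named by mutation_id")
    if (any(mutant_copies < 0)) config_error("mutant_copies must be >= 0")
  }
  if (any(ipc_copies < 0)) config_error("ipc_copies must be >= 0")
  structure(list(
    input_genomes = input_genomes, mutant_copies = mutant_copies,
    ipc_copies = ipc_copies, pcr_cycles_pre = as.integer(pcr_cycles_pre),
    per_base_error_per_cycle = per_base_error_per_cycle,
    enrich_cycles = as.integer(enrich_cycles),
    retain_mut = retain_mut, retain_wt = retain_wt,
    reads_per_sample = as.integer(reads_per_sample),
    read_len = as.integer(read_len), barcode = barcode,
    plasma_ml = plasma_ml, genome_mass_pg = genome_mass_pg,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# resolve ipc_copies to a full named vector over panel mutations
resolve_ipc_copies <- function(cfg, panel) {
  ids <- panel$mutations$mutation_id
  if (length(cfg$ipc_copies) == 1L && is.null(names(cfg$ipc_copies)))
    return(setNames(rep(as.integer(cfg$ipc_copies), length(ids)), ids))
  out <- setNames(rep(0L, length(ids)), ids)
  out[names(cfg$ipc_copies)] <- as.integer(cfg$ipc_copies)
  out
}

# binomial draw robust to sizes beyond .Machine$integer.max
big_rbinom <- function(size, prob) {
  if (size <= .Machine$integer.max) return(rbinom(1L, size, prob))
  mu <- size * prob
  if (mu < 1e7) rpois(1L, mu) else round(rnorm(1L, mu, sqrt(mu * (1 - prob))))
}

#' Simulate one sequenced sample with full ground truth
#'
#' Runs the generative model of [sim_config()] for one sample and returns the
#' read pairs plus a founder-level ground-truth table. Founder molecules are
#' wild-type (one aggregate pool per amplicon), genomic mutants (tracked
#' individually), and IPCs (tracked individually, each with a unique random
#' identifier drawn at the amplicon's IPC span). Each founder is amplified to
#' `2^pcr_cycles_pre` molecules, molecules survive enrichment independently,
#' and `reads_per_sample` read pairs are drawn from the surviving pool.
#'
#' @param panel a `ctdna_panel`.
#' @param cfg a `sim_config`.
#' @param out_dir if non-`NULL`, write `R1.fastq.gz`, `R2.fastq.gz` and
#'   `truth.tsv` there.
#' @param sample_id label used in read names and truth output.
#' @return object of class `scoda_sim`: list with `r1`, `r2` (each
#'   `list(id, seq, qual)`), `truth` (founder table with per-founder emitted
#'   read counts), `read_founder` (row of `truth` each read descends from),
#'   `config`, `sample_id`.
#' @export
simulate_sample <- function(panel, cfg, out_dir = NULL, sample_id = "sample1") {
  stopifnot(inherits(panel, "ctdna_panel"), inherits(cfg, "sim_config"))
  amp <- panel$amplicons
  mut <- panel$mutations
  idlen <- panel_identifier_len(panel)
  bl <- nchar(cfg$barcode)
  if (cfg$read_len <= bl + 20L)
    config_error("read_len too short for barcode plus informative sequence")

  with_seed(cfg$seed, {
    ipc_n <- resolve_ipc_copies(cfg, panel)
    mut_n <- setNames(rep(0L, nrow(mut)), mut$mutation_id)
    if (!is.null(cfg$mutant_copies)) {
      unknown <- setdiff(names(cfg$mutant_copies), mut$mutation_id)
      if (length(unknown))
        config_error("mutant_copies for unknown mutations: ",
                     paste(unknown, collapse = ", "))
      mut_n[names(cfg$mutant_copies)] <- as.integer(cfg$mutant_copies)
    }

    # founder table: one aggregate WT row per amplicon, one row per mutant
    # and per IPC founder molecule
    truth <- list()
    templates <- character(0)
    if (nrow(amp)) {
      truth[["wt"]] <- data.frame(
        class = "WT", mutation_id = NA_character_, identifier = NA_character_,
        amplicon_id = amp$amplicon_id, n_founders = round(cfg$input_genomes),
        stringsAsFactors = FALSE)
      templates <- c(templates, amp$sequence)
    }
    for (i in seq_len(nrow(mut))) {
      id <- mut$mutation_id[i]
      if (mut_n[[id]] > 0L) {
        truth[[paste0("mut_", id)]] <- data.frame(
          class = "MUT", mutation_id = id, identifier = NA_character_,
          amplicon_id = mut$amplicon_id[i], n_founders = 1L,
          stringsAsFactors = FALSE)[rep(1L, mut_n[[id]]), ]
        templates <- c(templates, rep(mutant_template(panel, id), mut_n[[id]]))
      }
      if (ipc_n[[id]] > 0L) {
        # identifiers must differ from the reference at the span: an IPC
        # indistinguishable from a genomic mutant cannot act as a control
        arow <- amp[amp$amplicon_id == mut$amplicon_id[i], , drop = FALSE]
        ipc_ref <- substr(arow$sequence, arow$ipc_start + 1L, arow$ipc_end)
        idents <- rand_dna(ipc_n[[id]], idlen)
        while (any(bad <- idents == ipc_ref))
          idents[bad] <- rand_dna(sum(bad), idlen)
        truth[[paste0("ipc_", id)]] <- data.frame(
          class = "IPC", mutation_id = id, identifier = idents,
          amplicon_id = mut$amplicon_id[i], n_founders = 1L,
          stringsAsFactors = FALSE)
        templates <- c(templates,
                       vapply(idents, function(x) mutant_template(panel, id, x),
                              character(1), USE.NAMES = FALSE))
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(class = character(0), mutation_id = character(0),
                 identifier = character(0), amplicon_id = character(0),
                 n_founders = integer(0))
    rownames(truth) <- NULL

    # amplification and enrichment survival per founder row
    m_copies <- 2^cfg$pcr_cycles_pre
    p_surv <- ifelse(truth$class == "WT",
                     cfg$retain_wt^cfg$enrich_cycles,
                     cfg$retain_mut^cfg$enrich_cycles)
    survivors <- numeric(nrow(truth))
    for (i in seq_len(nrow(truth)))
      survivors[i] <- big_rbinom(truth$n_founders[i] * m_copies, p_surv[i])
    truth$surviving_molecules <- survivors

    # sequencing: sample read pairs from the surviving molecule pool
    n_reads <- cfg$reads_per_sample
    if (n_reads > 0L && sum(survivors) > 0) {
      counts <- as.vector(rmultinom(1L, n_reads, prob = survivors))
    } else counts <- rep(0L, nrow(truth))
    truth$reads <- counts
    read_founder <- sample(rep.int(seq_len(nrow(truth)), counts))

    molecules <- templates[read_founder]
    # accumulated substitution errors along each read's PCR lineage
    e_read <- 1 - (1 - cfg$per_base_error_per_cycle)^cfg$pcr_cycles_pre
    if (e_read > 0 && length(molecules)) {
      lens <- nchar(molecules)
      n_err <- rbinom(length(molecules), lens, e_read)
      for (i in which(n_err > 0L)) {
        pos <- sample.int(lens[i], n_err[i])
        for (p in pos) {
          cur <- substr(molecules[i], p, p)
          substr(molecules[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      }
    }

    mol_len <- nchar(molecules)
    if (length(molecules)) {
      r1_core <- substr(molecules, 1L, pmin(cfg$read_len - bl, mol_len))
      r1_seq <- paste0(cfg$barcode, r1_core)
      r2_seq <- revcomp(substr(molecules, pmax(1L, mol_len - cfg$read_len + 1L),
                               mol_len))
    } else {
      r1_seq <- character(0)
      r2_seq <- character(0)
    }
    if (length(mol_len) &&
        any((cfg$read_len - bl) + cfg$read_len - mol_len < 20L))
      warning("read pairs overlap by fewer than 20 bases for some molecules")
    ids <- if (length(molecules))
      sprintf("%s:%06d", sample_id, seq_along(molecules)) else character(0)
    sim <- structure(list(
      r1 = list(id = ids, seq = r1_seq, qual = strrep("I", nchar(r1_seq))),
      r2 = list(id = ids, seq = r2_seq, qual = strrep("I", nchar(r2_seq))),
      truth = truth, read_founder = read_founder,
      config = cfg, sample_id = sample_id
    ), class = "scoda_sim")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fastq(sim$r1, file.path(out_dir, paste0(sample_id, "_R1.fastq.gz")))
      write_fastq(sim$r2, file.path(out_dir, paste0(sample_id, "_R2.fastq.gz")))
      write.table(truth, file.path(out_dir, paste0(sample_id, "_truth.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    sim
  })
}

#' Simulate a titration series for one mutation
#'
#' One sample per (copy level, replicate) sharing a common wild-type
#' background configuration, emulating characterization experiments in which
#' synthetic mutant DNA is titrated into reference wild-type DNA at defined
#' copy numbers.
#'
#' @param panel a `ctdna_panel`.
#' @param cfg_base `sim_config` shared by all samples (its `mutant_copies`
#'   and `seed` are overridden).
#' @param mutation_id the titrated mutation.
#' @param copy_levels non-negative integer vector of input copy numbers.
#' @param replicates replicates per level.
#' @param seed base seed; sample `k` uses `seed + k`.
#' @return list with `samples` (list of `scoda_sim`) and `design`
#'   (data.frame sample_id, input_copies, replicate, seed).
#' @export
simulate_titration <- function(panel, cfg_base, mutation_id, copy_levels,
                               replicates = 3L, seed = 1L) {
  if (any(copy_levels < 0)) config_error("copy_levels must be >= 0")
  if (!mutation_id %in% panel$mutations$mutation_id)
    config_error("unknown mutation_id: ", mutation_id)
  design <- expand.grid(replicate = seq_len(replicates),
                        input_copies = as.integer(copy_levels))
  design <- design[, c("input_copies", "replicate")]
  design$sample_id <- sprintf("titr_c%d_r%d", design$input_copies, design$replicate)
  design$seed <- seed + seq_len(nrow(design))
  if (any(design$seed >= 2^31)) config_error("seed too large")
  samples <- lapply(seq_len(nrow(design)), function(k) {
    cfg <- cfg_base
    cfg$mutant_copies <- setNames(design$input_copies[k], mutation_id)
    if (design$input_copies[k] == 0L) cfg$mutant_copies <- NULL
    cfg$seed <- design$seed[k]
    simulate_sample(panel, cfg, sample_id = design$sample_id[k])
  })
  names(samples) <- design$sample_id
  list(samples = samples, design = design)
}

#' Simulate wild-type background runs
#'
#' Wild-type-only samples (no mutant copies, IPCs spiked as configured), as
#' used to estimate per-mutation background distributions and limits of
#' detection. At least two runs are required (a standard deviation is
#' undefined otherwise).
#'
#' @param panel a `ctdna_panel`.
#' @param cfg `sim_config` template (its `mutant_copies` and `seed` are
#'   overridden).
#' @param n_runs number of background runs (>= 2).
#' @param seed base seed; run `k` uses `seed + k`.
#' @return list of `scoda_sim`, one per run.
#' @export
simulate_background <- function(panel, cfg, n_runs, seed = 1L) {
  if (n_runs < 2L)
    config_error("n_runs must be >= 2: background SD is undefined for one run")
  lapply(seq_len(n_runs), function(k) {
    c2 <- cfg
    c2$mutant_copies <- NULL
    c2$seed <- seed + k
    simulate_sample(panel, c2, sample_id = sprintf("bg%02d", k))
  })
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads `list(id, seq, qual)` of equal lengths.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(reads$id)) {
    lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
    writeLines(lines, con)
  } else writeLines(character(0), con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (gzip ok).
#' @return `list(id, seq, qual)`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) config_error("FASTQ does not exist: ", path)
  fa <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = names(fa), seq = unname(as.character(fa)),
       qual = unname(as.character(S4Vectors::mcols(fa)$qualities)))
}
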