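# Independent oracles and small fixtures used across the suite. The oracles
# deliberately avoid the code paths they check: edit distance is a hand-rolled
# DP (not utils::adist), the merge oracle enumerates every overlap with
# substring comparisons, and IPC grouping uses tapply on the truth table.

# full dynamic-programming Levenshtein distance
oracle_edit_dist <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- 0:length(B)
  for (i in seq_along(A)) {
    cur <- numeric(length(B) + 1L)
    cur[1] <- i
    for (j in seq_along(B)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (A[i] != B[j]))
    }
    prev <- cur
  }
  prev[length(B) + 1L]
}

# mask the ipc identifier span of an amplicon row in both sequences (same
# convention the aligner documents), then take the DP distance
oracle_masked_dist <- function(seq, amp_row) {
  i0 <- amp_row$ipc_start; i1 <- amp_row$ipc_end
  filler <- strrep("A", i1 - i0)
  mask <- function(x) {
    if (nchar(x) < i1) return(x)
    paste0(substr(x, 1, i0), filler, substr(x, i1 + 1, nchar(x)))
  }
  oracle_edit_dist(mask(seq), mask(amp_row$sequence))
}

# exhaustive best-amplicon search: smallest masked DP distance, ties to the
# lexicographically smallest amplicon id
oracle_align <- function(seq, panel, max_edit_frac) {
  amp <- panel$amplicons[order(panel$amplicons$amplicon_id), , drop = FALSE]
  d <- vapply(seq_len(nrow(amp)),
              function(j) oracle_masked_dist(seq, amp[j, ]), numeric(1))
  best <- which.min(d)
  aligned <- d[best] <= max_edit_frac * nchar(seq)
  list(amplicon_id = if (aligned) amp$amplicon_id[best] else NA_character_,
       edit_distance = as.integer(d[best]), aligned = aligned)
}

# enumerate all overlaps >= min_overlap of r1 against revcomp(r2); report the
# longest admissible one and the merged sequence with read-1 bases kept in
# the overlap (the equal-quality convention)
oracle_merge <- function(r1, r2, min_overlap, max_mismatch_frac) {
  b <- panelcall::revcomp(r2)
  L1 <- nchar(r1); L2 <- nchar(b)
  for (ov in seq(min(L1, L2), 1L)) {
    if (ov < min_overlap) break
    x <- substr(r1, L1 - ov + 1L, L1)
    y <- substr(b, 1L, ov)
    mm <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (mm <= max_mismatch_frac * ov) {
      return(list(ok = TRUE, overlap = ov,
                  merged = paste0(substr(r1, 1L, L1 - ov), x,
                                  substr(b, ov + 1L, L2))))
    }
  }
  list(ok = FALSE, overlap = NA_integer_, merged = NA_character_)
}

# brute-force IPC grouping straight from the simulator truth table
oracle_bins_from_truth <- function(truth, mutation_id) {
  sub <- truth[truth$class == "IPC" & truth$mutation_id == mutation_id &
                 truth$reads > 0, , drop = FALSE]
  if (!nrow(sub)) return(integer(0))
  counts <- tapply(sub$reads, sub$identifier, sum)
  sort(as.integer(counts), decreasing = TRUE)
}

# compact two-amplicon panel used by most unit tests: three substitutions
# (two sharing an amplicon) and one 6-base deletion
mini_panel <- function(seed = 11L) {
  rows <- data.frame(
    mutation_id = c("GENE1 A100X", "GENE1 B101Y", "GENE2 C200Z", "GENE2 D201del"),
    gene = c("GENE1", "GENE1", "GENE2", "GENE2"),
    amplicon_id = c("AMP1", "AMP1", "AMP2", "AMP2"),
    offset = c(60L, 64L, 60L, 70L),
    ref_allele = c("G", "C", "T", "ACCGTA"),
    alt_allele = c("T", "A", "G", "-"),
    published_lod_pct = c(0.001, 0.001, 0.001, 0.001),
    stringsAsFactors = FALSE)
  synthesize_references(rows, identifier_len = 8L, seed = seed)
}

# small, fast simulation settings shared by the simulation-driven tests
mini_cfg <- function(...) {
  args <- list(...)
  defaults <- list(input_genomes = 500, ipc_copies = 30L,
                   pcr_cycles_pre = 6L, per_base_error_per_cycle = 1e-4,
                   enrich_cycles = 10L, retain_mut = 0.9,
                   retain_wt = 0.9 * 10^(-2 / 10),  # 100-fold enrichment
                   reads_per_sample = 3000L, read_len = 80L,
                   barcode = "ACGTAGCA", seed = 1L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# run one simulated sample through the read-processing front end
process_sim <- function(sim, panel, sample_name = "S1", ...) {
  process_reads(sim$r1, sim$r2, panel,
                barcodes = setNames(sim$config$barcode, sample_name), ...)
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                collapse = "")
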