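#' Bin IPC clusters by identifier, sample and mutation
#'
#' Internal positive control clusters are grouped by every unique combination
#' of random identifier, sample barcode and mutation; each bin corresponds to
#' (at least) one spiked IPC founder molecule and its size is the number of
#' clusters that founder produced.
#'
#' @param clusters classified-cluster data.frame (as from [process_reads()]):
#'   must have `label`, `identifier`, `mutation_id` and, when multi-sample,
#'   `sample`.
#' @return data.frame: `sample`, `mutation_id`, `identifier`,
#'   `cluster_count` (>= 1); bin sizes sum to the number of IPC clusters.
#' @export
bin_ipcs <- function(clusters) {
  empty <- data.frame(sample = character(0), mutation_id = character(0),
                      identifier = character(0), cluster_count = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(clusters)) return(empty)
  ipc <- clusters[clusters$label == "IPC", , drop = FALSE]
  if (!nrow(ipc)) return(empty)
  if (is.null(ipc$sample)) ipc$sample <- "sample1"
  agg <- aggregate(list(cluster_count = rep(1L, nrow(ipc))),
                   by = list(sample = ipc$sample,
                             mutation_id = ipc$mutation_id,
                             identifier = ipc$identifier),
                   FUN = sum)
  agg <- agg[order(agg$sample, agg$mutation_id, -agg$cluster_count), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("sample", "mutation_id", "identifier", "cluster_count")]
}

# expected number of distinct identifiers when s founders draw uniformly
# from 4^identifier_len possibilities
expected_distinct_identifiers <- function(s, identifier_len) {
  K <- 4^identifier_len
  K * (1 - (1 - 1 / K)^s)
}

# solve the zero-truncated Poisson mean-cluster equation
# lambda / (1 - exp(-lambda)) = m  for lambda (m >= 1)
ztp_lambda <- function(m) {
  if (m <= 1 + 1e-9) return(0)
  uniroot(function(l) l / (1 - exp(-l)) - m,
          lower = 1e-9, upper = max(2 * m, 10), tol = 1e-10)$root
}

#' Estimate the per-mutation cluster yield from IPC bins
#'
#' The cluster yield is the average number of sequenced clusters produced per
#' spiked founder molecule; it converts mutant cluster counts into input
#' copies. The naive estimate divides total IPC clusters by the number of
#' observed identifier bins. The corrected estimate (default) additionally
#' accounts for founders that produced no cluster (zero-truncated Poisson
#' inversion of the mean bin size) and for identifier collisions (inversion
#' of the expected-distinct-identifier curve), both of which bias the naive
#' founder count down and the naive yield up; the founder estimate is capped
#' at the known spike-in count.
#'
#' @param bins IPC bins from [bin_ipcs()].
#' @param mutation_id mutation to estimate (must match `bins$mutation_id`).
#' @param sample sample id (default: the single sample present).
#' @param spiked_ipc_copies known number of spiked IPC molecules (> 0).
#' @param identifier_len identifier length in bases (for the collision
#'   correction).
#' @param correct apply the dropout + collision corrections (default TRUE).
#' @return list: `yield` (clusters per founder; `NA` with
#'   `flag = "no_ipc_observed"` when no IPC cluster was seen), `clusters`,
#'   `bins_observed`, `founders_est`, `flag`.
#' @export
estimate_yield <- function(bins, mutation_id, sample = NULL,
                           spiked_ipc_copies, identifier_len = 8L,
                           correct = TRUE) {
  if (spiked_ipc_copies <= 0) config_error("spiked_ipc_copies must be > 0")
  sub <- bins[bins$mutation_id == mutation_id, , drop = FALSE]
  if (!is.null(sample)) sub <- sub[sub$sample == sample, , drop = FALSE]
  TT <- sum(sub$cluster_count)
  B <- nrow(sub)
  if (B == 0L)
    return(list(yield = NA_real_, clusters = 0L, bins_observed = 0L,
                founders_est = NA_real_, flag = "no_ipc_observed"))
  founders <- B
  if (correct) {
    lam <- ztp_lambda(TT / B)
    observed_frac <- if (lam > 0) 1 - exp(-lam) else 1
    founders <- min(B / observed_frac, spiked_ipc_copies)
    # identifier collisions: distinct identifiers undercount founders
    K <- 4^identifier_len
    if (founders < K)
      founders <- min(log(1 - founders / K) / log(1 - 1 / K),
                      spiked_ipc_copies)
  }
  list(yield = TT / founders, clusters = TT, bins_observed = B,
       founders_est = founders, flag = NA_character_)
}

#' Convert a mutant cluster count into input copies
#'
#' @param C mutant cluster count (>= 0).
#' @param Y cluster yield (clusters per founder molecule; `NA` when
#'   unavailable).
#' @return estimated input copies `C / Y` (`NA` when the yield is missing).
#' @export
estimate_copies <- function(C, Y) {
  ifelse(is.na(Y), NA_real_, C / Y)
}

#' Mutant abundance as a percentage of input genomes
#'
#' @param N estimated mutant input copies.
#' @param input_genomes haploid genome equivalents in the sample (> 0).
#' @return abundance in percent, `100 * N / input_genomes`.
#' @export
abundance <- function(N, input_genomes) {
  if (any(input_genomes <= 0)) config_error("input_genomes must be > 0")
  100 * N / input_genomes
}

#' Normalize copies to a 5 mL plasma volume
#'
#' @param N copies detected in the sample.
#' @param plasma_ml plasma volume the sample was extracted from (> 0).
#' @return copies per 5 mL of plasma, `N * 5 / plasma_ml`.
#' @export
normalize_per_5ml <- function(N, plasma_ml) {
  if (any(plasma_ml <= 0)) config_error("plasma_ml must be > 0")
  N * 5 / plasma_ml
}

#' Genome equivalents from input DNA mass
#'
#' @param dna_mass_ng input DNA mass in nanograms.
#' @param genome_mass_pg picograms per haploid genome (default 3.3).
#' @return haploid genome equivalents.
#' @export
input_genomes_from_mass <- function(dna_mass_ng, genome_mass_pg = 3.3) {
  dna_mass_ng * 1000 / genome_mass_pg
}

#' Quantify every panel mutation in one sample
#'
#' Combines the classified clusters of one sample into per-mutation
#' molecule-scale quantities: mutant cluster count `C`, IPC-derived cluster
#' yield `Y`, estimated input copies `N = C / Y`, abundance
#' `100 * N / input_genomes`, and plasma-normalized copies per 5 mL. IPC
#' spike-ins are synthetic molecules and are excluded from the abundance
#' denominator. Mutations with no observed IPC cluster are flagged and
#' reported as missing (not zero).
#'
#' @param clusters classified clusters of one sample (rows with other
#'   `sample` values are ignored when `sample` is given).
#' @param panel a `ctdna_panel`.
#' @param spiked_ipc_copies IPC molecules spiked per mutation (scalar or
#'   named vector).
#' @param input_genomes genome equivalents; computed from `dna_mass_ng` when
#'   missing.
#' @param dna_mass_ng input DNA mass (used when `input_genomes` is `NULL`).
#' @param plasma_ml plasma volume (default 5).
#' @param sample sample id to quantify (default: all rows).
#' @param correct_yield see [estimate_yield()].
#' @return data.frame (one row per panel mutation): `sample`, `mutation_id`,
#'   `gene`, `mutant_clusters`, `ipc_clusters`, `ipc_bins`, `yield`,
#'   `est_copies`, `input_genomes`, `abundance_pct`, `copies_per_5ml`,
#'   `flag`.
#' @export
quantify_sample <- function(clusters, panel, spiked_ipc_copies = 100L,
                            input_genomes = NULL, dna_mass_ng = NULL,
                            plasma_ml = 5, sample = NULL,
                            correct_yield = TRUE) {
  if (is.null(input_genomes)) {
    if (is.null(dna_mass_ng))
      config_error("supply input_genomes or dna_mass_ng")
    input_genomes <- input_genomes_from_mass(dna_mass_ng, panel$genome_mass_pg)
  }
  if (!is.null(sample) && !is.null(clusters$sample))
    clusters <- clusters[!is.na(clusters$sample) & clusters$sample == sample, ,
                         drop = FALSE]
  sample_id <- if (!is.null(sample)) sample else
    if (nrow(clusters) && !is.null(clusters$sample))
      clusters$sample[1] else "sample1"
  mut <- panel$mutations
  ipc_map <- if (length(spiked_ipc_copies) == 1L && is.null(names(spiked_ipc_copies)))
    setNames(rep(spiked_ipc_copies, nrow(mut)), mut$mutation_id) else
      spiked_ipc_copies
  bins <- bin_ipcs(clusters)
  idlen <- panel_identifier_len(panel)

  rows <- lapply(seq_len(nrow(mut)), function(i) {
    id <- mut$mutation_id[i]
    C <- sum(clusters$label == "MUT" & clusters$mutation_id == id,
             na.rm = TRUE)
    ys <- estimate_yield(bins, id, sample = NULL,
                         spiked_ipc_copies = ipc_map[[id]],
                         identifier_len = idlen, correct = correct_yield)
    N <- estimate_copies(C, ys$yield)
    data.frame(
      sample = sample_id, mutation_id = id, gene = mut$gene[i],
      mutant_clusters = C, ipc_clusters = ys$clusters,
      ipc_bins = ys$bins_observed, yield = ys$yield, est_copies = N,
      input_genomes = input_genomes,
      abundance_pct = if (is.na(N)) NA_real_ else abundance(N, input_genomes),
      copies_per_5ml = if (is.na(N)) NA_real_ else normalize_per_5ml(N, plasma_ml),
      flag = ys$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
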