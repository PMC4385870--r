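#' Estimate per-mutation limits of detection from wild-type background runs
#'
#' For each panel mutation, the background abundance observed over multiple
#' wild-type runs gives a mean and sample standard deviation (n - 1
#' denominator); the limit of detection is the greater of the single-copy
#' allele fraction of the assay's standard input
#' (`100 / standard_input_genomes` percent) and the mean plus three standard
#' deviations of the background. Backgrounds are estimated per mutation, not
#' pooled.
#'
#' @param background_quants per-sample quantitation tables from
#'   [quantify_sample()], either a list or a single stacked data.frame with a
#'   `sample` column. At least two runs per mutation are required.
#' @param standard_input_genomes genome equivalents of the assay's standard
#'   input (> 0), defining the single-copy floor.
#' @return data.frame (`lod_table`): `mutation_id`, `background_mean`,
#'   `background_sd`, `n_background_runs`, `single_copy_fraction`, `lod_pct`
#'   (all percentages).
#' @export
estimate_lod <- function(background_quants, standard_input_genomes) {
  if (standard_input_genomes <= 0)
    config_error("standard_input_genomes must be > 0")
  bg <- if (is.data.frame(background_quants)) background_quants else
    do.call(rbind, background_quants)
  if (is.null(bg) || !nrow(bg)) config_error("no background quantitations")
  n_runs <- length(unique(bg$sample))
  if (n_runs < 2L)
    config_error("at least 2 background runs are required (SD undefined)")
  single_copy <- 100 / standard_input_genomes
  rows <- lapply(split(bg, bg$mutation_id), function(d) {
    a <- d$abundance_pct[!is.na(d$abundance_pct)]
    if (length(a) < 2L)
      config_error("fewer than 2 evaluable background runs for ",
                   d$mutation_id[1])
    mu <- mean(a); s <- sd(a)
    data.frame(mutation_id = d$mutation_id[1], background_mean = mu,
               background_sd = s, n_background_runs = length(a),
               single_copy_fraction = single_copy,
               lod_pct = max(single_copy, mu + 3 * s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mutation_id), , drop = FALSE]
}

#' Call mutations in a quantified sample
#'
#' A mutation is called positive only when at least a single mutant input
#' copy was observed (`est_copies >= 1`) and its abundance is strictly
#' greater than the mutation's limit of detection. Every panel mutation is
#' reported: negatives explicitly, and mutations whose yield was unavailable
#' as `"not_evaluable"` (never as negative). The raw margin to the LOD is
#' included so near-LOD signals remain inspectable.
#'
#' @param quant one sample's quantitation table from [quantify_sample()].
#' @param lods LOD table from [estimate_lod()]; must cover every mutation in
#'   `quant`.
#' @return data.frame: `sample`, `mutation_id`, `gene`, `est_copies`,
#'   `abundance_pct`, `copies_per_5ml`, `lod_pct`, `margin_pct`, `positive`
#'   (logical, `NA` when not evaluable), `call` (`"positive"`, `"negative"`,
#'   `"not_evaluable"`).
#' @export
call_mutations <- function(quant, lods) {
  missing_lod <- setdiff(quant$mutation_id, lods$mutation_id)
  if (length(missing_lod))
    config_error("LOD table lacks mutations: ",
                 paste(missing_lod, collapse = ", "))
  lod <- lods$lod_pct[match(quant$mutation_id, lods$mutation_id)]
  evaluable <- is.na(quant$flag) & !is.na(quant$est_copies)
  positive <- ifelse(evaluable,
                     quant$est_copies >= 1 & quant$abundance_pct > lod,
                     NA)
  data.frame(
    sample = quant$sample, mutation_id = quant$mutation_id,
    gene = quant$gene, est_copies = quant$est_copies,
    abundance_pct = quant$abundance_pct,
    copies_per_5ml = quant$copies_per_5ml,
    lod_pct = lod,
    margin_pct = quant$abundance_pct - lod,
    positive = positive,
    call = ifelse(!evaluable, "not_evaluable",
                  ifelse(positive, "positive", "negative")),
    stringsAsFactors = FALSE)
}
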