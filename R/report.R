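#' Titration characterization table
#'
#' One row per titration sample relating known input copies to the copies the
#' assay detected and the resulting call. Emulating the published
#' characterization plots, rows below `min_input` copies are excluded from
#' the titration table (sampling fluctuation dominates there) and zero-input
#' rows are routed to a separate background summary; nothing is silently
#' dropped.
#'
#' @param design data.frame with `sample_id` and `input_copies` (the
#'   simulator's titration design, or declared synthetic spike-in inputs).
#' @param quants stacked per-sample quantitation for the titrated mutation
#'   (rows of [quantify_sample()] output filtered to one `mutation_id`).
#' @param calls optional stacked call tables ([call_mutations()]) for the same
#'   mutation; adds a `called` column.
#' @param min_input smallest input copy number kept in the titration table
#'   (default 10).
#' @return list: `titration` (input >= min_input), `background` (input 0),
#'   `excluded` (0 < input < min_input).
#' @export
titration_report <- function(design, quants, calls = NULL, min_input = 10) {
  if (length(unique(quants$mutation_id)) > 1L)
    config_error("quants must be filtered to a single mutation")
  tab <- merge(design[, c("sample_id", "input_copies")],
               quants[, c("sample", "mutation_id", "est_copies",
                          "abundance_pct")],
               by.x = "sample_id", by.y = "sample", all.x = TRUE)
  if (!is.null(calls)) {
    tab <- merge(tab, calls[, c("sample", "mutation_id", "call")],
                 by.x = c("sample_id", "mutation_id"),
                 by.y = c("sample", "mutation_id"), all.x = TRUE)
    tab$called <- tab$call == "positive"
    tab$call <- NULL
  }
  tab <- tab[order(tab$input_copies, tab$sample_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(titration = tab[tab$input_copies >= min_input, , drop = FALSE],
       background = tab[tab$input_copies == 0, , drop = FALSE],
       excluded = tab[tab$input_copies > 0 & tab$input_copies < min_input, ,
                      drop = FALSE])
}

#' Concordance between two assays' per-patient calls
#'
#' Compares two call columns (e.g. this assay versus an orthogonal PCR assay
#' on the same specimens, or tissue versus plasma at the mutation level). A
#' demonstrated discordance requires both assays to report a result that
#' differs; a comparator marked not-analyzed does not count against
#' concordance, and the stricter evaluable-only fraction is also reported,
#' together with per-direction discordance counts.
#'
#' @param inputs data.frame with `patient_id` (unique), `assay_a`, `assay_b`:
#'   each a mutation label, `"WT"`, or a not-analyzed marker.
#' @param not_analyzed values (besides `NA`) meaning the assay was not run
#'   (default `"Not analyzed"`).
#' @return list: `n_total`, `n_evaluable` (both assays reported),
#'   `n_discordant`, `n_concordant` (= total - discordant), `pct_concordant`,
#'   `n_concordant_evaluable`, `pct_concordant_evaluable`, `n_a_mut_b_wt`,
#'   `n_b_mut_a_wt` (directional: one assay mutant, the other wild-type),
#'   `discordant_patients`.
#' @export
concordance <- function(inputs, not_analyzed = "Not analyzed") {
  if (!nrow(inputs)) config_error("empty concordance input")
  if (anyDuplicated(inputs$patient_id))
    config_error("patient_id must be unique")
  a <- trimws(as.character(inputs$assay_a))
  b <- trimws(as.character(inputs$assay_b))
  rep_a <- !is.na(a) & !(a %in% not_analyzed)
  rep_b <- !is.na(b) & !(b %in% not_analyzed)
  evaluable <- rep_a & rep_b
  disc <- evaluable & a != b
  n_total <- nrow(inputs)
  n_disc <- sum(disc)
  n_eval <- sum(evaluable)
  list(
    n_total = n_total,
    n_evaluable = n_eval,
    n_discordant = n_disc,
    n_concordant = n_total - n_disc,
    pct_concordant = 100 * (n_total - n_disc) / n_total,
    n_concordant_evaluable = n_eval - n_disc,
    pct_concordant_evaluable = if (n_eval) 100 * (n_eval - n_disc) / n_eval else NA_real_,
    n_a_mut_b_wt = sum(disc & a != "WT" & b == "WT"),
    n_b_mut_a_wt = sum(disc & b != "WT" & a == "WT"),
    discordant_patients = inputs$patient_id[disc]
  )
}

#' Packaged tissue qPCR-vs-assay concordance fixture
#'
#' A transcription of the published 19-patient KRAS tumor-tissue comparison
#' (this assay versus a conventional quantitative PCR method), for the
#' concordance worked example.
#'
#' @return data.frame: `patient_id`, `assay_a` (this assay's KRAS call),
#'   `assay_a_abundance_pct`, `assay_b` (conventional qPCR call).
#' @export
concordance_fixture <- function() {
  read.delim(system.file("extdata", "table3_concordance.tsv",
                         package = "panelcall"),
             comment.char = "#", stringsAsFactors = FALSE,
             colClasses = "character")
}

#' Assemble a longitudinal monitoring series for one patient
#'
#' Merges per-timepoint call tables into one plot-ready series (copies per
#' 5 mL of plasma over days from surgery, day 0 = surgery, with serum CEA and
#' clinical events attached when given) and flags two clinically meaningful
#' patterns per mutation: re-emergence (detected, then undetected at a later
#' timepoint, then detected again) and new-allele events (a mutation first
#' detected after surgery that was absent pre-operatively).
#'
#' @param calls stacked call tables with a `day` column (days from surgery;
#'   pre-operative draws have `day <= 0`) and a `patient_id` column.
#' @param annotations optional data.frame `patient_id`, `day`, `cea_ng_ml`,
#'   `event` merged onto the series.
#' @return list: `series` (per patient/mutation/day: copies_per_5ml,
#'   positive, plus annotations) and `flags` (per patient/mutation:
#'   `re_emergence`, `new_allele`).
#' @export
monitoring_series <- function(calls, annotations = NULL) {
  need <- c("patient_id", "day", "mutation_id", "positive", "copies_per_5ml")
  missing <- setdiff(need, names(calls))
  if (length(missing))
    config_error("calls lack columns: ", paste(missing, collapse = ", "))
  key <- interaction(calls$patient_id, calls$mutation_id, drop = TRUE)
  for (d in split(calls$day, key)) {
    if (anyDuplicated(d)) config_error("duplicate timepoints in series")
    if (is.unsorted(d)) config_error("timepoints must be provided sorted")
  }
  series <- calls[order(calls$patient_id, calls$mutation_id, calls$day),
                  intersect(c(need, "abundance_pct", "lod_pct", "call"),
                            names(calls)), drop = FALSE]
  if (!is.null(annotations))
    series <- merge(series, annotations, by = c("patient_id", "day"),
                    all.x = TRUE, sort = FALSE)
  flags <- do.call(rbind, lapply(split(series, interaction(
    series$patient_id, series$mutation_id, drop = TRUE)), function(d) {
      d <- d[order(d$day), ]
      pos <- d$positive %in% TRUE
      # detected, later undetected, later detected again
      re <- FALSE
      if (length(pos) >= 3L) {
        first_pos <- match(TRUE, pos)
        if (!is.na(first_pos)) {
          gap <- match(FALSE, pos[-seq_len(first_pos)]) + first_pos
          re <- !is.na(gap) && any(pos[-seq_len(gap)])
        }
      }
      pre <- d$day <= 0
      new_allele <- any(pos & !pre) && !any(pos & pre)
      data.frame(patient_id = d$patient_id[1], mutation_id = d$mutation_id[1],
                 re_emergence = re, new_allele = new_allele,
                 stringsAsFactors = FALSE)
    }))
  rownames(flags) <- NULL
  list(series = series, flags = flags)
}
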