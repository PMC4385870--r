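#' Mutation panel objects
#'
#' A `ctdna_panel` bundles the mutation catalogue of a hotspot assay with its
#' amplicon reference sequences. Each mutation is a replacement
#' `(offset, ref_allele, alt_allele)` on one amplicon, with `offset` 0-based
#' and spans half-open; deletions have an empty `alt_allele` (written `"-"` in
#' the TSV). Each amplicon carries primer spans at both ends and an
#' `ipc_identifier_span`: the interval where internal positive control (IPC)
#' molecules carry a random N-mer instead of reference sequence, which is how
#' spiked synthetic molecules are distinguished from genomic DNA downstream.
#'
#' @param mutations data.frame with columns `mutation_id`, `gene`,
#'   `amplicon_id`, `offset`, `ref_allele`, `alt_allele`,
#'   `published_lod_pct`.
#' @param amplicons data.frame with columns `amplicon_id`, `sequence`,
#'   `primer_fwd_start`, `primer_fwd_end`, `primer_rev_start`,
#'   `primer_rev_end`, `ipc_start`, `ipc_end` (all 0-based half-open).
#' @param genome_mass_pg mass of one haploid genome in picograms, used to
#'   convert input DNA mass to genome equivalents (default 3.3).
#' @return object of class `ctdna_panel`.
#' @export
new_panel <- function(mutations, amplicons, genome_mass_pg = 3.3) {
  mut_cols <- c("mutation_id", "gene", "amplicon_id", "offset",
                "ref_allele", "alt_allele", "published_lod_pct")
  amp_cols <- c("amplicon_id", "sequence", "primer_fwd_start", "primer_fwd_end",
                "primer_rev_start", "primer_rev_end", "ipc_start", "ipc_end")
  missing_m <- setdiff(mut_cols, names(mutations))
  missing_a <- setdiff(amp_cols, names(amplicons))
  if (length(missing_m)) config_error("mutation table lacks columns: ",
                                      paste(missing_m, collapse = ", "))
  if (length(missing_a)) config_error("amplicon table lacks columns: ",
                                      paste(missing_a, collapse = ", "))
  mutations <- as.data.frame(mutations)[, mut_cols]
  amplicons <- as.data.frame(amplicons)[, amp_cols]
  mutations$offset <- as.integer(mutations$offset)
  mutations$alt_allele[mutations$alt_allele %in% "-"] <- ""
  for (col in c("primer_fwd_start", "primer_fwd_end", "primer_rev_start",
                "primer_rev_end", "ipc_start", "ipc_end"))
    amplicons[[col]] <- as.integer(amplicons[[col]])
  structure(
    list(mutations = mutations, amplicons = amplicons,
         genome_mass_pg = genome_mass_pg),
    class = "ctdna_panel"
  )
}

#' @export
print.ctdna_panel <- function(x, ...) {
  cat(sprintf("ctdna_panel: %d mutations in %d genes across %d amplicons\n",
              nrow(x$mutations), length(unique(x$mutations$gene)),
              nrow(x$amplicons)))
  cat(sprintf("genome mass: %.2f pg/haploid genome; identifier length: %d\n",
              x$genome_mass_pg, panel_identifier_len(x)))
  invisible(x)
}

# identifier length implied by the ipc spans (validated to be uniform)
panel_identifier_len <- function(panel) {
  if (nrow(panel$amplicons) == 0L) return(0L)
  as.integer(unique(panel$amplicons$ipc_end - panel$amplicons$ipc_start))[1]
}

#' Validate a panel against its structural invariants
#'
#' Report-only: returns a character vector of human-readable violations
#' (empty means valid). Checked invariants: unique mutation ids; every
#' mutation resolves to an amplicon; `ref_allele != alt_allele`; the reference
#' allele matches the amplicon sequence at its offset;
#' `offset + nchar(ref_allele) <= amplicon length`; primer and IPC spans in
#' bounds; the IPC identifier span is disjoint from (and precedes) every
#' variant locus on its amplicon; sequences over A/C/G/T; uniform identifier
#' length; and pairwise-distinct mutant amplicon sequences (so every mutation
#' is unambiguously classifiable).
#'
#' @param panel a `ctdna_panel`.
#' @return character vector of violations (length 0 if valid).
#' @export
validate_panel <- function(panel) {
  v <- character(0)
  mut <- panel$mutations
  amp <- panel$amplicons
  if (anyDuplicated(mut$mutation_id))
    v <- c(v, paste("duplicate mutation_id:",
                    paste(unique(mut$mutation_id[duplicated(mut$mutation_id)]),
                          collapse = ", ")))
  if (anyDuplicated(amp$amplicon_id))
    v <- c(v, "duplicate amplicon_id")
  if (nrow(amp) && any(grepl("[^ACGT]", amp$sequence)))
    v <- c(v, "amplicon sequences contain non-ACGT characters")
  idlen <- unique(amp$ipc_end - amp$ipc_start)
  if (length(idlen) > 1L)
    v <- c(v, "ipc identifier span length differs between amplicons")
  for (i in seq_len(nrow(amp))) {
    a <- amp[i, ]
    L <- nchar(a$sequence)
    spans <- rbind(c(a$primer_fwd_start, a$primer_fwd_end),
                   c(a$primer_rev_start, a$primer_rev_end),
                   c(a$ipc_start, a$ipc_end))
    if (any(spans[, 1] < 0L) || any(spans[, 2] > L) || any(spans[, 1] >= spans[, 2]))
      v <- c(v, sprintf("amplicon %s: primer/ipc span out of bounds", a$amplicon_id))
  }
  idx <- match(mut$amplicon_id, amp$amplicon_id)
  for (i in seq_len(nrow(mut))) {
    m <- mut[i, ]
    if (is.na(idx[i])) {
      v <- c(v, sprintf("mutation %s: amplicon %s not in panel",
                        m$mutation_id, m$amplicon_id))
      next
    }
    a <- amp[idx[i], ]
    L <- nchar(a$sequence)
    if (m$ref_allele == m$alt_allele)
      v <- c(v, sprintf("mutation %s: ref_allele equals alt_allele", m$mutation_id))
    if (m$offset < 0L || m$offset + nchar(m$ref_allele) > L) {
      v <- c(v, sprintf("mutation %s: variant span outside amplicon", m$mutation_id))
      next
    }
    seen <- substr(a$sequence, m$offset + 1L, m$offset + nchar(m$ref_allele))
    if (!identical(seen, m$ref_allele))
      v <- c(v, sprintf("mutation %s: ref_allele %s does not match amplicon (%s)",
                        m$mutation_id, m$ref_allele, seen))
    if (m$offset < a$ipc_end)
      v <- c(v, sprintf("mutation %s: variant locus overlaps or precedes the ipc identifier span",
                        m$mutation_id))
  }
  # distinct mutant templates: identical mutant sequences cannot be told apart
  ok <- !is.na(idx)
  ok[ok] <- mut$offset[ok] >= 0L &
    mut$offset[ok] + nchar(mut$ref_allele[ok]) <= nchar(amp$sequence[idx[ok]])
  if (any(ok)) {
    tmpl <- vapply(which(ok), function(i) {
      substitute_allele(amp$sequence[idx[i]], mut$offset[i],
                        mut$ref_allele[i], mut$alt_allele[i])
    }, character(1))
    if (anyDuplicated(tmpl))
      v <- c(v, paste("indistinguishable mutant sequences:",
                      paste(mut$mutation_id[ok][duplicated(tmpl) | duplicated(tmpl, fromLast = TRUE)],
                            collapse = ", ")))
  }
  v
}

assert_valid_panel <- function(panel) {
  v <- validate_panel(panel)
  if (length(v)) config_error("invalid panel:\n  ", paste(v, collapse = "\n  "))
  invisible(panel)
}

#' Load a panel from a TSV mutation table, FASTA references and span sidecar
#'
#' The mutation table is tab-separated with columns `mutation_id`, `gene`,
#' `amplicon_id`, `offset`, `ref_allele`, `alt_allele`, `published_lod_pct`
#' (coordinates 0-based half-open; deletions use `alt_allele = "-"`;
#' `published_lod_pct` is assay metadata in percent, reference only).
#' Amplicon sequences come from `fasta_path`; primer and IPC identifier spans
#' from a JSON sidecar keyed by amplicon id.
#'
#' @param panel_path path to the mutation TSV.
#' @param fasta_path path to the amplicon FASTA.
#' @param spans_path path to the spans JSON sidecar.
#' @param genome_mass_pg picograms of DNA per haploid genome (default 3.3).
#' @return validated `ctdna_panel`.
#' @export
load_panel <- function(panel_path, fasta_path, spans_path,
                       genome_mass_pg = 3.3) {
  for (p in c(panel_path, fasta_path, spans_path))
    if (!file.exists(p)) config_error("panel input does not exist: ", p)
  mut <- read.delim(panel_path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (nrow(mut)) {
    mut$offset <- as.integer(mut$offset)
    mut$published_lod_pct <- as.numeric(mut$published_lod_pct)
  } else {
    mut$offset <- integer(0)
    mut$published_lod_pct <- numeric(0)
  }
  fa <- Biostrings::readDNAStringSet(fasta_path)
  spans <- jsonlite::read_json(spans_path, simplifyVector = TRUE)
  ids <- names(fa)
  get_span <- function(id, what) {
    s <- spans$amplicons[[id]][[what]]
    if (is.null(s) || length(s) != 2L)
      config_error("spans sidecar lacks ", what, " for amplicon ", id)
    as.integer(s)
  }
  amp <- data.frame(
    amplicon_id = ids,
    sequence = as.character(fa),
    stringsAsFactors = FALSE
  )
  sp <- lapply(ids, function(id) c(get_span(id, "primer_fwd"),
                                   get_span(id, "primer_rev"),
                                   get_span(id, "ipc_identifier")))
  sp <- do.call(rbind, sp)
  if (is.null(sp)) sp <- matrix(integer(0), 0, 6)
  amp$primer_fwd_start <- sp[, 1]; amp$primer_fwd_end <- sp[, 2]
  amp$primer_rev_start <- sp[, 3]; amp$primer_rev_end <- sp[, 4]
  amp$ipc_start <- sp[, 5]; amp$ipc_end <- sp[, 6]
  # amplicons with no mutation are allowed; mutations without amplicon are not
  missing_amp <- setdiff(mut$amplicon_id, amp$amplicon_id)
  if (length(missing_amp))
    config_error("mutation table references amplicons absent from FASTA: ",
                 paste(missing_amp, collapse = ", "))
  panel <- new_panel(mut, amp, genome_mass_pg = genome_mass_pg)
  assert_valid_panel(panel)
}

#' Write a panel back to TSV + FASTA + JSON
#'
#' Inverse of [load_panel()]; round-trips all panel content.
#'
#' @param panel a `ctdna_panel`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem (default `"panel"`).
#' @return invisibly, the three file paths.
#' @export
write_panel <- function(panel, dir, stem = "panel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  fasta <- file.path(dir, paste0(stem, "_amplicons.fasta"))
  spans <- file.path(dir, paste0(stem, "_spans.json"))
  mut <- panel$mutations
  mut$alt_allele[mut$alt_allele == ""] <- "-"
  con <- file(tsv, "w")
  writeLines("# coordinates are 0-based half-open; alt_allele '-' denotes a deletion", con)
  suppressWarnings(write.table(mut, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  fa <- Biostrings::DNAStringSet(setNames(panel$amplicons$sequence,
                                          panel$amplicons$amplicon_id))
  Biostrings::writeXStringSet(fa, fasta)
  sp <- lapply(seq_len(nrow(panel$amplicons)), function(i) {
    a <- panel$amplicons[i, ]
    list(primer_fwd = c(a$primer_fwd_start, a$primer_fwd_end),
         primer_rev = c(a$primer_rev_start, a$primer_rev_end),
         ipc_identifier = c(a$ipc_start, a$ipc_end))
  })
  names(sp) <- panel$amplicons$amplicon_id
  jsonlite::write_json(list(amplicons = sp), spans, auto_unbox = FALSE)
  invisible(c(tsv = tsv, fasta = fasta, spans = spans))
}

#' Synthesize amplicon reference sequences for a mutation table
#'
#' The assay's true primer and amplicon sequences are proprietary, so for a
#' self-contained panel this generates seeded random amplicons consistent
#' with every mutation's `(offset, ref_allele)`: reference alleles are written
#' into otherwise random sequence, and overlapping reference spans from
#' different mutations must agree (a conflict is an error). Regenerating with
#' the same seed is bit-identical. Layout per amplicon: forward primer
#' `[0, primer_len)`, IPC identifier span `[primer_len + 4,
#' primer_len + 4 + identifier_len)`, variant loci (which must start at or
#' after `min_variant_offset`), reverse primer at the 3' end.
#'
#' @param panel_rows mutation table as in [load_panel()] (`alt_allele` may use
#'   `"-"` for deletions).
#' @param identifier_len length of the IPC random identifier (>= 6).
#' @param seed integer seed; same seed, same sequences.
#' @param primer_len primer span length at each end.
#' @param min_variant_offset smallest allowed variant offset; amplicons are
#'   sized so every variant keeps at least `tail_pad` bases plus the reverse
#'   primer 3' of it.
#' @param tail_pad bases kept between the last variant base and the reverse
#'   primer.
#' @param genome_mass_pg passed through to the panel.
#' @return validated `ctdna_panel`.
#' @export
synthesize_references <- function(panel_rows, identifier_len = 8L, seed,
                                  primer_len = 20L, min_variant_offset = 60L,
                                  tail_pad = 20L, genome_mass_pg = 3.3) {
  if (identifier_len < 6L) config_error("identifier_len must be >= 6")
  rows <- as.data.frame(panel_rows)
  rows$alt_allele[rows$alt_allele %in% "-"] <- ""
  rows$offset <- as.integer(rows$offset)
  if (nrow(rows) && any(rows$offset < min_variant_offset))
    config_error("variant offsets must be >= min_variant_offset (",
                 min_variant_offset, ")")
  ipc_start <- primer_len + 4L
  ipc_end <- ipc_start + identifier_len
  amp_ids <- sort(unique(rows$amplicon_id))
  if (!length(amp_ids)) amp_ids <- character(0)
  amps <- with_seed(seed, {
    lapply(amp_ids, function(aid) {
      sub <- rows[rows$amplicon_id == aid, , drop = FALSE]
      need <- max(sub$offset + nchar(sub$ref_allele))
      len <- need + tail_pad + primer_len
      base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # pin reference alleles; overlapping pins must agree
      pinned <- rep(NA_character_, len)
      for (j in seq_len(nrow(sub))) {
        ref <- strsplit(sub$ref_allele[j], "")[[1]]
        pos <- sub$offset[j] + seq_along(ref)
        clash <- !is.na(pinned[pos]) & pinned[pos] != ref
        if (any(clash))
          config_error("conflicting reference alleles on amplicon ", aid,
                       " at offsets ", paste(pos[clash] - 1L, collapse = ", "))
        pinned[pos] <- ref
      }
      base[!is.na(pinned)] <- pinned[!is.na(pinned)]
      data.frame(amplicon_id = aid, sequence = paste(base, collapse = ""),
                 primer_fwd_start = 0L, primer_fwd_end = primer_len,
                 primer_rev_start = len - primer_len, primer_rev_end = len,
                 ipc_start = ipc_start, ipc_end = ipc_end,
                 stringsAsFactors = FALSE)
    })
  })
  amp <- if (length(amps)) do.call(rbind, amps) else
    data.frame(amplicon_id = character(0), sequence = character(0),
               primer_fwd_start = integer(0), primer_fwd_end = integer(0),
               primer_rev_start = integer(0), primer_rev_end = integer(0),
               ipc_start = integer(0), ipc_end = integer(0))
  panel <- new_panel(rows, amp, genome_mass_pg = genome_mass_pg)
  assert_valid_panel(panel)
}

#' The packaged 46-mutation panel
#'
#' Loads the panel shipped with the package: the published 46-mutation
#' catalogue (BRAF, EGFR, KRAS, PIK3CA hotspots with their published
#' limit-of-detection metadata) over synthetic amplicon references
#' (regenerable with `synthesize_references(seed = 7)`).
#'
#' @param genome_mass_pg picograms per haploid genome (default 3.3).
#' @return validated `ctdna_panel` with 46 mutations in 4 genes.
#' @export
default_panel <- function(genome_mass_pg = 3.3) {
  load_panel(
    system.file("extdata", "table1_panel.tsv", package = "panelcall"),
    system.file("extdata", "table1_amplicons_synthetic.fasta", package = "panelcall"),
    system.file("extdata", "table1_spans.json", package = "panelcall"),
    genome_mass_pg = genome_mass_pg
  )
}

# amplicon row for a mutation id (single row data.frame)
panel_amplicon_for <- function(panel, mutation_id) {
  m <- panel$mutations[panel$mutations$mutation_id == mutation_id, , drop = FALSE]
  if (nrow(m) != 1L) config_error("unknown mutation_id: ", mutation_id)
  panel$amplicons[panel$amplicons$amplicon_id == m$amplicon_id, , drop = FALSE]
}

#' Mutant amplicon sequence for a panel mutation
#'
#' @param panel a `ctdna_panel`.
#' @param mutation_id one of `panel$mutations$mutation_id`.
#' @param identifier optional identifier sequence written into the amplicon's
#'   IPC span (producing an IPC molecule template); `NULL` for a genomic
#'   mutant template.
#' @return single character string.
#' @export
mutant_template <- function(panel, mutation_id, identifier = NULL) {
  m <- panel$mutations[panel$mutations$mutation_id == mutation_id, , drop = FALSE]
  a <- panel_amplicon_for(panel, mutation_id)
  s <- a$sequence
  if (!is.null(identifier)) {
    if (nchar(identifier) != a$ipc_end - a$ipc_start)
      config_error("identifier length must be ", a$ipc_end - a$ipc_start)
    s <- paste0(substr(s, 1L, a$ipc_start), identifier,
                substr(s, a$ipc_end + 1L, nchar(s)))
  }
  substitute_allele(s, m$offset, m$ref_allele, m$alt_allele)
}

#' Packaged sample barcode set
#'
#' Eight-base inline barcodes with minimum pairwise Hamming distance 3,
#' supporting pooling of six or more samples per sequencing run.
#'
#' @param n number of barcodes to return (max 12).
#' @return named character vector (`S1`, `S2`, ...).
#' @export
default_barcodes <- function(n = 6L) {
  bc <- readLines(system.file("extdata", "barcodes8.txt", package = "panelcall"))
  bc <- bc[nzchar(bc) & !startsWith(bc, "#")]
  if (n > length(bc)) config_error("only ", length(bc), " packaged barcodes")
  setNames(bc[seq_len(n)], paste0("S", seq_len(n)))
}
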