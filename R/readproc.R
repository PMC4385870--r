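#' Merge paired-end reads by their best ungapped overlap
#'
#' Read 2 is reverse-complemented and slid against read 1; the merge uses the
#' longest overlap of at least `min_overlap` bases whose mismatch fraction is
#' at most `max_mismatch_frac`. Disagreeing bases in the overlap are resolved
#' toward the higher-quality base (ties toward read 1); merged qualities take
#' the per-base maximum. Pairs with no admissible overlap fail (they are
#' counted, never silently dropped).
#'
#' @param r1_seq,r2_seq character vectors of read sequences (read 2 in
#'   sequencing orientation).
#' @param r1_qual,r2_qual optional Phred+33 quality strings (default: constant
#'   high quality).
#' @param min_overlap minimum admissible overlap length (default 20).
#' @param max_mismatch_frac maximum mismatch fraction within the overlap
#'   (default 0.1).
#' @return data.frame with one row per pair: `merged`, `qual`, `overlap`,
#'   `mismatches`, `ok`. Failed pairs have `ok = FALSE` and `NA` sequence.
#' @export
merge_pairs <- function(r1_seq, r2_seq, r1_qual = NULL, r2_qual = NULL,
                        min_overlap = 20L, max_mismatch_frac = 0.1) {
  n <- length(r1_seq)
  if (length(r2_seq) != n) config_error("r1 and r2 must have equal length")
  if (n == 0L)
    return(data.frame(merged = character(0), qual = character(0),
                      overlap = integer(0), mismatches = integer(0),
                      ok = logical(0)))
  if (any(!nzchar(r1_seq)) || any(!nzchar(r2_seq)))
    config_error("reads must be non-empty")
  min_overlap <- as.integer(min_overlap)
  if (is.null(r1_qual)) r1_qual <- strrep("I", nchar(r1_seq))
  if (is.null(r2_qual)) r2_qual <- strrep("I", nchar(r2_seq))
  b <- revcomp(r2_seq)
  bq <- str_rev(r2_qual)

  merged <- rep(NA_character_, n)
  qual <- rep(NA_character_, n)
  overlap <- rep(NA_integer_, n)
  mism <- rep(NA_integer_, n)

  grp <- split(seq_len(n), paste(nchar(r1_seq), nchar(b)))
  for (ix in grp) {
    L1 <- nchar(r1_seq[ix[1]]); L2 <- nchar(b[ix[1]])
    A <- seq_raw_matrix(r1_seq[ix]); B <- seq_raw_matrix(b[ix])
    QA <- seq_raw_matrix(r1_qual[ix]); QB <- seq_raw_matrix(bq[ix])
    if (min(L1, L2) < min_overlap) next
    remaining <- seq_along(ix)
    for (ov in seq.int(min(L1, L2), min_overlap, by = -1L)) {
      if (!length(remaining)) break
      a_cols <- (L1 - ov + 1L):L1
      b_cols <- 1:ov
      ne <- A[remaining, a_cols, drop = FALSE] != B[remaining, b_cols, drop = FALSE]
      mm <- rowSums(ne)
      hit <- mm <= max_mismatch_frac * ov
      if (any(hit)) {
        rows <- remaining[hit]
        # consensus overlap: keep read-1 base unless read 2 has higher quality
        a_part <- A[rows, a_cols, drop = FALSE]
        b_part <- B[rows, b_cols, drop = FALSE]
        qa <- QA[rows, a_cols, drop = FALSE]
        qb <- QB[rows, b_cols, drop = FALSE]
        take_b <- (a_part != b_part) & (qb > qa)
        a_part[take_b] <- b_part[take_b]
        qmax <- qa; hi <- qb > qa; qmax[hi] <- qb[hi]
        core <- raw_matrix_seqs(a_part)
        qcore <- raw_matrix_seqs(qmax)
        g <- ix[rows]
        merged[g] <- paste0(substr(r1_seq[g], 1L, L1 - ov), core,
                            substr(b[g], ov + 1L, L2))
        qual[g] <- paste0(substr(r1_qual[g], 1L, L1 - ov), qcore,
                          substr(bq[g], ov + 1L, L2))
        overlap[g] <- ov
        mism[g] <- as.integer(mm[hit])
        remaining <- remaining[!hit]
      }
    }
  }
  data.frame(merged = merged, qual = qual, overlap = overlap,
             mismatches = mism, ok = !is.na(merged),
             stringsAsFactors = FALSE)
}

#' Demultiplex clusters by inline sample barcode
#'
#' The barcode is the fixed-length prefix of each (merged) cluster. The
#' barcode set must have minimum pairwise Hamming distance greater than
#' `2 * max_mismatch`, which makes every assignment unambiguous; clusters
#' matching no barcode within `max_mismatch` are unassigned (`NA`).
#'
#' @param seqs character vector of cluster sequences (barcode at position 1).
#' @param barcodes named character vector, sample id -> barcode (equal
#'   lengths).
#' @param max_mismatch maximum Hamming distance for an assignment (default 1).
#' @return character vector of sample ids (`NA` = unassigned), same length as
#'   `seqs`.
#' @export
demultiplex <- function(seqs, barcodes, max_mismatch = 1L) {
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1L) config_error("barcodes must have equal length")
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes))))
    config_error("barcodes must be named by sample id")
  if (length(barcodes) > 1L) {
    d <- adist(barcodes)
    if (min(d[upper.tri(d)]) <= 2L * max_mismatch)
      config_error("barcode set violates the distance precondition: ",
                   "min pairwise distance must exceed 2 * max_mismatch")
  }
  if (!length(seqs)) return(character(0))
  pre <- substr(seqs, 1L, bl)
  dmat <- vapply(barcodes, function(b) hamming_to_ref(pre, b),
                 integer(length(seqs)))
  dmat <- matrix(dmat, nrow = length(seqs))
  best <- max.col(-dmat, ties.method = "first")
  bestd <- dmat[cbind(seq_along(seqs), best)]
  out <- names(barcodes)[best]
  out[bestd > max_mismatch] <- NA_character_
  out
}

# R implementation of Levenshtein distance via utils::adist, grouped to keep
# the number of C calls small: one call per target sequence
edit_dist_to <- function(seqs, target) {
  if (!length(seqs)) return(integer(0))
  as.integer(adist(seqs, target))
}

# Edit distance of clusters to one amplicon with the amplicon's IPC
# identifier span treated as a wildcard: the span holds a random N-mer on IPC
# molecules by design, so its bases carry no alignment information. The span
# precedes every variant locus, so cluster and amplicon coordinates coincide
# there and both sides are overwritten with the same constant before the
# distance is computed.
edit_dist_to_amplicon <- function(seqs, amp_row) {
  if (!length(seqs)) return(integer(0))
  a <- amp_row$sequence
  i0 <- amp_row$ipc_start; i1 <- amp_row$ipc_end
  filler <- strrep("A", i1 - i0)
  a_masked <- paste0(substr(a, 1L, i0), filler, substr(a, i1 + 1L, nchar(a)))
  s_masked <- seqs
  long <- nchar(seqs) >= i1
  s_masked[long] <- paste0(substr(seqs[long], 1L, i0), filler,
                           substr(seqs[long], i1 + 1L, nchar(seqs[long])))
  edit_dist_to(s_masked, a_masked)
}

#' Assign clusters to panel amplicons by edit distance
#'
#' Finds each cluster's best amplicon by Levenshtein edit distance, with ties
#' broken toward the lexicographically smallest amplicon id (and flagged).
#' Each amplicon's IPC identifier span is treated as a wildcard (it carries a
#' random N-mer on IPC molecules by design), so identifiers do not count as
#' edits.
#' Clusters whose best distance exceeds `max_edit_frac * nchar(cluster)` are
#' unaligned.
#'
#' `method = "exhaustive"` computes the distance to every amplicon.
#' `method = "screen"` (the pipeline default) first ranks amplicons by
#' Hamming distance over the forward-primer prefix and computes edit
#' distances only for amplicons within `screen_margin` of the best prefix
#' match; with distinct primer sequences this returns the same assignment at
#' a fraction of the cost.
#'
#' @param seqs character vector of barcode-stripped cluster sequences.
#' @param panel a `ctdna_panel`.
#' @param max_edit_frac maximum edit distance as a fraction of cluster length
#'   (default 0.3).
#' @param method `"screen"` or `"exhaustive"`.
#' @param screen_margin prefix-distance slack for the screen shortlist.
#' @return data.frame: `amplicon_id` (`NA` when unaligned), `edit_distance`
#'   (to the best amplicon considered), `aligned`, `tie`.
#' @export
align_to_amplicons <- function(seqs, panel, max_edit_frac = 0.3,
                               method = c("screen", "exhaustive"),
                               screen_margin = 4L) {
  method <- match.arg(method)
  amp <- panel$amplicons[order(panel$amplicons$amplicon_id), , drop = FALSE]
  if (nrow(amp) == 0L) config_error("panel has no amplicons")
  n <- length(seqs)
  if (n == 0L)
    return(data.frame(amplicon_id = character(0), edit_distance = integer(0),
                      aligned = logical(0), tie = logical(0)))
  if (method == "exhaustive") {
    d <- matrix(NA_integer_, n, nrow(amp))
    for (j in seq_len(nrow(amp)))
      d[, j] <- edit_dist_to_amplicon(seqs, amp[j, ])
  } else {
    plen <- min(amp$primer_fwd_end - amp$primer_fwd_start)
    pre <- substr(seqs, 1L, plen)
    short <- nchar(pre) < plen
    pre[short] <- strrep("N", plen)  # too short to screen: distance maximal
    pd <- vapply(substr(amp$sequence, amp$primer_fwd_start + 1L,
                        amp$primer_fwd_start + plen),
                 function(p) hamming_to_ref(pre, p), integer(n))
    pd <- matrix(pd, nrow = n)
    keep <- pd <= apply(pd, 1L, min) + screen_margin
    d <- matrix(NA_integer_, n, nrow(amp))
    for (j in seq_len(nrow(amp))) {
      rows <- which(keep[, j])
      if (length(rows))
        d[rows, j] <- edit_dist_to_amplicon(seqs[rows], amp[j, ])
    }
  }
  bestd <- apply(d, 1L, min, na.rm = TRUE)
  nbest <- rowSums(d == bestd, na.rm = TRUE)
  best <- max.col(-replace(d, is.na(d), .Machine$integer.max),
                  ties.method = "first")
  out <- data.frame(
    amplicon_id = amp$amplicon_id[best],
    edit_distance = as.integer(bestd),
    aligned = bestd <= max_edit_frac * nchar(seqs),
    tie = nbest > 1L,
    stringsAsFactors = FALSE
  )
  out$amplicon_id[!out$aligned] <- NA_character_
  out
}

#' Classify aligned clusters as wild-type, mutant, IPC or unassigned
#'
#' Applies the panel's classification rule to each cluster given its amplicon
#' assignment. For each mutation on the amplicon, the cluster carries that
#' mutation when it matches the mutant amplicon sequence exactly over a local
#' window of `flank_match` reference bases on each side of the alt allele.
#' A cluster whose IPC identifier span differs from the reference and which
#' carries a mutation's alt allele is an IPC of that mutation (the identifier
#' is extracted from the span); with a reference identifier span it is a
#' mutant (MUT). A cluster matching the reference at every variant locus and
#' at the IPC span is wild-type (WT); anything else — including clusters with
#' an alt allele but divergent flanks — is conservatively UNASSIGNED. On
#' multi-mutation amplicons a cluster may carry several mutations and yields
#' one row per mutation.
#'
#' @param seqs barcode-stripped cluster sequences.
#' @param amplicon_id amplicon assignment per cluster (`NA` = unaligned), as
#'   from [align_to_amplicons()].
#' @param panel a `ctdna_panel`.
#' @param flank_match required matching reference bases flanking the alt
#'   allele (default 10).
#' @return data.frame with >= 1 row per cluster: `cluster` (index into
#'   `seqs`), `label` (`"WT"`, `"MUT"`, `"IPC"`, `"UNASSIGNED"`),
#'   `mutation_id`, `identifier`.
#' @export
classify_clusters <- function(seqs, amplicon_id, panel, flank_match = 10L) {
  n <- length(seqs)
  if (length(amplicon_id) != n)
    config_error("seqs and amplicon_id must have equal length")
  empty <- data.frame(cluster = integer(0), label = character(0),
                      mutation_id = character(0), identifier = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  out <- list()
  unassigned <- rep(TRUE, n)

  for (aid in unique(amplicon_id[!is.na(amplicon_id)])) {
    cs <- which(amplicon_id == aid)
    a <- panel$amplicons[panel$amplicons$amplicon_id == aid, , drop = FALSE]
    muts <- panel$mutations[panel$mutations$amplicon_id == aid, , drop = FALSE]
    s <- seqs[cs]
    len <- nchar(s)
    ipc_ref <- substr(a$sequence, a$ipc_start + 1L, a$ipc_end)
    ident <- substr(s, a$ipc_start + 1L, a$ipc_end)
    has_ident <- len >= a$ipc_end & ident != ipc_ref

    wt_ok <- len == nchar(a$sequence) & !has_ident
    hits <- vector("list", nrow(muts))
    for (j in seq_len(nrow(muts))) {
      m <- muts[j, ]
      tmpl <- substitute_allele(a$sequence, m$offset, m$ref_allele, m$alt_allele)
      Lm <- nchar(tmpl)
      w0 <- max(0L, m$offset - flank_match)
      w1 <- min(Lm, m$offset + nchar(m$alt_allele) + flank_match)
      expected <- substr(tmpl, w0 + 1L, w1)
      hits[[j]] <- len == Lm & substr(s, w0 + 1L, w1) == expected
      # WT requires the reference allele at every variant locus
      ref_here <- substr(s, m$offset + 1L, m$offset + nchar(m$ref_allele))
      wt_ok <- wt_ok & ref_here == m$ref_allele
    }
    hitmat <- if (nrow(muts)) do.call(cbind, hits) else
      matrix(FALSE, length(cs), 0L)
    any_hit <- if (ncol(hitmat)) rowSums(hitmat) > 0L else rep(FALSE, length(cs))

    for (j in seq_len(nrow(muts))) {
      ipc_rows <- which(hitmat[, j] & has_ident)
      mut_rows <- which(hitmat[, j] & !has_ident)
      if (length(ipc_rows))
        out[[length(out) + 1L]] <- data.frame(
          cluster = cs[ipc_rows], label = "IPC",
          mutation_id = muts$mutation_id[j], identifier = ident[ipc_rows],
          stringsAsFactors = FALSE)
      if (length(mut_rows))
        out[[length(out) + 1L]] <- data.frame(
          cluster = cs[mut_rows], label = "MUT",
          mutation_id = muts$mutation_id[j], identifier = NA_character_,
          stringsAsFactors = FALSE)
    }
    wt_rows <- which(wt_ok & !any_hit)
    if (length(wt_rows))
      out[[length(out) + 1L]] <- data.frame(
        cluster = cs[wt_rows], label = "WT", mutation_id = NA_character_,
        identifier = NA_character_, stringsAsFactors = FALSE)
    unassigned[cs[any_hit | (wt_ok & !any_hit)]] <- FALSE
  }
  un <- which(unassigned)
  if (length(un))
    out[[length(out) + 1L]] <- data.frame(
      cluster = un, label = "UNASSIGNED", mutation_id = NA_character_,
      identifier = NA_character_, stringsAsFactors = FALSE)
  res <- do.call(rbind, c(list(empty), out))
  res[order(res$cluster, res$mutation_id), , drop = FALSE]
}

#' Collapse sequencing-error IPC identifiers into their parent identifiers
#'
#' Directional single-linkage absorption as used for unique molecular
#' identifiers: an identifier `a` is merged into an identifier `b` when they
#' differ at a single base and `count(b) >= ratio * count(a)`, scanning from
#' the least to the most abundant identifier. This absorbs error-derived
#' identifiers (typically singletons one base away from a real founder) while
#' leaving genuinely distinct founders — which have comparable abundance —
#' intact.
#'
#' @param identifiers character vector of observed identifiers (one element
#'   per cluster).
#' @param ratio minimum parent/child abundance ratio for a merge (default 2).
#' @return character vector: the (possibly collapsed) identifier per cluster.
#' @export
collapse_identifiers <- function(identifiers, ratio = 2) {
  if (!length(identifiers)) return(identifiers)
  tab <- sort(table(identifiers), decreasing = TRUE)
  ids <- names(tab)
  k <- length(ids)
  if (k < 2L || k > 20000L) return(identifiers)
  counts <- as.integer(tab)
  parent <- seq_len(k)
  m <- seq_raw_matrix(ids)
  for (i in k:2) {
    cand <- seq_len(i - 1L)  # strictly more abundant (or earlier) identifiers
    dd <- rowSums(m[cand, , drop = FALSE] !=
                    matrix(m[i, ], length(cand), ncol(m), byrow = TRUE))
    ok <- cand[dd <= 1L & counts[cand] >= ratio * counts[i]]
    if (length(ok)) parent[i] <- ok[1L]
  }
  # follow chains to the root
  root <- parent
  repeat {
    nxt <- parent[root]
    if (all(nxt == root)) break
    root <- nxt
  }
  ids[root][match(identifiers, ids)]
}

#' Process raw read pairs into classified clusters
#'
#' The full read-processing front end: merge pairs, demultiplex by inline
#' barcode, strip the barcode, assign clusters to amplicons, classify them
#' against the panel, and collapse error-derived IPC identifiers per sample.
#' Identical read pairs are processed once and the result expanded, which is
#' exact and much faster on deeply sequenced amplicon data.
#'
#' @param r1,r2 `list(id, seq, qual)` as from [read_fastq()] /
#'   [simulate_sample()].
#' @param panel a `ctdna_panel`.
#' @param barcodes named character vector, sample id -> barcode.
#' @param min_overlap,max_mismatch_frac merge tolerances ([merge_pairs()]).
#' @param barcode_max_mismatch demultiplexing tolerance ([demultiplex()]).
#' @param max_edit_frac alignment tolerance ([align_to_amplicons()]).
#' @param flank_match classification flank ([classify_clusters()]).
#' @param collapse collapse IPC identifiers within Hamming distance 1 of a
#'   sufficiently more abundant identifier (default TRUE).
#' @return list with `clusters` (data.frame: read_id, sample, amplicon_id,
#'   edit_distance, label, mutation_id, identifier; one row per
#'   cluster-mutation) and `qc` (read-fate accounting: input pairs, merged,
#'   merge-failed, demultiplexed, unassigned-barcode, aligned, label counts).
#' @export
process_reads <- function(r1, r2, panel, barcodes,
                          min_overlap = 20L, max_mismatch_frac = 0.1,
                          barcode_max_mismatch = 1L, max_edit_frac = 0.3,
                          flank_match = 10L, collapse = TRUE) {
  n <- length(r1$seq)
  if (length(r2$seq) != n) config_error("R1/R2 read counts differ")
  qc <- list(input_pairs = n)
  empty_clusters <- data.frame(
    read_id = character(0), sample = character(0), amplicon_id = character(0),
    edit_distance = integer(0), label = character(0),
    mutation_id = character(0), identifier = character(0),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    qc <- c(qc, list(merged = 0L, merge_failed = 0L, demultiplexed = 0L,
                     unassigned_barcode = 0L, aligned = 0L,
                     labels = table(character(0))))
    return(list(clusters = empty_clusters, qc = qc))
  }

  key <- paste0(r1$seq, "\r", r2$seq)
  ukey <- !duplicated(key)
  umap <- match(key, key[ukey])  # read -> unique-pair index
  uidx <- which(ukey)

  mg <- merge_pairs(r1$seq[uidx], r2$seq[uidx], r1$qual[uidx], r2$qual[uidx],
                    min_overlap = min_overlap,
                    max_mismatch_frac = max_mismatch_frac)
  qc$merged <- sum(mg$ok[umap])
  qc$merge_failed <- n - qc$merged

  u_ok <- which(mg$ok)
  sample_u <- rep(NA_character_, nrow(mg))
  sample_u[u_ok] <- demultiplex(mg$merged[u_ok], barcodes,
                                max_mismatch = barcode_max_mismatch)
  sample_all <- sample_u[umap]
  qc$demultiplexed <- sum(!is.na(sample_all))
  qc$unassigned_barcode <- qc$merged - qc$demultiplexed

  bl <- unique(nchar(barcodes))
  core_u <- rep(NA_character_, nrow(mg))
  keep_u <- which(!is.na(sample_u))
  core_u[keep_u] <- substr(mg$merged[keep_u], bl + 1L,
                           nchar(mg$merged[keep_u]))

  aln_amp <- rep(NA_character_, nrow(mg))
  aln_dist <- rep(NA_integer_, nrow(mg))
  if (length(keep_u)) {
    aln <- align_to_amplicons(core_u[keep_u], panel,
                              max_edit_frac = max_edit_frac,
                              method = "screen")
    aln_amp[keep_u] <- aln$amplicon_id
    aln_dist[keep_u] <- aln$edit_distance
  }
  qc$aligned <- sum(!is.na(aln_amp[umap]) & !is.na(sample_all))

  cls <- classify_clusters(core_u, aln_amp, panel, flank_match = flank_match)
  # drop rows for unique pairs that never merged/demuxed (they are accounted
  # in qc, not clusters)
  cls <- cls[!is.na(sample_u[cls$cluster]), , drop = FALSE]

  # expand unique-pair classification back to all reads
  by_unique <- split(seq_len(n), umap)  # unique-pair index -> read indices
  expand <- by_unique[as.character(cls$cluster)]
  reps <- lengths(expand)
  ridx <- unlist(expand, use.names = FALSE)
  clusters <- data.frame(
    read_id = r1$id[ridx],
    sample = sample_all[ridx],
    amplicon_id = aln_amp[rep(cls$cluster, reps)],
    edit_distance = aln_dist[rep(cls$cluster, reps)],
    label = rep(cls$label, reps),
    mutation_id = rep(cls$mutation_id, reps),
    identifier = rep(cls$identifier, reps),
    stringsAsFactors = FALSE)

  if (collapse && any(clusters$label == "IPC")) {
    ipc <- clusters$label == "IPC"
    grp <- interaction(clusters$sample[ipc], clusters$mutation_id[ipc],
                       drop = TRUE)
    clusters$identifier[ipc] <- unsplit(
      lapply(split(clusters$identifier[ipc], grp), collapse_identifiers), grp)
  }
  qc$labels <- table(clusters$label[!duplicated(clusters$read_id)])
  list(clusters = clusters, qc = qc)
}
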