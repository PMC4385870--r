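test_that("merging recovers fully overlapping pairs and rejects junk", {
  set.seed(42)
  r1 <- rand_seq(60)
  m <- merge_pairs(r1, revcomp(r1))
  expect_true(m$ok)
  expect_identical(m$merged, r1)
  expect_identical(m$overlap, 60L)

  # disjoint random sequences fail
  m2 <- merge_pairs(rand_seq(50), rand_seq(50))
  expect_false(m2$ok)
  expect_true(is.na(m2$merged))

  expect_error(merge_pairs("ACGT", character(0)), "equal length")
  expect_error(merge_pairs("", "ACGT"), "non-empty")
})

test_that("overlap disagreements resolve toward the higher-quality base", {
  set.seed(43)
  core <- rand_seq(30)                       # the true 30 nt overlap
  left <- rand_seq(20)
  right <- rand_seq(20)
  mol1 <- paste0(left, core)                 # read 1 = left + overlap
  core_err <- core
  substr(core_err, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                      substr(core, 15, 15))[1]
  mol2 <- paste0(core_err, right)            # read 2 covers overlap + right
  r2 <- revcomp(mol2)

  hiq <- strrep("I", 50); loq <- strrep("#", 50)
  # read 1 higher quality: its base wins
  m <- merge_pairs(mol1, r2, hiq, loq, min_overlap = 20)
  expect_true(m$ok)
  expect_identical(m$overlap, 30L)
  expect_identical(m$mismatches, 1L)
  expect_identical(m$merged, paste0(left, core, right))
  # read 2 higher quality: its base wins
  m2 <- merge_pairs(mol1, r2, loq, hiq, min_overlap = 20)
  expect_identical(m2$merged, paste0(left, core_err, right))
})

test_that("merge_pairs agrees with the all-offsets overlap oracle", {
  set.seed(101)
  n <- 350
  r1 <- character(n); r2 <- character(n)
  for (i in seq_len(n)) {
    type <- i %% 3L
    if (type == 0L) {           # genuine overlap with 0-2 errors
      mol <- rand_seq(sample(45:80, 1))
      l1 <- sample(30:nchar(mol), 1)
      l2 <- sample(30:nchar(mol), 1)
      a <- substr(mol, 1, l1)
      b <- substr(mol, nchar(mol) - l2 + 1, nchar(mol))
      for (k in seq_len(sample(0:2, 1))) {
        p <- sample(nchar(b), 1)
        substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      r1[i] <- a; r2[i] <- revcomp(b)
    } else if (type == 1L) {    # unrelated reads
      r1[i] <- rand_seq(sample(30:70, 1)); r2[i] <- rand_seq(sample(30:70, 1))
    } else {                    # borderline short overlaps
      mol <- rand_seq(40)
      r1[i] <- substr(mol, 1, sample(22:30, 1))
      r2[i] <- revcomp(substr(mol, sample(8:18, 1), 40))
    }
  }
  got <- merge_pairs(r1, r2, min_overlap = 20, max_mismatch_frac = 0.1)
  for (i in seq_len(n)) {
    want <- oracle_merge(r1[i], r2[i], min_overlap = 20,
                         max_mismatch_frac = 0.1)
    expect_identical(got$ok[i], want$ok)
    if (want$ok) {
      expect_identical(got$overlap[i], want$overlap)
      expect_identical(got$merged[i], want$merged)  # equal-quality convention
    }
  }
})

test_that("demultiplexing assigns within tolerance and partitions all input", {
  bcs <- default_barcodes(6)
  expect_identical(length(bcs), 6L)
  d <- utils::adist(bcs)
  expect_gte(min(d[upper.tri(d)]), 3)

  tail <- strrep("T", 20)
  exact <- paste0(bcs[["S3"]], tail)
  one_mm <- exact; substr(one_mm, 2, 2) <- setdiff(c("A", "C", "G", "T"),
                                                   substr(exact, 2, 2))[1]
  two_mm <- one_mm; substr(two_mm, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                                    substr(one_mm, 5, 5))[1]
  got <- demultiplex(c(exact, one_mm, two_mm), bcs, max_mismatch = 1)
  expect_identical(got, c("S3", "S3", NA_character_))

  # assignment counts always sum to the input count
  set.seed(7)
  seqs <- vapply(1:200, function(i) rand_seq(30), character(1))
  got2 <- demultiplex(seqs, bcs, max_mismatch = 1)
  expect_length(got2, 200L)
  expect_identical(sum(!is.na(got2)) + sum(is.na(got2)), 200L)

  # ambiguous barcode sets are a configuration error
  expect_error(demultiplex("ACGTACGTAAA", c(a = "ACGTACGT", b = "ACGTACGA"),
                           max_mismatch = 1),
               "distance precondition")
})

test_that("amplicon assignment matches the full DP oracle", {
  panel <- mini_panel()
  set.seed(202)
  seqs <- character(400)
  for (i in seq_along(seqs)) {
    type <- i %% 4L
    if (type == 0L) {
      seqs[i] <- rand_seq(sample(60:120, 1))        # junk, should not align
    } else {
      a <- panel$amplicons[sample(nrow(panel$amplicons), 1), ]
      s <- a$sequence
      if (type == 2L) {                             # IPC-style identifier
        substr(s, a$ipc_start + 1, a$ipc_end) <- rand_seq(a$ipc_end - a$ipc_start)
      }
      for (k in seq_len(sample(0:4, 1))) {          # scattered substitutions
        p <- sample(nchar(s), 1)
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      seqs[i] <- s
    }
  }
  want <- lapply(seqs, oracle_align, panel = panel, max_edit_frac = 0.3)
  for (method in c("screen", "exhaustive")) {
    got <- align_to_amplicons(seqs, panel, max_edit_frac = 0.3, method = method)
    expect_identical(got$aligned, vapply(want, `[[`, logical(1), "aligned"))
    ok <- which(got$aligned)
    expect_identical(got$amplicon_id[ok],
                     vapply(want[ok], `[[`, character(1), "amplicon_id"))
    expect_identical(got$edit_distance[ok],
                     vapply(want[ok], `[[`, integer(1), "edit_distance"))
  }

  # trivial anchors: exact amplicon at distance 0; one substitution at 1
  a1 <- panel$amplicons$sequence[1]
  mut1 <- a1; substr(mut1, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                              substr(a1, 50, 50))[1]
  got <- align_to_amplicons(c(a1, mut1), panel)
  expect_identical(got$edit_distance, c(0L, 1L))
  expect_identical(got$amplicon_id,
                   rep(panel$amplicons$amplicon_id[1], 2))
})

test_that("classification labels reference, mutant and IPC clusters correctly", {
  panel <- mini_panel()
  a <- panel$amplicons[panel$amplicons$amplicon_id == "AMP1", ]
  m <- panel$mutations[panel$mutations$mutation_id == "GENE1 A100X", ]
  wt <- a$sequence
  mut <- mutant_template(panel, "GENE1 A100X")
  ident <- "CCCCGGGG"
  ipc <- mutant_template(panel, "GENE1 A100X", identifier = ident)
  del_ipc <- mutant_template(panel, "GENE2 D201del", identifier = ident)
  junk <- wt
  substr(junk, m$offset + 1, m$offset + 1) <- m$alt_allele  # alt allele...
  substr(junk, m$offset - 3, m$offset - 3) <- "N"           # ...divergent flank

  seqs <- c(wt, mut, ipc, del_ipc, junk)
  amps <- c("AMP1", "AMP1", "AMP1", "AMP2", "AMP1")
  got <- classify_clusters(seqs, amps, panel)
  expect_identical(got$label[got$cluster == 1], "WT")
  expect_identical(got$label[got$cluster == 2], "MUT")
  expect_identical(got$mutation_id[got$cluster == 2], "GENE1 A100X")
  expect_identical(got$label[got$cluster == 3], "IPC")
  expect_identical(got$identifier[got$cluster == 3], ident)
  expect_identical(got$label[got$cluster == 4], "IPC")
  expect_identical(got$mutation_id[got$cluster == 4], "GENE2 D201del")
  # alt allele with divergent flank is conservatively unassigned
  expect_identical(got$label[got$cluster == 5], "UNASSIGNED")

  # partition property: every cluster gets exactly one label
  labels_per_cluster <- tapply(got$label, got$cluster,
                               function(x) length(unique(x)))
  expect_true(all(labels_per_cluster == 1L))
})

test_that("noise-free simulator output is classified identically to truth", {
  panel <- mini_panel()
  cfg <- mini_cfg(per_base_error_per_cycle = 0,
                  mutant_copies = c("GENE1 A100X" = 10, "GENE2 D201del" = 10),
                  reads_per_sample = 4000L, seed = 13L)
  sim <- simulate_sample(panel, cfg)
  pr <- process_sim(sim, panel)
  got <- pr$clusters[!duplicated(pr$clusters$read_id), ]
  got <- got[match(sim$r1$id, got$read_id), ]
  truth_class <- sim$truth$class[sim$read_founder]
  expect_identical(got$label, truth_class)
  # and for mutant/IPC reads, the right mutation
  informative <- truth_class != "WT"
  expect_identical(got$mutation_id[informative],
                   sim$truth$mutation_id[sim$read_founder][informative])
  # IPC identifiers recovered exactly
  is_ipc <- truth_class == "IPC"
  expect_identical(got$identifier[is_ipc],
                   sim$truth$identifier[sim$read_founder][is_ipc])
})

test_that("noisy reads with a reference base at the locus are never called MUT", {
  panel <- mini_panel()
  cfg <- mini_cfg(per_base_error_per_cycle = 3e-3, pcr_cycles_pre = 8L,
                  mutant_copies = c("GENE1 A100X" = 20),
                  reads_per_sample = 5000L, seed = 29L)
  sim <- simulate_sample(panel, cfg)
  pr <- process_sim(sim, panel)
  mut_rows <- pr$clusters[pr$clusters$label == "MUT", ]
  # re-derive each called cluster's base at its mutation locus from the reads
  seq_by_id <- setNames(substr(sim$r1$seq, nchar(cfg$barcode) + 1L,
                               nchar(sim$r1$seq)), sim$r1$id)
  for (i in seq_len(nrow(mut_rows))) {
    m <- panel$mutations[panel$mutations$mutation_id == mut_rows$mutation_id[i], ]
    s <- seq_by_id[[mut_rows$read_id[i]]]
    expect_identical(substr(s, m$offset + 1, m$offset + nchar(m$alt_allele)),
                     m$alt_allele)
  }
  # label accounting: one label per read, totals partition the merged reads
  per_read <- pr$clusters[!duplicated(pr$clusters$read_id), ]
  expect_identical(nrow(per_read), pr$qc$demultiplexed)
})

test_that("identifier collapse absorbs errors but keeps distinct founders", {
  abundant1 <- rep("AAAAAAAA", 30)
  abundant2 <- rep("AAAAAAAT", 25)   # Hamming 1 from abundant1, comparable size
  err <- rep("AACAAAAA", 1)          # Hamming 1 singleton, error-derived
  far <- rep("GGGGCCCC", 10)
  got <- collapse_identifiers(c(abundant1, abundant2, err, far))
  expect_identical(unique(got[seq_len(30)]), "AAAAAAAA")
  expect_identical(unique(got[31:55]), "AAAAAAAT")   # not merged
  expect_identical(got[56], "AAAAAAAA")              # singleton absorbed
  expect_identical(unique(got[57:66]), "GGGGCCCC")
})
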