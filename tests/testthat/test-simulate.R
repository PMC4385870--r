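test_that("simulation is reproducible and conserves reads", {
  panel <- mini_panel()
  cfg <- mini_cfg(mutant_copies = c("GENE1 A100X" = 5), seed = 99L)
  s1 <- simulate_sample(panel, cfg)
  s2 <- simulate_sample(panel, cfg)
  expect_identical(s1$r1$seq, s2$r1$seq)
  expect_identical(s1$r2$seq, s2$r2$seq)
  expect_identical(s1$truth, s2$truth)

  # conservation: emitted reads match the request and every read has a founder
  expect_identical(sum(s1$truth$reads), cfg$reads_per_sample)
  expect_length(s1$read_founder, cfg$reads_per_sample)
  expect_true(all(s1$read_founder %in% seq_len(nrow(s1$truth))))
  expect_identical(as.vector(table(factor(s1$read_founder,
                                          levels = seq_len(nrow(s1$truth))))),
                   as.integer(s1$truth$reads))

  # a different seed gives different reads
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(simulate_sample(panel, cfg2)$r1$seq, s1$r1$seq))
})

test_that("FASTQ output round-trips through write_fastq/read_fastq", {
  panel <- mini_panel()
  sim <- simulate_sample(panel, mini_cfg(reads_per_sample = 200L))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x_R1.fastq.gz")
  write_fastq(sim$r1, path)
  back <- read_fastq(path)
  expect_identical(back$seq, sim$r1$seq)
  expect_identical(back$id, sim$r1$id)
  expect_identical(back$qual, sim$r1$qual)
})

test_that("noise-free wild-type runs produce only exact amplicon reads", {
  panel <- mini_panel()
  cfg <- mini_cfg(ipc_copies = 0L, per_base_error_per_cycle = 0,
                  retain_wt = 0.9, retain_mut = 0.9, reads_per_sample = 500L)
  sim <- simulate_sample(panel, cfg)
  expect_true(all(sim$truth$class == "WT"))
  # every read is barcode + exact amplicon prefix / suffix
  amp_by_id <- setNames(panel$amplicons$sequence, panel$amplicons$amplicon_id)
  src <- unname(amp_by_id[sim$truth$amplicon_id[sim$read_founder]])
  bl <- nchar(cfg$barcode)
  expect_identical(sim$r1$seq,
                   paste0(cfg$barcode, substr(src, 1, cfg$read_len - bl)))
  expect_identical(sim$r2$seq,
                   revcomp(substr(src, nchar(src) - cfg$read_len + 1,
                                  nchar(src))))
})

test_that("zero requested depth yields empty FASTQ but valid truth", {
  panel <- mini_panel()
  sim <- simulate_sample(panel, mini_cfg(reads_per_sample = 0L))
  expect_length(sim$r1$seq, 0L)
  expect_identical(sum(sim$truth$reads), 0L)
  expect_gt(nrow(sim$truth), 0L)
})

test_that("post-enrichment mutant:WT ratio follows the closed form", {
  # expected molecule ratio after enrichment:
  #   (mutants * retain_mut^E) / (WT * retain_wt^E)
  panel <- mini_panel()
  n_mut <- 400L
  cfg <- mini_cfg(input_genomes = 2000, ipc_copies = 0L,
                  mutant_copies = c("GENE1 A100X" = n_mut),
                  per_base_error_per_cycle = 0,
                  enrich_cycles = 8L, retain_mut = 0.9, retain_wt = 0.7,
                  reads_per_sample = 20000L, seed = 31L)
  sim <- simulate_sample(panel, cfg)
  factor_expected <- (cfg$retain_mut / cfg$retain_wt)^cfg$enrich_cycles
  wt_total <- 2L * 2000L  # one WT molecule per amplicon per genome equivalent
  ratio_expected <- (n_mut / wt_total) * factor_expected
  reads_mut <- sum(sim$truth$reads[sim$truth$class == "MUT"])
  reads_wt <- sum(sim$truth$reads[sim$truth$class == "WT"])
  ratio_obs <- reads_mut / reads_wt
  # delta-method standard error of a read-count ratio
  se <- ratio_obs * sqrt(1 / reads_mut + 1 / reads_wt)
  expect_lt(abs(ratio_obs - ratio_expected), 3 * se + 1e-12)
})

test_that("titration designs enumerate levels x replicates with shared background", {
  panel <- mini_panel()
  cfg <- mini_cfg(reads_per_sample = 300L)
  tt <- simulate_titration(panel, cfg, "GENE2 C200Z",
                           copy_levels = c(0, 10, 100), replicates = 3L,
                           seed = 7L)
  expect_length(tt$samples, 9L)
  expect_identical(nrow(tt$design), 9L)
  expect_setequal(tt$design$input_copies, c(0L, 10L, 100L))
  # level-0 samples are wild-type background
  zero <- tt$samples[[which(tt$design$input_copies == 0)[1]]]
  expect_false(any(zero$truth$class == "MUT"))
  ten <- tt$samples[[which(tt$design$input_copies == 10)[1]]]
  expect_identical(sum(ten$truth$class == "MUT"), 10L)
  expect_error(simulate_titration(panel, cfg, "GENE2 C200Z", copy_levels = -1),
               "copy_levels")
  expect_error(simulate_titration(panel, cfg, "nope", copy_levels = 1),
               "unknown mutation_id")
})

test_that("background runs require n >= 2 and are mutation-free without error", {
  panel <- mini_panel()
  cfg <- mini_cfg(per_base_error_per_cycle = 0, reads_per_sample = 500L,
                  mutant_copies = c("GENE1 A100X" = 3))
  expect_error(simulate_background(panel, cfg, n_runs = 1L), "n_runs")
  bg <- simulate_background(panel, cfg, n_runs = 3L, seed = 5L)
  expect_length(bg, 3L)
  for (s in bg) expect_false(any(s$truth$class == "MUT"))
})

test_that("error-driven background matches the analytic per-base expectation", {
  # With per-read substitution rate e = 1 - (1 - e_cycle)^cycles, a wild-type
  # read acquires a specific substitution alt allele with probability e/3 and
  # must keep its classification window otherwise clean: expected false
  # mutant clusters = reads_on_amplicon * e/3 * (1 - e)^(window - 1).
  panel <- mini_panel()
  cfg <- mini_cfg(input_genomes = 1000, ipc_copies = 0L,
                  per_base_error_per_cycle = 2e-3, pcr_cycles_pre = 5L,
                  retain_mut = 0.9, retain_wt = 0.9,
                  reads_per_sample = 30000L, seed = 77L)
  sim <- simulate_sample(panel, cfg)
  pr <- process_sim(sim, panel)
  e_read <- 1 - (1 - cfg$per_base_error_per_cycle)^cfg$pcr_cycles_pre
  flank <- 10L
  # pooled over the panel's substitution mutations
  subs <- panel$mutations[nchar(panel$mutations$ref_allele) == 1 &
                            nchar(panel$mutations$alt_allele) == 1, ]
  reads_per_amp <- table(sim$truth$amplicon_id[sim$read_founder])
  # the MUT label also needs the rest of the 21-base window and the 8-base
  # identifier span to stay error-free
  window <- 2L * flank + 1L
  idlen <- 8L
  expected <- sum(reads_per_amp[subs$amplicon_id] * e_read / 3 *
                    (1 - e_read)^(window - 1L + idlen))
  observed <- sum(pr$clusters$label == "MUT" &
                    pr$clusters$mutation_id %in% subs$mutation_id)
  expect_lt(abs(observed - expected), 3 * sqrt(expected) + 1e-9)
})

test_that("sim_config rejects inconsistent settings", {
  expect_error(sim_config(retain_mut = 0.5, retain_wt = 0.9), "retain_mut")
  expect_error(sim_config(per_base_error_per_cycle = 1.5), "probabilities")
  expect_error(sim_config(mutant_copies = c(5)), "named")
  expect_error(sim_config(mutant_copies = c(x = -1)), ">= 0")
  # mass-based input: 300 ng at 3.3 pg/genome
  cfg <- sim_config(dna_mass_ng = 300)
  expect_equal(cfg$input_genomes, 300 * 1000 / 3.3)
})
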