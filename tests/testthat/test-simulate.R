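test_that("a one-gene transcriptome round-trips through its files", {
  cfg <- scenario_config(n_genes = 1L, orf_length_codons = c(10L, 10L),
                         depth = 100, seed = 2L)
  sim <- simulate_scenario(cfg)
  expect_equal(nrow(sim$transcriptome$orfs), 1L)
  expect_equal(n_codons(sim$transcriptome$orfs[1, ]), 10L)
  expect_equal(nchar(sim$transcriptome$orfs$sequence), 30L)
  expect_error(scenario_config(orf_length_codons = c(3L, 4L)))
  dir <- withr::local_tempdir()
  write_scenario(sim, dir)
  tx2 <- load_annotation(file.path(dir, "orfs.bed"),
                         file.path(dir, "genome.fa"))
  expect_identical(tx2$orfs$sequence, sim$transcriptome$orfs$sequence)
  expect_identical(tx2$orfs$start, sim$transcriptome$orfs$start)
  reread <- suppressMessages(read_alignments(
    file.path(dir, "footprints.tsv"), 1, 100))
  expect_equal(nrow(reread), nrow(sim$footprints))
  expect_equal(reread$three_prime, sim$footprints$three_prime)
})

test_that("identical seeds give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(simulate_scenario(scenario("trmD_deg", n_genes = 10L,
                                            depth = 5000, seed = 77L)), d1)
  write_scenario(simulate_scenario(scenario("trmD_deg", n_genes = 10L,
                                            depth = 5000, seed = 77L)), d2)
  for (f in c("genome.fa", "orfs.bed", "footprints.tsv", "rnaseq.tsv",
              "config.yaml"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  d3 <- withr::local_tempdir()
  write_scenario(simulate_scenario(scenario("trmD_deg", n_genes = 10L,
                                            depth = 5000, seed = 78L)), d3)
  expect_false(identical(readLines(file.path(d1, "footprints.tsv")),
                         readLines(file.path(d3, "footprints.tsv"))))
})

test_that("codon frequencies converge to the usage law", {
  cfg <- scenario_config(n_genes = 400L, orf_length_codons = c(85L, 85L),
                         depth = 10, seed = 4L)
  tx <- simulate_transcriptome(cfg)
  # ~400 x 83 = 33200 interior codons (start/stop excluded)
  trip <- unlist(lapply(seq_len(nrow(tx$orfs)), function(i)
    orf_codons <- substring(tx$orfs$sequence[i],
                            seq(4, 3 * 84 - 2, by = 3),
                            seq(6, 3 * 84, by = 3))))
  n <- length(trip)
  p <- 1 / 61
  se <- sqrt(p * (1 - p) / n)
  freq <- table(factor(trip, levels = sense_codons())) / n
  expect_true(all(abs(freq - p) < 3.5 * se + 1e-6))
})

test_that("dwell calibration solves the joint closed form exactly", {
  cfg <- scenario_config(n_genes = 20L, orf_length_codons = c(60L, 150L),
                         seed = 8L, depth = 10)
  tx <- simulate_transcriptome(cfg)
  targets <- c(CCA = 3.5, CCG = 3.5, CGG = 3.0, CTA = 1.4)
  f <- calibrate_dwell(tx, targets, trim = 7L)
  # verify: expected instance-weighted mean score per family == target
  trim <- 7L
  nc <- (tx$orfs$end - tx$orfs$start) / 3
  k <- t(vapply(seq_len(nrow(tx$orfs)), function(i) {
    trip <- substring(tx$orfs$sequence[i],
                      3 * ((trim + 1):(nc[i] - trim)) - 2,
                      3 * ((trim + 1):(nc[i] - trim)))
    vapply(names(targets), function(cd) sum(trip == cd), numeric(1))
  }, numeric(length(targets))))
  L <- 3 * (nc - 2 * trim)
  D <- L + as.vector(k %*% (f - 1))
  for (j in seq_along(targets)) {
    expected_mean <- sum(k[, j] * f[j] * L / D) / sum(k[, j])
    expect_equal(expected_mean, unname(targets[j]), tolerance = 1e-9)
  }
  # factors exceed targets because enrichment inflates the gene mean
  expect_true(all(f >= targets - 1e-9))
})

test_that("uniform scenario recovers flat pause scores (null calibration)", {
  sim <- simulate_scenario(scenario("uniform", n_genes = 60L, depth = 3e5,
                                    seed = 21L))
  pt <- quiet_pipeline(sim$footprints, sim$transcriptome)
  expect_equal(mean(pt$per_codon$mean_score), 1, tolerance = 0.01)
  expect_true(all(abs(pt$per_codon$mean_score - 1) < 0.15))
})

test_that("RNA-seq read-through sets the leader/downstream density step", {
  fold_for <- function(rt, seed) {
    cfg <- scenario_config(
      attenuation = list(operon = "leu", readthrough_prob = rt),
      depth = 2e5, seed = seed)
    tx <- simulate_transcriptome(cfg)
    rna <- simulate_rnaseq(tx, cfg)
    tr <- build_track(rna, tx)
    attenuation_ratio(tr, tx$regions$leader,
                      tx$regions$downstream)$fold_decrease
  }
  expect_equal(fold_for(1, 6L), 1, tolerance = 0.05)
  expect_equal(fold_for(0.1, 6L), 10, tolerance = 0.08 * 10)
})

test_that("preset tables carry the published strain values", {
  expect_equal(unname(preset_targets("trmD_deg")[c("CCA", "CGG", "CTA")]),
               c(3.5, 3.0, 1.4))
  expect_equal(unname(preset_targets("trmD_cont")["CCG"]), 1.4)
  expect_equal(unname(preset_targets("trmD_KO_trm5minus")["CCC"]), 2.5)
  expect_equal(unname(preset_targets("trmD_WT_trm5minus")["CCT"]), 1.2)
  expect_error(preset_targets("nope"), "unknown")
  # arrest-buffer presets default to the 24-40 nt window
  expect_equal(scenario("trmD_KO_trm5minus")$read_length, c(24L, 40L))
  expect_equal(scenario("trmD_deg")$read_length, c(10L, 40L))
})

test_that("footprint lengths follow the configured law and 3' anchoring", {
  sim <- small_sim("trmD_KO_trm5minus", n_genes = 10L, depth = 2e4)
  expect_true(all(sim$footprints$length >= 24 &
                    sim$footprints$length <= 40))
  plus <- sim$footprints[sim$footprints$strand == "+", ]
  expect_true(all(plus$three_prime - plus$five_prime + 1L == plus$length))
  minus <- sim$footprints[sim$footprints$strand == "-", ]
  expect_true(all(minus$five_prime - minus$three_prime + 1L == minus$length))
})
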