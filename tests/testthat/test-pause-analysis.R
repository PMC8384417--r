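test_that("A-site shift moves density by the offset along coding direction", {
  tx <- toy_txome()
  tr <- empty_track(tx)
  tr <- set_density(tr, "chr", "+", 115L, 4)
  tr <- set_density(tr, "chr", "-", 210L, 2)

  expect_equal(shift_to_asite(tr, 0L)$values, tr$values)

  sh <- shift_to_asite(tr, 15L)
  expect_equal(sh$values$chr$`+`[100 + 1L], 4)   # + strand: p - offset
  expect_equal(sh$values$chr$`-`[225 + 1L], 2)   # - strand: p + offset
  expect_equal(track_total(sh), track_total(tr)) # interior counts conserved

  # density near the reference edge is dropped with a message
  tr2 <- set_density(empty_track(tx), "chr", "+", 5L, 1)
  expect_message(sh2 <- shift_to_asite(tr2, 15L), "dropped")
  expect_equal(track_total(sh2), 0)
})

test_that("gene mean density trims edges and handles empty tracks", {
  tx <- toy_txome()
  expect_equal(gene_mean_density(uniform_track(tx, 2), tx$orfs["geneA", ],
                                 trim_codons = 1L), 2.0)
  expect_equal(gene_mean_density(uniform_track(tx, 2), tx$orfs["geneA", ],
                                 trim_codons = 4L), 2.0)
  expect_equal(gene_mean_density(empty_track(tx), tx$orfs["geneA", ],
                                 trim_codons = 1L), 0)
  expect_error(gene_mean_density(empty_track(tx), tx$orfs["geneA", ],
                                 trim_codons = 5L), "no interior")

  # 30-codon ORF, all 60 reads within codon 10, trim 7:
  # interior = 30 - 14 = 16 codons = 48 nt -> 60/48 = 1.25 reads per nt
  orfs <- data.frame(gene_id = "g", ref_name = "chr", strand = "+",
                     start = 0L, end = 90L,
                     sequence = paste0("ATG", strrep("GCT", 28), "TAA"),
                     stringsAsFactors = FALSE)
  tx2 <- transcriptome(orfs, c(chr = 200L))
  tr <- set_density(empty_track(tx2), "chr", "+", 30:32, 20)
  expect_equal(gene_mean_density(tr, tx2$orfs["g", ], 7L), 60 / 48)
  expect_equal(60 / 48, 1.25)
})

test_that("gene coverage filter uses a strict threshold", {
  orfs <- data.frame(gene_id = "g", ref_name = "chr", strand = "+",
                     start = 0L, end = 180L,   # 60 codons
                     sequence = paste0("ATG", strrep("GCT", 58), "TAA"),
                     stringsAsFactors = FALSE)
  tx <- transcriptome(orfs, c(chr = 300L))
  place <- function(n) set_density(empty_track(tx), "chr", "+",
                                   seq_len(n) + 20L, 1)
  expect_false(gene_passes_filter(place(5), tx$orfs["g", ]))  # 0.083
  expect_true(gene_passes_filter(place(7), tx$orfs["g", ]))   # 0.117
  expect_false(gene_passes_filter(place(6), tx$orfs["g", ]))  # exactly 0.1
})

test_that("uniform tracks score exactly 1 and scores are scale invariant", {
  sim <- small_sim(n_genes = 4L, depth = 500)
  tx <- sim$transcriptome
  pt <- pause_scores(uniform_track(tx, 3.7), tx, shifted = TRUE)
  expect_true(all(pt$instances$score == 1))
  expect_true(all(pt$per_codon$mean_score == 1))
  expect_true(all(pt$per_amino_acid$mean_score == 1))

  tr <- build_track(sim$footprints, tx)
  p1 <- suppressMessages(pause_scores(tr, tx, min_reads_per_codon = 0))
  tr_scaled <- tr
  tr_scaled$values <- lapply(tr$values, function(v) lapply(v, `*`, 17.3))
  p2 <- suppressMessages(pause_scores(tr_scaled, tx,
                                      min_reads_per_codon = 0))
  expect_equal(p1$per_codon, p2$per_codon)
  expect_equal(p1$instances$score, p2$instances$score)
})

test_that("single-instance pause scores follow density / gene mean", {
  orfs <- data.frame(gene_id = "g", ref_name = "chr", strand = "+",
                     start = 0L, end = 90L,
                     sequence = paste0("ATG", strrep("CCA", 28), "TAA"),
                     stringsAsFactors = FALSE)
  tx <- transcriptome(orfs, c(chr = 200L))
  tr <- uniform_track(tx, 2)
  tr <- set_density(tr, "chr", "+", 3L * 10L, 10)  # codon 10 first nt
  pt <- pause_scores(tr, tx, shifted = TRUE, trim = 7L)
  gm <- gene_mean_density(tr, tx$orfs["g", ], 7L)
  inst <- pt$instances[pt$instances$codon_index == 10L, ]
  expect_equal(inst$score, 10 / gm)
  # zero density at the first nt is a legal score of 0
  tr0 <- set_density(tr, "chr", "+", 3L * 11L, 0)
  pt0 <- pause_scores(tr0, tx, shifted = TRUE)
  expect_equal(pt0$instances$score[pt0$instances$codon_index == 11L], 0)
})

test_that("pipeline table equals the brute-force oracle on a toy set", {
  sim <- small_sim(n_genes = 5L, depth = 5000, seed = 23L)
  reads <- sim$footprints
  pt <- quiet_pipeline(reads, sim$transcriptome, min_len = 10, max_len = 40)
  oracle <- brute_force_pause_table(
    reads[reads$length >= 10 & reads$length <= 40, ], sim$transcriptome)
  pc <- pt$per_codon[order(pt$per_codon$codon), ]
  expect_identical(pc$codon, oracle$codon)
  expect_equal(pc$mean_score, oracle$mean_score, tolerance = 1e-12)
  expect_identical(pc$n_instances, as.integer(oracle$n_instances))
})

test_that("stop codons are excluded and amino-acid aggregation is coherent", {
  sim <- small_sim(n_genes = 5L, depth = 5000)
  pt <- quiet_pipeline(sim$footprints, sim$transcriptome)
  expect_false(any(c("TAA", "TAG", "TGA") %in% pt$per_codon$codon))
  expect_true(all(pt$per_codon$codon %in% sense_codons()))
  # instance-weighted AA mean equals the weighted mean of its codon scores
  pro <- pt$per_codon[pt$per_codon$amino_acid == "P", ]
  expect_equal(pt$per_amino_acid["P", "mean_score"],
               sum(pro$mean_score * pro$n_instances) / sum(pro$n_instances))
  expect_equal(pt$per_amino_acid["P", "mean_of_codon_means"],
               mean(pro$mean_score))
})

test_that("closed-form recovery: score = f*L/(L + k(f-1)) within 3 SE", {
  # one hand-built gene with k = 4 interior CCG instances, dwell factor 6
  codons <- rep("GCT", 120)
  codons[1] <- "ATG"; codons[120] <- "TAA"
  codons[c(21, 41, 61, 81)] <- "CCG"   # 0-based indices 20, 40, 60, 80
  seqs <- paste(codons, collapse = "")
  genome <- Biostrings::DNAStringSet(paste0(strrep("A", 100), seqs,
                                            strrep("G", 100)))
  names(genome) <- "chr"
  orfs <- data.frame(gene_id = "g", ref_name = "chr", strand = "+",
                     start = 100L, end = 460L, sequence = seqs,
                     abundance = 1, stringsAsFactors = FALSE)
  tx <- transcriptome(orfs, c(chr = 560L), genome = genome)
  cfg <- scenario_config(n_genes = 1L, depth = 2e5, seed = 41L)
  fp <- simulate_footprints(tx, cfg, dwell = c(CCG = 6))
  pt <- quiet_pipeline(fp, tx, min_len = 10, max_len = 40)

  k <- 4; L <- 3 * (120 - 14); f <- 6
  expected <- f * L / (L + k * (f - 1))
  got <- pt$per_codon["CCG", ]
  expect_equal(got$n_instances, 4L)
  se <- stats::sd(pt$instances$score[pt$instances$triplet == "CCG"]) /
    sqrt(got$n_instances)
  expect_lt(abs(got$mean_score - expected), 3 * se + 0.02)
})

test_that("overlap exclusion and already-shifted tracks are honored", {
  tx <- toy_txome()
  orfs <- tx$orfs[, c("gene_id", "ref_name", "strand", "start", "end",
                      "sequence")]
  ov <- data.frame(gene_id = "ovl", ref_name = "chr", strand = "+",
                   start = 109L, end = 199L,
                   sequence = substr(as.character(tx$genome[["chr"]]),
                                     110, 199),
                   stringsAsFactors = FALSE)
  tx2 <- suppressWarnings(transcriptome(rbind(orfs, ov), tx$ref_lengths))
  tr <- uniform_track(tx2, 1)
  pt_all <- pause_scores(tr, tx2, shifted = TRUE, trim = 1L,
                         min_reads_per_codon = 0)
  pt_excl <- pause_scores(tr, tx2, shifted = TRUE, trim = 1L,
                          min_reads_per_codon = 0, exclude_overlaps = TRUE)
  genes_all <- unique(pt_all$instances$gene_id)
  genes_excl <- unique(pt_excl$instances$gene_id)
  expect_true("ovl" %in% genes_all)
  expect_false("ovl" %in% genes_excl)
  expect_false("geneA" %in% genes_excl)  # flagged by the overlap
  expect_true("geneB" %in% genes_excl)
})
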