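# All fixtures are built in code at test time.

# A tiny hand-assembled transcriptome: one plus- and one minus-strand ORF on
# one reference, with the genome sequence carried along.
toy_txome <- function() {
  # gene A: 30 nt (10 codons) at [100, 130) on +
  seq_a <- paste0("ATG", "CCAGGTCGGCTAAAATTTGGGCCC", "TAA")
  # gene B: 30 nt at [200, 230) on -
  seq_b <- paste0("ATG", "CGGCCAACGTTAGCTATGCATCAA", "TAA")
  stopifnot(nchar(seq_a) == 30, nchar(seq_b) == 30)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  genome_str <- paste0(strrep("A", 100), seq_a, strrep("C", 70),
                       rc(seq_b), strrep("G", 70))
  genome <- Biostrings::DNAStringSet(genome_str)
  names(genome) <- "chr"
  orfs <- data.frame(
    gene_id = c("geneA", "geneB"), ref_name = "chr",
    strand = c("+", "-"), start = c(100L, 200L), end = c(130L, 230L),
    sequence = c(seq_a, seq_b), stringsAsFactors = FALSE)
  transcriptome(orfs, c(chr = nchar(genome_str)), genome = genome)
}

# An empty raw track over a transcriptome's references.
empty_track <- function(txome) {
  values <- lapply(txome$ref_lengths, function(n)
    list(`+` = numeric(n), `-` = numeric(n)))
  structure(list(values = values, ref_lengths = txome$ref_lengths,
                 total_mapped = 0L, units = "raw"),
            class = "density_track")
}

# A track with constant density `value` at every coding position of every ORF
# (on the ORF's strand), zero elsewhere.
uniform_track <- function(txome, value = 2) {
  tr <- empty_track(txome)
  for (i in seq_len(nrow(txome$orfs))) {
    orf <- txome$orfs[i, ]
    pos <- if (orf$strand == "+") orf$start:(orf$end - 1L)
           else orf$start:(orf$end - 1L)
    tr$values[[orf$ref_name]][[orf$strand]][pos + 1L] <- value
  }
  tr$total_mapped <- as.integer(round(track_total(tr)))
  tr
}

# Set track density at given 0-based positions.
set_density <- function(track, ref, strand, pos0, value) {
  track$values[[ref]][[strand]][pos0 + 1L] <- value
  track$total_mapped <- as.integer(round(track_total(track)))
  track
}

# A quick small simulated scenario for pipeline-level tests.
small_sim <- function(name = "uniform", n_genes = 5L, depth = 2e4,
                      seed = 11L, ...) {
  cfg <- scenario(name, n_genes = n_genes, depth = depth, seed = seed,
                  orf_length_codons = c(20L, 60L), gap = 80L, ...)
  simulate_scenario(cfg)
}

quiet_pipeline <- function(...) suppressMessages(pause_pipeline(...))
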