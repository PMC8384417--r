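# Generative model for footprint and RNA-seq data. Footprints: a gene is
# sampled proportionally to abundance x total dwell, a ribosome position
# within the gene proportionally to per-nt dwell (enriched codons get an
# elevated weight at their first nt), and the observed 3' end is the position
# plus the A-site offset. Optional run-on blurring advances ribosomes a
# geometric number of codons post-lysis; optional collisions stack an extra
# footprint ~25 nt upstream of paused positions. RNA-seq: read 3' ends
# uniform within each ORF, proportional to abundance; an attenuation operon
# sets downstream abundance = leader abundance x readthrough probability.

# One versioned table of preset values: published strain-level mean pause
# scores per codon family and leader->downstream RNA density fold-decreases,
# plus the operon geometries used to emulate them.
preset_table <- function() {
  pro <- c("CCA", "CCC", "CCG", "CCT")
  list(
    version = "1.0",
    pause = list(
      uniform = numeric(0),
      trmD_cont = stats::setNames(rep(1.4, 4), pro),
      trmD_deg = c(stats::setNames(rep(3.5, 4), pro), CGG = 3.0, CTA = 1.4),
      trmD_WT_trm5minus = stats::setNames(rep(1.2, 4), pro),
      trmD_KO_trm5minus = c(stats::setNames(rep(2.5, 4), pro),
                            CGG = 3.0, CTA = 1.4)),
    read_length = list(
      uniform = c(10L, 40L), trmD_cont = c(10L, 40L), trmD_deg = c(10L, 40L),
      trmD_WT_trm5minus = c(24L, 40L), trmD_KO_trm5minus = c(24L, 40L)),
    attenuation_fold = list(leu = c(control = 29, deg = 4),
                            ilv = c(control = 45, deg = 9)),
    geometry = list(
      leu = list(leader_codons = 29L, gene_codons = 524L,
                 downstream_fraction = 1, leader_id = "leuL",
                 gene_id = "leuA"),
      ilv = list(leader_codons = 33L, gene_codons = 549L,
                 downstream_fraction = 0.5, leader_id = "ilvL",
                 gene_id = "ilvG")))
}

#' Published per-codon pause-score targets of a strain preset
#' @param name preset name.
#' @return Named numeric vector of target mean pause scores (DNA codons).
#' @export
preset_targets <- function(name) {
  tab <- preset_table()$pause
  if (!name %in% names(tab)) stop("unknown pause preset: ", name)
  tab[[name]]
}

#' Scenario configuration for the synthetic generator
#'
#' All randomness is governed by \code{seed}; identical configurations
#' produce byte-identical outputs.
#'
#' @param n_genes number of ORFs.
#' @param orf_length_codons inclusive (min, max) ORF length in codons,
#'   sampled uniformly.
#' @param codon_usage named probability vector over the 61 sense codons
#'   (default uniform).
#' @param expression_meanlog,expression_sdlog log-normal law of per-gene
#'   transcript abundance.
#' @param dwell_enrichment named factors (codon -> factor >= 0) applied at
#'   each codon's first nt; unlisted codons have factor 1.
#' @param pause_targets named target mean pause scores; when set, dwell
#'   factors are solved from the targets on the realized transcriptome
#'   (overrides \code{dwell_enrichment}).
#' @param dwell_mode "first_nt" (matches the measured statistic) or
#'   "whole_codon" (robustness mode).
#' @param read_length inclusive (min, max) footprint length in nt, uniform.
#' @param rna_read_length same for RNA-seq reads.
#' @param asite_offset nt from a ribosome's A-site first nt to the footprint
#'   3' end.
#' @param runon_blur probability that a ribosome translates one further codon
#'   post-lysis (geometric run-on; 0 = arrested at lysis).
#' @param collision_prob probability that a footprint at an enriched position
#'   seeds a stacked footprint ~25 nt upstream (+/- 2 nt jitter).
#' @param attenuation NULL, or list(operon = "leu"/"ilv",
#'   readthrough_prob) replacing the generic transcriptome with a
#'   leader + downstream-gene operon.
#' @param depth number of primary reads.
#' @param gap nt of random intergenic sequence between ORFs.
#' @param seed integer seed.
#' @return A \code{scenario_config} list.
#' @export
scenario_config <- function(n_genes = 200L, orf_length_codons = c(150L, 450L),
                            codon_usage = NULL, expression_meanlog = 0,
                            expression_sdlog = 1, dwell_enrichment = NULL,
                            pause_targets = NULL,
                            dwell_mode = c("first_nt", "whole_codon"),
                            read_length = c(10L, 40L),
                            rna_read_length = c(30L, 50L),
                            asite_offset = 15L, runon_blur = 0,
                            collision_prob = 0, attenuation = NULL,
                            depth = 1e6, gap = 100L, seed = 1L) {
  dwell_mode <- match.arg(dwell_mode)
  if (is.null(codon_usage)) {
    codon_usage <- stats::setNames(rep(1 / 61, 61), sense_codons())
  } else {
    names(codon_usage) <- normalize_codons(names(codon_usage))
    if (!setequal(names(codon_usage), sense_codons()))
      stop("codon_usage must be named by the 61 sense codons")
    if (abs(sum(codon_usage) - 1) > 1e-8 || any(codon_usage < 0))
      stop("codon_usage must be a probability vector")
    codon_usage <- codon_usage[sense_codons()]
  }
  stopifnot(length(orf_length_codons) == 2,
            orf_length_codons[1] >= 5L,
            orf_length_codons[1] <= orf_length_codons[2],
            read_length[1] <= read_length[2],
            runon_blur >= 0, runon_blur < 1,
            collision_prob >= 0, collision_prob <= 1,
            asite_offset >= 0, depth >= 1, gap >= 60L)
  if (!is.null(dwell_enrichment))
    names(dwell_enrichment) <- normalize_codons(names(dwell_enrichment))
  if (!is.null(pause_targets))
    names(pause_targets) <- normalize_codons(names(pause_targets))
  if (!is.null(attenuation)) {
    stopifnot(attenuation$operon %in% c("leu", "ilv"),
              attenuation$readthrough_prob > 0,
              attenuation$readthrough_prob <= 1)
  }
  structure(list(n_genes = as.integer(n_genes),
                 orf_length_codons = as.integer(orf_length_codons),
                 codon_usage = codon_usage,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 dwell_enrichment = dwell_enrichment,
                 pause_targets = pause_targets, dwell_mode = dwell_mode,
                 read_length = as.integer(read_length),
                 rna_read_length = as.integer(rna_read_length),
                 asite_offset = as.integer(asite_offset),
                 runon_blur = runon_blur, collision_prob = collision_prob,
                 attenuation = attenuation, depth = as.integer(depth),
                 gap = as.integer(gap), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Named scenario presets
#'
#' Pause presets set per-codon target scores to the published strain values
#' (solved into dwell factors on the realized transcriptome); the trm5-
#' presets use the 24-40 nt high-Mg2+ arrest read-length window. Attenuation
#' presets configure a two-segment operon whose read-through probability is
#' the inverse of the published leader-to-downstream fold-decrease.
#'
#' @param name one of "uniform", "trmD_cont", "trmD_deg",
#'   "trmD_WT_trm5minus", "trmD_KO_trm5minus", "attenuation_control",
#'   "attenuation_deg".
#' @param operon "leu" or "ilv" (attenuation presets only).
#' @param ... overrides passed to \code{\link{scenario_config}} (e.g.
#'   \code{depth}, \code{seed}, \code{n_genes}, \code{runon_blur}).
#' @return A \code{scenario_config}.
#' @export
scenario <- function(name = c("uniform", "trmD_cont", "trmD_deg",
                              "trmD_WT_trm5minus", "trmD_KO_trm5minus",
                              "attenuation_control", "attenuation_deg"),
                     operon = c("leu", "ilv"), ...) {
  name <- match.arg(name)
  operon <- match.arg(operon)
  tab <- preset_table()
  over <- list(...)
  if (name %in% names(tab$pause)) {
    targets <- tab$pause[[name]]
    args <- list(pause_targets = if (length(targets)) targets else NULL,
                 read_length = tab$read_length[[name]])
  } else {
    strain <- sub("attenuation_", "", name)
    fold <- tab$attenuation_fold[[operon]][[strain]]
    args <- list(attenuation = list(operon = operon,
                                    readthrough_prob = 1 / fold))
  }
  do.call(scenario_config, utils::modifyList(args, over))
}

# Uniform integer draw over an inclusive [min, max] range (robust to
# degenerate single-value ranges, unlike sample()).
sample_range <- function(range, n) {
  vals <- seq.int(range[1], range[2])
  vals[sample.int(length(vals), n, replace = TRUE)]
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a transcriptome
#'
#' Generic mode: \code{n_genes} ORFs (start codon, interior codons drawn from
#' \code{codon_usage}, stop codon) placed on one synthetic reference with
#' random intergenic gaps, random strands, and log-normal per-gene abundance.
#' Attenuation mode (when \code{config$attenuation} is set): a two-segment
#' operon (leader ORF + downstream gene) with downstream abundance = leader
#' abundance x readthrough probability; the measurement regions are attached
#' as \code{txome$regions}.
#'
#' @param config a \code{scenario_config}.
#' @return A \code{transcriptome} with an \code{abundance} column and the
#'   genome sequences attached.
#' @export
simulate_transcriptome <- function(config) {
  set.seed(config$seed)
  if (!is.null(config$attenuation))
    return(simulate_operon(config))
  n <- config$n_genes
  lens <- sample_range(config$orf_length_codons, n)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  usage <- config$codon_usage
  seqs <- vapply(lens, function(L) {
    paste0("ATG",
           paste(sample(names(usage), L - 2L, replace = TRUE, prob = usage),
                 collapse = ""),
           sample(c("TAA", "TAG", "TGA"), 1L))
  }, character(1))
  abundance <- stats::rlnorm(n, config$expression_meanlog,
                             config$expression_sdlog)

  gap <- config$gap
  starts <- integer(n)
  pieces <- character(2L * n + 1L)
  at <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- random_nt(gap)
    at <- at + gap
    starts[i] <- at
    coding <- seqs[i]
    if (strands[i] == "-")
      coding <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(coding)))
    pieces[2L * i] <- coding
    at <- at + nchar(seqs[i])
  }
  pieces[2L * n + 1L] <- random_nt(gap)
  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- "synthetic_chr"

  orfs <- data.frame(gene_id = sprintf("gene%03d", seq_len(n)),
                     ref_name = "synthetic_chr", strand = strands,
                     start = starts, end = starts + 3L * lens,
                     sequence = seqs, abundance = abundance,
                     stringsAsFactors = FALSE)
  transcriptome(orfs, c(synthetic_chr = at + gap), genome = genome)
}

simulate_operon <- function(config) {
  geo <- preset_table()$geometry[[config$attenuation$operon]]
  usage <- config$codon_usage
  mk_seq <- function(nc)
    paste0("ATG",
           paste(sample(names(usage), nc - 2L, replace = TRUE, prob = usage),
                 collapse = ""), "TAA")
  leader_len <- 3L * geo$leader_codons
  gene_len <- 3L * geo$gene_codons
  gap <- 150L
  leader_start <- 100L
  gene_start <- leader_start + leader_len + gap
  total <- gene_start + gene_len + 100L

  leader_seq <- mk_seq(geo$leader_codons)
  gene_seq <- mk_seq(geo$gene_codons)
  genome <- Biostrings::DNAStringSet(paste0(
    random_nt(leader_start), leader_seq, random_nt(gap), gene_seq,
    random_nt(100L)))
  names(genome) <- "operon"

  rt <- config$attenuation$readthrough_prob
  orfs <- data.frame(
    gene_id = c(geo$leader_id, geo$gene_id), ref_name = "operon",
    strand = "+",
    start = c(leader_start, gene_start),
    end = c(leader_start + leader_len, gene_start + gene_len),
    sequence = c(leader_seq, gene_seq),
    abundance = c(1, rt), stringsAsFactors = FALSE)
  txome <- transcriptome(orfs, c(operon = total), genome = genome)
  down_len <- as.integer(round(gene_len * geo$downstream_fraction))
  txome$regions <- list(
    leader = region("operon", leader_start, leader_start + leader_len, "+",
                    geo$leader_id),
    downstream = region("operon", gene_start, gene_start + down_len, "+",
                        geo$gene_id))
  txome
}

#' Solve dwell enrichment factors from target pause scores
#'
#' For one enriched codon in an otherwise uniform gene, the expected
#' recovered score at dwell factor f is f * L / (L + k (f - 1)), with L the
#' interior nt length and k the interior instance count, because the enriched
#' instances inflate the gene-mean denominator. With several enriched
#' families sharing the denominator, the factors are solved jointly by fixed
#' point so that the expected instance-weighted mean score of each family
#' over the realized transcriptome equals its target.
#'
#' @param txome a \code{transcriptome}.
#' @param targets named target mean scores (codon -> score).
#' @param trim edge codons excluded from scoring (must match the analysis).
#' @return Named dwell factors, same names as \code{targets}.
#' @export
calibrate_dwell <- function(txome, targets, trim = 7L) {
  if (length(targets) == 0) return(numeric(0))
  orfs <- txome$orfs
  nc <- as.integer((orfs$end - orfs$start) / 3L)
  use <- nc > 2L * trim
  cods <- names(targets)
  k <- matrix(0L, nrow(orfs), length(cods),
              dimnames = list(orfs$gene_id, cods))
  for (i in which(use)) {
    trip <- orf_codons(orfs[i, ])[(trim + 1L):(nc[i] - trim)]
    tt <- table(factor(trip, levels = cods))
    k[i, ] <- as.integer(tt)
  }
  L <- ifelse(use, 3 * (nc - 2L * trim), 0)
  N <- colSums(k)
  if (any(N == 0))
    stop("no interior instances of: ",
         paste(cods[N == 0], collapse = ","))
  f <- targets
  for (it in 1:200) {
    D <- L + as.numeric(k %*% (f - 1))
    S <- colSums(k * ifelse(D > 0, L / D, 0))
    f_new <- targets * N / S
    if (max(abs(f_new - f)) < 1e-12) { f <- f_new; break }
    f <- f_new
  }
  f
}

# Per-nt dwell weight vector of one ORF under the enrichment map.
dwell_weights <- function(orf, dwell, mode = "first_nt") {
  L <- orf$end - orf$start
  w <- rep(1, L)
  if (length(dwell) == 0) return(w)
  trip <- orf_codons(orf)
  for (cod in names(dwell)) {
    hit <- which(trip == cod) - 1L
    if (length(hit) == 0) next
    if (mode == "first_nt") w[3L * hit + 1L] <- dwell[[cod]]
    else w[as.vector(outer(1:3, 3L * hit, `+`))] <- dwell[[cod]]
  }
  w
}

#' Simulate ribosome footprints
#'
#' @param txome a \code{transcriptome} with abundances (from
#'   \code{\link{simulate_transcriptome}}).
#' @param config a \code{scenario_config}.
#' @param dwell named dwell factors; by default resolved from the config
#'   (calibrated targets if set, else \code{dwell_enrichment}).
#' @return data.frame of aligned reads (\code{ref_name}, \code{strand},
#'   \code{five_prime}, \code{three_prime}, \code{length}) with the resolved
#'   dwell factors as attribute \code{"dwell_factors"}.
#' @export
simulate_footprints <- function(txome, config, dwell = NULL) {
  if (is.null(dwell)) {
    dwell <- if (!is.null(config$pause_targets))
      calibrate_dwell(txome, config$pause_targets)
    else if (!is.null(config$dwell_enrichment)) config$dwell_enrichment
    else numeric(0)
  }
  set.seed(config$seed + 1L)
  orfs <- txome$orfs
  n <- nrow(orfs)
  w_list <- lapply(seq_len(n), function(i)
    dwell_weights(orfs[i, ], dwell, config$dwell_mode))
  gene_w <- orfs$abundance * vapply(w_list, sum, numeric(1))
  gene_idx <- sample.int(n, config$depth, replace = TRUE, prob = gene_w)
  cnt <- tabulate(gene_idx, nbins = n)

  active <- which(cnt > 0L)
  pos_l <- lapply(active, function(i)
    sample.int(length(w_list[[i]]), cnt[i], replace = TRUE,
               prob = w_list[[i]]) - 1L)
  gene <- rep.int(active, cnt[active])
  pos <- unlist(pos_l, use.names = FALSE)

  if (config$runon_blur > 0) {
    adv <- 3L * stats::rgeom(length(pos), prob = 1 - config$runon_blur)
    pos <- pos + adv
    L <- (orfs$end - orfs$start)[gene]
    keep <- pos < L
    gene <- gene[keep]; pos <- pos[keep]
  }

  if (config$collision_prob > 0 && length(dwell) > 0) {
    enriched <- logical(length(pos))
    for (idx in split(seq_along(pos), gene)) {
      g <- gene[idx[1]]
      enriched[idx] <- w_list[[g]][pos[idx] + 1L] > 1
    }
    coll <- enriched & stats::runif(length(pos)) < config$collision_prob
    if (any(coll)) {
      cpos <- pos[coll] - 25L + sample(-2:2, sum(coll), replace = TRUE)
      cgene <- gene[coll]
      gene <- c(gene, cgene)
      pos <- c(pos, cpos)
    }
  }

  len <- sample_range(config$read_length, length(pos))
  reads <- positions_to_reads(txome, gene, pos, len, config$asite_offset)
  attr(reads, "dwell_factors") <- dwell
  reads
}

# Map within-ORF coding positions (0-based, position of the ribosome A-site
# first nt) to genomic read coordinates: 3' end = position + offset along the
# coding direction.
positions_to_reads <- function(txome, gene, pos, len, offset) {
  orfs <- txome$orfs
  st <- orfs$strand[gene]
  plus <- st == "+"
  three <- orfs$start[gene] + pos + offset
  three[!plus] <- (orfs$end[gene] - 1L - pos - offset)[!plus]
  five <- three - (len - 1L)
  five[!plus] <- (three + (len - 1L))[!plus]
  rl <- txome$ref_lengths[orfs$ref_name[gene]]
  keep <- three >= 0L & three < rl & five >= 0L & five < rl
  data.frame(ref_name = orfs$ref_name[gene], strand = st,
             five_prime = as.integer(five), three_prime = as.integer(three),
             length = as.integer(len),
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

#' Simulate RNA-seq reads
#'
#' Read 3' ends are uniform within each ORF, with genes sampled
#' proportionally to abundance x length; under an attenuation configuration
#' the operon transcriptome already encodes the leader/downstream abundance
#' step.
#'
#' @param txome a \code{transcriptome} with abundances.
#' @param config a \code{scenario_config}.
#' @return data.frame of aligned reads.
#' @export
simulate_rnaseq <- function(txome, config) {
  set.seed(config$seed + 2L)
  orfs <- txome$orfs
  n <- nrow(orfs)
  L <- orfs$end - orfs$start
  gene_idx <- sample.int(n, config$depth, replace = TRUE,
                         prob = orfs$abundance * L)
  cnt <- tabulate(gene_idx, nbins = n)
  active <- which(cnt > 0L)
  gene <- rep.int(active, cnt[active])
  pos <- unlist(lapply(active, function(i)
    sample.int(L[i], cnt[i], replace = TRUE) - 1L), use.names = FALSE)
  len <- sample_range(config$rna_read_length, length(pos))
  positions_to_reads(txome, gene, pos, len, 0L)
}

#' Run a full scenario simulation
#'
#' @param config a \code{scenario_config} (see \code{\link{scenario}} for
#'   presets).
#' @return A \code{ribopause_simulation}: list with \code{transcriptome},
#'   \code{footprints}, \code{rnaseq}, \code{dwell_factors}, \code{config}.
#' @export
simulate_scenario <- function(config) {
  txome <- simulate_transcriptome(config)
  fp <- simulate_footprints(txome, config)
  rna <- simulate_rnaseq(txome, config)
  structure(list(transcriptome = txome, footprints = fp, rnaseq = rna,
                 dwell_factors = attr(fp, "dwell_factors"), config = config),
            class = "ribopause_simulation")
}

#' @export
print.ribopause_simulation <- function(x, ...) {
  cat("Simulated scenario: ", nrow(x$transcriptome$orfs), " ORFs, ",
      nrow(x$footprints), " footprints, ", nrow(x$rnaseq),
      " RNA-seq reads (seed ", x$config$seed, ")\n", sep = "")
  if (length(x$dwell_factors) > 0) {
    cat("  dwell factors:\n")
    print(round(x$dwell_factors, 3))
  }
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits the genome FASTA, ORF BED, footprint and RNA-seq TSVs, and the
#' resolved configuration (including solved dwell factors and the preset
#' table version) as YAML.
#'
#' @param sim a \code{ribopause_simulation}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcriptome(sim$transcriptome, file.path(dir, "genome.fa"),
                      file.path(dir, "orfs.bed"))
  write_alignments_tsv(sim$footprints, file.path(dir, "footprints.tsv"))
  write_alignments_tsv(sim$rnaseq, file.path(dir, "rnaseq.tsv"))
  cfg <- sim$config
  cfg$codon_usage <- as.list(cfg$codon_usage)
  resolved <- c(unclass(cfg),
                list(dwell_factors = as.list(sim$dwell_factors),
                     preset_table_version = preset_table()$version))
  yaml::write_yaml(resolved, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Footprints-to-pause-scores convenience pipeline
#'
#' Applies the read-length filter, builds the raw 3'-end track, and computes
#' the pause-score table.
#'
#' @param reads data.frame of aligned reads or path to an alignment file.
#' @param txome a \code{transcriptome}.
#' @param min_len,max_len read-length window.
#' @param asite_offset,trim,min_reads_per_codon,exclude_overlaps passed to
#'   \code{\link{pause_scores}}.
#' @return A \code{pause_score_table}.
#' @export
pause_pipeline <- function(reads, txome, min_len = 10L, max_len = 40L,
                           asite_offset = 15L, trim = 7L,
                           min_reads_per_codon = 0.1,
                           exclude_overlaps = FALSE) {
  if (is.character(reads))
    reads <- read_alignments(reads, min_len, max_len)
  else
    reads <- reads[reads$length >= min_len & reads$length <= max_len, ,
                   drop = FALSE]
  track <- build_track(reads, txome, normalize = "raw")
  pause_scores(track, txome, asite_offset = asite_offset, trim = trim,
               min_reads_per_codon = min_reads_per_codon,
               exclude_overlaps = exclude_overlaps)
}
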