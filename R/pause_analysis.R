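# A-site pause scores. The statistic: for each instance of a codon, the
# density at the first nt of the codon (A-site-shifted track) divided by the
# mean per-nt density of its ORF, then averaged over all instances of each
# codon type across the transcriptome. The first and last `trim` codons of
# every ORF are excluded both from the instance set and from the gene-mean
# denominator, so a strictly uniform track scores exactly 1 everywhere.

#' Shift a 3'-end density track to A-site positions
#'
#' Reattributes the density at each 3'-end position p to the coding-direction
#' position p - offset (strand-aware: p - offset on the plus strand,
#' p + offset on the minus strand). Counts shifted off the reference are
#' dropped with a message; interior counts are conserved.
#'
#' @param track a \code{density_track} of 3'-end counts.
#' @param offset non-negative A-site offset in nt (distance from the
#'   footprint 3' end back to the first nt of the A-site codon). The default
#'   15 nt is the canonical bacterial footprint geometry; override per sample.
#' @return The shifted \code{density_track}.
#' @export
shift_to_asite <- function(track, offset = 15L) {
  stopifnot(offset >= 0)
  offset <- as.integer(offset)
  if (offset == 0L) return(track)
  lost <- 0
  for (ref in names(track$values)) {
    n <- track$ref_lengths[[ref]]
    p <- track$values[[ref]][["+"]]
    new_p <- numeric(n)
    if (n > offset)
      new_p[seq_len(n - offset)] <- p[(offset + 1L):n]
    lost <- lost + sum(p[seq_len(min(offset, n))])
    m <- track$values[[ref]][["-"]]
    new_m <- numeric(n)
    if (n > offset)
      new_m[(offset + 1L):n] <- m[seq_len(n - offset)]
    lost <- lost + sum(m[seq.int(n, by = -1L, length.out = min(offset, n))])
    track$values[[ref]][["+"]] <- new_p
    track$values[[ref]][["-"]] <- new_m
  }
  if (lost > 0)
    message(format(lost), " unit(s) of density shifted off-reference dropped")
  track
}

# Per-nt density over an ORF, ordered 5'->3' along the coding strand.
orf_density <- function(track, orf) {
  v <- track$values[[orf$ref_name]][[orf$strand]]
  v[orf_coding_positions(orf) + 1L]
}

#' Mean per-nucleotide density on an ORF interior
#'
#' Mean density over the ORF excluding the first and last \code{trim_codons}
#' codons, matching the trimming applied to the pause-score instance set.
#'
#' @param track a \code{density_track}.
#' @param orf one-row ORF data.frame.
#' @param trim_codons codons trimmed from each end (default 7).
#' @return Mean reads (or rpm) per nt over the interior.
#' @export
gene_mean_density <- function(track, orf, trim_codons = 7L) {
  nc <- n_codons(orf)
  if (nc <= 2L * trim_codons)
    stop("ORF ", orf$gene_id, " has no interior after trimming ",
         trim_codons, " codons from each end")
  d <- orf_density(track, orf)
  mean(d[(3L * trim_codons + 1L):(length(d) - 3L * trim_codons)])
}

#' Gene-level coverage filter
#'
#' A gene is analyzed only when its average footprint coverage exceeds
#' \code{min_reads_per_codon} reads per codon over the whole ORF (strict
#' inequality; a gene at exactly the threshold is excluded).
#'
#' @param track a \code{density_track} (raw counts).
#' @param orf one-row ORF data.frame.
#' @param min_reads_per_codon threshold, default 0.1.
#' @return Logical.
#' @export
gene_passes_filter <- function(track, orf, min_reads_per_codon = 0.1) {
  sum(orf_density(track, orf)) / n_codons(orf) > min_reads_per_codon
}

#' Per-codon A-site pause scores
#'
#' Computes, for every instance of every sense codon in the transcriptome,
#' the A-site-shifted density at the first nt of the codon divided by the
#' mean density of its ORF, and aggregates unweighted instance means per
#' codon type and per amino acid. The first and last \code{trim} codons of
#' each ORF are ignored; genes are included only when they carry more than
#' \code{min_reads_per_codon} reads per codon on average; stop codons are
#' never scored.
#'
#' @param track a \code{density_track} of 3'-end counts (raw counts
#'   recommended; the score is scale-invariant).
#' @param transcriptome a \code{transcriptome}.
#' @param asite_offset nt between the footprint 3' end and the first nt of
#'   the A-site codon (default 15; ignored when \code{shifted = TRUE}).
#' @param trim codons ignored at each ORF end (default 7).
#' @param min_reads_per_codon gene-inclusion threshold (default 0.1, strict).
#' @param exclude_overlaps drop genes flagged as overlapping another ORF.
#' @param shifted set TRUE if \code{track} is already A-site shifted.
#' @return An object of class \code{pause_score_table}: list with
#'   \code{per_codon} (codon, amino_acid, mean_score, n_instances),
#'   \code{per_amino_acid} (instance-level mean and mean of codon means),
#'   \code{instances} (per-instance scores), \code{asite_offset}, and the
#'   filter settings used.
#' @export
pause_scores <- function(track, transcriptome, asite_offset = 15L,
                         trim = 7L, min_reads_per_codon = 0.1,
                         exclude_overlaps = FALSE, shifted = FALSE) {
  if (!shifted) track <- shift_to_asite(track, asite_offset)
  orfs <- transcriptome$orfs
  sense <- sense_codons()

  res <- vector("list", nrow(orfs))
  n_filtered <- 0L
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    nc <- n_codons(orf)
    if (nc <= 2L * trim) next
    if (exclude_overlaps && orf$overlaps) next
    if (!gene_passes_filter(track, orf, min_reads_per_codon)) {
      n_filtered <- n_filtered + 1L
      next
    }
    d <- orf_density(track, orf)
    interior <- (3L * trim + 1L):(length(d) - 3L * trim)
    gm <- mean(d[interior])
    if (gm == 0) next
    idx <- trim:(nc - trim - 1L)                    # 0-based codon indices
    trip <- orf_codons(orf)[idx + 1L]
    keep <- trip %in% sense
    idx <- idx[keep]; trip <- trip[keep]
    if (length(idx) == 0) next
    res[[i]] <- data.frame(gene_id = orf$gene_id, codon_index = idx,
                           triplet = trip,
                           score = d[3L * idx + 1L] / gm,
                           stringsAsFactors = FALSE)
  }
  instances <- do.call(rbind, res)
  if (is.null(instances) || nrow(instances) == 0)
    stop("no codon instances survive the gene filters")

  mean_by <- tapply(instances$score, instances$triplet, mean)
  n_by <- tapply(instances$score, instances$triplet, length)
  per_codon <- data.frame(codon = names(mean_by),
                          amino_acid = codon_to_aa(names(mean_by)),
                          mean_score = as.numeric(mean_by),
                          n_instances = as.integer(n_by),
                          stringsAsFactors = FALSE)
  per_codon <- per_codon[order(per_codon$amino_acid, per_codon$codon), ]
  rownames(per_codon) <- per_codon$codon

  aa <- codon_to_aa(instances$triplet)
  aa_mean <- tapply(instances$score, aa, mean)
  aa_codon_mean <- tapply(per_codon$mean_score, per_codon$amino_acid, mean)
  per_aa <- data.frame(amino_acid = names(aa_mean),
                       mean_score = as.numeric(aa_mean),
                       mean_of_codon_means =
                         as.numeric(aa_codon_mean[names(aa_mean)]),
                       n_instances =
                         as.integer(tapply(instances$score, aa, length)),
                       stringsAsFactors = FALSE)
  rownames(per_aa) <- per_aa$amino_acid

  structure(list(per_codon = per_codon, per_amino_acid = per_aa,
                 instances = instances,
                 asite_offset = if (shifted) NA_integer_
                                else as.integer(asite_offset),
                 filters = list(trim = as.integer(trim),
                                min_reads_per_codon = min_reads_per_codon,
                                exclude_overlaps = exclude_overlaps),
                 n_genes_scored = length(unique(instances$gene_id)),
                 n_genes_below_coverage = n_filtered),
            class = "pause_score_table")
}

#' @export
print.pause_score_table <- function(x, n = 10, ...) {
  cat("A-site pause scores:", nrow(x$per_codon), "codon types,",
      nrow(x$instances), "instances over", x$n_genes_scored, "genes\n")
  cat("  offset =", x$asite_offset, "nt; trim =", x$filters$trim,
      "codons; min coverage >", x$filters$min_reads_per_codon,
      "reads/codon (", x$n_genes_below_coverage, "genes excluded )\n")
  top <- x$per_codon[order(-x$per_codon$mean_score), ][seq_len(
    min(n, nrow(x$per_codon))), ]
  cat("  highest mean scores:\n")
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.pause_score_table <- function(object, ...) {
  object$per_amino_acid[order(-object$per_amino_acid$mean_score), ]
}

#' @export
plot.pause_score_table <- function(x, ...) {
  pc <- x$per_codon
  cols <- ifelse(pc$amino_acid == "P", "firebrick",
                 ifelse(pc$codon == "CGG", "forestgreen",
                        ifelse(pc$codon == "CTA", "dodgerblue", "grey60")))
  graphics::barplot(pc$mean_score, names.arg = pc$codon, las = 2,
                    cex.names = 0.55, col = cols, border = NA,
                    ylab = "mean pause score", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Write a pause-score table as TSV
#' @param x a \code{pause_score_table}.
#' @param path output path.
#' @param instances also write per-instance scores to
#'   \code{<path>.instances.tsv}.
#' @return Invisibly, \code{path}.
#' @export
write_pause_table <- function(x, path, instances = FALSE) {
  utils::write.table(x$per_codon, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (instances)
    utils::write.table(x$instances, paste0(path, ".instances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
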