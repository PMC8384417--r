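# Gene-level quantification (rpm counts -> RPKM, ribosome occupancy),
# leader-vs-downstream transcriptional-attenuation density ratios, and
# gene-set expression-shift comparisons.

#' Per-gene expression and ribosome occupancy
#'
#' Sums assigned read positions over each ORF for the RNA-seq and (optionally)
#' Ribo-seq tracks and computes RPKM = counts * 1e9 / (total_mapped *
#' length_nt) and the ribosome occupancy RO = ribo_rpkm / rna_rpkm. RO is
#' reported NA and flagged when rna_rpkm is zero.
#'
#' @param track_rna raw-count \code{density_track} of RNA-seq reads.
#' @param track_ribo raw-count \code{density_track} of footprints, or NULL.
#' @param transcriptome a \code{transcriptome}.
#' @return An \code{expression_table}: data.frame with one row per gene
#'   (gene_id, length_nt, rna_counts, rna_rpkm, ribo_counts, ribo_rpkm, ro,
#'   ro_defined), with the track totals as attributes.
#' @export
quantify <- function(track_rna, track_ribo, transcriptome) {
  if (track_rna$total_mapped == 0)
    stop("RNA-seq track has zero mapped reads")
  if (!is.null(track_ribo) && track_ribo$total_mapped == 0)
    stop("Ribo-seq track has zero mapped reads")
  orfs <- transcriptome$orfs
  len <- orfs$end - orfs$start
  counts_on <- function(track) {
    vapply(seq_len(nrow(orfs)), function(i)
      sum(orf_density(track, orfs[i, ])), numeric(1))
  }
  rpkm <- function(counts, total) counts * 1e9 / (total * len)

  rna_counts <- counts_on(track_rna)
  tab <- data.frame(gene_id = orfs$gene_id, length_nt = len,
                    rna_counts = rna_counts,
                    rna_rpkm = rpkm(rna_counts, track_rna$total_mapped),
                    stringsAsFactors = FALSE)
  if (!is.null(track_ribo)) {
    tab$ribo_counts <- counts_on(track_ribo)
    tab$ribo_rpkm <- rpkm(tab$ribo_counts, track_ribo$total_mapped)
    tab$ro_defined <- tab$rna_rpkm > 0
    tab$ro <- ifelse(tab$ro_defined, tab$ribo_rpkm / tab$rna_rpkm, NA_real_)
  }
  rownames(tab) <- tab$gene_id
  structure(tab, class = c("expression_table", "data.frame"),
            rna_total = track_rna$total_mapped,
            ribo_total = if (is.null(track_ribo)) NA_integer_
                         else track_ribo$total_mapped)
}

#' Define a genomic region
#'
#' @param ref_name reference name.
#' @param start,end 0-based half-open interval.
#' @param strand "+" or "-".
#' @param name optional label.
#' @return A \code{region} list.
#' @export
region <- function(ref_name, start, end, strand, name = NA_character_) {
  stopifnot(end > start, strand %in% c("+", "-"))
  structure(list(ref_name = ref_name, start = as.integer(start),
                 end = as.integer(end), strand = strand, name = name),
            class = "region")
}

#' Read named regions from a BED6 file
#' @param path BED6 path.
#' @return Named list of \code{region} objects (names from the BED name
#'   column).
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- lapply(seq_along(gr), function(i)
    region(as.character(GenomicRanges::seqnames(gr)[i]),
           GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i],
           as.character(GenomicRanges::strand(gr)[i]), gr$name[i]))
  names(out) <- gr$name
  out
}

region_density <- function(track, reg) {
  v <- track$values[[reg$ref_name]][[reg$strand]]
  sum(v[(reg$start + 1L):reg$end]) / (reg$end - reg$start)
}

#' Leader-to-downstream attenuation ratio
#'
#' Length-adjusted RNA-seq density (reads per nt) in the leader region divided
#' by that in the downstream region. Under transcriptional attenuation the
#' leader is transcribed constitutively while downstream transcription
#' requires terminator read-through, so the fold-decrease measures termination
#' efficiency; ribosome stalling in the leader lowers it. The ratio is
#' unit-invariant (raw vs rpm).
#'
#' @param track_rna a \code{density_track} of RNA-seq reads.
#' @param leader_region,downstream_region \code{region} objects on the same
#'   strand, disjoint.
#' @return An \code{attenuation_result}: list with the two regions, their
#'   densities, \code{fold_decrease}, and an \code{infinite} flag when the
#'   downstream density is zero.
#' @export
attenuation_ratio <- function(track_rna, leader_region, downstream_region) {
  if (leader_region$strand != downstream_region$strand)
    stop("leader and downstream regions must be on the same strand")
  if (leader_region$ref_name == downstream_region$ref_name &&
      leader_region$start < downstream_region$end &&
      downstream_region$start < leader_region$end)
    stop("leader and downstream regions overlap")
  ld <- region_density(track_rna, leader_region)
  dd <- region_density(track_rna, downstream_region)
  structure(list(leader_region = leader_region,
                 downstream_region = downstream_region,
                 leader_density = ld, downstream_density = dd,
                 fold_decrease = if (dd > 0) ld / dd else Inf,
                 infinite = dd == 0, units = track_rna$units),
            class = "attenuation_result")
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat(sprintf(
    "Attenuation: leader %.4g / downstream %.4g %s per nt -> %.3g-fold decrease%s\n",
    x$leader_density, x$downstream_density, x$units, x$fold_decrease,
    if (x$infinite) " (downstream density is zero)" else ""))
  invisible(x)
}

#' Expression shifts of gene sets between two conditions
#'
#' For each gene set, computes log2(mutant RPKM / control RPKM) over the
#' set's genes, the median shift, a one-sample t-test of the log ratios
#' against 0, and a Mann-Whitney (Wilcoxon rank-sum) test of the set's ratios
#' against all quantified genes outside the set. Genes with zero counts in
#' either condition are excluded unless a pseudocount is supplied (added to
#' the raw counts before RPKM); exclusions are reported. Sets with fewer than
#' 3 usable genes have their statistics suppressed (NA).
#'
#' @param expr_mutant,expr_control \code{expression_table}s from
#'   \code{\link{quantify}} over the same transcriptome.
#' @param gene_sets named list of character vectors of gene ids.
#' @param pseudocount count added to both conditions (default 0 = exclude
#'   zero-count genes).
#' @return A \code{gene_set_shift} data.frame: set_label, n, n_missing,
#'   n_zero_excluded, median_log2, p_t, p_mw; per-set log2 ratios in the
#'   \code{"ratios"} attribute.
#' @export
compare_gene_sets <- function(expr_mutant, expr_control, gene_sets,
                              pseudocount = 0) {
  common <- intersect(expr_mutant$gene_id, expr_control$gene_id)
  m <- expr_mutant[common, ]
  c0 <- expr_control[common, ]
  mt <- attr(expr_mutant, "rna_total")
  ct <- attr(expr_control, "rna_total")
  mc <- m$rna_counts + pseudocount
  cc <- c0$rna_counts + pseudocount
  defined <- mc > 0 & cc > 0
  log2r <- stats::setNames(
    log2((mc * 1e9 / (mt * m$length_nt)) /
           (cc * 1e9 / (ct * c0$length_nt))), common)[defined]

  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  rows <- lapply(names(gene_sets), function(lbl) {
    set <- gene_sets[[lbl]]
    missing <- setdiff(set, common)
    if (length(missing) > 0)
      message("set '", lbl, "': ", length(missing),
              " gene(s) absent from the expression tables")
    in_set <- intersect(set, names(log2r))
    n_zero <- length(intersect(set, common)) - length(in_set)
    r <- log2r[in_set]
    other <- log2r[setdiff(names(log2r), set)]
    suff <- length(r) >= 3
    data.frame(
      set_label = lbl, n = length(r), n_missing = length(missing),
      n_zero_excluded = n_zero,
      median_log2 = if (suff) stats::median(r) else NA_real_,
      p_t = if (suff) stats::t.test(r, mu = 0)$p.value else NA_real_,
      p_mw = if (suff && length(other) >= 1)
        stats::wilcox.test(r, other)$p.value else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ratios <- lapply(gene_sets, function(set)
    log2r[intersect(set, names(log2r))])
  structure(out, class = c("gene_set_shift", "data.frame"), ratios = ratios)
}

#' Read a gene set from a plain-text file (one gene id per line)
#' @param path file path.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
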