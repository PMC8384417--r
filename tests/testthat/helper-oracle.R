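# Independent brute-force recomputation of the per-codon pause table.
# Deliberately avoids the package's track/shift machinery: it recomputes 3'
# ends, A-site shifts, per-position counts, gene means and instance scores
# from the raw read table with its own arithmetic, enumerating every codon
# position one at a time. Only usable on toy inputs.
brute_force_pause_table <- function(reads, txome, asite_offset = 15L,
                                    trim = 7L, min_rpc = 0.1) {
  stops <- c("TAA", "TAG", "TGA")
  scores <- list()
  for (gid in txome$orfs$gene_id) {
    orf <- txome$orfs[txome$orfs$gene_id == gid, ]
    nc <- (orf$end - orf$start) %/% 3L
    if (nc <= 2L * trim) next
    gpos <- if (orf$strand == "+") orf$start:(orf$end - 1L)
            else (orf$end - 1L):orf$start
    r <- reads[reads$ref_name == orf$ref_name &
                 reads$strand == orf$strand, ]
    p3 <- ifelse(r$strand == "+", r$five_prime + r$length - 1L,
                 r$five_prime - r$length + 1L)
    shifted <- ifelse(r$strand == "+", p3 - asite_offset, p3 + asite_offset)
    cnt <- vapply(gpos, function(g) sum(shifted == g), numeric(1))
    if (sum(cnt) / nc <= min_rpc) next
    L <- length(cnt)
    gm <- mean(cnt[(3L * trim + 1L):(L - 3L * trim)])
    if (gm == 0) next
    for (i in trim:(nc - trim - 1L)) {
      trip <- substr(orf$sequence, 3L * i + 1L, 3L * i + 3L)
      if (trip %in% stops) next
      scores[[length(scores) + 1L]] <-
        data.frame(triplet = trip, score = cnt[3L * i + 1L] / gm)
    }
  }
  df <- do.call(rbind, scores)
  agg <- aggregate(score ~ triplet, df, mean)
  n <- aggregate(score ~ triplet, df, length)
  data.frame(codon = agg$triplet, mean_score = agg$score,
             n_instances = n$score)[order(agg$triplet), ]
}
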