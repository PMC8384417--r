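# Codon-aligned metagene profiles: average gene-mean-normalized ribosome
# density at offsets around every instance of a codon type. Offsets are in nt
# along the coding direction relative to the codon's first nt, so negative
# offsets are 5' (upstream) of the codon. Collision density from stacked
# ribosomes appears ~25 nt upstream (offset ~ -25); post-lysis run-on
# translation moves ribosomes forward, spreading an A-site pause toward
# downstream offsets (+3, +6: the aligned codon then sits in the P/E sites).

#' Codon-aligned average density profile
#'
#' For every instance of the query codon(s) in genes passing the same
#' coverage filter and edge trim as the pause score, takes the window of
#' per-nt A-site-shifted density at offsets -window..+window around the
#' codon's first nt, divides it by the gene's interior mean density, and
#' averages elementwise across instances. Window positions falling outside
#' the ORF are masked rather than dropped, with per-offset coverage counts,
#' so short genes still contribute.
#'
#' @param track a \code{density_track} of 3'-end counts.
#' @param transcriptome a \code{transcriptome}.
#' @param codons character vector of codon triplets to align on (U or T).
#' @param window half-width of the profile in nt (default 50).
#' @param asite_offset,trim,min_reads_per_codon,shifted as in
#'   \code{\link{pause_scores}}.
#' @param purge_adjacent drop instances with another query-codon instance
#'   within \code{window} nt (diagnostic mode; default keeps them).
#' @return An object of class \code{metagene_profile}: list with
#'   \code{offsets} (-window..window), \code{mean_density},
#'   \code{n_covering} (per-offset instance coverage), \code{n_instances},
#'   \code{codons}, and \code{peaks} (from \code{\link{find_peaks}} with
#'   default settings).
#' @export
codon_metagene <- function(track, transcriptome, codons, window = 50L,
                           asite_offset = 15L, trim = 7L,
                           min_reads_per_codon = 0.1, shifted = FALSE,
                           purge_adjacent = FALSE) {
  codons <- normalize_codons(codons)
  if (!shifted) track <- shift_to_asite(track, asite_offset)
  window <- as.integer(window)
  offs <- seq.int(-window, window)
  sums <- numeric(length(offs))
  cov <- integer(length(offs))
  n_instances <- 0L

  orfs <- transcriptome$orfs
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    nc <- n_codons(orf)
    if (nc <= 2L * trim) next
    if (!gene_passes_filter(track, orf, min_reads_per_codon)) next
    d <- orf_density(track, orf)
    interior <- (3L * trim + 1L):(length(d) - 3L * trim)
    gm <- mean(d[interior])
    if (gm == 0) next
    idx <- trim:(nc - trim - 1L)
    trip <- orf_codons(orf)[idx + 1L]
    idx <- idx[trip %in% codons]
    if (length(idx) == 0) next
    q <- 3L * idx                       # first-nt coding offsets, 0-based
    if (purge_adjacent && length(q) > 1) {
      gaps_ok <- vapply(seq_along(q), function(j)
        all(abs(q[-j] - q[j]) > window), logical(1))
      q <- q[gaps_ok]
      if (length(q) == 0) next
    }
    for (p0 in q) {
      at <- p0 + offs
      valid <- at >= 0L & at < length(d)
      sums[valid] <- sums[valid] + d[at[valid] + 1L] / gm
      cov[valid] <- cov[valid] + 1L
      n_instances <- n_instances + 1L
    }
  }
  if (n_instances == 0L)
    stop("no instances of ", paste(codons, collapse = ","),
         " qualify for the metagene profile")

  mean_density <- ifelse(cov > 0L, sums / cov, NA_real_)
  prof <- structure(list(offsets = offs, mean_density = mean_density,
                         n_covering = cov, n_instances = n_instances,
                         codons = codons, peaks = NULL),
                    class = "metagene_profile")
  prof$peaks <- find_peaks(prof)
  prof
}

#' Local maxima of a metagene profile
#'
#' Reports local maxima above \code{min_height}, selected greedily by height
#' with at least \code{min_separation} nt between reported peaks. Heights are
#' normalized densities, not background-subtracted.
#'
#' @param profile a \code{metagene_profile} (or a numeric vector with an
#'   \code{offsets} attribute-free 1:n axis).
#' @param min_height minimum normalized density for a peak (default 1.5).
#' @param min_separation minimum nt between reported peaks (default 3, one
#'   codon, so A/P/E-site peaks remain distinguishable).
#' @return data.frame with columns \code{offset}, \code{height}.
#' @export
find_peaks <- function(profile, min_height = 1.5, min_separation = 3L) {
  if (inherits(profile, "metagene_profile")) {
    v <- profile$mean_density
    offs <- profile$offsets
  } else {
    v <- as.numeric(profile)
    offs <- seq_along(v)
  }
  n <- length(v)
  v0 <- ifelse(is.na(v), -Inf, v)
  left <- c(-Inf, v0[-n])
  right <- c(v0[-1], -Inf)
  cand <- which(v0 >= left & v0 >= right & v0 > min_height)
  cand <- cand[order(-v0[cand])]
  chosen <- integer(0)
  for (i in cand) {
    if (all(abs(offs[i] - offs[chosen]) >= min_separation))
      chosen <- c(chosen, i)
  }
  chosen <- chosen[order(offs[chosen])]
  data.frame(offset = offs[chosen], height = v0[chosen])
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("Metagene profile aligned at", paste(x$codons, collapse = ","),
      "(", x$n_instances, "instances, window +/-",
      max(x$offsets), "nt )\n")
  if (nrow(x$peaks) > 0) {
    cat("  peaks:\n")
    print(x$peaks, row.names = FALSE, digits = 3)
  } else cat("  no peaks above threshold\n")
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$offsets, x$mean_density, type = "l",
                 xlab = "offset from codon first nt (nt)",
                 ylab = "mean normalized density", ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  if (nrow(x$peaks) > 0)
    graphics::points(x$peaks$offset, x$peaks$height, pch = 19,
                     col = "firebrick")
  invisible(x)
}

#' Write a metagene profile as TSV
#' @param x a \code{metagene_profile}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_metagene <- function(x, path) {
  utils::write.table(
    data.frame(offset = x$offsets, mean_density = x$mean_density,
               n_covering = x$n_covering),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
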