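# Aligned reads are kept as a plain data.frame with 0-based genomic
# coordinates: five_prime / three_prime are the biological 5' and 3' terminal
# nucleotides of the read (so five_prime > three_prime on the minus strand).

#' Read aligned footprints or RNA-seq reads with a length filter
#'
#' Accepts SAM/BAM (standard FLAG-derived strand; the reference span of the
#' alignment defines the end coordinates, so soft-clips do not shift the 3'
#' end) or the package's 4-column TSV dialect
#' \code{ref <TAB> strand <TAB> five_prime <TAB> length} with \code{five_prime}
#' the 0-based genomic coordinate of the biological 5' end (rightmost base for
#' minus-strand reads). Reads outside \code{[min_len, max_len]} are dropped
#' and the kept/dropped counts reported.
#'
#' @param path input file (.tsv/.txt, .sam, or .bam).
#' @param min_len,max_len inclusive read-length window in nt. The default
#'   10-40 nt window suits conventional footprint libraries; use 24-40 nt for
#'   high-Mg2+ arrest libraries where shorter reads position ambiguously.
#' @param format override format detection ("tsv", "sam", "bam").
#' @return data.frame with columns \code{ref_name}, \code{strand},
#'   \code{five_prime}, \code{three_prime}, \code{length}.
#' @export
read_alignments <- function(path, min_len = 10L, max_len = 40L,
                            format = NULL) {
  stopifnot(min_len <= max_len)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", sam = "sam", bam = "bam",
                     stop("cannot guess alignment format from extension '",
                          ext, "'; pass format="))
  }
  reads <- switch(format,
                  tsv = read_alignments_tsv(path),
                  sam = read_alignments_bam(Rsamtools::asBam(
                    path, tempfile(), overwrite = TRUE)),
                  bam = read_alignments_bam(path),
                  stop("unknown alignment format: ", format))
  if (nrow(reads) == 0) stop("no alignments parsed from ", path)
  keep <- reads$length >= min_len & reads$length <= max_len
  message(sum(keep), " read(s) retained, ", sum(!keep),
          " dropped by the ", min_len, "-", max_len, " nt length filter")
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0)
    stop("all reads removed by the length filter [", min_len, ", ",
         max_len, "]")
  rownames(reads) <- NULL
  reads
}

read_alignments_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(data.frame())
  header <- startsWith(first, "ref")
  tb <- utils::read.table(path, sep = "\t", header = header,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("ref", "strand", "five_prime",
                                        "length"))
  bad <- !(tb$strand %in% c("+", "-")) | is.na(tb$five_prime) |
    is.na(tb$length) | tb$length < 1L
  if (any(bad)) {
    warning(sum(bad), " unparseable TSV record(s) skipped")
    tb <- tb[!bad, , drop = FALSE]
  }
  data.frame(ref_name = tb$ref, strand = tb$strand,
             five_prime = as.integer(tb$five_prime),
             three_prime = ifelse(tb$strand == "+",
                                  tb$five_prime + tb$length - 1L,
                                  tb$five_prime - tb$length + 1L),
             length = as.integer(tb$length), stringsAsFactors = FALSE)
}

read_alignments_bam <- function(path) {
  ga <- GenomicAlignments::readGAlignments(path)
  if (length(ga) == 0) return(data.frame())
  strand <- as.character(GenomicAlignments::strand(ga))
  start0 <- GenomicAlignments::start(ga) - 1L   # aligned reference span
  end0 <- GenomicAlignments::end(ga) - 1L
  data.frame(ref_name = as.character(GenomicAlignments::seqnames(ga)),
             strand = strand,
             five_prime = ifelse(strand == "+", start0, end0),
             three_prime = ifelse(strand == "+", end0, start0),
             length = end0 - start0 + 1L, stringsAsFactors = FALSE)
}

#' Write reads in the package's alignment TSV dialect
#'
#' @param reads data.frame as returned by \code{\link{read_alignments}} or
#'   the simulators.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_alignments_tsv <- function(reads, path) {
  out <- data.frame(ref = reads$ref_name, strand = reads$strand,
                    five_prime = reads$five_prime, length = reads$length)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ribosome position of a read
#'
#' The ribosome position is anchored at the read's 3' end: the rightmost
#' genomic coordinate for plus-strand reads and the leftmost for minus-strand
#' reads. Two reads sharing a 3' end map to the same position regardless of
#' their lengths.
#'
#' @param reads data.frame of aligned reads.
#' @param mode position assignment rule; only \code{"three_prime"} is defined.
#' @return Integer vector of 0-based genomic coordinates.
#' @export
assign_position <- function(reads, mode = "three_prime") {
  mode <- match.arg(mode, "three_prime")
  if (is.null(reads$three_prime))
    return(ifelse(reads$strand == "+",
                  reads$five_prime + reads$length - 1L,
                  reads$five_prime - reads$length + 1L))
  reads$three_prime
}

#' Build a strand-aware per-nucleotide density track
#'
#' Counts assigned read positions per nucleotide on each (reference, strand).
#' In raw mode the track sum equals the number of retained reads exactly; rpm
#' mode scales by 1e6 / total_mapped, where total_mapped counts the reads
#' retained after the length filter and bounds check (recorded on the track).
#'
#' @param reads data.frame of aligned reads (already length-filtered).
#' @param transcriptome a \code{transcriptome} (supplies reference lengths).
#' @param normalize "raw" counts or "rpm" (reads per million mapped reads).
#' @return An object of class \code{density_track}: list with \code{values}
#'   (per reference, a list of plus/minus numeric vectors),
#'   \code{ref_lengths}, \code{total_mapped}, \code{units}.
#' @export
build_track <- function(reads, transcriptome, normalize = c("raw", "rpm")) {
  normalize <- match.arg(normalize)
  rl <- transcriptome$ref_lengths
  pos <- assign_position(reads)
  inb <- reads$ref_name %in% names(rl)
  inb[inb] <- pos[inb] >= 0L & pos[inb] < rl[reads$ref_name[inb]]
  if (any(!inb))
    warning(sum(!inb), " read position(s) outside reference bounds skipped")
  reads <- reads[inb, , drop = FALSE]
  pos <- pos[inb]

  values <- lapply(names(rl), function(ref) {
    n <- rl[[ref]]
    sel <- reads$ref_name == ref
    list(`+` = tabulate(pos[sel & reads$strand == "+"] + 1L, nbins = n),
         `-` = tabulate(pos[sel & reads$strand == "-"] + 1L, nbins = n))
  })
  names(values) <- names(rl)
  values <- lapply(values, function(v) lapply(v, as.numeric))

  total <- nrow(reads)
  if (normalize == "rpm") {
    if (total == 0) stop("cannot rpm-normalize an empty track")
    values <- lapply(values, function(v) lapply(v, function(x)
      x * 1e6 / total))
  }
  structure(list(values = values, ref_lengths = rl, total_mapped = total,
                 units = normalize),
            class = "density_track")
}

#' Total signal in a density track
#' @param track a \code{density_track}.
#' @return Sum over all references and strands.
#' @export
track_total <- function(track) {
  sum(vapply(track$values, function(v) sum(v$`+`) + sum(v$`-`), numeric(1)))
}

#' Convert a raw track to rpm
#' @param track a raw-count \code{density_track}.
#' @return The rpm-scaled track.
#' @export
track_rpm <- function(track) {
  if (track$units == "rpm") return(track)
  if (track$total_mapped == 0) stop("cannot rpm-normalize an empty track")
  track$values <- lapply(track$values, function(v)
    lapply(v, function(x) x * 1e6 / track$total_mapped))
  track$units <- "rpm"
  track
}

#' @export
print.density_track <- function(x, ...) {
  cat("Density track (", x$units, "): ", length(x$values),
      " reference(s), total_mapped = ", x$total_mapped,
      ", signal = ", format(track_total(x)), "\n", sep = "")
  invisible(x)
}

format_wig_value <- function(x) {
  ifelse(x == round(x), sprintf("%.0f", x), sprintf("%.10g", x))
}

#' Write a density track as WIG
#'
#' variableStep WIG with 1-based coordinates and one block per
#' (reference, strand); the strand is carried as a \code{strand=} attribute on
#' the variableStep line (a dialect extension, re-read by
#' \code{\link{read_wig}}). Only nonzero positions are written; an empty track
#' produces a header-only file. write -> read -> write is byte-stable.
#'
#' @param track a \code{density_track}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"ribopause %s\"",
                     track$units), con)
  writeLines(sprintf("#total_mapped=%d", track$total_mapped), con)
  for (ref in names(track$values)) {
    for (st in c("+", "-")) {
      v <- track$values[[ref]][[st]]
      nz <- which(v != 0)
      if (length(nz) == 0) next
      writeLines(sprintf("variableStep chrom=%s strand=%s", ref, st), con)
      writeLines(sprintf("%d\t%s", nz, format_wig_value(v[nz])), con)
    }
  }
  invisible(path)
}

#' Read a WIG file written by \code{\link{write_wig}}
#'
#' @param path WIG path.
#' @param ref_lengths named integer vector of reference lengths (WIG does not
#'   carry them).
#' @return A \code{density_track}.
#' @export
read_wig <- function(path, ref_lengths) {
  lines <- readLines(path)
  units <- if (any(grepl("name=\"ribopause rpm\"", lines, fixed = TRUE)))
    "rpm" else "raw"
  total <- 0L
  tm <- grep("^#total_mapped=", lines, value = TRUE)
  if (length(tm) > 0) total <- as.integer(sub("^#total_mapped=", "", tm[1]))
  values <- lapply(ref_lengths, function(n)
    list(`+` = numeric(n), `-` = numeric(n)))
  ref <- NULL; st <- NULL
  for (ln in lines) {
    if (startsWith(ln, "track") || startsWith(ln, "#")) next
    if (startsWith(ln, "variableStep")) {
      ref <- sub(".*chrom=(\\S+).*", "\\1", ln)
      st <- sub(".*strand=(\\S+).*", "\\1", ln)
      if (!ref %in% names(ref_lengths))
        stop("WIG block on unknown reference: ", ref)
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    values[[ref]][[st]][as.integer(f[1])] <- as.numeric(f[2])
  }
  structure(list(values = values,
                 ref_lengths = stats::setNames(as.integer(ref_lengths),
                                               names(ref_lengths)),
                 total_mapped = total, units = units),
            class = "density_track")
}

#' Write a density track as bedGraph
#'
#' 0-based half-open intervals, run-length compressed, one \code{track} block
#' per strand. Zero-valued runs are omitted.
#'
#' @param track a \code{density_track}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (st in c("+", "-")) {
    writeLines(sprintf(
      "track type=bedGraph name=\"ribopause %s (%s)\"", track$units, st), con)
    for (ref in names(track$values)) {
      v <- track$values[[ref]][[st]]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (!any(keep)) next
      writeLines(sprintf("%s\t%d\t%d\t%s", ref, starts[keep], ends[keep],
                         format_wig_value(r$values[keep])), con)
    }
  }
  invisible(path)
}
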