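# Coordinate convention used throughout the package: 0-based, half-open
# [start, end) on the forward genomic strand. Codon i (0-based) of an ORF
# occupies coding-strand offsets [3i, 3i + 3). WIG/bedGraph writers convert
# to their 1-based / 0-based external dialects at the boundary.

#' The 61 sense codons (DNA alphabet)
#'
#' @return Character vector of the 61 codons that encode amino acids, in the
#'   order of the standard genetic code table.
#' @export
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Translate codons to one-letter amino acids
#'
#' @param codons character vector of DNA triplets.
#' @return Character vector of one-letter amino-acid codes ("*" for stops).
#' @export
codon_to_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[normalize_codons(codons)])
}

# Uppercase and map RNA U to internal DNA T.
normalize_codons <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Construct a transcriptome from an ORF table and reference lengths
#'
#' Validates each ORF against the coding-region invariants (length a positive
#' multiple of 3 with at least 3 codons, coordinates inside the named
#' reference, sequence consistent with the coordinates) and drops offenders
#' with a warning. Overlapping ORFs are permitted but flagged in the
#' \code{overlaps} column.
#'
#' @param orfs data.frame with columns \code{gene_id}, \code{ref_name},
#'   \code{strand} ("+"/"-"), \code{start}, \code{end} (0-based half-open),
#'   \code{sequence} (coding strand, start codon through stop codon).
#'   An optional \code{abundance} column is carried through.
#' @param ref_lengths named integer vector of reference lengths (nt).
#' @param genome optional \code{DNAStringSet} of the reference sequences;
#'   when present, ORF sequences are checked against it.
#' @return An object of class \code{transcriptome}: a list with elements
#'   \code{orfs} (validated data.frame) and \code{ref_lengths}, plus
#'   \code{genome} when supplied.
#' @export
transcriptome <- function(orfs, ref_lengths, genome = NULL) {
  stopifnot(is.data.frame(orfs), !is.null(names(ref_lengths)))
  req <- c("gene_id", "ref_name", "strand", "start", "end", "sequence")
  missing_cols <- setdiff(req, names(orfs))
  if (length(missing_cols) > 0)
    stop("orfs is missing columns: ", paste(missing_cols, collapse = ", "))
  orfs$sequence <- normalize_codons(orfs$sequence)

  if (anyDuplicated(orfs$gene_id))
    stop("duplicated gene_id values in ORF table")
  unknown_ref <- !(orfs$ref_name %in% names(ref_lengths))
  if (any(unknown_ref))
    stop("ORFs on references absent from the FASTA: ",
         paste(unique(orfs$ref_name[unknown_ref]), collapse = ", "))

  len <- orfs$end - orfs$start
  ok <- rep(TRUE, nrow(orfs))
  reason <- character(nrow(orfs))
  bad <- !(orfs$strand %in% c("+", "-"))
  reason[bad & ok] <- "strand must be '+' or '-'"; ok <- ok & !bad
  bad <- len != nchar(orfs$sequence)
  reason[bad & ok] <- "coordinate span does not match sequence length"
  ok <- ok & !bad
  bad <- (len %% 3L != 0L) | (len < 9L)
  reason[bad & ok] <- "length not a multiple of 3 with >= 3 codons"
  ok <- ok & !bad
  bad <- orfs$start < 0L | orfs$end > ref_lengths[orfs$ref_name]
  reason[bad & ok] <- "outside reference bounds"; ok <- ok & !bad
  bad <- grepl("[^ACGT]", orfs$sequence)
  reason[bad & ok] <- "sequence has non-ACGT/U characters"; ok <- ok & !bad

  if (!is.null(genome)) {
    idx <- which(ok)
    for (i in idx) {
      extracted <- extract_orf_sequence(genome, orfs$ref_name[i],
                                        orfs$strand[i], orfs$start[i],
                                        orfs$end[i])
      if (extracted != orfs$sequence[i]) {
        ok[i] <- FALSE
        reason[i] <- "sequence does not match the reference"
      }
    }
  }

  if (any(!ok))
    warning(sum(!ok), " ORF(s) dropped: ",
            paste(sprintf("%s (%s)", orfs$gene_id[!ok], reason[!ok]),
                  collapse = "; "))
  orfs <- orfs[ok, , drop = FALSE]
  if (nrow(orfs) == 0) stop("no valid ORFs remain")
  rownames(orfs) <- orfs$gene_id

  gr <- GenomicRanges::GRanges(orfs$ref_name,
                               IRanges::IRanges(orfs$start + 1L, orfs$end))
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                      drop.self = TRUE)
  orfs$overlaps <- seq_len(nrow(orfs)) %in%
    S4Vectors::queryHits(hits)

  out <- list(orfs = orfs,
              ref_lengths = stats::setNames(as.integer(ref_lengths),
                                            names(ref_lengths)),
              genome = genome)
  class(out) <- "transcriptome"
  out
}

extract_orf_sequence <- function(genome, ref, strand, start, end) {
  s <- Biostrings::subseq(genome[[ref]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("Transcriptome:", nrow(x$orfs), "ORFs on",
      length(x$ref_lengths), "reference(s)\n")
  cat("  codons per ORF:",
      paste(range((x$orfs$end - x$orfs$start) / 3L), collapse = "-"), "\n")
  if (any(x$orfs$overlaps))
    cat("  ", sum(x$orfs$overlaps), "ORF(s) overlap another ORF\n")
  invisible(x)
}

#' Number of codons in an ORF
#'
#' @param orf one-row data.frame (a row of \code{transcriptome$orfs}).
#' @return Integer codon count (start codon through stop codon).
#' @export
n_codons <- function(orf) as.integer((orf$end - orf$start) / 3L)

#' Genomic coordinate of the first nucleotide of a codon
#'
#' The first nucleotide is the 5'-most coding-strand base of the codon:
#' \code{start + 3i} on the plus strand and \code{end - 1 - 3i} on the minus
#' strand (0-based genomic coordinates).
#'
#' @param orf one-row data.frame with \code{strand}, \code{start}, \code{end}.
#' @param codon_index 0-based codon index (vectorized).
#' @return Integer genomic coordinate(s).
#' @export
codon_first_nt <- function(orf, codon_index) {
  nc <- n_codons(orf)
  if (any(codon_index < 0L | codon_index >= nc))
    stop("codon_index out of range [0, ", nc - 1L, "]")
  if (orf$strand == "+") orf$start + 3L * codon_index
  else orf$end - 1L - 3L * codon_index
}

# Genomic coordinates of all coding positions, ordered 5' -> 3' along the
# coding strand.
orf_coding_positions <- function(orf) {
  if (orf$strand == "+") seq.int(orf$start, orf$end - 1L)
  else seq.int(orf$end - 1L, orf$start)
}

# Codon triplets of an ORF, in coding order.
orf_codons <- function(orf) {
  nc <- n_codons(orf)
  substring(orf$sequence, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
}

#' Load an ORF annotation and reference sequences
#'
#' Reads a BED6/BED12 or GFF3 annotation (CDS features only for GFF3)
#' together with a multi-record FASTA, extracts each coding sequence, and
#' returns a validated \code{\link{transcriptome}}. ORFs violating the
#' coding-region invariants (non-multiple-of-3 length, out-of-bounds
#' coordinates, undefined strand) are dropped with a warning; a missing
#' reference sequence is fatal. U is normalized to T at load time.
#'
#' @param annotation_file path to a BED or GFF3 file.
#' @param fasta_file path to the reference FASTA.
#' @param format "bed" or "gff3"; guessed from the file extension by default.
#' @return A \code{transcriptome} object.
#' @export
load_annotation <- function(annotation_file, fasta_file, format = NULL) {
  if (!file.exists(fasta_file))
    stop("FASTA file not found: ", fasta_file)
  if (!file.exists(annotation_file))
    stop("annotation file not found: ", annotation_file)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(annotation_file))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot guess annotation format from extension '",
                          ext, "'; pass format="))
  }

  raw <- Biostrings::readBStringSet(fasta_file)
  names(raw) <- sub("\\s.*$", "", names(raw))
  genome <- Biostrings::DNAStringSet(normalize_codons(as.character(raw)))
  ref_lengths <- stats::setNames(Biostrings::width(genome), names(genome))

  gr <- rtracklayer::import(annotation_file, format = format)
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids)) ids <- gr$locus_tag
    if (is.null(ids)) ids <- paste0("CDS_", seq_along(gr))
    ids[is.na(ids)] <- paste0("CDS_", which(is.na(ids)))
  } else {
    ids <- gr$name
    if (is.null(ids)) ids <- paste0("ORF_", seq_along(gr))
  }
  if (length(gr) == 0) stop("annotation contains no usable features")

  strand <- as.character(GenomicRanges::strand(gr))
  undef <- strand == "*"
  if (any(undef)) {
    warning(sum(undef), " feature(s) with undefined strand '.' dropped")
    gr <- gr[!undef]; ids <- ids[!undef]; strand <- strand[!undef]
  }

  ref <- as.character(GenomicRanges::seqnames(gr))
  missing_ref <- setdiff(unique(ref), names(ref_lengths))
  if (length(missing_ref) > 0)
    stop("reference sequence(s) missing from FASTA: ",
         paste(missing_ref, collapse = ", "))

  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  seqs <- character(length(gr))
  inb <- start0 >= 0L & end0 <= ref_lengths[ref]
  mult3 <- (end0 - start0) %% 3L == 0L & (end0 - start0) >= 9L
  usable <- inb & mult3
  for (i in which(usable))
    seqs[i] <- extract_orf_sequence(genome, ref[i], strand[i],
                                    start0[i], end0[i])
  # placeholder sequences let transcriptome() report the reason uniformly
  seqs[!usable] <- strrep("N", pmax(end0 - start0, 1L)[!usable])

  orfs <- data.frame(gene_id = ids, ref_name = ref, strand = strand,
                     start = start0, end = end0, sequence = seqs,
                     stringsAsFactors = FALSE)
  transcriptome(orfs, ref_lengths, genome = genome)
}

#' Write a transcriptome back to FASTA and BED6
#'
#' @param txome a \code{transcriptome} with its \code{genome} element set.
#' @param fasta_file,bed_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcriptome <- function(txome, fasta_file, bed_file) {
  if (is.null(txome$genome))
    stop("transcriptome carries no genome sequences")
  Biostrings::writeXStringSet(txome$genome, fasta_file)
  o <- txome$orfs
  gr <- GenomicRanges::GRanges(o$ref_name,
                               IRanges::IRanges(o$start + 1L, o$end),
                               strand = o$strand)
  gr$name <- o$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, bed_file, format = "bed")
  invisible(c(fasta_file, bed_file))
}
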