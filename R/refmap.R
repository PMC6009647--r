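## Reference motif maps: site finding, in-silico PCR, FASTA/BED plumbing.
## Coordinates are 0-based throughout; intervals are half-open [start, end).

#' Construct a reference motif map
#'
#' A reference map is the "theoretical map" of a labeling experiment: the
#' ordered motif-site coordinates on a named sequence.  Positions are 0-based
#' motif starts; a site's position for downstream alignment is the motif
#' start, not the modified base (the discrepancy of a few bp is far below the
#' ~100 bp localization precision).
#'
#' @param name sequence name.
#' @param length sequence length in bp.
#' @param motif recognition motif (characters A, C, G, T).
#' @param positions 0-based motif start coordinates, strictly increasing.
#' @param strands strand per site, \code{"+"} or \code{"-"}.  Palindromic
#'   motifs produce exactly one \code{"+"} site per genomic location.
#' @return an object of class \code{"reference_map"}: a list with elements
#'   \code{name}, \code{length}, \code{motif} and \code{sites} (a data frame
#'   with columns \code{position} and \code{strand}).
#' @export
reference_map <- function(name, length, motif, positions = integer(),
                          strands = rep("+", base::length(positions))) {
  motif <- toupper(motif)
  .check_dna(motif, "motif")
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("site positions must be strictly increasing")
  if (base::length(positions) &&
      (min(positions) < 0 || max(positions) > length - nchar(motif)))
    stop("site positions must lie in [0, length - motif length]")
  if (!all(strands %in% c("+", "-")))
    stop("strands must be '+' or '-'")
  structure(list(
    name = as.character(name),
    length = as.integer(length),
    motif = motif,
    sites = data.frame(position = positions,
                       strand = as.character(strands),
                       stringsAsFactors = FALSE)
  ), class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("reference_map '%s': %d bp, motif %s, %d site(s)\n",
              x$name, x$length, x$motif, nrow(x$sites)))
  if (nrow(x$sites)) {
    cat("  positions:", paste0(x$sites$position, x$sites$strand,
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of sites in a reference map
#' @param map a \code{reference_map}.
#' @return integer site count.
#' @export
n_sites <- function(map) nrow(map$sites)

## validate a DNA string; error names the first offending symbol and its
## 1-based position
.check_dna <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || !nzchar(x))
    stop(sprintf("%s must be a non-empty DNA string", what))
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0)
    stop(sprintf("%s contains non-ACGT character '%s' at position %d",
                 what, substr(x, bad, bad), as.integer(bad)))
  invisible(x)
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## 0-based start positions of exact matches of `pattern` in `subject`
.match_starts <- function(pattern, subject)
  Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject))) - 1L

#' Find motif sites on both strands of a sequence
#'
#' Scans the forward strand for \code{motif} and for its reverse complement
#' (reported as strand \code{"-"}).  If the motif is self-reverse-
#' complementary (palindromic, e.g. TCGA) each genomic location is reported
#' once, with strand \code{"+"}.  IUPAC ambiguity codes are rejected.
#'
#' @param sequence DNA string over A, C, G, T.
#' @param motif recognition motif, e.g. \code{"TCGA"} for M.TaqI.
#' @param name sequence name recorded in the map.
#' @return a \code{\link{reference_map}} with sites sorted by position.
#' @examples
#' find_sites("ATCGAT", "TCGA")      # one palindromic site at position 1
#' find_sites("GGATGAACATCC", "GGATG")  # forward site and a reverse site
#' @export
find_sites <- function(sequence, motif, name = "seq") {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  .check_dna(sequence, "sequence")
  .check_dna(motif, "motif")
  if (nchar(motif) > nchar(sequence))
    stop("motif is longer than the sequence")
  fwd <- .match_starts(motif, sequence)
  rc <- .revcomp(motif)
  if (rc == motif) {
    pos <- fwd
    strand <- rep("+", length(pos))
  } else {
    rev <- .match_starts(rc, sequence)
    pos <- c(fwd, rev)
    strand <- c(rep("+", length(fwd)), rep("-", length(rev)))
  }
  ord <- order(pos, strand)
  reference_map(name, nchar(sequence), motif, pos[ord], strand[ord])
}

#' In-silico PCR: extract the amplicon delimited by two primers
#'
#' Requires exactly one exact match of the forward primer on the forward
#' strand and exactly one binding site of the reverse primer (an exact match
#' of its reverse complement) downstream of it.  Returns the inclusive
#' subsequence from the start of the forward-primer match to the end of the
#' reverse-primer binding site, i.e. the full amplicon.
#'
#' @param template DNA string.
#' @param fwd_primer forward primer, 5'-3' on the forward strand.
#' @param rev_primer reverse primer, 5'-3' on the reverse strand.
#' @return the amplicon as a DNA string.
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer) {
  template <- toupper(gsub(" ", "", template))
  fwd_primer <- toupper(gsub(" ", "", fwd_primer))
  rev_primer <- toupper(gsub(" ", "", rev_primer))
  .check_dna(template, "template")
  .check_dna(fwd_primer, "fwd_primer")
  .check_dna(rev_primer, "rev_primer")
  fstart <- .match_starts(fwd_primer, template)
  if (length(fstart) != 1)
    stop(sprintf("amplification error: forward primer has %d binding site(s), need exactly 1",
                 length(fstart)))
  rc <- .revcomp(rev_primer)
  rstart <- .match_starts(rc, template)
  rstart <- rstart[rstart > fstart]  # binding sites downstream of fwd match
  if (length(rstart) != 1)
    stop(sprintf("amplification error: reverse primer has %d downstream binding site(s), need exactly 1",
                 length(rstart)))
  substr(template, fstart + 1L, rstart + nchar(rev_primer))
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @return a named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first) || !startsWith(trimws(lines[first]), ">"))
    stop(sprintf("malformed FASTA: line %d does not start with '>'",
                 if (is.na(first)) 1L else first))
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(set)),
                  sub("\\s.*$", "", names(set)))
}

#' Write sequences to a FASTA file
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a reference map as BED
#'
#' Records are 0-based half-open intervals \code{[position, position + motif
#' length)}; the name column carries the motif and the strand column is
#' populated.
#'
#' @param map a \code{\link{reference_map}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(map, path) {
  if (nrow(map$sites) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = map$name,
    ranges = IRanges::IRanges(start = map$sites$position + 1L,
                              width = nchar(map$motif)),
    strand = map$sites$strand,
    name = rep(map$motif, nrow(map$sites)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a reference map from BED
#'
#' BED does not carry the sequence length, so supply \code{seq_length} for an
#' exact round trip; by default the end of the last interval is used.
#'
#' @param path path to a BED file written by \code{\link{write_map}}.
#' @param seq_length sequence length in bp, or \code{NULL} to infer.
#' @param motif motif, or \code{NULL} to take it from the name column.
#' @return a \code{\link{reference_map}}.
#' @export
read_map <- function(path, seq_length = NULL, motif = NULL) {
  if (length(readLines(path, warn = FALSE)) == 0) {
    if (is.null(motif)) motif <- "TCGA"
    if (is.null(seq_length)) seq_length <- nchar(motif)
    return(reference_map(basename(path), seq_length, motif))
  }
  gr <- rtracklayer::import(path, format = "bed")
  pos <- GenomicRanges::start(gr) - 1L
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  if (is.null(motif)) {
    nm <- S4Vectors::mcols(gr)$name
    motif <- if (!is.null(nm) && nzchar(nm[1])) nm[1] else
      strrep("N", GenomicRanges::width(gr)[1])
  }
  if (is.null(seq_length)) seq_length <- max(GenomicRanges::end(gr))
  ord <- order(pos)
  reference_map(as.character(GenomicRanges::seqnames(gr))[1], seq_length,
                motif, pos[ord], strand[ord])
}
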