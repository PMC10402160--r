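#' Load a genome for random-access sequence retrieval
#'
#' Reads a FASTA file (or accepts a named character vector of contig
#' sequences) into an in-memory handle used by all sequence-facing functions.
#' Sequences are uppercased and IUPAC ambiguity codes other than N are mapped
#' to N, since the downstream encoder defines exactly five symbols.
#'
#' @param x Path to a FASTA file, or a named character vector of contig
#'   sequences.
#' @return An object of class `genome_handle` with contig names, lengths, and
#'   the sequences.
#' @examples
#' g <- genome_handle(c(chr = "ACGTACGTACGT"))
#' contig_lengths(g)
#' @export
genome_handle <- function(x) {
  if (inherits(x, "genome_handle")) return(x)
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    if (!file.exists(x)) stop("FASTA file not found: ", x)
    ss <- Biostrings::readDNAStringSet(x)
    names(ss) <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
  } else if (is.character(x) && !is.null(names(x))) {
    seqs <- x
  } else {
    stop("genome_handle() expects a FASTA path or a named character vector")
  }
  seqs <- toupper(seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  structure(list(seqs = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "genome_handle")
}

#' @rdname genome_handle
#' @param genome A `genome_handle`.
#' @export
contig_names <- function(genome) names(genome$seqs)

#' @rdname genome_handle
#' @export
contig_lengths <- function(genome) genome$lengths

#' @export
print.genome_handle <- function(x, ...) {
  cat(sprintf("genome_handle: %d contig(s), %s bp total\n",
              length(x$seqs), format(sum(as.numeric(x$lengths)),
                                     big.mark = ",")))
  invisible(x)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences over \{A,C,G,T,N\}.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# vectorised plus-strand fetch with N padding; starts/ends are 0-based
# half-open and may run off either contig end
fetch_plus <- function(genome, contig, starts, ends) {
  len <- genome$lengths[[contig]]
  s2 <- pmax(starts, 0L)
  e2 <- pmin(ends, len)
  core <- ifelse(e2 > s2, substring(genome$seqs[[contig]], s2 + 1L, e2), "")
  left <- pmax(0L, pmin(ends, 0L) - starts)
  right <- pmax(0L, ends - pmax(starts, len))
  paste0(strrep("N", left), core, strrep("N", right))
}

#' Fetch a genomic window in transcription sense
#'
#' Returns exactly `end - start` uppercase bases of the window
#' `[start, end)` (0-based half-open).  Positions outside the contig are
#' filled with `N`.  For `strand = "-"` the reverse complement is returned,
#' so the caller always sees the transcription sense.
#'
#' @param genome A [genome_handle()].
#' @param contig Contig name.
#' @param start,end 0-based half-open window; `start < end`.  May extend
#'   beyond the contig (padded with N).
#' @param strand `"+"` or `"-"`.
#' @return A single character string of length `end - start`.
#' @examples
#' g <- genome_handle(c(chr = "AAAACCCC"))
#' fetch_window(g, "chr", 0, 4)            # "AAAA"
#' fetch_window(g, "chr", -3, 2)           # "NNNAA"
#' fetch_window(g, "chr", 4, 8, "-")       # "GGGG"
#' @export
fetch_window <- function(genome, contig, start, end, strand = "+") {
  genome <- genome_handle(genome)
  if (!contig %in% names(genome$seqs))
    stop("contig not found in genome: ", contig)
  if (length(start) != 1L || length(end) != 1L || start >= end)
    stop("need scalar start < end")
  out <- fetch_plus(genome, contig, as.integer(start), as.integer(end))
  if (identical(strand, "-")) out <- revcomp(out)
  out
}
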