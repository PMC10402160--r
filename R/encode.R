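# canonical label-channel order; all downstream code goes through these
# accessors rather than raw indices
CHANNELS <- c(neither = 1L, acceptor = 2L, donor = 3L)

#' Label channel accessors
#'
#' The model emits three per-position channels.  Their internal order is
#' fixed here and exposed by name so that no other code depends on raw
#' indices.
#'
#' @param name One of `"neither"`, `"acceptor"`, `"donor"`.
#' @return The 1-based channel index.
#' @export
channel_index <- function(name = c("neither", "acceptor", "donor")) {
  CHANNELS[[match.arg(name)]]
}

#' @rdname channel_index
#' @export
channel_names <- function() names(CHANNELS)

# in-window label offsets (0-based): donor at 200, acceptor at 600
DONOR_INDEX <- 200L
ACCEPTOR_INDEX <- 600L

#' Extract the 800nt donor-acceptor pair window
#'
#' For each junction, 400nt around the donor site followed by 400nt around
#' the acceptor site, in transcription sense, totalling exactly 800nt.  The
#' donor site (first intronic base) sits at 0-based window position 200 and
#' the acceptor label position (first exonic base after the intron) at 600,
#' so a canonical junction shows `GT` at positions 200-201 and `AG` at
#' 598-599.  For intron length L between 200 and 400 the two intronic flanks
#' overlap; for L = 200 they are identical; for L < 200 each flank keeps the
#' whole intron, truncated at the opposite site and padded with Ns on the
#' intron side.  Positions beyond the contig ends are N-padded.
#'
#' @param genome A [genome_handle()].
#' @param junctions A [junction_frame()] (or a single-row one).
#' @param flank Exonic/intronic flank per side (fixed at 200 in the trained
#'   model; exposed for completeness).
#' @return Character vector of `4 * flank`-nt windows, one per junction,
#'   with attributes `donor_index` and `acceptor_index`.
#' @export
extract_pair_window <- function(genome, junctions, flank = 200L) {
  genome <- genome_handle(genome)
  stopifnot_cols(junctions, c("contig", "start", "end", "strand"))
  n <- nrow(junctions)
  out <- character(n)
  if (n) {
    L <- junctions$end - junctions$start
    if (any(L < 1L)) stop("invalid junction: intron length < 1")
    m <- pmin(L, flank)
    padN <- strrep("N", flank - m)
    for (contig in unique(junctions$contig)) {
      idx <- which(junctions$contig == contig)
      plus <- idx[junctions$strand[idx] != "-"]
      minus <- idx[junctions$strand[idx] == "-"]
      if (length(plus)) {
        s <- junctions$start[plus]; e <- junctions$end[plus]
        donor <- paste0(fetch_plus(genome, contig, s - flank, s + m[plus]),
                        padN[plus])
        acceptor <- paste0(padN[plus],
                           fetch_plus(genome, contig, e - m[plus], e + flank))
        out[plus] <- paste0(donor, acceptor)
      }
      if (length(minus)) {
        s <- junctions$start[minus]; e <- junctions$end[minus]
        donor <- paste0(revcomp(fetch_plus(genome, contig, e - m[minus],
                                           e + flank)), padN[minus])
        acceptor <- paste0(padN[minus],
                           revcomp(fetch_plus(genome, contig, s - flank,
                                              s + m[minus])))
        out[minus] <- paste0(donor, acceptor)
      }
    }
  }
  structure(out, donor_index = flank, acceptor_index = 3L * flank)
}

#' One-hot encode a DNA sequence
#'
#' `A`, `C`, `G`, `T` map to the four unit rows and `N` to the all-zero row;
#' any other symbol is mapped to `N` with a warning.
#'
#' @param sequence A single DNA string.
#' @return An `nchar(sequence) x 4` 0/1 matrix with columns `A,C,G,T`.
#' @export
one_hot <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- !v %in% c("A", "C", "G", "T", "N")
  if (any(bad)) {
    warning(sprintf("%d non-ACGTN symbol(s) mapped to N", sum(bad)))
    v[bad] <- "N"
  }
  m <- matrix(0L, nrow = length(v), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  code <- match(v, c("A", "C", "G", "T"))
  ok <- !is.na(code)
  m[cbind(which(ok), code[ok])] <- 1L
  m
}

# integer codes (0 = N, 1..4 = A,C,G,T) for a vector of equal-length
# sequences; returns an L x n matrix for the network engine
encode_codes <- function(sequences) {
  if (!length(sequences)) return(matrix(integer(0), 0, 0))
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal length")
  v <- unlist(strsplit(toupper(sequences), "", fixed = TRUE), use.names = FALSE)
  code <- match(v, c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  matrix(as.integer(code), nrow = L)
}

#' Build the per-position label target for a pair window
#'
#' Exactly one position carries the donor label (0-based 200) and one the
#' acceptor label (0-based 600); all others are "neither".  Each position's
#' three channels sum to one.
#'
#' @param window An 800nt window from [extract_pair_window()] (only its
#'   length is used).
#' @param positive Logical; negative examples are labelled "neither"
#'   everywhere.
#' @return A `3 x length` 0/1 matrix with rownames
#'   `c("neither", "acceptor", "donor")`.
#' @export
make_label <- function(window, positive = TRUE) {
  L <- nchar(window)
  m <- matrix(0L, nrow = 3L, ncol = L, dimnames = list(channel_names(), NULL))
  m[channel_index("neither"), ] <- 1L
  if (positive) {
    m[, DONOR_INDEX + 1L] <- 0L
    m[channel_index("donor"), DONOR_INDEX + 1L] <- 1L
    m[, ACCEPTOR_INDEX + 1L] <- 0L
    m[channel_index("acceptor"), ACCEPTOR_INDEX + 1L] <- 1L
  }
  m
}
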