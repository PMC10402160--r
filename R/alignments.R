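# SAM flag bits used throughout
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Read spliced alignments from SAM or BAM
#'
#' Returns one row per alignment record with 0-based positions, parsed
#' NH/XS tags, and (for SAM input) any remaining tags preserved verbatim.
#' BAM files are read through `Rsamtools`.
#'
#' @param path A `.sam` or `.bam` file.
#' @return A data frame of alignment records with attribute `"header"`
#'   holding the SAM header lines.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(read_alignments_bam(path))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(body)) {
    out <- empty_alignments()
    attr(out, "header") <- hdr
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop(sprintf("malformed SAM record at data line %d (needs 11 fields)",
                 which(nf < 11L)[1]))
  f <- function(i) vapply(parts, `[[`, character(1), i)
  tags <- vapply(parts, function(p)
    if (length(p) > 11L) paste(p[-(1:11)], collapse = "\t") else "",
    character(1))
  df <- data.frame(
    qname = f(1), flag = as.integer(f(2)), rname = f(3),
    pos = as.integer(f(4)) - 1L, mapq = as.integer(f(5)), cigar = f(6),
    rnext = f(7), pnext = as.integer(f(8)) - 1L, tlen = as.integer(f(9)),
    seq = f(10), qual = f(11), stringsAsFactors = FALSE)
  df$nh <- tag_int(tags, "NH")
  df$xs <- tag_chr(tags, "XS")
  df$tags <- strip_tags(tags, c("NH", "XS"))
  attr(df, "header") <- hdr
  df
}

read_alignments_bam <- function(path) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
             "mpos", "isize", "seq", "qual"),
    tag = c("NH", "XS"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  df <- data.frame(
    qname = b$qname, flag = as.integer(b$flag),
    rname = as.character(b$rname), pos = ifelse(is.na(b$pos), -1L, b$pos - 1L),
    mapq = as.integer(b$mapq), cigar = as.character(b$cigar),
    rnext = ifelse(is.na(as.character(b$mrnm)), "*", as.character(b$mrnm)),
    pnext = ifelse(is.na(b$mpos), -1L, b$mpos - 1L),
    tlen = ifelse(is.na(b$isize), 0L, b$isize),
    seq = as.character(b$seq), qual = as.character(b$qual),
    stringsAsFactors = FALSE)
  df$nh <- if (!is.null(b$tag$NH)) as.integer(b$tag$NH) else rep(NA_integer_, n)
  df$xs <- if (!is.null(b$tag$XS)) as.character(b$tag$XS) else rep(NA_character_, n)
  df$tags <- rep("", n)
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$text
  hdr_lines <- vapply(seq_along(hdr), function(i)
    paste(c(names(hdr)[i], hdr[[i]]), collapse = "\t"), character(1))
  attr(df, "header") <- hdr_lines
  df
}

empty_alignments <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             rnext = character(), pnext = integer(), tlen = integer(),
             seq = character(), qual = character(), nh = integer(),
             xs = character(), tags = character(), stringsAsFactors = FALSE)
}

tag_int <- function(tags, name) {
  out <- rep(NA_integer_, length(tags))
  m <- regexpr(paste0("(^|\t)", name, ":i:-?\\d+"), tags)
  hit <- m > 0
  out[hit] <- as.integer(sub(paste0(".*", name, ":i:"), "",
                             regmatches(tags, m)))
  out
}

tag_chr <- function(tags, name) {
  out <- rep(NA_character_, length(tags))
  m <- regexpr(paste0("(^|\t)", name, ":A:[^\t]"), tags)
  hit <- m > 0
  mm <- regmatches(tags, m)
  out[hit] <- substr(mm, nchar(mm), nchar(mm))
  out
}

strip_tags <- function(tags, names) {
  for (nm in names)
    tags <- gsub(paste0("(^|\t)", nm, ":[AifZ]:[^\t]*"), "", tags)
  sub("^\t+", "", tags)
}

#' Write alignment records as SAM (optionally BAM)
#'
#' Records are emitted in their current row order.  A `.bam` destination is
#' produced by writing SAM and converting with `Rsamtools::asBam`.
#'
#' @param records Alignment data frame from [read_alignments()].
#' @param path Output `.sam` or `.bam` path.
#' @param header Character vector of SAM header lines; defaults to the
#'   records' `"header"` attribute.
#' @return The output path, invisibly.
#' @export
write_alignments <- function(records, path, header = attr(records, "header")) {
  to_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  sam_path <- if (to_bam) tempfile(fileext = ".sam") else path
  tagf <- character(nrow(records))
  if (nrow(records)) {
    tagf <- ifelse(is.na(records$nh), "", paste0("NH:i:", records$nh))
    xs <- ifelse(is.na(records$xs), "", paste0("XS:A:", records$xs))
    tagf <- paste(tagf, xs, records$tags, sep = "\t")
    tagf <- gsub("\t+", "\t", paste0("\t", tagf))
    tagf <- sub("\t+$", "", tagf)
    tagf[tagf == "\t"] <- ""
  }
  lines <- c(header %||% character(0),
             if (nrow(records))
               paste0(paste(records$qname, records$flag, records$rname,
                            records$pos + 1L, records$mapq, records$cigar,
                            records$rnext,
                            ifelse(records$pnext < 0L, 0L, records$pnext + 1L),
                            records$tlen, records$seq, records$qual,
                            sep = "\t"), tagf))
  writeLines(lines, sam_path)
  if (to_bam) {
    dest <- sub("\\.bam$", "", path, ignore.case = TRUE)
    Rsamtools::asBam(sam_path, dest, overwrite = TRUE, indexDestination = TRUE)
    unlink(sam_path)
  }
  invisible(path)
}

# parse a CIGAR string into (len, op) pairs
cigar_parse <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", m)),
       op = sub("^\\d+", "", m))
}

# reference span consumed by a CIGAR
cigar_ref_span <- function(cigar) {
  p <- cigar_parse(cigar)
  sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
}

# N-op intervals (0-based half-open) of one alignment
cigar_introns <- function(pos, cigar) {
  p <- cigar_parse(cigar)
  ref_ops <- p$op %in% c("M", "D", "N", "=", "X")
  starts <- pos + c(0L, cumsum(p$len * ref_ops))[seq_along(p$op)]
  idx <- which(p$op == "N")
  if (!length(idx)) return(NULL)
  data.frame(start = starts[idx], end = starts[idx] + p$len[idx])
}

#' Extract splice junctions from spliced alignments
#'
#' Every CIGAR `N` operation yields one junction keyed by
#' (contig, start, end, strand); `support` counts the alignments containing
#' that exact junction.  Strand comes from the aligner's `XS` tag when
#' present, otherwise it is inferred from the intron motif
#' (GT..AG forward, CT..AC reverse), otherwise `"."`.
#'
#' @param x Alignment data frame from [read_alignments()], or a SAM/BAM path.
#' @param genome Optional [genome_handle()] for motif-based strand inference.
#' @param primary_only Drop secondary/supplementary alignments before
#'   counting.
#' @param count_duplicates Count alignments carrying the PCR-duplicate flag.
#' @return A coordinate-sorted [junction_frame()] with support counts;
#'   attribute `"n_skipped"` counts records whose CIGAR begins or ends with
#'   an N operation (skipped with a warning).
#' @export
junctions_from_alignments <- function(x, genome = NULL, primary_only = FALSE,
                                      count_duplicates = TRUE) {
  rec <- if (is.character(x)) read_alignments(x) else x
  keep <- !has_flag(rec$flag, FLAG_UNMAPPED)
  if (primary_only)
    keep <- keep & !has_flag(rec$flag, FLAG_SECONDARY) &
      !has_flag(rec$flag, FLAG_SUPPLEMENTARY)
  if (!count_duplicates) keep <- keep & !has_flag(rec$flag, FLAG_DUP)
  rec <- rec[keep & grepl("N", rec$cigar, fixed = TRUE), , drop = FALSE]
  n_skipped <- 0L
  if (!nrow(rec)) {
    out <- junction_frame()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  pieces <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    p <- cigar_parse(rec$cigar[i])
    core <- p$op[!p$op %in% c("S", "H")]
    if (length(core) && (core[1] == "N" || core[length(core)] == "N")) {
      n_skipped <- n_skipped + 1L
      next
    }
    iv <- cigar_introns(rec$pos[i], rec$cigar[i])
    if (!is.null(iv)) {
      iv$contig <- rec$rname[i]
      iv$xs <- rec$xs[i]
      pieces[[i]] <- iv
    }
  }
  if (n_skipped)
    warning(sprintf("skipped %d alignment(s) whose CIGAR starts/ends with N",
                    n_skipped))
  all <- do.call(rbind, pieces)
  if (is.null(all) || !nrow(all)) {
    out <- junction_frame()
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  key <- paste(all$contig, all$start, all$end, sep = ":")
  sup <- table(key)
  first <- all[!duplicated(key), , drop = FALSE]
  fkey <- paste(first$contig, first$start, first$end, sep = ":")
  # strand: first non-NA XS per junction, else motif, else '.'
  xs_of <- tapply(all$xs, key, function(v) {
    v <- v[!is.na(v) & v %in% c("+", "-")]
    if (length(v)) v[1] else NA_character_
  })
  strand <- unname(xs_of[fkey])
  if (!is.null(genome)) {
    need <- which(is.na(strand))
    for (i in need)
      strand[i] <- infer_strand(genome, first$contig[i], first$start[i],
                                first$end[i])
  }
  strand[is.na(strand)] <- "."
  out <- junction_frame(contig = first$contig, start = first$start,
                        end = first$end, strand = strand,
                        support = as.integer(sup[fkey]),
                        source = "alignment")
  out <- out[order(out$contig, out$start, out$end, out$strand), , drop = FALSE]
  out$name <- sprintf("J%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# strand from terminal intron dinucleotides
infer_strand <- function(genome, contig, start, end) {
  genome <- genome_handle(genome)
  if (!contig %in% names(genome$seqs)) return(NA_character_)
  d <- fetch_plus(genome, contig, start, start + 2L)
  a <- fetch_plus(genome, contig, end - 2L, end)
  if (d == "GT" && a == "AG") "+"
  else if (d == "CT" && a == "AC") "-"
  else NA_character_
}

#' Filter junctions by alignment support
#'
#' Keeps junctions with `support >= min_support`.  The default of 100
#' reflects the curation rule that positive examples must carry strong
#' alignment evidence.
#'
#' @param junctions A [junction_frame()].
#' @param min_support Minimum support (inclusive).
#' @return The filtered junction frame.
#' @export
filter_by_support <- function(junctions, min_support = 100L) {
  stopifnot_cols(junctions, "support")
  junctions[junctions$support >= min_support, , drop = FALSE]
}
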