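#' Parse a GFF3/GTF annotation into transcript models
#'
#' Reads an annotation file and returns one transcript model per transcript:
#' its gene, contig, strand and ordered exon intervals (converted to 0-based
#' half-open coordinates at this boundary).  Transcripts whose exons overlap
#' one another are malformed and are excluded; the number of exclusions is
#' reported in the result and via a message.
#'
#' @param path Path to a GFF3 or GTF file.
#' @param format `"auto"` (by extension), `"gff3"` or `"gtf"`.
#' @return An object of class `transcript_models`: a list with elements
#'   `transcripts` (data frame: `tx`, `gene`, `contig`, `strand`, `biotype`),
#'   `exons` (data frame: `tx`, `contig`, `strand`, `start`, `end`, 0-based
#'   half-open, sorted within transcript) and `n_excluded`.
#' @export
parse_annotation <- function(path, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(data_idx)) {
    nfield <- lengths(regmatches(lines[data_idx],
                                 gregexpr("\t", lines[data_idx], fixed = TRUE))) + 1L
    bad <- data_idx[nfield != 9L]
    if (length(bad))
      stop(sprintf("malformed annotation line %d in %s (expected 9 fields)",
                   bad[1], path))
  } else {
    return(empty_transcript_models())
  }
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)

  ex <- gr[md$type == "exon"]
  if (!length(ex)) return(empty_transcript_models())
  exmd <- S4Vectors::mcols(ex)

  if (format == "gtf") {
    tx_id <- as.character(exmd$transcript_id)
    gene_of_tx <- tapply(as.character(exmd$gene_id), tx_id, `[`, 1L)
  } else {
    par <- exmd$Parent
    tx_id <- vapply(as.list(par), function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
    # map transcript -> gene from transcript-level records
    is_tx <- md$type %in% c("mRNA", "transcript")
    txrec <- gr[is_tx]
    txmd <- S4Vectors::mcols(txrec)
    tpar <- vapply(as.list(txmd$Parent),
                   function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
    gene_of_tx <- setNames(tpar, as.character(txmd$ID))
  }

  exons <- data.frame(
    tx = tx_id,
    contig = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = BiocGenerics::start(ex) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(ex),
    stringsAsFactors = FALSE
  )
  exons <- exons[order(exons$tx, exons$start, exons$end), , drop = FALSE]

  # drop transcripts with overlapping exons
  keep_tx <- tapply(seq_len(nrow(exons)), exons$tx, function(idx) {
    s <- exons$start[idx]; e <- exons$end[idx]
    length(idx) < 2L || all(s[-1] >= e[-length(e)])
  })
  bad_tx <- names(keep_tx)[!keep_tx]
  n_excluded <- length(bad_tx)
  if (n_excluded)
    message(sprintf("parse_annotation: excluded %d transcript(s) with overlapping exons",
                    n_excluded))
  exons <- exons[!exons$tx %in% bad_tx, , drop = FALSE]

  tx_tab <- exons[!duplicated(exons$tx),
                  c("tx", "contig", "strand"), drop = FALSE]
  tx_tab$gene <- unname(gene_of_tx[tx_tab$tx])
  biotype_col <- intersect(c("gene_biotype", "transcript_biotype", "biotype",
                             "gene_type"), names(md))
  tx_tab$biotype <- NA_character_
  if (length(biotype_col) && length(ex)) {
    bt <- as.character(exmd[[biotype_col[1]]])
    bt_of_tx <- tapply(bt, tx_id, `[`, 1L)
    tx_tab$biotype <- unname(bt_of_tx[tx_tab$tx])
  }
  rownames(exons) <- rownames(tx_tab) <- NULL
  structure(list(transcripts = tx_tab[, c("tx", "gene", "contig", "strand", "biotype")],
                 exons = exons, n_excluded = n_excluded),
            class = "transcript_models")
}

empty_transcript_models <- function() {
  structure(list(
    transcripts = data.frame(tx = character(), gene = character(),
                             contig = character(), strand = character(),
                             biotype = character(), stringsAsFactors = FALSE),
    exons = data.frame(tx = character(), contig = character(),
                       strand = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE),
    n_excluded = 0L), class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d transcript(s), %d exon record(s), %d excluded\n",
              nrow(x$transcripts), nrow(x$exons), x$n_excluded))
  invisible(x)
}

#' Derive introns from transcript models
#'
#' One junction per adjacent exon pair, deduplicated across isoforms by
#' (contig, start, end, strand).  Single-exon transcripts contribute nothing.
#' The junction start is the first intronic base and the end is the first
#' exonic base after the intron (0-based half-open).
#'
#' @param models A [parse_annotation()] result.
#' @return A junction data frame (see [junction_frame()]), coordinate-sorted,
#'   with `intron_num` (index of the intron within its first transcript) and
#'   `parents` (comma-separated transcript ids) columns.
#' @export
introns_from_annotation <- function(models) {
  ex <- models$exons
  if (!nrow(ex)) return(junction_frame())
  parts <- split(seq_len(nrow(ex)), ex$tx)
  recs <- lapply(names(parts), function(tx) {
    idx <- parts[[tx]]
    if (length(idx) < 2L) return(NULL)
    s <- ex$start[idx]; e <- ex$end[idx]
    data.frame(contig = ex$contig[idx[1]],
               start = e[-length(e)],
               end = s[-1],
               strand = ex$strand[idx[1]],
               tx = tx,
               intron_num = seq_len(length(idx) - 1L),
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs) || !nrow(recs)) return(junction_frame())
  recs <- recs[recs$end > recs$start, , drop = FALSE]
  key <- paste(recs$contig, recs$start, recs$end, recs$strand, sep = ":")
  parents <- tapply(recs$tx, key, function(v) paste(unique(v), collapse = ","))
  first <- recs[!duplicated(key), , drop = FALSE]
  first$parents <- unname(parents[paste(first$contig, first$start, first$end,
                                        first$strand, sep = ":")])
  first <- first[order(first$contig, first$start, first$end), , drop = FALSE]
  out <- junction_frame(contig = first$contig, start = first$start,
                        end = first$end, strand = first$strand,
                        support = 0L,
                        name = sprintf("J%05d", seq_len(nrow(first))),
                        source = "annotation")
  out$intron_num <- first$intron_num
  out$parents <- first$parents
  rownames(out) <- NULL
  out
}

#' Stranded gene loci from transcript models
#'
#' The locus of a gene is the range spanned by its exons; used for the
#' opposite-strand rules of negative-set curation.
#'
#' @param models A [parse_annotation()] result.
#' @param biotype Optional biotype filter (e.g. `"protein_coding"`); applied
#'   only when the annotation carries biotypes.
#' @return Data frame with `gene`, `contig`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
gene_loci <- function(models, biotype = NULL) {
  tx <- models$transcripts
  ex <- models$exons
  if (!nrow(ex))
    return(data.frame(gene = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  if (!is.null(biotype) && any(!is.na(tx$biotype)))
    tx <- tx[!is.na(tx$biotype) & tx$biotype %in% biotype, , drop = FALSE]
  gene_of_tx <- setNames(ifelse(is.na(tx$gene), tx$tx, tx$gene), tx$tx)
  ex <- ex[ex$tx %in% tx$tx, , drop = FALSE]
  ex$gene <- unname(gene_of_tx[ex$tx])
  strand_of_gene <- tapply(ex$strand, ex$gene, `[`, 1L)
  contig_of_gene <- tapply(ex$contig, ex$gene, `[`, 1L)
  out <- data.frame(
    gene = names(strand_of_gene),
    contig = unname(contig_of_gene),
    start = as.integer(tapply(ex$start, ex$gene, min)),
    end = as.integer(tapply(ex$end, ex$gene, max)),
    strand = unname(strand_of_gene),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
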