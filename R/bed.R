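#' Construct a junction table
#'
#' The junction is the central record of the package: a strand-aware intron
#' interval in 0-based half-open coordinates, where `start` is the first
#' intronic base and `end` is the first exonic base after the intron.
#'
#' @param contig,start,end,strand Interval fields; `strand` one of
#'   `"+"`, `"-"`, `"."`.
#' @param support Number of alignments supporting the junction.
#' @param name Junction name (auto-generated when `NA`).
#' @param source One of `"alignment"`, `"annotation"`, `"generated"`,
#'   `"unlabeled"`.
#' @param label Curation label: `"positive-main"`, `"positive-alt"`,
#'   `"negative-1"`, `"negative-random"` or `"unlabeled"`.
#' @return A `data.frame` with those columns.
#' @export
junction_frame <- function(contig = character(), start = integer(),
                           end = integer(), strand = character(),
                           support = integer(), name = NA_character_,
                           source = "unlabeled", label = "unlabeled") {
  n <- max(length(contig), length(start), length(end), length(strand))
  if (n == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), support = integer(),
                      name = character(), source = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  if (length(support) == 0L) support <- 0L
  df <- data.frame(contig = as.character(contig),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   support = as.integer(support),
                   name = as.character(name),
                   source = as.character(source),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  if (any(df$end - df$start < 1L))
    stop("junctions must satisfy end - start >= 1")
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  auto <- is.na(df$name)
  if (any(auto)) df$name[auto] <- sprintf("J%05d", which(auto))
  df
}

#' Write junctions as a six-column BED file
#'
#' Columns are CHROM, START, END, NAME, a numeric fifth column, STRAND, with
#' 0-based half-open coordinates and deterministic coordinate-sorted order.
#' The fifth column carries the alignment support count in the package's
#' internal dialect, or the within-transcript intron number for
#' annotation-derived junction files.
#'
#' @param junctions A [junction_frame()].
#' @param path Output path.
#' @param fifth Which field to place in column 5.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path,
                               fifth = c("support", "intron_num")) {
  fifth <- match.arg(fifth)
  stopifnot_cols(junctions, c("contig", "start", "end", "strand"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!nrow(junctions)) return(invisible(path))
  ord <- order(junctions$contig, junctions$start, junctions$end,
               junctions$strand)
  j <- junctions[ord, , drop = FALSE]
  score <- if (fifth == "support") j$support %||% 0L
           else j$intron_num %||% rep(1L, nrow(j))
  if (is.null(score)) score <- 0L
  name <- j$name %||% sprintf("J%05d", seq_len(nrow(j)))
  writeLines(paste(j$contig, j$start, j$end, name, score, j$strand,
                   sep = "\t"), con)
  invisible(path)
}

#' Read a six-column junction BED file
#'
#' @param path BED6 path as written by [write_junction_bed()].
#' @param fifth Interpretation of column 5 (see [write_junction_bed()]).
#' @param source Value for the `source` column of the result.
#' @return A [junction_frame()].
#' @export
read_junction_bed <- function(path, fifth = c("support", "intron_num"),
                              source = "unlabeled") {
  fifth <- match.arg(fifth)
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) return(junction_frame())
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("contig", "start", "end", "name", "score",
                                 "strand"))
  out <- junction_frame(contig = df$contig, start = df$start, end = df$end,
                        strand = df$strand,
                        support = if (fifth == "support") df$score else 0L,
                        name = df$name, source = source)
  if (fifth == "intron_num") out$intron_num <- df$score
  out
}
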