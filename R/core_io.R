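# Coordinate conventions and on-disk formats shared by the pipeline.
#
# All user-facing coordinates are 1-based inclusive, matching Ensembl and the
# Chr5:551935:556936-style locus notation used in enhancer databases.  BED
# files are converted to/from 0-based half-open at the I/O boundary
# (delegated to rtracklayer, which implements exactly that convention).

#' Construct genomic intervals as a GRanges
#'
#' Thin constructor used throughout the package: coordinates are 1-based and
#' inclusive, `end >= start >= 1`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unstranded, default).
#' @return A [GenomicRanges::GRanges] object.
#' @export
#' @examples
#' gi("Chr5", 551935, 556936)
gi <- function(chrom, start, end, strand = "*") {
  if (any(start < 1L)) stop("interval start must be >= 1")
  if (any(end < start)) stop("interval end must be >= start")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

#' Interval length in base pairs
#'
#' Length under the 1-based inclusive convention, `end - start + 1`.
#'
#' @param x A `GRanges`.
#' @return Integer vector of widths in bp.
#' @export
interval_length <- function(x) {
  BiocGenerics::width(x)
}

#' Do two intervals overlap?
#'
#' Strand-agnostic overlap: true iff the two intervals share a chromosome and
#' `a.start <= b.end && b.start <= a.end`.  Vectorised over pairs.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b) {
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  same &
    (GenomicRanges::start(a) <= GenomicRanges::end(b)) &
    (GenomicRanges::start(b) <= GenomicRanges::end(a))
}

#' Length of an upstream promoter window
#'
#' Upstream offsets denote the half-open interval `[-far, -near)` relative to
#' the TSS, so a window "between 2108 and 1126 bp upstream" spans
#' `2108 - 1126 = 982` bp.  This is the only convention consistent with the
#' deletion-construct spans 982, 148 and 35 bp.
#'
#' @param offset_far Distal offset in bp upstream of the TSS (positive).
#' @param offset_near Proximal offset in bp upstream (non-negative,
#'   `< offset_far`).
#' @return Window length in bp.
#' @export
#' @examples
#' upstream_window_length(2108, 1126) # 982
upstream_window_length <- function(offset_far, offset_near) {
  if (any(offset_near < 0)) stop("offset_near must be >= 0")
  if (any(offset_far <= offset_near)) {
    stop("offset_far must be strictly greater than offset_near")
  }
  offset_far - offset_near
}

#' Resolve an upstream window to genome coordinates
#'
#' For a `+` strand gene the window `[-far, -near)` lies at
#' `[tss - far, tss - near - 1]`; for a `-` strand gene it is mirrored
#' downstream in genome coordinates, `[tss + near + 1, tss + far]`.  Windows
#' running past a chromosome edge are truncated and flagged.
#'
#' @param chrom Chromosome name.
#' @param tss 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param offset_far,offset_near Upstream offsets in bp (see
#'   [upstream_window_length()]).
#' @param chrom_length Length of the chromosome in bp (used for truncation);
#'   `NA` skips the right-edge check.
#' @param strand_resolved If `FALSE`, ignore strand and always take the
#'   window on the left of the TSS in genome coordinates.
#' @return A length-1 `GRanges` with a logical metadata column `truncated`.
#' @export
resolve_upstream_window <- function(chrom, tss, strand,
                                    offset_far, offset_near = 0,
                                    chrom_length = NA_integer_,
                                    strand_resolved = TRUE) {
  upstream_window_length(offset_far, offset_near)
  use_minus <- strand_resolved && identical(as.character(strand), "-")
  if (use_minus) {
    s <- tss + offset_near + 1
    e <- tss + offset_far
  } else {
    s <- tss - offset_far
    e <- tss - offset_near - 1
  }
  truncated <- FALSE
  if (s < 1L) {
    s <- 1L
    truncated <- TRUE
  }
  if (!is.na(chrom_length) && e > chrom_length) {
    e <- chrom_length
    truncated <- TRUE
  }
  if (e < s) stop("upstream window collapsed to zero length after truncation")
  if (truncated) {
    warning("upstream window for TSS ", tss, " truncated at chromosome edge")
  }
  g <- gi(chrom, s, e, if (use_minus) "-" else "+")
  S4Vectors::mcols(g)$truncated <- truncated
  g
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased; gzip-compressed files are handled transparently.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # drop description after first whitespace, keep bare chrom names
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(as.character(g)))
}

#' Write a genome to FASTA
#'
#' @param genome Named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Extract sequence for intervals
#'
#' Minus-strand intervals return the reverse complement of the plus-strand
#' slice.
#'
#' @param genome Named `DNAStringSet`.
#' @param x `GRanges`.
#' @return Character vector of sequences.
#' @export
get_interval_seq <- function(genome, x) {
  chrom <- as.character(GenomicRanges::seqnames(x))
  bad <- !(chrom %in% names(genome))
  if (any(bad)) stop("unknown chromosome: ", paste(unique(chrom[bad]), collapse = ", "))
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(GenomicRanges::end(x) > lens)) {
    stop("interval extends past chromosome end")
  }
  out <- vapply(seq_along(x), function(i) {
    s <- Biostrings::subseq(genome[[chrom[i]]],
                            GenomicRanges::start(x)[i],
                            GenomicRanges::end(x)[i])
    if (as.character(GenomicRanges::strand(x)[i]) == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    as.character(s)
  }, character(1))
  out
}

#' Read / write loci as BED
#'
#' BED is 0-based half-open on disk; these wrappers present 1-based inclusive
#' `GRanges` in memory (conversion handled by rtracklayer).
#'
#' @param path File path.
#' @return `read_bed()` returns a `GRanges`.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @param x `GRanges` to write; a `name` metadata column becomes the BED name
#'   field.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}

#' Read an enhancer-annotation table
#'
#' Parses the curated enhancer-annotation TSV dialect: columns
#' `enhancer_id`, `source`, `chrom`, `start`, `stop`, `genes`, with gene
#' lists semicolon-separated (empty or `"Not indicated"` meaning no
#' annotated regulation) and coordinates possibly containing grouping spaces
#' as printed in database exports (e.g. `"556 903"`).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with a list-column `genes`; attribute
#'   `"granges"` holds the intervals as a `GRanges` named by enhancer id.
#' @export
read_enhancer_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("enhancer_id", "source", "chrom", "start", "stop", "genes")
  if (!all(need %in% names(df))) {
    stop("enhancer table must have columns: ", paste(need, collapse = ", "))
  }
  num <- function(x) as.integer(gsub("[ ,]", "", x))
  df$start <- num(df$start)
  df$stop <- num(df$stop)
  genes <- strsplit(df$genes, ";")
  genes <- lapply(genes, function(g) {
    g <- trimws(g)
    g <- g[nzchar(g)]
    g[!tolower(g) %in% "not indicated"]
  })
  out <- data.frame(enhancer_id = df$enhancer_id, source = df$source,
                    chrom = df$chrom, start = df$start, stop = df$stop,
                    stringsAsFactors = FALSE)
  out$genes <- genes
  attr(out, "granges") <- stats::setNames(
    gi(out$chrom, out$start, out$stop), out$enhancer_id)
  out
}

#' Intervals of an enhancer table
#'
#' @param tab A table from [read_enhancer_table()].
#' @return `GRanges` named by enhancer id.
#' @export
enhancer_granges <- function(tab) {
  g <- attr(tab, "granges")
  if (is.null(g)) g <- stats::setNames(gi(tab$chrom, tab$start, tab$stop),
                                       tab$enhancer_id)
  g
}

#' Read a promoter/TSS definition table
#'
#' Four-column TSV: `gene`, `chrom`, `tss`, `strand`.
#'
#' @param path Path to the TSV file.
#' @return data.frame with those columns.
#' @export
read_promoter_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) {
    stop("promoter table must have columns: ", paste(need, collapse = ", "))
  }
  df$tss <- as.integer(df$tss)
  df
}

# combine GRanges whose seqlevels may differ without the Seqinfo chatter
.c_gr <- function(...) suppressWarnings(c(...))
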