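# Pore-C concatemer mining: multi-mapping masking, per-fragment alignment of
# concatemer reads, best-hit resolution, and LG4:promoter co-occurrence
# calling.
#
# Ranking note: candidate placements are ranked by raw alignment score.  At
# fixed scoring parameters and database size the BLAST e-value is monotone
# decreasing in score, so "lowest e-value" and "highest score" select the
# same placement; score is used as the e-value surrogate throughout, with a
# default floor of min_score = 100.

#' Read Pore-C reads from FASTA/FASTQ
#'
#' Format is inferred from the file extension (`.fq`/`.fastq` vs
#' `.fa`/`.fasta`), gzipped or not.
#'
#' @param path Input file.
#' @return Named `DNAStringSet`.
#' @export
read_porec_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  rd <- Biostrings::readDNAStringSet(path, format = fmt)
  names(rd) <- sub("\\s.*$", "", names(rd))
  rd
}

#' Mask multi-mapping stretches of promoter sequences
#'
#' Every maximal substring longer than `min_len` bp that perfectly matches
#' two or more locations in the genome (either strand) is replaced by `N`;
#' all other bases are left unchanged.  A promoter that is itself a genomic
#' substring counts its own locus as one occurrence, so only genuinely
#' duplicated stretches are masked.  A duplication of exactly `min_len` bp
#' is *not* masked (the rule is strictly "> min_len").
#'
#' @param promoter_seqs Named character vector or `DNAStringSet` of
#'   promoter sequences (genomic substrings).
#' @param genome Named `DNAStringSet`.
#' @param min_len Length threshold in bp (default 100).
#' @return Named character vector of masked sequences.
#' @export
mask_multimapping <- function(promoter_seqs, genome, min_len = 100L) {
  if (is(promoter_seqs, "DNAStringSet")) {
    promoter_seqs <- stats::setNames(as.character(promoter_seqs),
                                     names(promoter_seqs))
  }
  w <- min_len + 1L
  subject <- c(genome, Biostrings::reverseComplement(genome))
  out <- promoter_seqs
  for (id in seq_along(promoter_seqs)) {
    s <- toupper(promoter_seqs[[id]])
    L <- nchar(s)
    if (L < w) { out[[id]] <- s; next }
    starts <- seq_len(L - w + 1L)
    wins <- substring(s, starts, starts + w - 1L)
    ok <- !grepl("[^ACGT]", wins)
    counts <- integer(length(wins))
    if (any(ok)) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(wins[ok]))
      m <- Biostrings::vcountPDict(pd, subject)
      counts[ok] <- rowSums(m)
    }
    multi <- counts >= 2L
    if (any(multi)) {
      keep <- strsplit(s, "")[[1]]
      for (i in which(multi)) keep[starts[i]:(starts[i] + w - 1L)] <- "N"
      out[[id]] <- paste(keep, collapse = "")
    } else {
      out[[id]] <- s
    }
  }
  out
}

#' Resolve the best placement among tied candidates
#'
#' Highest alignment score wins; ties are broken by smallest genomic
#' coordinate (chromosome name, then start), and the winner keeps
#' `is_ambiguous = TRUE` when the best score was tied.
#'
#' @param candidates data.frame of candidate placements with columns
#'   `chrom`, `tstart`, `score` (plus any others, carried through).
#' @return The chosen row with `n_equal_best` and `is_ambiguous` added.
#' @export
resolve_best <- function(candidates) {
  stopifnot(nrow(candidates) >= 1L)
  best <- candidates[candidates$score == max(candidates$score), , drop = FALSE]
  ord <- order(best$chrom, best$tstart)
  chosen <- best[ord[1L], , drop = FALSE]
  chosen$n_equal_best <- nrow(best)
  chosen$is_ambiguous <- nrow(best) > 1L
  chosen
}

#' Align concatemer read fragments to a genome
#'
#' Seed-and-extend: exact k-mer seeds (`word_size`) clustered per
#' (chromosome, strand, diagonal band), banded affine-gap local extension
#' with the given scores, then greedy segmentation of each read: the
#' highest-scoring candidate is accepted, equally scoring placements of the
#' same read segment are counted in `n_equal_best` (ties resolved by
#' [resolve_best()]), all candidates overlapping the accepted read span are
#' discarded, and the process repeats until nothing scores `min_score` or
#' more.
#'
#' @param reads Named `DNAStringSet` (or named character vector) of reads.
#' @param genome Named `DNAStringSet`.
#' @param word_size Seed k-mer length (default 15).
#' @param match,mismatch Match / mismatch scores (defaults +2 / -3).
#' @param gap_open,gap_extend Affine gap costs (defaults 5 / 2; a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @param min_score Minimum reported alignment score (default 100, the
#'   e-value-surrogate floor).
#' @param band Diagonal band half-width for clustering and extension
#'   (default 15).
#' @return data.frame of fragment alignments: `read_id`, `qstart`, `qend`
#'   (1-based on the read), `chrom`, `tstart`, `tend`, `strand`, `score`,
#'   `n_equal_best`, `is_ambiguous`.  Reads shorter than `word_size`
#'   produce no rows.
#' @export
align_read_fragments <- function(reads, genome, word_size = 15L,
                                 match = 2L, mismatch = -3L,
                                 gap_open = 5L, gap_extend = 2L,
                                 min_score = 100L, band = 15L) {
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  chrom_names <- names(genome)
  cand <- cpp_align_candidates(as.character(genome), as.character(reads),
                               as.integer(word_size), as.integer(match),
                               as.integer(mismatch), as.integer(gap_open),
                               as.integer(gap_extend), as.integer(min_score),
                               as.integer(band), 150L, 200L, 512L)
  empty <- data.frame(read_id = character(), qstart = integer(),
                      qend = integer(), chrom = character(),
                      tstart = numeric(), tend = numeric(),
                      strand = character(), score = integer(),
                      n_equal_best = integer(), is_ambiguous = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  cand$chrom <- chrom_names[cand$chrom]
  # at a ligation junction the local alignment of one fragment can extend a
  # few net-positive-scoring bases into the next, so neighbouring segments
  # may overlap slightly on the read; such edges are trimmed rather than
  # treated as conflicts
  slop <- 30L
  res <- lapply(split(cand, cand$read), function(df) {
    picked <- list()
    while (nrow(df) > 0L) {
      chosen <- resolve_best(df)
      # ties = equally scoring placements of (essentially) the same segment
      ovl <- pmin(df$qend, chosen$qend) - pmax(df$qstart, chosen$qstart) + 1L
      wmax <- pmax(df$qend - df$qstart + 1L, chosen$qend - chosen$qstart + 1L)
      same_seg <- df$score == chosen$score & ovl >= 0.5 * wmax
      chosen$n_equal_best <- sum(same_seg)
      chosen$is_ambiguous <- chosen$n_equal_best > 1L
      picked[[length(picked) + 1L]] <- chosen
      df <- df[!same_seg & ovl <= slop, , drop = FALSE]
      if (nrow(df) > 0L) {
        # trim residual junction overlap off the remaining candidates
        right <- df$qstart <= chosen$qend & df$qend > chosen$qend
        if (any(right)) {
          o <- chosen$qend - df$qstart[right] + 1L
          df$qstart[right] <- df$qstart[right] + o
          plus <- df$strand[right] == "+"
          df$tstart[right][plus] <- df$tstart[right][plus] + o[plus]
          df$tend[right][!plus] <- df$tend[right][!plus] - o[!plus]
          df$score[right] <- df$score[right] - abs(match) * o
        }
        left <- df$qend >= chosen$qstart & df$qstart < chosen$qstart
        if (any(left)) {
          o <- df$qend[left] - chosen$qstart + 1L
          df$qend[left] <- df$qend[left] - o
          plus <- df$strand[left] == "+"
          df$tend[left][plus] <- df$tend[left][plus] - o[plus]
          df$tstart[left][!plus] <- df$tstart[left][!plus] + o[!plus]
          df$score[left] <- df$score[left] - abs(match) * o
        }
        df <- df[df$qend - df$qstart + 1L >= word_size &
                   df$score >= min_score, , drop = FALSE]
      }
    }
    do.call(rbind, picked)
  })
  out <- do.call(rbind, res)
  out$read_id <- names(reads)[out$read]
  out <- out[order(out$read, out$qstart),
             c("read_id", "qstart", "qend", "chrom", "tstart", "tend",
               "strand", "score", "n_equal_best", "is_ambiguous")]
  rownames(out) <- NULL
  out
}

#' Fragment alignments as GRanges
#'
#' @param alignments data.frame from [align_read_fragments()].
#' @return `GRanges` with the alignment fields as metadata columns.
#' @export
alignment_granges <- function(alignments) {
  g <- gi(alignments$chrom, alignments$tstart, alignments$tend,
          alignments$strand)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    alignments[c("read_id", "qstart", "qend", "score", "n_equal_best",
                 "is_ambiguous")])
  g
}

#' Detect LG4:promoter co-occurrence within single reads
#'
#' For each read, emits one contact record per (LG4 fragment, promoter
#' fragment) pair in which one resolved fragment overlaps an LG4 interval
#' and a *different* fragment (non-overlapping read span) overlaps a
#' promoter window.  Ambiguous (tied-placement) fragments are excluded by
#' default.
#'
#' @param alignments data.frame from [align_read_fragments()].
#' @param lg4_set `GRanges` of LG4 loci (named, or with an `lg4_id`
#'   metadata column).
#' @param promoters data.frame of promoter records (needs `gene`, `chrom`,
#'   `win_start`, `win_end`), or a named `GRanges` of promoter windows.
#' @param include_ambiguous Include tied-placement fragments (default
#'   FALSE).
#' @return data.frame of contacts: `read_id`, `lg4_id`, `promoter_gene`,
#'   coordinates and scores of the two supporting fragments.
#' @export
detect_cooccurrence <- function(alignments, lg4_set, promoters,
                                include_ambiguous = FALSE) {
  empty <- data.frame(read_id = character(), lg4_id = character(),
                      promoter_gene = character(),
                      lg4_chrom = character(), lg4_tstart = numeric(),
                      lg4_tend = numeric(), lg4_score = integer(),
                      prom_chrom = character(), prom_tstart = numeric(),
                      prom_tend = numeric(), prom_score = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  al <- alignments
  if (!include_ambiguous) al <- al[!al$is_ambiguous, , drop = FALSE]
  if (nrow(al) == 0L) return(empty)
  if (is.data.frame(promoters)) {
    prom_gr <- promoter_granges(promoters)
  } else {
    prom_gr <- promoters
  }
  lg4_ids <- names(lg4_set)
  if (is.null(lg4_ids)) lg4_ids <- S4Vectors::mcols(lg4_set)$lg4_id
  frag_gr <- gi(al$chrom, al$tstart, al$tend)
  ov_l <- suppressWarnings(GenomicRanges::findOverlaps(
    frag_gr, unstrand_gr(lg4_set), ignore.strand = TRUE))
  ov_p <- suppressWarnings(GenomicRanges::findOverlaps(
    frag_gr, unstrand_gr(prom_gr), ignore.strand = TRUE))
  if (length(ov_l) == 0L || length(ov_p) == 0L) return(empty)
  lhits <- data.frame(row = S4Vectors::queryHits(ov_l),
                      lg4_id = lg4_ids[S4Vectors::subjectHits(ov_l)],
                      stringsAsFactors = FALSE)
  phits <- data.frame(row = S4Vectors::queryHits(ov_p),
                      gene = names(prom_gr)[S4Vectors::subjectHits(ov_p)],
                      stringsAsFactors = FALSE)
  lhits$read_id <- al$read_id[lhits$row]
  phits$read_id <- al$read_id[phits$row]
  pairs <- merge(lhits, phits, by = "read_id")
  if (nrow(pairs) == 0L) return(empty)
  # the two fragments must be distinct, with non-overlapping read spans
  keep <- pairs$row.x != pairs$row.y &
    !(al$qstart[pairs$row.x] <= al$qend[pairs$row.y] &
        al$qstart[pairs$row.y] <= al$qend[pairs$row.x])
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  out <- data.frame(
    read_id = pairs$read_id, lg4_id = pairs$lg4_id,
    promoter_gene = pairs$gene,
    lg4_chrom = al$chrom[pairs$row.x], lg4_tstart = al$tstart[pairs$row.x],
    lg4_tend = al$tend[pairs$row.x], lg4_score = al$score[pairs$row.x],
    prom_chrom = al$chrom[pairs$row.y], prom_tstart = al$tstart[pairs$row.y],
    prom_tend = al$tend[pairs$row.y], prom_score = al$score[pairs$row.y],
    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$read_id, out$lg4_id, out$promoter_gene), , drop = FALSE]
}

#' Summarise contacts per LG4:promoter pair
#'
#' @param contacts data.frame from [detect_cooccurrence()].
#' @return data.frame `(lg4_id, promoter_gene, n_reads)` sorted by
#'   descending read support.
#' @export
contact_summary <- function(contacts) {
  if (nrow(contacts) == 0L) {
    return(data.frame(lg4_id = character(), promoter_gene = character(),
                      n_reads = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(read_id ~ lg4_id + promoter_gene, data = contacts,
                          FUN = function(x) length(unique(x)))
  names(agg)[3] <- "n_reads"
  agg <- agg[order(-agg$n_reads, agg$lg4_id, agg$promoter_gene), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
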