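# G-run detection, minimal G4 motif finding, GGG-repeat density profiling and
# LG4 locus calling.
#
# Conventions: a "G-run" is a maximal stretch of >= min_run consecutive G on
# one strand.  Minus-strand G-runs are C-runs of the plus-strand sequence and
# are reported in plus-strand coordinates.  N never matches G or C, so a run
# interrupted by N is two runs.

#' Find maximal G-runs
#'
#' Maximal runs of at least `min_run` consecutive `G` (`strand = "+"`) or `C`
#' reported as minus-strand G-runs (`strand = "-"`), in plus-strand
#' coordinates.
#'
#' @param seq A single DNA string over `A,C,G,T,N`.
#' @param min_run Minimum run length (default 3).
#' @param strand `"+"` or `"-"`.
#' @return data.frame with columns `start`, `end`, `width`, `strand`
#'   (1-based inclusive), sorted by start.
#' @export
#' @examples
#' find_g_runs("AGGGA") # one run, 2..4
find_g_runs <- function(seq, min_run = 3L, strand = "+") {
  stopifnot(length(seq) == 1L, min_run >= 1L)
  seq <- toupper(seq)
  base <- if (identical(strand, "-")) "C" else "G"
  if (!nzchar(seq)) {
    return(data.frame(start = integer(), end = integer(),
                      width = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr(paste0(base, "{", min_run, ",}"), seq)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      width = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  w <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + w - 1L,
             width = as.integer(w),
             strand = rep(strand, length(m)), stringsAsFactors = FALSE)
}

#' Count GGG repeats in a sequence
#'
#' The default `"tiling"` mode tiles each maximal G-run into non-overlapping
#' GGG units: a run of length L contributes `floor(L / 3)` repeats (so
#' `GGGGGG` counts 2 and `GGGGG` counts 1).  `"runs"` mode instead counts
#' the number of maximal runs of length >= 3.
#'
#' @inheritParams find_g_runs
#' @param counting_mode `"tiling"` (default) or `"runs"`.
#' @return Integer count.
#' @export
count_ggg_repeats <- function(seq, strand = "+", counting_mode = c("tiling", "runs")) {
  counting_mode <- match.arg(counting_mode)
  runs <- find_g_runs(seq, 3L, strand)
  if (nrow(runs) == 0L) return(0L)
  if (counting_mode == "tiling") sum(runs$width %/% 3L) else nrow(runs)
}

#' Find minimal G4 motifs
#'
#' A minimal quadruplex motif is four G-runs of length >= 3 separated by
#' three loops whose lengths all fall in `[loop_min, loop_max]`
#' (GGGnGGGnGGGnGGG).  Runs are maximal, so loops never begin or end with G;
#' overlapping alternatives are resolved leftmost-first and reported motifs
#' never share a G-run.
#'
#' @inheritParams find_g_runs
#' @param loop_min,loop_max Loop length bounds in bp (defaults 1 and 7).
#' @return data.frame with columns `start`, `end`, `width`, `strand` and a
#'   list-column `loop_lengths`.
#' @export
find_min_g4_motifs <- function(seq, loop_min = 1L, loop_max = 7L, strand = "+") {
  stopifnot(loop_min >= 1L, loop_max >= loop_min)
  runs <- find_g_runs(seq, 3L, strand)
  n <- nrow(runs)
  res <- list()
  i <- 1L
  while (i <= n - 3L) {
    gaps <- runs$start[(i + 1L):(i + 3L)] - runs$end[i:(i + 2L)] - 1L
    if (all(gaps >= loop_min & gaps <= loop_max)) {
      res[[length(res) + 1L]] <- list(start = runs$start[i],
                                      end = runs$end[i + 3L],
                                      loops = gaps)
      i <- i + 4L
    } else {
      i <- i + 1L
    }
  }
  if (length(res) == 0L) {
    out <- data.frame(start = integer(), end = integer(), width = integer(),
                      strand = character(), stringsAsFactors = FALSE)
    out$loop_lengths <- list()
    return(out)
  }
  out <- data.frame(start = vapply(res, `[[`, integer(1), "start"),
                    end = vapply(res, `[[`, integer(1), "end"),
                    stringsAsFactors = FALSE)
  out$width <- out$end - out$start + 1L
  out$strand <- strand
  out$loop_lengths <- lapply(res, `[[`, "loops")
  out
}

# G-runs for one chromosome on both strands, cached layout used by the
# window profiler and LG4 caller.
chrom_runs <- function(seq) {
  list(plus = find_g_runs(seq, 3L, "+"),
       minus = find_g_runs(seq, 3L, "-"))
}

# GGG repeats (tiling or runs mode) within windows, from precomputed runs.
# Clipping a maximal run at a window edge yields the maximal run of the
# window substring, so this equals count_ggg_repeats() on each substring.
windowed_counts <- function(runs, starts, ends, counting_mode) {
  if (nrow(runs) == 0L) return(integer(length(starts)))
  win <- IRanges::IRanges(starts, ends)
  rr <- IRanges::IRanges(runs$start, runs$end)
  ov <- IRanges::findOverlaps(win, rr)
  if (length(ov) == 0L) return(integer(length(starts)))
  qs <- S4Vectors::queryHits(ov)
  ss <- S4Vectors::subjectHits(ov)
  clip_w <- pmin(runs$end[ss], ends[qs]) - pmax(runs$start[ss], starts[qs]) + 1L
  contrib <- if (counting_mode == "tiling") clip_w %/% 3L else as.integer(clip_w >= 3L)
  out <- integer(length(starts))
  agg <- tapply(contrib, qs, sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' GGG-repeat density profile along a chromosome
#'
#' Sliding windows tiled from the chromosome start; density is GGG repeats
#' per 1000 bp on each strand.  The final partial window is scaled by its
#' true length.
#'
#' @param genome Named `DNAStringSet` (or a single character sequence).
#' @param chrom Chromosome name (ignored when `genome` is a bare sequence).
#' @param window Window size in bp (default 1000).
#' @param step Step between window starts in bp (default 100).
#' @param counting_mode See [count_ggg_repeats()].
#' @return data.frame with `start`, `end`, `count_plus`, `count_minus`,
#'   `density_plus`, `density_minus`.
#' @export
ggg_density_profile <- function(genome, chrom = NULL, window = 1000L,
                                step = 100L, counting_mode = "tiling") {
  stopifnot(window >= step, step >= 1L)
  seq <- .one_chrom_seq(genome, chrom)
  len <- nchar(seq)
  starts <- seq.int(1L, max(1L, len), by = step)
  starts <- starts[starts <= len]
  ends <- pmin(starts + window - 1L, len)
  runs <- chrom_runs(seq)
  cp <- windowed_counts(runs$plus, starts, ends, counting_mode)
  cm <- windowed_counts(runs$minus, starts, ends, counting_mode)
  w <- ends - starts + 1L
  data.frame(start = starts, end = ends,
             count_plus = cp, count_minus = cm,
             density_plus = cp * 1000 / w,
             density_minus = cm * 1000 / w)
}

.one_chrom_seq <- function(genome, chrom) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    return(toupper(genome))
  }
  if (is.null(chrom)) {
    if (length(genome) == 1L) chrom <- names(genome)[1] else
      stop("chrom must be given for a multi-chromosome genome")
  }
  as.character(genome[[chrom]])
}

#' Call long G4-rich (LG4) loci
#'
#' Windows whose GGG-repeat density on either strand reaches
#' `density_threshold` (repeats per 1000 bp) are marked; overlapping or
#' adjacent marked windows are merged.  Because a window only partially
#' overlapping a dense block can still clear the threshold, a merged region
#' over-extends into the flanking background by up to
#' `window * (1 - threshold/block density)` on each side; each region is
#' therefore trimmed to the span of step-sized cells whose fine-scale
#' density also meets the threshold, then snapped to the outermost
#' contributing G/C run so call boundaries are sequence-anchored.  Calls
#' shorter than `min_length` are discarded.
#'
#' @param genome Named `DNAStringSet`.
#' @param density_threshold Minimum density in GGG repeats per 1000 bp
#'   (default 80, the LG4 criterion).
#' @param window,step Scan geometry in bp (defaults 1000 / 100).
#' @param min_length Minimum call length in bp (default 1000).
#' @param counting_mode See [count_ggg_repeats()].
#' @return `GRanges` with metadata columns `lg4_id`, `ggg_count_plus`,
#'   `ggg_count_minus`, `peak_density`, `qualifying_strand`.
#' @export
call_lg4 <- function(genome, density_threshold = 80, window = 1000L,
                     step = 100L, min_length = 1000L,
                     counting_mode = "tiling") {
  stopifnot(density_threshold > 0, min_length > 0)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  calls <- list()
  for (chrom in names(genome)) {
    seq <- as.character(genome[[chrom]])
    prof <- ggg_density_profile(genome, chrom, window, step, counting_mode)
    hit_p <- prof$density_plus >= density_threshold
    hit_m <- prof$density_minus >= density_threshold
    hit <- hit_p | hit_m
    if (!any(hit)) next
    marked <- IRanges::IRanges(prof$start[hit], prof$end[hit])
    merged <- IRanges::reduce(marked, min.gapwidth = 1L)
    runs <- chrom_runs(seq)
    allruns <- rbind(runs$plus, runs$minus)
    rr <- IRanges::IRanges(allruns$start, allruns$end)
    for (k in seq_along(merged)) {
      rs <- IRanges::start(merged)[k]
      re <- IRanges::end(merged)[k]
      # fine-scale trim: step cells (on the scan grid) whose own density
      # clears the threshold delimit the dense core of the region
      cs <- seq.int(rs, re, by = step)
      ce <- pmin(cs + step - 1L, re)
      ccp <- windowed_counts(runs$plus, cs, ce, counting_mode)
      ccm <- windowed_counts(runs$minus, cs, ce, counting_mode)
      cw <- ce - cs + 1L
      qual <- (ccp * 1000 / cw >= density_threshold) |
        (ccm * 1000 / cw >= density_threshold)
      if (any(qual)) {
        rs2 <- cs[which(qual)[1L]]
        re2 <- ce[max(which(qual))]
      } else {
        rs2 <- rs
        re2 <- re
      }
      ov <- IRanges::findOverlaps(IRanges::IRanges(rs2, re2), rr)
      if (length(ov) == 0L) next
      hits <- S4Vectors::subjectHits(ov)
      s <- max(rs, min(allruns$start[hits]))
      e <- min(re, max(allruns$end[hits]))
      if (e - s + 1L < min_length) next
      sub <- substring(seq, s, e)
      cp <- count_ggg_repeats(sub, "+", counting_mode)
      cm <- count_ggg_repeats(sub, "-", counting_mode)
      in_call <- prof$start <= re & prof$end >= rs
      peak <- max(pmax(prof$density_plus, prof$density_minus)[in_call])
      qp <- any(hit_p & in_call)
      qm <- any(hit_m & in_call)
      qual <- if (qp && qm) "both" else if (qm) "-" else "+"
      g <- gi(chrom, s, e)
      S4Vectors::mcols(g) <- S4Vectors::DataFrame(
        lg4_id = NA_character_, ggg_count_plus = cp, ggg_count_minus = cm,
        peak_density = peak, qualifying_strand = qual)
      calls[[length(calls) + 1L]] <- g
    }
  }
  if (length(calls) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      lg4_id = character(), ggg_count_plus = integer(),
      ggg_count_minus = integer(), peak_density = numeric(),
      qualifying_strand = character())
    return(out)
  }
  out <- do.call(.c_gr, calls)
  S4Vectors::mcols(out)$lg4_id <- sprintf("LG4_%03d", seq_along(out))
  names(out) <- S4Vectors::mcols(out)$lg4_id
  out
}

#' Composite-G4 availability ratio
#'
#' Ratio of the G triplets an LG4 can contribute on both strands to the mean
#' both-strand triplet count of its candidate target promoters: how many
#' fold more quadruplex-forming sequence the enhancer offers than an average
#' partner promoter.
#'
#' @param lg4 A single LG4 call from [call_lg4()] (metadata columns
#'   `ggg_count_plus`/`ggg_count_minus`), or a list/vector with those two
#'   counts.
#' @param promoters data.frame of promoter records with a
#'   `triplet_count_total` column (see [count_window_triplets()]).
#' @return Numeric ratio; `NA` with attribute `flag = "zero_promoter_mean"`
#'   when the promoter mean is zero.
#' @export
composite_availability_ratio <- function(lg4, promoters) {
  if (is(lg4, "GRanges")) {
    stopifnot(length(lg4) == 1L)
    lg4_total <- S4Vectors::mcols(lg4)$ggg_count_plus +
      S4Vectors::mcols(lg4)$ggg_count_minus
  } else {
    lg4_total <- lg4[["ggg_count_plus"]] + lg4[["ggg_count_minus"]]
  }
  stopifnot(nrow(promoters) >= 1L)
  m <- mean(promoters$triplet_count_total)
  if (m == 0) {
    out <- NA_real_
    attr(out, "flag") <- "zero_promoter_mean"
    return(out)
  }
  lg4_total / m
}
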