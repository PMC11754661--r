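# Matched-control generation and enrichment statistics: promoter G-triplet
# counting, enhancer-overlap enrichment, chi-square triplet enrichment,
# neighborhood fusion test, and the shared t-test wrapper.

new_enrichment_result <- function(statistic_name, statistic, df, p_value,
                                  effect_summary = NULL, flag = NULL) {
  structure(list(statistic_name = statistic_name,
                 statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value),
                 effect_summary = effect_summary, flag = flag),
            class = "lg4_enrichment")
}

#' @export
print.lg4_enrichment <- function(x, ...) {
  cat("Enrichment test:", x$statistic_name, "\n")
  cat(sprintf("  statistic = %.4g, df = %.4g, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$effect_summary)) {
    es <- x$effect_summary
    cat("  effect:", paste(sprintf("%s = %.4g", names(es), unlist(es)),
                           collapse = ", "), "\n")
  }
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Count G triplets in a promoter's upstream window
#'
#' Resolves the upstream window for a TSS (default 5 kb, strand-resolved)
#' and counts GGG repeats on both strands of the window sequence.
#'
#' @param gene Gene identifier.
#' @param chrom,tss,strand TSS definition.
#' @param genome Named `DNAStringSet`.
#' @param window_bp Upstream window size in bp (default 5000).
#' @param counting_mode See [count_ggg_repeats()].
#' @param strand_resolved See [resolve_upstream_window()].
#' @return One-row data.frame (a promoter record) with the window
#'   coordinates, per-strand triplet counts, `triplet_count_total`, and a
#'   `truncated` flag.
#' @export
count_window_triplets <- function(gene, chrom, tss, strand, genome,
                                  window_bp = 5000L,
                                  counting_mode = "tiling",
                                  strand_resolved = TRUE) {
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  win <- withCallingHandlers(
    resolve_upstream_window(chrom, tss, strand, window_bp, 0L,
                            chrom_length = clen,
                            strand_resolved = strand_resolved),
    warning = function(w) invokeRestart("muffleWarning"))
  # counts are strand-of-genome counts over the window interval
  seq_plus <- get_interval_seq(genome, gi(chrom,
                                          GenomicRanges::start(win),
                                          GenomicRanges::end(win)))
  tp <- count_ggg_repeats(seq_plus, "+", counting_mode)
  tm <- count_ggg_repeats(seq_plus, "-", counting_mode)
  data.frame(gene = gene, chrom = chrom, tss = tss, strand = strand,
             win_start = GenomicRanges::start(win),
             win_end = GenomicRanges::end(win),
             truncated = S4Vectors::mcols(win)$truncated,
             triplet_count_plus = tp, triplet_count_minus = tm,
             triplet_count_total = tp + tm,
             stringsAsFactors = FALSE)
}

#' Promoter records for a TSS table
#'
#' Vectorised wrapper around [count_window_triplets()].
#'
#' @param tss_table data.frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @inheritParams count_window_triplets
#' @return data.frame of promoter records, one row per gene.
#' @export
promoter_records <- function(tss_table, genome, window_bp = 5000L,
                             counting_mode = "tiling",
                             strand_resolved = TRUE) {
  rows <- lapply(seq_len(nrow(tss_table)), function(i) {
    count_window_triplets(tss_table$gene[i], tss_table$chrom[i],
                          tss_table$tss[i], tss_table$strand[i],
                          genome, window_bp, counting_mode, strand_resolved)
  })
  do.call(rbind, rows)
}

#' Promoter windows as GRanges
#'
#' @param promoters data.frame from [promoter_records()].
#' @return `GRanges` named by gene.
#' @export
promoter_granges <- function(promoters) {
  stats::setNames(gi(promoters$chrom, promoters$win_start, promoters$win_end),
                  promoters$gene)
}

#' Generate length- and composition-matched control loci
#'
#' For each source locus, draws a random genomic interval of exactly the
#' same length whose GC fraction is within `gc_tolerance` of the source,
#' not overlapping any source locus or any previously placed control of the
#' same set.  Sampling is seeded and reproducible.
#'
#' @param loci `GRanges` of source loci.
#' @param genome Named `DNAStringSet`.
#' @param n_sets Number of independent control sets.
#' @param gc_tolerance Allowed absolute GC-fraction difference (default
#'   0.02).
#' @param seed Integer seed.
#' @param max_tries Draws attempted per locus before giving up.
#' @return List of `n_sets` `GRanges`.
#' @export
matched_control_loci <- function(loci, genome, n_sets = 5L,
                                 gc_tolerance = 0.02, seed = 1L,
                                 max_tries = 1000L) {
  set.seed(seed)
  src_gc <- .gc_fraction(get_interval_seq(genome, unstrand_gr(loci)))
  lens <- BiocGenerics::width(loci)
  chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    placed <- GenomicRanges::GRanges()
    for (i in seq_along(loci)) {
      L <- lens[i]
      ok_chroms <- names(chrom_lens)[chrom_lens >= L]
      if (length(ok_chroms) == 0L) {
        stop("no chromosome long enough for control of locus ", i)
      }
      found <- FALSE
      for (try in seq_len(max_tries)) {
        chrom <- if (length(ok_chroms) == 1L) ok_chroms else
          sample(ok_chroms, 1L, prob = chrom_lens[ok_chroms])
        start <- sample.int(chrom_lens[[chrom]] - L + 1L, 1L)
        cand <- gi(chrom, start, start + L - 1L)
        if (length(suppressWarnings(
          GenomicRanges::findOverlaps(cand, unstrand_gr(loci)))) > 0L) next
        if (length(placed) > 0L &&
            length(suppressWarnings(
              GenomicRanges::findOverlaps(cand, placed))) > 0L) next
        gc <- .gc_fraction(get_interval_seq(genome, cand))
        if (abs(gc - src_gc[i]) > gc_tolerance) next
        placed <- .c_gr(placed, cand)
        found <- TRUE
        break
      }
      if (!found) {
        stop("could not place a matched control for locus ", i,
             " (", as.character(GenomicRanges::seqnames(loci))[i], ":",
             GenomicRanges::start(loci)[i], "-",
             GenomicRanges::end(loci)[i], ") after ", max_tries, " tries")
      }
    }
    out[[s]] <- placed
  }
  out
}

.gc_fraction <- function(seqs) {
  s <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::letterFrequency(s, letters = c("G", "C"))
  rowSums(f) / Biostrings::width(s)
}

unstrand_gr <- function(x) {
  GenomicRanges::strand(x) <- "*"
  x
}

#' Count annotated enhancers overlapping a locus
#'
#' Number of annotation intervals overlapping the locus (any overlap on the
#' same chromosome; annotations on other chromosomes are ignored).
#'
#' @param lg4 A length-1 `GRanges`.
#' @param annotations `GRanges` of annotation intervals, or a table from
#'   [read_enhancer_table()].
#' @return Integer count.
#' @export
count_annotation_overlaps <- function(lg4, annotations) {
  stopifnot(length(lg4) == 1L)
  if (is.data.frame(annotations)) annotations <- enhancer_granges(annotations)
  GenomicRanges::countOverlaps(unstrand_gr(lg4), unstrand_gr(annotations),
                               ignore.strand = TRUE)
}

#' Enhancer-overlap enrichment of loci versus matched controls
#'
#' Compares how often real loci overlap at least one annotation with how
#' often matched control loci do.  The default `"indicators"` mode compares
#' per-locus 0/1 overlap indicators of the real loci against the pooled
#' control loci with an unpaired one-tailed pooled-variance t-test
#' (direction: real > control).  `"sets"` mode instead treats the real
#' overlap count as a single observation against the per-set control counts
#' (Crawford-Howell single-case t).
#'
#' @param loci `GRanges` of real loci.
#' @param control_sets List of `GRanges` control sets (>= 2 for
#'   `"indicators"`).
#' @param annotations `GRanges` or enhancer table.
#' @param mode `"indicators"` (default) or `"sets"`.
#' @return An `lg4_enrichment` result (one-tailed t).
#' @export
overlap_enrichment_test <- function(loci, control_sets, annotations,
                                    mode = c("indicators", "sets")) {
  mode <- match.arg(mode)
  if (is.data.frame(annotations)) annotations <- enhancer_granges(annotations)
  ind <- function(x) as.integer(GenomicRanges::countOverlaps(
    unstrand_gr(x), unstrand_gr(annotations), ignore.strand = TRUE) > 0L)
  real <- ind(loci)
  if (mode == "sets") {
    counts <- vapply(control_sets, function(s) sum(ind(s)), numeric(1))
    n <- length(counts)
    if (stats::sd(counts) == 0) {
      return(new_enrichment_result(
        "t_one_tailed", NA_real_, n - 1,
        if (sum(real) > counts[1]) 0 else if (sum(real) == counts[1]) 0.5 else 1,
        list(real_count = sum(real), control_mean = mean(counts)),
        flag = "degenerate_zero_variance"))
    }
    tstat <- (sum(real) - mean(counts)) /
      (stats::sd(counts) * sqrt(1 + 1 / n))
    p <- stats::pt(tstat, df = n - 1, lower.tail = FALSE)
    return(new_enrichment_result("t_one_tailed", tstat, n - 1, p,
                                 list(real_count = sum(real),
                                      control_mean = mean(counts))))
  }
  if (length(control_sets) < 2L) stop("need at least 2 control sets")
  ctrl <- unlist(lapply(control_sets, ind))
  if (stats::sd(real) == 0 && stats::sd(ctrl) == 0) {
    p <- if (mean(real) > mean(ctrl)) 0 else if (mean(real) == mean(ctrl)) 0.5 else 1
    return(new_enrichment_result(
      "t_one_tailed", if (mean(real) == mean(ctrl)) 0 else NA_real_,
      length(real) + length(ctrl) - 2, p,
      list(real_rate = mean(real), control_rate = mean(ctrl)),
      flag = "degenerate_zero_variance"))
  }
  tt <- stats::t.test(real, ctrl, alternative = "greater", var.equal = TRUE)
  new_enrichment_result("t_one_tailed", tt$statistic, tt$parameter,
                        tt$p.value,
                        list(real_rate = mean(real), control_rate = mean(ctrl)))
}

#' Pearson chi-square on a 2x2 table
#'
#' No continuity correction, df = 1.  Flags the result when any expected
#' cell is below 5.
#'
#' @param tab A 2x2 numeric matrix of counts.
#' @return An `lg4_enrichment` result.
#' @export
chi_square_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  flag <- if (any(ct$expected < 5)) "low_expected_count" else NULL
  new_enrichment_result("chi_square", ct$statistic, ct$parameter, ct$p.value,
                        flag = flag)
}

#' Chi-square test of G-triplet enrichment between promoter groups
#'
#' Builds a 2x2 occupancy table [triplet bp, non-triplet bp] x [group A,
#' group B], where triplet bp = 3 x total triplet count and non-triplet bp
#' = total window bp - triplet bp, and applies Pearson chi-square without
#' continuity correction (df = 1).  Occupancy (rather than raw counts) lets
#' groups with unequal total window lengths be compared on the same scale.
#'
#' @param group_a,group_b data.frames of promoter records (from
#'   [promoter_records()]): need `triplet_count_total`, `win_start`,
#'   `win_end`.
#' @return An `lg4_enrichment` result with per-kb densities in
#'   `effect_summary`.
#' @export
chi_square_triplet_enrichment <- function(group_a, group_b) {
  stopifnot(nrow(group_a) >= 1L, nrow(group_b) >= 1L)
  occ <- function(g) {
    trip <- 3 * sum(g$triplet_count_total)
    total <- sum(g$win_end - g$win_start + 1)
    c(trip = trip, non = total - trip, total = total)
  }
  a <- occ(group_a)
  b <- occ(group_b)
  tab <- rbind(a[c("trip", "non")], b[c("trip", "non")])
  res <- chi_square_2x2(tab)
  res$effect_summary <- list(
    density_a = 1000 * a[["trip"]] / 3 / a[["total"]],
    density_b = 1000 * b[["trip"]] / 3 / b[["total"]],
    fold = (a[["trip"]] / a[["total"]]) / (b[["trip"]] / b[["total"]]))
  res
}

#' Neighborhood gene-fusion enrichment test
#'
#' Counts, for each neighborhood (a set of gene ids), the fusion pairs with
#' both partners inside that neighborhood, and compares real versus control
#' per-neighborhood counts with an unpaired two-tailed Welch t-test.
#'
#' @param neighborhood_genes List of character vectors (gene-id sets) for
#'   the real neighborhoods.
#' @param fusion_pairs Two-column matrix/data.frame of fused gene pairs.
#' @param control_neighborhood_genes List of gene-id sets for control
#'   neighborhoods.
#' @return An `lg4_enrichment` result; the per-neighborhood counts are in
#'   `effect_summary`.
#' @export
fusion_neighborhood_test <- function(neighborhood_genes, fusion_pairs,
                                     control_neighborhood_genes) {
  fp <- as.data.frame(fusion_pairs, stringsAsFactors = FALSE)
  count_intra <- function(genes) {
    if (nrow(fp) == 0L) return(0L)
    sum(fp[[1]] %in% genes & fp[[2]] %in% genes)
  }
  real <- vapply(neighborhood_genes, count_intra, integer(1))
  ctrl <- vapply(control_neighborhood_genes, count_intra, integer(1))
  eff <- list(real_mean = mean(real), control_mean = mean(ctrl))
  if (nrow(fp) == 0L || (stats::sd(real) == 0 && stats::sd(ctrl) == 0)) {
    return(new_enrichment_result("t_two_tailed_welch", 0,
                                 length(real) + length(ctrl) - 2, 1, eff,
                                 flag = "degenerate"))
  }
  tt <- stats::t.test(real, ctrl)
  new_enrichment_result("t_two_tailed_welch", tt$statistic, tt$parameter,
                        tt$p.value, eff)
}

#' Welch t-test wrapper
#'
#' Unpaired t-test with Welch-Satterthwaite degrees of freedom.  One-tailed
#' tests use direction `x > y`.
#'
#' @param x,y Numeric vectors (length >= 2 each).
#' @param tails 1 or 2.
#' @return An `lg4_enrichment` result.
#' @export
welch_t_test <- function(x, y, tails = 2L) {
  stopifnot(length(x) >= 2L, length(y) >= 2L, tails %in% c(1L, 2L))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(new_enrichment_result(
      if (tails == 2L) "t_two_tailed_welch" else "t_one_tailed",
      0, length(x) + length(y) - 2,
      if (mean(x) == mean(y)) 1 else 0,
      list(mean_diff = mean(x) - mean(y)), flag = "degenerate_zero_variance"))
  }
  alt <- if (tails == 1L) "greater" else "two.sided"
  tt <- stats::t.test(x, y, alternative = alt)
  new_enrichment_result(
    if (tails == 2L) "t_two_tailed_welch" else "t_one_tailed",
    tt$statistic, tt$parameter, tt$p.value,
    list(mean_diff = mean(x) - mean(y)))
}
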