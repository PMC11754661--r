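test_that("promoter window triplet counts recover the planted counts", {
  sim <- small_sim(seed = 13L)
  proms <- promoter_records(sim$promoter_truth[
    c("gene", "chrom", "tss", "strand")], sim$genome)
  # plants are isolated plus-strand GGGs; the scrubbed window adds nothing
  expect_equal(proms$triplet_count_plus,
               sim$promoter_truth$planted_triplets)
  expect_equal(proms$triplet_count_minus, c(0L, 0L))
  expect_equal(proms$triplet_count_total,
               proms$triplet_count_plus + proms$triplet_count_minus)
  expect_true(any(proms$triplet_count_plus == 237L))

  # hand-checkable window: GGG + CCC on an otherwise inert background
  g <- Biostrings::DNAStringSet(c(c1 = paste0(
    strrep("A", 1000), "GGGAAACCC", strrep("A", 4991), "T")))
  rec <- count_window_triplets("g1", "c1", 6001L, "+", g, window_bp = 5000L)
  expect_equal(rec$triplet_count_plus, 1L)
  expect_equal(rec$triplet_count_minus, 1L)
  expect_equal(rec$triplet_count_total, 2L)
  rec0 <- count_window_triplets("g0", "c1", 1001L, "+", g, window_bp = 1000L)
  expect_equal(rec0$triplet_count_total, 0L)
  # truncated windows are flagged but still counted
  expect_warning(
    rt <- count_window_triplets("gt", "c1", 500L, "+", g, window_bp = 5000L),
    NA)
  expect_true(rt$truncated)
})

test_that("matched controls respect length, GC tolerance, and non-overlap", {
  # heterogeneous genome: two chromosomes at different background GC
  g <- Biostrings::DNAStringSet(c(cA = random_dna(60000, seed = 171, gc = 0.38),
                                  cB = random_dna(60000, seed = 172, gc = 0.52)))
  loci <- gi(c("cA", "cB"), c(10001L, 30001L), c(11000L, 31500L))
  src_len <- interval_length(loci)
  gc_of <- function(x) {
    s <- Biostrings::DNAStringSet(get_interval_seq(g, x))
    rowSums(Biostrings::letterFrequency(s, c("G", "C"))) / Biostrings::width(s)
  }
  src_gc <- gc_of(loci)
  sets <- matched_control_loci(loci, g, n_sets = 100L,
                               gc_tolerance = 0.02, seed = 17L)
  expect_length(sets, 100L)
  for (s in sets) {
    expect_equal(interval_length(s), src_len)
    expect_true(all(abs(gc_of(s) - src_gc) <= 0.02))
    expect_length(suppressWarnings(GenomicRanges::findOverlaps(s, loci)), 0L)
    expect_length(GenomicRanges::findOverlaps(s, drop.self = TRUE), 0L)
  }
  # determinism
  again <- matched_control_loci(loci, g, n_sets = 3L, seed = 17L)
  expect_identical(as.character(GenomicRanges::granges(again[[2]])),
                   as.character(GenomicRanges::granges(
                     matched_control_loci(loci, g, n_sets = 3L,
                                          seed = 17L)[[2]])))
  # impossible placement errors out naming the locus
  tiny <- Biostrings::DNAStringSet(c(c1 = strrep("A", 2100)))
  expect_error(matched_control_loci(gi("c1", 1, 2000), tiny, n_sets = 1L,
                                    max_tries = 10L, seed = 1L),
               "control")
})

test_that("annotation overlap counts reproduce the curated-table values", {
  tab <- read_enhancer_table(table1_path())
  lg4 <- utils::read.delim(lg4_loci_path())
  chr5 <- gi("Chr5", 551935, 556936)
  chr12 <- gi("Chr12", 132685134, 132690031)
  expect_equal(count_annotation_overlaps(chr5, tab), 13L)
  expect_equal(count_annotation_overlaps(chr12, tab), 9L)
  expect_equal(count_annotation_overlaps(chr5, GenomicRanges::GRanges()), 0L)
  # equals the sum of pairwise overlaps, order-independent
  ann <- enhancer_granges(tab)
  expect_equal(count_annotation_overlaps(chr5, ann),
               sum(vapply(seq_along(ann), function(i)
                 intervals_overlap(chr5, ann[i]), logical(1))))
  expect_equal(count_annotation_overlaps(chr5, rev(ann)), 13L)
})

test_that("overlap enrichment t-test matches hand formulas and handles degeneracy", {
  # textbook pooled-variance case on indicator-like vectors
  a <- c(1, 1, 1, 0, 1)
  b <- c(0, 0, 1, 0, 0)
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(pooled_var * (1 / 5 + 1 / 5))
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "greater")
  expect_equal(unname(tt$statistic), t_hand, tolerance = 1e-12)

  # constructed loci: real all overlap, controls (almost) never do
  ann <- gi("c1", seq(1000, 20000, by = 1000), seq(1000, 20000, by = 1000) + 99)
  real <- gi("c1", seq(1000, 20000, by = 1000), seq(1000, 20000, by = 1000) + 49)
  ctrl1 <- gi("c1", seq(30050, 39550, by = 500), seq(30050, 39550, by = 500) + 9)
  ctrl2 <- c(gi("c1", 1010, 1019),  # one overlap breaks zero variance
             gi("c1", seq(41000, 50000, by = 500), seq(41000, 50000, by = 500) + 9))
  res <- overlap_enrichment_test(real, list(ctrl1, ctrl2), ann)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$statistic_name, "t_one_tailed")

  # identical indicator vectors give t = 0, p = 0.5
  res0 <- overlap_enrichment_test(real, list(real, real), ann)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 0.5)

  # sets mode: single-case t against per-set counts
  res_sets <- overlap_enrichment_test(real, list(ctrl1, ctrl2, ctrl1),
                                      ann, mode = "sets")
  expect_true(res_sets$p_value < 0.05 || !is.null(res_sets$flag))
})

test_that("chi-square kernel matches the Pearson formula oracle", {
  tab <- matrix(c(10, 90, 20, 80), nrow = 2, byrow = TRUE)
  res <- chi_square_2x2(tab)
  # independent Pearson formula
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_hand <- sum((tab - E)^2 / E)
  expect_equal(res$statistic, chi_hand, tolerance = 1e-12)
  expect_equal(round(res$statistic, 4), 3.9216)
  expect_equal(res$df, 1)
  # symmetry in group order
  expect_equal(chi_square_2x2(tab[2:1, ])$statistic, res$statistic)
  # identical row proportions: exactly 0, p = 1
  res0 <- chi_square_2x2(matrix(c(10, 90, 30, 270), 2, byrow = TRUE))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  # low expected counts are flagged
  expect_equal(chi_square_2x2(matrix(c(1, 9, 2, 8), 2))$flag,
               "low_expected_count")
})

test_that("promoter-group chi-square detects a planted density difference", {
  mk <- function(counts, width = 5000L) {
    data.frame(triplet_count_total = counts,
               win_start = 1L, win_end = width)
  }
  # identical groups: zero statistic
  res0 <- chi_square_triplet_enrichment(mk(rep(10L, 5)), mk(rep(10L, 5)))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)

  set.seed(19)
  g_a <- mk(rpois(50, 90))   # ~3x the density of group B
  g_b <- mk(rpois(50, 30))
  res <- chi_square_triplet_enrichment(g_a, g_b)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$effect_summary$fold, 2)
})

test_that("chi-square type-I error is calibrated under its own null model", {
  # per-bp independent occupancy (binomial cells), 1000 replicates
  set.seed(101)
  n_bp <- 50 * 5000
  q <- 3 * 142 / 5000
  rej <- 0L
  for (r in 1:1000) {
    oa <- rbinom(1, n_bp, q)
    ob <- rbinom(1, n_bp, q)
    tab <- matrix(c(oa, n_bp - oa, ob, n_bp - ob), 2, byrow = TRUE)
    if (chi_square_2x2(tab)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})

test_that("fusion neighborhood counts and test behave as specified", {
  nb <- list(c("A", "B", "C"), c("D", "E"))
  fp <- data.frame(g1 = c("A", "A"), g2 = c("B", "X"))
  # (A,B) is intra for neighborhood 1; (A,X) is not intra anywhere
  res <- fusion_neighborhood_test(nb, fp, list(c("P", "Q"), c("R", "S")))
  expect_equal(res$effect_summary$real_mean, 0.5)
  expect_equal(res$effect_summary$control_mean, 0)

  # empty fusion list: degenerate flagged result
  res0 <- fusion_neighborhood_test(nb, fp[0, ], nb)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$flag, "degenerate")

  # planted Poisson enrichment is detected
  set.seed(23)
  mk_nb <- function(i) paste0("n", i, "_", letters[1:6])
  real_nb <- lapply(1:20, mk_nb)
  ctrl_nb <- lapply(21:40, mk_nb)
  pairs <- list()
  for (i in 1:20) {
    for (k in seq_len(rpois(1, 3))) {
      pairs[[length(pairs) + 1L]] <- sample(real_nb[[i]], 2)
    }
    for (k in seq_len(rpois(1, 0.3))) {
      pairs[[length(pairs) + 1L]] <- sample(ctrl_nb[[i]], 2)
    }
  }
  fp2 <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  res2 <- fusion_neighborhood_test(real_nb, fp2, ctrl_nb)
  expect_lt(res2$p_value, 0.01)
})

test_that("Welch t matches the hand formula and a permutation oracle", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  t_hand <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  df_hand <- (var(x) / 4 + var(y) / 4)^2 /
    ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  res <- welch_t_test(x, y)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$statistic_name, "t_two_tailed_welch")

  # x = y gives t = 0
  expect_equal(welch_t_test(c(1, 5, 9), c(1, 5, 9))$statistic, 0)

  # two-sided p within Monte-Carlo error of a permutation null
  set.seed(29)
  x2 <- rnorm(6) + 1.2
  y2 <- rnorm(6)
  obs <- abs(welch_t_test(x2, y2)$statistic)
  pool <- c(x2, y2)
  perm <- replicate(1e4, {
    idx <- sample(12, 6)
    abs(welch_t_test(pool[idx], pool[-idx])$statistic)
  })
  p_perm <- mean(perm >= obs)
  p_welch <- welch_t_test(x2, y2)$p_value
  se <- sqrt(p_perm * (1 - p_perm) / 1e4)
  expect_lt(abs(p_welch - p_perm), max(4 * se, 0.02))
})
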