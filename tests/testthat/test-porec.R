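# Alignment and contact-calling tests run on one shared simulated genome
# with a planted duplication for ambiguity checks.

dup_sim <- make_genome(genome_spec(
  chrom_lengths = c(chrA = 120000L, chrB = 80000L),
  lg4s = data.frame(chrom = "chrA", start = 60001L, unit = "GGGT",
                    n_units = 400L, jitter = TRUE),
  promoters = data.frame(gene = "promX", chrom = "chrA", tss = 30000L,
                         strand = "+", planted_triplets = 100L),
  duplications = data.frame(chrom = "chrB", start = 10001L, end = 10600L,
                            n_copies = 1L),
  seed = 59L))

test_that("multi-mapping masking follows the strict >100 bp duplication rule", {
  g <- dup_sim$genome
  # promoter-like sequence containing the 600 bp duplicated block
  probe <- get_interval_seq(g, gi("chrB", 9801, 10800))
  masked <- mask_multimapping(c(p1 = probe), g)
  chars <- strsplit(masked[["p1"]], "")[[1]]
  # the duplicated 600 bp core is fully masked, flanks intact
  expect_true(all(chars[201:800] == "N"))
  expect_true(all(chars[1:195] != "N"))
  expect_true(all(chars[806:1000] != "N"))

  # unique sequence comes back unchanged
  uniq <- get_interval_seq(g, gi("chrA", 20001, 21000))
  expect_identical(mask_multimapping(c(u = uniq), g)[["u"]], uniq)

  # a duplication of exactly min_len bp is NOT masked
  g2 <- Biostrings::DNAStringSet(c(
    c1 = paste0(random_dna(500, 61), substring(probe, 201, 300),
                random_dna(500, 62), substring(probe, 201, 300),
                random_dna(500, 63))))
  seq100 <- get_interval_seq(g2, gi("c1", 501, 600))
  probe2 <- get_interval_seq(g2, gi("c1", 401, 700))
  expect_identical(mask_multimapping(c(q = probe2), g2, min_len = 100L)[["q"]],
                   probe2)
})

test_that("alignment scores are exact for verbatim and one-substitution fragments", {
  g <- dup_sim$genome
  frag <- get_interval_seq(g, gi("chrA", 20001, 20500))
  a <- align_read_fragments(c(r1 = frag), g)
  expect_equal(nrow(a), 1L)
  expect_equal(a$score, 1000L)
  expect_equal(a$tstart, 20001)
  expect_equal(a$tend, 20500)
  expect_equal(a$qstart, 1L)
  expect_equal(a$qend, 500L)
  expect_equal(a$n_equal_best, 1L)
  expect_equal(a$strand, "+")

  frag2 <- frag
  orig <- substring(frag2, 250, 250)
  substring(frag2, 250, 250) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  a2 <- align_read_fragments(c(r2 = frag2), g)
  expect_equal(a2$score, 995L)
  expect_equal(a2$tstart, 20001)
  expect_equal(a2$tend, 20500)

  # reverse-complement fragment maps to the same interval on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  a3 <- align_read_fragments(c(r3 = rc), g)
  expect_equal(a3$score, 1000L)
  expect_equal(a3$strand, "-")
  expect_equal(a3$tstart, 20001)

  # reads shorter than the word size produce no alignments
  expect_equal(nrow(align_read_fragments(c(tiny = "ACGTACGT"), g)), 0L)
})

test_that("duplicated loci give tied placements resolved by lowest coordinate", {
  g <- dup_sim$genome
  dup <- dup_sim$duplication_truth
  frag <- get_interval_seq(g, gi("chrB", 10101, 10500))  # inside the source
  a <- align_read_fragments(c(r = frag), g)
  expect_equal(nrow(a), 1L)
  expect_equal(a$n_equal_best, 2L)
  expect_true(a$is_ambiguous)
  # tie resolved to the smallest (chrom, start)
  copy_chrom <- as.character(GenomicRanges::seqnames(dup))
  copy_start <- GenomicRanges::start(dup) + 100L
  placements <- data.frame(chrom = c("chrB", copy_chrom),
                           tstart = c(10101, copy_start))
  expected <- placements[order(placements$chrom, placements$tstart), ][1, ]
  expect_equal(a$chrom, expected$chrom)
  expect_equal(a$tstart, expected$tstart)
})

test_that("resolve_best picks argmax score then lexicographic coordinate", {
  cands <- data.frame(chrom = c("Chr2", "Chr1"), tstart = c(500, 900),
                      score = c(990, 1000))
  expect_equal(resolve_best(cands)$tstart, 900)
  tied <- data.frame(chrom = c("Chr2", "Chr1"), tstart = c(500, 900),
                     score = c(1000, 1000))
  r <- resolve_best(tied)
  expect_equal(r$chrom, "Chr1")
  expect_true(r$is_ambiguous)
  expect_equal(r$n_equal_best, 2L)
  # random candidate sets match a brute-force oracle
  set.seed(31)
  for (i in 1:20) {
    df <- data.frame(chrom = sample(c("c1", "c2", "c3"), 8, TRUE),
                     tstart = sample(1e5, 8),
                     score = sample(900:1000, 8, TRUE))
    got <- resolve_best(df)
    best <- df[df$score == max(df$score), ]
    oracle <- best[order(best$chrom, best$tstart), ][1, ]
    expect_equal(got$chrom, oracle$chrom)
    expect_equal(got$tstart, oracle$tstart)
  }
})

test_that("contact calling recovers the simulation truth exactly at zero error", {
  pairs <- data.frame(lg4_id = "planted_LG4_01", gene = "promX",
                      probability = 0.5)
  pc <- simulate_porec(dup_sim, contact_model(pairs, n_reads = 60L,
                                              seed = 31L))
  aln <- align_read_fragments(pc$reads, dup_sim$genome)
  contacts <- detect_cooccurrence(aln, dup_sim$lg4_truth,
                                  dup_sim$promoter_truth)
  truth <- pc$contact_truth$read_id[pc$contact_truth$is_contact]
  expect_setequal(unique(contacts$read_id), truth)
  # no contact record pairs overlapping read spans
  if (nrow(contacts) > 0L) {
    for (i in seq_len(nrow(contacts))) {
      row <- contacts[i, ]
      f1 <- aln[aln$read_id == row$read_id & aln$tstart == row$lg4_tstart, ][1, ]
      f2 <- aln[aln$read_id == row$read_id & aln$tstart == row$prom_tstart, ][1, ]
      expect_true(f1$qend < f2$qstart || f2$qend < f1$qstart)
    }
  }
  # a read with LG4 fragments but no promoter fragment yields no contact
  only_lg4 <- aln[!aln$read_id %in% truth, ]
  ct0 <- detect_cooccurrence(only_lg4, dup_sim$lg4_truth,
                             dup_sim$promoter_truth)
  expect_equal(nrow(ct0), 0L)
})

test_that("placement survives 5% substitution error for 300+ bp fragments", {
  g <- dup_sim$genome
  set.seed(67)
  n <- 60
  starts <- sample(5000:45000, n)
  ok <- 0L
  for (i in seq_len(n)) {
    frag <- get_interval_seq(g, gi("chrA", starts[i], starts[i] + 349L))
    chars <- strsplit(frag, "")[[1]]
    hit <- which(runif(350) < 0.05)
    for (h in hit) chars[h] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[h]), 1)
    a <- align_read_fragments(stats::setNames(paste(chars, collapse = ""),
                                              "f"), g)
    if (nrow(a) == 1L && a$chrom == "chrA" &&
        abs(a$tstart - starts[i]) <= 5 && !a$is_ambiguous) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.9)
})

test_that("contact summaries tally distinct supporting reads", {
  expect_equal(nrow(contact_summary(detect_cooccurrence(
    data.frame(read_id = character(), qstart = integer(), qend = integer(),
               chrom = character(), tstart = numeric(), tend = numeric(),
               strand = character(), score = integer(),
               n_equal_best = integer(), is_ambiguous = logical()),
    dup_sim$lg4_truth, dup_sim$promoter_truth))), 0L)
  fake <- data.frame(read_id = c("r1", "r1", "r2"),
                     lg4_id = "L1", promoter_gene = "geneA",
                     lg4_chrom = "c", lg4_tstart = 1, lg4_tend = 2,
                     lg4_score = 10, prom_chrom = "c", prom_tstart = 5,
                     prom_tend = 6, prom_score = 10)
  cs <- contact_summary(fake)
  expect_equal(cs$n_reads, 2L)
  expect_equal(cs$lg4_id, "L1")
})
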