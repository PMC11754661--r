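# Shared fixtures, built in code at load time.

# brute-force character-scan oracle for maximal G/C runs
oracle_g_runs <- function(seq, min_run = 3L, strand = "+") {
  base <- if (strand == "-") "C" else "G"
  chars <- strsplit(toupper(seq), "")[[1]]
  res <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (identical(chars[i], base)) {
      j <- i
      while (j < n && identical(chars[j + 1L], base)) j <- j + 1L
      if (j - i + 1L >= min_run) {
        res[[length(res) + 1L]] <- c(start = i, end = j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(), end = integer(), width = integer()))
  }
  out <- as.data.frame(do.call(rbind, res))
  out$width <- out$end - out$start + 1L
  out
}

# greedy tiling oracle for GGG repeat counts
oracle_ggg_count <- function(seq, strand = "+") {
  runs <- oracle_g_runs(seq, 3L, strand)
  if (nrow(runs) == 0L) return(0L)
  sum(runs$width %/% 3L)
}

# leftmost-greedy motif oracle built on the char-scan runs
oracle_min_g4 <- function(seq, loop_min = 1L, loop_max = 7L) {
  runs <- oracle_g_runs(seq, 3L, "+")
  out <- list()
  i <- 1L
  while (i <= nrow(runs) - 3L) {
    gaps <- runs$start[(i + 1L):(i + 3L)] - runs$end[i:(i + 2L)] - 1L
    if (all(gaps >= loop_min & gaps <= loop_max)) {
      out[[length(out) + 1L]] <- c(start = runs$start[i], end = runs$end[i + 3L])
      i <- i + 4L
    } else i <- i + 1L
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

random_dna <- function(n, seed, gc = 0.4) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

table1_path <- function() {
  system.file("extdata", "table1_enhancers.tsv", package = "lg4scape")
}

lg4_loci_path <- function() {
  system.file("extdata", "lg4_loci.tsv", package = "lg4scape")
}

# small simulated genome reused by alignment/contact tests
small_sim <- function(seed = 7L) {
  make_genome(genome_spec(
    chrom_lengths = c(chrA = 200000L, chrB = 120000L),
    lg4s = data.frame(chrom = "chrA", start = 100001L, unit = "GGGT",
                      n_units = 500L, jitter = TRUE),
    promoters = data.frame(gene = c("prom1", "prom2"),
                           chrom = c("chrA", "chrB"),
                           tss = c(60000L, 60000L),
                           strand = c("+", "-"),
                           planted_triplets = c(237L, 150L)),
    seed = seed))
}
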