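# Seeded synthetic data: genomes with planted LG4 blocks, G-triplet-enriched
# promoter windows and verbatim duplications; DpnII-style digestion; and
# proximity-ligated concatemer (Pore-C-like) reads with per-fragment strand
# flips and substitution errors.  Everything is deterministic given the
# spec/model seed.

#' Specify a synthetic genome
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param background_gc Background GC fraction for i.i.d. bases (default
#'   0.4, which keeps the background GGG-repeat density far below the LG4
#'   threshold: the expected density is ~5 repeats/kb per strand).
#' @param lg4s data.frame with columns `chrom`, `start`, `unit`, `n_units`,
#'   and optionally `jitter` (logical): each locus is `n_units` copies of
#'   `unit` from `start`.  With `jitter = TRUE` the non-G positions of each
#'   copy are randomised (the G content, and hence the planted triplet
#'   count, is unchanged) so the block is aperiodic and uniquely mappable;
#'   with `jitter = FALSE` the block is the exact tandem repeat.
#' @param promoters data.frame with columns `gene`, `chrom`, `tss`,
#'   `strand`, `planted_triplets`: the upstream window is scrubbed of
#'   background G/C runs and receives exactly `planted_triplets` isolated
#'   GGG tracts on the plus strand.
#' @param duplications data.frame with columns `chrom`, `start`, `end`,
#'   `n_copies`: the source interval is copied verbatim to `n_copies`
#'   random non-overlapping locations.
#' @param gc_regions data.frame with columns `chrom`, `start`, `end`, `gc`:
#'   background stretches re-drawn i.i.d. at a different GC fraction, giving
#'   the genome the compositional heterogeneity that length- and
#'   GC-matched control sampling needs (still i.i.d., so no G-run
#'   enrichment beyond what the GC implies).
#' @param seed Integer seed.
#' @param window_bp Promoter window size in bp (default 5000).
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(chrom_lengths, background_gc = 0.4,
                        lg4s = NULL, promoters = NULL, duplications = NULL,
                        gc_regions = NULL, seed = 1L, window_bp = 5000L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1))
  if (!is.null(lg4s) && is.null(lg4s$jitter)) lg4s$jitter <- FALSE
  structure(list(chrom_lengths = chrom_lengths,
                 background_gc = background_gc,
                 lg4s = lg4s, promoters = promoters,
                 duplications = duplications, gc_regions = gc_regions,
                 seed = as.integer(seed), window_bp = as.integer(window_bp)),
            class = "genome_spec")
}

.lg4_footprints <- function(spec) {
  if (is.null(spec$lg4s) || nrow(spec$lg4s) == 0L) return(GenomicRanges::GRanges())
  len <- nchar(spec$lg4s$unit) * spec$lg4s$n_units
  gi(spec$lg4s$chrom, spec$lg4s$start, spec$lg4s$start + len - 1L)
}

.promoter_footprints <- function(spec) {
  p <- spec$promoters
  if (is.null(p) || nrow(p) == 0L) return(GenomicRanges::GRanges())
  wins <- lapply(seq_len(nrow(p)), function(i) {
    unstrand_gr(resolve_upstream_window(
      p$chrom[i], p$tss[i], p$strand[i], spec$window_bp, 0L,
      chrom_length = spec$chrom_lengths[[p$chrom[i]]]))
  })
  do.call(.c_gr, wins)
}

# break every G-run and C-run of length >= 3 in a character vector
.scrub_runs <- function(chars) {
  s <- paste(chars, collapse = "")
  repeat {
    m <- regexpr("GGG|CCC", s)
    if (m == -1L) break
    mid <- as.integer(m) + 1L
    chars[mid] <- if (chars[mid] == "G") "T" else "A"
    substr(s, mid, mid) <- chars[mid]
  }
  chars
}

#' Generate a synthetic genome with planted features
#'
#' Background bases are drawn i.i.d. at `background_gc`; LG4 blocks,
#' promoter triplet plants and duplications are then written over the
#' background (see [genome_spec()]).  Promoter windows are scrubbed of
#' background G/C runs before planting, so the plus-strand triplet count of
#' the window is exactly `planted_triplets` and the minus-strand count is
#' zero.  All randomness is driven by `spec$seed`; identical specs produce
#' byte-identical genomes.
#'
#' @param spec A [genome_spec()].
#' @return List of class `lg4_sim_genome`: `genome` (`DNAStringSet`),
#'   `lg4_truth` (`GRanges` with `lg4_id`, `unit`, `n_units`),
#'   `promoter_truth` (data.frame with window coordinates and planted
#'   counts), `duplication_truth` (`GRanges` of placed copies with
#'   `source_id`), and `spec`.
#' @export
make_genome <- function(spec) {
  stopifnot(is(spec, "genome_spec"))
  set.seed(spec$seed)
  # planted footprints must not overlap one another
  foots <- .c_gr(.lg4_footprints(spec), .promoter_footprints(spec),
             if (!is.null(spec$duplications) && nrow(spec$duplications) > 0L)
               gi(spec$duplications$chrom, spec$duplications$start,
                  spec$duplications$end) else GenomicRanges::GRanges(),
             if (!is.null(spec$gc_regions) && nrow(spec$gc_regions) > 0L)
               gi(spec$gc_regions$chrom, spec$gc_regions$start,
                  spec$gc_regions$end) else GenomicRanges::GRanges())
  if (length(foots) > 1L) {
    hits <- GenomicRanges::findOverlaps(foots, foots, ignore.strand = TRUE)
    if (length(hits) > length(foots)) {
      stop("planted elements overlap one another; adjust the spec")
    }
  }
  for (g in unique(as.character(GenomicRanges::seqnames(foots)))) {
    if (!g %in% names(spec$chrom_lengths)) stop("unknown chromosome: ", g)
  }
  if (length(foots) > 0L) {
    ends <- GenomicRanges::end(foots)
    lim <- spec$chrom_lengths[as.character(GenomicRanges::seqnames(foots))]
    if (any(ends > lim)) stop("planted element extends past chromosome end")
  }

  gc <- spec$background_gc
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- lapply(spec$chrom_lengths, function(L) {
    sample(names(probs), L, replace = TRUE, prob = probs)
  })

  # GC-shifted background regions
  if (!is.null(spec$gc_regions) && nrow(spec$gc_regions) > 0L) {
    r <- spec$gc_regions
    for (i in seq_len(nrow(r))) {
      gcr <- r$gc[i]
      pr <- c(A = (1 - gcr) / 2, C = gcr / 2, G = gcr / 2, T = (1 - gcr) / 2)
      n <- r$end[i] - r$start[i] + 1L
      chroms[[r$chrom[i]]][r$start[i]:r$end[i]] <-
        sample(names(pr), n, replace = TRUE, prob = pr)
    }
  }

  # promoter windows: scrub background runs, then plant isolated GGGs
  prom_truth <- NULL
  if (!is.null(spec$promoters) && nrow(spec$promoters) > 0L) {
    p <- spec$promoters
    rows <- vector("list", nrow(p))
    for (i in seq_len(nrow(p))) {
      win <- resolve_upstream_window(
        p$chrom[i], p$tss[i], p$strand[i], spec$window_bp, 0L,
        chrom_length = spec$chrom_lengths[[p$chrom[i]]])
      ws <- GenomicRanges::start(win)
      we <- GenomicRanges::end(win)
      seg <- .scrub_runs(chroms[[p$chrom[i]]][ws:we])
      k <- p$planted_triplets[i]
      if (k > 0L) {
        slots <- seq.int(3L, length(seg) - 5L, by = 6L)
        if (k > length(slots)) {
          stop("window too small for ", k, " planted triplets (gene ",
               p$gene[i], ")")
        }
        at <- sort(sample(slots, k))
        for (a in at) {
          seg[a:(a + 2L)] <- "G"
          if (seg[a - 1L] %in% c("G", "C")) seg[a - 1L] <- "T"
          if (seg[a + 3L] %in% c("G", "C")) seg[a + 3L] <- "T"
        }
      }
      chroms[[p$chrom[i]]][ws:we] <- seg
      rows[[i]] <- data.frame(gene = p$gene[i], chrom = p$chrom[i],
                              tss = p$tss[i], strand = p$strand[i],
                              win_start = ws, win_end = we,
                              planted_triplets = k,
                              stringsAsFactors = FALSE)
    }
    prom_truth <- do.call(rbind, rows)
  }

  # LG4 blocks
  lg4_truth <- GenomicRanges::GRanges()
  if (!is.null(spec$lg4s) && nrow(spec$lg4s) > 0L) {
    l <- spec$lg4s
    glist <- vector("list", nrow(l))
    for (i in seq_len(nrow(l))) {
      unit <- strsplit(toupper(l$unit[i]), "")[[1]]
      block <- rep(unit, l$n_units[i])
      if (isTRUE(l$jitter[i])) {
        nonG <- which(rep(unit != "G", l$n_units[i]))
        block[nonG] <- sample(c("A", "C", "T"), length(nonG), replace = TRUE)
        block <- .fix_ccc(block)
      }
      s <- l$start[i]
      e <- s + length(block) - 1L
      chroms[[l$chrom[i]]][s:e] <- block
      g <- gi(l$chrom[i], s, e)
      S4Vectors::mcols(g) <- S4Vectors::DataFrame(
        lg4_id = sprintf("planted_LG4_%02d", i),
        unit = l$unit[i], n_units = l$n_units[i])
      glist[[i]] <- g
    }
    lg4_truth <- do.call(.c_gr, glist)
    names(lg4_truth) <- S4Vectors::mcols(lg4_truth)$lg4_id
  }

  # verbatim duplications
  dup_truth <- GenomicRanges::GRanges()
  if (!is.null(spec$duplications) && nrow(spec$duplications) > 0L) {
    d <- spec$duplications
    occupied <- .c_gr(.lg4_footprints(spec), .promoter_footprints(spec),
                  gi(d$chrom, d$start, d$end))
    placed <- list()
    for (i in seq_len(nrow(d))) {
      src <- chroms[[d$chrom[i]]][d$start[i]:d$end[i]]
      L <- length(src)
      for (cp in seq_len(d$n_copies[i])) {
        done <- FALSE
        for (try in seq_len(1000L)) {
          chrom <- sample(names(spec$chrom_lengths), 1L)
          if (spec$chrom_lengths[[chrom]] < L) next
          s <- sample.int(spec$chrom_lengths[[chrom]] - L + 1L, 1L)
          cand <- gi(chrom, s, s + L - 1L)
          if (length(suppressWarnings(GenomicRanges::findOverlaps(
            cand, occupied, ignore.strand = TRUE))) > 0L) next
          chroms[[chrom]][s:(s + L - 1L)] <- src
          S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
            source_id = sprintf("dup_%02d", i))
          placed[[length(placed) + 1L]] <- cand
          occupied <- .c_gr(occupied, unstrand_gr(cand))
          done <- TRUE
          break
        }
        if (!done) stop("could not place duplication copy for source ", i)
      }
    }
    if (length(placed) > 0L) dup_truth <- do.call(.c_gr, placed)
  }

  genome <- Biostrings::DNAStringSet(
    vapply(chroms, paste, character(1), collapse = ""))
  structure(list(genome = genome, lg4_truth = lg4_truth,
                 promoter_truth = prom_truth, duplication_truth = dup_truth,
                 spec = spec),
            class = "lg4_sim_genome")
}

# replace the middle base of any CCC run so jittered blocks add no
# minus-strand triplets
.fix_ccc <- function(chars) {
  s <- paste(chars, collapse = "")
  repeat {
    m <- regexpr("CCC", s)
    if (m == -1L) break
    mid <- as.integer(m) + 1L
    chars[mid] <- "T"
    substr(s, mid, mid) <- "T"
  }
  chars
}

#' @export
print.lg4_sim_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$genome), "chromosome(s),",
      sum(Biostrings::width(x$genome)), "bp total\n")
  cat("  planted LG4s:", length(x$lg4_truth),
      "| promoters:", if (is.null(x$promoter_truth)) 0 else nrow(x$promoter_truth),
      "| duplication copies:", length(x$duplication_truth), "\n")
  invisible(x)
}

#' Restriction digest of a genome
#'
#' Places a cut immediately before (5' of) every occurrence of the
#' recognition site, so fragments tile each chromosome exactly; fragment k
#' runs from one cut to the base before the next.  The default site `GATC`
#' is the DpnII recognition sequence.
#'
#' @param genome Named `DNAStringSet` or an `lg4_sim_genome`.
#' @param site Recognition sequence (default `"GATC"`).
#' @return `GRanges` of digest fragments with a `frag_id` metadata column.
#' @export
digest_genome <- function(genome, site = "GATC") {
  stopifnot(nzchar(site))
  if (is(genome, "lg4_sim_genome")) genome <- genome$genome
  out <- list()
  for (chrom in names(genome)) {
    seq <- as.character(genome[[chrom]])
    m <- gregexpr(site, seq, fixed = TRUE)[[1]]
    cuts <- if (m[1] == -1L) integer(0) else as.integer(m)
    cuts <- cuts[cuts > 1L]
    starts <- c(1L, cuts)
    ends <- c(cuts - 1L, nchar(seq))
    out[[chrom]] <- gi(chrom, starts, ends)
  }
  frags <- do.call(.c_gr, unname(out))
  S4Vectors::mcols(frags)$frag_id <- sprintf("frag_%06d", seq_along(frags))
  frags
}

#' Specify a Pore-C read simulation
#'
#' @param contact_pairs data.frame with columns `lg4_id`, `gene`,
#'   `probability`: candidate enhancer:promoter contacts and the
#'   per-read probability that a read drawn for that pair is
#'   contact-bearing.
#' @param n_reads Number of reads.
#' @param fragments_per_read Integer vector `c(min, max)` (default 3..12);
#'   `min` must be >= 2 so contact-capable reads exist.
#' @param substitution_rate Per-base substitution probability (default 0).
#' @param seed Integer seed.
#' @param neighborhood_bp Filler fragments are drawn within this distance
#'   of the contact anchors (default 250 kb), mimicking insulated-
#'   neighborhood locality.
#' @param min_frag_len Minimum digest-fragment length used in reads
#'   (default 150 bp, comfortably alignable at the default scoring).
#' @return A `contact_model` list.
#' @export
contact_model <- function(contact_pairs, n_reads,
                          fragments_per_read = c(3L, 12L),
                          substitution_rate = 0, seed = 1L,
                          neighborhood_bp = 250000L, min_frag_len = 150L) {
  stopifnot(all(contact_pairs$probability >= 0),
            all(contact_pairs$probability <= 1),
            fragments_per_read[1] >= 2L,
            fragments_per_read[2] >= fragments_per_read[1],
            substitution_rate >= 0, substitution_rate < 1)
  structure(list(contact_pairs = contact_pairs, n_reads = as.integer(n_reads),
                 fragments_per_read = as.integer(fragments_per_read),
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed),
                 neighborhood_bp = as.integer(neighborhood_bp),
                 min_frag_len = as.integer(min_frag_len)),
            class = "contact_model")
}

.inject_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      alt <- bases[bases != chars[i]]
      chars[i] <- alt[sample.int(3L, 1L)]
    }
  }
  paste(chars, collapse = "")
}

#' Simulate Pore-C concatemer reads
#'
#' Each read is a shuffled concatenation of digest fragments.  With the
#' pair's contact probability the read is contact-bearing: it contains at
#' least one fragment overlapping the LG4 and one overlapping the promoter
#' window, plus filler fragments from the surrounding neighborhoods;
#' otherwise all fragments come from one random neighborhood.  Filler
#' fragments never overlap any planted LG4 or promoter window, so the truth
#' contact labels are exact.  Each fragment is independently reverse-
#' complemented with probability 0.5 and substitutions are injected at
#' `substitution_rate`.  Fully seeded and reproducible.
#'
#' @param sim An `lg4_sim_genome` from [make_genome()].
#' @param model A [contact_model()].
#' @return List: `reads` (named `DNAStringSet`), `fragment_truth`
#'   (data.frame of every fragment's source interval and orientation),
#'   `contact_truth` (data.frame with `read_id`, `lg4_id`, `gene`,
#'   `is_contact`), `model`.
#' @export
simulate_porec <- function(sim, model) {
  stopifnot(is(sim, "lg4_sim_genome"), is(model, "contact_model"))
  set.seed(model$seed)
  genome <- sim$genome
  frags <- digest_genome(genome)
  flen <- BiocGenerics::width(frags)
  eligible <- flen >= model$min_frag_len

  pairs <- model$contact_pairs
  lg4_ids <- names(sim$lg4_truth)
  if (!all(pairs$lg4_id %in% lg4_ids)) {
    stop("contact_pairs reference unknown LG4 ids: ",
         paste(setdiff(pairs$lg4_id, lg4_ids), collapse = ", "))
  }
  prom <- sim$promoter_truth
  if (!all(pairs$gene %in% prom$gene)) {
    stop("contact_pairs reference unknown genes: ",
         paste(setdiff(pairs$gene, prom$gene), collapse = ", "))
  }
  prom_gr <- stats::setNames(gi(prom$chrom, prom$win_start, prom$win_end),
                             prom$gene)
  anchors_gr <- .c_gr(unstrand_gr(sim$lg4_truth), unstrand_gr(prom_gr))
  ov_anchor <- suppressWarnings(GenomicRanges::countOverlaps(
    frags, anchors_gr, ignore.strand = TRUE)) > 0L
  filler_ok <- eligible & !ov_anchor

  frag_idx_for <- function(gr) {
    which(eligible & suppressWarnings(GenomicRanges::countOverlaps(
      frags, unstrand_gr(gr), ignore.strand = TRUE)) > 0L)
  }
  lg4_frag_idx <- lapply(seq_len(nrow(pairs)), function(i) {
    frag_idx_for(sim$lg4_truth[pairs$lg4_id[i]])
  })
  prom_frag_idx <- lapply(seq_len(nrow(pairs)), function(i) {
    frag_idx_for(prom_gr[pairs$gene[i]])
  })
  for (i in seq_len(nrow(pairs))) {
    if (length(lg4_frag_idx[[i]]) == 0L) {
      stop("no usable digest fragment overlaps ", pairs$lg4_id[i])
    }
    if (length(prom_frag_idx[[i]]) == 0L) {
      stop("no usable digest fragment overlaps the ", pairs$gene[i],
           " promoter window")
    }
  }
  neighborhood_of <- function(idx) {
    ctr <- frags[idx]
    hood <- GenomicRanges::resize(unstrand_gr(ctr),
                                  BiocGenerics::width(ctr) + 2L * model$neighborhood_bp,
                                  fix = "center")
    which(filler_ok & suppressWarnings(GenomicRanges::countOverlaps(
      frags, hood, ignore.strand = TRUE)) > 0L)
  }
  global_pool <- which(filler_ok)
  if (length(global_pool) == 0L) stop("no filler fragments available")

  frag_seqs <- NULL  # lazily extracted per read
  reads <- character(model$n_reads)
  frag_rows <- vector("list", model$n_reads)
  contact_rows <- vector("list", model$n_reads)
  fmin <- model$fragments_per_read[1]
  fmax <- model$fragments_per_read[2]
  for (r in seq_len(model$n_reads)) {
    read_id <- sprintf("simread_%05d", r)
    pair_i <- if (nrow(pairs) == 1L) 1L else sample.int(nrow(pairs), 1L)
    is_contact <- stats::runif(1) < pairs$probability[pair_i]
    nfrag <- if (fmin == fmax) fmin else sample(fmin:fmax, 1L)
    if (is_contact) {
      fl <- .sample1(lg4_frag_idx[[pair_i]])
      fp <- .sample1(prom_frag_idx[[pair_i]])
      pool <- unique(c(neighborhood_of(fl), neighborhood_of(fp)))
      nfill <- min(nfrag - 2L, length(pool))
      fills <- if (nfill > 0L) sample(pool, nfill) else integer(0)
      idx <- c(fl, fp, fills)
    } else {
      anchor <- .sample1(global_pool)
      pool <- neighborhood_of(anchor)
      n <- min(nfrag, length(pool))
      idx <- if (n > 1L) c(anchor, sample(setdiff(pool, anchor), n - 1L)) else anchor
    }
    idx <- idx[sample.int(length(idx))]
    flip <- stats::runif(length(idx)) < 0.5
    segs <- character(length(idx))
    for (j in seq_along(idx)) {
      g <- frags[idx[j]]
      s <- get_interval_seq(genome, g)
      if (flip[j]) {
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      }
      segs[j] <- .inject_substitutions(s, model$substitution_rate)
    }
    reads[r] <- paste(segs, collapse = "")
    frag_rows[[r]] <- data.frame(
      read_id = read_id, order = seq_along(idx),
      chrom = as.character(GenomicRanges::seqnames(frags[idx])),
      start = GenomicRanges::start(frags[idx]),
      end = GenomicRanges::end(frags[idx]),
      strand_in_read = ifelse(flip, "-", "+"),
      stringsAsFactors = FALSE)
    contact_rows[[r]] <- data.frame(
      read_id = read_id, lg4_id = pairs$lg4_id[pair_i],
      gene = pairs$gene[pair_i], is_contact = is_contact,
      stringsAsFactors = FALSE)
  }
  reads <- stats::setNames(Biostrings::DNAStringSet(reads),
                           sprintf("simread_%05d", seq_len(model$n_reads)))
  list(reads = reads,
       fragment_truth = do.call(rbind, frag_rows),
       contact_truth = do.call(rbind, contact_rows),
       model = model)
}

.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Write reads as FASTQ
#'
#' Plain-text FASTQ with constant quality (`I`); pairs with
#' [read_porec_reads()].
#'
#' @param reads Named `DNAStringSet` or character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  if (is(reads, "DNAStringSet")) {
    reads <- stats::setNames(as.character(reads), names(reads))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+",
                 strrep("I", nchar(reads[[i]]))), con)
  }
  invisible(path)
}
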