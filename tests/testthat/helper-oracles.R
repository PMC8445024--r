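# Independent oracles and small fixture builders shared across tests.

# Brute-force maximal-density-segment oracle: a naive recursive
# transliteration of the nested maximal-scoring-segment definition. For
# a run of sites, every candidate break is scored by exhaustively
# re-summing the prefix/suffix (no shared code or cumulative sums with
# the implementation); the break with the lowest density splits the
# segment, which is reported with the density range over which it is
# maximal (ties: prefix side, smallest index — the documented rule).
oracle_density_segments <- function(pos, val) {
  seg_sum <- function(a, b) {
    s <- 0
    for (k in a:b) s <- s + val[k]
    s
  }
  dens <- function(a, b) seg_sum(a, b) / (pos[b] - pos[a] + 1)
  out <- data.table::data.table(start = integer(), end = integer(),
                                n_sites = integer(), total = numeric(),
                                density = numeric(), min_den = numeric(),
                                max_den = numeric())
  visit <- function(i, j, min_den) {
    if (i == j) {
      out <<- rbind(out, data.table::data.table(
        start = pos[i], end = pos[j], n_sites = 1L, total = val[i],
        density = dens(i, i), min_den = min_den, max_den = Inf))
      return(invisible())
    }
    cand <- data.table::data.table(side = character(), k = integer(),
                                   d = numeric())
    for (k in i:(j - 1)) {
      cand <- rbind(cand,
                    data.table::data.table(side = "prefix", k = k,
                                           d = dens(i, k)))
    }
    for (k in (i + 1):j) {
      cand <- rbind(cand,
                    data.table::data.table(side = "suffix", k = k,
                                           d = dens(k, j)))
    }
    brk <- min(cand$d)
    out <<- rbind(out, data.table::data.table(
      start = pos[i], end = pos[j], n_sites = j - i + 1L,
      total = seg_sum(i, j), density = dens(i, j),
      min_den = min_den, max_den = brk))
    pre <- cand[side == "prefix" & d == brk]
    if (nrow(pre)) {
      k <- min(pre$k)
      visit(i, k, brk)
      visit(k + 1L, j, brk)
    } else {
      k <- min(cand[side == "suffix" & d == brk]$k)
      visit(i, k - 1L, brk)
      visit(k, j, brk)
    }
  }
  if (length(pos)) visit(1L, length(pos), 0)
  out[order(start, -(end - start))]
}

# Apply the peak filters + outermost-survivor selection to an oracle
# cluster family (mirrors the documented filtering contract).
oracle_filter_peaks <- function(fam, min_density = 10, max_length = 200,
                                density_fold = 2) {
  keep <- fam[density >= min_density & (end - start + 1L) <= max_length &
                max_den / pmax(min_den, .Machine$double.xmin) >=
                  density_fold]
  if (nrow(keep) <= 1L) return(keep)
  keep <- keep[order(start, -(end - start))]
  sel <- logical(nrow(keep))
  last_end <- -Inf
  for (r in seq_len(nrow(keep))) {
    if (keep$start[r] > last_end) {
      sel[r] <- TRUE
      last_end <- keep$end[r]
    }
  }
  keep[sel]
}

# Small random genome as a named character vector -> DNAStringSet
random_genome <- function(len = 5000, gc = 0.5, name = "chrT", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
             collapse = "")
  Biostrings::DNAStringSet(setNames(s, name))
}

# Overwrite genome sequence at 1-based position
plant_motif <- function(genome, contig, at, motif) {
  s <- as.character(genome[[contig]])
  s <- paste0(substr(s, 1, at - 1), motif,
              substr(s, at + nchar(motif), nchar(s)))
  out <- as.character(genome)
  out[contig] <- s
  Biostrings::DNAStringSet(out)
}

# Two-gene toy annotation on one contig for region tests
toy_annotation <- function() {
  genes <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(c(1001, 6001), c(3000, 8000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"))
  exons <- list(
    gA = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(1001, 1801, 2601), c(1200, 2000, 3000)),
      strand = "+"),
    gB = GenomicRanges::GRanges("chrT",
      IRanges::IRanges(c(6001, 7501), c(6500, 8000)), strand = "-"))
  utr3 <- list(
    gA = GenomicRanges::GRanges("chrT", IRanges::IRanges(2801, 3000),
                                strand = "+"),
    gB = GenomicRanges::GRanges("chrT", IRanges::IRanges(6001, 6200),
                                strand = "-"))
  gene_annotation(genes, exons, utr3)
}

# Manifest builder
toy_manifest <- function(variants, experiment = "mutants", reps = 2,
                         condition = "untreated") {
  dt <- data.table::CJ(variant = variants, replicate = seq_len(reps),
                       sorted = FALSE)
  dt[, sample_id := paste0(variant, "_", replicate)]
  dt[, `:=`(experiment = experiment, condition = condition, batch = 1L)]
  dt[]
}
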