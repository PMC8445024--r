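# Motif-based binding-region calling around 50th-percentile thresholded
# crosslinks, merging into binding regions, the 36-class
# length/density/motif-type classification, and per-sample cDNA
# quantification with the region filters and class normalization.

#' Call genomic motif positions around thresholded crosslinks
#'
#' Sequences in a window around each tXn are scanned for the queried
#' motifs at the supplied reference offsets (the offsets at which each
#' motif was enriched in the reference enrichment run). Occurrences are
#' deduplicated genomically and keep their motif-family label.
#'
#' @param genome genome.
#' @param txn data.table(chrom, strand, pos) of thresholded crosslinks
#'   (typically the 50th-percentile set from merged experiments).
#' @param motif_groups named list of motif vectors, one per family
#'   (e.g. YG/YA/AA).
#' @param ref_offsets either a numeric vector of offsets applied to every
#'   motif, or a named list motif -> offsets.
#' @param window scan window around each tXn (default c(-30, 30)).
#' @return data.table(chrom, strand, start, end, group, kmer) of
#'   deduplicated genomic motif occurrences (start/end 1-based closed).
#' @export
call_motif_positions <- function(genome, txn, motif_groups, ref_offsets,
                                 window = c(-30, 30)) {
  if (!is.list(motif_groups) || is.null(names(motif_groups))) {
    stop("motif_groups must be a named list of motif families")
  }
  all_motifs <- unlist(motif_groups, use.names = FALSE)
  if (anyDuplicated(all_motifs)) {
    stop("motif families must partition the motif list")
  }
  k <- nchar(all_motifs[1])
  txn <- as.data.table(txn)
  win <- extract_oriented_window(genome, txn$chrom, txn$pos, txn$strand,
                                 c(window[1], window[2]))
  keep <- !attr(win, "truncated")
  win <- win[keep]
  txn <- txn[keep]
  code <- kmer_code_matrix(win, k)
  offs <- window[1]:(window[2] - k + 1L)
  kmers <- all_kmers(k)
  group_of <- rep(names(motif_groups), lengths(motif_groups))
  names(group_of) <- all_motifs
  if (!is.list(ref_offsets)) {
    ref_offsets <- setNames(rep(list(ref_offsets), length(all_motifs)),
                            all_motifs)
  }
  out <- list()
  for (mot in all_motifs) {
    off_ok <- intersect(ref_offsets[[mot]], offs)
    if (!length(off_ok)) next
    cols <- match(off_ok, offs)
    mc <- match(mot, kmers)
    hit <- which(code[, cols, drop = FALSE] == mc, arr.ind = TRUE)
    if (!nrow(hit)) next
    o <- off_ok[hit[, 2]]
    site <- txn[hit[, 1]]
    gstart <- ifelse(site$strand == "+", site$pos + o,
                     site$pos - o - (k - 1L))
    out[[mot]] <- data.table(chrom = site$chrom, strand = site$strand,
                             start = as.integer(gstart),
                             end = as.integer(gstart + k - 1L),
                             group = group_of[[mot]], kmer = mot)
  }
  res <- rbindlist(out)
  if (!nrow(res)) {
    return(data.table(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      group = character(), kmer = character()))
  }
  unique(res, by = c("chrom", "strand", "start"))[
    order(chrom, strand, start)]
}

#' Merge motif positions into binding regions
#'
#' Single-linkage merge per contig and strand: motif occurrences whose
#' start-to-start distance is at most `gap` join one region. The region
#' span runs from the first motif start to the last motif end; density is
#' the fraction of the span covered by at least one motif occurrence.
#'
#' @param positions motif-position table from [call_motif_positions()].
#' @param gap merge distance in nt (default 30).
#' @return data.table(chrom, strand, start, end, length, n_yg, n_ya,
#'   n_aa, density).
#' @export
merge_into_regions <- function(positions, gap = 30) {
  pos <- as.data.table(positions)[order(chrom, strand, start)]
  if (!nrow(pos)) {
    return(data.table(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      length = integer(), n_yg = integer(),
                      n_ya = integer(), n_aa = integer(),
                      density = numeric()))
  }
  pos[, new_region := c(TRUE, diff(start) > gap |
                          chrom[-1] != chrom[-.N] |
                          strand[-1] != strand[-.N]), by = NULL]
  pos[, rid := cumsum(new_region)]
  covered_len <- function(s, e) {
    o <- order(s); s <- s[o]; e <- e[o]
    tot <- 0L; cur_s <- s[1]; cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] > cur_e) {
        tot <- tot + cur_e - cur_s + 1L
        cur_s <- s[i]; cur_e <- e[i]
      } else cur_e <- max(cur_e, e[i])
    }
    tot + cur_e - cur_s + 1L
  }
  reg <- pos[, {
    rs <- min(start); re <- max(end)
    .(chrom = chrom[1], strand = strand[1], start = rs, end = re,
      length = re - rs + 1L,
      n_yg = sum(group == "YG"), n_ya = sum(group == "YA"),
      n_aa = sum(group == "AA"),
      density = covered_len(start, end) / (re - rs + 1L))
  }, by = rid][, rid := NULL]
  reg[]
}

# Split n ranked items into three contiguous groups with sizes differing
# by at most one; extras go to the earlier groups.
tercile_sizes <- function(n) {
  base <- n %/% 3L
  rem <- n %% 3L
  base + c(rem >= 1L, rem >= 2L, 0L)
}

#' Classify binding regions into the 36 length/density/motif-type classes
#'
#' Regions are placed into four length classes (1-30, 31-60, 61-100,
#' >100 nt); each length class is split into density terciles of equal
#' size (low/medium/high, ties by genomic order); each of the 12 cells is
#' split into three motif-type subclasses: the top `cap` regions by
#' (YG+1)/(AA+1) ratio, then from the remainder the top `cap` by
#' (AA+1)/(other motifs+1) ratio, then the rest. The cap is 3000 (1500
#' for the >100 nt class) or the cell size when smaller.
#'
#' @param regions region table from [merge_into_regions()] (or any table
#'   with chrom, strand, start, length, n_yg, n_ya, n_aa, density).
#' @param caps subclass caps per length bin.
#' @return input with columns length_class, density_class, subclass and
#'   class_id (1..36) appended; class_id =
#'   (length class - 1) * 9 + (density tercile - 1) * 3 + subclass.
#' @export
classify_regions <- function(regions,
                             caps = c(3000L, 3000L, 3000L, 1500L)) {
  reg <- copy(as.data.table(regions))
  if (!nrow(reg)) {
    reg[, `:=`(length_class = integer(), density_class = integer(),
               subclass = integer(), class_id = integer())]
    return(reg)
  }
  reg[, length_class := cut(length, c(0, 30, 60, 100, Inf),
                            labels = FALSE)]
  bad <- reg[, .N, by = length_class][N < 9L]
  if (nrow(bad)) {
    stop("need at least 9 regions per length class to form density ",
         "terciles (class ", bad$length_class[1], " has ", bad$N[1], ")")
  }
  reg[, row_id := .I]
  setorder(reg, length_class, density, chrom, start)
  reg[, density_class := {
    sz <- tercile_sizes(.N)
    rep(1:3, sz)
  }, by = length_class]
  reg[, total_motifs := n_yg + n_ya + n_aa]
  reg[, subclass := {
    n <- .N
    cap <- min(caps[length_class[1]], n)
    r1 <- (n_yg + 1) / (n_aa + 1)
    ord1 <- order(-r1, -total_motifs, chrom, start)
    sub <- integer(n)
    a <- ord1[seq_len(cap)]
    sub[a] <- 1L
    restn <- setdiff(seq_len(n), a)
    if (length(restn)) {
      r2 <- (n_aa + 1) / (n_yg + n_ya + 1)
      ord2 <- restn[order(-r2[restn], -total_motifs[restn],
                          chrom[restn], start[restn])]
      b <- ord2[seq_len(min(cap, length(ord2)))]
      sub[b] <- 2L
      sub[setdiff(restn, b)] <- 3L
    }
    sub
  }, by = .(length_class, density_class)]
  reg[, class_id := (length_class - 1L) * 9L +
        (density_class - 1L) * 3L + subclass]
  setorder(reg, row_id)
  reg[, c("row_id", "total_motifs") := NULL]
  reg[]
}

#' Quantify, filter and summarize binding regions across samples
#'
#' Per-region per-sample cDNA counts are the summed track counts within
#' the region span (same strand). Regions are retained when their total
#' count in the designated experiment exceeds 100, or when they lie
#' inside a gene, have a designated-experiment count above 10 and carry
#' at least 10% of the count of the gene-maximal region. Per-class
#' per-sample totals are normalized by the across-sample mean of the
#' class, so each class row has mean 1.
#'
#' @param regions classified region table from [classify_regions()].
#' @param tracks named list of `cs_track`.
#' @param manifest manifest (sample_id, experiment, variant).
#' @param annotation `cs_annotation` for host-gene assignment (midpoint
#'   rule); regions outside genes are exempt from the gene-relative
#'   filter.
#' @param designated_experiment experiment label used by the filters
#'   (default "HD").
#' @return list(regions [filtered regions + host_gene + per-sample count
#'   columns], class_summary [data.table class_id x sample normalized],
#'   counts [long data.table]).
#' @export
quantify_filter_summarize <- function(regions, tracks, manifest,
                                      annotation,
                                      designated_experiment = "HD") {
  man <- as.data.table(manifest)
  if (!designated_experiment %in% man$experiment) {
    stop("manifest has no samples of experiment '",
         designated_experiment, "'")
  }
  reg <- copy(as.data.table(regions))
  reg[, region_idx := .I]
  # host gene by midpoint
  mid <- (reg$start + reg$end) %/% 2L
  midgr <- GenomicRanges::GRanges(reg$chrom, IRanges::IRanges(mid, mid),
                                  strand = reg$strand)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    midgr, annotation$genes, ignore.strand = FALSE))
  reg[, host_gene := NA_character_]
  reg$host_gene[S4Vectors::queryHits(hits)] <-
    annotation$genes$gene_id[S4Vectors::subjectHits(hits)]
  counts <- rbindlist(lapply(names(tracks), function(sid) {
    dt <- as.data.table(tracks[[sid]])
    ov <- dt[reg[, .(region_idx, chrom, strand, start, end)],
             on = .(chrom, strand, pos >= start, pos <= end),
             nomatch = NULL, allow.cartesian = TRUE]
    ov[, .(count = sum(count)), by = region_idx][, sample_id := sid]
  }))
  full <- CJ(region_idx = reg$region_idx, sample_id = names(tracks))
  counts <- counts[full, on = .(region_idx, sample_id)]
  counts[is.na(count), count := 0L]
  counts <- merge(counts, man[, .(sample_id, experiment)],
                  by = "sample_id")
  de_total <- counts[experiment == designated_experiment,
                     .(de_count = sum(count)), by = region_idx]
  reg <- merge(reg, de_total, by = "region_idx", all.x = TRUE)
  reg[is.na(de_count), de_count := 0L]
  reg[, gene_max := max(de_count), by = host_gene]
  keep <- reg$de_count > 100 |
    (!is.na(reg$host_gene) & reg$de_count > 10 &
       reg$de_count >= 0.10 * reg$gene_max)
  reg_f <- reg[keep]
  counts_f <- counts[region_idx %in% reg_f$region_idx]
  cls <- counts_f[reg_f[, .(region_idx, class_id)], on = "region_idx"]
  summ <- cls[, .(total = sum(count)), by = .(class_id, sample_id)]
  summ[, normalized := total / mean(total), by = class_id]
  wide <- dcast(summ, class_id ~ sample_id, value.var = "normalized")
  list(regions = reg_f, class_summary = wide, counts = counts_f,
       class_totals = summ)
}
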