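# Density peak calling on crosslink sites and regional percentile
# thresholding into tXn (thresholded) and oXn (background) sets.

#' Maximal-density segment decomposition of a run of crosslink sites
#'
#' Implements the nested maximal-scoring-segment recursion over
#' per-position cDNA counts: for a segment of sites the break with the
#' lowest prefix/suffix density is found, the segment is reported with the
#' density range over which it is maximal, and the two halves are visited
#' recursively. The resulting cluster family is laminar.
#'
#' @param pos sorted integer positions (1-based).
#' @param val positive counts, same length.
#' @return data.table(start, end, n_sites, total, density, min_den, max_den)
#'   of all clusters in the hierarchy. `density` is total/(end-start+1);
#'   `min_den`/`max_den` bound the density parameter range over which the
#'   cluster is a maximal segment (Inf for single sites at the bottom).
#' @keywords internal
paraclu_decompose <- function(pos, val) {
  n <- length(pos)
  if (n == 0L) {
    return(data.table(start = integer(), end = integer(),
                      n_sites = integer(), total = numeric(),
                      density = numeric(), min_den = numeric(),
                      max_den = numeric()))
  }
  res <- vector("list", 0L)
  stack <- list(list(i = 1L, j = n, min_den = 0))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr$i; j <- fr$j
    tot <- sum(val[i:j])
    len <- pos[j] - pos[i] + 1L
    if (i == j) {
      res[[length(res) + 1L]] <- list(pos[i], pos[j], 1L, tot,
                                      tot / len, fr$min_den, Inf)
      next
    }
    idx <- i:(j - 1L)
    csum <- cumsum(val[i:j])
    pre_tot <- csum[seq_len(j - i)]
    pre_den <- pre_tot / (pos[idx] - pos[i] + 1L)
    suf_tot <- tot - pre_tot
    suf_den <- suf_tot / (pos[j] - pos[idx + 1L] + 1L)
    dmin_pre <- min(pre_den); dmin_suf <- min(suf_den)
    brk_den <- min(dmin_pre, dmin_suf)
    res[[length(res) + 1L]] <- list(pos[i], pos[j], j - i + 1L, tot,
                                    tot / len, fr$min_den, brk_den)
    if (dmin_pre <= dmin_suf) {
      k <- idx[which.min(pre_den)]        # split after prefix [i..k]
    } else {
      k <- idx[which.min(suf_den)]        # split before suffix [k+1..j]
    }
    stack[[length(stack) + 1L]] <- list(i = i, j = k, min_den = brk_den)
    stack[[length(stack) + 1L]] <- list(i = k + 1L, j = j, min_den = brk_den)
  }
  out <- rbindlist(res)
  setnames(out, c("start", "end", "n_sites", "total", "density",
                  "min_den", "max_den"))
  out
}

#' Call crosslink density peaks within regions
#'
#' Peaks are high-density crosslink intervals called per region and strand
#' with a Paraclu-style maximal-segment decomposition, then filtered on
#' cluster density (cDNA/nt), maximum length, and density-fold stability
#' (max_den/min_den); among surviving nested clusters only the outermost
#' are kept, so final peaks within a region never overlap.
#'
#' @param track `cs_track`.
#' @param regions `GRanges` from [derive_threshold_regions()] (or any
#'   GRanges with a `region_id` column).
#' @param min_density minimum cluster density in cDNA/nt (default 10).
#' @param max_length maximum cluster length in nt (default 200).
#' @param density_fold minimum max_den/min_den stability ratio (default 2).
#' @return data.table(region_id, chrom, strand, start, end, n_sites, total,
#'   density, min_den, max_den).
#' @export
call_peaks <- function(track, regions, min_density = 10, max_length = 200,
                       density_fold = 2) {
  site_region <- assign_sites_to_regions(track, regions)
  if (!nrow(site_region)) {
    return(data.table(region_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      total = numeric(), density = numeric(),
                      min_den = numeric(), max_den = numeric()))
  }
  peaks <- site_region[order(region_id, strand, pos),
    {
      cl <- paraclu_decompose(pos, count)
      cl <- cl[density >= min_density & (end - start + 1L) <= max_length &
                 max_den / pmax(min_den, .Machine$double.xmin) >= density_fold]
      if (nrow(cl) > 1L) {
        cl <- cl[order(start, -(end - start))]
        keep <- logical(nrow(cl))
        last_end <- -Inf
        for (r in seq_len(nrow(cl))) {
          if (cl$start[r] > last_end) {
            keep[r] <- TRUE
            last_end <- cl$end[r]
          }
        }
        cl <- cl[keep]
      }
      cl
    },
    by = .(region_id, chrom, strand)]
  peaks[]
}

# Map each crosslink site to hosting regions (same strand for stranded
# regions; intergenic regions are unstranded and accept both strands).
# A site inside two overlapping genes appears once per hosting region.
assign_sites_to_regions <- function(track, regions) {
  dt <- as.data.table(track)
  if (!nrow(dt)) {
    return(data.table(chrom = character(), strand = character(),
                      pos = integer(), count = integer(),
                      region_id = character()))
  }
  sites <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos),
                                  strand = dt$strand)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(sites, regions, ignore.strand = FALSE))
  out <- dt[S4Vectors::queryHits(hits)]
  out[, region_id := regions$region_id[S4Vectors::subjectHits(hits)]]
  out
}

nearest_rank_threshold <- function(counts, percentile) {
  s <- sort(counts)
  idx <- max(1L, ceiling(percentile / 100 * length(s)))
  s[idx]
}

#' Partition crosslinks into thresholded (tXn) and background (oXn) sets
#'
#' For each region the threshold is the nearest-rank percentile of the
#' cDNA counts of sites inside that region's peaks; all sites in the
#' region with a count at or above the threshold become tXn and the rest
#' oXn. Regions without peaks contribute no tXn.
#'
#' @param track `cs_track`.
#' @param peaks output of [call_peaks()] on the same track.
#' @param regions `GRanges` with `region_id`.
#' @param percentile percentile in `[0, 100]` (default 70).
#' @return list with `sites`: data.table(chrom, strand, pos, count,
#'   region_id, set = "tXn"/"oXn") and `thresholds`: data.table(region_id,
#'   threshold, n_in_peaks). Sites outside every region are returned in
#'   `orphans` and treated as background.
#' @export
threshold_crosslinks <- function(track, peaks, regions, percentile = 70) {
  if (percentile < 0 || percentile > 100) {
    stop("percentile must be in [0, 100]")
  }
  site_region <- assign_sites_to_regions(track, regions)
  ip <- rep(FALSE, nrow(site_region))
  if (nrow(peaks) && nrow(site_region)) {
    pk <- peaks[, .(region_id, strand, start, end)]
    ov <- site_region[, .(row = .I, region_id, strand, pos)][
      pk, on = .(region_id, strand, pos >= start, pos <= end), nomatch = NULL]
    ip[unique(ov$row)] <- TRUE
  }
  site_region[, in_peak := ip]
  thr <- site_region[in_peak == TRUE,
                     .(threshold = nearest_rank_threshold(count, percentile),
                       n_in_peaks = .N), by = region_id]
  site_region[, threshold := thr[site_region, on = "region_id",
                                 x.threshold]]
  site_region[, set := fifelse(!is.na(threshold) & count >= threshold,
                               "tXn", "oXn")]
  dt <- as.data.table(track)
  orphan <- dt[!site_region[, .(chrom, strand, pos)],
               on = .(chrom, strand, pos)]
  list(sites = site_region[, .(chrom, strand, pos, count, region_id,
                               in_peak, threshold, set)],
       thresholds = thr,
       orphans = orphan)
}

#' Extract tXn or oXn site tables from a partition
#'
#' Optionally restricts to sites hosted by regions of given kinds (e.g.
#' `kinds = "intron"` for intronic motif discovery, the usual choice
#' for nuclear RBPs).
#'
#' @param partition result of [threshold_crosslinks()].
#' @param set `"tXn"` or `"oXn"`.
#' @param unique_sites collapse duplicated (chrom,strand,pos) rows arising
#'   from overlapping gene regions (default TRUE).
#' @param regions the `GRanges` the partition was built from; required
#'   when `kinds` is given.
#' @param kinds optional region kinds to keep (subset of
#'   intron/merged_exons/intergenic).
#' @return data.table(chrom, strand, pos, count).
#' @export
partition_sites <- function(partition, set = c("tXn", "oXn"),
                            unique_sites = TRUE, regions = NULL,
                            kinds = NULL) {
  wanted <- match.arg(set)
  sites <- partition$sites
  if (!is.null(kinds)) {
    if (is.null(regions)) stop("kinds filtering needs the regions object")
    keep_ids <- regions$region_id[regions$kind %in% kinds]
    sites <- sites[sites$region_id %in% keep_ids]
  }
  out <- sites[sites$set == wanted, .(chrom, strand, pos, count)]
  if (wanted == "oXn" && is.null(kinds) && nrow(partition$orphans)) {
    out <- rbind(out, partition$orphans[, .(chrom, strand, pos, count)])
  }
  if (unique_sites) out <- unique(out, by = c("chrom", "strand", "pos"))
  out[order(chrom, strand, pos)]
}

#' Merge crosslink tracks by summing counts
#' @param tracks list of `cs_track`.
#' @param sample_id id for the merged track.
#' @return `cs_track`.
#' @export
merge_tracks <- function(tracks, sample_id = "merged") {
  dt <- rbindlist(lapply(tracks, as.data.table))
  crosslink_track(dt[, .(count = sum(count)), by = .(chrom, strand, pos)],
                  sample_id)
}
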