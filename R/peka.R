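# Positional k-mer enrichment analysis (PEKA) around thresholded
# crosslink sites, its comparative two-iteration variant, motif grouping
# and metaprofile coverage curves.

#' Encode fixed-width sequence windows as k-mer code matrices
#'
#' @param windows character vector of equal-width windows (A/C/G/T/N).
#' @param k k-mer length.
#' @return integer matrix (n windows x n offsets) of 1-based k-mer codes
#'   in `1:4^k` (lexicographic, A<C<G<T); NA where the k-mer overlaps an N.
#' @keywords internal
kmer_code_matrix <- function(windows, k) {
  n <- length(windows)
  w <- nchar(windows[1])
  chars <- matrix(match(unlist(strsplit(windows, "", fixed = TRUE)),
                        DNA_BASES) - 1L,
                  nrow = n, ncol = w, byrow = TRUE)
  noff <- w - k + 1L
  code <- matrix(0, n, noff)
  for (t in 0:(k - 1L)) {
    code <- code + chars[, (1L + t):(noff + t), drop = FALSE] * 4^(k - 1L - t)
  }
  mode(code) <- "integer"
  code + 1L
}

all_kmers <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(DNA_BASES), k),
                                  stringsAsFactors = FALSE)))
}

# Occurrence counts per offset for a subset of window rows:
# returns matrix 4^k x length(cols) of site counts.
count_kmers_at <- function(code, rows, cols, nbins) {
  out <- matrix(0L, nbins, length(cols))
  for (ci in seq_along(cols)) {
    v <- code[rows, cols[ci]]
    v <- v[!is.na(v)]
    if (length(v)) out[, ci] <- tabulate(v, nbins)
  }
  out
}

#' Positional k-mer occurrence profile around crosslink sites
#'
#' Windows span -150..150 nt around each site in transcript orientation
#' (k-mers are indexed by their start offset). Sites whose window is
#' clipped at a contig edge are excluded. Occurrences are counted in the
#' proximal window and summarized as a mean per-site occurrence over the
#' two distal windows.
#'
#' @param genome genome.
#' @param sites data.table(chrom, strand, pos) of anchor sites.
#' @param k k-mer length (default 6).
#' @param proximal proximal offset range (default c(-40, 40)).
#' @param distal list of two distal offset ranges (defaults
#'   c(-150, -100) and c(100, 150)).
#' @param keep_codes keep the window code matrix in the result (used by
#'   the scoring routines to avoid recomputation).
#' @return object of class `cs_peka_profile`: list(k, n_sites, offsets,
#'   prox_counts [4^k x offsets], distal_mean [per-site occurrence per
#'   k-mer], kmers, eps).
#' @export
positional_profile <- function(genome, sites, k = 6,
                               proximal = c(-40, 40),
                               distal = list(c(-150, -100), c(100, 150)),
                               keep_codes = FALSE) {
  if (k <= 0) stop("k must be positive")
  sites <- as.data.table(sites)
  if (!nrow(sites)) stop("no sites supplied")
  lo <- min(proximal[1], min(vapply(distal, `[`, 0, 1)))
  hi <- max(proximal[2], max(vapply(distal, `[`, 0, 2))) + k - 1L
  win <- extract_oriented_window(genome, sites$chrom, sites$pos,
                                 sites$strand, c(lo, hi))
  ok <- !attr(win, "truncated")
  win <- win[ok]
  n <- length(win)
  if (!n) stop("all windows clipped at contig edges")
  code <- kmer_code_matrix(win, k)
  nbins <- 4L^k
  off2col <- function(o) o - lo + 1L
  prox_off <- proximal[1]:proximal[2]
  prox_counts <- count_kmers_at(code, seq_len(n), off2col(prox_off), nbins)
  dist_off <- unlist(lapply(distal, function(d) d[1]:d[2]))
  dist_counts <- count_kmers_at(code, seq_len(n), off2col(dist_off), nbins)
  structure(list(
    k = k, n_sites = n, offsets = prox_off,
    prox_counts = prox_counts,
    distal_mean = rowSums(dist_counts) / length(dist_off) / n,
    kmers = all_kmers(k),
    eps = 0.5 / n,
    codes = if (keep_codes) list(code = code, lo = lo, kept = which(ok))
            else NULL), class = "cs_peka_profile")
}

#' Normalize a positional profile by its distal background
#'
#' The per-site occurrence at each proximal offset is divided by the mean
#' per-site distal occurrence of the same k-mer plus a pseudocount
#' `0.5/n_sites`, so an unenriched k-mer sits near 1.
#'
#' @param profile `cs_peka_profile`.
#' @return numeric matrix (4^k x offsets) of normalized occurrences.
#' @export
normalize_profile <- function(profile) {
  (profile$prox_counts / profile$n_sites) /
    (profile$distal_mean + profile$eps)
}

#' Select enrichment offsets for each k-mer
#'
#' In standard mode the core -13..13 offsets are always included, plus any
#' flank offset (-40..-14 or 14..40) whose normalized occurrence exceeds
#' `flank_threshold`. In comparative mode only offsets anywhere in the
#' proximal window with normalized occurrence above the threshold are
#' chosen (no automatic core).
#'
#' @param normalized matrix from [normalize_profile()].
#' @param offsets offset vector matching the matrix columns.
#' @param flank_threshold threshold (2 standard, 4 comparative).
#' @param mode `"standard"` or `"comparative"`.
#' @param core core offset range included unconditionally in standard mode.
#' @return logical matrix (4^k x offsets): chosen offsets per k-mer.
#' @export
select_positions <- function(normalized, offsets, flank_threshold = 2,
                             mode = c("standard", "comparative"),
                             core = c(-13, 13)) {
  mode <- match.arg(mode)
  above <- normalized > flank_threshold
  if (mode == "comparative") return(above)
  core_cols <- offsets >= core[1] & offsets <= core[2]
  above[, core_cols] <- TRUE
  above
}

# Mean normalized occurrence over chosen offsets, per k-mer.
# counts: 4^k x offsets site-count matrix; chosen: logical same shape;
# distal: per-site distal mean per k-mer; n: site count.
mean_norm_occurrence <- function(counts, chosen, distal, n, eps) {
  norm <- (counts / n) / (distal + eps)
  num <- rowSums(norm * chosen)
  den <- rowSums(chosen)
  ifelse(den > 0, num / den, NA_real_)
}

#' PEKA enrichment scores for all k-mers
#'
#' For each k-mer the mean normalized occurrence over its chosen offsets
#' at tXn is compared with the same quantity computed around control
#' groups of sites resampled from the background (oXn) set; the score is
#' the z-score of the tXn value against the control distribution. K-mers
#' are ranked by score (ties broken lexicographically).
#'
#' @param genome genome.
#' @param txn data.table(chrom, strand, pos) of thresholded crosslinks.
#' @param oxn data.table(chrom, strand, pos) of background crosslinks.
#' @param k k-mer length.
#' @param n_controls number of control groups (default 100).
#' @param seed RNG seed governing all control draws.
#' @param flank_threshold offset-selection threshold.
#' @param mode offset-selection mode (see [select_positions()]).
#' @return `cs_peka`: list with `table` (data.table kmer, m, ctrl_mean,
#'   ctrl_sd, score, rank), `chosen` matrix, `profile`, `n_controls`,
#'   `seed`.
#' @export
peka_score <- function(genome, txn, oxn, k = 6, n_controls = 100,
                       seed = 42, flank_threshold = 2,
                       mode = c("standard", "comparative")) {
  mode <- match.arg(mode)
  prof <- positional_profile(genome, txn, k = k)
  normalized <- normalize_profile(prof)
  chosen <- select_positions(normalized, prof$offsets, flank_threshold,
                             mode = mode)
  m <- mean_norm_occurrence(prof$prox_counts, chosen, prof$distal_mean,
                            prof$n_sites, prof$eps)
  ctrl <- control_statistics(genome, oxn, chosen, n_txn = prof$n_sites,
                             k = k, n_controls = n_controls, seed = seed)
  score <- (m - ctrl$mean) / ctrl$sd
  score[ctrl$sd == 0 & !is.na(m) & m == ctrl$mean] <- 0
  score[ctrl$sd == 0 & !is.na(m) & m != ctrl$mean] <-
    sign(m - ctrl$mean)[ctrl$sd == 0 & !is.na(m) & m != ctrl$mean] * Inf
  tab <- data.table(kmer = prof$kmers, m = m,
                    ctrl_mean = ctrl$mean, ctrl_sd = ctrl$sd, score = score)
  tab[, rank := frank(-score, ties.method = "first",
                      na.last = "keep")]
  setorder(tab, rank, kmer, na.last = TRUE)
  structure(list(table = tab, chosen = chosen, profile = prof,
                 normalized = normalized, n_controls = n_controls,
                 seed = seed),
            class = "cs_peka")
}

# Control-group mean/sd of the per-kmer mean normalized occurrence.
# Each group samples n_txn sites from the background set without
# replacement (with replacement, with a message, when the background is
# smaller than the foreground).
control_statistics <- function(genome, oxn, chosen, n_txn, k, n_controls,
                               seed) {
  oxn <- as.data.table(oxn)
  prof_bg <- positional_profile(genome, oxn, k = k, keep_codes = TRUE)
  code <- prof_bg$codes$code
  lo <- prof_bg$codes$lo
  nbg <- prof_bg$n_sites
  replace <- nbg < n_txn
  if (replace) message("background smaller than foreground; sampling ",
                       "control groups with replacement")
  nbins <- 4L^k
  prox_cols <- (-40:40) - lo + 1L
  dist_cols <- c((-150):(-100), 100:150) - lo + 1L
  use_col <- which(colSums(chosen) > 0)
  ms <- matrix(NA_real_, nbins, n_controls)
  set.seed(seed)
  for (g in seq_len(n_controls)) {
    rows <- sample.int(nbg, n_txn, replace = replace)
    pc <- matrix(0L, nbins, ncol(chosen))
    pc[, use_col] <- count_kmers_at(code, rows, prox_cols[use_col], nbins)
    dc <- count_kmers_at(code, rows, dist_cols, nbins)
    distal <- rowSums(dc) / length(dist_cols) / n_txn
    ms[, g] <- mean_norm_occurrence(pc, chosen, distal, n_txn,
                                    0.5 / n_txn)
  }
  list(mean = rowMeans(ms), sd = apply(ms, 1, sd), samples = ms)
}

#' Comparative PEKA across samples against a fixed reference
#'
#' Iteration 1 runs PEKA on the reference tXn/oXn in comparative mode
#' (offset threshold 4) and freezes, per k-mer: the chosen offsets, the
#' distal normalization means, and the control-group statistics. Iteration
#' 2 computes, for each case sample, only the k-mer occurrence around its
#' own tXn at the frozen offsets, normalizes with the frozen distal means,
#' and expresses enrichment and a z-score relative to the frozen control
#' statistics. This isolates between-sample differences in motif
#' occurrence around tXn from normalization differences.
#'
#' @param genome genome.
#' @param ref_txn,ref_oxn reference site tables (e.g. merged WT
#'   replicates).
#' @param case_txn named list of per-sample tXn tables.
#' @param k k-mer length.
#' @param n_controls,seed control sampling.
#' @param flank_threshold iteration-1 offset threshold (default 4).
#' @param min_sites case samples with fewer tXn are excluded with a
#'   warning (default 100).
#' @return `cs_comparative`: list(reference = `cs_peka`, samples =
#'   data.table(sample_id, kmer, m, enrichment, log2_enrichment, score)).
#' @export
comparative_peka <- function(genome, ref_txn, ref_oxn, case_txn, k = 6,
                             n_controls = 100, seed = 42,
                             flank_threshold = 4, min_sites = 100) {
  ref <- peka_score(genome, ref_txn, ref_oxn, k = k,
                    n_controls = n_controls, seed = seed,
                    flank_threshold = flank_threshold,
                    mode = "comparative")
  eps <- ref$profile$eps
  distal <- ref$profile$distal_mean
  chosen <- ref$chosen
  res <- list()
  for (sid in names(case_txn)) {
    txn <- as.data.table(case_txn[[sid]])
    if (nrow(txn) < min_sites) {
      warning("sample ", sid, " has fewer than ", min_sites,
              " tXn; excluded")
      next
    }
    prof <- positional_profile(genome, txn, k = k)
    m <- mean_norm_occurrence(prof$prox_counts, chosen, distal,
                              prof$n_sites, eps)
    enr <- (m + eps) / (ref$table$ctrl_mean[match(prof$kmers,
                                                  ref$table$kmer)] + eps)
    ctab <- ref$table[match(prof$kmers, ref$table$kmer)]
    res[[sid]] <- data.table(sample_id = sid, kmer = prof$kmers, m = m,
                             enrichment = (m + eps) / (ctab$ctrl_mean + eps),
                             log2_enrichment =
                               log2((m + eps) / (ctab$ctrl_mean + eps)),
                             score = (m - ctab$ctrl_mean) / ctab$ctrl_sd)
  }
  structure(list(reference = ref, samples = rbindlist(res)),
            class = "cs_comparative")
}

#' Relative motif enrichment table across variants
#'
#' K-mers are ranked by their mean PEKA score across variants
#' (replicate-averaged); the top `top_n` are kept. Heatmap values are the
#' replicate-averaged log2 enrichments with the per-motif mean across
#' variants subtracted, so every row sums to zero. Rows are ordered by the
#' condensation gradient: mean relative enrichment in the
#' condensation-capable variants minus the deficient ones, descending.
#'
#' @param comp `cs_comparative`.
#' @param manifest manifest with sample_id and variant columns.
#' @param top_n number of motifs (default 20).
#' @param capable,deficient variant labels anchoring the gradient.
#' @return list(matrix [motif x variant, rows zero-mean], scores
#'   data.table, order).
#' @export
relative_enrichment_table <- function(comp, manifest, top_n = 20,
                                      capable = c("WT", "G335A"),
                                      deficient = c("A326P", "316del346")) {
  man <- as.data.table(manifest)
  tab <- merge(comp$samples, man[, .(sample_id, variant)], by = "sample_id")
  byvar <- tab[, .(log2_enrichment = mean(log2_enrichment),
                   score = mean(score)), by = .(variant, kmer)]
  kstat <- byvar[, .(mean_score = mean(score)), by = kmer]
  kstat <- kstat[is.finite(mean_score)]  # kmers never enriched at the
                                         # reference have no fixed offsets
  setorder(kstat, -mean_score, kmer)
  top <- head(kstat$kmer, top_n)
  wide <- dcast(byvar[kmer %in% top], kmer ~ variant,
                value.var = "log2_enrichment")
  mat <- as.matrix(wide, rownames = "kmer")
  mat <- mat - rowMeans(mat)
  cap <- intersect(capable, colnames(mat))
  def <- intersect(deficient, colnames(mat))
  grad <- rowMeans(mat[, cap, drop = FALSE]) -
    rowMeans(mat[, def, drop = FALSE])
  mat <- mat[order(-grad), , drop = FALSE]
  list(matrix = mat, scores = kstat[kmer %in% top],
       gradient = sort(grad, decreasing = TRUE))
}

#' Group motifs by condensation sensitivity
#'
#' The depletion factor of each motif is the ratio of its mean linear
#' enrichment in condensation-capable variants to condensation-deficient
#' ones. Factors above 1.3 define the most condensation-sensitive group
#' (labelled YG-containing [UG]n), factors in (1.1, 1.3] the modestly
#' sensitive group (YA), and the rest the insensitive group (AA). A
#' warning is emitted when a group-1 motif lacks UG-repeat character.
#'
#' @param mat motif x variant matrix of relative log2 enrichments.
#' @param capable,deficient variant labels.
#' @return data.table(kmer, factor, group) with group in
#'   c("YG", "YA", "AA").
#' @export
group_motifs <- function(mat, capable = c("WT", "G335A"),
                         deficient = c("A326P", "316del346")) {
  cap <- intersect(capable, colnames(mat))
  def <- intersect(deficient, colnames(mat))
  lin <- 2^mat
  fac <- rowMeans(lin[, cap, drop = FALSE]) /
    rowMeans(lin[, def, drop = FALSE])
  grp <- fifelse(fac > 1.3, "YG", fifelse(fac > 1.1, "YA", "AA"))
  out <- data.table(kmer = rownames(mat), factor = fac, group = grp)
  ug <- grepl("TG|GT", out$kmer)
  if (any(out$group == "YG" & !ug)) {
    warning("group-1 motif without UG-repeat character: ",
            out$kmer[out$group == "YG" & !ug][1])
  }
  out[]
}

#' Metaprofile of motif coverage around crosslink events
#'
#' Each crosslink site contributes its cDNA count (capped at `cap`) at
#' every offset where a motif from the set starts in its oriented window;
#' the per-offset sums are divided by the total capped count, expressed in
#' percent and smoothed with a rolling mean.
#'
#' @param genome genome.
#' @param sites data.table(chrom, strand, pos, count).
#' @param motifs character vector of k-mers (one common length).
#' @param window offset window (default c(-150, 150)).
#' @param cap per-site cDNA count cap (default 20).
#' @param smooth rolling-mean window (default 6; 1 disables smoothing).
#' @return data.table(offset, percent).
#' @export
metaprofile_coverage <- function(genome, sites, motifs,
                                 window = c(-150, 150), cap = 20,
                                 smooth = 6) {
  if (!length(motifs)) stop("motif set is empty")
  k <- nchar(motifs[1])
  stopifnot(all(nchar(motifs) == k))
  sites <- as.data.table(sites)
  win <- extract_oriented_window(genome, sites$chrom, sites$pos,
                                 sites$strand,
                                 c(window[1], window[2] + k - 1L))
  keep <- !attr(win, "truncated")
  win <- win[keep]
  wt <- pmin(sites$count[keep], cap)
  code <- kmer_code_matrix(win, k)
  motif_codes <- match(motifs, all_kmers(k))
  hit <- matrix(code %in% motif_codes, nrow = nrow(code))
  cov <- colSums(hit * wt) / sum(wt) * 100
  offs <- window[1]:window[2]
  if (smooth > 1) {
    cov <- rolling_mean(cov, smooth)
    offs <- offs[seq_along(cov)] + (smooth - 1L) %/% 2L
  }
  data.table(offset = offs, percent = cov)
}
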