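# Generators for synthetic genomes, annotations, crosslink tracks,
# 3'-end reads, dPAU profiles, FRAP traces and foci stacks, each carrying
# the planted ground truth that downstream tests compare against. All
# generators are pure functions of (parameters, seed).

#' Canonical UG-repeat-derived motif families
#'
#' Three families of 6-mers emulating the UG-dinucleotide-repeat motifs
#' distinguished by the substitution interrupting the repeat (Y = C/U):
#' YG-containing, YA-containing and AA-containing [UG]n (DNA alphabet).
#' @export
cs_motif_groups <- list(
  YG = c("TGTGTG", "GTGTGT", "TGCGTG", "GTGCGT", "CGTGTG", "TGTGCG",
         "GCGTGT", "CGTGCG"),
  YA = c("TGTGTA", "GTGTAT", "TGTATG", "TATGTG", "TGTGCA", "GTGCAT",
         "GCATGT", "CATGTG"),
  AA = c("TGTGAA", "GTGAAT", "TGAATG", "GAATGT", "AATGTG", "ATGAAT",
         "AATGAA", "GAAATG")
)

#' Default per-variant binding scale factors at CR-dependent regions
#'
#' Monotone gradient from condensation-promoting to condensation-deficient
#' variants; all configurable in the simulators.
#' @export
cs_variant_scales <- c(WT = 1.0, G335A = 1.15, G294A = 0.95, Q331K = 0.8,
                       M337P = 0.65, A326P = 0.5, "316del346" = 0.5)

random_dna <- function(n, gc = 0.45) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

splice_seq <- function(seq, at, insert) {
  # overwrite seq at 1-based position `at` with `insert`
  paste0(substr(seq, 1, at - 1L), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

#' Default region specification for the planted motif-region landscape
#'
#' Covers the four length classes with YG, YA and AA motif content at low
#' to high density. Long (>100 nt) YG/YA regions are CR-dependent (their
#' crosslink signal scales with the variant's condensation capacity);
#' short dense AA regions are CR-independent.
#' @param n_each regions per spec row.
#' @export
default_region_spec <- function(n_each = 8) {
  spec <- data.table(
    group = c("YG", "YA", "AA", "YG", "YA", "AA",
              "YG", "YA", "AA", "YG", "YA", "AA"),
    length = c(24L, 24L, 24L, 48L, 48L, 48L, 80L, 80L, 80L, 160L, 160L, 160L),
    density = c(0.8, 0.5, 0.8, 0.6, 0.4, 0.6, 0.5, 0.3, 0.5, 0.4, 0.3, 0.4),
    cr_dependent = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  spec[rep(seq_len(.N), each = n_each)]
}

#' Simulate a genome with gene annotation and planted motif regions
#'
#' Background sequence is i.i.d. at the requested GC content; motif
#' regions are planted by overwriting intronic sequence with evenly
#' spaced motifs from the requested family at the requested density.
#' Regions are placed in introns, separated by at least 200 nt.
#'
#' @param n_contigs,contig_len,gc,n_genes genome layout parameters.
#' @param region_spec data.table(group, length, density, cr_dependent);
#'   one planted region per row (see [default_region_spec()]).
#' @param variant_scales named per-variant scale factors applied at
#'   CR-dependent regions (CR-independent regions always scale 1).
#' @param utr3_len 3'UTR length carved from the last exon.
#' @param seed RNG seed.
#' @return list(genome [DNAStringSet], annotation [cs_annotation],
#'   truth [data.table of planted regions with genomic coordinates,
#'   realized density and per-variant scales]).
#' @export
simulate_genome_and_regions <- function(n_contigs = 1, contig_len = 200000,
                                        gc = 0.45, n_genes = 8,
                                        region_spec = default_region_spec(),
                                        variant_scales = cs_variant_scales,
                                        utr3_len = 1000, seed = 1) {
  region_spec <- as.data.table(region_spec)
  if (any(region_spec$density > 1)) stop("motif density cannot exceed 1")
  if (any(region_spec$density <= 0)) stop("motif density must be positive")
  set.seed(seed)
  contigs <- setNames(vapply(seq_len(n_contigs),
                             function(i) random_dna(contig_len, gc), ""),
                      paste0("chr", seq_len(n_contigs)))
  # gene layout: genes round-robin across contigs, three exons with two
  # introns, last-exon 3'UTR
  per_contig <- ceiling(n_genes / n_contigs)
  slot <- contig_len %/% (per_contig + 1L)
  gene_len <- min(18000L, slot - 1000L)
  exon_len <- 1200L
  genes <- vector("list", n_genes)
  exons <- list(); utr3 <- list()
  intron_slots <- list()
  for (i in seq_len(n_genes)) {
    contig <- paste0("chr", (i - 1L) %% n_contigs + 1L)
    islot <- (i - 1L) %/% n_contigs
    gstart <- islot * slot + 500L
    gend <- gstart + gene_len - 1L
    strand <- if (i %% 2L == 1L) "+" else "-"
    gid <- sprintf("gene%02d", i)
    e1 <- c(gstart, gstart + exon_len - 1L)
    e2 <- c(gstart + (gene_len - exon_len) %/% 2L, 0L)
    e2[2] <- e2[1] + exon_len - 1L
    e3 <- c(gend - exon_len + 1L, gend)
    genes[[i]] <- data.table(gene_id = gid, chrom = contig,
                             start = gstart, end = gend, strand = strand)
    exons[[gid]] <- GenomicRanges::GRanges(contig,
      IRanges::IRanges(c(e1[1], e2[1], e3[1]), c(e1[2], e2[2], e3[2])),
      strand = strand)
    u <- if (strand == "+") c(gend - utr3_len + 1L, gend)
         else c(gstart, gstart + utr3_len - 1L)
    utr3[[gid]] <- GenomicRanges::GRanges(contig,
      IRanges::IRanges(u[1], u[2]), strand = strand)
    intron_slots[[gid]] <- data.table(
      chrom = contig, strand = strand, gene_id = gid,
      start = c(e1[2] + 1L, e2[2] + 1L), end = c(e2[1] - 1L, e3[1] - 1L))
  }
  gdt <- rbindlist(genes)
  ggr <- GenomicRanges::GRanges(gdt$chrom,
                                IRanges::IRanges(gdt$start, gdt$end),
                                strand = gdt$strand, gene_id = gdt$gene_id)
  introns <- rbindlist(intron_slots)
  # place planted regions into introns with >= 200 nt separation
  introns[, cursor := start + 100L]
  truth <- vector("list", nrow(region_spec))
  irow <- 1L
  for (r in seq_len(nrow(region_spec))) {
    L <- region_spec$length[r]
    placed <- FALSE
    for (tries in seq_len(nrow(introns))) {
      cand <- (irow - 1L) %% nrow(introns) + 1L
      irow <- irow + 1L
      if (introns$cursor[cand] + L + 200L < introns$end[cand]) {
        rs <- introns$cursor[cand]
        introns[cand, cursor := rs + L + 200L]
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("region spec does not fit into the intron space")
    grp <- region_spec$group[r]
    d <- region_spec$density[r]
    n_mot <- max(1L, round(d * L / 6))
    starts <- if (n_mot == 1L) 0L else unique(round(seq(0, L - 6L,
                                                        length.out = n_mot)))
    motifs <- sample(cs_motif_groups[[grp]], length(starts), replace = TRUE)
    contig <- introns$chrom[cand]
    strand <- introns$strand[cand]
    seqs <- contigs[[contig]]
    for (j in seq_along(starts)) {
      gpos <- if (strand == "+") rs + starts[j]
              else rs + L - 6L - starts[j]
      ins <- if (strand == "+") motifs[j] else revcomp_chr(motifs[j])
      seqs <- splice_seq(seqs, gpos, ins)
    }
    contigs[[contig]] <- seqs
    covered <- length(unique(unlist(lapply(starts, function(s) s:(s + 5L)))))
    truth[[r]] <- data.table(
      region_id = sprintf("planted%03d", r), chrom = contig,
      strand = strand, start = rs, end = rs + L - 1L,
      gene_id = introns$gene_id[cand], group = grp, length = L,
      density = covered / L,
      cr_dependent = region_spec$cr_dependent[r])
  }
  truth <- rbindlist(truth)
  for (v in names(variant_scales)) {
    truth[, (paste0("scale_", v)) :=
            fifelse(cr_dependent, variant_scales[[v]], 1)]
  }
  genome <- Biostrings::DNAStringSet(contigs)
  ann <- gene_annotation(ggr, exons, utr3)
  list(genome = genome, annotation = ann, truth = truth)
}

#' Simulate per-sample crosslink tracks over a planted region landscape
#'
#' Expected signal over a planted region is proportional to
#' depth x region length x the variant's scale factor at that region;
#' crosslink sites sit at the planted motif starts with Poisson counts.
#' Background crosslinks are scattered Poisson-uniformly over gene spans
#' with count 1 each (aggregated when positions collide).
#'
#' @param truth planted-region truth from [simulate_genome_and_regions()].
#' @param annotation matching annotation (for background placement).
#' @param manifest manifest rows to simulate (sample_id, variant).
#' @param depth expected signal cDNA count per sample at scale 1.
#' @param background_frac expected background count as a fraction of
#'   depth.
#' @param noise_sd lognormal sd of per-region per-sample depth jitter
#'   (0 = none).
#' @param seed RNG seed.
#' @return named list of `cs_track`.
#' @export
simulate_crosslink_tracks <- function(truth, annotation, manifest,
                                      depth = 1e5, background_frac = 0.3,
                                      noise_sd = 0, seed = 1) {
  set.seed(seed)
  man <- as.data.table(manifest)
  need <- paste0("scale_", unique(man$variant))
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop("truth lacks scale factors for variant(s): ",
                         paste(sub("scale_", "", miss), collapse = ", "))
  if (depth == 0) {
    out <- lapply(man$sample_id, function(sid)
      crosslink_track(data.table(chrom = character(), pos = integer(),
                                 strand = character(), count = integer()),
                      sid))
    names(out) <- man$sample_id
    return(out)
  }
  gspan <- as.data.table(GenomicRanges::granges(annotation$genes))
  wl <- truth$length / sum(truth$length)
  tracks <- list()
  for (s in seq_len(nrow(man))) {
    sid <- man$sample_id[s]
    scales <- truth[[paste0("scale_", man$variant[s])]]
    rows <- list()
    for (r in seq_len(nrow(truth))) {
      L <- truth$length[r]
      # crosslinks at every region nucleotide so that peak density (and
      # hence peak calling) responds to the variant's binding scale
      jit <- if (noise_sd > 0) exp(rnorm(1, 0, noise_sd)) else 1
      lam <- depth * wl[r] * scales[r] * jit / L
      cnt <- rpois(L, lam)
      keep <- cnt > 0
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.table(
          chrom = truth$chrom[r],
          pos = truth$start[r] + (0:(L - 1L))[keep],
          strand = truth$strand[r], count = cnt[keep])
      }
    }
    n_bg <- rpois(1, depth * background_frac)
    if (n_bg > 0) {
      gi <- sample.int(nrow(gspan), n_bg, replace = TRUE,
                       prob = gspan$width)
      bpos <- as.integer(gspan$start[gi] +
                           floor(runif(n_bg) * gspan$width[gi]))
      bg <- data.table(chrom = as.character(gspan$seqnames[gi]),
                       pos = bpos,
                       strand = as.character(gspan$strand[gi]),
                       count = 1L)
      # weak background crosslinking sits outside the strongly bound
      # planted regions, so it does not dilute their peak statistics
      inside <- bg[, .(chrom, strand, pos, idx = .I)][
        truth, on = .(chrom, strand, pos >= start, pos <= end),
        nomatch = NULL]$idx
      if (length(inside)) bg <- bg[-inside]
      rows[[length(rows) + 1L]] <- bg
    }
    tracks[[sid]] <- crosslink_track(rbindlist(rows), sid)
  }
  tracks
}

#' Plant polyA sites and internal-priming decoys into a genome
#'
#' Each gene with a 3'UTR receives a proximal and a distal PAS 400 nt
#' apart inside the UTR; a canonical polyA signal (AATAAA) is written
#' 25-20 nt upstream of each site and the 20 nt downstream are rewritten
#' with a controlled A content. One internal-priming decoy per gene is
#' written inside the gene body as a genomic A stretch.
#'
#' @param genome genome from [simulate_genome_and_regions()].
#' @param annotation matching annotation.
#' @param frac_dependent fraction of genes whose rescue response is
#'   CR-dependent.
#' @param downstream_a_content A fraction written downstream of true PAS
#'   (default 0.25; must be <= 0.5 so true sites survive the canonical
#'   filter).
#' @param seed RNG seed.
#' @return list(genome [modified], truth data.table(gene_id, chrom,
#'   strand, prox_pos, dist_pos, decoy_pos, group)).
#' @export
plant_pas <- function(genome, annotation, frac_dependent = 0.4,
                      downstream_a_content = 0.25, seed = 1) {
  set.seed(seed)
  contigs <- genome_as_character(genome)
  mk_downstream <- function() {
    nA <- round(20 * downstream_a_content)
    paste(sample(c(rep("A", nA), sample(c("C", "G", "T"), 20 - nA,
                                        replace = TRUE))), collapse = "")
  }
  write_site <- function(contig, pos, strand) {
    # canonical signal at transcript offsets -25..-20, controlled
    # downstream content at +1..+20
    if (strand == "+") {
      contigs[[contig]] <<- splice_seq(contigs[[contig]], pos - 25L, "AATAAA")
      contigs[[contig]] <<- splice_seq(contigs[[contig]], pos + 1L,
                                       mk_downstream())
    } else {
      contigs[[contig]] <<- splice_seq(contigs[[contig]], pos + 20L,
                                       revcomp_chr("AATAAA"))
      contigs[[contig]] <<- splice_seq(contigs[[contig]], pos - 20L,
                                       revcomp_chr(mk_downstream()))
    }
  }
  rows <- list()
  gids <- names(annotation$utr3)
  dep <- rep(FALSE, length(gids))
  if (length(gids)) {
    dep[sample.int(length(gids), round(frac_dependent * length(gids)))] <- TRUE
  }
  for (i in seq_along(gids)) {
    gid <- gids[i]
    u <- annotation$utr3[[gid]][1]
    contig <- as.character(GenomicRanges::seqnames(u))
    strand <- as.character(GenomicRanges::strand(u))
    us <- GenomicRanges::start(u); ue <- GenomicRanges::end(u)
    if (strand == "+") {
      prox <- us + 200L; dist <- us + 600L
    } else {
      prox <- ue - 200L; dist <- ue - 600L
    }
    write_site(contig, prox, strand)
    write_site(contig, dist, strand)
    g <- annotation$genes[annotation$genes$gene_id == gid]
    mid <- (GenomicRanges::start(g) + GenomicRanges::end(g)) %/% 2L
    decoy <- mid + sample(-500:500, 1)
    # A-rich stretch spanning transcript offsets -2..+22 of the decoy
    if (strand == "+") {
      contigs[[contig]] <- splice_seq(contigs[[contig]], decoy - 2L,
                                      strrep("A", 25L))
    } else {
      contigs[[contig]] <- splice_seq(contigs[[contig]], decoy - 22L,
                                      strrep("T", 25L))
    }
    rows[[i]] <- data.table(gene_id = gid, chrom = contig, strand = strand,
                            prox_pos = prox, dist_pos = dist,
                            decoy_pos = decoy,
                            group = fifelse(dep[i], "CR-dependent",
                                            "CR-independent"))
  }
  list(genome = Biostrings::DNAStringSet(contigs), truth = rbindlist(rows))
}

#' Default proximal-usage model for planted PAS
#'
#' Proximal-site usage is 0.75 under knockdown; rescue moves it toward
#' 0.35 with full efficiency for every variant at CR-independent genes,
#' and with a condensation-graded efficiency at CR-dependent genes.
#' @param variant,condition,group vectors (recycled).
#' @param rescue_efficiency named per-variant efficiency at CR-dependent
#'   genes.
#' @export
pas_usage_model <- function(variant, condition, group,
                            rescue_efficiency = c(WT = 1, G335A = 1,
                                                  G294A = 0.9, Q331K = 0.8,
                                                  M337P = 0.4, A326P = 0.2,
                                                  "316del346" = 0.1)) {
  kd <- 0.75; full <- 0.35
  n <- max(length(variant), length(condition), length(group))
  variant <- rep_len(variant, n)
  condition <- rep_len(condition, n)
  group <- rep_len(group, n)
  eff <- fifelse(group == "CR-independent", 1,
                 unname(rescue_efficiency[variant]))
  fifelse(condition == "knockdown", kd, kd - (kd - full) * eff)
}

#' Simulate 3'-end sequencing read ends from planted PAS
#'
#' Read 3' ends jitter uniformly within +/- `jitter` nt of the true PAS;
#' a configured fraction carries untemplated A tails of length >= 5.
#' Decoy (internal-priming) reads are emitted at the planted genomic
#' A-stretches with apparent tails >= 5 templated by the genome.
#'
#' @param pas_truth truth table from [plant_pas()].
#' @param manifest manifest rows (sample_id, variant, condition).
#' @param depth expected reads per gene per sample.
#' @param jitter maximal read-end offset (default 10).
#' @param tail_frac fraction of true-PAS reads with tails >= 5.
#' @param decoy_frac decoy reads as a fraction of true reads.
#' @param seed RNG seed.
#' @return data.table(sample_id, chrom, pos, strand, tail).
#' @export
simulate_threeprime_reads <- function(pas_truth, manifest, depth = 1000,
                                      jitter = 10, tail_frac = 0.85,
                                      decoy_frac = 0.05, seed = 1) {
  set.seed(seed)
  man <- as.data.table(manifest)
  out <- list()
  for (s in seq_len(nrow(man))) {
    sid <- man$sample_id[s]
    p_prox <- pas_usage_model(man$variant[s], man$condition[s],
                              pas_truth$group)
    for (g in seq_len(nrow(pas_truth))) {
      n <- rpois(1, depth)
      if (n == 0) next
      n_prox <- rbinom(1, n, p_prox[g])
      mk <- function(center, m) {
        if (m == 0) return(NULL)
        pos <- center + sample(seq(-jitter, jitter), m, replace = TRUE)
        tail <- ifelse(runif(m) < tail_frac, 5L + rpois(m, 4),
                       rpois(m, 1.5))
        data.table(sample_id = sid, chrom = pas_truth$chrom[g],
                   pos = as.integer(pos), strand = pas_truth$strand[g],
                   tail = as.integer(tail))
      }
      out[[length(out) + 1L]] <- mk(pas_truth$prox_pos[g], n_prox)
      out[[length(out) + 1L]] <- mk(pas_truth$dist_pos[g], n - n_prox)
      n_dec <- rpois(1, depth * decoy_frac)
      if (n_dec > 0) {
        out[[length(out) + 1L]] <- data.table(
          sample_id = sid, chrom = pas_truth$chrom[g],
          pos = pas_truth$decoy_pos[g] +
            sample(seq(-2L, 2L), n_dec, replace = TRUE),
          strand = pas_truth$strand[g],
          tail = 5L + rpois(n_dec, 4))
      }
    }
  }
  rbindlist(out)
}

#' Simulate per-gene dPAU profiles across rescue variants
#'
#' CR-independent genes show the full wild-type usage change for every
#' variant; CR-dependent genes show it attenuated along the condensation
#' gradient. Gaussian noise is added to every entry and each gene's raw
#' direction is randomized (orientation is recovered downstream).
#'
#' @param n_independent,n_dependent gene counts (defaults 82 and 54).
#' @param effect wild-type dPAU magnitude (default 0.4).
#' @param noise_sd Gaussian noise sd (default 0.05).
#' @param attenuation named per-variant dPAU multipliers for
#'   CR-dependent genes.
#' @param seed RNG seed.
#' @return list(dpau [gene x variant matrix], labels [character],
#'   genes [ids]).
#' @export
simulate_dpau_profiles <- function(n_independent = 82, n_dependent = 54,
                                   effect = 0.4, noise_sd = 0.05,
                                   attenuation = c(WT = 1, G335A = 1,
                                                   G294A = 0.9,
                                                   Q331K = 0.8, M337P = 0.4,
                                                   A326P = 0.2,
                                                   "316del346" = 0.1),
                                   seed = 1) {
  set.seed(seed)
  n <- n_independent + n_dependent
  variants <- names(attenuation)
  mu <- matrix(effect, n, length(variants),
               dimnames = list(NULL, variants))
  if (n_dependent > 0) {
    dep_rows <- (n_independent + 1):n
    mu[dep_rows, ] <- matrix(effect * attenuation, n_dependent,
                             length(variants), byrow = TRUE)
  }
  sign <- sample(c(-1, 1), n, replace = TRUE)
  dpau <- (mu + matrix(rnorm(n * length(variants), 0, noise_sd), n)) * sign
  rownames(dpau) <- sprintf("gene%03d", seq_len(n))
  list(dpau = dpau,
       labels = rep(c("CR-independent", "CR-dependent"),
                    c(n_independent, n_dependent)),
       genes = rownames(dpau))
}

#' Simulate a FRAP trace
#'
#' Post-bleach recovery follows `Y(t) = plateau - (plateau - initial) *
#' exp(-k t)` plus Gaussian noise; the trace carries `n_prebleach`
#' pre-bleach points at intensity 1 and a constant (optionally drifting)
#' control ROI.
#'
#' @param k rate constant (1/s).
#' @param plateau,initial normalized plateau and first post-bleach value.
#' @param noise_sd Gaussian noise sd.
#' @param n_points total number of frames.
#' @param interval frame interval in seconds (default 0.326).
#' @param n_prebleach pre-bleach frames (default 5).
#' @param scale arbitrary intensity scale factor.
#' @param control_drift multiplicative linear drift of the control ROI
#'   over the trace (e.g. -0.2 for 20% decay).
#' @param seed RNG seed.
#' @return list(times, intensity, control, bleach_index, truth).
#' @export
simulate_frap <- function(k = 0.05, plateau = 0.8, initial = 0.2,
                          noise_sd = 0.01, n_points = 200,
                          interval = 0.326, n_prebleach = 5, scale = 1000,
                          control_drift = 0, seed = 1) {
  set.seed(seed)
  times <- (seq_len(n_points) - 1) * interval
  bleach_index <- n_prebleach + 1L
  tpost <- times[bleach_index:n_points] - times[bleach_index]
  y <- c(rep(1, n_prebleach),
         plateau - (plateau - initial) * exp(-k * tpost))
  drift <- 1 + control_drift * (seq_len(n_points) - 1) / (n_points - 1)
  control <- scale * drift
  intensity <- scale * y * drift + rnorm(n_points, 0, noise_sd * scale)
  list(times = times, intensity = intensity, control = control,
       bleach_index = bleach_index,
       truth = list(k = k, plateau = plateau, initial = initial))
}

#' Simulate a 3D intensity stack with planted nuclear foci
#'
#' A circular nuclear mask sits at the image center; foci are Gaussian
#' blobs of the given amplitude over a flat background, with centers
#' inside the mask and pairwise separated.
#'
#' @param dims c(nx, ny, nz).
#' @param n_foci number of planted foci.
#' @param amplitude focus peak intensity as a multiple of background.
#' @param sigma Gaussian radius (voxels).
#' @param background flat background intensity.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return list(stack [3D array], mask [2D logical], truth
#'   data.table(x, y, z, amplitude)).
#' @export
simulate_foci_stack <- function(dims = c(48, 48, 8), n_foci = 3,
                                amplitude = 5, sigma = 1.2,
                                background = 100, noise_sd = 2, seed = 1) {
  set.seed(seed)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rad <- min(nx, ny) / 2 - 2
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  mask <- (xs - cx)^2 + (ys - cy)^2 <= rad^2
  stack <- array(background, dims)
  centers <- list()
  min_sep <- 6
  guard <- 0L
  while (length(centers) < n_foci && guard < 10000L) {
    guard <- guard + 1L
    cand <- c(runif(1, cx - rad + 4, cx + rad - 4),
              runif(1, cy - rad + 4, cy + rad - 4),
              runif(1, 2, nz - 1))
    if (!mask[round(cand[1]), round(cand[2])]) next
    ok <- all(vapply(centers, function(cc)
      sqrt(sum((cc[1:2] - cand[1:2])^2)) >= min_sep, TRUE))
    if (ok) centers[[length(centers) + 1L]] <- cand
  }
  if (length(centers) < n_foci) stop("could not place all foci")
  for (cc in centers) {
    for (z in seq_len(nz)) {
      g <- exp(-(((xs - cc[1])^2 + (ys - cc[2])^2) / (2 * sigma^2) +
                   (z - cc[3])^2 / (2 * sigma^2)))
      stack[, , z] <- stack[, , z] + amplitude * background * g
    }
  }
  stack <- stack + array(rnorm(prod(dims), 0, noise_sd), dims)
  truth <- rbindlist(lapply(centers, function(cc)
    data.table(x = cc[1], y = cc[2], z = cc[3],
               amplitude = amplitude * background)))
  list(stack = stack, mask = mask, truth = truth)
}

#' Simulate classification-ready binding-region feature tables
#'
#' Emits synthetic binding-region rows (coordinates, length, motif counts
#' per family, density) populating all four length classes with varied
#' density and YG/YA/AA composition, for exercising the 36-class
#' classifier at scale without sequence-level simulation.
#'
#' @param n_per_bin regions per length bin (1-30, 31-60, 61-100, >100).
#'   Defaults are large enough that every density tercile cell exceeds
#'   twice its subclass cap, so all 36 classes are populated.
#' @param seed RNG seed.
#' @return data.table(chrom, strand, start, end, length, n_yg, n_ya,
#'   n_aa, density).
#' @export
simulate_region_features <- function(n_per_bin = c(18600, 18600, 18600,
                                                   9600), seed = 1) {
  set.seed(seed)
  bins <- list(c(1, 30), c(31, 60), c(61, 100), c(101, 400))
  out <- list()
  for (b in seq_along(bins)) {
    n <- n_per_bin[b]
    len <- sample(bins[[b]][1]:bins[[b]][2], n, replace = TRUE)
    density <- runif(n, 0.05, 1)
    total <- pmax(1L, round(density * len / 6))
    w <- matrix(rgamma(3 * n, shape = 0.7), n, 3)
    p <- w / rowSums(w)
    counts <- t(vapply(seq_len(n), function(i)
      as.integer(rmultinom(1, total[i], p[i, ])), integer(3)))
    start <- cumsum(len + 50L)
    out[[b]] <- data.table(chrom = paste0("chrS", b), strand = "+",
                           start = start, end = start + len - 1L,
                           length = len, n_yg = counts[, 1],
                           n_ya = counts[, 2], n_aa = counts[, 3],
                           density = density)
  }
  rbindlist(out)
}
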