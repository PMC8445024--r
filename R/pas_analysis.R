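# PolyA-site atlas construction from 3'-end read ends, internal-priming
# filtering, usage quantification, Dirichlet-multinomial /
# beta-binomial differential usage, and dPAU with representative and
# partner site selection.

#' The 16 alternative polyA-signal hexamers
#'
#' Searched (after the canonical AATAAA/ATTAAA) in the 40-nt window
#' upstream of a candidate PAS cluster.
#' @export
alternative_pas_signals <- c(
  "TATAAA", "AGTAAA", "AATACA", "CATAAA", "AATATA", "GATAAA", "AATGAA",
  "AAGAAA", "ACTAAA", "AATAGA", "AATAAT", "AACAAA", "ATTACA", "ATTATA",
  "AACAAG", "AATAAG")

#' Select read ends with untemplated polyA-tail evidence
#' @param read_ends data.table with a `tail` column.
#' @param min_tail minimum tail length (default 5).
#' @export
select_tail_evidence <- function(read_ends, min_tail = 5) {
  as.data.table(read_ends)[tail >= min_tail]
}

#' Build candidate PAS clusters from tail-supported read ends
#'
#' 3'-end positions at distance 1 on the same contig and strand are
#' merged; clusters supported by fewer than `min_reads` reads are
#' dropped. The representative position is the modal position (ties
#' resolved toward the 3' end in transcript orientation).
#'
#' @param read_ends data.table(chrom, pos, strand) — one row per read
#'   (sample identity is ignored; the atlas pools all samples).
#' @param min_reads minimum reads per cluster (default 2).
#' @return data.table(chrom, strand, pos [representative], n_reads,
#'   cluster_start, cluster_end).
#' @export
build_candidate_clusters <- function(read_ends, min_reads = 2) {
  cov <- as.data.table(read_ends)[, .(n = .N), by = .(chrom, strand, pos)]
  setorder(cov, chrom, strand, pos)
  cov[, cl := cumsum(c(TRUE, diff(pos) > 1L |
                         chrom[-1] != chrom[-.N] |
                         strand[-1] != strand[-.N]))]
  cl <- cov[, {
    best <- if (strand[1] == "+") max(pos[n == max(n)])
            else min(pos[n == max(n)])
    .(chrom = chrom[1], strand = strand[1], pos = best,
      n_reads = sum(n), cluster_start = min(pos), cluster_end = max(pos))
  }, by = cl][, cl := NULL]
  cl[n_reads >= min_reads][order(chrom, strand, pos)]
}

#' Classify polyA-signal category and filter internal-priming artifacts
#'
#' A content is the A fraction (transcript orientation) of the 20 nt
#' downstream of the cluster; the signal category comes from the 40-nt
#' upstream window: canonical (AATAAA/ATTAAA), alternative (one of the 16
#' listed hexamers) or none. Clusters with A content strictly above
#' 50% / 40% / 30% respectively are removed.
#'
#' @param genome genome.
#' @param clusters cluster table from [build_candidate_clusters()].
#' @param thresholds removal thresholds per category.
#' @return list(retained, removed): cluster tables with `signal` and
#'   `a_content` columns; clusters with clipped windows carry
#'   `clipped = TRUE`.
#' @export
internal_priming_filter <- function(genome, clusters,
                                    thresholds = c(canonical = 0.5,
                                                   alternative = 0.4,
                                                   none = 0.3)) {
  cl <- copy(as.data.table(clusters))
  if (!nrow(cl)) return(list(retained = cl, removed = cl))
  up <- extract_oriented_window(genome, cl$chrom, cl$pos, cl$strand,
                                c(-40, -1))
  down <- extract_oriented_window(genome, cl$chrom, cl$pos, cl$strand,
                                  c(1, 20))
  cl[, clipped := attr(up, "truncated") | attr(down, "truncated")]
  has_any <- function(seqs, pats) {
    hit <- rep(FALSE, length(seqs))
    for (p in pats) hit <- hit | grepl(p, seqs, fixed = TRUE)
    hit
  }
  cl[, signal := fifelse(has_any(up, c("AATAAA", "ATTAAA")), "canonical",
                         fifelse(has_any(up, alternative_pas_signals),
                                 "alternative", "none"))]
  cl[, a_content := (nchar(down) -
                       nchar(gsub("A", "", down, fixed = TRUE))) / 20]
  drop <- cl$a_content > thresholds[cl$signal]
  list(retained = cl[!drop], removed = cl[drop])
}

#' Finalize the PAS atlas: merge, pick indicative sites, assign genes
#'
#' Retained clusters within 200 nt (single linkage per contig/strand) are
#' merged and the cluster with the most reads kept as the indicative
#' site (ties resolved toward the 3' end in transcript orientation).
#' Indicative sites are assigned hierarchically to an annotated 3'UTR,
#' the 1 kb downstream of a 3'UTR, or a gene body; remaining intergenic
#' sites are discarded.
#'
#' @param clusters retained clusters from [internal_priming_filter()].
#' @param annotation `cs_annotation`.
#' @param merge_dist merge distance (default 200).
#' @param downstream_extent downstream window after the 3'UTR (default
#'   1000).
#' @return data.table(pas_id, chrom, strand, pos, n_reads, signal,
#'   a_content, gene_id, assignment).
#' @export
finalize_atlas <- function(clusters, annotation, merge_dist = 200,
                           downstream_extent = 1000) {
  cl <- as.data.table(clusters)
  if (!nrow(cl)) {
    return(data.table(pas_id = character(), chrom = character(),
                      strand = character(), pos = integer(),
                      n_reads = integer(), gene_id = character(),
                      assignment = character()))
  }
  setorder(cl, chrom, strand, pos)
  cl[, grp := cumsum(c(TRUE, diff(pos) > merge_dist |
                         chrom[-1] != chrom[-.N] |
                         strand[-1] != strand[-.N]))]
  ind <- cl[, {
    mx <- n_reads == max(n_reads)
    best <- if (strand[1] == "+") which(mx & pos == max(pos[mx]))
            else which(mx & pos == min(pos[mx]))
    .SD[best[1]]
  }, by = grp][, grp := NULL]
  # hierarchical gene assignment
  gr <- GenomicRanges::GRanges(ind$chrom, IRanges::IRanges(ind$pos, ind$pos),
                               strand = ind$strand)
  assign_first <- function(targets_grl) {
    res <- rep(NA_character_, length(gr))
    if (!length(targets_grl)) return(res)
    tg <- unlist(GenomicRanges::GRangesList(targets_grl))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, tg))
    res[S4Vectors::queryHits(hits)] <-
      names(tg)[S4Vectors::subjectHits(hits)]
    res
  }
  utr <- annotation$utr3
  a_utr <- assign_first(utr)
  down <- if (length(utr)) {
    endpoints <- lapply(names(utr), function(gid) {
      u <- utr[[gid]]
      str <- as.character(GenomicRanges::strand(u)[1])
      if (str == "+") {
        e <- max(GenomicRanges::end(u))
        GenomicRanges::GRanges(GenomicRanges::seqnames(u)[1],
                               IRanges::IRanges(e + 1L,
                                                e + downstream_extent),
                               strand = str)
      } else {
        s <- min(GenomicRanges::start(u))
        GenomicRanges::GRanges(GenomicRanges::seqnames(u)[1],
                               IRanges::IRanges(max(1L,
                                                    s - downstream_extent),
                                                s - 1L),
                               strand = str)
      }
    })
    names(endpoints) <- names(utr)
    assign_first(endpoints)
  } else rep(NA_character_, length(gr))
  gene_spans <- setNames(
    lapply(seq_along(annotation$genes), function(i)
      GenomicRanges::granges(annotation$genes[i])),
    annotation$genes$gene_id)
  a_gene <- assign_first(gene_spans)
  ind[, assignment := fifelse(!is.na(a_utr), "3'UTR",
                              fifelse(!is.na(down), "downstream1kb",
                                      fifelse(!is.na(a_gene), "gene_body",
                                              "intergenic")))]
  ind[, gene_id := fifelse(!is.na(a_utr), a_utr,
                           fifelse(!is.na(down), down, a_gene))]
  ind <- ind[assignment != "intergenic"]
  setorder(ind, chrom, strand, pos)
  ind[, pas_id := sprintf("%s:%s:%d", chrom, strand, pos)]
  ind[]
}

#' Count PAS usage from all read ends
#'
#' Every read (tail-supported or not) is counted toward the PAS whose
#' 200-nt upstream window (strand-aware) contains its 3' end. Ends
#' eligible for two PAS windows are assigned to the nearer PAS, ties to
#' the downstream (3') PAS.
#'
#' @param read_ends data.table(sample_id, chrom, pos, strand).
#' @param atlas atlas from [finalize_atlas()].
#' @param window upstream window size (default 200).
#' @return list(matrix [PAS x sample counts], pas2gene named vector).
#' @export
count_usage <- function(read_ends, atlas, window = 200) {
  ends <- as.data.table(read_ends)
  pas <- as.data.table(atlas)[, .(pas_id, chrom, strand, pas_pos = pos,
                                  gene_id)]
  pas[, `:=`(win_start = fifelse(strand == "+", pas_pos - window, pas_pos),
             win_end = fifelse(strand == "+", pas_pos, pas_pos + window))]
  # non-equi join reports x's position under the join column names, so
  # carry a row index and recover the true read end afterwards
  ov <- ends[, .(chrom, strand, end_pos = pos, sample_id, read = .I)][
    pas, on = .(chrom, strand, end_pos >= win_start, end_pos <= win_end),
    nomatch = NULL, allow.cartesian = TRUE]
  ov[, end_actual := ends$pos[read]]
  ov[, dist := abs(end_actual - pas_pos)]
  ov[, downstream_rank := fifelse(strand == "+", pas_pos, -pas_pos)]
  setorder(ov, read, dist, -downstream_rank)
  ov <- ov[!duplicated(read)]
  counts <- ov[, .N, by = .(pas_id, sample_id)]
  samples <- sort(unique(ends$sample_id))
  mat <- matrix(0L, nrow(pas), length(samples),
                dimnames = list(pas$pas_id, samples))
  mat[cbind(match(counts$pas_id, pas$pas_id),
            match(counts$sample_id, samples))] <- counts$N
  list(matrix = mat, pas2gene = setNames(pas$gene_id, pas$pas_id))
}

#' Filter the PAS count matrix for differential testing
#'
#' Removes PAS in genes with fewer than `gene_min` reads in at least 75%
#' of replicates across all conditions, and PAS that themselves have
#' fewer than `pas_min` reads in at least 75% of replicates even in
#' their better condition. Genes reduced to fewer than two PAS are
#' dropped.
#'
#' @param mat PAS x sample count matrix.
#' @param pas2gene named PAS -> gene map.
#' @param manifest manifest (sample_id, condition).
#' @param conditions the two condition labels compared.
#' @param gene_min,pas_min,prop filter parameters.
#' @return filtered matrix (attribute `pas2gene` updated).
#' @export
filter_counts <- function(mat, pas2gene, manifest,
                          conditions = c("knockdown", "rescue"),
                          gene_min = 10, pas_min = 5, prop = 0.75) {
  man <- as.data.table(manifest)
  keep_samp <- man[condition %in% conditions, sample_id]
  mat <- mat[, colnames(mat) %in% keep_samp, drop = FALSE]
  cond <- man$condition[match(colnames(mat), man$sample_id)]
  genes <- pas2gene[rownames(mat)]
  gene_tot <- rowsum(mat, genes)
  low_gene <- rowMeans(gene_tot < gene_min) >= prop
  bad_genes <- rownames(gene_tot)[low_gene]
  frac_low <- sapply(conditions, function(cc)
    rowMeans(mat[, cond == cc, drop = FALSE] < pas_min))
  low_pas <- apply(frac_low, 1, min) >= prop
  keep <- !low_pas & !genes %in% bad_genes
  mat <- mat[keep, , drop = FALSE]
  genes <- genes[keep]
  multi <- names(table(genes))[table(genes) >= 2]
  mat <- mat[genes %in% multi, , drop = FALSE]
  structure(mat, pas2gene = pas2gene[rownames(mat)])
}

# Dirichlet-multinomial log-likelihood for one gene.
# y: samples x PAS count matrix; p: proportions (len J); gamma: precision.
dm_loglik <- function(y, p, gamma) {
  n <- rowSums(y)
  a <- gamma * p
  sum(lgamma(gamma) - lgamma(n + gamma)) +
    sum(lgamma(sweep(y, 2, a, "+")) - rep(lgamma(a), each = nrow(y)))
}

softmax <- function(z) {
  e <- exp(c(0, z))
  e / sum(e)
}

fit_dm <- function(y, groups, gamma = NULL) {
  # ML fit of per-group proportions; the precision is either estimated
  # jointly (gamma = NULL) or held fixed at a supplied value
  J <- ncol(y)
  glev <- unique(groups)
  G <- length(glev)
  pool <- colSums(y) + 0.5
  p0 <- pool / sum(pool)
  z0 <- log(p0[-1] / p0[1])
  est_gamma <- is.null(gamma)
  par0 <- c(rep(z0, G), if (est_gamma) log(10))
  nll <- function(par) {
    gm <- if (est_gamma) {
      lg <- par[length(par)]
      if (lg > 12 || lg < -8) return(1e10)
      exp(lg)
    } else gamma
    tot <- 0
    for (gi in seq_len(G)) {
      z <- par[((gi - 1) * (J - 1) + 1):(gi * (J - 1))]
      p <- softmax(z)
      tot <- tot - dm_loglik(y[groups == glev[gi], , drop = FALSE], p, gm)
    }
    if (!is.finite(tot)) 1e10 else tot
  }
  fit <- if (length(par0) == 1L) {
    opt <- stats::optimize(function(z) nll(z), c(-12, 12), tol = 1e-10)
    list(par = opt$minimum, value = opt$objective, convergence = 0L)
  } else {
    optim(par0, nll, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10))
  }
  props <- matrix(NA_real_, G, J, dimnames = list(glev, colnames(y)))
  for (gi in seq_len(G)) {
    z <- fit$par[((gi - 1) * (J - 1) + 1):(gi * (J - 1))]
    props[gi, ] <- softmax(z)
  }
  list(loglik = -fit$value, props = props,
       gamma = if (est_gamma) exp(fit$par[length(fit$par)]) else gamma,
       convergence = fit$convergence)
}

#' Dirichlet-multinomial likelihood-ratio test of differential PAS usage
#'
#' Per gene, the null model shares PAS proportions across conditions and
#' the alternative fits condition-specific proportions; the precision is
#' estimated by maximum likelihood under each model and the LR statistic
#' is referred to a chi-square with (conditions-1) x (PAS-1) degrees of
#' freedom, with Benjamini-Hochberg correction across genes. Each PAS
#' additionally gets an analogous beta-binomial test (this PAS versus the
#' rest of the gene).
#'
#' @param mat filtered PAS x sample count matrix from [filter_counts()].
#' @param manifest manifest (sample_id, condition).
#' @param conditions the two condition labels compared (proportion
#'   differences are reported as `conditions[2] - conditions[1]`).
#' @return list(genes = data.table(gene_id, lr, df, p, padj, gamma),
#'   pas = data.table(gene_id, pas_id, p, padj and fitted usage per
#'   condition plus dpau)).
#' @export
dm_lrt <- function(mat, manifest, conditions = c("knockdown", "rescue")) {
  pas2gene <- attr(mat, "pas2gene")
  if (is.null(pas2gene)) stop("matrix lacks pas2gene attribute")
  man <- as.data.table(manifest)
  if (is.null(colnames(mat)) || !all(colnames(mat) %in% man$sample_id)) {
    stop("count matrix columns must be sample ids present in the manifest")
  }
  cond <- man$condition[match(colnames(mat), man$sample_id)]
  if (any(!cond %in% conditions)) stop("samples outside the comparison")
  if (min(table(cond)) < 2) stop("need >= 2 replicates per condition")
  genes <- unique(pas2gene)
  gres <- list(); pres <- list()
  for (g in genes) {
    rows <- which(pas2gene == g)
    y <- t(mat[rows, , drop = FALSE])
    colnames(y) <- rownames(mat)[rows]
    if (any(rowSums(y) == 0)) y <- y + 0.5  # zero-total samples, flagged
    # precision is estimated once under the null model (the distribution
    # the test statistic is referred to) and held fixed in both fits
    null_ml <- fit_dm(y, rep("all", nrow(y)))
    null_fit <- fit_dm(y, rep("all", nrow(y)), gamma = null_ml$gamma)
    alt_fit <- fit_dm(y, cond, gamma = null_ml$gamma)
    lr <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
    df <- (length(conditions) - 1) * (ncol(y) - 1)
    gres[[g]] <- data.table(gene_id = g, lr = lr, df = df,
                            p = pchisq(lr, df, lower.tail = FALSE),
                            gamma = null_ml$gamma)
    prop <- alt_fit$props[conditions, , drop = FALSE]
    for (j in seq_len(ncol(y))) {
      if (ncol(y) == 2) {
        # with two PAS the this-vs-rest beta-binomial model coincides
        # with the gene-level Dirichlet-multinomial
        lrb <- lr
      } else {
        yb <- cbind(y[, j], rowSums(y) - y[, j])
        nm <- fit_dm(yb, rep("all", nrow(yb)))
        nb <- fit_dm(yb, rep("all", nrow(yb)), gamma = nm$gamma)
        abf <- fit_dm(yb, cond, gamma = nm$gamma)
        lrb <- max(0, 2 * (abf$loglik - nb$loglik))
      }
      pres[[paste(g, j)]] <- data.table(
        gene_id = g, pas_id = colnames(y)[j],
        usage_1 = prop[1, j], usage_2 = prop[2, j],
        dpau = prop[2, j] - prop[1, j],
        lr = lrb, p = pchisq(lrb, 1, lower.tail = FALSE))
    }
  }
  gtab <- rbindlist(gres)
  gtab[, padj := p.adjust(p, "BH")]
  ptab <- rbindlist(pres)
  ptab[, padj := p.adjust(p, "BH")]
  setnames(ptab, c("usage_1", "usage_2"),
           paste0("usage_", conditions))
  list(genes = gtab[], pas = ptab[], conditions = conditions)
}

#' Representative and partner PAS with dPAU
#'
#' dPAU is the fitted usage difference (second minus first condition,
#' i.e. rescue minus knockdown). Within each significant gene the
#' representative PAS is the one with the lowest adjusted p value (ties:
#' highest usage); genes whose representative changes usage by less than
#' `min_change` are dropped. The partner is the PAS with the largest
#' usage change in the opposite direction.
#'
#' @param res result of [dm_lrt()].
#' @param min_change minimum |dPAU| of the representative (default 0.10).
#' @param alpha gene-level significance threshold (default 0.05).
#' @return data.table(gene_id, pas_id, dpau, padj, partner_pas,
#'   partner_dpau).
#' @export
dpau_and_representatives <- function(res, min_change = 0.10,
                                     alpha = 0.05) {
  sig <- res$genes[padj < alpha, gene_id]
  ptab <- res$pas[gene_id %in% sig]
  if (!nrow(ptab)) {
    return(data.table(gene_id = character(), pas_id = character(),
                      dpau = numeric(), padj = numeric(),
                      partner_pas = character(),
                      partner_dpau = numeric()))
  }
  u1 <- paste0("usage_", res$conditions[1])
  u2 <- paste0("usage_", res$conditions[2])
  ptab[, usage_mean := (get(u1) + get(u2)) / 2]
  rep_tab <- ptab[, {
    o <- order(padj, -usage_mean)
    r <- .SD[o[1]]
    opp <- .SD[sign(dpau) == -sign(r$dpau)]
    partner <- if (nrow(opp)) opp[which.max(abs(dpau))] else NULL
    .(pas_id = r$pas_id, dpau = r$dpau, padj = r$padj,
      partner_pas = if (is.null(partner)) NA_character_ else
        partner$pas_id,
      partner_dpau = if (is.null(partner)) NA_real_ else partner$dpau)
  }, by = gene_id]
  rep_tab[abs(dpau) >= min_change]
}
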