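mk_ends <- function(pos, strand = "+", tail = 6L, sample_id = "s1",
                    chrom = "chrT") {
  data.table::data.table(sample_id = sample_id, chrom = chrom,
                         pos = as.integer(pos), strand = strand,
                         tail = as.integer(rep_len(tail, length(pos))))
}

test_that("tail selection keeps >= 5 untemplated As", {
  re <- mk_ends(1:100, tail = rep(c(5L, 4L, 7L, 0L), 25))
  kept <- select_tail_evidence(re)
  expect_equal(nrow(kept), 50)
  expect_true(all(kept$tail >= 5))
  expect_equal(nrow(select_tail_evidence(re[0])), 0)
})

test_that("candidate clusters merge adjacent positions and drop
           singletons", {
  re <- mk_ends(c(100, 101, 101, 103))
  cl <- build_candidate_clusters(re)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$pos, 101)        # modal position
  expect_equal(cl$n_reads, 3)
  expect_equal(cl[, .(cluster_start, cluster_end)],
               data.table::data.table(cluster_start = 100L,
                                      cluster_end = 101L))
  # tie in the mode resolves 3'-ward (strand-aware)
  tie_p <- build_candidate_clusters(mk_ends(c(200, 201)))
  expect_equal(tie_p$pos, 201)
  tie_m <- build_candidate_clusters(mk_ends(c(200, 201), strand = "-"))
  expect_equal(tie_m$pos, 200)
  # a run of consecutive positions is one cluster
  run <- build_candidate_clusters(mk_ends(300:309))
  expect_equal(nrow(run), 1)
})

test_that("internal-priming filter applies category-specific strict
           thresholds", {
  base <- strrep("G", 400)
  mk_gen <- function(upstream, downstream, pos = 200) {
    s <- paste0(substr(base, 1, pos - 41), upstream,
                substr(base, pos, pos), downstream,
                strrep("G", 400))
    Biostrings::DNAStringSet(setNames(substr(s, 1, 400), "chrT"))
  }
  cl <- data.table::data.table(chrom = "chrT", strand = "+", pos = 200L,
                               n_reads = 10L, cluster_start = 200L,
                               cluster_end = 200L)
  # canonical signal, 60% downstream A -> removed
  g1 <- mk_gen(paste0("AATAAA", strrep("C", 34)),
               paste0(strrep("A", 12), strrep("C", 8)))
  r1 <- internal_priming_filter(g1, cl)
  expect_equal(nrow(r1$removed), 1)
  expect_equal(r1$removed$signal, "canonical")
  expect_equal(r1$removed$a_content, 0.6)
  # canonical signal, exactly 50% -> kept (not "over 50%")
  g2 <- mk_gen(paste0("AATAAA", strrep("C", 34)),
               paste0(strrep("A", 10), strrep("C", 10)))
  r2 <- internal_priming_filter(g2, cl)
  expect_equal(nrow(r2$retained), 1)
  # alternative signal at 45% -> removed; at exactly 40% -> kept
  g3 <- mk_gen(paste0("TATAAA", strrep("C", 34)),
               paste0(strrep("A", 9), strrep("C", 11)))
  expect_equal(internal_priming_filter(g3, cl)$removed$signal,
               "alternative")
  g4 <- mk_gen(paste0("TATAAA", strrep("C", 34)),
               paste0(strrep("A", 8), strrep("C", 12)))
  expect_equal(internal_priming_filter(g4, cl)$retained$signal,
               "alternative")
  # no signal, 35% -> removed
  g5 <- mk_gen(strrep("C", 40), paste0(strrep("A", 7), strrep("C", 13)))
  r5 <- internal_priming_filter(g5, cl)
  expect_equal(r5$removed$signal, "none")
})

test_that("atlas finalization merges within 200 nt with the 3' tie rule
           and assigns genes hierarchically", {
  ann <- toy_annotation()
  mk_cl <- function(pos, n, strand = "+") data.table::data.table(
    chrom = "chrT", strand = strand, pos = as.integer(pos),
    n_reads = as.integer(n), cluster_start = as.integer(pos),
    cluster_end = as.integer(pos), clipped = FALSE, signal = "canonical",
    a_content = 0.2)
  at1 <- finalize_atlas(rbind(mk_cl(2900, 5), mk_cl(3050, 9)), ann)
  expect_equal(nrow(at1), 1)
  expect_equal(at1$pos, 3050)
  # equal counts -> most 3'
  at2 <- finalize_atlas(rbind(mk_cl(2800, 5), mk_cl(2900, 5)), ann)
  expect_equal(at2$pos, 2900)
  at2m <- finalize_atlas(rbind(mk_cl(6100, 5, "-"), mk_cl(6250, 5, "-")),
                         ann)
  expect_equal(at2m$pos, 6100)
  # hierarchical assignment: 3'UTR beats gene body; downstream window
  at3 <- finalize_atlas(rbind(mk_cl(2900, 5), mk_cl(3400, 5),
                              mk_cl(1500, 5), mk_cl(5000, 5)), ann)
  expect_equal(at3[pos == 2900, assignment], "3'UTR")
  expect_equal(at3[pos == 3400, assignment], "downstream1kb")
  expect_equal(at3[pos == 1500, assignment], "gene_body")
  expect_false(5000 %in% at3$pos)  # intergenic discarded
  # idempotence and spacing invariant
  again <- finalize_atlas(at3[, .(chrom, strand, pos, n_reads,
                                  cluster_start = pos,
                                  cluster_end = pos)], ann)
  expect_equal(again$pos, at3$pos)
  sp <- at3[order(strand, pos), diff(pos), by = strand]
  expect_true(all(abs(sp$V1) > 200))
})

test_that("usage counting is strand-aware with nearest-site
           disambiguation", {
  ann <- toy_annotation()
  atlas <- data.table::data.table(
    pas_id = c("p1", "p2"), chrom = "chrT", strand = "+",
    pos = c(2800L, 2950L), n_reads = 10L, gene_id = "gA",
    assignment = "3'UTR")
  ends <- mk_ends(c(2650, 2599, 2860, 2890, 2955))
  cu <- count_usage(ends, atlas)
  # 2650: only in the p1 window [2600, 2800]; 2599: 201 nt upstream of
  # p1, outside both windows; 2860 and 2890: only in the p2 window
  # [2750, 2950]; 2955: downstream of both -> uncounted
  expect_equal(cu$matrix["p1", "s1"], 1)
  expect_equal(cu$matrix["p2", "s1"], 2)
  # an end in the overlap of two windows goes to the nearer PAS
  cu2 <- count_usage(mk_ends(2770), atlas)
  expect_equal(cu2$matrix["p1", "s1"], 1)
  expect_equal(cu2$matrix["p2", "s1"], 0)
  # minus strand counts the mirror-image window
  atlas_m <- data.table::data.table(
    pas_id = "m1", chrom = "chrT", strand = "-", pos = 6100L,
    n_reads = 10L, gene_id = "gB", assignment = "3'UTR")
  cum <- count_usage(mk_ends(c(6150, 6301), strand = "-"), atlas_m)
  expect_equal(unname(cum$matrix["m1", "s1"]), 1)
})

test_that("count filtering removes weak genes and PAS per the 75% rules", {
  man <- data.table::data.table(
    sample_id = paste0("s", 1:12),
    condition = rep(c("knockdown", "rescue"), each = 6))
  mat <- matrix(20L, 4, 12,
                dimnames = list(paste0("p", 1:4), man$sample_id))
  p2g <- setNames(c("g1", "g1", "g2", "g2"), rownames(mat))
  # gene g2 weak in 9 of 12 replicates (75%)
  mat[c("p3", "p4"), 1:9] <- 2L
  f <- filter_counts(mat, p2g, man)
  expect_equal(rownames(f), c("p1", "p2"))
  # a PAS with >= 5 reads in all rescue replicates survives the PAS rule
  mat2 <- matrix(20L, 4, 12,
                 dimnames = list(paste0("p", 1:4), man$sample_id))
  mat2["p2", 1:6] <- 0L   # dead in knockdown, alive in rescue
  f2 <- filter_counts(mat2, p2g, man)
  expect_true("p2" %in% rownames(f2))
  # PAS weak in the better condition drops, and a gene reduced to one
  # PAS drops entirely
  mat3 <- matrix(20L, 4, 12,
                 dimnames = list(paste0("p", 1:4), man$sample_id))
  mat3["p2", c(1:5, 7:11)] <- 1L
  f3 <- filter_counts(mat3, p2g, man)
  expect_false("p2" %in% rownames(f3))
  expect_false("p1" %in% rownames(f3))
  expect_equal(rownames(f3), c("p3", "p4"))
})

test_that("the DM likelihood-ratio test is calibrated and powerful", {
  set.seed(71)
  rdir <- function(n, a) {
    x <- matrix(rgamma(n * length(a), a), n, byrow = TRUE)
    x / rowSums(x)
  }
  man <- data.table::data.table(
    sample_id = paste0("s", 1:12),
    condition = rep(c("knockdown", "rescue"), each = 6))
  build <- function(ngene, p1, p2, prefix, gamma = 50, depth = 200) {
    rows <- lapply(seq_len(ngene), function(g) {
      if (is.null(p1)) {
        p <- rdir(1, c(2, 2))[1, ]; pa <- p; pb <- p
      } else { pa <- p1; pb <- p2 }
      ps <- rbind(rdir(6, gamma * pa), rdir(6, gamma * pb))
      sapply(seq_len(12), function(s) rmultinom(1, depth, ps[s, ]))
    })
    mat <- do.call(rbind, rows)
    rownames(mat) <- paste0(prefix, seq_len(nrow(mat)))
    colnames(mat) <- man$sample_id
    attr(mat, "pas2gene") <- setNames(rep(paste0(prefix, "g", 1:ngene),
                                          each = 2), rownames(mat))
    mat
  }
  null_res <- dm_lrt(build(400, NULL, NULL, "n"), man)
  t1 <- mean(null_res$genes$p < 0.05)
  expect_gte(t1, 0.03); expect_lte(t1, 0.07)
  pow_res <- dm_lrt(build(150, c(0.6, 0.4), c(0.3, 0.7), "h"), man)
  expect_gt(mean(pow_res$genes[, p.adjust(p, "BH")] < 0.05), 0.9)
  # fitted proportions behave: sum to 1 per condition, dPAU sums to 0
  pt <- pow_res$pas
  sums <- pt[, .(s1 = sum(usage_knockdown), s2 = sum(usage_rescue),
                 sd = sum(dpau)), by = gene_id]
  expect_true(all(abs(sums$s1 - 1) < 1e-6))
  expect_true(all(abs(sums$s2 - 1) < 1e-6))
  expect_true(all(abs(sums$sd) < 1e-6))
  # identical counts in both conditions -> LR ~ 0, p ~ 1
  same <- matrix(rep(c(30L, 70L), 12), 2, 12,
                 dimnames = list(c("pa", "pb"), man$sample_id))
  attr(same, "pas2gene") <- setNames(c("g", "g"), c("pa", "pb"))
  res0 <- dm_lrt(same, man)
  expect_lt(res0$genes$lr, 1e-4)
  expect_gt(res0$genes$p, 0.99)
})

test_that("representative and partner PAS selection follows the dPAU
           rules", {
  res <- list(
    genes = data.table::data.table(gene_id = c("g1", "g2"),
                                   lr = c(20, 20), df = 1,
                                   p = c(1e-5, 1e-5),
                                   padj = c(2e-5, 2e-5), gamma = 50),
    pas = data.table::data.table(
      gene_id = c("g1", "g1", "g2", "g2"),
      pas_id = c("a", "b", "c", "d"),
      usage_knockdown = c(0.8, 0.2, 0.52, 0.48),
      usage_rescue = c(0.5, 0.5, 0.43, 0.57),
      dpau = c(-0.3, 0.3, -0.09, 0.09),
      lr = 20, p = 1e-5, padj = c(1e-5, 2e-5, 1e-5, 1e-5)),
    conditions = c("knockdown", "rescue"))
  reps <- dpau_and_representatives(res)
  # g1: representative = lowest padj (a), partner = opposite sign (b)
  expect_equal(reps[gene_id == "g1", pas_id], "a")
  expect_equal(reps[gene_id == "g1", dpau], -0.3)
  expect_equal(reps[gene_id == "g1", partner_pas], "b")
  # g2 representative |dPAU| = 0.09 < 0.10 -> gene excluded
  expect_false("g2" %in% reps$gene_id)
  # padj tie resolves to the higher-usage PAS
  res$pas[gene_id == "g1", padj := 1e-5]
  reps2 <- dpau_and_representatives(res)
  expect_equal(reps2[gene_id == "g1", pas_id], "a")  # usage 0.65 > 0.35
})

test_that("planted PAS experiments are recovered end to end", {
  sim <- simulate_genome_and_regions(seed = 11, n_genes = 10)
  pp <- plant_pas(sim$genome, sim$annotation, frac_dependent = 0.4,
                  seed = 2)
  man <- data.table::CJ(variant = c("WT", "316del346"),
                        condition = c("knockdown", "rescue"),
                        replicate = 1:3)
  man[, sample_id := paste(variant, condition, replicate, sep = "_")]
  man[, `:=`(experiment = "pas", batch = 1L)]
  re <- simulate_threeprime_reads(pp$truth, man, depth = 400, seed = 9)
  cc <- build_candidate_clusters(select_tail_evidence(re))
  ipf <- internal_priming_filter(pp$genome, cc)
  # planted decoys removed, true sites kept
  dec <- pp$truth[, .(chrom, strand, pos = decoy_pos)]
  hits_decoy <- function(tb) sum(vapply(seq_len(nrow(tb)), function(i)
    any(dec$chrom == tb$chrom[i] & abs(dec$pos - tb$pos[i]) <= 10), TRUE))
  expect_equal(hits_decoy(ipf$retained), 0)
  expect_gte(hits_decoy(ipf$removed), nrow(dec) * 0.95)
  atlas <- finalize_atlas(ipf$retained, sim$annotation)
  expect_equal(nrow(atlas), 2 * nrow(pp$truth))
  truep <- c(pp$truth$prox_pos, pp$truth$dist_pos)
  expect_true(all(vapply(atlas$pos, function(p)
    any(abs(truep - p) <= 10), TRUE)))
  cu <- count_usage(re, atlas)
  fm <- filter_counts(cu$matrix, cu$pas2gene, man)
  mv <- man[variant == "316del346"]
  fv <- fm[, colnames(fm) %in% mv$sample_id, drop = FALSE]
  attr(fv, "pas2gene") <- attr(fm, "pas2gene")
  res <- dm_lrt(fv, mv)
  reps <- dpau_and_representatives(res)
  lab <- merge(reps, pp$truth[, .(gene_id, group)], by = "gene_id")
  # the CR deletion rescues independent genes, not dependent ones
  expect_gte(sum(lab$group == "CR-independent"), 5)
  expect_lte(sum(lab$group == "CR-dependent"), 1)
})
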