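# Sites spaced so that every -150..155 window fits the contig
spaced_sites <- function(n, strand = "+", from = 400, by = 400) {
  data.table::data.table(chrom = "chrT",
                         pos = seq(from, by = by, length.out = n),
                         strand = strand)
}

test_that("positional profiles count k-mer starts at exact offsets", {
  gen <- random_genome(8000, seed = 31)
  sites <- spaced_sites(10)
  for (p in sites$pos) gen <- plant_motif(gen, "chrT", p + 5, "TGTGTG")
  prof <- positional_profile(gen, sites)
  occ <- prof$prox_counts[match("TGTGTG", prof$kmers), ]
  expect_equal(occ[prof$offsets == 5], 10)
  expect_true(all(prof$prox_counts <= prof$n_sites))
  expect_true(all(prof$distal_mean >= 0))
  expect_error(positional_profile(gen, sites, k = 0), "k must be")
})

test_that("minus-strand profiles equal plus-strand profiles of the
           reverse-complemented locus", {
  gen <- random_genome(8000, seed = 32)
  sites <- spaced_sites(8, strand = "-")
  prof_minus <- positional_profile(gen, sites)
  L <- Biostrings::width(gen)[1]
  rc <- Biostrings::DNAStringSet(setNames(
    as.character(Biostrings::reverseComplement(gen[[1]])), "chrT"))
  sites_rc <- data.table::copy(sites)[, `:=`(pos = L - pos + 1L,
                                             strand = "+")]
  prof_plus <- positional_profile(rc, sites_rc)
  expect_equal(prof_minus$prox_counts, prof_plus$prox_counts)
  expect_equal(prof_minus$distal_mean, prof_plus$distal_mean)
})

test_that("occurrence rates on random sequence match the i.i.d.
           expectation", {
  gen <- random_genome(200000, gc = 0.5, seed = 33)
  sites <- spaced_sites(400, from = 300, by = 490)
  prof <- positional_profile(gen, sites)
  rate <- mean(prof$prox_counts) / prof$n_sites
  expect_equal(rate, 4^-6, tolerance = 0.15)
})

test_that("profile normalization uses the distal background", {
  gen <- random_genome(60000, seed = 34)
  sites <- spaced_sites(50, from = 400, by = 1100)
  # motif at +5 in 50% of sites
  for (p in sites$pos[1:25]) gen <- plant_motif(gen, "chrT", p + 5, "ACGTAC")
  prof <- positional_profile(gen, sites)
  normd <- normalize_profile(prof)
  i <- match("ACGTAC", prof$kmers)
  # direct recomputation from raw windows
  win <- extract_oriented_window(gen, sites$chrom, sites$pos, sites$strand,
                                 c(-150, 155))
  at5 <- sum(substr(win, 151 + 5, 156 + 5) == "ACGTAC")
  expect_equal(at5, 25)
  dist_off <- c(-150:-100, 100:150)
  dist_occ <- mean(vapply(dist_off, function(o)
    sum(substr(win, 151 + o, 156 + o) == "ACGTAC"), 0)) / 50
  expect_equal(normd[i, prof$offsets == 5],
               (25 / 50) / (dist_occ + 0.5 / 50))
  expect_true(normd[i, prof$offsets == 5] > 20)
  # zero proximal + zero distal gives 0
  zero <- prof$prox_counts == 0 &
    matrix(prof$distal_mean == 0, nrow = 4096, ncol = 81)
  expect_true(all(normd[zero] == 0))
  # unenriched k-mers sit near 1 once the per-kmer background rate
  # dominates the pseudocount (short k-mers on random sequence)
  gen3 <- random_genome(300000, seed = 341)
  sites3 <- spaced_sites(1000, from = 300, by = 295)
  prof3 <- positional_profile(gen3, sites3, k = 3)
  normd3 <- normalize_profile(prof3)
  expect_lt(abs(median(normd3) - 1), 0.1)
})

test_that("position selection follows the core/flank rules", {
  offsets <- -40:40
  normalized <- matrix(1, 2, 81)
  chosen <- select_positions(normalized, offsets)
  expect_equal(unname(rowSums(chosen)), c(27, 27))
  expect_true(all(chosen[, offsets >= -13 & offsets <= 13]))
  normalized[1, offsets == 20] <- 3
  chosen <- select_positions(normalized, offsets)
  expect_true(chosen[1, offsets == 20])
  expect_equal(sum(chosen[1, ]), 28)
  # comparative mode: only offsets above threshold, no automatic core
  normalized2 <- matrix(1, 1, 81)
  normalized2[1, offsets == 0] <- 5
  normalized2[1, offsets == 30] <- 4.5
  ch2 <- select_positions(normalized2, offsets, flank_threshold = 4,
                          mode = "comparative")
  expect_equal(which(ch2[1, ]), which(offsets %in% c(0, 30)))
})

test_that("planted motifs outrank everything and the null is centered", {
  gen <- random_genome(300000, seed = 35)
  set.seed(36)
  all_pos <- sort(sample(300:299600, 3000))
  txn_pos <- sample(all_pos, 500)
  oxn_pos <- setdiff(all_pos, txn_pos)
  for (p in sample(txn_pos, 300)) gen <- plant_motif(gen, "chrT", p + 4,
                                                     "TGTGTG")
  txn <- data.table::data.table(chrom = "chrT", pos = txn_pos, strand = "+")
  oxn <- data.table::data.table(chrom = "chrT", pos = oxn_pos, strand = "+")
  res <- peka_score(gen, txn, oxn, seed = 37)
  expect_equal(res$table$kmer[1], "TGTGTG")
  # determinism under the seed
  res2 <- peka_score(gen, txn, oxn, seed = 37)
  expect_identical(res$table, res2$table)

  # null (tXn exchangeable with oXn): with the offset set fixed a priori
  # (core -13..13 only, no data-driven flank selection) the score is
  # unbiased; with flank selection the residual mean stays far below
  # genuine enrichment scores
  gen0 <- random_genome(300000, seed = 38)
  set.seed(39)
  pos0 <- sort(sample(300:299600, 3000))
  t0 <- sample(pos0, 600)
  txn0 <- data.table::data.table(chrom = "chrT", pos = t0, strand = "+")
  oxn0 <- data.table::data.table(chrom = "chrT", pos = setdiff(pos0, t0),
                                 strand = "+")
  null_fixed <- peka_score(gen0, txn0, oxn0, seed = 40,
                           flank_threshold = Inf)
  scf <- null_fixed$table$score
  expect_lt(abs(mean(scf[is.finite(scf)])), 0.1)
  null_res <- peka_score(gen0, txn0, oxn0, seed = 40)
  sc <- null_res$table$score
  expect_lt(abs(mean(sc[is.finite(sc)])), 2)
})

test_that("comparative enrichment is frozen to the reference", {
  gen <- random_genome(300000, seed = 41)
  set.seed(42)
  pos <- sort(sample(300:299600, 2500))
  txn_pos <- sample(pos, 600)
  for (p in sample(txn_pos, 350)) gen <- plant_motif(gen, "chrT", p + 3,
                                                     "TGTGTG")
  txn <- data.table::data.table(chrom = "chrT", pos = txn_pos, strand = "+")
  oxn <- data.table::data.table(chrom = "chrT",
                                pos = setdiff(pos, txn_pos), strand = "+")
  cmp <- comparative_peka(gen, txn, oxn,
                          list(self = txn, half = txn[1:300]), seed = 43)
  ref_m <- cmp$reference$table[order(kmer), m]
  self_m <- cmp$samples[sample_id == "self"][order(kmer), m]
  expect_equal(self_m, ref_m)
  # identical tXn reproduce the reference enrichment exactly
  i <- which(cmp$samples$sample_id == "self" &
               cmp$samples$kmer == "TGTGTG")
  expect_gt(cmp$samples$log2_enrichment[i], 1)
  # sub-sampled case keeps finite values only at frozen offsets
  expect_true(all(is.na(cmp$samples[is.na(m), score])))
  expect_warning(
    comparative_peka(gen, txn, oxn, list(tiny = txn[1:10]), seed = 1),
    "excluded")
})

test_that("relative enrichment tables are zero-mean with top_n rows", {
  gen <- random_genome(300000, seed = 44)
  set.seed(45)
  pos <- sort(sample(300:299600, 2500))
  txn_pos <- sample(pos, 600)
  for (p in sample(txn_pos, 350)) gen <- plant_motif(gen, "chrT", p + 3,
                                                     "TGTGTG")
  txn <- data.table::data.table(chrom = "chrT", pos = txn_pos, strand = "+")
  oxn <- data.table::data.table(chrom = "chrT",
                                pos = setdiff(pos, txn_pos), strand = "+")
  cases <- list(WT_1 = txn, WT_2 = txn[seq(1, 600, 2)],
                A326P_1 = txn[1:400], A326P_2 = txn[101:500])
  cmp <- comparative_peka(gen, txn, oxn, cases, seed = 46)
  man <- toy_manifest(c("WT", "A326P"))
  rel <- relative_enrichment_table(cmp, man, top_n = 12)
  expect_equal(nrow(rel$matrix), 12)
  expect_true(all(abs(rowMeans(rel$matrix)) < 1e-9))
  # single-variant input: normalization removes everything
  rel1 <- relative_enrichment_table(cmp, man[variant == "WT"], top_n = 5)
  expect_true(all(abs(rel1$matrix) < 1e-12))
})

test_that("motif grouping applies the depletion-factor thresholds", {
  mk <- function(f) log2(c(WT = f, G335A = f, A326P = 1, "316del346" = 1))
  mat <- rbind(A = mk(1.4), B = mk(1.2), C = mk(1.0))
  colnames(mat) <- c("WT", "G335A", "A326P", "316del346")
  suppressWarnings(grp <- group_motifs(mat))
  expect_equal(grp$group, c("YG", "YA", "AA"))
  expect_equal(grp$factor, c(1.4, 1.2, 1.0))
  expect_warning(group_motifs(mat), "UG-repeat")
})

test_that("metaprofile coverage caps counts and stays in [0, 100]", {
  gen <- random_genome(30000, seed = 47)
  sites <- spaced_sites(20, from = 400, by = 600)
  for (p in sites$pos) gen <- plant_motif(gen, "chrT", p + 5, "TGTGTG")
  sites[, count := 1L]
  mp <- metaprofile_coverage(gen, sites, "TGTGTG", smooth = 1)
  expect_equal(mp[offset == 5, percent], 100)
  base <- mp[abs(offset) > 20, percent]
  expect_lt(mean(base), 1)
  # a huge count contributes at most the cap
  sites2 <- data.table::copy(sites)
  sites2$count[1] <- 1000L
  mp2 <- metaprofile_coverage(gen, sites2, "TGTGTG", smooth = 1)
  w <- 20 + 19  # capped weight of site 1 plus the rest
  expect_equal(mp2[offset == 5, percent], 100)
  mp3 <- metaprofile_coverage(gen, sites2, c("TGTGTG", "AAAAAA"))
  expect_true(all(mp3$percent >= 0 & mp3$percent <= 100))
  expect_error(metaprofile_coverage(gen, sites, character(0)), "empty")
})
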