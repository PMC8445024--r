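# condensyn

Analyses linking RNA-binding-protein condensation to binding-region-
specific RNA assembly and polyA-site regulation, built around the
TDP-43 model system: iCLIP crosslink thresholding, positional k-mer
enrichment (PEKA) and its comparative cross-sample variant, motif-based
binding-region calling with a 36-class classification, a 3'-end-seq
polyA-site atlas with internal-priming filtering and
Dirichlet-multinomial differential usage, k-medoids rescue-pattern
clustering, and FRAP / four-parameter-logistic kinetics with 3D foci
counting. A synthetic-data module generates genomes, crosslink tracks,
3'-end reads, dPAU profiles, FRAP traces and image stacks with planted
ground truth, so the whole pipeline is testable end to end without any
external download.

## The science in brief

TDP-43 condenses through a transient α-helix in the conserved region
(CR) of its C-terminal domain. The package quantifies how mutations
that perturb this condensation change two things:

1. **Where the protein assembles on RNA.** Crosslink sites with high
   cDNA counts (tXn) are found by per-region density peak calling
   (Paraclu-style, minValue 10, max length 200) plus a nearest-rank
   70th-percentile threshold. For each 6-mer, a PEKA score measures
   positional enrichment around tXn against 100 control groups drawn
   from background crosslinks:
   `score = (m − mean(m_ctrl)) / sd(m_ctrl)`, where `m` is the mean
   distal-normalized occurrence over the enriched offsets. Motif
   positions near tXn merge (gap ≤ 30 nt) into binding regions,
   classified by 4 length bins × 3 density terciles × 3 motif-type
   subclasses (YG-/YA-/AA-containing [UG]n) into 36 classes;
   per-class, per-variant normalized cDNA counts reveal which classes
   need condensation-competent protein.
2. **Which polyadenylation choices depend on condensation.** A PAS
   atlas is built from tailed 3' ends (A-content internal-priming
   filters conditioned on the polyA-signal category; 200-nt merging),
   usage is tested per gene with a Dirichlet-multinomial likelihood
   ratio (BH-corrected), and per-gene rescue patterns
   (dPAU = usage(rescue) − usage(knockdown), oriented so the WT change
   is positive) are clustered by PAM with silhouette model selection
   into full-rescue (CR-independent) and attenuated (CR-dependent)
   groups.

## Worked example

```r
library(condensyn)
library(data.table)

# a synthetic genome with planted UG-repeat motif regions, and
# crosslink tracks whose signal scales with each variant's
# condensation capacity at CR-dependent regions
sim    <- simulate_genome_and_regions(seed = 7)
regs   <- derive_threshold_regions(sim$annotation, sim$genome)
man    <- data.table(sample_id = c("WT_1", "A326P_1"),
                     experiment = "mutants",
                     variant = c("WT", "A326P"),
                     condition = "untreated", batch = 1, replicate = 1)
tracks <- simulate_crosslink_tracks(sim$truth, sim$annotation, man,
                                    depth = 1.2e5, seed = 3)

pk   <- call_peaks(tracks$WT_1, regs)            # density >= 10, <= 200 nt
part <- threshold_crosslinks(tracks$WT_1, pk, regs, percentile = 70)
txn  <- partition_sites(part, "tXn")
oxn  <- partition_sites(part, "oXn")
res  <- peka_score(sim$genome, txn, oxn, seed = 5)
head(res$table, 3)
#>      kmer        m ctrl_mean   ctrl_sd    score  rank
#> 1: GTGCGA 4.891304 0.7921621 0.1067666 38.39348     1
#> 2: GTGTGG 4.701348 0.8601769 0.1011602 37.97118     2
#> 3: TGAAAT 4.648577 0.8232102 0.1038479 36.83625     3
```

The top-ranked 6-mers come from the planted UG-repeat motif landscape
(including the shifted and junction k-mers a dense repeat region
produces): `m` is the motif's mean normalized occurrence at its
enriched offsets around thresholded crosslinks, and the score is its
z-score against 100 background control groups — a score near 38 means
the motif occurs many control standard deviations more often around
tXn than around resampled background crosslinks.

Clustering rescue patterns:

```r
sim <- simulate_dpau_profiles(seed = 1)   # 82 + 54 genes, the study design
cl  <- cluster_rescue_profiles(sim$dpau)
cl$k                        # 2   (average-silhouette selection)
table(cl$labels)
#> attenuated full-rescue
#>         55          81
```

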