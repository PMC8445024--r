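# Orientation and featurization of per-gene dPAU rescue patterns, PAM
# (k-medoids) clustering and silhouette-based model selection into
# CR-dependent and CR-independent groups.

#' Orient dPAU profiles and build the two clustering features
#'
#' Every gene's dPAU vector is multiplied by the sign of its wild-type
#' value, so the wild-type change is always positive. The two features
#' are (i) the relative dPAU of the CR-deletion variant versus wild type
#' (their oriented ratio) and (ii) the absolute dPAU difference between
#' wild type and the CR deletion. Features are z-scored before
#' clustering. Genes missing any variant value or with a wild-type dPAU
#' of exactly zero are excluded with a warning.
#'
#' @param dpau gene x variant matrix of dPAU values.
#' @param wt,deletion column names of the wild-type and CR-deletion
#'   variants.
#' @param standardize z-score the features (default TRUE).
#' @return data.table(gene_id, oriented dPAU columns, rel_dpau,
#'   abs_dpau, rel_z, abs_z).
#' @export
orient_and_featurize <- function(dpau, wt = "WT", deletion = "316del346",
                                 standardize = TRUE) {
  stopifnot(wt %in% colnames(dpau), deletion %in% colnames(dpau))
  complete <- complete.cases(dpau)
  nonzero <- dpau[, wt] != 0
  drop <- !complete | !nonzero
  if (any(drop, na.rm = TRUE)) {
    warning(sum(drop, na.rm = TRUE),
            " gene(s) dropped (missing variant dPAU or WT dPAU = 0)")
  }
  keep <- which(complete & nonzero)
  m <- dpau[keep, , drop = FALSE] * sign(dpau[keep, wt])
  rel <- m[, deletion] / m[, wt]
  ab <- m[, wt] - m[, deletion]
  zs <- function(x) if (standardize) (x - mean(x)) / sd(x) else x
  out <- data.table(gene_id = rownames(m))
  for (v in colnames(m)) out[, (paste0("dpau_", v)) := m[, v]]
  out[, `:=`(rel_dpau = rel, abs_dpau = ab,
             rel_z = zs(rel), abs_z = zs(ab))]
  out[]
}

#' K-medoids (PAM) clustering of rescue features
#'
#' Classic partitioning-around-medoids (build + swap phases) on
#' Euclidean distances; deterministic for a given feature table.
#'
#' @param features data.table from [orient_and_featurize()] (uses the
#'   rel_z/abs_z columns) or a numeric matrix.
#' @param k number of clusters.
#' @return `cluster::pam` object.
#' @export
kmedoids_pam <- function(features, k) {
  x <- feature_matrix(features)
  if (k > nrow(x)) stop("k exceeds the number of genes")
  cluster::pam(x, k, metric = "euclidean")
}

feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  ft <- as.data.table(features)
  x <- as.matrix(ft[, .(rel_z, abs_z)])
  rownames(x) <- ft$gene_id
  x
}

#' Silhouette-based selection of the number of clusters
#'
#' Runs PAM over `k_range` and returns the k maximizing the mean
#' silhouette width (ties go to the smallest k).
#'
#' @param features feature table or matrix.
#' @param k_range candidate cluster counts (default 2:8).
#' @return list(k, widths [named numeric]).
#' @export
optimal_k_silhouette <- function(features, k_range = 2:8) {
  x <- feature_matrix(features)
  k_range <- k_range[k_range < nrow(x)]
  widths <- vapply(k_range, function(k)
    cluster::pam(x, k, metric = "euclidean")$silinfo$avg.width, 0)
  names(widths) <- k_range
  list(k = k_range[which.max(widths)], widths = widths)
}

#' Cluster rescue profiles into CR-dependent and CR-independent groups
#'
#' Convenience wrapper: featurize, select k by average silhouette, run
#' PAM, and label the cluster with the higher mean relative dPAU as the
#' full-rescue (CR-independent) group.
#'
#' @param dpau gene x variant dPAU matrix.
#' @param k_range candidate cluster counts.
#' @param ... passed to [orient_and_featurize()].
#' @return list(features, k, pam, labels [named: "full-rescue" /
#'   "attenuated" for k = 2, cluster index otherwise], silhouette).
#' @export
cluster_rescue_profiles <- function(dpau, k_range = 2:8, ...) {
  feats <- orient_and_featurize(dpau, ...)
  sel <- optimal_k_silhouette(feats, k_range)
  fit <- kmedoids_pam(feats, sel$k)
  labels <- fit$clustering
  names(labels) <- feats$gene_id
  if (sel$k == 2) {
    mean_rel <- tapply(feats$rel_dpau, fit$clustering, mean)
    full <- as.integer(names(which.max(mean_rel)))
    labels <- ifelse(fit$clustering == full, "full-rescue", "attenuated")
    names(labels) <- feats$gene_id
  }
  list(features = feats, k = sel$k, pam = fit, labels = labels,
       silhouette = sel$widths)
}
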