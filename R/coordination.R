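# Sample clustering and the mitonuclear-coordination readout: within-treatment
# coherence (mean pairwise Pearson r) and two-cut treatment-separation purity,
# contrasted between the nuclear-encoded and mtDNA-encoded probe subsets.

#' Pairwise-complete Pearson correlation between samples
#'
#' @param x Probes x samples matrix (log2 ratios; NAs allowed).
#' @param min_shared Minimum probes shared by a sample pair (default 3).
#' @return Samples x samples correlation matrix.
#' @export
correlation_matrix <- function(x, min_shared = 3L) {
  if (ncol(x) < 2L) stop("need at least two samples")
  shared <- crossprod(!is.na(x))
  if (any(shared < min_shared)) {
    bad <- which(shared < min_shared, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    pair <- if (nrow(bad)) {
      paste(colnames(x)[bad[1, 1]], colnames(x)[bad[1, 2]], sep = " / ")
    } else "(diagonal)"
    stop("sample pair ", pair, " shares fewer than ", min_shared, " probes")
  }
  cmat <- cor(x, use = "pairwise.complete.obs")
  diag(cmat) <- 1
  cmat
}

#' Average-linkage agglomerative clustering on a correlation matrix
#'
#' Distance is `1 - r`. Linkage follows the Lance-Williams update for
#' unweighted average linkage (UPGMA). Ties are broken deterministically in
#' favor of the pair whose smallest original sample index is lowest. Returns
#' an `hclust`-compatible object so that [stats::cutree()] and plotting work.
#'
#' @param cmat Symmetric correlation matrix with unit diagonal.
#' @return Object of class `hclust`.
#' @export
hierarchical_cluster <- function(cmat) {
  if (!isSymmetric(unname(cmat), tol = 1e-8)) {
    stop("correlation matrix must be symmetric")
  }
  n <- nrow(cmat)
  labels <- colnames(cmat)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- 1 - cmat
  diag(d) <- Inf

  # active cluster bookkeeping: id (hclust convention), size, smallest member
  id <- -seq_len(n)
  size <- rep(1L, n)
  minmem <- seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL; best_d <- Inf
    for (ii in seq_along(act)) {
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        i <- act[ii]; j <- act[jj]
        dij <- d[i, j]
        better <- dij < best_d - 1e-12
        tie <- abs(dij - best_d) <= 1e-12
        if (better ||
            (tie && min(minmem[i], minmem[j]) <
               min(minmem[best[1]], minmem[best[2]]))) {
          best <- c(i, j); best_d <- dij
        }
      }
    }
    i <- best[1]; j <- best[2]
    # hclust convention: singletons (negative) before clusters (positive);
    # two singletons ordered by original index, two clusters by merge step
    a <- id[i]; b <- id[j]
    pr <- if (a < 0 && b < 0) -sort(c(-a, -b)) else
          if (a > 0 && b > 0) sort(c(a, b)) else c(min(a, b), max(a, b))
    merge[step, ] <- pr
    height[step] <- best_d

    # Lance-Williams average-linkage update into slot i
    for (k in act) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    minmem[i] <- min(minmem[i], minmem[j])
    id[i] <- step
    active[j] <- FALSE
  }

  # leaf order by left-to-right traversal of the merge tree
  traverse <- function(node) {
    if (node < 0) return(-node)
    c(traverse(merge[node, 1]), traverse(merge[node, 2]))
  }
  order <- traverse(n - 1L)

  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "average",
                 dist.method = "1 - pearson", call = match.call()),
            class = "hclust")
}

#' Mean within-treatment pairwise correlation (coherence r)
#'
#' @param cmat Samples x samples correlation matrix.
#' @param design Data.frame with columns `sample_id` and `treatment` covering
#'   every matrix column.
#' @return Data.frame with columns `treatment`, `r`, `n`. Singleton
#'   treatments get `r = NA`.
#' @export
group_coherence <- function(cmat, design) {
  idx <- match(colnames(cmat), design$sample_id)
  if (anyNA(idx)) stop("design does not cover all samples")
  treat <- design$treatment[idx]
  out <- lapply(unique(treat), function(tr) {
    cols <- which(treat == tr)
    r <- if (length(cols) < 2L) NA_real_ else {
      sub <- cmat[cols, cols]
      mean(sub[upper.tri(sub)])
    }
    data.frame(treatment = tr, r = r, n = length(cols),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-cluster treatment-separation purity
#'
#' The dendrogram is cut into two clusters; purity is the fraction of samples
#' whose cluster's majority treatment equals their own; a tied cluster
#' contributes the size of one tied class.
#'
#' @param hc An `hclust` object over the samples.
#' @param design Data.frame with `sample_id` and `treatment`.
#' @return Purity in `[0, 1]`.
#' @export
treatment_separation <- function(hc, design) {
  k <- cutree(hc, k = 2L)
  idx <- match(hc$labels, design$sample_id)
  if (anyNA(idx)) stop("design does not cover all samples")
  treat <- design$treatment[idx]
  correct <- 0L
  for (cl in unique(k)) {
    tab <- table(treat[k == cl])
    correct <- correct + max(tab)
  }
  correct / length(k)
}

#' Cluster one probe subset and compute its coordination statistics
#'
#' @param values Probes x samples matrix for the subset (e.g. from
#'   [subset_by_origin()]).
#' @param design Data.frame with `sample_id` and `treatment`.
#' @param subset Name recorded in the result.
#' @return Object of class `cluster_result`: list with `subset`,
#'   `correlations`, `dendrogram`, `coherence`, `purity`, `leaf_order`.
#' @export
cluster_subset <- function(values, design, subset = "subset") {
  cmat <- correlation_matrix(values)
  hc <- hierarchical_cluster(cmat)
  structure(list(subset = subset,
                 correlations = cmat,
                 dendrogram = hc,
                 coherence = group_coherence(cmat, design),
                 purity = treatment_separation(hc, design),
                 leaf_order = hc$labels[hc$order]),
            class = "cluster_result")
}

#' Contrast coordination between nuclear-mito and mtDNA probe subsets
#'
#' Reports the purity difference `purity(nuclear_mito) - purity(mtdna)`, the
#' per-treatment coherence of each subset, and labels the sample set
#' `"disrupted"` when the difference exceeds `margin` (nuclear-encoded
#' mitochondrial genes separate by treatment while mtDNA-encoded genes
#' intermix), `"coordinated"` otherwise.
#'
#' @param result_nuclear `cluster_result` for the nuclear-mito subset.
#' @param result_mtdna `cluster_result` for the mtDNA subset.
#' @param margin Purity-difference margin for the disrupted label.
#' @return List with `purity_nuclear_mito`, `purity_mtdna`,
#'   `purity_difference`, `coherence` (both subsets), `label`.
#' @export
coordination_contrast <- function(result_nuclear, result_mtdna,
                                  margin = 0.2) {
  sn <- colnames(result_nuclear$correlations)
  sm <- colnames(result_mtdna$correlations)
  if (!setequal(sn, sm)) {
    stop("subset results were computed on different sample sets")
  }
  diff <- result_nuclear$purity - result_mtdna$purity
  coh <- rbind(
    cbind(subset = result_nuclear$subset, result_nuclear$coherence),
    cbind(subset = result_mtdna$subset, result_mtdna$coherence)
  )
  list(purity_nuclear_mito = result_nuclear$purity,
       purity_mtdna = result_mtdna$purity,
       purity_difference = diff,
       coherence = coh,
       label = if (diff > margin) "disrupted" else "coordinated")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An `hclust` object.
#' @return Newick character scalar (branch lengths from merge heights).
#' @export
dendrogram_newick <- function(hc) {
  node_height <- function(node) if (node < 0) 0 else hc$height[node]
  build <- function(node) {
    if (node < 0) return(hc$labels[-node])
    h <- hc$height[node]
    kids <- vapply(hc$merge[node, ], function(ch) {
      sprintf("%s:%.6g", build(ch), h - node_height(ch))
    }, "")
    sprintf("(%s,%s)", kids[1], kids[2])
  }
  paste0(build(nrow(hc$merge)), ";")
}
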