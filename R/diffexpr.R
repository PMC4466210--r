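# Differential expression per the study's rule (Welch t, Benjamini-Hochberg
# FDR, fold change >= 1.5) and Fisher-exact gene-set enrichment.

#' Welch's two-sample t-test
#'
#' `t = (mean_A - mean_B) / sqrt(s2_A/n_A + s2_B/n_B)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p from the t
#' distribution.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least two values per group")
  }
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) stop("degenerate test: zero variance in both groups")
  na <- length(a); nb <- length(b)
  se2a <- va / na; se2b <- vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Row-wise Welch t over two column-subsets of a matrix; NAs allowed.
# Returns a data.frame(t, df, p, n_a, n_b, mean_a, mean_b).
.welch_t_rows <- function(x, cols_a, cols_b) {
  xa <- x[, cols_a, drop = FALSE]; xb <- x[, cols_b, drop = FALSE]
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- apply(xa, 1L, var, na.rm = TRUE)
  vb <- apply(xb, 1L, var, na.rm = TRUE)
  se2a <- va / na; se2b <- vb / nb
  tstat <- (ma - mb) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  data.frame(t = tstat, df = df, p = p, n_a = na, n_b = nb,
             mean_a = ma, mean_b = mb)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are `min over j >= i of p(j) * m / j` on the sorted scale,
#' capped at 1, returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adjusted <- rev(cummin(rev(ranked)))
  adjusted <- pmin(adjusted, 1)
  out <- numeric(m)
  out[ord] <- adjusted
  out
}

#' Call differentially expressed probes (clones vs controls)
#'
#' Fold change is `2^(mean log2 ratio in clones - mean log2 ratio in
#' controls)`. A probe is differentially expressed when
#' `fold_change >= fc_threshold` or `fold_change <= 1/fc_threshold`
#' (both boundaries inclusive) and the Benjamini-Hochberg adjusted Welch p is
#' `<= alpha` (inclusive; set `adjust = "raw"` to threshold the unadjusted p
#' instead). Probes missing in more than half of either group's samples are
#' dropped with a recorded reason.
#'
#' @param values Probes x samples matrix of combined log2 ratios (e.g. an
#'   `expression_matrix` `values` element restricted to informative probes).
#' @param design Data.frame with `sample_id` and `treatment`
#'   (`clone`/`control`) covering the matrix columns.
#' @param annotation Probe annotation (for `genome_of_origin`); optional.
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param alpha Significance threshold on the (adjusted) p (default 0.05).
#' @param adjust `"BH"` (default) or `"raw"`.
#' @return Data.frame of class `de_result` with columns `probe_id`,
#'   `gene_symbol`, `genome_of_origin`, `log2fc`, `fold_change`, `welch_t`,
#'   `welch_df`, `p_raw`, `p_adj`, `de`, `direction`; attribute `dropped`
#'   lists probes excluded for missingness.
#' @export
call_de <- function(values, design, annotation = NULL,
                    fc_threshold = 1.5, alpha = 0.05,
                    adjust = c("BH", "raw")) {
  adjust <- match.arg(adjust)
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  idx <- match(colnames(values), design$sample_id)
  if (anyNA(idx)) stop("design does not cover all samples")
  treat <- design$treatment[idx]
  cols_a <- which(treat == "clone"); cols_b <- which(treat == "control")
  if (length(cols_a) < 2L || length(cols_b) < 2L) {
    stop("need at least two clones and two controls")
  }

  n_a_obs <- rowSums(!is.na(values[, cols_a, drop = FALSE]))
  n_b_obs <- rowSums(!is.na(values[, cols_b, drop = FALSE]))
  keep <- n_a_obs > length(cols_a) / 2 & n_b_obs > length(cols_b) / 2 &
    n_a_obs >= 2 & n_b_obs >= 2
  dropped <- rownames(values)[!keep]
  x <- values[keep, , drop = FALSE]

  w <- .welch_t_rows(x, cols_a, cols_b)
  log2fc <- w$mean_a - w$mean_b
  p_adj <- bh_adjust(w$p)
  p_eff <- if (adjust == "BH") p_adj else w$p
  fc <- 2^log2fc
  up <- fc >= fc_threshold & p_eff <= alpha
  down <- fc <= 1 / fc_threshold & p_eff <= alpha
  direction <- ifelse(up, "up", ifelse(down, "down", "none"))

  out <- data.frame(probe_id = rownames(x),
                    log2fc = log2fc, fold_change = fc,
                    welch_t = w$t, welch_df = w$df,
                    p_raw = w$p, p_adj = p_adj,
                    de = up | down, direction = direction,
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    ai <- match(out$probe_id, annotation$probe_id)
    out$gene_symbol <- annotation$gene_symbol[ai]
    out$genome_of_origin <- annotation$genome_of_origin[ai]
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("de_result", class(out))
  out
}

#' Partition differentially expressed probes by genome of origin
#'
#' @param de A `de_result` from [call_de()] (must carry `genome_of_origin`,
#'   i.e. `call_de()` was given an annotation) or any data.frame with
#'   `probe_id`, `de`, `direction`.
#' @param annotation Used to annotate when `de` lacks `genome_of_origin`.
#' @return Data.frame with columns `genome_of_origin`, `up`, `down`, `total`.
#' @export
partition_by_origin <- function(de, annotation = NULL) {
  if (!"genome_of_origin" %in% names(de)) {
    if (is.null(annotation)) stop("no annotation available")
    ai <- match(de$probe_id, annotation$probe_id)
    if (anyNA(ai)) {
      stop("unannotated probe(s): ",
           paste(de$probe_id[is.na(ai)][1:min(3, sum(is.na(ai)))],
                 collapse = ", "))
    }
    de$genome_of_origin <- annotation$genome_of_origin[ai]
  }
  if (anyNA(de$genome_of_origin)) stop("unannotated probe(s) in DE results")
  hits <- de[de$de, , drop = FALSE]
  origins <- c("nuclear", "mitochondrial")
  out <- lapply(origins, function(o) {
    sub <- hits[hits$genome_of_origin == o, , drop = FALSE]
    data.frame(genome_of_origin = o,
               up = sum(sub$direction == "up"),
               down = sum(sub$direction == "down"),
               total = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the two-sided p is the sum of probabilities
#' of all tables (under the hypergeometric null) whose probability does not
#' exceed that of the observed table (minimum-likelihood method). The sample
#' odds ratio `(a*d)/(b*c)` gets a 0.5 (Haldane) continuity correction only
#' when some cell is zero; the p-value is never continuity-corrected. A zero
#' row or column margin gives `p = 1` and a missing odds ratio.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`a`,`b` top row; `c`,`d` bottom row); alternatively `a` may be a 2x2
#'   matrix.
#' @return List with `odds_ratio`, `p`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (any(cells == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p = p)
}

#' Gene-set enrichment of a DE set by Fisher's exact test
#'
#' For each set, tests the 2x2 table (DE and in set, DE not in set, set not
#' DE, neither) over the supplied universe; p-values are Benjamini-Hochberg
#' adjusted across sets.
#'
#' @param de_genes Character vector of differentially expressed gene
#'   identifiers (must be a subset of `universe`).
#' @param gene_sets Named list of character vectors (each a subset of
#'   `universe`).
#' @param universe Character vector: all testable genes.
#' @return Data.frame with `gene_set`, the four cell counts, `odds_ratio`,
#'   `p`, `p_adj`, sorted by `p`.
#' @export
enrich <- function(de_genes, gene_sets, universe) {
  de_genes <- unique(de_genes)
  outside <- setdiff(de_genes, universe)
  if (length(outside)) {
    stop("DE gene(s) outside universe: ",
         paste(utils::head(outside, 3), collapse = ", "))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    a <- length(intersect(de_genes, set))
    b <- length(setdiff(de_genes, set))
    c <- length(setdiff(set, de_genes))
    d <- length(universe) - a - b - c
    ft <- fisher_exact(a, b, c, d)
    data.frame(gene_set = nm, de_in_set = a, de_not_set = b,
               set_not_de = c, neither = d,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (read).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "")
  sets
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @param description Optional per-set description (recycled).
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
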