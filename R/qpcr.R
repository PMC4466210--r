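# Comparative-CT (delta-delta-Ct) relative quantification, group comparison
# by F-test-then-one-sided-t, and microarray directionality concordance.

#' Comparative-CT relative quantification
#'
#' Replicate Cts are averaged per sample and gene. Then
#' `delta_ct = Ct_gene - Ct_control_gene`,
#' `delta_delta_ct = delta_ct - delta_ct(calibrator)` and
#' `rq = 2^(-delta_delta_ct)` (perfect, 2-fold-per-cycle amplification
#' efficiency assumed). The calibrator sample has `rq = 1` for every gene.
#'
#' @param records Data.frame with columns `sample`, `gene`, `ct` (a
#'   `replicate` column is allowed and averaged over).
#' @param control_gene Internal-control gene (default `"TBB2"`).
#' @param calibrator_sample Calibrator sample name (default `"REF"`).
#' @return Data.frame with `sample`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `rq`.
#' @export
comparative_ct <- function(records, control_gene = "TBB2",
                           calibrator_sample = "REF") {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(records))) {
    stop("records must have columns sample, gene, ct")
  }
  mean_ct <- stats::aggregate(ct ~ sample + gene, data = records, FUN = mean)

  ctrl <- mean_ct[mean_ct$gene == control_gene, c("sample", "ct")]
  if (nrow(ctrl) == 0) stop("control gene ", control_gene, " absent")
  names(ctrl)[2] <- "ct_control"

  targets <- mean_ct[mean_ct$gene != control_gene, , drop = FALSE]
  missing_ctrl <- setdiff(unique(targets$sample), ctrl$sample)
  if (length(missing_ctrl)) {
    stop("control gene ", control_gene, " missing for sample(s): ",
         paste(missing_ctrl, collapse = ", "))
  }
  dat <- merge(targets, ctrl, by = "sample")
  dat$delta_ct <- dat$ct - dat$ct_control

  cal <- dat[dat$sample == calibrator_sample, c("gene", "delta_ct")]
  missing_cal <- setdiff(unique(dat$gene), cal$gene)
  if (nrow(cal) == 0 || length(missing_cal)) {
    stop("calibrator sample ", calibrator_sample, " missing for gene(s): ",
         paste(if (length(missing_cal)) missing_cal else unique(dat$gene),
               collapse = ", "))
  }
  names(cal)[2] <- "delta_ct_cal"
  dat <- merge(dat, cal, by = "gene")
  dat$delta_delta_ct <- dat$delta_ct - dat$delta_ct_cal
  dat$rq <- 2^(-dat$delta_delta_ct)
  out <- dat[order(dat$gene, dat$sample),
             c("sample", "gene", "delta_ct", "delta_delta_ct", "rq")]
  rownames(out) <- NULL
  out
}

#' Compare clone vs control relative expression for one gene
#'
#' Variances are first compared by a two-sided F-test at `alpha_f`. When the
#' F-test is not significant a pooled-variance one-sided t-test is used; when
#' it is significant, a Welch one-sided t-test. The test direction (which
#' one-sided alternative) is taken from the microarray fold change of the
#' same gene (`"up"`: clones > controls). Significance is declared at
#' `p < alpha` (strict).
#'
#' @param clones,controls Numeric vectors of relative expression (or log
#'   relative expression) per group, length >= 2 each.
#' @param direction `"up"` or `"down"`: the microarray direction being
#'   validated.
#' @param alpha_f F-test significance level (default 0.05).
#' @param alpha One-sided t significance level (default 0.05).
#' @return List with `f_p`, `equal_variance`, `method` (`"pooled"` or
#'   `"welch"`), `t`, `df`, `t_p`, `significant`.
#' @export
compare_groups <- function(clones, controls, direction = c("up", "down"),
                           alpha_f = 0.05, alpha = 0.05) {
  if (is.null(direction) || length(direction) == 0 || is.na(direction[1])) {
    stop("test direction unspecified (no microarray result for this gene)")
  }
  direction <- match.arg(direction)
  clones <- clones[!is.na(clones)]; controls <- controls[!is.na(controls)]
  n1 <- length(clones); n2 <- length(controls)
  if (n1 < 2L || n2 < 2L) stop("need at least two values per group")

  v1 <- var(clones); v2 <- var(controls)
  if (v1 == 0 && v2 == 0) {
    f_p <- 1
  } else if (v2 == 0 || v1 == 0) {
    f_p <- 0
  } else {
    f_stat <- v1 / v2
    pf_lower <- pf(f_stat, n1 - 1, n2 - 1)
    f_p <- min(1, 2 * min(pf_lower, 1 - pf_lower))
  }
  equal_var <- f_p >= alpha_f

  diff <- mean(clones) - mean(controls)
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "pooled"
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    method <- "welch"
  }
  if (se == 0) {
    tstat <- 0; t_p <- 0.5
  } else {
    tstat <- diff / se
    t_p <- if (direction == "up") pt(tstat, df, lower.tail = FALSE)
           else pt(tstat, df, lower.tail = TRUE)
  }
  list(f_p = f_p, equal_variance = equal_var, method = method,
       t = tstat, df = df, t_p = t_p, significant = t_p < alpha)
}

#' qPCR vs microarray directionality concordance
#'
#' For each validated gene, the microarray direction (sign of the DE fold
#' change) is compared with the qPCR direction (sign of
#' `mean(clone rq) - mean(control rq)`). Genes absent from either platform
#' are reported as missing rather than discordant.
#'
#' @param rq Data.frame from [comparative_ct()] (columns `sample`, `gene`,
#'   `rq`).
#' @param design Data.frame with `sample_id` and `treatment`
#'   (`clone`/`control`).
#' @param de Data.frame with `gene_symbol` and `log2fc` (e.g. a `de_result`).
#' @param genes Genes to report (default: all genes in `rq`).
#' @return List with `table` (per-gene directions and agreement) and
#'   `agreement_fraction` (over genes present on both platforms).
#' @export
concordance <- function(rq, design, de, genes = unique(rq$gene)) {
  rows <- lapply(genes, function(g) {
    sub <- rq[rq$gene == g & rq$sample %in% design$sample_id, , drop = FALSE]
    micro <- de$log2fc[match(g, de$gene_symbol)]
    if (nrow(sub) == 0 || is.na(micro)) {
      return(data.frame(gene = g, microarray = NA_character_,
                        qpcr = NA_character_, agree = NA,
                        stringsAsFactors = FALSE))
    }
    treat <- design$treatment[match(sub$sample, design$sample_id)]
    qdiff <- mean(sub$rq[treat == "clone"]) -
      mean(sub$rq[treat == "control"])
    qd <- if (qdiff > 0) "up" else if (qdiff < 0) "down" else "none"
    md <- if (micro > 0) "up" else if (micro < 0) "down" else "none"
    data.frame(gene = g, microarray = md, qpcr = qd,
               agree = identical(md, qd), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  usable <- !is.na(tab$agree)
  list(table = tab,
       agreement_fraction = if (any(usable)) mean(tab$agree[usable])
                            else NA_real_)
}
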