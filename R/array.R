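# Two-channel array processing: background subtraction, present calls,
# per-slide Lowess (MA) normalization, dye-swap combination and the
# informative-probe filter.

#' Write / read a tab-delimited two-channel slide file
#'
#' The dialect is GenePix-result-like: a small `#`-prefixed header block
#' (format version, slide id, sample id, dye orientation) followed by a
#' tab-delimited table with columns `probe_id`, `F635_Median`, `B635_Median`,
#' `F532_Median`, `B532_Median`, `F532_pct_sat2sd`, `F635_pct_sat2sd`
#' (the `pct` columns are the fraction of feature pixels more than two SD
#' above background, per channel). Column order is free; columns are matched
#' by name.
#'
#' @param slide Slide object: list with `slide_id`, `sample_id`,
#'   `dye_orientation` and `data` (the per-probe data.frame).
#' @param path File path.
#' @return The path (write) or a slide object (read).
#' @export
write_slide <- function(slide, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mitonuclear slide v1",
               paste0("# slide_id=", slide$slide_id),
               paste0("# sample_id=", slide$sample_id),
               paste0("# dye_orientation=", slide$dye_orientation)), con)
  write.table(slide$data, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_slide
#' @export
read_slide <- function(path) {
  lines <- readLines(path, n = 20L)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(hit)) stop("slide header missing ", key, " in ", path)
    sub(paste0("^# ", key, "="), "", hit[1])
  }
  data <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("probe_id", "F635_Median", "B635_Median", "F532_Median",
            "B532_Median", "F532_pct_sat2sd", "F635_pct_sat2sd")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("slide file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  list(slide_id = get("slide_id"), sample_id = get("sample_id"),
       dye_orientation = get("dye_orientation"),
       data = data[, c(need, setdiff(names(data), need))])
}

#' Local background subtraction
#'
#' `corrected = max(foreground - background, floor)` per channel; probes hit
#' by the floor are flagged.
#'
#' @param slide A slide object (see [read_slide()]).
#' @param floor Small positive constant replacing non-positive differences.
#' @return The slide with columns `cy5`, `cy3` (background-corrected
#'   intensities) and `floored` added to `data`.
#' @export
subtract_background <- function(slide, floor = 0.5) {
  d <- slide$data
  if (any(d$F635_Median < 0 | d$B635_Median < 0 |
          d$F532_Median < 0 | d$B532_Median < 0)) {
    stop("negative foreground/background intensity")
  }
  cy5 <- d$F635_Median - d$B635_Median
  cy3 <- d$F532_Median - d$B532_Median
  floored <- cy5 < floor | cy3 < floor
  d$cy5 <- pmax(cy5, floor)
  d$cy3 <- pmax(cy3, floor)
  d$floored <- floored
  slide$data <- d
  slide
}

#' Present call from pixel statistics
#'
#' A probe is present when at least 70% of its feature pixels exceed
#' background + 2 SD in either channel (boundary inclusive).
#'
#' @param frac_cy3,frac_cy5 Fractions in `[0, 1]` (vectorized).
#' @param cutoff Presence cutoff, default 0.70.
#' @return Logical vector.
#' @export
call_present <- function(frac_cy3, frac_cy5, cutoff = 0.70) {
  if (any(c(frac_cy3, frac_cy5) < 0 | c(frac_cy3, frac_cy5) > 1)) {
    stop("pixel fractions must lie in [0, 1]")
  }
  pmax(frac_cy3, frac_cy5) >= cutoff
}

#' Per-slide Lowess (MA) normalization
#'
#' Computes `A = 0.5*log2(cy5*cy3)` and the dye-space ratio
#' `M = log2(cy5/cy3)` from background-corrected intensities, fits a locally
#' weighted regression of M on A (tricube weights, robustifying iterations)
#' and subtracts the fitted intensity-dependent bias. The returned M values
#' (raw and normalized) are oriented sample/reference using the slide's dye
#' orientation. Probes flagged by the background floor get missing M.
#'
#' @param slide A background-subtracted slide (see [subtract_background()]).
#' @param span Lowess span `f` (fraction of points in each window).
#' @param iterations Robustifying iterations.
#' @param min_probes Minimum usable probes required to fit.
#' @return Object of class `normalization_fit`: list with `probe_id`, `A`,
#'   `M_raw`, `fitted`, `M_norm` (all sample/reference oriented), `slide_id`,
#'   `sample_id`, `dye_orientation`, `span`, `iterations`.
#' @export
lowess_normalize <- function(slide, span = 0.3, iterations = 3L,
                             min_probes = 50L) {
  d <- slide$data
  usable <- d$cy5 > 0 & d$cy3 > 0 & !d$floored
  if (sum(usable) < min_probes) {
    stop("too few usable probes (", sum(usable), " < ", min_probes,
         ") on slide ", slide$slide_id)
  }
  a <- 0.5 * log2(d$cy5 * d$cy3)
  m_dye <- log2(d$cy5 / d$cy3)
  a[!usable] <- NA_real_
  m_dye[!usable] <- NA_real_

  fit <- lowess(a[usable], m_dye[usable], f = span, iter = iterations)
  fitted_dye <- rep(NA_real_, nrow(d))
  fitted_dye[usable] <- approx(fit$x, fit$y, xout = a[usable], rule = 2,
                               ties = mean)$y
  m_norm_dye <- m_dye - fitted_dye

  s <- switch(slide$dye_orientation,
              sample_in_Cy5 = 1, sample_in_Cy3 = -1,
              stop("unknown dye orientation: ", slide$dye_orientation))
  structure(list(probe_id = d$probe_id,
                 A = a,
                 M_raw = s * m_dye,
                 fitted = fitted_dye,
                 M_norm = s * m_norm_dye,
                 slide_id = slide$slide_id, sample_id = slide$sample_id,
                 dye_orientation = slide$dye_orientation,
                 span = span, iterations = iterations),
            class = "normalization_fit")
}

#' Combine a dye-swap pair into one per-probe log ratio
#'
#' Both fits are already oriented sample/reference; the pair is averaged
#' probe-wise. A probe missing on one slide takes the other slide's value;
#' missing on both stays missing.
#'
#' @param fit1,fit2 `normalization_fit` objects for the same sample with
#'   opposite dye orientations.
#' @return Named numeric vector of combined log2(sample/reference) ratios.
#' @export
combine_dye_swap <- function(fit1, fit2) {
  if (!identical(fit1$sample_id, fit2$sample_id)) {
    stop("dye-swap pair spans different samples: ", fit1$sample_id, " vs ",
         fit2$sample_id)
  }
  if (identical(fit1$dye_orientation, fit2$dye_orientation)) {
    stop("both slides have orientation ", fit1$dye_orientation,
         "; need a dye swap")
  }
  if (!identical(fit1$probe_id, fit2$probe_id)) {
    stop("slides carry different probe sets")
  }
  m <- cbind(fit1$M_norm, fit2$M_norm)
  combined <- rowMeans(m, na.rm = TRUE)
  combined[is.nan(combined)] <- NA_real_
  stats::setNames(combined, fit1$probe_id)
}

#' Informative-probe filter
#'
#' A probe is informative when (1) it is present (70% pixel rule, per
#' channel) in more than `presence_cutoff` of the slides in the reference
#' channel OR in the sample channel (strict >); (2) its median
#' background-corrected raw intensity exceeds `intensity_cutoff` (strict >)
#' in a channel satisfying clause 1; and (3) the SD of its combined
#' normalized log2 ratios across samples is below `sd_cutoff` (strict <).
#'
#' @param combined Probes x samples matrix of combined log2 ratios.
#' @param present_sample,present_reference Probes x slides logical matrices
#'   of per-channel present calls mapped to the sample / reference role.
#' @param intensity_sample,intensity_reference Probes x slides matrices of
#'   background-corrected intensities by channel role.
#' @param presence_cutoff,intensity_cutoff,sd_cutoff The three thresholds
#'   (defaults 0.90, 100, 1.4).
#' @return Object of class `expression_matrix`: list with `values` (the
#'   combined matrix), `informative` (logical), and `filter_detail` (per
#'   probe, which clauses passed).
#' @export
filter_informative <- function(combined,
                               present_sample, present_reference,
                               intensity_sample, intensity_reference,
                               presence_cutoff = 0.90,
                               intensity_cutoff = 100,
                               sd_cutoff = 1.4) {
  pres_s <- rowMeans(present_sample) > presence_cutoff
  pres_r <- rowMeans(present_reference) > presence_cutoff
  clause1 <- pres_s | pres_r

  med_s <- apply(intensity_sample, 1L, median)
  med_r <- apply(intensity_reference, 1L, median)
  # intensity is evaluated in a channel that satisfied the presence clause
  clause2 <- (pres_s & med_s > intensity_cutoff) |
    (pres_r & med_r > intensity_cutoff)

  ratio_sd <- apply(combined, 1L, sd, na.rm = TRUE)
  clause3 <- !is.na(ratio_sd) & ratio_sd < sd_cutoff

  informative <- clause1 & clause2 & clause3
  if (is.null(rownames(combined))) {
    rownames(combined) <- sprintf("P%05d", seq_len(nrow(combined)))
  }
  detail <- data.frame(probe_id = rownames(combined),
                       presence = clause1, intensity = clause2,
                       variability = clause3, informative = informative,
                       ratio_sd = ratio_sd,
                       stringsAsFactors = FALSE)
  structure(list(values = combined, informative = informative,
                 filter_detail = detail,
                 thresholds = list(presence = presence_cutoff,
                                   intensity = intensity_cutoff,
                                   sd = sd_cutoff)),
            class = "expression_matrix")
}

#' Select the informative probes of one genome-of-origin subset
#'
#' @param em An `expression_matrix`.
#' @param annotation Probe annotation covering all probes (see
#'   [generate_probe_annotation()]).
#' @param which `"global"` (all informative), `"nuclear_mito"` (informative,
#'   mitochondrial function, nuclear-encoded) or `"mtdna"` (informative,
#'   mtDNA-encoded).
#' @return The values matrix restricted to the subset's probes.
#' @export
subset_by_origin <- function(em, annotation,
                             which = c("global", "nuclear_mito", "mtdna")) {
  which <- match.arg(which)
  probes <- rownames(em$values)
  idx <- match(probes, annotation$probe_id)
  if (anyNA(idx)) stop("annotation does not cover all probes")
  ann <- annotation[idx, ]
  keep <- switch(which,
    global = em$informative,
    nuclear_mito = em$informative & ann$mito_function &
      ann$genome_of_origin == "nuclear",
    mtdna = em$informative & ann$genome_of_origin == "mitochondrial"
  )
  em$values[keep, , drop = FALSE]
}

#' Process a full slide set into a filtered expression matrix
#'
#' Runs background subtraction, present calls, per-slide Lowess
#' normalization, dye-swap combination per sample and the informative filter.
#'
#' @param slides Named list of slide objects.
#' @param design Data.frame with one row per slide: `slide_id`, `sample_id`,
#'   `dye_orientation`.
#' @param span,iterations Lowess parameters.
#' @param presence_cutoff,intensity_cutoff,sd_cutoff Filter thresholds.
#' @param floor Background-subtraction floor.
#' @return An `expression_matrix` whose `values` are probes x samples; also
#'   carries `samples` (column order) and `fits` are discarded to save
#'   memory.
#' @export
build_expression_matrix <- function(slides, design, span = 0.3,
                                    iterations = 3L,
                                    presence_cutoff = 0.90,
                                    intensity_cutoff = 100,
                                    sd_cutoff = 1.4, floor = 0.5) {
  stopifnot(all(design$slide_id %in% names(slides)))
  sample_ids <- unique(design$sample_id)
  probe_id <- slides[[design$slide_id[1]]]$data$probe_id
  n_probes <- length(probe_id)
  n_slides <- nrow(design)

  combined <- matrix(NA_real_, n_probes, length(sample_ids),
                     dimnames = list(probe_id, sample_ids))
  present_sample <- matrix(FALSE, n_probes, n_slides)
  present_reference <- matrix(FALSE, n_probes, n_slides)
  intensity_sample <- matrix(NA_real_, n_probes, n_slides)
  intensity_reference <- matrix(NA_real_, n_probes, n_slides)

  fits_by_sample <- stats::setNames(vector("list", length(sample_ids)),
                                    sample_ids)
  for (i in seq_len(n_slides)) {
    sl <- slides[[design$slide_id[i]]]
    if (!identical(sl$data$probe_id, probe_id)) {
      stop("slide ", sl$slide_id, " has a different probe set")
    }
    sl <- subtract_background(sl, floor = floor)
    pres5 <- sl$data$F635_pct_sat2sd >= 0.70
    pres3 <- sl$data$F532_pct_sat2sd >= 0.70
    if (sl$dye_orientation == "sample_in_Cy5") {
      present_sample[, i] <- pres5; present_reference[, i] <- pres3
      intensity_sample[, i] <- sl$data$cy5
      intensity_reference[, i] <- sl$data$cy3
    } else {
      present_sample[, i] <- pres3; present_reference[, i] <- pres5
      intensity_sample[, i] <- sl$data$cy3
      intensity_reference[, i] <- sl$data$cy5
    }
    fit <- lowess_normalize(sl, span = span, iterations = iterations)
    fits_by_sample[[sl$sample_id]] <-
      c(fits_by_sample[[sl$sample_id]], list(fit))
  }

  for (sid in sample_ids) {
    pair <- fits_by_sample[[sid]]
    if (length(pair) != 2L) {
      stop("sample ", sid, " has ", length(pair), " slides; expected a ",
           "dye-swap pair")
    }
    combined[, sid] <- combine_dye_swap(pair[[1]], pair[[2]])
  }

  em <- filter_informative(combined, present_sample, present_reference,
                           intensity_sample, intensity_reference,
                           presence_cutoff, intensity_cutoff, sd_cutoff)
  em$samples <- sample_ids
  em
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d probes x %d samples, %d informative (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$informative),
              100 * mean(x$informative)))
  invisible(x)
}

#' Informative fraction as the printed percentage
#'
#' @param n_informative Informative probe count.
#' @param n_total Total probe count.
#' @param digits Decimal places (default 1, matching reported values).
#' @return Numeric percentage.
#' @export
informative_percent <- function(n_informative, n_total, digits = 1L) {
  round(100 * n_informative / n_total, digits)
}
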