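# Synthetic-data generator: emulates the full study design (ND1 haplotype
# references, 22-animal cohort, 44 dye-swap two-channel arrays over 13,310
# probes, and a qPCR panel tied to the same latent expression truth).

#' Default ND1 discriminating-position panel
#'
#' Seven breed-specific ND1 polymorphisms distinguishing the Large White and
#' Duroc maternal lineages, 1-based on the ND1 coding strand with base 1 at
#' the ND1 start.
#'
#' @return A data.frame with columns `position`, `large_white`, `duroc`.
#' @export
nd1_panel <- function() {
  data.frame(
    position = c(342L, 369L, 420L, 438L, 459L, 489L, 712L),
    large_white = c("T", "T", "T", "G", "G", "C", "C"),
    duroc = c("C", "C", "C", "A", "A", "A", "T"),
    stringsAsFactors = FALSE
  )
}

# Panel positions carried in genotypes but identical in both references.
.shared_panel_calls <- function() c(`316` = "C", `528` = "T")

#' Run code with a temporary RNG seed, restoring global RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Evaluate a polynomial with ascending coefficients c0 + c1*x + c2*x^2 + ...
.polyval <- function(coeffs, x) {
  out <- rep(0, length(x))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * x^(k - 1L)
  out
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic study in one validated list. Defaults
#' reproduce the published design: 13,310 probes of which 534 are
#' nuclear-encoded mitochondrial-function genes and 32 mtDNA-encoded; a cohort
#' of 7 deceased clones + 5 controls and 5 live clones + 5 controls (44
#' dye-swap arrays in total).
#'
#' @param n_probes Total probe count.
#' @param n_nuclear_mito Nuclear-encoded mitochondrial-function probes.
#' @param n_mtdna mtDNA-encoded probes.
#' @param cohort Data.frame with columns `group` (`deceased`/`live`),
#'   `role` (`clone`/`control`) and `count`.
#' @param coordination_rho Fraction (in `[0,1]`) of mtDNA-encoded gene variance
#'   shared with the nuclear-mitochondrial latent factor. 1 = fully
#'   coordinated expression, 0 = independent.
#' @param treatment_effect_sd SD (log2 units) of per-probe expression shifts
#'   applied to clones.
#' @param treatment_factor_shift Shift (in factor SD units) of the
#'   nuclear-mitochondrial program score in clones; this is the route by which
#'   a treatment signal propagates to mtDNA-encoded genes when
#'   `coordination_rho > 0`.
#' @param treatment_effect_scope Which probes receive per-probe clone shifts:
#'   `"nuclear"` (default: everything not mtDNA-encoded), `"all"`,
#'   `"nuclear_mito"`, `"mtdna"` or `"none"`.
#' @param noise_sd Per-measurement technical noise SD, log2 units.
#' @param probe_baseline_sd SD (log2 units) of the per-probe tissue-versus-
#'   reference baseline profile shared by every sample; this is what makes
#'   all samples of one tissue correlate highly against a pooled reference.
#' @param factor_sd_control,factor_sd_clone SD of the nuclear-mitochondrial
#'   program score within controls and within clones (clones are more
#'   variable, reflecting heterogeneous reprogramming).
#' @param biological_sd_control,biological_sd_clone SD (log2 units) of
#'   per-sample, per-probe biological deviations. The larger clone value is
#'   what renders cloned animals less mutually coherent than controls.
#' @param dye_bias_coeffs Ascending polynomial coefficients of the
#'   intensity-dependent dye bias in M as a function of A.
#' @param present_fraction_null Fraction of probes simulated as unexpressed so
#'   that they fail the 70%-of-pixels present rule.
#' @param heteroplasmy_fraction Fraction of clones carrying a minor
#'   (donor-cell derived) mtDNA haplotype.
#' @param heteroplasmy_range Range the minor-haplotype fraction is drawn from.
#' @param seed Integer seed; identical configurations give bit-identical
#'   outputs.
#' @param baseline_log2_range Range of per-probe baseline log2 intensities
#'   (default spans raw values of roughly 1e2 to 1e5).
#' @param background_mean,background_sd Per-spot local background level.
#' @param array_a_sd Slide-to-slide jitter of per-probe A values.
#' @param loading_mean,loading_sd Distribution of per-probe loadings on the
#'   latent factors.
#' @param qpcr_noise_sd Ct measurement noise, cycles.
#' @param qpcr_replicates Technical qPCR replicates per sample and gene.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 13310L,
                       n_nuclear_mito = 534L,
                       n_mtdna = 32L,
                       cohort = NULL,
                       coordination_rho = 0.5,
                       treatment_effect_sd = 0.5,
                       treatment_factor_shift = 1.5,
                       treatment_effect_scope = c("nuclear", "all",
                                                  "nuclear_mito", "mtdna",
                                                  "none"),
                       noise_sd = 0.4,
                       probe_baseline_sd = 1.0,
                       factor_sd_control = 0.4,
                       factor_sd_clone = 0.7,
                       biological_sd_control = 0.15,
                       biological_sd_clone = 0.4,
                       dye_bias_coeffs = c(2.0, -0.25, 0.006),
                       present_fraction_null = 0.2,
                       heteroplasmy_fraction = 0.25,
                       heteroplasmy_range = c(0.05, 0.20),
                       seed = 1L,
                       baseline_log2_range = c(5, 17),
                       background_mean = 60,
                       background_sd = 8,
                       array_a_sd = 0.2,
                       loading_mean = 0.6,
                       loading_sd = 0.4,
                       qpcr_noise_sd = 0.15,
                       qpcr_replicates = 3L) {
  if (is.null(cohort)) {
    cohort <- data.frame(
      group = c("deceased", "deceased", "live", "live"),
      role = c("clone", "control", "clone", "control"),
      count = c(7L, 5L, 5L, 5L),
      stringsAsFactors = FALSE
    )
  }
  treatment_effect_scope <- match.arg(treatment_effect_scope)
  cfg <- list(
    n_probes = as.integer(n_probes),
    n_nuclear_mito = as.integer(n_nuclear_mito),
    n_mtdna = as.integer(n_mtdna),
    cohort = cohort,
    coordination_rho = coordination_rho,
    treatment_effect_sd = treatment_effect_sd,
    treatment_factor_shift = treatment_factor_shift,
    treatment_effect_scope = treatment_effect_scope,
    noise_sd = noise_sd,
    probe_baseline_sd = probe_baseline_sd,
    factor_sd_control = factor_sd_control,
    factor_sd_clone = factor_sd_clone,
    biological_sd_control = biological_sd_control,
    biological_sd_clone = biological_sd_clone,
    dye_bias_coeffs = as.numeric(dye_bias_coeffs),
    present_fraction_null = present_fraction_null,
    heteroplasmy_fraction = heteroplasmy_fraction,
    heteroplasmy_range = as.numeric(heteroplasmy_range),
    seed = as.integer(seed),
    baseline_log2_range = as.numeric(baseline_log2_range),
    background_mean = background_mean,
    background_sd = background_sd,
    array_a_sd = array_a_sd,
    loading_mean = loading_mean,
    loading_sd = loading_sd,
    qpcr_noise_sd = qpcr_noise_sd,
    qpcr_replicates = as.integer(qpcr_replicates)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (n_nuclear_mito + n_mtdna > n_probes) {
      stop("n_nuclear_mito + n_mtdna exceeds n_probes")
    }
    if (coordination_rho < 0 || coordination_rho > 1) {
      stop("coordination_rho must lie in [0, 1]")
    }
    for (nm in c("treatment_effect_sd", "noise_sd", "qpcr_noise_sd",
                 "array_a_sd", "background_sd")) {
      if (config[[nm]] < 0) stop(nm, " must be >= 0")
    }
    if (present_fraction_null < 0 || present_fraction_null > 1) {
      stop("present_fraction_null must lie in [0, 1]")
    }
    if (heteroplasmy_fraction < 0 || heteroplasmy_fraction > 1) {
      stop("heteroplasmy_fraction must lie in [0, 1]")
    }
    req <- c("group", "role", "count")
    if (!all(req %in% names(cohort))) {
      stop("cohort must have columns group, role, count")
    }
    if (any(cohort$count < 0)) stop("cohort counts must be >= 0")
  })
  invisible(config)
}

#' Generate a synthetic Large White / Duroc ND1 reference pair
#'
#' Builds a random in-frame coding backbone (default 957 bases, the length of
#' porcine ND1) and plants the panel substitutions so that, by construction,
#' every panel substitution is synonymous under the vertebrate mitochondrial
#' code. The two returned references differ exactly at the panel positions.
#'
#' @param seed Integer seed.
#' @param panel Data.frame as from [nd1_panel()]: `position`, `large_white`,
#'   `duroc`.
#' @param seq_length Backbone length; must be a multiple of 3 and cover all
#'   panel positions.
#' @param nonsense_at_528 If `TRUE`, the codon containing base 528 is fixed to
#'   `TAT` (Tyr) so that the single-base variant `T528A` creates a `TAA` stop;
#'   the planted variant is reported in the `nonsense_variant` element.
#' @param shared_calls Named character vector of panel positions carried in
#'   genotypes but identical in both references (defaults: 316 = C, 528 = T).
#' @return A list with elements `large_white` and `duroc` (each a
#'   [haplotype_reference()]), `panel`, and `nonsense_variant` (or `NULL`).
#' @export
generate_reference_pair <- function(seed = 1L,
                                    panel = nd1_panel(),
                                    seq_length = 957L,
                                    nonsense_at_528 = FALSE,
                                    shared_calls = .shared_panel_calls()) {
  seq_length <- as.integer(seq_length)
  if (seq_length %% 3L != 0L) stop("seq_length must be a multiple of 3")
  if (nrow(panel) > 0 && any(panel$position > seq_length)) {
    bad <- panel$position[panel$position > seq_length]
    stop("panel position(s) beyond sequence length: ",
         paste(bad, collapse = ", "))
  }
  shared_pos <- as.integer(names(shared_calls))
  if (length(shared_pos) && any(shared_pos > seq_length)) {
    stop("shared panel position beyond sequence length")
  }
  sense <- setdiff(names(.mito_code), .mito_stop_codons)
  n_codons <- seq_length %/% 3L

  with_seed(seed, {
    codons <- sample(sense, n_codons, replace = TRUE)
    codons[1L] <- "ATG"

    codon_of <- function(pos) ((pos - 1L) %/% 3L) + 1L
    offset_of <- function(pos) ((pos - 1L) %% 3L) + 1L

    constrained <- c(panel$position, shared_pos)
    if (anyDuplicated(codon_of(constrained))) {
      stop("two constrained panel positions fall in the same codon")
    }

    # Shared positions: any sense codon carrying the required base.
    for (i in seq_along(shared_pos)) {
      pos <- shared_pos[i]; o <- offset_of(pos)
      cand <- sense[substr(sense, o, o) == shared_calls[i]]
      codons[codon_of(pos)] <- sample(cand, 1L)
    }
    nonsense_variant <- NULL
    if (nonsense_at_528) {
      if (!"528" %in% names(shared_calls) || shared_calls[["528"]] != "T") {
        stop("nonsense_at_528 requires shared call T at position 528")
      }
      codons[codon_of(528L)] <- "TAT"
      nonsense_variant <- list(position = 528L, ref = "T", alt = "A")
    }

    # Panel positions: codon must carry the Large White base and the Duroc
    # substitution must be synonymous and non-stop.
    if (nrow(panel) > 0) {
      for (i in seq_len(nrow(panel))) {
        pos <- panel$position[i]; o <- offset_of(pos)
        ref_b <- toupper(panel$large_white[i])
        alt_b <- toupper(panel$duroc[i])
        cand <- sense[substr(sense, o, o) == ref_b]
        ok <- vapply(cand, function(cd) {
          alt_cd <- cd
          substr(alt_cd, o, o) <- alt_b
          alt_cd %in% sense &&
            identical(unname(.mito_code[alt_cd]), unname(.mito_code[cd]))
        }, logical(1))
        if (!any(ok)) {
          stop("requested synonymous substitution impossible at position ",
               pos, " given the reading frame")
        }
        codons[codon_of(pos)] <- sample(cand[ok], 1L)
      }
    }

    seq_a <- paste(codons, collapse = "")
    seq_b <- seq_a
    if (nrow(panel) > 0) {
      for (i in seq_len(nrow(panel))) {
        substr(seq_b, panel$position[i], panel$position[i]) <-
          toupper(panel$duroc[i])
      }
    }

    all_pos <- sort(unique(c(panel$position, shared_pos)))
    call_at <- function(s, pos) substr(s, pos, pos)
    calls_a <- stats::setNames(vapply(all_pos, call_at, "", s = seq_a), all_pos)
    calls_b <- stats::setNames(vapply(all_pos, call_at, "", s = seq_b), all_pos)

    list(
      large_white = haplotype_reference("Large White", "AF486874",
                                        calls_a, seq_a),
      duroc = haplotype_reference("Duroc", "AY337045", calls_b, seq_b),
      panel = panel,
      nonsense_variant = nonsense_variant
    )
  })
}

# Breed assignment mirroring the published cohort when counts match the
# default design; round-robin otherwise.
.default_breed_pattern <- list(
  deceased.control = rep("Large White", 5),
  deceased.clone = c("Large White", "Large White", "Large White", "Duroc",
                     "Large White", "Duroc", "Duroc"),
  live.control = rep("Duroc", 5),
  live.clone = c("Large White", "Large White", "Large White", "Duroc",
                 "Large White")
)

.assign_breeds <- function(group, role, count) {
  key <- paste(group, role, sep = ".")
  pat <- .default_breed_pattern[[key]]
  if (!is.null(pat) && length(pat) == count) return(pat)
  rep(c("Large White", "Duroc"), length.out = count)
}

#' Generate the synthetic animal cohort with panel genotypes
#'
#' Breed (maternal-lineage) labels default to the published assignments when
#' cohort counts match the default design. A configurable fraction of clones
#' carries a minor (donor-cell derived) mtDNA haplotype; when the minor
#' fraction exceeds `heteroplasmy_threshold` the sequencing peaks are mixed
#' and the genotype carries IUPAC ambiguity codes at the discriminating
#' positions, flagged as heteroplasmic.
#'
#' @param config A [sim_config()].
#' @param references Reference pair, as from [generate_reference_pair()].
#' @param heteroplasmy_threshold Minor fraction above which mixed peaks appear
#'   in the genotype calls (default 0.25).
#' @return List with `animals` (data.frame), `genotypes` (list of
#'   [panel_genotype()]), and `references`.
#' @export
generate_cohort <- function(config = sim_config(),
                            references = generate_reference_pair(config$seed),
                            heteroplasmy_threshold = 0.25) {
  validate_sim_config(config)
  refs <- list(references$large_white, references$duroc)
  names(refs) <- vapply(refs, function(r) r$breed_name, "")
  disc <- discriminating_positions(references$large_white, references$duroc)

  rows <- list()
  for (i in seq_len(nrow(config$cohort))) {
    g <- config$cohort$group[i]; r <- config$cohort$role[i]
    n <- config$cohort$count[i]
    if (n == 0) next
    breeds <- .assign_breeds(g, r, n)
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = sprintf("%s_%s_%d", g, r, seq_len(n)),
      group = g, role = r, breed = breeds,
      stringsAsFactors = FALSE
    )
  }
  animals <- do.call(rbind, rows)
  rownames(animals) <- NULL

  with_seed(config$seed + 101L, {
    is_clone <- animals$role == "clone"
    het <- is_clone & runif(nrow(animals)) < config$heteroplasmy_fraction
    minor <- ifelse(het,
                    runif(nrow(animals), config$heteroplasmy_range[1],
                          config$heteroplasmy_range[2]),
                    0)
    animals$heteroplasmic <- het
    animals$minor_fraction <- minor

    genotypes <- vector("list", nrow(animals))
    for (i in seq_len(nrow(animals))) {
      major <- refs[[animals$breed[i]]]
      other <- refs[[setdiff(names(refs), animals$breed[i])]]
      calls <- major$panel_calls
      mixed <- stats::setNames(rep(FALSE, length(calls)), names(calls))
      if (het[i] && minor[i] > heteroplasmy_threshold) {
        for (p in as.character(disc)) {
          calls[p] <- .iupac_code(c(major$panel_calls[p],
                                    other$panel_calls[p]))
          mixed[p] <- TRUE
        }
      }
      genotypes[[i]] <- panel_genotype(animals$animal_id[i], animals$group[i],
                                       animals$role[i], calls, mixed)
    }
    names(genotypes) <- animals$animal_id
    list(animals = animals, genotypes = genotypes, references = references)
  })
}

#' Probe annotation for the synthetic platform
#'
#' Lays out `n_nuclear_mito` nuclear-encoded mitochondrial-function probes,
#' then `n_mtdna` mtDNA-encoded probes (named after the canonical mtDNA
#' genes), then the remaining nuclear probes. The nine qPCR validation genes
#' are mapped onto the first nuclear-mito probes and `TBB2` (the qPCR internal
#' control) onto the first non-mitochondrial probe. Probes carry gene-set
#' labels (`OXPHOS`, `FATTY ACID METABOLISM`) used by the enrichment stage.
#'
#' @param config A [sim_config()].
#' @return Data.frame with columns `probe_id`, `gene_symbol`,
#'   `genome_of_origin`, `mito_function`, `gene_sets`.
#' @export
generate_probe_annotation <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$n_probes; n_nm <- config$n_nuclear_mito; n_mt <- config$n_mtdna
  probe_id <- sprintf("PROBE_%05d", seq_len(n))
  origin <- rep("nuclear", n)
  mito <- rep(FALSE, n)
  idx_nm <- seq_len(n_nm)
  idx_mt <- n_nm + seq_len(n_mt)
  origin[idx_mt] <- "mitochondrial"
  mito[c(idx_nm, idx_mt)] <- TRUE

  symbol <- sprintf("GENE%05d", seq_len(n))
  qpcr_genes <- c("GLUL", "CEBPA", "NOTCH3", "NDUFA4", "UQCR", "ACSL1",
                  "COX4I1", "COX7C", "P38")
  symbol[idx_nm] <- sprintf("NMG%04d", seq_len(n_nm))
  symbol[seq_along(qpcr_genes)] <- qpcr_genes
  mt_names <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
                "COX1", "COX2", "COX3", "ATP6", "ATP8", "CYTB",
                "RNR1", "RNR2", sprintf("MT-TRNA%d", seq_len(max(0, n_mt - 15))))
  symbol[idx_mt] <- mt_names[seq_len(n_mt)]
  first_other <- n_nm + n_mt + 1L
  if (first_other <= n) symbol[first_other] <- "TBB2"

  gene_sets <- rep("", n)
  # OXPHOS: a block of nuclear-mito probes, the qPCR OXPHOS genes and the
  # mtDNA protein-coding genes.
  ox_nm <- idx_nm[10:min(129, n_nm)]
  gene_sets[ox_nm] <- "OXPHOS"
  gene_sets[match(c("NDUFA4", "UQCR", "COX4I1", "COX7C"), symbol)] <- "OXPHOS"
  mt_protein <- idx_mt[symbol[idx_mt] %in% c("ND1", "ND2", "ND3", "ND4",
                                             "ND4L", "ND5", "ND6", "COX1",
                                             "COX2", "COX3", "ATP6", "ATP8",
                                             "CYTB")]
  gene_sets[mt_protein] <- "OXPHOS"
  fa_nm <- idx_nm[130:min(189, n_nm)]
  gene_sets[fa_nm] <- "FATTY ACID METABOLISM"
  gene_sets[match("ACSL1", symbol)] <- "FATTY ACID METABOLISM"

  data.frame(probe_id = probe_id, gene_symbol = symbol,
             genome_of_origin = origin, mito_function = mito,
             gene_sets = gene_sets, stringsAsFactors = FALSE)
}

#' Generate latent (true) log2 expression for the cohort
#'
#' Implements the latent factor model. Every probe carries a tissue-versus-
#' reference baseline `b_i` (SD `probe_baseline_sd`) shared by all samples.
#' Sample j has a nuclear-mitochondrial program score
#' `f_j = shift*clone_j + sd(role_j) * z_j` (clones are shifted by
#' `treatment_factor_shift` and more variable) and an independent
#' mitochondrial factor `g_j`; nuclear-mito probes add `loading_i * f_j`,
#' mtDNA probes `loading_i * h_j` with `h_j = sqrt(rho) f_j +
#' sqrt(1-rho) g_j`, so the coordination parameter rho controls how much of
#' the mtDNA program (treatment response included) is shared with the
#' nuclear one. Per-probe clone shifts (`treatment_effect_sd`) apply to the
#' probes in `treatment_effect_scope`, and per-sample biological noise
#' (`biological_sd_*`, larger in clones) perturbs every probe. Values are
#' log2 ratios versus the common reference RNA; controls carry no treatment
#' effect.
#'
#' @param config A [sim_config()].
#' @param cohort Optional cohort from [generate_cohort()]; generated from
#'   `config` when missing.
#' @return An object of class `latent_expression`: list with `matrix`
#'   (probes x samples), `treatment_effects`, `factor_loadings`,
#'   `factor_scores`, `samples`, `annotation`, `config`.
#' @export
generate_latent <- function(config = sim_config(), cohort = NULL) {
  validate_sim_config(config)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  annotation <- generate_probe_annotation(config)
  samples <- cohort$animals[, c("animal_id", "group", "role")]
  names(samples)[1] <- "sample_id"
  n <- config$n_probes
  n_s <- nrow(samples)
  clone <- as.numeric(samples$role == "clone")

  with_seed(config$seed + 202L, {
    f_sd <- ifelse(clone == 1, config$factor_sd_clone,
                   config$factor_sd_control)
    f <- config$treatment_factor_shift * clone + f_sd * rnorm(n_s)
    g <- rnorm(n_s)
    rho <- config$coordination_rho
    h <- sqrt(rho) * f + sqrt(1 - rho) * g
    baseline <- rnorm(n, 0, config$probe_baseline_sd)

    loadings <- rep(0, n)
    idx_nm <- seq_len(config$n_nuclear_mito)
    idx_mt <- config$n_nuclear_mito + seq_len(config$n_mtdna)
    loadings[idx_nm] <- abs(rnorm(length(idx_nm), config$loading_mean,
                                  config$loading_sd))
    loadings[idx_mt] <- abs(rnorm(length(idx_mt), config$loading_mean,
                                  config$loading_sd))

    scope_idx <- switch(config$treatment_effect_scope,
      all = seq_len(n),
      nuclear = which(annotation$genome_of_origin == "nuclear"),
      nuclear_mito = which(annotation$mito_function &
                             annotation$genome_of_origin == "nuclear"),
      mtdna = which(annotation$genome_of_origin == "mitochondrial"),
      none = integer(0)
    )
    delta <- rep(0, n)
    delta[scope_idx] <- rnorm(length(scope_idx), 0, config$treatment_effect_sd)
    # the qPCR internal-control gene carries no treatment effect
    delta[annotation$gene_symbol == "TBB2"] <- 0

    mat <- matrix(baseline, nrow = n, ncol = n_s,
                  dimnames = list(annotation$probe_id, samples$sample_id))
    mat[idx_nm, ] <- mat[idx_nm, ] + loadings[idx_nm] %o% f
    mat[idx_mt, ] <- mat[idx_mt, ] + loadings[idx_mt] %o% h
    mat <- mat + delta %o% clone
    bio_sd <- ifelse(clone == 1, config$biological_sd_clone,
                     config$biological_sd_control)
    mat <- mat + matrix(rnorm(n * n_s), n, n_s) %*% diag(bio_sd, n_s)

    structure(list(matrix = mat, baseline = baseline,
                   treatment_effects = delta,
                   factor_loadings = loadings,
                   factor_scores = list(f = f, g = g, h = h),
                   samples = samples, annotation = annotation,
                   config = config),
              class = "latent_expression")
  })
}

#' Generate the dye-swap two-channel array dataset
#'
#' Each sample yields two slides with opposite dye orientation. Channel
#' intensities follow `Cy5 = 2^(A + M/2)`, `Cy3 = 2^(A - M/2)` where the
#' dye-space log ratio is `M = orientation * latent + bias(A) + noise` with
#' `bias` the configured intensity-dependent polynomial. Local backgrounds are
#' added to the foregrounds so that background subtraction recovers the
#' signal. Per-probe pixel-presence fractions are drawn so that roughly
#' `present_fraction_null` of probes fail the 70% rule.
#'
#' @param config A [sim_config()].
#' @param latent A `latent_expression` from [generate_latent()].
#' @return List with `slides` (named list of slide objects; see
#'   [write_slide()]) and `design` (one row per slide).
#' @export
generate_array_dataset <- function(config = sim_config(),
                                   latent = generate_latent(config)) {
  validate_sim_config(config)
  if (nrow(latent$matrix) != config$n_probes) {
    stop("latent matrix dimensions do not match config")
  }
  samples <- latent$samples
  n <- config$n_probes

  with_seed(config$seed + 303L, {
    baseline <- runif(n, config$baseline_log2_range[1],
                      config$baseline_log2_range[2])
    expressed <- runif(n) >= config$present_fraction_null

    slides <- list()
    design_rows <- list()
    for (j in seq_len(nrow(samples))) {
      for (k in 1:2) {
        orient <- if (k == 1L) "sample_in_Cy5" else "sample_in_Cy3"
        s <- if (k == 1L) 1 else -1
        slide_id <- sprintf("%s_s%d", samples$sample_id[j], k)
        a <- baseline + rnorm(n, 0, config$array_a_sd)
        m_dye <- s * latent$matrix[, j] +
          .polyval(config$dye_bias_coeffs, a) +
          rnorm(n, 0, config$noise_sd)
        cy5 <- 2^(a + m_dye / 2)
        cy3 <- 2^(a - m_dye / 2)
        bg5 <- pmax(rnorm(n, config$background_mean, config$background_sd), 1)
        bg3 <- pmax(rnorm(n, config$background_mean, config$background_sd), 1)
        frac <- function() ifelse(expressed, runif(n, 0.75, 1),
                                  runif(n, 0.30, 0.69))
        data <- data.frame(
          probe_id = rownames(latent$matrix),
          F635_Median = cy5 + bg5, B635_Median = bg5,
          F532_Median = cy3 + bg3, B532_Median = bg3,
          F532_pct_sat2sd = frac(), F635_pct_sat2sd = frac(),
          stringsAsFactors = FALSE
        )
        slides[[slide_id]] <- list(slide_id = slide_id,
                                   sample_id = samples$sample_id[j],
                                   dye_orientation = orient,
                                   data = data)
        design_rows[[length(design_rows) + 1L]] <- data.frame(
          slide_id = slide_id, sample_id = samples$sample_id[j],
          group = samples$group[j], role = samples$role[j],
          dye_orientation = orient, stringsAsFactors = FALSE
        )
      }
    }
    list(slides = slides, design = do.call(rbind, design_rows))
  })
}

#' Generate a qPCR Ct table consistent with the latent expression
#'
#' Assumes perfect (2-fold per cycle) amplification efficiency:
#' `Ct = baseline_gene - true_log2_expression + noise`. The calibrator sample
#' (the pooled reference RNA) has true log2 expression 0 for every gene, and
#' the internal-control gene carries no treatment effect in the default
#' annotation layout, so the comparative-CT method inverts the generator
#' exactly when `noise_sd = 0`.
#'
#' @param latent A `latent_expression`.
#' @param genes Character vector of gene symbols to assay (the internal
#'   control is always added).
#' @param noise_sd Ct noise SD in cycles.
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per sample and gene.
#' @param control_gene Internal-control gene symbol.
#' @param calibrator_sample Name given to the calibrator (reference) sample.
#' @return Data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @export
generate_qpcr_panel <- function(latent,
                                genes = c("GLUL", "CEBPA", "NOTCH3", "NDUFA4",
                                          "UQCR", "ACSL1", "COX4I1", "COX7C",
                                          "P38"),
                                noise_sd = 0.15,
                                seed = 1L,
                                n_replicates = 3L,
                                control_gene = "TBB2",
                                calibrator_sample = "REF") {
  genes <- union(genes, control_gene)
  idx <- match(genes, latent$annotation$gene_symbol)
  if (anyNA(idx)) {
    stop("unknown gene(s): ", paste(genes[is.na(idx)], collapse = ", "))
  }
  sample_ids <- c(calibrator_sample, latent$samples$sample_id)
  expr <- cbind(REF = 0, latent$matrix[idx, , drop = FALSE])
  colnames(expr) <- sample_ids
  rownames(expr) <- genes

  with_seed(seed + 404L, {
    baseline <- stats::setNames(runif(length(genes), 18, 28), genes)
    out <- expand.grid(replicate = seq_len(n_replicates), sample = sample_ids,
                       gene = genes, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    out <- out[, c("sample", "gene", "replicate")]
    out$ct <- baseline[out$gene] - expr[cbind(out$gene, out$sample)] +
      rnorm(nrow(out), 0, noise_sd)
    rownames(out) <- NULL
    out
  })
}

#' Run the whole generator and optionally write every pipeline input to disk
#'
#' Produces the reference pair, cohort (with FASTA-writable ND1 fragments),
#' latent expression, dye-swap slide set, design, annotation and qPCR tables.
#' With `outdir` set, writes `references.fasta`, `animals.fasta`,
#' `design.tsv`, `annotation.tsv`, `qpcr.tsv`, `sim_config.yaml` and (when
#' `write_slides = TRUE`) one tab-delimited slide file per array under
#' `slides/`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory, or `NULL` for in-memory only.
#' @param write_slides Whether to write the (large) per-slide files.
#' @return Invisible list with `references`, `cohort`, `latent`, `arrays`,
#'   `qpcr`, `annotation`.
#' @export
simulate_study <- function(config = sim_config(), outdir = NULL,
                           write_slides = FALSE) {
  validate_sim_config(config)
  references <- generate_reference_pair(config$seed)
  cohort <- generate_cohort(config, references)
  latent <- generate_latent(config, cohort)
  arrays <- generate_array_dataset(config, latent)
  qpcr <- generate_qpcr_panel(latent, noise_sd = config$qpcr_noise_sd,
                              seed = config$seed,
                              n_replicates = config$qpcr_replicates)
  sim <- list(references = references, cohort = cohort, latent = latent,
              arrays = arrays, qpcr = qpcr, annotation = latent$annotation)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_reference_fasta(references, file.path(outdir, "references.fasta"))
    write_animal_fasta(cohort, file.path(outdir, "animals.fasta"))
    design <- merge(arrays$design,
                    cohort$animals[, c("animal_id", "breed")],
                    by.x = "sample_id", by.y = "animal_id", sort = FALSE)
    write.table(design, file.path(outdir, "design.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(latent$annotation, file.path(outdir, "annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(qpcr, file.path(outdir, "qpcr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cfg <- config
    class(cfg) <- NULL
    cfg$cohort <- as.list(cfg$cohort)
    yaml::write_yaml(cfg, file.path(outdir, "sim_config.yaml"))
    if (write_slides) {
      slide_dir <- file.path(outdir, "slides")
      dir.create(slide_dir, showWarnings = FALSE)
      for (sl in arrays$slides) {
        write_slide(sl, file.path(slide_dir, paste0(sl$slide_id, ".tsv")))
      }
    }
  }
  invisible(sim)
}

#' Write the reference pair as FASTA
#' @param references As from [generate_reference_pair()].
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(references, path) {
  seqs <- Biostrings::DNAStringSet(c(references$large_white$coding_sequence,
                                     references$duroc$coding_sequence))
  names(seqs) <- c(
    paste(gsub(" ", "_", references$large_white$breed_name),
          references$large_white$accession_label),
    paste(gsub(" ", "_", references$duroc$breed_name),
          references$duroc$accession_label)
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write per-animal ND1 fragments as FASTA
#'
#' Each animal's fragment is its assigned breed's reference sequence;
#' detectable heteroplasmy is rendered as IUPAC ambiguity codes at the
#' discriminating positions (mixed sequencing peaks).
#'
#' @param cohort As from [generate_cohort()].
#' @param path Output FASTA path.
#' @export
write_animal_fasta <- function(cohort, path) {
  refs <- list(cohort$references$large_white, cohort$references$duroc)
  names(refs) <- vapply(refs, function(r) r$breed_name, "")
  seqs <- character(nrow(cohort$animals))
  for (i in seq_len(nrow(cohort$animals))) {
    s <- refs[[cohort$animals$breed[i]]]$coding_sequence
    gt <- cohort$genotypes[[cohort$animals$animal_id[i]]]
    mixed_pos <- as.integer(names(gt$calls)[gt$mixed])
    for (p in mixed_pos) substr(s, p, p) <- unname(gt$calls[as.character(p)])
    seqs[i] <- s
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- cohort$animals$animal_id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

# IUPAC ambiguity code for a set of bases.
.iupac_map <- c(A = "A", C = "C", G = "G", T = "T",
                AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

.iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  code <- .iupac_map[key]
  if (is.na(code)) stop("cannot encode bases: ", key)
  unname(code)
}

# Bases coded by an IUPAC symbol.
.iupac_bases <- function(code) {
  key <- names(.iupac_map)[match(toupper(code), .iupac_map)]
  if (is.na(key)) stop("not an IUPAC code: ", code)
  strsplit(key, "")[[1]]
}
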