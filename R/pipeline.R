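# End-to-end orchestration: simulate -> lineage -> normalize -> cluster ->
# DE -> enrichment -> qPCR, with a consolidated JSON report. The deceased and
# live cohorts are processed independently (each group's arrays are filtered,
# clustered and tested against its own age-matched controls), matching the
# study design.

#' Default pipeline configuration
#'
#' One named list holds every threshold of the analysis: the 70% pixel
#' presence rule, the >90% across-slide presence clause, the >100 raw
#' intensity clause, the <1.4 ratio-SD clause, the 1.5 fold-change and 0.05
#' FDR differential-expression rule, the 0.25 heteroplasmy detection
#' threshold, the Lowess span, and the purity margin of the coordination
#' contrast.
#'
#' @param seed Integer seed forwarded to the simulator.
#' @param sim Named list of [sim_config()] overrides.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, sim = list()) {
  structure(list(
    seed = as.integer(seed),
    sim = sim,
    thresholds = list(
      present = 0.70,
      presence = 0.90,
      intensity = 100,
      sd = 1.4,
      fc = 1.5,
      alpha = 0.05,
      heteroplasmy = 0.25,
      lowess_span = 0.3,
      lowess_iterations = 3L,
      purity_margin = 0.2
    ),
    qpcr = list(control_gene = "TBB2", calibrator = "REF"),
    stages = list(lineage = TRUE, arrays = TRUE, cluster = TRUE,
                  de = TRUE, enrich = TRUE, qpcr = TRUE)
  ), class = "run_config")
}

#' Validate a pipeline configuration
#' @param config A `run_config` list.
#' @return The config, invisibly; stops with a message on the first invalid
#'   threshold.
#' @export
validate_run_config <- function(config) {
  th <- config$thresholds
  in_unit <- function(x) is.numeric(x) && x > 0 && x < 1
  if (!in_unit(th$present)) stop("invalid threshold: present must be in (0,1)")
  if (!in_unit(th$presence)) {
    stop("invalid threshold: presence must be in (0,1)")
  }
  if (!is.numeric(th$intensity) || th$intensity < 0) {
    stop("invalid threshold: intensity must be >= 0")
  }
  if (!is.numeric(th$sd) || th$sd <= 0) {
    stop("invalid threshold: sd must be > 0")
  }
  if (!is.numeric(th$fc) || th$fc < 1) {
    stop("invalid threshold: fc must be >= 1")
  }
  if (!in_unit(th$alpha)) stop("invalid threshold: alpha must be in (0,1)")
  if (!in_unit(th$heteroplasmy)) {
    stop("invalid threshold: heteroplasmy must be in (0,1)")
  }
  if (!in_unit(th$lowess_span)) {
    stop("invalid threshold: lowess_span must be in (0,1)")
  }
  if (!is.numeric(th$purity_margin) || th$purity_margin < 0 ||
      th$purity_margin > 1) {
    stop("invalid threshold: purity_margin must be in [0,1]")
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML, merged over the defaults
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_run_config()
  for (nm in names(user)) {
    if (is.list(config[[nm]]) && is.list(user[[nm]])) {
      config[[nm]] <- modifyList(config[[nm]], user[[nm]])
    } else {
      config[[nm]] <- user[[nm]]
    }
  }
  config$seed <- as.integer(config$seed)
  validate_run_config(config)
  config
}

# Gene sets from the annotation's gene_sets column -> named list of symbols.
.annotation_gene_sets <- function(annotation) {
  labs <- setdiff(unique(unlist(strsplit(annotation$gene_sets, ";"))), "")
  sets <- lapply(labs, function(l) {
    annotation$gene_symbol[vapply(strsplit(annotation$gene_sets, ";"),
                                  function(x) l %in% x, logical(1))]
  })
  stats::setNames(sets, labs)
}

#' Run the full synthetic-study pipeline
#'
#' Stages run in dependency order; a failing stage stops the run with the
#' stage named. With `outdir` set, writes per-stage outputs, a stage manifest
#' and the consolidated `report.json`.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param outdir Output directory or `NULL` for in-memory only.
#' @return The report, invisibly: a list with `lineage`, `arrays`,
#'   `coordination`, `de`, `enrichment`, `qpcr` sections plus `config`.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL) {
  validate_run_config(config)
  th <- config$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list()

  sim <- stage("simulate", {
    scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    simulate_study(scfg)
  })
  manifest$simulate <- list(seed = config$seed, overrides = config$sim)
  report <- list(config = list(seed = config$seed, thresholds = th))

  if (isTRUE(config$stages$lineage)) {
    report$lineage <- stage("lineage", {
      refs <- list(sim$references$large_white, sim$references$duroc)
      calls <- lapply(sim$cohort$genotypes, assign_lineage, refs = refs)
      rep <- lineage_report(calls, sim$cohort$animals)
      planted <- sim$cohort$animals$breed
      assigned <- vapply(calls, function(x) x$assigned_breed, "")
      het <- detect_heteroplasmy(sim$cohort$animals$minor_fraction,
                                 th$heteroplasmy)
      list(calls = calls, report = rep,
           recovered_fraction = mean(assigned == planted),
           heteroplasmy_detected = sum(het))
    })
  }

  groups <- unique(sim$arrays$design$group)
  per_group <- list()
  for (g in groups) {
    gdesign <- sim$arrays$design[sim$arrays$design$group == g, , drop = FALSE]
    sdesign <- unique(gdesign[, c("sample_id", "role")])
    names(sdesign)[2] <- "treatment"

    em <- stage(paste0("arrays[", g, "]"), {
      build_expression_matrix(
        sim$arrays$slides[gdesign$slide_id], gdesign,
        span = th$lowess_span, iterations = th$lowess_iterations,
        presence_cutoff = th$presence, intensity_cutoff = th$intensity,
        sd_cutoff = th$sd
      )
    })
    res <- list(
      n_informative = sum(em$informative),
      informative_percent = informative_percent(sum(em$informative),
                                                nrow(em$values))
    )

    if (isTRUE(config$stages$cluster)) {
      res$coordination <- stage(paste0("cluster[", g, "]"), {
        subsets <- lapply(c(global = "global", nuclear_mito = "nuclear_mito",
                            mtdna = "mtdna"), function(w) {
          cluster_subset(subset_by_origin(em, sim$annotation, w), sdesign, w)
        })
        contrast <- coordination_contrast(subsets$nuclear_mito,
                                          subsets$mtdna,
                                          margin = th$purity_margin)
        list(subsets = subsets, contrast = contrast)
      })
    }

    if (isTRUE(config$stages$de)) {
      res$de <- stage(paste0("de[", g, "]"), {
        values <- em$values[em$informative, , drop = FALSE]
        de <- call_de(values, sdesign, sim$annotation,
                      fc_threshold = th$fc, alpha = th$alpha)
        list(results = de, by_origin = partition_by_origin(de),
             n_de = sum(de$de))
      })
      if (isTRUE(config$stages$enrich)) {
        res$enrichment <- stage(paste0("enrich[", g, "]"), {
          de <- res$de$results
          universe <- unique(de$gene_symbol)
          sets <- .annotation_gene_sets(sim$annotation)
          sets <- lapply(sets, intersect, y = universe)
          enrich(unique(de$gene_symbol[de$de]), sets, universe)
        })
      }
    }
    per_group[[g]] <- res
  }
  report$groups <- per_group

  if (isTRUE(config$stages$qpcr)) {
    report$qpcr <- stage("qpcr", {
      rq <- comparative_ct(sim$qpcr,
                           control_gene = config$qpcr$control_gene,
                           calibrator_sample = config$qpcr$calibrator)
      out <- list()
      for (g in groups) {
        if (is.null(per_group[[g]]$de)) next
        gdesign <- sim$arrays$design[sim$arrays$design$group == g, ,
                                     drop = FALSE]
        sdesign <- unique(gdesign[, c("sample_id", "role")])
        names(sdesign)[2] <- "treatment"
        de <- per_group[[g]]$de$results
        genes <- intersect(unique(rq$gene), de$gene_symbol)
        tests <- lapply(genes, function(gene) {
          sub <- rq[rq$gene == gene & rq$sample %in% sdesign$sample_id, ]
          treat <- sdesign$treatment[match(sub$sample, sdesign$sample_id)]
          dir <- de$log2fc[match(gene, de$gene_symbol)]
          dir <- if (dir >= 0) "up" else "down"
          ct <- compare_groups(log2(sub$rq[treat == "clone"]),
                               log2(sub$rq[treat == "control"]),
                               direction = dir, alpha = th$alpha)
          c(list(gene = gene, direction = dir), ct)
        })
        conc <- concordance(rq, sdesign, de, genes = genes)
        out[[g]] <- list(tests = tests, concordance = conc)
      }
      list(rq = rq, by_group = out)
    })
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(report$lineage)) {
      write_lineage_calls(report$lineage$calls,
                          file.path(outdir, "lineage_calls.tsv"))
    }
    for (g in names(per_group)) {
      if (!is.null(per_group[[g]]$de)) {
        write.table(per_group[[g]]$de$results,
                    file.path(outdir, paste0("de_results_", g, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    jsonlite::write_json(.report_summary(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
  }
  invisible(report)
}

# JSON-friendly condensation of the in-memory report.
.report_summary <- function(report) {
  out <- list(config = report$config)
  if (!is.null(report$lineage)) {
    out$lineage <- list(
      counts = report$lineage$report$counts,
      survival_table = as.data.frame(as.table(
        report$lineage$report$survival_table)),
      recovered_fraction = report$lineage$recovered_fraction,
      unresolved = report$lineage$report$unresolved
    )
  }
  out$groups <- lapply(report$groups, function(res) {
    o <- list(n_informative = res$n_informative,
              informative_percent = res$informative_percent)
    if (!is.null(res$coordination)) {
      o$coordination <- list(
        purity = lapply(res$coordination$subsets, function(s) s$purity),
        coherence = res$coordination$contrast$coherence,
        purity_difference = res$coordination$contrast$purity_difference,
        label = res$coordination$contrast$label
      )
    }
    if (!is.null(res$de)) {
      o$de <- list(n_de = res$de$n_de, by_origin = res$de$by_origin)
    }
    if (!is.null(res$enrichment)) {
      o$enrichment <- res$enrichment
    }
    o
  })
  if (!is.null(report$qpcr)) {
    out$qpcr <- lapply(report$qpcr$by_group, function(gq) {
      list(
        tests = lapply(gq$tests, function(t) {
          t[c("gene", "direction", "f_p", "method", "t_p", "significant")]
        }),
        agreement_fraction = gq$concordance$agreement_fraction
      )
    })
  }
  out
}

#' Minimal command-line entry point
#'
#' Supports `run [--config FILE] [--outdir DIR] [--seed N]` (full pipeline)
#' and `simulate [--outdir DIR] [--seed N] [--write-slides]` (generator
#' only).
#'
#' @param args Character vector, defaults to [base::commandArgs()] trailing
#'   arguments.
#' @return Exit code 0, invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    stop("usage: run|simulate [--config FILE] [--outdir DIR] [--seed N]")
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  outdir <- opt("--outdir", ".")
  if (cmd == "run") {
    cfg_path <- opt("--config")
    config <- if (is.null(cfg_path)) default_run_config(seed = seed)
              else read_run_config(cfg_path)
    if (!is.null(opt("--seed"))) config$seed <- seed
    run_pipeline(config, outdir = outdir)
  } else if (cmd == "simulate") {
    simulate_study(sim_config(seed = seed), outdir = outdir,
                   write_slides = "--write-slides" %in% args)
  } else {
    stop("unknown command: ", cmd)
  }
  invisible(0L)
}
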