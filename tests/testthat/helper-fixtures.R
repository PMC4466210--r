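# Shared fixtures: the printed ND1 genotype table, reference rows, small
# simulation configs, and independent oracles used across test files.

table2_path <- function(file) {
  system.file("extdata", file, package = "mitonuclear", mustWork = TRUE)
}

# The two printed reference rows as haplotype_reference objects.
table2_references <- function() {
  tab <- read.delim(table2_path("table2_references.tsv"),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  pos_cols <- grep("^pos_", names(tab), value = TRUE)
  positions <- as.integer(sub("^pos_", "", pos_cols))
  lapply(seq_len(nrow(tab)), function(i) {
    haplotype_reference(tab$breed[i], tab$accession[i],
                        stats::setNames(unlist(tab[i, pos_cols]), positions))
  })
}

# The 22 printed animal rows (parser warns once about the "T2" artifact).
table2_animals <- function() {
  suppressWarnings(read_panel_genotypes(table2_path("table2_nd1_genotypes.tsv")))
}

# A light config: full cohort design, few probes, for fast end-to-end runs.
small_config <- function(seed = 1L, ...) {
  sim_config(n_probes = 400L, n_nuclear_mito = 60L, n_mtdna = 16L,
             seed = seed, ...)
}

# Independent full-translation oracle for codon effects: translate the whole
# reference and variant sequences with Biostrings' vertebrate mitochondrial
# genetic code (plain codon table, no initiator-codon special-casing) and
# compare the affected residues. Vectorized over cases.
oracle_codon_effects <- function(cds, positions, alts) {
  code <- Biostrings::getGeneticCode("SGC1")
  alt_cds <- cds
  for (i in seq_along(cds)) {
    substr(alt_cds[i], positions[i], positions[i]) <- alts[i]
  }
  tr <- function(v) {
    as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(v),
                            genetic.code = code, no.init.codon = TRUE)))
  }
  aa_ref <- tr(cds); aa_alt <- tr(alt_cds)
  ci <- ((positions - 1) %/% 3) + 1
  r <- substr(aa_ref, ci, ci); a <- substr(aa_alt, ci, ci)
  ifelse(r == a, "synonymous", ifelse(a == "*", "nonsense", "missense"))
}

# Exhaustive two-sided Fisher p by direct enumeration over the support.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  pr <- vapply(xs, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
}

# Deceased-group design (7 clones + 5 controls) from a latent object.
deceased_design <- function(latent) {
  keep <- latent$samples$group == "deceased"
  data.frame(sample_id = latent$samples$sample_id[keep],
             treatment = latent$samples$role[keep],
             stringsAsFactors = FALSE)
}
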