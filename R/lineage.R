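# Maternal-lineage determination from ND1 panel genotypes.
#
# The published analysis ranked whole-fragment BLAST bit scores; here lineage
# is assigned by counting exact matches at the discriminating panel positions,
# which determines every published assignment without alignment machinery.

#' Construct a breed haplotype reference
#'
#' @param breed_name Breed, e.g. `"Large White"`.
#' @param accession_label Label of the matching public reference (metadata
#'   only; the packaged sequences are synthetic backbones).
#' @param panel_calls Named character vector, 1-based position -> base.
#' @param coding_sequence Optional in-frame DNA string (base 1 = first base of
#'   codon 1).
#' @return Object of class `haplotype_reference`.
#' @export
haplotype_reference <- function(breed_name, accession_label, panel_calls,
                                coding_sequence = NULL) {
  pos <- as.integer(names(panel_calls))
  if (anyNA(pos) || any(pos < 1L)) {
    stop("panel_calls must be named by 1-based positions")
  }
  if (is.unsorted(pos, strictly = TRUE)) {
    ord <- order(pos)
    panel_calls <- panel_calls[ord]
    pos <- pos[ord]
  }
  if (!all(toupper(panel_calls) %in% c("A", "C", "G", "T"))) {
    stop("reference panel calls must be A, C, G or T")
  }
  structure(list(breed_name = breed_name,
                 accession_label = accession_label,
                 panel_calls = stats::setNames(toupper(panel_calls), pos),
                 coding_sequence = coding_sequence),
            class = "haplotype_reference")
}

#' Construct a panel genotype for one animal
#'
#' @param animal_id Animal identifier.
#' @param group `"deceased"` or `"live"`.
#' @param role `"clone"` or `"control"`.
#' @param calls Named character vector position -> base or IUPAC ambiguity
#'   code (mixed sequencing peaks).
#' @param mixed Logical vector parallel to `calls`: `TRUE` where the call is
#'   an explicitly heteroplasmic mixed peak. Defaults to flagging multi-base
#'   IUPAC codes (everything except `A`,`C`,`G`,`T`,`N`).
#' @return Object of class `panel_genotype`.
#' @export
panel_genotype <- function(animal_id, group, role, calls, mixed = NULL) {
  calls <- toupper(calls)
  if (any(calls == "" | is.na(calls))) stop("empty genotype call")
  ok <- calls %in% .iupac_map
  if (!all(ok)) {
    stop("non-IUPAC character(s) in calls: ",
         paste(unique(calls[!ok]), collapse = ", "))
  }
  pos <- as.integer(names(calls))
  if (anyNA(pos)) stop("calls must be named by positions")
  ord <- order(pos)
  calls <- stats::setNames(calls[ord], pos[ord])
  if (is.null(mixed)) {
    mixed <- stats::setNames(!(calls %in% c("A", "C", "G", "T", "N")),
                             names(calls))
  } else {
    mixed <- stats::setNames(as.logical(mixed)[ord], pos[ord])
  }
  structure(list(animal_id = animal_id, group = group, role = role,
                 calls = calls, mixed = mixed),
            class = "panel_genotype")
}

#' Read panel base calls from a sequenced ND1 fragment
#'
#' Coordinates are 1-based on the ND1 coding strand with base 1 at the ND1
#' start; `offset` is the ND1 coordinate of the fragment's first base, so the
#' call for position `p` is read at fragment index `p - offset + 1`.
#'
#' @param fragment DNA string (IUPAC characters allowed).
#' @param offset ND1 coordinate of fragment base 1 (default 1).
#' @param panel_positions Integer vector of panel positions to read.
#' @param animal_id,group,role Metadata carried into the genotype.
#' @return A [panel_genotype()]. Multi-base IUPAC codes are flagged as mixed
#'   peaks; `N` is carried but never flagged.
#' @export
extract_panel_genotype <- function(fragment, offset = 1L, panel_positions,
                                   animal_id = "unknown", group = NA_character_,
                                   role = NA_character_) {
  fragment <- toupper(fragment)
  chars <- strsplit(fragment, "")[[1]]
  bad <- setdiff(unique(chars), .iupac_map)
  if (length(bad)) {
    stop("non-IUPAC character(s) in fragment: ", paste(bad, collapse = ", "))
  }
  idx <- panel_positions - offset + 1L
  uncovered <- panel_positions[idx < 1L | idx > length(chars)]
  if (length(uncovered)) {
    stop("panel position(s) not covered by fragment: ",
         paste(uncovered, collapse = ", "))
  }
  calls <- stats::setNames(chars[idx], panel_positions)
  panel_genotype(animal_id, group, role, calls)
}

#' Positions at which two haplotype references differ
#'
#' @param ref_a,ref_b [haplotype_reference()] objects sharing one position
#'   set.
#' @return Ascending integer vector of discriminating positions.
#' @export
discriminating_positions <- function(ref_a, ref_b) {
  pa <- names(ref_a$panel_calls); pb <- names(ref_b$panel_calls)
  if (!setequal(pa, pb)) {
    stop("references cover different position sets")
  }
  pos <- sort(as.integer(pa))
  key <- as.character(pos)
  pos[ref_a$panel_calls[key] != ref_b$panel_calls[key]]
}

# Does an observed call match a reference base? Mixed (explicitly
# heteroplasmic) IUPAC calls match when the reference base is among the coded
# set; bare N (or any unflagged ambiguity) never matches.
.call_matches <- function(call, mixed, ref_base) {
  if (call %in% c("A", "C", "G", "T")) return(call == ref_base)
  if (isTRUE(mixed) && call != "N") return(ref_base %in% .iupac_bases(call))
  FALSE
}

#' Assign maternal breed lineage from a panel genotype
#'
#' Each reference is scored by exact matches at the discriminating positions
#' (positions at which the references differ). The unique maximizer wins;
#' ties or all-zero scores yield `"UNRESOLVED"`. Private variants are panel
#' positions where the observed base differs from every reference;
#' where a reference coding sequence is available each private variant is
#' classified under the vertebrate mitochondrial code.
#'
#' @param genotype A [panel_genotype()].
#' @param refs List of two or more [haplotype_reference()] objects.
#' @return Object of class `lineage_call`: list with `animal_id`,
#'   `assigned_breed`, `match_score`, `scores_per_reference`,
#'   `private_variants` (data.frame), `codon_effects` (data.frame).
#' @export
assign_lineage <- function(genotype, refs) {
  if (length(refs) < 2L) stop("need at least two references")
  breeds <- vapply(refs, function(r) r$breed_name, "")
  names(refs) <- breeds

  # Discriminating positions: positions where the references do not all agree.
  pos_all <- sort(as.integer(names(refs[[1]]$panel_calls)))
  key_all <- as.character(pos_all)
  calls_mat <- vapply(refs, function(r) {
    if (!setequal(names(r$panel_calls), key_all)) {
      stop("references cover different position sets")
    }
    r$panel_calls[key_all]
  }, character(length(key_all)))
  disc <- pos_all[apply(calls_mat, 1L, function(x) length(unique(x)) > 1L)]
  if (!length(disc)) stop("references have no discriminating positions")

  gpos <- as.integer(names(genotype$calls))
  disc_cov <- intersect(disc, gpos)
  if (!length(disc_cov)) {
    stop("genotype covers none of the discriminating positions")
  }

  scores <- stats::setNames(integer(length(refs)), breeds)
  for (b in breeds) {
    scores[b] <- sum(vapply(disc_cov, function(p) {
      k <- as.character(p)
      .call_matches(genotype$calls[[k]], genotype$mixed[[k]],
                    refs[[b]]$panel_calls[[k]])
    }, logical(1)))
  }
  top <- max(scores)
  winners <- breeds[scores == top]
  assigned <- if (top == 0L || length(winners) > 1L) "UNRESOLVED" else winners

  # Private variants over all shared panel positions.
  shared <- intersect(pos_all, gpos)
  priv <- list()
  for (p in shared) {
    k <- as.character(p)
    call <- genotype$calls[[k]]
    ref_bases <- unique(unname(calls_mat[k, ]))
    matches_any <- any(vapply(ref_bases, function(rb) {
      .call_matches(call, genotype$mixed[[k]], rb)
    }, logical(1)))
    if (!matches_any && call != "N") {
      priv[[length(priv) + 1L]] <- data.frame(
        position = p, observed = call,
        reference_bases = paste(ref_bases, collapse = "/"),
        stringsAsFactors = FALSE
      )
    }
  }
  private_variants <- if (length(priv)) do.call(rbind, priv) else
    data.frame(position = integer(0), observed = character(0),
               reference_bases = character(0), stringsAsFactors = FALSE)

  # Codon effects for unambiguous private variants, against the assigned
  # (or first) reference's coding sequence.
  eff_ref <- if (assigned != "UNRESOLVED") refs[[assigned]] else refs[[1]]
  effects <- list()
  for (i in seq_len(nrow(private_variants))) {
    p <- private_variants$position[i]
    obs <- private_variants$observed[i]
    eff <- "unknown"
    if (!is.null(eff_ref$coding_sequence) && obs %in% c("A", "C", "G", "T") &&
        p <= nchar(eff_ref$coding_sequence)) {
      eff <- classify_codon_effect(eff_ref$coding_sequence, p, obs)
    }
    effects[[i]] <- data.frame(position = p, effect = eff,
                               stringsAsFactors = FALSE)
  }
  codon_effects <- if (length(effects)) do.call(rbind, effects) else
    data.frame(position = integer(0), effect = character(0),
               stringsAsFactors = FALSE)

  structure(list(animal_id = genotype$animal_id, assigned_breed = assigned,
                 match_score = if (assigned == "UNRESOLVED") top else
                   unname(scores[assigned]),
                 scores_per_reference = scores,
                 discriminating_positions = sort(disc),
                 private_variants = private_variants,
                 codon_effects = codon_effects),
            class = "lineage_call")
}

#' Is a heteroplasmy mixture detectable by Sanger sequencing?
#'
#' A minor-haplotype fraction is detectable only when it strictly exceeds the
#' detection threshold (default 0.25: a higher-than-25% mixture shows as a
#' secondary peak).
#'
#' @param minor_fraction Minor-haplotype fraction in `[0, 0.5]`.
#' @param threshold Detection threshold in `(0, 1)`.
#' @return Logical.
#' @export
detect_heteroplasmy <- function(minor_fraction, threshold = 0.25) {
  if (any(minor_fraction < 0 | minor_fraction > 0.5)) {
    stop("minor_fraction must lie in [0, 0.5]")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  minor_fraction > threshold
}

#' Summarize lineage calls against the cohort design
#'
#' @param calls List of `lineage_call` objects.
#' @param design Data.frame with columns `animal_id`, `group`, `role`.
#' @return List with `counts` (group x role x breed data.frame),
#'   `survival_table` (breed x group 2x2 matrix of clone counts, suitable for
#'   [fisher_exact()]), and `unresolved` (character vector of animal ids).
#' @export
lineage_report <- function(calls, design) {
  if (length(calls) == 0) {
    counts <- data.frame(group = character(0), role = character(0),
                         breed = character(0), n = integer(0),
                         stringsAsFactors = FALSE)
    return(list(counts = counts,
                survival_table = matrix(0L, 2, 2,
                  dimnames = list(breed = c("Large White", "Duroc"),
                                  group = c("deceased", "live"))),
                unresolved = character(0)))
  }
  ids <- vapply(calls, function(x) x$animal_id, "")
  breed <- vapply(calls, function(x) x$assigned_breed, "")
  missing <- setdiff(design$animal_id, ids)
  if (length(missing)) {
    stop("design animals without a lineage call: ",
         paste(missing, collapse = ", "))
  }
  df <- merge(design[, c("animal_id", "group", "role")],
              data.frame(animal_id = ids, breed = breed,
                         stringsAsFactors = FALSE),
              by = "animal_id")
  unresolved <- df$animal_id[df$breed == "UNRESOLVED"]
  df <- df[df$breed != "UNRESOLVED", ]
  counts <- as.data.frame(table(group = df$group, role = df$role,
                                breed = df$breed),
                          responseName = "n", stringsAsFactors = FALSE)
  counts <- counts[counts$n > 0 | TRUE, ]
  clones <- df[df$role == "clone", ]
  breeds <- sort(unique(df$breed))
  groups <- c("deceased", "live")
  surv <- matrix(0L, nrow = length(breeds), ncol = 2,
                 dimnames = list(breed = breeds, group = groups))
  for (b in breeds) for (g in groups) {
    surv[b, g] <- sum(clones$breed == b & clones$group == g)
  }
  list(counts = counts, survival_table = surv, unresolved = unresolved)
}

#' Read Table-2-style panel genotypes from a TSV file
#'
#' Expects columns `animal_id`, `group`, `role`, optionally `breed` (the
#' printed assignment, carried through as `breed_printed`), and one column per
#' panel position named `pos_<position>`. A call consisting of a base followed
#' by trailing digits (a typesetting artifact such as `"T2"`) is read as the
#' base, with a warning.
#'
#' @param path TSV file path.
#' @return List with `genotypes` (list of [panel_genotype()]) and `table`
#'   (the parsed data.frame).
#' @export
read_panel_genotypes <- function(path) {
  # colClasses guards against all-"T" base columns parsing as logical
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  pos_cols <- grep("^pos_", names(tab), value = TRUE)
  if (!length(pos_cols)) stop("no pos_<position> columns found in ", path)
  positions <- as.integer(sub("^pos_", "", pos_cols))
  genotypes <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    raw <- toupper(as.character(unlist(tab[i, pos_cols])))
    artifact <- grepl("^[A-Z][0-9]+$", raw)
    if (any(artifact)) {
      warning("animal ", tab$animal_id[i], ": trailing digits stripped from ",
              "call(s) ", paste(raw[artifact], collapse = ", "),
              " (typesetting artifact)")
      raw[artifact] <- substr(raw[artifact], 1, 1)
    }
    genotypes[[i]] <- panel_genotype(tab$animal_id[i], tab$group[i],
                                     tab$role[i],
                                     stats::setNames(raw, positions))
  }
  names(genotypes) <- tab$animal_id
  list(genotypes = genotypes, table = tab)
}

#' Write lineage calls as a TSV
#' @param calls List of `lineage_call` objects.
#' @param path Output path.
#' @export
write_lineage_calls <- function(calls, path) {
  rows <- lapply(calls, function(x) {
    data.frame(
      animal_id = x$animal_id,
      assigned_breed = x$assigned_breed,
      match_score = x$match_score,
      scores = paste(sprintf("%s=%d", names(x$scores_per_reference),
                             x$scores_per_reference), collapse = ";"),
      private_variants = if (nrow(x$private_variants)) {
        paste(sprintf("%d%s", x$private_variants$position,
                      x$private_variants$observed), collapse = ";")
      } else "",
      codon_effects = if (nrow(x$codon_effects)) {
        paste(sprintf("%d:%s", x$codon_effects$position,
                      x$codon_effects$effect), collapse = ";")
      } else "",
      stringsAsFactors = FALSE
    )
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.lineage_call <- function(x, ...) {
  cat("Lineage call for", x$animal_id, "->", x$assigned_breed,
      sprintf("(score %d/%d)\n", x$match_score,
              length(x$discriminating_positions)))
  if (nrow(x$private_variants)) {
    cat("  private variants:",
        paste(sprintf("%d%s", x$private_variants$position,
                      x$private_variants$observed), collapse = ", "), "\n")
  }
  invisible(x)
}
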