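test_that("welch_t basics and closed-form agreement", {
  a <- c(1, 2, 3, 4)
  w <- welch_t(a, rev(a))            # same values, shuffled
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate")
  expect_error(welch_t(1, c(1, 2)), "two values")
  # equal variances & n: Welch reduces to Student's t exactly
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6, 1)
    w <- welch_t(x, y)
    st <- t.test(x, y, var.equal = FALSE)  # oracle: stats implementation
    expect_equal(w$t, unname(st$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(st$parameter), tolerance = 1e-10)
    expect_equal(w$p, st$p.value, tolerance = 1e-10)
    # with equal n, the Welch statistic equals the pooled Student statistic
    sp2 <- (var(x) + var(y)) / 2
    t_student <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 6))
    expect_equal(w$t, t_student, tolerance = 1e-10)
  }
})

test_that("welch p tracks the exhaustive permutation distribution (n = 5/5)", {
  # the permutation null over 10 observations has 252 splits, so the
  # achievable granularity is ~0.004 and t-distribution agreement at n = 5
  # is on the order of a few hundredths
  set.seed(3)
  idx <- utils::combn(10, 5)
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(5, 0.8)
    w <- welch_t(a, b)
    pool <- c(a, b)
    tperm <- apply(idx, 2, function(k) abs(welch_t(pool[k], pool[-k])$t))
    pperm <- mean(tperm >= abs(w$t) - 1e-12)
    expect_lt(abs(w$p - pperm), 0.05)
  }
})

test_that("welch type-I error is calibrated under unequal variances", {
  set.seed(42)
  n_rep <- 10000
  a <- matrix(rnorm(5 * n_rep, 0, 2), n_rep, 5)
  b <- matrix(rnorm(5 * n_rep, 0, 1), n_rep, 5)
  res <- .welch_t_rows(cbind(a, b), 1:5, 6:10)
  rate <- mean(res$p <= 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("bh_adjust matches hand computation and the reference implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust is deterministic and order-equivariant", {
  # note: the step-up transform is NOT idempotent in general
  # (e.g. (0.2, 0.9) -> (0.4, 0.9) -> (0.8, 0.9)); what holds is
  # determinism and equivariance under permutation of the inputs
  set.seed(9)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_identical(bh_adjust(p), adj)
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-14)
  # monotone: a smaller raw p never gets a larger adjusted p
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

de_design <- function(n1 = 5, n2 = 5) {
  data.frame(sample_id = paste0("s", seq_len(n1 + n2)),
             treatment = rep(c("clone", "control"), c(n1, n2)),
             stringsAsFactors = FALSE)
}

test_that("call_de boundaries are inclusive for both fold change and p", {
  set.seed(14)
  x <- matrix(rnorm(200 * 10, 0, 0.3), 200, 10,
              dimnames = list(sprintf("P%03d", 1:200), paste0("s", 1:10)))
  # force one probe to an exact 1.5 fold change with a clear shift
  x[1, 1:5] <- c(0.9, 1.0, 1.1, 1.0, 1.0) + log2(1.5) - 1
  x[1, 6:10] <- c(-0.1, 0, 0.1, 0, 0)
  de <- call_de(x, de_design())
  row <- de[de$probe_id == "P001", ]
  expect_equal(row$fold_change, 1.5, tolerance = 1e-12)
  # re-run with alpha set to this probe's exact adjusted p: still called
  de2 <- call_de(x, de_design(), alpha = row$p_adj, fc_threshold = 1.5)
  expect_true(de2$de[de2$probe_id == "P001"])
  expect_identical(de2$direction[de2$probe_id == "P001"], "up")
})

test_that("swapping treatment labels inverts fold changes and keeps the DE set", {
  set.seed(15)
  x <- matrix(rnorm(300 * 10, 0, 0.4), 300, 10,
              dimnames = list(sprintf("P%03d", 1:300), paste0("s", 1:10)))
  x[1:30, 1:5] <- x[1:30, 1:5] + 1.2
  d1 <- de_design()
  d2 <- d1; d2$treatment <- rev(d1$treatment)
  deA <- call_de(x, d1)
  deB <- call_de(x, d2)
  expect_equal(deB$fold_change, 1 / deA$fold_change, tolerance = 1e-12)
  expect_identical(deB$de, deA$de)
  expect_identical(deB$direction == "up", deA$direction == "down")
})

test_that("null matrices yield a controlled false-discovery proportion", {
  # quick matrix-level null check (the full-pipeline version is in the
  # acceptance suite)
  set.seed(16)
  fdp <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(534 * 10, 0, 0.4), 534, 10,
                dimnames = list(sprintf("P%03d", 1:534), paste0("s", 1:10)))
    de <- call_de(x, de_design())
    if (sum(de$de) > 0) 1 else 0
  }, numeric(1))
  expect_lte(mean(fdp), 0.1)
})

test_that("planted effects are recovered: mean recall >= 0.6 over 100 seeds", {
  recalls <- vapply(1:100, function(s) {
    set.seed(s)
    x <- matrix(rnorm(534 * 10, 0, 0.3), 534, 10,
                dimnames = list(sprintf("P%03d", 1:534), paste0("s", 1:10)))
    x[1:50, 1:5] <- x[1:50, 1:5] + 1   # true fold change 2.0
    mean(call_de(x, de_design())$de[1:50])
  }, numeric(1))
  expect_gte(mean(recalls), 0.6)
})

test_that("probes missing in over half of a group are dropped with a reason", {
  set.seed(18)
  x <- matrix(rnorm(50), 5, 10,
              dimnames = list(sprintf("P%03d", 1:5), paste0("s", 1:10)))
  x[1, 1:3] <- NA
  de <- call_de(x, de_design())
  expect_false("P001" %in% de$probe_id)
  expect_identical(attr(de, "dropped"), "P001")
})

test_that("partition_by_origin counts match a set-intersection oracle", {
  ann <- generate_probe_annotation(small_config())
  set.seed(20)
  de <- data.frame(probe_id = ann$probe_id,
                   de = runif(nrow(ann)) < 0.1,
                   direction = "none", stringsAsFactors = FALSE)
  de$direction[de$de] <- sample(c("up", "down"), sum(de$de), replace = TRUE)
  part <- partition_by_origin(de, ann)
  for (o in c("nuclear", "mitochondrial")) {
    oracle <- length(intersect(which(de$de),
                               which(ann$genome_of_origin == o)))
    expect_identical(part$total[part$genome_of_origin == o], oracle)
  }
  expect_equal(sum(part$total), sum(de$de))
  # planted mtDNA-only DE -> nuclear count 0
  de$de <- ann$genome_of_origin == "mitochondrial"
  de$direction <- ifelse(de$de, "up", "none")
  part2 <- partition_by_origin(de, ann)
  expect_identical(part2$total[part2$genome_of_origin == "nuclear"], 0L)
  # empty DE set -> all zeros
  de$de <- FALSE; de$direction <- "none"
  expect_true(all(partition_by_origin(de, ann)$total == 0L))
})

test_that("fisher_exact equals exhaustive enumeration and the reference test", {
  # the extreme 5/0/0/5 table: two point masses of the hypergeometric
  ft <- fisher_exact(5, 0, 0, 5)
  expect_equal(ft$p, oracle_fisher_p(5, 0, 0, 5), tolerance = 1e-12)
  expect_equal(ft$p, 2 / choose(10, 5), tolerance = 1e-12)
  # identical row proportions: no association
  expect_equal(fisher_exact(2, 2, 3, 3)$p, 1)
  # all tables with cells up to 5 (margins <= 10) vs both oracles
  for (a in 0:5) for (b in 0:5) for (c in 0:5) for (d in 0:5) {
    got <- fisher_exact(a, b, c, d)$p
    expect_equal(got, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
    if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) {
      ref <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
      expect_equal(got, ref, tolerance = 1e-7)
    }
  }
  # a spot-check at larger margins (<= 12)
  set.seed(22)
  for (i in 1:50) {
    cells <- sample(0:6, 4, replace = TRUE)
    got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])$p
    expect_equal(got, oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("fisher_exact degenerate margins and odds-ratio conventions", {
  deg <- fisher_exact(0, 0, 3, 4)
  expect_equal(deg$p, 1)
  expect_true(is.na(deg$odds_ratio))
  # Haldane correction only when a cell is zero
  expect_equal(fisher_exact(5, 0, 1, 5)$odds_ratio,
               (5.5 * 5.5) / (0.5 * 1.5))
  expect_equal(fisher_exact(4, 2, 1, 3)$odds_ratio, (4 * 3) / (2 * 1))
  expect_error(fisher_exact(1.5, 2, 3, 4), "integers")
})

test_that("enrich: empty DE set, exact-set recovery, and planted concentration", {
  universe <- sprintf("G%03d", 1:60)
  sets <- list(SETA = universe[1:12], SETB = universe[13:40])
  e0 <- enrich(character(0), sets, universe)
  expect_true(all(e0$p == 1))
  # DE set equal to SETA exactly: p equals the exhaustive hypergeometric tail
  e1 <- enrich(universe[1:12], sets, universe)
  expect_equal(e1$p[e1$gene_set == "SETA"],
               oracle_fisher_p(12, 0, 0, 48), tolerance = 1e-12)
  expect_error(enrich("NOT_THERE", sets, universe), "outside universe")
  # planted concentration ranks the planted set first in >= 95/100 seeds
  first <- vapply(1:100, function(s) {
    set.seed(s)
    de <- unique(c(sample(universe[1:12], 8),
                   sample(universe[41:60], 2)))
    e <- enrich(de, sets, universe)
    e$gene_set[1] == "SETA"
  }, logical(1))
  expect_gte(mean(first), 0.95)
})

test_that("GMT round trip", {
  sets <- list(OXPHOS = c("NDUFA4", "UQCR"), FA = c("ACSL1"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
})
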