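# helpers to build tiny slides in code
make_slide <- function(cy5, cy3, bg = 100, frac5 = 0.9, frac3 = 0.9,
                       orientation = "sample_in_Cy5", sample_id = "s1",
                       slide_id = "s1_a") {
  n <- length(cy5)
  list(slide_id = slide_id, sample_id = sample_id,
       dye_orientation = orientation,
       data = data.frame(probe_id = sprintf("P%04d", seq_len(n)),
                         F635_Median = cy5 + bg, B635_Median = rep(bg, n),
                         F532_Median = cy3 + bg, B532_Median = rep(bg, n),
                         F532_pct_sat2sd = rep(frac3, length.out = n),
                         F635_pct_sat2sd = rep(frac5, length.out = n),
                         stringsAsFactors = FALSE))
}

test_that("background subtraction floors and flags degenerate probes", {
  sl <- list(slide_id = "x", sample_id = "s", dye_orientation = "sample_in_Cy5",
             data = data.frame(probe_id = c("a", "b"),
                               F635_Median = c(1000, 50), B635_Median = c(100, 100),
                               F532_Median = c(500, 400), B532_Median = c(100, 100),
                               F532_pct_sat2sd = 1, F635_pct_sat2sd = 1))
  out <- subtract_background(sl)
  expect_equal(out$data$cy5, c(900, 0.5))
  expect_equal(out$data$cy3, c(400, 300))
  expect_identical(out$data$floored, c(FALSE, TRUE))
  sl$data$F635_Median[1] <- -1
  expect_error(subtract_background(sl), "negative")
})

test_that("present call boundary is inclusive at 70% in either channel", {
  expect_true(call_present(0.10, 0.71))
  expect_true(call_present(0.70, 0.00))
  expect_false(call_present(0.69, 0.69))
  expect_error(call_present(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("lowess normalization removes a constant M shift exactly", {
  set.seed(5)
  a_level <- 2^runif(500, 6, 14)
  sl <- make_slide(cy5 = a_level * 2, cy3 = a_level)  # M = 1 everywhere
  fit <- lowess_normalize(subtract_background(sl))
  expect_equal(max(abs(fit$M_norm), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("lowess removes a planted polynomial bias (per-decile check)", {
  cfg <- sim_config(n_probes = 4000L, n_nuclear_mito = 60L, n_mtdna = 16L,
                    dye_bias_coeffs = c(10, -2, 0.1), noise_sd = 0.2,
                    present_fraction_null = 0)
  lat <- generate_latent(cfg)
  lat$matrix[] <- 0
  arr <- generate_array_dataset(cfg, lat)
  # span finer than the pipeline default: the planted bias is strongly
  # curved and local-linear smoothing underfits curvature at wide spans
  fit <- lowess_normalize(subtract_background(arr$slides[[1]]), span = 0.2)
  dec <- cut(fit$A, quantile(fit$A, 0:10 / 10), include.lowest = TRUE)
  expect_true(all(abs(tapply(fit$M_norm, dec, median)) < 0.05))
  # and the fitted curve tracks the planted polynomial away from the edges
  inner <- fit$A > quantile(fit$A, 0.05) & fit$A < quantile(fit$A, 0.95)
  planted <- 0.1 * (fit$A - 10)^2
  expect_lt(median(abs(fit$fitted - planted)[inner]), 0.05)
})

test_that("a monotone planted bias yields a monotone fitted curve", {
  set.seed(8)
  a_level <- 2^runif(1000, 6, 14)
  a_log <- log2(a_level)
  bias <- 0.3 * (a_log - 6)          # increasing in A
  m <- bias + rnorm(1000, 0, 0.05)
  sl <- make_slide(cy5 = a_level * 2^(m / 2), cy3 = a_level * 2^(-m / 2))
  fit <- lowess_normalize(subtract_background(sl))
  ord <- order(fit$A)
  diffs <- diff(fit$fitted[ord])
  expect_true(all(diffs > -0.02))    # monotone within smoothing tolerance
})

test_that("lowess errors with too few usable probes", {
  sl <- make_slide(cy5 = rep(1000, 10), cy3 = rep(1000, 10))
  expect_error(lowess_normalize(subtract_background(sl)), "too few")
})

test_that("dye-swap combination orients, averages, and handles missingness", {
  f1 <- structure(list(probe_id = c("a", "b", "c"),
                       M_norm = c(1.0, 0.8, NA),
                       sample_id = "s1", dye_orientation = "sample_in_Cy5"),
                  class = "normalization_fit")
  f2 <- structure(list(probe_id = c("a", "b", "c"),
                       M_norm = c(1.0, NA, NA),
                       sample_id = "s1", dye_orientation = "sample_in_Cy3"),
                  class = "normalization_fit")
  comb <- combine_dye_swap(f1, f2)
  expect_equal(unname(comb), c(1.0, 0.8, NA))
  # swapping the slide order changes nothing
  expect_equal(combine_dye_swap(f2, f1), comb)
  f2$dye_orientation <- "sample_in_Cy5"
  expect_error(combine_dye_swap(f1, f2), "dye swap")
  f2$dye_orientation <- "sample_in_Cy3"; f2$sample_id <- "s2"
  expect_error(combine_dye_swap(f1, f2), "different samples")
})

test_that("zero-noise dye-swap pair recovers the latent ratios through the full path", {
  # full-size slide: the lowess trend estimate has sampling wiggle of order
  # sd(M)/sqrt(span * n), so exact recovery needs many probes
  cfg <- sim_config(noise_sd = 0, dye_bias_coeffs = 0, array_a_sd = 0,
                    present_fraction_null = 0)
  lat <- generate_latent(cfg)
  arr <- generate_array_dataset(cfg, lat)
  gdesign <- arr$design[arr$design$sample_id == lat$samples$sample_id[1], ]
  fits <- lapply(gdesign$slide_id, function(id) {
    lowess_normalize(subtract_background(arr$slides[[id]]))
  })
  comb <- combine_dye_swap(fits[[1]], fits[[2]])
  truth <- lat$matrix[, 1]
  # lowess subtracts the per-intensity median of M, which for uncorrelated
  # baseline vs intensity is near zero; agreement is tight but not exact
  expect_lt(median(abs(comb - truth), na.rm = TRUE), 0.05)
  # without normalization the recovery is exact: raw M equals the latent value
  d <- subtract_background(arr$slides[[gdesign$slide_id[1]]])$data
  expect_equal(log2(d$cy5 / d$cy3), unname(truth), tolerance = 1e-9)
})

test_that("informative filter clauses match a hand-enumerated toy fixture", {
  # 6 probes x 10 slides; clause pattern chosen probe by probe
  n <- 6; ns <- 10
  comb <- matrix(rep(c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1), ns), n, ns)
  comb[4, ] <- c(rep(3, 5), rep(-3, 5))           # SD >= 1.4 -> fails clause 3
  pres_s <- matrix(TRUE, n, ns)
  pres_s[2, ] <- c(rep(TRUE, 9), FALSE)           # exactly 90% -> fails strict
  pres_r <- matrix(FALSE, n, ns)
  pres_r[2, ] <- TRUE                              # but reference channel rescues probe 2
  int_s <- matrix(1000, n, ns)
  int_r <- matrix(1000, n, ns)
  int_s[3, ] <- 100                                # exactly 100 -> fails strict >
  int_r[3, ] <- 100
  pres_s[5, ] <- FALSE; pres_r[5, ] <- FALSE       # fails presence everywhere
  em <- filter_informative(comb, pres_s, pres_r, int_s, int_r)
  expect_identical(unname(em$informative), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  # every exclusion is attributed to at least one named clause
  excl <- em$filter_detail[!em$filter_detail$informative, ]
  expect_true(all(!excl$presence | !excl$intensity | !excl$variability))
  # conservation
  expect_equal(sum(em$informative) + sum(!em$informative), n)
})

test_that("presence of exactly 90% is excluded (strict more-than)", {
  n <- 1; ns <- 10
  comb <- matrix(0.1, n, ns)
  pres <- matrix(c(rep(TRUE, 9), FALSE), n, ns)
  em <- filter_informative(comb, pres, matrix(FALSE, n, ns),
                           matrix(1000, n, ns), matrix(1000, n, ns))
  expect_false(any(em$informative))
})

test_that("filter is monotone in its cutoffs", {
  set.seed(12)
  n <- 80; ns <- 12
  comb <- matrix(rnorm(n * ns, 0, rep(runif(n, 0.2, 2.5), ns)), n, ns)
  pres_s <- matrix(runif(n * ns) < 0.9, n, ns)
  pres_r <- matrix(runif(n * ns) < 0.9, n, ns)
  int_s <- matrix(2^runif(n * ns, 5, 14), n, ns)
  int_r <- matrix(2^runif(n * ns, 5, 14), n, ns)
  base <- filter_informative(comb, pres_s, pres_r, int_s, int_r)
  looser_sd <- filter_informative(comb, pres_s, pres_r, int_s, int_r,
                                  sd_cutoff = 2.5)
  expect_true(all(looser_sd$informative[base$informative]))
  stricter_pres <- filter_informative(comb, pres_s, pres_r, int_s, int_r,
                                      presence_cutoff = 0.99)
  expect_true(all(base$informative[stricter_pres$informative]))
})

test_that("subset_by_origin returns the three published subset sizes", {
  cfg <- small_config()
  ann <- generate_probe_annotation(cfg)
  comb <- matrix(0, cfg$n_probes, 4,
                 dimnames = list(ann$probe_id, paste0("s", 1:4)))
  em <- structure(list(values = comb,
                       informative = rep(TRUE, cfg$n_probes)),
                  class = "expression_matrix")
  expect_identical(nrow(subset_by_origin(em, ann, "global")), cfg$n_probes)
  expect_identical(nrow(subset_by_origin(em, ann, "nuclear_mito")),
                   cfg$n_nuclear_mito)
  expect_identical(nrow(subset_by_origin(em, ann, "mtdna")), cfg$n_mtdna)
  expect_error(subset_by_origin(em, ann, "nope"))
  # random informative masks match a set-intersection oracle
  set.seed(4)
  for (i in 1:10) {
    em$informative <- runif(cfg$n_probes) < 0.5
    got <- nrow(subset_by_origin(em, ann, "nuclear_mito"))
    oracle <- length(intersect(which(em$informative),
                               which(ann$mito_function &
                                       ann$genome_of_origin == "nuclear")))
    expect_identical(got, oracle)
  }
  em$informative <- rep(FALSE, cfg$n_probes)
  expect_identical(nrow(subset_by_origin(em, ann, "mtdna")), 0L)
})

test_that("normalization is idempotent", {
  cfg <- sim_config()   # full-size slide; see wiggle note above
  arr <- generate_array_dataset(cfg)
  sl <- subtract_background(arr$slides[[1]])
  fit1 <- lowess_normalize(sl)
  # rebuild a slide whose dye-space M is the normalized M, same A
  s <- if (sl$dye_orientation == "sample_in_Cy5") 1 else -1
  m_dye <- s * fit1$M_norm
  sl2 <- sl
  sl2$data$F635_Median <- 2^(fit1$A + m_dye / 2) + sl$data$B635_Median
  sl2$data$F532_Median <- 2^(fit1$A - m_dye / 2) + sl$data$B532_Median
  fit2 <- lowess_normalize(subtract_background(sl2))
  delta <- abs(fit2$M_norm - fit1$M_norm)
  expect_lt(quantile(delta, 0.99, na.rm = TRUE), 0.05)
})
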