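test_that("TPM normalization follows the defining formula and conserves columns", {
  counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10, 10))
  lengths <- tibble::tibble(gene = c("g1", "g2"), length = c(1000, 2000))
  tpm <- compute_tpm(counts, lengths)
  expect_equal(tpm$s1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  one <- compute_tpm(tibble::tibble(gene = "g1", s1 = 7),
                     tibble::tibble(gene = "g1", length = 500))
  expect_equal(one$s1, 1e6)

  set.seed(14)
  mat <- tibble::tibble(gene = sprintf("g%02d", 1:50))
  for (s in c("a", "b", "c")) mat[[s]] <- rpois(50, 40)
  lens <- tibble::tibble(gene = mat$gene, length = runif(50, 200, 5000))
  tpm2 <- compute_tpm(mat, lens)
  for (s in c("a", "b", "c")) {
    expect_equal(sum(tpm2[[s]]), 1e6, tolerance = 1e-6)
  }
  mat$a <- 0
  expect_error(compute_tpm(mat, lens), "all-zero")
})

test_that("paired test returns unit fold and p near 1 on identical profiles", {
  se <- simulate_expression(n_pairs = 4, n_genes = 10, fold_map = numeric(0),
                            seed = 15)
  expr <- se$expr
  for (i in seq_len(nrow(se$pairs))) {
    expr[[se$pairs$mut_sample[i]]] <- expr[[se$pairs$wt_sample[i]]]
  }
  de <- paired_de_test(expr, se$pairs, expr$gene[1])
  expect_equal(de$fold_change, 1)
  expect_equal(de$p_value, 1)
  expect_error(paired_de_test(expr, se$pairs[1:2, ], expr$gene[1]), "3 matched")
})

test_that("fold estimate is the geometric mean of pair ratios and is equivariant", {
  se <- simulate_expression(n_pairs = 6, n_genes = 5, seed = 16)
  de <- paired_de_test(se$expr, se$pairs, "MYH7")
  expect_equal(de$fold_change, exp(mean(log(de$ratios))), tolerance = 1e-6)
  # scaling all MUT samples by k scales the fold by k (pseudocount off)
  scaled <- se$expr
  for (s in se$pairs$mut_sample) scaled[[s]] <- scaled[[s]] * 2
  de2 <- paired_de_test(scaled, se$pairs, "MYH7", pseudocount = 0)
  de1 <- paired_de_test(se$expr, se$pairs, "MYH7", pseudocount = 0)
  expect_equal(de2$fold_change, 2 * de1$fold_change, tolerance = 1e-9)
})

test_that("planted fold changes are recovered and ranked by strength", {
  se <- simulate_expression(n_pairs = 8, n_genes = 300,
                            fold_map = c(BIG = 12, SMALL = 3.2), seed = 17)
  scan <- de_scan(se$expr, se$pairs, all_genes = TRUE)
  called <- scan$gene[scan$called]
  expect_true(all(c("BIG", "SMALL") %in% called))
  expect_lt(which(scan$gene == "BIG"), which(scan$gene == "SMALL"))
  # impossible fold threshold empties the call set
  none <- de_scan(se$expr, se$pairs, min_fold = Inf)
  expect_equal(nrow(none), 0)
  # the highlighted gene is reported even when not called
  hl <- de_scan(se$expr, se$pairs, highlight_gene = "G0001")
  expect_true("G0001" %in% hl$gene)
})

test_that("scan calls only planted genes in a mostly-null matrix", {
  planted <- c(D1 = 5, D2 = 8, D3 = 3.5, D4 = 10, D5 = 4)
  hits <- 0
  set.seed(18)
  for (i in 1:10) {
    se <- simulate_expression(n_pairs = 8, n_genes = 2000, fold_map = planted)
    scan <- de_scan(se$expr, se$pairs)
    hits <- hits + setequal(scan$gene[scan$called], names(planted))
  }
  expect_gte(hits / 10, 0.9)
})

test_that("zero-zero pairs are dropped with a warning", {
  se <- simulate_expression(n_pairs = 5, n_genes = 5, fold_map = numeric(0),
                            seed = 19)
  expr <- se$expr
  expr[1, c(se$pairs$mut_sample[1], se$pairs$wt_sample[1])] <- 0
  expect_warning(de <- paired_de_test(expr, se$pairs, expr$gene[1]), "zero")
  expect_equal(de$n_pairs, 4)
})

test_that("densitometry model recovers a null effect and ignores loading rescale", {
  sim <- simulate_densitometry(effect = 0, seed = 20)
  fit <- densitometry_model(sim$records)
  expect_lt(abs(fit$percent_increase), 3 * fit$se_percent)

  # identical MUT/WT densities: exactly 0% increase
  flat <- tibble::tibble(pair_id = rep(c("p1", "p2"), each = 2),
                         genotype = rep(c("MUT", "WT"), 2),
                         band_density = c(2, 2, 3, 3),
                         loading_density = c(1, 1, 1.5, 1.5),
                         replicate = 1L)
  expect_equal(densitometry_model(flat)$percent_increase, 0, tolerance = 1e-10)

  sim2 <- simulate_densitometry(seed = 21)
  fit2 <- densitometry_model(sim2$records)
  doubled <- sim2$records
  doubled$loading_density <- doubled$loading_density * 2
  doubled$band_density <- doubled$band_density  # band unchanged
  fit3 <- densitometry_model(doubled)
  # doubling the loading control shifts the intercept, not the genotype effect
  expect_equal(fit3$percent_increase, fit2$percent_increase, tolerance = 1e-9)
  expect_error(densitometry_model(sim2$records[sim2$records$genotype == "MUT", ]),
               "MUT and WT")
})

test_that("densitometry blocking absorbs per-pair batch factors", {
  sim <- simulate_densitometry(seed = 22)
  fit <- densitometry_model(sim$records)
  batched <- sim$records
  factors <- c(pair1 = 0.5, pair2 = 2, pair3 = 5, pair4 = 0.1)
  batched$band_density <- batched$band_density * factors[batched$pair_id]
  fit_b <- densitometry_model(batched)
  expect_equal(fit_b$percent_increase, fit$percent_increase, tolerance = 1e-9)
  expect_equal(fit_b$se_percent, fit$se_percent, tolerance = 1e-9)
})
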