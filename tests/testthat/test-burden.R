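test_that("two-sided Fisher p matches hand enumeration on frozen tables", {
  # C(8,4) = 70 support: tables at most as probable as (3,1,1,3) sum to 34/70
  expect_equal(fisher_exact_two_sided(carrier_table(3, 1, 1, 3))$p_value,
               34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(carrier_table(0, 10, 0, 10))$p_value, 1)
  expect_error(carrier_table(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_exact_two_sided(carrier_table(0, 0, 5, 5)), "margins")
})

test_that("Fisher implementation agrees with enumeration oracle over random small tables", {
  set.seed(101)
  for (i in 1:500) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (c + d) == 0) next
    p_impl <- fisher_exact_two_sided(carrier_table(a, b, c, d))$p_value
    p_oracle <- fisher_oracle(a, b, c, d)
    expect_equal(p_impl, p_oracle, tolerance = 1e-10,
                 label = sprintf("table (%d,%d,%d,%d)", a, b, c, d))
  }
})

test_that("Fisher p is invariant under transposition and row swap with relabeling", {
  set.seed(102)
  for (i in 1:50) {
    t <- sample(0:12, 4, replace = TRUE)
    if (t[1] + t[2] == 0 || t[3] + t[4] == 0 ||
        t[1] + t[3] == 0 || t[2] + t[4] == 0) next
    p <- fisher_exact_two_sided(carrier_table(t[1], t[2], t[3], t[4]))$p_value
    p_transposed <- fisher_exact_two_sided(carrier_table(t[1], t[3], t[2], t[4]))$p_value
    p_swapped <- fisher_exact_two_sided(carrier_table(t[3], t[4], t[1], t[2]))$p_value
    expect_equal(p, p_transposed, tolerance = 1e-12)
    expect_equal(p, p_swapped, tolerance = 1e-12)
  }
})

test_that("odds ratio, Woolf interval and Haldane policy follow closed forms", {
  expect_equal(odds_ratio(carrier_table(1, 1, 1, 1))$or, 1)
  orr <- odds_ratio(carrier_table(20, 170, 31, 1032))
  expect_equal(orr$or, (20 * 1032) / (170 * 31), tolerance = 1e-12)
  expect_equal(orr$ci_low, exp(log(orr$or) - qnorm(0.975) *
                                 sqrt(1/20 + 1/170 + 1/31 + 1/1032)),
               tolerance = 1e-12)
  expect_equal(round(orr$ci_low, 1), 2.2)
  expect_equal(round(orr$ci_high, 1), 7.0)

  expect_error(odds_ratio(carrier_table(0, 10, 5, 5)), "haldane")
  hal <- odds_ratio(carrier_table(0, 10, 5, 5), zero_cell = "haldane")
  expect_equal(hal$or, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_true(hal$haldane_applied)

  # Haldane converges to the raw OR as cells grow
  raw <- odds_ratio(carrier_table(200, 1700, 310, 10320))$or
  hal_big <- odds_ratio(carrier_table(200, 1700, 310, 10320),
                        zero_cell = "haldane")$or
  expect_equal(hal_big, raw, tolerance = 5e-3)
})

test_that("enrichment percentage is the ratio of carrier fractions", {
  expect_equal(enrichment_percent(carrier_table(10, 90, 10, 90)), 100)
  expect_equal(enrichment_percent(carrier_table(20, 170, 31, 1032)),
               100 * (20 / 190) / (31 / 1063), tolerance = 1e-12)
  expect_warning(inf <- enrichment_percent(carrier_table(5, 5, 0, 10)),
                 "infinite")
  expect_equal(inf, Inf)
})

test_that("carrier collapsing counts multi-variant subjects once and handles missingness", {
  geno <- tibble::tibble(
    variant_id = c("v1", "v2", "v1", "v2", "v1", "v2"),
    gene = "MYH6",
    subject_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
    allele_count = c(1L, 1L, 0L, 0L, NA, NA)
  )
  subjects <- tibble::tibble(subject_id = c("s1", "s2", "s3"),
                             status = c("case", "case", "control"))
  expect_warning(
    carr <- collapse_carriers(geno, c("v1", "v2"), subjects, gene = "MYH6"),
    "all-missing")
  expect_equal(nrow(carr), 2)  # compound-het subject counted once, s3 dropped
  expect_equal(carr$carrier, c(TRUE, FALSE))
  # empty qualifying set: no carriers
  none <- collapse_carriers(geno[geno$allele_count %in% 0L, ],
                            character(0), subjects)
  expect_equal(sum(none$carrier), 0)
})

test_that("simulated cohort joined to the burden machinery recovers truth counts", {
  co <- simulate_cohort(seed = 31)
  carr <- collapse_carriers(co$genotypes, co$variants$variant_id, co$subjects,
                            gene = "MYH6")
  tab <- as_carrier_table(carr)
  expect_equal(tab$a, co$truth$MYH6$case_carriers)
  expect_equal(tab$c, co$truth$MYH6$control_carriers)
  expect_equal(tab$a + tab$b, 190)
  expect_equal(tab$c + tab$d, 1063)
})

test_that("gene burden scan ranks a planted gene first and applies Bonferroni", {
  genes <- c("MYH6", sprintf("NULL%02d", 1:4))
  co <- simulate_cohort(f_case = c(0.105, rep(0.029, 4)),
                        f_ctrl = 0.029, genes = genes, seed = 32)
  scan <- gene_burden_scan(co$genotypes, co$variants$variant_id, co$subjects,
                           genes)
  expect_equal(scan$gene[1], "MYH6")
  expect_equal(unique(scan$bonferroni_alpha), 0.05 / 5)
  expect_true(scan$significant[scan$gene == "MYH6"])
  # single-gene list: threshold equals alpha
  one <- gene_burden_scan(co$genotypes, co$variants$variant_id, co$subjects,
                          "MYH6")
  expect_equal(one$bonferroni_alpha, 0.05)
  expect_warning(gene_burden_scan(co$genotypes, co$variants$variant_id,
                                  co$subjects, c("MYH6", "ABSENT")),
                 "absent")
})
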