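make_geno <- function(...) {
  # ... = named vectors of allele counts per subject, one name per variant
  vars <- list(...)
  dplyr::bind_rows(purrr::imap(vars, function(gt, vid) {
    tibble::tibble(variant_id = vid, chrom = "14",
                   pos = as.integer(sub("v", "", vid)) * 100L,
                   ref = "A", alt = "T",
                   subject_id = names(gt), allele_count = unname(gt))
  }))
}

test_that("segregation filter keeps shared-affected variants and subtracts the unaffected", {
  g <- make_geno(
    v1 = c(`IV:1` = 1, `IV:3` = 1, `II:4` = 1, `III:2` = 0),   # pass
    v2 = c(`IV:1` = 1, `IV:3` = 1, `II:4` = 1, `III:2` = 1),   # mother carries
    v3 = c(`IV:1` = 1, `IV:3` = 0, `II:4` = 1, `III:2` = 0),   # not shared
    v4 = c(`IV:1` = 1, `IV:3` = NA, `II:4` = 1, `III:2` = 0),  # untyped required
    v5 = c(`IV:1` = 2, `IV:3` = 1, `II:4` = 1, `III:2` = NA)   # untyped excluded ok
  )
  req <- c("IV:1", "IV:3", "II:4"); exc <- "III:2"
  pass <- segregation_filter(g, req, exc)
  expect_setequal(pass$variant_id, c("v1", "v5"))
  det <- segregation_filter(g, req, exc, details = TRUE)
  reason <- setNames(det$reason, det$variant_id)
  expect_equal(reason[["v2"]], "excluded-carrier")
  expect_equal(reason[["v3"]], "required-not-shared")
  expect_equal(reason[["v4"]], "untyped-required")
  expect_equal(reason[["v5"]], "untyped-excluded")

  expect_error(segregation_filter(g, req, c(exc, "IV:1")), "disjoint")
  expect_error(segregation_filter(g, c(req, "ghost"), exc), "ghost")
})

test_that("segregation filter is order-invariant and anti-monotone in the config", {
  sim <- simulate_pedigree_vcf(n_background = 80, seed = 11)
  g <- sim$genotypes
  req <- sim$truth$required; exc <- sim$truth$excluded
  base <- segregation_filter(g, req, exc)
  set.seed(2)
  shuffled <- g[sample(nrow(g)), ]
  expect_equal(segregation_filter(shuffled, req, exc), base)
  # adding a required or excluded member can only shrink the passing set
  wider_req <- segregation_filter(g, c(req, "III:1"), exc)
  expect_true(all(wider_req$variant_id %in% base$variant_id))
})

test_that("passing variants reduce to unique sorted candidate genes", {
  passing <- tibble::tibble(chrom = "14", pos = c(100L, 150L, 900L, 5000L),
                            ref = "A", alt = "T",
                            variant_id = paste0("v", 1:4))
  gene_map <- tibble::tibble(gene = c("GENE2", "GENE1"), chrom = "14",
                             start = c(800L, 50L), end = c(1000L, 200L))
  expect_message(cand <- reduce_to_genes(passing, gene_map), "1 passing")
  expect_equal(cand$gene, c("GENE1", "GENE2"))
  expect_equal(attr(cand, "n_unassigned"), 1L)
  # overlapping intervals assign the variant to both genes
  overlap_map <- dplyr::bind_rows(gene_map,
    tibble::tibble(gene = "GENE3", chrom = "14", start = 90L, end = 160L))
  expect_setequal(reduce_to_genes(passing, overlap_map)$gene,
                  c("GENE1", "GENE2", "GENE3"))
  expect_equal(nrow(reduce_to_genes(passing[0, ], gene_map)), 0)
})

test_that("expression prioritization thresholds, ranks and keeps unknown genes", {
  expr <- tibble::tibble(gene = c("A", "B", "MYH6"), tpm = c(1, 0, 5000))
  out <- prioritize_by_expression(c("A", "B", "MYH6"), expr, min_tpm = 10)
  expect_equal(out$gene[out$status == "expressed"], "MYH6")
  all_in <- prioritize_by_expression(c("A", "B", "MYH6"), expr, min_tpm = 0)
  expect_equal(all_in$gene[all_in$status == "expressed"],
               c("MYH6", "A", "B"))
  with_unknown <- prioritize_by_expression(c("A", "NOVEL1"), expr, min_tpm = 0)
  expect_equal(with_unknown$status[with_unknown$gene == "NOVEL1"], "unknown")
})

test_that("the 20-gene candidate list reduces to the single heart-expressed gene", {
  # mirrors the study design: 20 candidates, one highly expressed in heart
  candidates <- c(sprintf("GENE%02d", 1:19), "MYH6")
  heart <- tibble::tibble(gene = candidates,
                          tpm = c(runif(19, 0, 5), 4000))
  out <- prioritize_by_expression(candidates, heart, min_tpm = 10)
  expect_equal(out$gene[out$status == "expressed"], "MYH6")
})

test_that("inheritance classification follows parental genotypes and typedness", {
  expect_equal(classify_inheritance(1, mother_gt = 0, father_gt = 1), "paternal")
  expect_equal(classify_inheritance(1, mother_gt = 0, father_gt = 0), "de_novo")
  expect_equal(classify_inheritance(1, mother_gt = 0, father_gt = NA), "nonmaternal")
  expect_equal(classify_inheritance(1, mother_gt = NA, father_gt = 0), "nonpaternal")
  expect_equal(classify_inheritance(1, mother_gt = 1, father_gt = 1), "biparental")
  expect_equal(classify_inheritance(1, mother_gt = 1, father_gt = NA), "maternal")
  expect_equal(classify_inheritance(1, mother_gt = NA, father_gt = NA), "unknown")
  expect_error(classify_inheritance(0, 1, 1), "carry")
})

test_that("compound heterozygosity is flagged with a phase summary", {
  two_trans <- tibble::tibble(variant_name = c("S385L", "M436V"),
                              inherit = c("maternal", "nonmaternal"))
  res <- detect_compound_het(two_trans)
  expect_true(res$flagged)
  expect_equal(res$phase, "trans-supported")

  one <- detect_compound_het(tibble::tibble(variant_name = "R443P",
                                            inherit = "paternal"))
  expect_false(one$flagged)

  cis <- detect_compound_het(tibble::tibble(variant_name = c("A", "B"),
                                            inherit = c("maternal", "maternal")))
  expect_equal(cis$phase, "cis-likely")

  unk <- detect_compound_het(tibble::tibble(variant_name = c("A", "B"),
                                            inherit = c("unknown", "unknown")))
  expect_equal(unk$phase, "phase-unknown")
})
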