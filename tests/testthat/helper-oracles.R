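# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementations.

# two-sided Fisher p by direct enumeration with stats::dhyper
fisher_oracle <- function(a, b, c, d) {
  support <- max(0, a + c - (c + d)):min(a + b, a + c)
  probs <- dhyper(support, m = a + c, n = b + d, k = a + b)
  p_obs <- dhyper(a, m = a + c, n = b + d, k = a + b)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive permutation distribution of the Gehan U statistic over all
# group relabelings preserving group sizes
gehan_permutation_p <- function(records) {
  n <- nrow(records)
  n1 <- sum(records$group == sort(unique(records$group))[1])
  obs <- gehan_breslow_test(records)$U
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(k) {
    g <- rep("g2", n); g[k] <- "g1"
    rec <- records
    rec$group <- g
    gehan_breslow_test(rec)$U
  })
  mean(abs(us) >= abs(obs) - 1e-9)
}

fixture_path <- function() {
  cardioburden_example("table1_myh6_variants.tsv")
}

# small 3-sample VCF used by several io tests
write_toy_vcf <- function(path, gts = c("0/1", "0/0", "1/1")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("14", "100", ".", "C", "G", ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  ), path)
  path
}
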