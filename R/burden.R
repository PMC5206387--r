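# Stage-2 engine: collapse rare, damaging variants to per-subject carrier
# status and test case/control enrichment with a two-sided Fisher exact test
# computed from first principles (log-space hypergeometric enumeration).

#' Construct a 2x2 carrier table
#'
#' @param a Case carriers.
#' @param b Case non-carriers.
#' @param c Control carriers.
#' @param d Control non-carriers.
#' @return An object of class `carrier_table`.
#' @examples
#' carrier_table(20, 170, 31, 1032)
#' @export
carrier_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) abort("carrier table cells must be non-negative")
  if (any(cells != round(cells))) abort("carrier table cells must be integers")
  structure(as.list(cells), class = "carrier_table")
}

#' @export
print.carrier_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("case", "control"), c("carrier", "noncarrier")))
  print(m)
  invisible(x)
}

# cumulative log factorials 0..n without assuming a gamma function
log_factorials <- local({
  cache <- c(0)
  function(n) {
    if (n + 1 > length(cache)) {
      old <- length(cache)
      cache <<- c(cache, cumsum(log(seq(old, n))) + cache[old])
    }
    cache[seq_len(n + 1)]
  }
})

#' Two-sided Fisher exact test for a 2x2 table, from first principles
#'
#' Computes the exact two-sided p-value under the probability-mass
#' definition: the sum of hypergeometric probabilities, over all tables with
#' the observed margins, that do not exceed the probability of the observed
#' table. Probabilities are computed in log space from cached log-factorials;
#' a relative tolerance of `1e-7` guards floating-point tie comparisons.
#'
#' @param table A [carrier_table()] (or anything coercible via
#'   `carrier_table(a, b, c, d)` when `a`..`d` are given instead).
#' @return An object of class `fisher_exact` with elements `p_value`,
#'   `table` and `estimate` (the sample odds ratio, `NA` when undefined).
#' @examples
#' fisher_exact_two_sided(carrier_table(3, 1, 1, 3))$p_value  # 34/70
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(inherits(table, "carrier_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  r1 <- a + b   # cases
  c1 <- a + c   # carriers
  if (r1 == 0 || (c + d) == 0) abort("both case and control margins must be positive")
  lf <- log_factorials(n)
  lfac <- function(k) lf[k + 1]
  # log P(x) for table (x, r1-x, c1-x, d+...) with fixed margins
  log_p <- function(x) {
    lfac(r1) + lfac(n - r1) + lfac(c1) + lfac(n - c1) - lfac(n) -
      (lfac(x) + lfac(r1 - x) + lfac(c1 - x) + lfac(n - r1 - c1 + x))
  }
  support <- seq(max(0L, c1 - (n - r1)), min(r1, c1))
  lp <- vapply(support, log_p, numeric(1))
  lp_obs <- log_p(a)
  # log(1 + 1e-7) ~ 1e-7: a 1e-7 relative tolerance on the probability scale
  p <- sum(exp(lp[lp <= lp_obs + 1e-7]))
  p <- min(1, p)
  structure(list(p_value = p, table = table,
                 estimate = if (b * c > 0) (a * d) / (b * c) else NA_real_),
            class = "fisher_exact")
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat("Two-sided Fisher exact test\n")
  cat(sprintf("  p = %.6g, sample OR = %.4g\n", x$p_value, x$estimate))
  invisible(x)
}

#' Sample odds ratio with Woolf confidence interval
#'
#' OR = (a d)/(b c); the 95% interval is
#' exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)). A zero cell either raises an
#' error or, under the Haldane policy, adds 0.5 to every cell.
#'
#' @param table A [carrier_table()].
#' @param zero_cell Either `"error"` (default) or `"haldane"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble: `or`, `ci_low`, `ci_high`, `haldane_applied`.
#' @examples
#' odds_ratio(carrier_table(20, 170, 31, 1032))
#' @export
odds_ratio <- function(table, zero_cell = c("error", "haldane"),
                       conf_level = 0.95) {
  stopifnot(inherits(table, "carrier_table"))
  zero_cell <- arg_match(zero_cell)
  cells <- c(table$a, table$b, table$c, table$d)
  haldane <- FALSE
  if (any(cells == 0)) {
    if (zero_cell == "error") {
      abort("zero cell in carrier table; use zero_cell = \"haldane\"")
    }
    cells <- cells + 0.5
    haldane <- TRUE
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(or = or,
         ci_low = exp(log(or) - z * se),
         ci_high = exp(log(or) + z * se),
         haldane_applied = haldane)
}

#' Carrier-frequency enrichment as a percentage ratio
#'
#' 100 x (case carrier fraction) / (control carrier fraction); equal
#' fractions give 100. With zero control carriers the enrichment is
#' infinite and reported as `Inf` with a warning.
#'
#' @param table A [carrier_table()].
#' @return The enrichment percentage.
#' @examples
#' enrichment_percent(carrier_table(20, 170, 31, 1032))  # ~361
#' @export
enrichment_percent <- function(table) {
  stopifnot(inherits(table, "carrier_table"))
  case_frac <- table$a / (table$a + table$b)
  if (table$c == 0) {
    warn("zero control carriers: enrichment is infinite")
    return(Inf)
  }
  ctrl_frac <- table$c / (table$c + table$d)
  100 * case_frac / ctrl_frac
}

#' Collapse qualifying variants to per-subject carrier status
#'
#' A subject is a carrier iff it carries at least one qualifying variant in
#' the gene; subjects carrying several qualifying variants (for example a
#' compound heterozygote) count once. Subjects with all genotypes missing at
#' the qualifying sites are excluded from denominators with a warning.
#'
#' @param genotypes Long genotype tibble (`subject_id`, `variant_id`,
#'   `allele_count`; a `gene` column restricts sites when `gene` is given).
#' @param qualifying_ids Character vector of qualifying `variant_id`s
#'   (typically rare & damaging sites from [annotate_variants()]).
#' @param subjects Tibble (`subject_id`, `status` in `{"case", "control"}`);
#'   subjects absent from `genotypes` are treated as typed non-carriers only
#'   if `assume_typed = TRUE`.
#' @param gene Optional gene symbol to restrict to (requires a `gene` column).
#' @param assume_typed Treat subjects with no genotype rows as confirmed
#'   non-carriers (default `TRUE`, matching a sites-only carrier export).
#' @return Tibble (`subject_id`, `status`, `carrier`); excluded subjects are
#'   dropped.
#' @export
collapse_carriers <- function(genotypes, qualifying_ids, subjects, gene = NULL,
                              assume_typed = TRUE) {
  g <- genotypes
  if (!is.null(gene)) {
    if (!"gene" %in% names(g)) abort("genotypes need a 'gene' column to filter by gene")
    g <- filter(g, .data$gene == !!gene)
  }
  g <- filter(g, .data$variant_id %in% qualifying_ids)
  per_subject <- g %>%
    group_by(.data$subject_id) %>%
    summarise(all_missing = all(is.na(.data$allele_count)),
              carrier = any(.data$allele_count >= 1, na.rm = TRUE),
              .groups = "drop")
  out <- subjects %>% left_join(per_subject, by = "subject_id")
  untyped <- is.na(out$carrier)
  if (any(untyped) && !assume_typed) {
    warn(sprintf("%d subject(s) with no genotype data excluded", sum(untyped)))
    out <- out[!untyped, , drop = FALSE]
  } else if (any(untyped)) {
    out$carrier[untyped] <- FALSE
    out$all_missing[untyped] <- FALSE
  }
  if (any(out$all_missing)) {
    warn(sprintf("%d subject(s) with all-missing genotypes excluded from denominators",
                 sum(out$all_missing)))
    out <- out[!out$all_missing, , drop = FALSE]
  }
  select(out, "subject_id", "status", "carrier")
}

#' Build the 2x2 carrier table from per-subject carrier status
#'
#' @param carriers Tibble (`subject_id`, `status`, `carrier`) as from
#'   [collapse_carriers()].
#' @return A [carrier_table()].
#' @export
as_carrier_table <- function(carriers) {
  carrier_table(
    a = sum(carriers$status == "case" & carriers$carrier),
    b = sum(carriers$status == "case" & !carriers$carrier),
    c = sum(carriers$status == "control" & carriers$carrier),
    d = sum(carriers$status == "control" & !carriers$carrier)
  )
}

#' Per-gene carrier burden scan
#'
#' For each gene, collapses qualifying variants to carrier status and reports
#' carrier counts, carrier percentages, enrichment, the exact two-sided
#' Fisher p, the sample odds ratio with Woolf interval, and the
#' Bonferroni-adjusted significance threshold `alpha / n_genes` (raw p is
#' always reported; the design tests each candidate gene
#' individually).
#'
#' @param genotypes Long genotype tibble with a `gene` column.
#' @param qualifying_ids Qualifying `variant_id`s across all genes.
#' @param subjects Tibble (`subject_id`, `status`).
#' @param genes Character vector of genes to test.
#' @param alpha Family-wise significance level, default 0.05.
#' @return A tibble with one row per gene: `gene`, `a`, `b`, `c`, `d`,
#'   `carrier_pct_cases`, `carrier_pct_controls`, `enrichment_pct`,
#'   `p_fisher`, `or`, `ci_low`, `ci_high`, `bonferroni_alpha`,
#'   `significant`. Genes absent from the genotype data yield an `NA` row
#'   with a warning.
#' @export
gene_burden_scan <- function(genotypes, qualifying_ids, subjects, genes,
                             alpha = 0.05) {
  thr <- alpha / length(genes)
  rows <- purrr::map(genes, function(g) {
    if (!g %in% genotypes$gene) {
      warn(paste0("gene '", g, "' absent from genotype data"))
      return(tibble(gene = g, a = NA_integer_, b = NA_integer_,
                    c = NA_integer_, d = NA_integer_,
                    carrier_pct_cases = NA_real_, carrier_pct_controls = NA_real_,
                    enrichment_pct = NA_real_, p_fisher = NA_real_,
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    }
    carriers <- collapse_carriers(genotypes, qualifying_ids, subjects, gene = g)
    tab <- as_carrier_table(carriers)
    fe <- fisher_exact_two_sided(tab)
    orr <- odds_ratio(tab, zero_cell = "haldane")
    tibble(gene = g, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
           carrier_pct_cases = 100 * tab$a / (tab$a + tab$b),
           carrier_pct_controls = 100 * tab$c / (tab$c + tab$d),
           enrichment_pct = if (tab$c > 0) enrichment_percent(tab) else NA_real_,
           p_fisher = fe$p_value, or = orr$or, ci_low = orr$ci_low,
           ci_high = orr$ci_high)
  })
  bind_rows(rows) %>%
    mutate(bonferroni_alpha = thr,
           significant = !is.na(.data$p_fisher) & .data$p_fisher < thr) %>%
    arrange(.data$p_fisher)
}

#' @rdname fisher_exact_two_sided
#' @param x A `fisher_exact` object.
#' @param ... Unused.
#' @export
tidy.fisher_exact <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p_value,
         a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d)
}
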