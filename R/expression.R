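# Stage-4 engine: TPM normalization, matched-pair fold-change testing on
# log2 ratios, a thresholded differential-expression scan, and a
# pair-blocked linear model for Western blot densitometry.

#' Transcripts-per-million normalization
#'
#' TPM_g = 1e6 (c_g / l_g) / sum_h (c_h / l_h) per sample, so every sample
#' column sums to one million.
#'
#' @param counts Expression tibble with a `gene` column and one numeric
#'   column per sample (raw counts), as from [read_expression_matrix()].
#' @param lengths Tibble (`gene`, `length`) of effective transcript lengths
#'   in bases, or a named numeric vector.
#' @return A tibble of the same shape with TPM values.
#' @export
compute_tpm <- function(counts, lengths) {
  if (is.data.frame(lengths)) lengths <- setNames(lengths$length, lengths$gene)
  len <- lengths[counts$gene]
  if (any(is.na(len))) {
    abort(paste0("missing length for gene ",
                 counts$gene[which(is.na(len))[1]]))
  }
  if (any(len <= 0)) abort("effective lengths must be positive")
  out <- counts
  for (col in setdiff(names(counts), "gene")) {
    rate <- counts[[col]] / len
    total <- sum(rate)
    if (total == 0) abort(paste0("sample '", col, "' has all-zero counts"))
    out[[col]] <- unname(1e6 * rate / total)
  }
  out
}

# log2 MUT/WT ratio per pair for one gene, with pseudocount; pairs where both
# members are zero are dropped with a warning
pair_log2_ratios <- function(expr, pairs, gene, pseudocount = 0.5) {
  row <- expr[expr$gene == gene, , drop = FALSE]
  if (nrow(row) != 1) abort(paste0("gene '", gene, "' not found (or duplicated)"))
  mut <- as.numeric(row[, pairs$mut_sample])
  wt <- as.numeric(row[, pairs$wt_sample])
  both_zero <- mut == 0 & wt == 0
  if (any(both_zero)) {
    warn(sprintf("gene %s: %d pair(s) with zero expression in both members dropped",
                 gene, sum(both_zero)))
    mut <- mut[!both_zero]; wt <- wt[!both_zero]
  }
  log2((mut + pseudocount) / (wt + pseudocount))
}

#' Matched-pair differential expression test for one gene
#'
#' The fold change is the geometric mean of per-pair MUT/WT expression
#' ratios (after adding a pseudocount); significance is a paired t-test on
#' the log2 ratios.
#'
#' @param expr Expression tibble (`gene` column + sample columns, TPM or
#'   otherwise comparably normalized).
#' @param pairs Tibble describing the matched pairs, with columns
#'   `mut_sample` and `wt_sample` naming expression columns (optionally
#'   `pair_id`, `tissue`, and matching covariates).
#' @param gene Gene to test.
#' @param pseudocount Added to both members before the log ratio
#'   (default 0.5, in the expression unit).
#' @return An object of class `paired_de`: list with `gene`, `fold_change`
#'   (MUT/WT), `log2_fold`, `statistic`, `p_value`, `n_pairs`, `ratios`
#'   (per-pair MUT/WT ratios).
#' @export
paired_de_test <- function(expr, pairs, gene, pseudocount = 0.5) {
  if (nrow(pairs) < 3) abort("at least 3 matched pairs required")
  lr <- pair_log2_ratios(expr, pairs, gene, pseudocount)
  n <- length(lr)
  if (n < 3) abort("fewer than 3 usable pairs after dropping zero-zero pairs")
  m <- mean(lr)
  s <- sd(lr)
  if (s == 0) {
    stat <- if (m == 0) 0 else Inf
    p <- if (m == 0) 1 else 0
  } else {
    stat <- m / (s / sqrt(n))
    p <- 2 * pt(abs(stat), df = n - 1, lower.tail = FALSE)
  }
  structure(list(gene = gene, fold_change = 2^m, log2_fold = m,
                 statistic = stat, p_value = p, n_pairs = n,
                 ratios = 2^lr), class = "paired_de")
}

#' @export
print.paired_de <- function(x, ...) {
  cat(sprintf("Paired test for %s: fold change %.3g (MUT/WT), t = %.3g, p = %.3g (%d pairs)\n",
              x$gene, x$fold_change, x$statistic, x$p_value, x$n_pairs))
  invisible(x)
}

#' @rdname paired_de_test
#' @param x A `paired_de` object.
#' @param ... Unused.
#' @export
tidy.paired_de <- function(x, ...) {
  tibble(gene = x$gene, estimate = x$fold_change, log2_fold = x$log2_fold,
         statistic = x$statistic, p.value = x$p_value, n_pairs = x$n_pairs)
}

#' Differential-expression scan over all genes
#'
#' Runs the matched-pair test for every gene (vectorized), applies
#' Benjamini-Hochberg correction, and flags genes passing both the fold and
#' p-value thresholds. The collapsed candidate gene itself, when present, is
#' reported whether or not it passes (its transcript level is of interest
#' even when unchanged).
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param pairs Matched-pair tibble (see [paired_de_test()]).
#' @param min_fold Minimum fold change in either direction (default 3).
#' @param max_p Maximum raw p-value (default 5e-3).
#' @param pseudocount Pseudocount before the log ratio (default 0.5).
#' @param highlight_gene Optional gene symbol always included in the output.
#' @return A tibble with one row per gene — `gene`, `fold_change`,
#'   `log2_fold`, `statistic`, `p.value`, `q.value` (BH), `called` — sorted
#'   by p among called genes; only called genes (plus `highlight_gene`) are
#'   returned unless `all_genes = TRUE`.
#' @param all_genes Return every gene rather than only the called set.
#' @export
de_scan <- function(expr, pairs, min_fold = 3, max_p = 5e-3, pseudocount = 0.5,
                    highlight_gene = NULL, all_genes = FALSE) {
  if (nrow(pairs) < 3) abort("at least 3 matched pairs required")
  mut <- as.matrix(expr[, pairs$mut_sample])
  wt <- as.matrix(expr[, pairs$wt_sample])
  lr <- log2((mut + pseudocount) / (wt + pseudocount))
  n <- ncol(lr)
  m <- rowMeans(lr)
  s <- sqrt(rowSums((lr - m)^2) / (n - 1))
  stat <- m / (s / sqrt(n))
  stat[s == 0 & m == 0] <- 0
  p <- 2 * pt(abs(stat), df = n - 1, lower.tail = FALSE)
  p[s == 0 & m == 0] <- 1
  res <- tibble(gene = expr$gene, fold_change = 2^m, log2_fold = m,
                statistic = stat, p.value = p,
                q.value = p.adjust(p, method = "BH")) %>%
    mutate(called = (.data$fold_change >= min_fold |
                       .data$fold_change <= 1 / min_fold) &
                    .data$p.value <= max_p) %>%
    arrange(.data$p.value)
  if (all_genes) return(res)
  keep <- res$called
  if (!is.null(highlight_gene)) keep <- keep | res$gene %in% highlight_gene
  res[keep, , drop = FALSE]
}

#' Pair-blocked linear model for densitometry
#'
#' Models the log of the loading-normalized band density
#' (band / loading control) as genotype effect + pair block, fit by least
#' squares. The genotype effect is reported as a percent increase,
#' 100 (exp(beta) - 1), with its standard error propagated by the delta
#' method. Per-pair multiplicative batch factors are absorbed by the
#' blocking term; rescaling all loading densities leaves the estimate
#' unchanged.
#'
#' @param records Densitometry tibble (`pair_id`, `genotype` in
#'   `{"MUT","WT"}`, `band_density`, `loading_density`, `replicate`).
#' @return An object of class `densitometry_fit`: list with
#'   `percent_increase`, `se_percent`, `beta` (log-scale effect), `se_beta`,
#'   `p_value`, `n_pairs`, `fit` (the underlying `lm`).
#' @export
densitometry_model <- function(records) {
  if (n_distinct(records$genotype) < 2) {
    abort("both MUT and WT measurements are required")
  }
  if (n_distinct(records$pair_id) < 2) abort("at least 2 pairs required")
  dat <- tibble(
    y = log(records$band_density / records$loading_density),
    genotype = factor(records$genotype, levels = c("WT", "MUT")),
    pair = factor(records$pair_id)
  )
  fit <- lm(y ~ genotype + pair, data = dat)
  beta <- coef(fit)[["genotypeMUT"]]
  # suppress summary.lm's note on zero-residual (degenerate but valid) input
  se_beta <- sqrt(suppressWarnings(vcov(fit))["genotypeMUT", "genotypeMUT"])
  t_stat <- beta / se_beta
  df <- fit$df.residual
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  structure(list(
    percent_increase = 100 * (exp(beta) - 1),
    se_percent = 100 * exp(beta) * se_beta,
    beta = beta, se_beta = se_beta, p_value = p,
    n_pairs = n_distinct(records$pair_id), fit = fit
  ), class = "densitometry_fit")
}

#' @export
print.densitometry_fit <- function(x, ...) {
  cat(sprintf("Densitometry (pair-blocked): %+.1f%% (SE %.1f%%), p = %.3g over %d pairs\n",
              x$percent_increase, x$se_percent, x$p_value, x$n_pairs))
  invisible(x)
}

#' @rdname densitometry_model
#' @param x A `densitometry_fit`.
#' @param ... Unused.
#' @export
tidy.densitometry_fit <- function(x, ...) {
  tibble(term = "genotypeMUT", estimate = x$beta, std.error = x$se_beta,
         percent_increase = x$percent_increase, se_percent = x$se_percent,
         p.value = x$p_value)
}

#' @rdname densitometry_model
#' @export
glance.densitometry_fit <- function(x, ...) {
  tibble(percent_increase = x$percent_increase, se_percent = x$se_percent,
         p.value = x$p_value, n_pairs = x$n_pairs,
         df.residual = x$fit$df.residual)
}
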