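# Synthetic-data generators. Each generator reproduces the statistical
# structure one pipeline stage assumes — subject-level carrier status for the
# case-control cohort, Mendelian transmission through a fixed family
# structure for the segregation filter, exponential event times for the
# survival comparison, and log-normal matched-pair expression — and returns
# a truth record sufficient to score the downstream stage.

#' The default multigenerational pedigree template
#'
#' A three-generation family with two affected siblings (IV:1, IV:3), their
#' affected father (III:1), an unaffected mother (III:2), and an affected
#' paternal great aunt (II:4) reachable through ungenotyped ancestors —
#' the structure the segregation filter was designed around. Genotyped
#' members are IV:1, IV:3, III:1, III:2 (genome) and II:4 (exome).
#'
#' @return A tibble of class `pedigree` with an extra `genotyped` column.
#' @export
pedigree_template <- function() {
  ped <- tibble(
    family_id = "F1",
    id        = c("I:1", "I:2", "II:1", "II:2", "II:4", "III:1", "III:2", "IV:1", "IV:3"),
    father_id = c(NA, NA, "I:1", NA, "I:1", "II:1", NA, "III:1", "III:1"),
    mother_id = c(NA, NA, "I:2", NA, "I:2", "II:2", NA, "III:2", "III:2"),
    sex       = c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L, 1L),
    affected  = c(NA, NA, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    genotyped = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  as_pedigree(ped)
}

# P(child genotype | mother, father genotypes) under Mendelian transmission
# of a biallelic variant; genotypes are alt-allele counts 0/1/2
mendelian_prob <- function(child, mother, father) {
  tm <- mother / 2; tf <- father / 2
  p0 <- (1 - tm) * (1 - tf)
  p1 <- tm * (1 - tf) + tf * (1 - tm)
  p2 <- tm * tf
  ifelse(child == 0, p0, ifelse(child == 1, p1, p2))
}

#' Exact probability that a background variant passes the segregation filter
#'
#' Enumerates every genotype configuration of the pedigree (founders in
#' Hardy-Weinberg proportions at the given allele frequency, descendants by
#' Mendelian transmission) and sums the probability of configurations in
#' which every required member carries the allele and every excluded member
#' is homozygous reference. This is the analytic expectation against which
#' simulated background leakage is scored.
#'
#' @param pedigree Pedigree tibble (parents must precede children; the
#'   [pedigree_template()] already is ordered).
#' @param required,excluded Member ids as in [segregation_filter()].
#' @param maf Population alternate-allele frequency.
#' @return The passing probability for one variant.
#' @export
segregation_pass_probability <- function(pedigree, required, excluded, maf) {
  ids <- pedigree$id
  n <- length(ids)
  hwe <- c(`0` = (1 - maf)^2, `1` = 2 * maf * (1 - maf), `2` = maf^2)
  configs <- as.matrix(expand.grid(rep(list(0:2), n)))
  colnames(configs) <- ids
  prob <- rep(1, nrow(configs))
  for (i in seq_len(n)) {
    f <- pedigree$father_id[i]; m <- pedigree$mother_id[i]
    if (is.na(f)) {
      prob <- prob * hwe[as.character(configs[, i])]
    } else {
      prob <- prob * mendelian_prob(configs[, i], configs[, m], configs[, f])
    }
  }
  ok <- rep(TRUE, nrow(configs))
  for (id in required) ok <- ok & configs[, id] >= 1
  for (id in excluded) ok <- ok & configs[, id] == 0
  sum(prob[ok])
}

#' Simulate a family genotype set for the segregation filter
#'
#' Plants one dominant variant carried (heterozygous) by every affected
#' member and absent from the unaffected members, then adds background
#' variants drawn at a fixed population frequency with Mendelian
#' transmission through the pedigree. Only genotyped members appear in the
#' output, mirroring a real sequencing design.
#'
#' @param n_background Number of background variants (default 500).
#' @param background_maf Population allele frequency of background variants
#'   (default 0.05).
#' @param pedigree Pedigree template with a `genotyped` column.
#' @param seed Random seed.
#' @return A list: `genotypes` (long tibble over genotyped members),
#'   `pedigree`, and `truth` (`planted_variant_id`, `pass_probability` for a
#'   background variant, `expected_leakage`).
#' @export
simulate_pedigree_vcf <- function(n_background = 500, background_maf = 0.05,
                                  pedigree = pedigree_template(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genotyped <- pedigree$id[pedigree$genotyped]
  affected <- pedigree$id[!is.na(pedigree$affected) & pedigree$affected]
  unaffected <- pedigree$id[!is.na(pedigree$affected) & !pedigree$affected]
  planted <- setNames(integer(length(pedigree$id)), pedigree$id)
  planted[affected] <- 1L
  # carry the allele down the untyped ancestral path so transmission is
  # Mendelian-consistent: founders I:1 and intermediate II:1 are carriers
  planted[c("I:1", "II:1")] <- 1L
  rows <- list(tibble(chrom = "14", pos = 1000L, ref = "C", alt = "G",
                      subject_id = genotyped,
                      allele_count = unname(planted[genotyped])))
  if (n_background > 0) {
    # one genotype matrix (variant x member), founders in HWE proportions,
    # descendants by Mendelian transmission; vectorized across variants
    gt <- matrix(0L, nrow = n_background, ncol = nrow(pedigree),
                 dimnames = list(NULL, pedigree$id))
    for (i in seq_len(nrow(pedigree))) {
      f <- pedigree$father_id[i]; m <- pedigree$mother_id[i]
      gt[, i] <- if (is.na(f)) {
        rbinom(n_background, 2, background_maf)
      } else {
        rbinom(n_background, 1, gt[, m] / 2) + rbinom(n_background, 1, gt[, f] / 2)
      }
    }
    bg <- tibble(
      chrom = "14",
      pos = rep(10000L + seq_len(n_background), each = length(genotyped)),
      ref = "A", alt = "T",
      subject_id = rep(genotyped, n_background),
      allele_count = as.integer(t(gt[, genotyped, drop = FALSE]))
    )
    rows <- c(rows, list(bg))
  }
  genotypes <- bind_rows(rows) %>%
    mutate(variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                              sep = ":")) %>%
    select("variant_id", "chrom", "pos", "ref", "alt", "subject_id",
           "allele_count")
  required <- intersect(affected, genotyped)
  excluded <- intersect(unaffected, setdiff(genotyped, required))
  p_pass <- segregation_pass_probability(pedigree, required,
                                         setdiff(excluded, required),
                                         background_maf)
  list(
    genotypes = genotypes,
    pedigree = pedigree,
    truth = list(planted_variant_id = "14:1000:C:G",
                 required = required,
                 excluded = setdiff(excluded, required),
                 pass_probability = p_pass,
                 expected_leakage = n_background * p_pass)
  )
}

# distinct qualifying-variant template drawn from the packaged fixture
variant_template <- function() {
  tab <- read_variant_table(cardioburden_example("table1_myh6_variants.tsv"))
  tab %>%
    distinct(.data$variant_name, .keep_all = TRUE) %>%
    mutate(gene = "MYH6",
           variant_id = paste("14", .data$coordinate_start, .data$ref_allele,
                              .data$alt_allele, sep = ":")) %>%
    select("variant_id", "gene", "variant_name", "domain", "exon",
           "pp2", "sift", "novel", "pop_freq_pct")
}

#' Simulate a labeled case-control cohort
#'
#' Each case (control) is independently a qualifying-variant carrier with
#' probability `f_case` (`f_ctrl`), per gene; carriers of the primary gene
#' receive one variant sampled from a template modeled on the packaged
#' variant table, carriers of any other gene a synthetic site. Simulation is
#' at the subject (carrier) level, matching the carrier-collapsing test.
#'
#' @param n_cases,n_controls Cohort sizes (defaults 190 and 1063).
#' @param f_case,f_ctrl Carrier frequencies (defaults 0.105 and 0.029),
#'   recycled across `genes`.
#' @param genes Genes to simulate (default `"MYH6"`).
#' @param seed Random seed.
#' @return A list: `genotypes` (long tibble with `gene` column), `subjects`
#'   (`subject_id`, `status`), `variants` (template metadata) and `truth`
#'   (per-gene carrier counts).
#' @export
simulate_cohort <- function(n_cases = 190, n_controls = 1063,
                            f_case = 0.105, f_ctrl = 0.029,
                            genes = "MYH6", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(f_case >= 0 & f_case <= 1), all(f_ctrl >= 0 & f_ctrl <= 1))
  f_case <- rep_len(f_case, length(genes))
  f_ctrl <- rep_len(f_ctrl, length(genes))
  subjects <- tibble(
    subject_id = c(sprintf("case_%03d", seq_len(n_cases)),
                   sprintf("ctrl_%04d", seq_len(n_controls))),
    status = rep(c("case", "control"), c(n_cases, n_controls))
  )
  tmpl <- variant_template()
  geno <- list(); truth <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    p <- if_else(subjects$status == "case", f_case[i], f_ctrl[i])
    carrier <- rbinom(nrow(subjects), 1, p) == 1
    vids <- if (g == "MYH6") tmpl$variant_id else paste0(g, ":site1")
    assigned <- if_else(carrier,
                        sample(vids, nrow(subjects), replace = TRUE),
                        NA_character_)
    rows <- purrr::map(vids, function(v) {
      tibble(variant_id = v, gene = g, subject_id = subjects$subject_id,
             allele_count = as.integer(!is.na(assigned) & assigned == v))
    })
    geno[[g]] <- bind_rows(rows)
    truth[[g]] <- list(
      case_carriers = sum(carrier & subjects$status == "case"),
      control_carriers = sum(carrier & subjects$status == "control"),
      carrier_ids = subjects$subject_id[carrier]
    )
  }
  variants <- bind_rows(
    tmpl[tmpl$gene %in% genes, ],
    tibble(variant_id = paste0(setdiff(genes, "MYH6"), ":site1"),
           gene = setdiff(genes, "MYH6"))
  )
  list(genotypes = bind_rows(geno), subjects = subjects,
       variants = variants, truth = truth)
}

#' Simulate a two-group transplant-free survival cohort
#'
#' Event times are exponential with a group-specific hazard (variant
#' carriers at `hazard_ratio` times the wild-type hazard); a fixed fraction
#' of subjects, chosen at random, is censored uniformly before its event
#' time.
#'
#' @param n_mut,n_wt Group sizes (defaults 10 and 62).
#' @param hazard_wt Wild-type hazard per year (default `log(2) / 15`,
#'   a 15-year median transplant-free survival).
#' @param hazard_ratio Carrier/wild-type hazard ratio (default 3).
#' @param censor_frac Fraction of subjects censored (default 0.2).
#' @param seed Random seed.
#' @return A list: `records` (tibble `subject_id`, `group`, `time`, `event`,
#'   `age_years`) and `truth` (the generating parameters).
#' @export
simulate_survival <- function(n_mut = 10, n_wt = 62,
                              hazard_wt = log(2) / 15, hazard_ratio = 3,
                              censor_frac = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_mut + n_wt
  group <- rep(c("MUT", "WT"), c(n_mut, n_wt))
  hazard <- if_else(group == "MUT", hazard_wt * hazard_ratio, hazard_wt)
  t_event <- rexp(n, rate = hazard)
  censored <- rep(FALSE, n)
  n_cens <- round(censor_frac * n)
  if (n_cens > 0) censored[sample.int(n, n_cens)] <- TRUE
  time <- if_else(censored, runif(n, 0, t_event), t_event)
  list(
    records = tibble(subject_id = sprintf("S%03d", seq_len(n)), group = group,
                     time = time, event = !censored,
                     age_years = runif(n, 6, 25)),
    truth = list(hazard_wt = hazard_wt, hazard_ratio = hazard_ratio,
                 censor_frac = censor_frac)
  )
}

#' Simulate matched-pair expression data
#'
#' Gene expression is log-normal on the log2 scale with a shared per-pair
#' intercept (absorbed by the paired analysis) and independent per-sample
#' noise; genes listed in `fold_map` receive the log2 of the planted fold in
#' the MUT member of every pair.
#'
#' @param n_pairs Number of matched pairs (default 8).
#' @param n_genes Number of genes (default 2000).
#' @param fold_map Named numeric vector of planted MUT/WT folds
#'   (default `c(MYH7 = 3.46)`); empty vector for a null matrix.
#' @param pair_sd SD of the per-pair log2 intercept (default 0.5).
#' @param noise_sd SD of the per-sample log2 noise (default 0.18).
#' @param base_log2 Mean and SD of per-gene baseline log2 expression
#'   (default `c(6, 2)`).
#' @param seed Random seed.
#' @return A list: `expr` (tibble `gene` + one column per sample), `pairs`
#'   (tibble `pair_id`, `mut_sample`, `wt_sample`, `tissue`) and `truth`
#'   (the fold map).
#' @export
simulate_expression <- function(n_pairs = 8, n_genes = 2000,
                                fold_map = c(MYH7 = 3.46),
                                pair_sd = 0.5, noise_sd = 0.18,
                                base_log2 = c(6, 2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- c(names(fold_map), sprintf("G%04d", seq_len(n_genes)))
  genes <- unique(genes)
  mu <- rnorm(length(genes), base_log2[1], base_log2[2])
  planted <- setNames(rep(0, length(genes)), genes)
  planted[names(fold_map)] <- log2(fold_map)
  pair_ids <- sprintf("P%02d", seq_len(n_pairs))
  expr <- tibble(gene = genes)
  for (i in seq_len(n_pairs)) {
    b <- rnorm(1, 0, pair_sd)
    wt <- mu + b + rnorm(length(genes), 0, noise_sd)
    mut <- mu + b + planted + rnorm(length(genes), 0, noise_sd)
    expr[[paste0("MUT_", pair_ids[i])]] <- 2^mut
    expr[[paste0("WT_", pair_ids[i])]] <- 2^wt
  }
  pairs <- tibble(pair_id = pair_ids,
                  mut_sample = paste0("MUT_", pair_ids),
                  wt_sample = paste0("WT_", pair_ids),
                  tissue = rep_len(c("atrial_septum", "right_ventricle"), n_pairs))
  list(expr = expr, pairs = pairs, truth = list(fold_map = fold_map))
}

#' Simulate Western blot densitometry
#'
#' Loading-normalized band ratios are log-normal with a per-pair block
#' effect and replicate noise; MUT samples carry a planted multiplicative
#' genotype effect.
#'
#' @param n_pairs Number of tissue pairs (default 4).
#' @param n_replicates Technical replicates per sample (default 5).
#' @param effect Fractional increase in MUT vs WT (default 0.62, i.e. +62%).
#' @param pair_sd SD of the per-pair log intercept (default 0.5).
#' @param noise_sd SD of the per-replicate log noise (default 0.3).
#' @param seed Random seed.
#' @return A list: `records` (densitometry tibble) and `truth`
#'   (`percent_increase`).
#' @export
simulate_densitometry <- function(n_pairs = 4, n_replicates = 5, effect = 0.62,
                                  pair_sd = 0.5, noise_sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(seq_len(n_pairs), function(i) {
    b <- rnorm(1, 0, pair_sd)
    gapdh <- runif(2 * n_replicates, 0.8, 1.2)
    log_ratio <- c(b + log(1 + effect) + rnorm(n_replicates, 0, noise_sd),
                   b + rnorm(n_replicates, 0, noise_sd))
    tibble(pair_id = sprintf("pair%d", i),
           genotype = rep(c("MUT", "WT"), each = n_replicates),
           band_density = exp(log_ratio) * gapdh,
           loading_density = gapdh,
           replicate = rep(seq_len(n_replicates), 2))
  })
  list(records = bind_rows(rows),
       truth = list(percent_increase = 100 * effect))
}
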