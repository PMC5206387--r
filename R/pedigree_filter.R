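# Stage-1 engine: reduce genome-wide variants to candidate genes by
# affected-sharing and unaffected-subtraction, prioritize candidates by
# cardiac expression, and classify per-variant inheritance.

#' Segregation filter under a dominant sharing model
#'
#' Keeps variants whose alternate allele is present (allele count >= 1) in
#' every required carrier (the affected relatives) and confirmed absent
#' (allele count 0, not missing) in every excluded carrier (the unaffected
#' relatives being subtracted). Sharing requires allele presence, not
#' identical zygosity, matching a dominant, incompletely penetrant model.
#'
#' A site untyped in a required member is dropped with reason
#' `"untyped-required"` rather than passed; a site untyped in an excluded
#' member is retained (absence of evidence) with reason
#' `"untyped-excluded"` recorded when `details = TRUE`.
#'
#' @param genotypes Long genotype tibble as from [read_vcf_lite()].
#' @param required Character vector of subject ids that must carry.
#' @param excluded Character vector of subject ids that must not carry.
#' @param details If `TRUE`, return the per-variant decision table
#'   (columns `variant_id`, `pass`, `reason`) instead of only passing rows.
#' @return Tibble of passing variants (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`), or the decision table when `details = TRUE`.
#' @export
segregation_filter <- function(genotypes, required, excluded, details = FALSE) {
  if (length(intersect(required, excluded)) > 0) {
    abort("required and excluded carrier sets must be disjoint")
  }
  present <- unique(genotypes$subject_id)
  missing_ids <- setdiff(c(required, excluded), present)
  if (length(missing_ids) > 0) {
    abort(paste0("subject(s) not in genotype data: ",
                 paste(missing_ids, collapse = ", ")))
  }
  decisions <- genotypes %>%
    filter(.data$subject_id %in% c(required, excluded)) %>%
    group_by(.data$variant_id, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      req_untyped = any(is.na(.data$allele_count[.data$subject_id %in% required])),
      req_all_carry = all(.data$allele_count[.data$subject_id %in% required] >= 1),
      excl_untyped = any(is.na(.data$allele_count[.data$subject_id %in% excluded])),
      excl_carrier = any(.data$allele_count[.data$subject_id %in% excluded] >= 1,
                         na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      reason = case_when(
        .data$req_untyped ~ "untyped-required",
        !.data$req_all_carry ~ "required-not-shared",
        .data$excl_carrier ~ "excluded-carrier",
        .data$excl_untyped ~ "untyped-excluded",
        TRUE ~ "pass"
      ),
      pass = .data$reason %in% c("pass", "untyped-excluded")
    ) %>%
    arrange(.data$chrom, .data$pos)
  if (details) {
    return(select(decisions, "variant_id", "chrom", "pos", "ref", "alt",
                  "pass", "reason"))
  }
  decisions %>% filter(.data$pass) %>%
    select("variant_id", "chrom", "pos", "ref", "alt")
}

#' Map passing variants to candidate genes
#'
#' @param passing Tibble with `chrom` and `pos` columns (1-based).
#' @param gene_map Tibble with columns `gene`, `chrom`, `start`, `end`
#'   (1-based, fully closed intervals). Overlapping genes each receive the
#'   variant.
#' @return Tibble with a single sorted `gene` column of unique candidate
#'   symbols; the number of variants falling outside every interval is
#'   attached as attribute `n_unassigned` and reported via a message.
#' @export
reduce_to_genes <- function(passing, gene_map) {
  if (nrow(passing) == 0) {
    out <- tibble(gene = character())
    attr(out, "n_unassigned") <- 0L
    return(out)
  }
  hits <- passing %>%
    left_join(gene_map, by = "chrom", relationship = "many-to-many") %>%
    filter(!is.na(.data$gene), .data$pos >= .data$start, .data$pos <= .data$end)
  n_unassigned <- nrow(passing) -
    nrow(semi_join(passing, hits, by = c("chrom", "pos")))
  if (n_unassigned > 0) {
    inform(sprintf("%d passing variant(s) outside every gene interval dropped",
                   n_unassigned))
  }
  out <- hits %>% distinct(.data$gene) %>% arrange(.data$gene)
  attr(out, "n_unassigned") <- as.integer(n_unassigned)
  out
}

#' Prioritize candidate genes by cardiac expression
#'
#' @param candidates Tibble with a `gene` column (or a character vector).
#' @param heart_expression Tibble with columns `gene` and `tpm`.
#' @param min_tpm Minimum expression to retain a candidate (TPM).
#' @return Tibble with columns `gene`, `tpm`, `status`: genes at or above
#'   `min_tpm` first, ranked by descending expression (`status =
#'   "expressed"`), then genes absent from the expression table
#'   (`status = "unknown"`, never silently dropped).
#' @export
prioritize_by_expression <- function(candidates, heart_expression, min_tpm = 10) {
  genes <- if (is.data.frame(candidates)) candidates$gene else candidates
  joined <- tibble(gene = genes) %>%
    left_join(heart_expression, by = "gene")
  expressed <- joined %>%
    filter(!is.na(.data$tpm), .data$tpm >= min_tpm) %>%
    arrange(desc(.data$tpm)) %>%
    mutate(status = "expressed")
  unknown <- joined %>% filter(is.na(.data$tpm)) %>% mutate(status = "unknown")
  bind_rows(expressed, unknown)
}

#' Classify the inheritance of a carried variant from parental genotypes
#'
#' @param child_gt,mother_gt,father_gt Alternate-allele counts (0, 1, 2),
#'   `NA` when the parent is untyped. The child must carry the allele.
#' @return One of `de_novo`, `maternal`, `paternal`, `biparental`,
#'   `nonmaternal`, `nonpaternal`, `unknown` (vectorized).
#' @examples
#' classify_inheritance(1, mother_gt = 0, father_gt = 1)  # paternal
#' classify_inheritance(1, mother_gt = 0, father_gt = NA) # nonmaternal
#' @export
classify_inheritance <- function(child_gt, mother_gt, father_gt) {
  n <- max(length(child_gt), length(mother_gt), length(father_gt))
  child_gt <- rep_len(child_gt, n)
  mother_gt <- rep_len(mother_gt, n)
  father_gt <- rep_len(father_gt, n)
  if (any(is.na(child_gt)) || any(child_gt < 1)) {
    abort("child must carry the alternate allele")
  }
  m <- !is.na(mother_gt) & mother_gt >= 1   # mother carries
  f <- !is.na(father_gt) & father_gt >= 1   # father carries
  m0 <- !is.na(mother_gt) & mother_gt == 0  # mother typed ref
  f0 <- !is.na(father_gt) & father_gt == 0  # father typed ref
  case_when(
    m0 & f0 ~ "de_novo",
    m & f ~ "biparental",
    m ~ "maternal",
    f ~ "paternal",
    is.na(mother_gt) & f0 ~ "nonpaternal",
    is.na(father_gt) & m0 ~ "nonmaternal",
    TRUE ~ "unknown"
  )
}

#' Flag potential compound heterozygosity within one gene
#'
#' A subject carrying two or more distinct variant sites in the same gene is
#' flagged; the phase summary is `"trans-supported"` when the inheritance
#' calls place two alleles on different parental origins (one maternal-side,
#' one non-maternal/paternal-side), `"cis-likely"` when all calls share one
#' parental origin, else `"phase-unknown"`.
#'
#' @param subject_variants Tibble of one subject's variants in one gene with
#'   columns `variant_name` and `inherit`.
#' @return One-row tibble: `n_variants`, `flagged`, `phase`.
#' @export
detect_compound_het <- function(subject_variants) {
  if (nrow(subject_variants) == 0) abort("at least one variant required")
  n_sites <- n_distinct(subject_variants$variant_name)
  if (n_sites < 2) {
    return(tibble(n_variants = n_sites, flagged = FALSE, phase = NA_character_))
  }
  inh <- unique(subject_variants$inherit)
  maternal_side <- c("maternal", "nonpaternal")
  paternal_side <- c("paternal", "nonmaternal")
  has_m <- any(inh %in% maternal_side)
  has_p <- any(inh %in% paternal_side)
  phase <- if (has_m && has_p) "trans-supported"
           else if ((has_m || has_p) && all(inh %in% c(maternal_side, paternal_side)) &&
                    !(has_m && has_p)) "cis-likely"
           else "phase-unknown"
  tibble(n_variants = n_sites, flagged = TRUE, phase = phase)
}
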