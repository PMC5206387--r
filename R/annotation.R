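# Variant annotation: residue parsing, functional consequence, protein-domain
# assignment, and the rare / damaging classification used to select
# qualifying variants for the carrier burden test.

#' Default alpha-myosin heavy chain domain boundaries
#'
#' Residue ranges (1-based, closed) for the myosin head/motor, neck (lever
#' arm / light-chain binding) and coiled-coil tail regions. Any partition
#' consistent with the packaged variant table's labels is acceptable; these
#' defaults are head 1-778, neck 779-840, tail 841-1939.
#'
#' @return A tibble with columns `domain`, `start`, `end`.
#' @export
default_domain_boundaries <- function() {
  tibble(domain = c("head", "neck", "tail"),
         start = c(1L, 779L, 841L),
         end = c(778L, 840L, 1939L))
}

#' Default thresholds for the rare/damaging classification
#'
#' A missense variant is called damaging when PolyPhen-2 >= `pp2_min` or
#' SIFT <= `sift_max`; protein-truncating and in-frame indel variants are
#' always damaging. A variant is rare when flagged novel or when its
#' population frequency is at most `max_freq_pct` percent.
#'
#' @return A named list with `pp2_min`, `sift_max` and `max_freq_pct`.
#' @export
default_annotation_config <- function() {
  list(pp2_min = 0.5, sift_max = 0.05, max_freq_pct = 0.5)
}

#' Parse the residue number from a protein-notation variant name
#'
#' @param variant_name Names such as `"R443P"` (missense), `"K850-"`
#'   (deleted residue) or `"E1754X"` (premature stop).
#' @return Integer residue numbers.
#' @export
parse_residue_number <- function(variant_name) {
  m <- stringr::str_match(variant_name, "^[A-Z](\\d+)")
  res <- as.integer(m[, 2])
  if (any(is.na(res))) {
    abort(paste0("cannot parse residue number from '",
                 variant_name[which(is.na(res))[1]], "'"))
  }
  res
}

#' Classify functional consequence from name and alleles
#'
#' @param variant_name Protein-notation name; a trailing `"X"` marks a
#'   nonsense (premature stop) variant.
#' @param ref_allele,alt_allele Printed alleles; `alt_allele == "-"` marks a
#'   deletion, in-frame when the deleted length is divisible by 3.
#' @return Character vector in `{"missense", "nonsense", "inframe_deletion",
#'   "other"}`.
#' @export
classify_consequence <- function(variant_name, ref_allele, alt_allele) {
  case_when(
    stringr::str_ends(variant_name, "X") ~ "nonsense",
    alt_allele == "-" & nchar(ref_allele) %% 3 == 0 ~ "inframe_deletion",
    alt_allele == "-" ~ "other",
    stringr::str_detect(variant_name, "^[A-Z]\\d+[A-Z]$") ~ "missense",
    TRUE ~ "other"
  )
}

#' Assign a protein residue to a domain
#'
#' @param residue_number Positive integer residue position(s).
#' @param boundaries Domain boundary tibble as from
#'   [default_domain_boundaries()]; must partition `1..protein_length`.
#' @return Character vector of domain labels.
#' @examples
#' classify_domain(c(443, 795, 850))
#' @export
classify_domain <- function(residue_number, boundaries = default_domain_boundaries()) {
  stopifnot(all(residue_number >= 1))
  if (any(boundaries$start[-1] != boundaries$end[-nrow(boundaries)] + 1L) ||
      boundaries$start[1] != 1L) {
    abort("domain boundaries must form a contiguous partition starting at residue 1")
  }
  protein_length <- max(boundaries$end)
  if (any(residue_number > protein_length)) {
    abort(sprintf("residue %d beyond protein length %d",
                  residue_number[which(residue_number > protein_length)[1]],
                  protein_length))
  }
  idx <- findInterval(residue_number, boundaries$start)
  boundaries$domain[idx]
}

#' Annotate a variant table
#'
#' Adds `residue_number`, `consequence` and (when absent) a recomputed
#' `domain` column, then the `damaging` / `rare` calls under the supplied
#' thresholds.
#'
#' @param variants Variant tibble as from [read_variant_table()].
#' @param config Threshold list as from [default_annotation_config()].
#' @param boundaries Domain boundaries as from [default_domain_boundaries()].
#' @return The input tibble with columns `residue_number`, `consequence`,
#'   `domain_assigned`, `damaging`, `damaging_reason`, `rare` added.
#' @export
annotate_variants <- function(variants,
                              config = default_annotation_config(),
                              boundaries = default_domain_boundaries()) {
  out <- variants %>%
    mutate(
      residue_number = parse_residue_number(.data$variant_name),
      consequence = classify_consequence(.data$variant_name, .data$ref_allele,
                                         .data$alt_allele),
      domain_assigned = classify_domain(.data$residue_number, boundaries)
    )
  dmg <- is_damaging(out, config)
  out$damaging <- dmg$damaging
  out$damaging_reason <- dmg$reason
  out$rare <- is_rare(out, config$max_freq_pct)
  out
}

#' Call a variant damaging, with a reason code
#'
#' A variant is damaging when its consequence is protein-truncating
#' (nonsense) or an in-frame deletion, or — for missense — when
#' PolyPhen-2 >= `pp2_min` or SIFT <= `sift_max`. A missense variant with
#' both scores missing is indeterminate (`NA`), distinct from not damaging.
#'
#' @param variants Annotated tibble containing `consequence`, `pp2`, `sift`.
#' @param config Threshold list; see [default_annotation_config()].
#' @return A tibble with logical `damaging` (`NA` = indeterminate) and
#'   character `reason` (`"nonsense"`, `"inframe_deletion"`, `"pp2"`,
#'   `"sift"`, `"none"`, `"indeterminate"`).
#' @export
is_damaging <- function(variants, config = default_annotation_config()) {
  tibble(
    damaging = case_when(
      variants$consequence %in% c("nonsense", "inframe_deletion") ~ TRUE,
      !is.na(variants$pp2) & variants$pp2 >= config$pp2_min ~ TRUE,
      !is.na(variants$sift) & variants$sift <= config$sift_max ~ TRUE,
      is.na(variants$pp2) & is.na(variants$sift) ~ NA,
      TRUE ~ FALSE
    ),
    reason = case_when(
      variants$consequence == "nonsense" ~ "nonsense",
      variants$consequence == "inframe_deletion" ~ "inframe_deletion",
      !is.na(variants$pp2) & variants$pp2 >= config$pp2_min ~ "pp2",
      !is.na(variants$sift) & variants$sift <= config$sift_max ~ "sift",
      is.na(variants$pp2) & is.na(variants$sift) ~ "indeterminate",
      TRUE ~ "none"
    )
  )
}

#' Call a variant rare
#'
#' @param variants Tibble with `novel` and `pop_freq_pct` columns.
#' @param max_freq_pct Rarity threshold in percent; default 0.5.
#' @return Logical vector: novel-flagged variants are rare at any threshold,
#'   otherwise rare iff `pop_freq_pct <= max_freq_pct`.
#' @export
is_rare <- function(variants, max_freq_pct = 0.5) {
  stopifnot(max_freq_pct > 0)
  variants$novel | (!is.na(variants$pop_freq_pct) &
                      variants$pop_freq_pct <= max_freq_pct)
}

#' Summarise a variant set
#'
#' Counts records, distinct variants (keyed on `variant_name`), distinct
#' novel variants, distinct carrier subjects, distinct variants per domain,
#' and distinct variants per exon.
#'
#' @param variants Variant tibble (annotated or raw fixture layout).
#' @return A list with `n_records`, `n_distinct_variants`, `n_novel_distinct`,
#'   `n_subjects`, `per_domain` (tibble domain / n_distinct) and `per_exon`
#'   (tibble exon / n_distinct).
#' @examples
#' tab <- read_variant_table(cardioburden_example("table1_myh6_variants.tsv"))
#' summarize_variant_set(tab)$n_distinct_variants
#' @export
summarize_variant_set <- function(variants) {
  if (nrow(variants) == 0) abort("empty variant set")
  dom <- if ("domain_assigned" %in% names(variants)) variants$domain_assigned
         else variants$domain
  distinct_tab <- variants %>%
    mutate(.dom = dom) %>%
    distinct(.data$variant_name, .keep_all = TRUE)
  list(
    n_records = nrow(variants),
    n_distinct_variants = n_distinct(variants$variant_name),
    n_novel_distinct = sum(distinct_tab$novel),
    n_subjects = n_distinct(variants$subject_id),
    per_domain = distinct_tab %>% count(domain = .data$.dom, name = "n_distinct"),
    per_exon = distinct_tab %>% count(exon = .data$exon, name = "n_distinct")
  )
}
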