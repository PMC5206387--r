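# Readers and writers for every tabular input the pipeline touches:
# the packaged variant table, VCF-like genotypes, PED pedigrees, and the
# survival / expression / densitometry tables.

INHERIT_CODES <- c(
  "de novo" = "de_novo", "Mat" = "maternal", "NonMat" = "nonmaternal",
  "Pat" = "paternal", "NonPat" = "nonpaternal", "NA" = "unknown"
)

#' Read an annotated variant table
#'
#' Reads a tab-separated variant table in the layout of the packaged
#' alpha-myosin heavy chain (MYH6) fixture: one row per observed variant with
#' genomic coordinate (GRCh37, 1-based), ref/alt alleles (`"-"` marks a
#' deletion), protein domain, exon, protein-notation variant name (e.g.
#' `"R443P"`), carrier subject id, PolyPhen-2 and SIFT scores, an inheritance
#' code and a population frequency. The frequency column holds either a
#' percentage such as `"0.22%"` or the literal `"novel"`; novel is modelled as
#' a logical flag with a missing frequency (unobserved, not proven absent).
#'
#' @param path Path to a TSV file with the fixture header.
#' @return A tibble with one row per variant record; `pop_freq_pct` is the
#'   frequency in percent (`NA` when novel), `novel` the novelty flag, and
#'   `inherit` one of `de_novo`, `maternal`, `nonmaternal`, `paternal`,
#'   `nonpaternal`, `unknown`.
#' @examples
#' tab <- read_variant_table(cardioburden_example("table1_myh6_variants.tsv"))
#' nrow(tab)
#' @export
read_variant_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character())
  required <- c("coordinate_start", "ref_allele", "alt_allele", "domain", "exon",
                "variant_name", "subject_id", "pp2", "sift", "inherit", "pop_freq")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("variant table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(tibble(
      coordinate_start = integer(), ref_allele = character(),
      alt_allele = character(), domain = character(), exon = integer(),
      variant_name = character(), subject_id = character(),
      pp2 = double(), sift = double(), inherit = character(),
      pop_freq_pct = double(), novel = logical()
    ))
  }
  bad_inherit <- setdiff(unique(raw$inherit), names(INHERIT_CODES))
  if (length(bad_inherit) > 0) {
    abort(paste0("unknown inheritance code(s): ",
                 paste(bad_inherit, collapse = ", ")))
  }
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(if_else(x == "NA", NA_character_, x)))
    bad <- which(!is.na(x) & x != "NA" & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("malformed value in column '%s' at data line %d: '%s'",
                    col, bad[1], x[bad[1]]))
    }
    out
  }
  coord <- parse_num(raw$coordinate_start, "coordinate_start")
  exon <- parse_num(raw$exon, "exon")
  bad_coord <- which(is.na(coord) | coord <= 0)
  if (length(bad_coord) > 0) {
    abort(sprintf("non-positive or missing coordinate at data line %d", bad_coord[1]))
  }
  bad_exon <- which(is.na(exon) | exon < 1 | exon > 39)
  if (length(bad_exon) > 0) {
    abort(sprintf("exon outside 1..39 at data line %d", bad_exon[1]))
  }
  novel <- raw$pop_freq == "novel"
  freq_chr <- if_else(novel | raw$pop_freq == "NA", NA_character_,
                      stringr::str_remove(raw$pop_freq, "%$"))
  tibble(
    coordinate_start = as.integer(coord),
    ref_allele = raw$ref_allele,
    alt_allele = raw$alt_allele,
    domain = raw$domain,
    exon = as.integer(exon),
    variant_name = raw$variant_name,
    subject_id = raw$subject_id,
    pp2 = parse_num(raw$pp2, "pp2"),
    sift = parse_num(raw$sift, "sift"),
    inherit = unname(INHERIT_CODES[raw$inherit]),
    pop_freq_pct = parse_num(freq_chr, "pop_freq"),
    novel = novel
  )
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
cardioburden_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "cardioburden")))
  }
  path <- system.file("extdata", file, package = "cardioburden")
  if (!nzchar(path)) abort(paste0("no packaged example file '", file, "'"))
  path
}

#' Read a minimal VCF into a long genotype table
#'
#' Parses a VCF v4.x text file, keeping only the GT field, into a tidy long
#' table of per-subject alternate-allele counts. Multiallelic records are
#' rejected; split them upstream. Coordinates stay 1-based as in the VCF.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A tibble with columns `variant_id` (`chrom:pos:ref:alt`), `chrom`,
#'   `pos`, `ref`, `alt`, `subject_id` and `allele_count` (0, 1, 2 or `NA`
#'   for `./.`).
#' @export
read_vcf_lite <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  header_i <- which(stringr::str_starts(lines, "#CHROM"))
  if (length(header_i) != 1) abort("VCF must contain exactly one #CHROM header line")
  header <- stringr::str_split_1(lines[header_i], "\t")
  if (length(header) < 10) abort("VCF has no sample columns")
  samples <- header[10:length(header)]
  body <- lines[-seq_len(header_i)]
  body <- body[!stringr::str_starts(body, "#")]
  if (length(body) == 0) {
    return(tibble(variant_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), subject_id = character(),
                  allele_count = integer()))
  }
  fields <- stringr::str_split(body, "\t")
  n_expected <- length(header)
  purrr::iwalk(fields, function(f, i) {
    if (length(f) != n_expected) {
      abort(sprintf("VCF record %d has %d fields; header implies %d samples",
                    i, length(f), length(samples)))
    }
  })
  rows <- purrr::imap(fields, function(f, i) {
    alt <- f[5]
    if (stringr::str_detect(alt, ",")) {
      abort(sprintf("multiallelic record at line %d (ALT '%s'); split it first", i, alt))
    }
    fmt <- stringr::str_split_1(f[9], ":")
    gt_idx <- which(fmt == "GT")
    if (length(gt_idx) != 1) abort(sprintf("record %d lacks a GT field", i))
    gts <- purrr::map_chr(f[10:n_expected], ~ stringr::str_split_1(.x, ":")[gt_idx])
    alleles <- stringr::str_split(gts, "[/|]")
    ac <- purrr::map_int(alleles, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(a != "0")
    })
    tibble(chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = alt,
           subject_id = samples, allele_count = ac)
  })
  out <- bind_rows(rows)
  out$variant_id <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
  select(out, "variant_id", "chrom", "pos", "ref", "alt", "subject_id", "allele_count")
}

#' Write a long genotype table as a minimal VCF
#'
#' Inverse of [read_vcf_lite()]: allele counts 0/1/2 become genotypes
#' `0/0`, `0/1`, `1/1`; `NA` becomes `./.`.
#'
#' @param genotypes Long genotype tibble as returned by [read_vcf_lite()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf_lite <- function(genotypes, path) {
  samples <- unique(genotypes$subject_id)
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  wide <- genotypes %>%
    mutate(gt = if_else(is.na(.data$allele_count), "./.",
                        gt_of[as.character(.data$allele_count)])) %>%
    select("variant_id", "chrom", "pos", "ref", "alt", "subject_id", "gt") %>%
    tidyr::pivot_wider(names_from = "subject_id", values_from = "gt") %>%
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- purrr::pmap_chr(wide, function(variant_id, chrom, pos, ref, alt, ...) {
    paste(c(chrom, pos, variant_id, ref, alt, ".", "PASS", ".", "GT",
            c(...)[samples]), collapse = "\t")
  })
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a 6-column PED pedigree file
#'
#' @param path Path to a whitespace-delimited PED file with columns family,
#'   individual, father, mother, sex (1 = male, 2 = female), phenotype
#'   (2 = affected, 1 = unaffected, 0/-9 = unknown). `0` marks a missing
#'   parent.
#' @return A tibble of class `pedigree` with columns `family_id`, `id`,
#'   `father_id`, `mother_id` (`NA` when missing), `sex`, `affected`
#'   (`TRUE`/`FALSE`/`NA`).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_table(path, col_names = c("family_id", "id", "father_id",
                                               "mother_id", "sex", "phenotype"),
                           col_types = "cccccc")
  as_pedigree(mutate(ped,
    father_id = if_else(.data$father_id == "0", NA_character_, .data$father_id),
    mother_id = if_else(.data$mother_id == "0", NA_character_, .data$mother_id),
    sex = as.integer(.data$sex),
    affected = case_when(.data$phenotype == "2" ~ TRUE,
                         .data$phenotype == "1" ~ FALSE,
                         TRUE ~ NA),
    phenotype = NULL
  ))
}

#' Validate and class a pedigree tibble
#'
#' Checks that parent links resolve to members of the pedigree and that
#' parentage is acyclic (no individual is its own ancestor).
#'
#' @param members Tibble with columns `family_id`, `id`, `father_id`,
#'   `mother_id`, `sex`, `affected`.
#' @return The validated tibble with class `pedigree`.
#' @export
as_pedigree <- function(members) {
  members <- as_tibble(members)
  if (anyDuplicated(members$id)) abort("duplicate individual id in pedigree")
  parents <- c(members$father_id, members$mother_id)
  unknown <- setdiff(parents[!is.na(parents)], members$id)
  if (length(unknown) > 0) {
    abort(paste0("parent id(s) not present in pedigree: ",
                 paste(unknown, collapse = ", ")))
  }
  # depth-first ancestor walk; revisiting an individual on the current path
  # means a parentage cycle (e.g. someone listed as their own father)
  parent_of <- stats::setNames(
    purrr::map2(members$father_id, members$mother_id, ~ c(.x, .y)[!is.na(c(.x, .y))]),
    members$id
  )
  visit <- function(id, path) {
    if (id %in% path) abort(paste0("cyclic parentage involving '", id, "'"))
    for (p in parent_of[[id]]) visit(p, c(path, id))
  }
  purrr::walk(members$id, visit, path = character())
  class(members) <- c("pedigree", class(members))
  members
}

#' Write a pedigree as a 6-column PED file
#'
#' Inverse of [read_pedigree()].
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  lines <- sprintf("%s %s %s %s %d %s",
                   pedigree$family_id, pedigree$id,
                   if_else(is.na(pedigree$father_id), "0", pedigree$father_id),
                   if_else(is.na(pedigree$mother_id), "0", pedigree$mother_id),
                   pedigree$sex,
                   case_when(is.na(pedigree$affected) ~ "0",
                             pedigree$affected ~ "2",
                             TRUE ~ "1"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a transplant-free survival table
#'
#' @param path TSV with columns `subject`, `group`, `time_years`, `event`
#'   and optionally `age_years`. `event` is 1 for death or transplant,
#'   0 for censored.
#' @return A tibble with columns `subject_id`, `group`, `time`, `event`
#'   (logical) and `age_years` if present.
#' @export
read_survival_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("subject", "group", "time_years", "event")
  if (!all(need %in% names(raw))) {
    abort(paste0("survival table needs columns ", paste(need, collapse = ", ")))
  }
  num <- function(col) {
    out <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(out) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in column '%s', data row %d", col, bad[1]))
    }
    out
  }
  time <- num("time_years")
  if (any(time < 0, na.rm = TRUE)) abort("negative follow-up time")
  out <- tibble(subject_id = raw$subject, group = raw$group,
                time = time, event = num("event") == 1)
  if ("age_years" %in% names(raw)) out$age_years <- num("age_years")
  out
}

#' Read a gene-by-sample expression matrix
#'
#' @param path TSV whose first column (`gene`) holds gene identifiers and
#'   remaining columns hold per-sample values (counts or TPM).
#' @return A tibble with a `gene` column followed by one numeric column per
#'   sample.
#' @export
read_expression_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_character()))
  if (!"gene" %in% names(raw)) abort("expression matrix needs a 'gene' column")
  if (anyDuplicated(raw$gene)) {
    abort(paste0("duplicate gene id: ", raw$gene[duplicated(raw$gene)][1]))
  }
  for (col in setdiff(names(raw), "gene")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric cell in column '%s', data row %d", col, bad[1]))
    }
    raw[[col]] <- vals
  }
  raw
}

#' Read a Western blot densitometry table
#'
#' @param path TSV with columns `pair`, `genotype` (MUT/WT), `band`
#'   (target-band density), `gapdh` (loading-control density) and optionally
#'   `replicate`.
#' @return A tibble with columns `pair_id`, `genotype`, `band_density`,
#'   `loading_density`, `replicate`.
#' @export
read_densitometry_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("pair", "genotype", "band", "gapdh")
  if (!all(need %in% names(raw))) {
    abort(paste0("densitometry table needs columns ", paste(need, collapse = ", ")))
  }
  num <- function(col) {
    out <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(out) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in column '%s', data row %d", col, bad[1]))
    }
    out
  }
  band <- num("band"); gapdh <- num("gapdh")
  if (any(band <= 0) || any(gapdh <= 0)) abort("band densities must be positive")
  tibble(
    pair_id = raw$pair,
    genotype = raw$genotype,
    band_density = band,
    loading_density = gapdh,
    replicate = if ("replicate" %in% names(raw)) as.integer(raw$replicate)
                else as.integer(stats::ave(band, raw$pair, raw$genotype,
                                           FUN = seq_along))
  )
}

#' Write a densitometry table
#'
#' Inverse of [read_densitometry_table()].
#' @param records Densitometry tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_densitometry_table <- function(records, path) {
  out <- tibble(pair = records$pair_id, genotype = records$genotype,
                band = records$band_density, gapdh = records$loading_density,
                replicate = records$replicate)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Convert a printed-style indel to left-anchored VCF style
#'
#' The packaged variant table stores the in-frame deletion as
#' `ref = "CTT", alt = "-"` exactly as printed. VCF requires an anchor base:
#' the deletion of `CTT` at position p becomes position p - 1,
#' `ref = anchor + "CTT"`, `alt = anchor`.
#'
#' @param pos 1-based start of the printed allele.
#' @param ref,alt Printed ref/alt, `alt = "-"` for a deletion.
#' @param anchor The reference base immediately 5' of `pos`; unknown without
#'   a reference sequence, so defaults to `"N"`.
#' @return A one-row tibble with VCF-style `pos`, `ref`, `alt`.
#' @export
to_vcf_style <- function(pos, ref, alt, anchor = "N") {
  if (alt != "-") return(tibble(pos = pos, ref = ref, alt = alt))
  tibble(pos = pos - 1L, ref = paste0(anchor, ref), alt = anchor)
}
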