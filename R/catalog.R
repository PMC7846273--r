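#' Load population variant catalogs from VCF
#'
#' Reads one or more catalog VCFs (e.g. extracts of 1000 Genomes, ESP,
#' ExAC, gnomAD) into a tidy SNV table. Multi-allelic records are
#' decomposed to one row per alternate allele; non-SNV alleles are skipped
#' with a message; variants present in several files are deduplicated on
#' `(chrom, pos, ref, alt)` with their sources merged.
#'
#' @param paths Character vector of VCF paths.
#' @param sources Labels for each file (default: file name without
#'   extension).
#' @return A tibble `chrom`, `pos`, `ref`, `alt`, `source`, `af` (allele
#'   frequency parsed from an `AF` INFO field when present, else `NA`).
#' @export
load_catalog <- function(paths, sources = NULL) {
  if (is.null(sources)) sources <- sub("\\.vcf(\\.gz)?$", "", basename(paths))
  stopifnot(length(sources) == length(paths))
  per_file <- purrr::map2(paths, sources, .load_one_catalog)
  bind_rows(per_file) |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(source = paste(unique(.data$source), collapse = ","),
              af = if (all(is.na(.data$af))) NA_real_ else
                max(.data$af, na.rm = TRUE),
              .groups = "drop")
}

.load_one_catalog <- function(path, source) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), source = character(0), af = numeric(0)))
  }
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  af_list <- purrr::map2(fix$INFO, n_alt, .parse_info_af)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  out <- tibble(chrom = fix$CHROM[idx], pos = as.integer(fix$POS[idx]),
                ref = toupper(fix$REF[idx]),
                alt = toupper(unlist(alt_list)),
                source = source, af = unlist(af_list))
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    message("skipped ", sum(!snv), " non-SNV allele(s) in ", basename(path))
  }
  out[snv, , drop = FALSE]
}

.parse_info_af <- function(info, n_alt) {
  if (is.na(info)) return(rep(NA_real_, n_alt))
  m <- regmatches(info, regexpr("(?:^|;)AF=([^;]+)", info))
  if (length(m) == 0L) return(rep(NA_real_, n_alt))
  vals <- suppressWarnings(as.numeric(
    strsplit(sub("^;?AF=", "", m), ",", fixed = TRUE)[[1]]))
  length(vals) <- n_alt
  vals
}

#' Match reported tumor mutations against a population-variant catalog
#'
#' For each reported mutation, determines whether an identical allele
#' (`exact_allele`), a different allele at the same position
#' (`position_only`), or nothing (`none`) is present in standing genetic
#' variation. When a reference genome is supplied, mutations whose reported
#' alternate allele equals the reference base are additionally detected:
#' these are flagged `in_reference` (and take that status unless an exact
#' catalog match exists), since a "mutation" identical to the reference
#' assembly cannot be a genuine somatic change and would otherwise inflate
#' the unmatched count.
#'
#' @param mutations Tibble of reported mutations: `patient_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `context` (`"intronic"`/`"exonic"`), `label`
#'   (free-form, e.g. an IVS-style name; carried through unparsed).
#' @param catalog Catalog tibble from [load_catalog()] (or
#'   [sim_variant_catalog()]).
#' @param reference Optional genome for the `in_reference` check.
#' @param min_af Optional minimum catalog allele frequency for a catalog
#'   entry to count as a match (default: presence suffices).
#' @return A tibble of class `overlap_report`: the input columns plus
#'   `status` (`exact_allele`, `in_reference`, `position_only`, `none`),
#'   `in_reference` (logical), and `matched_sources`. Summary fractions via
#'   [glance()].
#' @export
match_mutations <- function(mutations, catalog, reference = NULL,
                            min_af = NULL) {
  stopifnot(all(mutations$ref != mutations$alt),
            all(nchar(mutations$ref) == 1L), all(nchar(mutations$alt) == 1L))
  if (!is.null(min_af)) {
    catalog <- catalog |> filter(!is.na(.data$af), .data$af >= min_af)
  }
  genome <- if (!is.null(reference)) .load_genome(reference) else NULL
  exact <- catalog |>
    mutate(exact = TRUE) |>
    select("chrom", "pos", "ref", "alt", "exact",
           matched_sources = "source")
  pos_only <- catalog |> distinct(.data$chrom, .data$pos) |>
    mutate(at_pos = TRUE)
  in_ref <- if (is.null(genome)) rep(FALSE, nrow(mutations)) else {
    vapply(seq_len(nrow(mutations)), function(i) {
      ch <- mutations$chrom[i]
      ch %in% names(genome) &&
        toupper(substring(genome[[ch]], mutations$pos[i],
                          mutations$pos[i])) == mutations$alt[i]
    }, logical(1))
  }
  out <- mutations |>
    left_join(exact, by = c("chrom", "pos", "ref", "alt")) |>
    left_join(pos_only, by = c("chrom", "pos")) |>
    mutate(
      in_reference = in_ref,
      status = dplyr::case_when(
        !is.na(.data$exact) ~ "exact_allele",
        .data$in_reference ~ "in_reference",
        !is.na(.data$at_pos) ~ "position_only",
        TRUE ~ "none"
      )
    ) |>
    select(-"exact", -"at_pos")
  class(out) <- c("overlap_report", class(out))
  out
}

#' @rdname match_mutations
#' @param x An `overlap_report` tibble.
#' @param ... Unused.
#' @export
glance.overlap_report <- function(x, ...) {
  n <- nrow(x)
  n_exact <- sum(x$status == "exact_allele")
  tibble(
    n_mutations = n,
    n_exact = n_exact,
    fraction_exact = n_exact / n,
    fraction_position_or_exact =
      sum(x$status %in% c("exact_allele", "position_only")) / n,
    n_in_reference = sum(x$in_reference)
  )
}

#' @rdname match_mutations
#' @export
tidy.overlap_report <- function(x, ...) {
  as_tibble(x) |>
    select("patient_id", "chrom", "pos", "ref", "alt", "context", "label",
           "status", "in_reference", "matched_sources")
}

#' Per-patient overlap with standing variation
#'
#' Flags each patient according to whether at least one of their reported
#' mutations matches a catalog allele exactly, and reports the cohort
#' fraction of flagged patients.
#'
#' @param report `overlap_report` from [match_mutations()].
#' @return A tibble `patient_id`, `n_mutations`, `n_exact`, `matched`, with
#'   the cohort fraction in `attr(x, "cohort_fraction")`.
#' @export
per_patient_overlap <- function(report) {
  out <- as_tibble(report) |>
    group_by(.data$patient_id) |>
    summarise(n_mutations = n(),
              n_exact = sum(.data$status == "exact_allele"),
              matched = any(.data$status == "exact_allele"),
              .groups = "drop")
  zero <- out$patient_id[out$n_mutations == 0L]
  if (length(zero) > 0) {
    warning("excluding patient(s) with zero mutations: ",
            paste(zero, collapse = ", "))
    out <- out |> filter(.data$n_mutations > 0L)
  }
  attr(out, "cohort_fraction") <- mean(out$matched)
  out
}

#' Overlap fractions stratified by genic context
#'
#' Reports match fractions separately for intronic and exonic mutations,
#' the contrast showing that catalog overlap concentrates in one context.
#'
#' @param report `overlap_report` from [match_mutations()].
#' @return A tibble `context`, `n`, `n_exact`, `fraction_exact`,
#'   `fraction_position_or_exact`.
#' @export
stratify_by_context <- function(report) {
  if (nrow(report) == 0L) {
    return(tibble(context = character(0), n = integer(0),
                  n_exact = integer(0), fraction_exact = numeric(0),
                  fraction_position_or_exact = numeric(0)))
  }
  if (any(is.na(report$context)) ||
      !all(report$context %in% c("intronic", "exonic"))) {
    stop("every mutation must be labeled 'intronic' or 'exonic'")
  }
  as_tibble(report) |>
    group_by(.data$context) |>
    summarise(
      n = n(),
      n_exact = sum(.data$status == "exact_allele"),
      fraction_exact = sum(.data$status == "exact_allele") / n(),
      fraction_position_or_exact =
        sum(.data$status %in% c("exact_allele", "position_only")) / n(),
      .groups = "drop"
    )
}

#' Write an overlap summary as JSON
#'
#' Serializes the mutation-level, per-patient, and per-context overlap
#' fractions to a JSON file.
#'
#' @param report `overlap_report` from [match_mutations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_summary <- function(report, path) {
  pp <- per_patient_overlap(report)
  summary <- list(
    overall = as.list(glance(report)),
    per_patient = list(
      n_patients = nrow(pp),
      n_matched = sum(pp$matched),
      fraction = attr(pp, "cohort_fraction")
    ),
    per_context = stratify_by_context(report)
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
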