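#' Shipped target loci for the UPF1/KRAS reanalysis
#'
#' The two gene loci over which the matched tumor-normal reanalysis is run
#' in the motivating study: *UPF1* (chr19:18940305-18979266) and *KRAS*
#' (chr12:25356390-25405419), hg19/GRCh37 assembly, 1-based closed
#' coordinates. Use these when running the caller on real hg19 alignments;
#' the synthetic generators build their own toy loci.
#'
#' @return A tibble `name`, `chrom`, `start`, `end`.
#' @export
default_target_loci <- function() {
  tibble(
    name = c("UPF1", "KRAS"),
    chrom = c("chr19", "chr12"),
    start = c(18940305L, 25356390L),
    end = c(18979266L, 25405419L)
  )
}

#' Per-site base counts over target loci
#'
#' Builds a per-position pileup of A/C/G/T counts from aligned reads.
#' Deletions and alignment gaps spanning a position contribute neither depth
#' nor alternate support there; reads flagged as duplicates are excluded
#' when the input carries duplicate marks, and unmapped reads are skipped.
#' No base-quality filter is applied by default, reproducing literal
#' count-threshold calling; set `min_baseq` to filter.
#'
#' @param alignments SAM or BAM path (coordinate-sortable; conversion and
#'   indexing happen in a temporary directory).
#' @param loci Tibble of target loci (`name`, `chrom`, `start`, `end`),
#'   1-based closed; see [default_target_loci()].
#' @param reference Reference genome covering the loci (FASTA path,
#'   `DNAStringSet`, or named character vector).
#' @param min_baseq Minimum base quality (default 0 = no filter).
#' @return A tibble with one row per locus position: `locus`, `chrom`,
#'   `pos`, `ref`, counts `A`, `C`, `G`, `T`, and `depth` (sum of the four).
#'   Positions with no coverage are present with zero counts.
#' @export
pileup_region <- function(alignments, loci, reference, min_baseq = 0L) {
  stopifnot(all(loci$start < loci$end))
  genome <- .load_genome(reference)
  for (i in seq_len(nrow(loci))) {
    ch <- loci$chrom[i]
    if (!ch %in% names(genome) || nchar(genome[[ch]]) < loci$end[i]) {
      stop("reference does not cover locus ", loci$name[i],
           " (", ch, ":", loci$start[i], "-", loci$end[i], ")")
    }
  }
  bam <- .as_indexed_bam(alignments)
  which <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start, loci$end))
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(
      which = which,
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isDuplicate = FALSE)),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1000000L, min_base_quality = as.integer(min_baseq),
      min_mapq = 0L, min_nucleotide_depth = 1L,
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      ignore_query_Ns = TRUE,
      include_deletions = FALSE, include_insertions = FALSE))
  counts <- as_tibble(p) |>
    mutate(chrom = as.character(.data$seqnames),
           nucleotide = as.character(.data$nucleotide)) |>
    filter(.data$nucleotide %in% c("A", "C", "G", "T")) |>
    select("chrom", "pos", "nucleotide", "count") |>
    distinct(.data$chrom, .data$pos, .data$nucleotide, .keep_all = TRUE)
  grid <- purrr::map(seq_len(nrow(loci)), function(i) {
    pos <- seq.int(loci$start[i], loci$end[i])
    tibble(locus = loci$name[i], chrom = loci$chrom[i], pos = pos,
           ref = toupper(unlist(strsplit(
             substring(genome[[loci$chrom[i]]], loci$start[i], loci$end[i]),
             "", fixed = TRUE))))
  }) |> bind_rows()
  wide <- counts |>
    tidyr::pivot_wider(names_from = "nucleotide", values_from = "count",
                       values_fill = 0L)
  for (b in c("A", "C", "G", "T")) if (!b %in% names(wide)) wide[[b]] <- 0L
  grid |>
    left_join(wide |> select("chrom", "pos", "A", "C", "G", "T"),
              by = c("chrom", "pos")) |>
    mutate(across(c("A", "C", "G", "T"), ~ dplyr::coalesce(.x, 0L)),
           depth = .data$A + .data$C + .data$G + .data$T)
}

#' Threshold-based variant calling from a pileup
#'
#' An alternate allele is called at a site when the site's depth is at least
#' `min_depth` and the allele is supported by at least `min_alt_reads`
#' reads -- the deliberately permissive criteria used to maximize
#' sensitivity in the matched tumor-normal reanalysis (defaults: depth >= 9,
#' >= 2 supporting reads). Multiple alternate alleles at one site are
#' evaluated independently. SNVs only.
#'
#' @param pileup Output of [pileup_region()].
#' @param min_depth,min_alt_reads Calling thresholds; both must be >= 1.
#' @return A tibble of calls: `locus`, `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, `vaf` (`alt_count/depth`).
#' @examples
#' p <- tibble::tibble(locus = "L", chrom = "c", pos = 1L, ref = "G",
#'                     A = 2L, C = 0L, G = 7L, T = 0L, depth = 9L)
#' call_variants(p)  # called: depth 9, alt 2
#' @export
call_variants <- function(pileup, min_depth = 9L, min_alt_reads = 2L) {
  stopifnot(min_depth >= 1L, min_alt_reads >= 1L)
  long <- pileup |>
    tidyr::pivot_longer(cols = c("A", "C", "G", "T"),
                        names_to = "alt", values_to = "alt_count") |>
    filter(.data$alt != .data$ref,
           .data$depth >= min_depth,
           .data$alt_count >= min_alt_reads) |>
    mutate(vaf = .data$alt_count / .data$depth)
  long |> select(dplyr::any_of("locus"), "chrom", "pos", "ref", "alt",
                 "depth", "alt_count", "vaf")
}

#' Matched-normal subtraction of tumor variant calls
#'
#' A tumor call is *somatic* when the same position/allele is not called in
#' the patient-matched normal sample under identical thresholds. Normal
#' sites below the depth threshold cannot be called by construction; such
#' tumor calls remain somatic under the literal rule but are flagged
#' `low_coverage` so they can be reviewed.
#'
#' @param tumor_calls Calls from [call_variants()] on the tumor pileup.
#' @param normal_pileup [pileup_region()] output for the matched normal;
#'   required (a missing normal is an error, not an implicit pass).
#' @param min_depth,min_alt_reads Thresholds, applied identically to the
#'   normal.
#' @param patient_id Optional label carried into the output.
#' @return `tumor_calls` with `normal_status`
#'   (`absent`/`present`/`low_coverage`), `is_somatic`
#'   (`normal_status != "present"`), and `patient_id` columns.
#' @export
subtract_matched_normal <- function(tumor_calls, normal_pileup,
                                    min_depth = 9L, min_alt_reads = 2L,
                                    patient_id = NA_character_) {
  if (missing(normal_pileup) || is.null(normal_pileup)) {
    stop("matched normal pileup is required")
  }
  normal_calls <- call_variants(normal_pileup, min_depth, min_alt_reads) |>
    mutate(in_normal = TRUE) |>
    select("chrom", "pos", "alt", "in_normal")
  normal_depth <- normal_pileup |> select("chrom", "pos", normal_depth = "depth")
  tumor_calls |>
    left_join(normal_calls, by = c("chrom", "pos", "alt")) |>
    left_join(normal_depth, by = c("chrom", "pos")) |>
    mutate(
      normal_status = dplyr::case_when(
        !is.na(.data$in_normal) ~ "present",
        is.na(.data$normal_depth) | .data$normal_depth < min_depth ~
          "low_coverage",
        TRUE ~ "absent"
      ),
      is_somatic = .data$normal_status != "present",
      patient_id = patient_id
    ) |>
    select(-"in_normal", -"normal_depth")
}

#' Positive-control sensitivity calibration
#'
#' Verifies that the calling thresholds detect a known hotspot driver
#' mutation (e.g. *KRAS* G12/G13) in every tumor sample of a cohort -- the
#' criterion used to choose the permissive thresholds in the first place.
#'
#' @param calls Somatic calls across samples, with a `patient_id` column.
#' @param control_sites Tibble of control positions (`chrom`, `pos`).
#' @param samples Character vector of all tumor sample/patient ids in the
#'   cohort (samples without any call must still be assessed). Must be
#'   nonempty.
#' @param loci Optional loci tibble; when given, every control site must lie
#'   within a locus (otherwise an error -- the control cannot be observed).
#' @return A tibble of class `nmd_calibration`: `patient_id`,
#'   `control_detected`; the cohort-level verdict is in
#'   `attr(x, "overall_pass")` and via [glance()].
#' @export
calibrate_sensitivity <- function(calls, control_sites, samples,
                                  loci = NULL) {
  if (length(samples) == 0L) stop("empty sample set")
  if (!is.null(loci)) {
    inside <- vapply(seq_len(nrow(control_sites)), function(i) {
      any(loci$chrom == control_sites$chrom[i] &
            loci$start <= control_sites$pos[i] &
            loci$end >= control_sites$pos[i])
    }, logical(1))
    if (!all(inside)) {
      stop("control site(s) outside all configured loci: ",
           paste0(control_sites$chrom[!inside], ":",
                  control_sites$pos[!inside], collapse = ", "))
    }
  }
  hits <- calls |>
    filter(.data$is_somatic) |>
    inner_join(control_sites, by = c("chrom", "pos")) |>
    distinct(.data$patient_id) |>
    pull("patient_id")
  out <- tibble(patient_id = samples,
                control_detected = samples %in% hits)
  attr(out, "overall_pass") <- all(out$control_detected)
  class(out) <- c("nmd_calibration", class(out))
  out
}

#' @rdname calibrate_sensitivity
#' @param x An `nmd_calibration` tibble.
#' @param ... Unused.
#' @export
glance.nmd_calibration <- function(x, ...) {
  tibble(n_samples = nrow(x),
         n_detected = sum(x$control_detected),
         overall_pass = all(x$control_detected),
         failed_samples = paste(x$patient_id[!x$control_detected],
                                collapse = ","))
}

#' Per-gene median variant allele frequency
#'
#' Summarizes somatic calls by gene/locus as the median VAF (midpoint for
#' even counts, the usual [stats::median()] convention).
#'
#' @param calls Somatic calls (rows with `is_somatic == FALSE` are dropped
#'   if the column is present).
#' @param gene_col Column naming the gene grouping (default `"locus"`).
#' @return A tibble `gene`, `n_calls`, `median_vaf`.
#' @export
summarize_af <- function(calls, gene_col = "locus") {
  if ("is_somatic" %in% names(calls)) {
    calls <- calls |> filter(.data$is_somatic)
  }
  if (nrow(calls) == 0L) {
    warning("no somatic calls to summarize; empty groups omitted")
    return(tibble(gene = character(0), n_calls = integer(0),
                  median_vaf = numeric(0)))
  }
  calls |>
    group_by(gene = .data[[gene_col]]) |>
    summarise(n_calls = n(), median_vaf = median(.data$vaf),
              .groups = "drop")
}

#' Write somatic calls as a VCF 4.2 file
#'
#' Emits one record per called alternate allele, with INFO fields `DP`
#' (site depth), `ALTC` (alternate-supporting reads), `VAF`, and
#' `NORMAL_STATUS` (matched-normal status when available).
#'
#' @param calls Call tibble from [subtract_matched_normal()] (or
#'   [call_variants()]).
#' @param path Output path.
#' @param sample Sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(calls, path, sample = "TUMOR") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=nmdmutscan",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at site\">",
    "##INFO=<ID=ALTC,Number=1,Type=Integer,Description=\"Reads supporting alternate allele\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=NORMAL_STATUS,Number=1,Type=String,Description=\"Matched normal status: absent, present, low_coverage\">",
    paste0("##nmdmutscanSample=", sample),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  ns <- if ("normal_status" %in% names(calls)) calls$normal_status
        else rep("absent", nrow(calls))
  body <- if (nrow(calls) == 0L) character(0) else paste(
    calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
    sprintf("DP=%d;ALTC=%d;VAF=%.6g;NORMAL_STATUS=%s",
            calls$depth, calls$alt_count, calls$vaf, ns),
    sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
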