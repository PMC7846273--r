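#' Read transcript models from a GTF file
#'
#' Parses a GTF annotation into a tidy exon table: one row per exon, with
#' transcript-level columns (gene, chromosome, strand, coding region)
#' repeated. The coding region, when annotated, is stored as the genomic
#' extent of the CDS *including* the termination codon: GTF dialects that
#' emit separate `stop_codon` features (Ensembl-style) have those merged
#' into the CDS extent.
#'
#' @param path Path to a GTF file with `exon` features; `CDS` and
#'   `stop_codon` features are optional.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based, closed), `cds_start`, `cds_end`
#'   (`NA` when the transcript has no annotated CDS). Exons are sorted in
#'   transcript (5'->3') order within each transcript.
#' @details Transcripts that appear only in non-exon features are skipped
#'   with a warning. Records with unknown strand (`"."`) are an error: the
#'   50-nt rule and junction enumeration are strand-aware.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' sim <- sim_transcripts(2, seed = 1)
#' write_models_gtf(sim$models, gtf)
#' read_transcript_models(gtf)
#' @export
read_transcript_models <- function(path) {
  .pre_validate_gtf(path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  if (!all(c("type", "gene_id", "transcript_id") %in% names(df))) {
    stop("GTF lacks required attributes (gene_id, transcript_id)")
  }
  df <- df |>
    mutate(strand = as.character(.data$strand),
           seqnames = as.character(.data$seqnames))
  feat <- df |> filter(.data$type %in% c("exon", "CDS", "stop_codon"))
  if (any(feat$strand == "*")) {
    bad <- feat$transcript_id[feat$strand == "*"][1]
    stop("record with unknown strand '.' for transcript ", bad)
  }
  exons <- feat |>
    filter(.data$type == "exon") |>
    select(gene_id = "gene_id", transcript_id = "transcript_id",
           chrom = "seqnames", strand = "strand",
           start = "start", end = "end")
  no_exon <- setdiff(unique(feat$transcript_id), unique(exons$transcript_id))
  if (length(no_exon) > 0) {
    warning("skipping ", length(no_exon),
            " transcript(s) with zero exon features: ",
            paste(no_exon, collapse = ", "))
  }
  cds <- feat |>
    filter(.data$type %in% c("CDS", "stop_codon")) |>
    group_by(.data$transcript_id) |>
    summarise(cds_start = min(.data$start), cds_end = max(.data$end),
              .groups = "drop")
  out <- exons |>
    left_join(cds, by = "transcript_id") |>
    group_by(.data$transcript_id) |>
    arrange(if (first(.data$strand) == "+") .data$start else -.data$start,
            .by_group = TRUE) |>
    ungroup()
  .validate_models(out)
  out
}

# cheap line-level pre-validation so malformed records are reported with
# their line number (rtracklayer's errors are opaque)
.pre_validate_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 8L]
  if (length(bad) > 0) {
    stop("malformed GTF record at line ", bad[1], " of ", path,
         " (expected >= 8 tab-separated fields)")
  }
  invisible(TRUE)
}

.validate_models <- function(models) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand",
                  "start", "end") %in% names(models)))
  if (any(models$end < models$start)) stop("exon with end < start")
  if (!all(models$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ov <- models |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(bad = any(.data$start[-1] <= .data$end[-n()]), .groups = "drop")
  if (any(ov$bad)) {
    stop("overlapping exons within transcript(s): ",
         paste(ov$transcript_id[ov$bad], collapse = ", "))
  }
  invisible(models)
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_transcript_models()]: emits one `exon` feature per row
#' and, for transcripts with an annotated coding region, `CDS` features
#' covering the coding extent (termination codon included) intersected with
#' the exons.
#'
#' @param models Exon table as returned by [read_transcript_models()] or
#'   [sim_transcripts()].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_models_gtf <- function(models, path) {
  .validate_models(models)
  rows <- list()
  rows$exon <- models |> mutate(type = "exon")
  cds <- models |>
    filter(!is.na(.data$cds_start)) |>
    mutate(start = pmax(.data$start, .data$cds_start),
           end = pmin(.data$end, .data$cds_end)) |>
    filter(.data$start <= .data$end) |>
    mutate(type = "CDS")
  all <- bind_rows(rows$exon, cds)
  gr <- GenomicRanges::GRanges(
    seqnames = all$chrom,
    ranges = IRanges::IRanges(all$start, all$end),
    strand = all$strand,
    type = all$type,
    gene_id = all$gene_id,
    transcript_id = all$transcript_id,
    # nominal frame for CDS features; the reader only uses the CDS extent
    phase = ifelse(all$type == "CDS", 0L, NA_integer_)
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Classify transcripts as NMD substrates by the 50-nt rule
#'
#' A transcript is annotated as a nonsense-mediated decay (NMD) substrate
#' when its termination codon lies more than 50 spliced nucleotides upstream
#' of the final exon-exon junction. The distance is measured in mRNA
#' coordinates from the *last* base of the stop codon to the last base
#' before the final junction; single-exon transcripts have no junction and
#' are never NMD substrates.
#'
#' @param models Exon table (see [read_transcript_models()]). Transcripts
#'   with an annotated CDS use its 3' end as the stop codon (the CDS extent
#'   includes the termination codon in this package's convention).
#' @param genome Optional genome (FASTA path, `DNAStringSet`, or named
#'   character vector). When a transcript lacks an annotated CDS, the open
#'   reading frame is derived from the spliced sequence: translation starts
#'   at the 5'-most AUG and ends at the first in-frame stop.
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `stop_codon_tx_pos`, `last_junction_tx_pos`, `distance_nt`
#'   (`last_junction_tx_pos - stop_codon_tx_pos`), `is_nmd_substrate`, and
#'   `status` (`"ok"` or `"no_orf"`). Transcripts with no derivable ORF are
#'   flagged `no_orf` and reported as non-substrates, never silently
#'   defaulted.
#' @examples
#' sim <- sim_transcripts(5, seed = 1)
#' classify_nmd(sim$models)
#' @export
classify_nmd <- function(models, genome = NULL) {
  .validate_models(models)
  if (!is.null(genome)) genome <- .load_genome(genome)
  per_tx <- split(models, models$transcript_id)
  res <- purrr::map(per_tx, function(ex) {
    ex <- .tx_order(as.data.frame(ex))
    w <- .exon_widths(ex)
    L <- sum(w)
    n_ex <- nrow(ex)
    last_junc <- if (n_ex >= 2L) as.integer(L - w[n_ex]) else NA_integer_
    stop_tx <- NA_integer_
    status <- "ok"
    if (!is.na(ex$cds_start[1])) {
      stop_g <- if (ex$strand[1] == "+") ex$cds_end[1] else ex$cds_start[1]
      stop_tx <- .genomic_to_tx(stop_g, ex)
      if (is.na(stop_tx)) stop("CDS boundary of ", ex$transcript_id[1],
                               " falls outside its exons")
    } else if (!is.null(genome)) {
      stop_tx <- .derive_orf_stop(.spliced_seq(ex, genome))
      if (is.na(stop_tx)) status <- "no_orf"
    } else {
      status <- "no_orf"
    }
    dist <- if (!is.na(stop_tx) && !is.na(last_junc)) {
      as.integer(last_junc - stop_tx)
    } else NA_integer_
    tibble(
      transcript_id = ex$transcript_id[1],
      stop_codon_tx_pos = stop_tx,
      last_junction_tx_pos = last_junc,
      distance_nt = dist,
      is_nmd_substrate = !is.na(dist) && dist > NMD_DISTANCE_NT,
      status = status
    )
  })
  bind_rows(res)
}

# spliced-coordinate position of the last base of the first in-frame stop
# codon downstream of the 5'-most AUG; NA when no ORF is derivable
.derive_orf_stop <- function(mrna) {
  mrna <- toupper(mrna)
  atg <- regexpr("ATG", mrna, fixed = TRUE)
  if (atg < 0) return(NA_integer_)
  stops <- c("TAA", "TAG", "TGA")
  i <- as.integer(atg)
  L <- nchar(mrna)
  while (i + 2L <= L) {
    codon <- substr(mrna, i, i + 2L)
    if (codon %in% stops && i > atg) return(as.integer(i + 2L))
    i <- i + 3L
  }
  NA_integer_
}

#' Enumerate all co-linear splice junctions within each gene
#'
#' Collects the 5' splice sites (donors) and 3' splice sites (acceptors)
#' used by any transcript of a gene and forms every co-linear donor/acceptor
#' combination -- the acceptor must lie downstream of the donor in
#' transcription direction. This deliberately includes junctions absent from
#' every annotated transcript (for example an exon-9 to exon-12 junction
#' diagnostic of a two-exon skipping event), the construction used to build
#' a splice-junction alignment database.
#'
#' @param models Exon table covering one or more genes.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `donor`,
#'   `acceptor`: `donor` is the genomic coordinate of the last exonic base of
#'   the upstream exon, `acceptor` the first exonic base of the downstream
#'   exon. Deduplicated on `(chrom, donor, acceptor, strand)`. Single-exon
#'   genes contribute no junctions.
#' @examples
#' sim <- sim_transcripts(2, seed = 1, n_exons = 4:4)
#' enumerate_junctions(sim$models)
#' @export
enumerate_junctions <- function(models) {
  .validate_models(models)
  per_gene <- split(models, list(models$gene_id, models$strand, models$chrom),
                    drop = TRUE)
  res <- purrr::map(per_gene, function(g) {
    g <- as.data.frame(g)
    donors <- integer(0); acceptors <- integer(0)
    for (tx in split(g, g$transcript_id)) {
      intr <- .tx_introns(tx)
      donors <- c(donors, intr$donor)
      acceptors <- c(acceptors, intr$acceptor)
    }
    donors <- unique(donors); acceptors <- unique(acceptors)
    if (length(donors) == 0L) return(NULL)
    pairs <- expand.grid(donor = donors, acceptor = acceptors)
    keep <- if (g$strand[1] == "+") pairs$acceptor > pairs$donor
            else pairs$acceptor < pairs$donor
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L) return(NULL)
    tibble(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
           donor = as.integer(pairs$donor),
           acceptor = as.integer(pairs$acceptor))
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(gene_id = character(0), chrom = character(0),
                  strand = character(0), donor = integer(0),
                  acceptor = integer(0)))
  }
  out |>
    distinct(.data$chrom, .data$donor, .data$acceptor, .data$strand,
             .keep_all = TRUE) |>
    arrange(.data$chrom, .data$donor, .data$acceptor)
}

#' Classify intron type from terminal dinucleotides
#'
#' Major-spliceosome (U2-type) introns carry GT..AG termini; minor
#' (U12-type) introns carry AT..AC. Anything else -- including the rare
#' GC-AG class and non-ACGT characters -- is classified `unknown` and is
#' excluded from downstream differential-splicing summaries, a conservative
#' restriction that avoids confounding by intron type.
#'
#' @param donor_dinucleotide,acceptor_dinucleotide Character vectors of
#'   intron-terminal dinucleotides in transcription orientation (first two
#'   and last two intronic bases).
#' @return Character vector in `{"U2", "U12", "unknown"}`.
#' @examples
#' classify_intron_type(c("GT", "AT", "GC"), c("AG", "AC", "AG"))
#' @export
classify_intron_type <- function(donor_dinucleotide, acceptor_dinucleotide) {
  d <- toupper(donor_dinucleotide)
  a <- toupper(acceptor_dinucleotide)
  dplyr::case_when(
    d == "GT" & a == "AG" ~ "U2",
    d == "AT" & a == "AC" ~ "U12",
    TRUE ~ "unknown"
  )
}

#' Intron-terminal dinucleotides for a junction table
#'
#' Looks up the first and last two intronic bases (in transcription
#' orientation) for each junction, for use with [classify_intron_type()].
#'
#' @param junctions Junction tibble from [enumerate_junctions()].
#' @param genome Genome (FASTA path, `DNAStringSet`, or named character).
#' @return `junctions` with `donor_dinuc`, `acceptor_dinuc` and
#'   `intron_class` columns added.
#' @export
junction_dinucleotides <- function(junctions, genome) {
  genome <- .load_genome(genome)
  get2 <- function(chrom, from) substring(genome[[chrom]], from, from + 1L)
  dd <- character(nrow(junctions)); ad <- character(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    ch <- junctions$chrom[i]
    if (junctions$strand[i] == "+") {
      dd[i] <- get2(ch, junctions$donor[i] + 1L)
      ad[i] <- get2(ch, junctions$acceptor[i] - 2L)
    } else {
      dd[i] <- .revcomp(get2(ch, junctions$donor[i] - 2L))
      ad[i] <- .revcomp(get2(ch, junctions$acceptor[i] + 1L))
    }
  }
  junctions |>
    mutate(donor_dinuc = dd, acceptor_dinuc = ad,
           intron_class = classify_intron_type(dd, ad))
}

#' NMD relevance of alternative-splicing events
#'
#' An event is *NMD relevant* when at least one, but not all, of its child
#' isoforms is a predicted NMD substrate: differential use of the event then
#' changes the NMD-substrate burden of the gene's output.
#'
#' @param children Long tibble linking events to their child isoforms:
#'   columns `event_id`, `transcript_id`, and `role` (e.g. `"inclusion"`,
#'   `"exclusion"`).
#' @param nmd_annotations Output of [classify_nmd()] covering every child.
#' @return A tibble with `event_id`, `n_children`, `n_nmd`, `nmd_relevant`,
#'   and `nmd_role` -- the role of the single NMD child when exactly one
#'   child is a substrate (`NA` otherwise), used to orient burden directions.
#' @examples
#' sim <- sim_splicing_events(n_events = 4, seed = 1)
#' ann <- classify_nmd(sim$models)
#' classify_event_nmd_relevance(sim$children, ann)
#' @export
classify_event_nmd_relevance <- function(children, nmd_annotations) {
  missing <- setdiff(children$transcript_id, nmd_annotations$transcript_id)
  if (length(missing) > 0) {
    stop("missing NMD annotation for child isoform(s): ",
         paste(missing, collapse = ", "))
  }
  children |>
    left_join(nmd_annotations |>
                select("transcript_id", "is_nmd_substrate"),
              by = "transcript_id") |>
    group_by(.data$event_id) |>
    summarise(
      n_children = n(),
      n_nmd = sum(.data$is_nmd_substrate),
      nmd_relevant = sum(.data$is_nmd_substrate) > 0L &
        sum(.data$is_nmd_substrate) < n(),
      nmd_role = if (sum(.data$is_nmd_substrate) == 1L)
        .data$role[.data$is_nmd_substrate] else NA_character_,
      .groups = "drop"
    )
}

#' Attach NMD relevance and intron class to an event catalog
#'
#' Convenience wrapper joining [classify_event_nmd_relevance()] onto the
#' event table, so downstream filtering (U2-only, NMD-relevant-only) is a
#' plain `dplyr::filter()`.
#'
#' @param events Event tibble with `event_id`, `event_type`, and (optionally)
#'   `intron_class` columns.
#' @param children,nmd_annotations As in [classify_event_nmd_relevance()].
#' @return `events` with `nmd_relevant` and `nmd_role` columns added.
#' @export
annotate_events <- function(events, children, nmd_annotations) {
  rel <- classify_event_nmd_relevance(children, nmd_annotations)
  events |>
    left_join(rel |> select("event_id", "nmd_relevant", "nmd_role"),
              by = "event_id")
}
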