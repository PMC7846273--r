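#' Count isoform-discriminating ("informative") reads for splicing events
#'
#' An informative read is one whose gapped alignment is consistent with
#' exactly one child isoform of an event: every junction the read spans must
#' be a junction of that child, and every aligned block must fall inside the
#' child's exons. Reads consistent with several children (e.g. contained in
#' a shared exon) or with none are discarded as uninformative.
#'
#' @param alignments Path to a SAM or BAM file of gapped alignments.
#' @param models Exon table covering every child isoform.
#' @param children Event-to-isoform link table (`event_id`, `transcript_id`,
#'   `role`).
#' @param read_length Read length used to compute the number of informative
#'   read-start positions per isoform (for length normalization of PSI).
#'   Default 50; pass `NULL` to infer the modal query width from the data.
#' @param sample_id Sample label carried into the output; defaults to the
#'   alignment file name.
#' @return A tibble with one row per event child: `event_id`, `sample_id`,
#'   `transcript_id`, `role`, `reads` (informative reads assigned), and
#'   `positions` (informative read-start positions of that isoform).
#' @examples
#' sim <- sim_splicing_events(n_events = 1, seed = 1)
#' sam <- tempfile(fileext = ".sam")
#' sim_event_sam(sim, reads_per_child = c(inclusion = 7, exclusion = 3),
#'               path = sam, seed = 2)
#' count_informative_reads(sam, sim$models, sim$children)
#' @export
count_informative_reads <- function(alignments, models, children,
                                    read_length = 50L, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- basename(alignments)
  bam <- .as_indexed_bam(alignments)
  gal <- GenomicAlignments::readGAlignments(bam)
  if (is.null(read_length)) {
    read_length <- as.integer(names(sort(table(
      GenomicAlignments::qwidth(gal)), decreasing = TRUE))[1])
  }
  read_chrom <- as.character(GenomicAlignments::seqnames(gal))
  blocks <- GenomicAlignments::grglist(gal)
  introns <- GenomicAlignments::junctions(gal)

  out <- purrr::map(split(children, children$event_id), function(ch) {
    ch <- as.data.frame(ch)
    child_tx <- lapply(ch$transcript_id, function(tx) {
      .tx_order(as.data.frame(models[models$transcript_id == tx, ]))
    })
    chrom <- child_tx[[1]]$chrom[1]
    span <- range(unlist(lapply(child_tx, function(e) c(e$start, e$end))))
    cand <- which(read_chrom == chrom &
                    BiocGenerics::start(gal) <= span[2] &
                    BiocGenerics::end(gal) >= span[1])
    n_skip <- sum(read_chrom != chrom)
    if (n_skip > 0) {
      message(n_skip, " alignment(s) on other chromosomes skipped for event ",
              ch$event_id[1])
    }
    counts <- integer(nrow(ch))
    for (i in cand) {
      b <- blocks[[i]]
      j <- introns[[i]]
      compat <- vapply(child_tx, function(ex) {
        .read_compatible(BiocGenerics::start(b), BiocGenerics::end(b),
                         BiocGenerics::start(j), BiocGenerics::end(j), ex)
      }, logical(1))
      if (sum(compat) == 1L) {
        counts[which(compat)] <- counts[which(compat)] + 1L
      }
    }
    pos <- .informative_positions(child_tx, read_length)
    tibble(event_id = ch$event_id[1], sample_id = sample_id,
           transcript_id = ch$transcript_id, role = ch$role,
           reads = counts, positions = pos)
  })
  bind_rows(out)
}

# is a read (aligned blocks + spanned introns, genomic coordinates)
# consistent with an isoform given as an exon table in transcript order?
.read_compatible <- function(bs, be, is_, ie, exons) {
  # every intron the read spans must be an intron of the isoform
  intr <- .tx_introns(exons)
  if (length(is_) > 0) {
    ileft <- pmin(intr$left, intr$right) + 1L
    iright <- pmax(intr$left, intr$right) - 1L
    for (k in seq_along(is_)) {
      if (!any(ileft == is_[k] & iright == ie[k])) return(FALSE)
    }
  }
  # every aligned block must lie within the exon union
  for (k in seq_along(bs)) {
    inside <- any(exons$start <= bs[k] & exons$end >= be[k])
    if (!inside) return(FALSE)
  }
  TRUE
}

# number of read-start positions along each child's spliced sequence that
# yield a read uniquely consistent with that child (brute force over the
# child's transcript coordinates; events are small)
.informative_positions <- function(child_tx, read_length) {
  vapply(seq_along(child_tx), function(ci) {
    ex <- child_tx[[ci]]
    L <- sum(.exon_widths(ex))
    n_inf <- 0L
    for (s in seq_len(max(L - read_length + 1L, 0L))) {
      bl <- .tx_interval_blocks(s, s + read_length - 1L, ex)
      # introns crossed by this placement
      if (nrow(bl) > 1L) {
        is_ <- bl$end[-nrow(bl)] + 1L
        ie <- bl$start[-1] - 1L
      } else {
        is_ <- integer(0); ie <- integer(0)
      }
      compat <- vapply(child_tx, function(other) {
        .read_compatible(bl$start, bl$end, is_, ie, other)
      }, logical(1))
      if (sum(compat) == 1L && compat[ci]) n_inf <- n_inf + 1L
    }
    max(n_inf, 1L)  # positive by type contract; degenerate geometries clamp to 1
  }, integer(1))
}

#' Count reads supporting each splice junction
#'
#' Tallies, per junction, the gapped alignments whose spanned intron matches
#' the junction exactly -- the per-junction read support displayed alongside
#' sashimi-style coverage plots.
#'
#' @param alignments SAM or BAM path.
#' @param junctions Optional junction table from [enumerate_junctions()]; when
#'   supplied, counts are reported for (and joined onto) those junctions,
#'   zero-filled. Otherwise all observed junctions are reported.
#' @return A tibble `chrom`, `left`, `right`, `reads` where `left`/`right`
#'   are the genomic coordinates of the flanking exonic bases, plus the
#'   columns of `junctions` when given.
#' @export
count_junction_reads <- function(alignments, junctions = NULL) {
  bam <- .as_indexed_bam(alignments)
  gal <- GenomicAlignments::readGAlignments(bam)
  j <- unlist(GenomicAlignments::junctions(gal))
  obs <- tibble(
    chrom = as.character(GenomicAlignments::seqnames(j)),
    left = BiocGenerics::start(j) - 1L,
    right = BiocGenerics::end(j) + 1L
  ) |>
    dplyr::count(.data$chrom, .data$left, .data$right, name = "reads")
  if (is.null(junctions)) return(obs)
  junctions |>
    mutate(left = pmin(.data$donor, .data$acceptor),
           right = pmax(.data$donor, .data$acceptor)) |>
    left_join(obs, by = c("chrom", "left", "right")) |>
    mutate(reads = dplyr::coalesce(.data$reads, 0L)) |>
    select(-"left", -"right")
}

#' Estimate PSI from informative read counts
#'
#' The percent-spliced-in estimate is a length-normalized count ratio: each
#' child's read count is divided by its number of informative read-start
#' positions, and PSI is the inclusion child's share of the summed
#' densities,
#' \deqn{\hat\Psi = \frac{r_i/p_i}{r_i/p_i + r_e/p_e}.}
#' This is a deterministic point estimator standing where a Bayesian
#' isoform-quantification posterior would sit in a full pipeline.
#'
#' @param counts Tibble from [count_informative_reads()] or
#'   [sim_event_counts()]: `event_id`, `sample_id`, `role`
#'   (`inclusion`/`exclusion`), `reads`, `positions`.
#' @return One row per event and sample: read/position columns in wide form,
#'   `total_reads`, and `psi` (`NA` with `status = "no_reads"` when the event
#'   has zero informative reads in that sample; `status = "ok"` otherwise).
#' @examples
#' counts <- tibble::tibble(
#'   event_id = "ev1", sample_id = "s1",
#'   role = c("inclusion", "exclusion"),
#'   reads = c(30L, 10L), positions = c(3L, 1L))
#' estimate_psi(counts)  # psi = 0.5
#' @export
estimate_psi <- function(counts) {
  stopifnot(all(counts$role %in% c("inclusion", "exclusion")))
  wide <- counts |>
    select("event_id", "sample_id", "role", "reads", "positions") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("reads", "positions"))
  wide |>
    mutate(
      total_reads = .data$reads_inclusion + .data$reads_exclusion,
      inc_density = .data$reads_inclusion / .data$positions_inclusion,
      exc_density = .data$reads_exclusion / .data$positions_exclusion,
      psi = if_else(.data$total_reads > 0L,
                    .data$inc_density / (.data$inc_density + .data$exc_density),
                    NA_real_),
      status = if_else(.data$total_reads > 0L, "ok", "no_reads")
    )
}

#' Differential-splicing test with the three-criterion filter
#'
#' For each event, per-replicate PSI values are compared between two groups
#' with a two-sided t-test, and the event passes the filter when all three
#' criteria hold: (1) an informative-read floor (default: at least 20
#' informative reads, required of every sample), (2) an effect-size
#' criterion -- absolute PSI change of at least 10 percentage points *or* an
#' isoform-expression fold change of at least 2 -- and (3) raw p <= 0.05.
#' No multiplicity correction is applied; the filter operates on raw
#' p-values by design.
#'
#' @param psi_tbl Output of [estimate_psi()].
#' @param group_a,group_b Character vectors of `sample_id`s for the two
#'   conditions (`delta_psi = mean_psi_b - mean_psi_a`; group B is the test
#'   condition).
#' @param min_reads Informative-read floor (default 20).
#' @param min_reads_scope `"per_sample"` (default; every sample of the event
#'   must meet the floor) or `"total"` (summed over samples).
#' @param dpsi_min Minimum absolute PSI change (default 0.10, inclusive).
#' @param fc_min Fold-change threshold (default 2).
#' @param fc_scale `"linear"` (default): passes when the fold change or its
#'   reciprocal is at least `fc_min`; `"log2"`: passes when
#'   `|log2(fold change)| >= fc_min`. Both readings of the published
#'   criterion are supported because the two are attested side by side.
#' @param p_max Raw p-value threshold (default 0.05, inclusive).
#' @param t_variant `"pooled"` (Student, default) or `"welch"`.
#' @param nmd_role Optional tibble (`event_id`, `nmd_role`) orienting the
#'   `direction` column toward the NMD-substrate child.
#' @return A tibble of class `nmd_diff` with one row per testable event:
#'   group means, `delta_psi`, `fold_change` (inclusion-isoform density
#'   ratio, B over A), `p_value`, the three criterion columns
#'   (`reads_ok`, `effect_ok`, `p_ok`), `passes_filter`, `direction`
#'   (`nmd_up`/`nmd_down`/`none`), and `reason` for excluded events.
#'   Events with fewer than two defined-PSI replicates in either group are
#'   excluded (`reason = "insufficient_replicates"`); events failing the
#'   read floor are excluded before testing (`reason = "low_reads"`,
#'   `p_value = NA`).
#' @export
test_differential <- function(psi_tbl, group_a, group_b,
                              min_reads = 20L,
                              min_reads_scope = c("per_sample", "total"),
                              dpsi_min = 0.10, fc_min = 2,
                              fc_scale = c("linear", "log2"),
                              p_max = 0.05,
                              t_variant = c("pooled", "welch"),
                              nmd_role = NULL) {
  min_reads_scope <- match.arg(min_reads_scope)
  fc_scale <- match.arg(fc_scale)
  t_variant <- match.arg(t_variant)
  dat <- psi_tbl |> filter(.data$sample_id %in% c(group_a, group_b))
  res <- purrr::map(split(dat, dat$event_id), function(ev) {
    samples_present <- unique(ev$sample_id)
    # a sample with no row contributes zero informative reads
    reads_vec <- c(ev$total_reads,
                   rep(0L, length(setdiff(c(group_a, group_b), samples_present))))
    reads_ok <- if (min_reads_scope == "per_sample") {
      all(reads_vec >= min_reads)
    } else {
      sum(reads_vec) >= min_reads
    }
    base <- tibble(event_id = ev$event_id[1],
                   mean_psi_a = NA_real_, mean_psi_b = NA_real_,
                   delta_psi = NA_real_, fold_change = NA_real_,
                   p_value = NA_real_, reads_ok = reads_ok,
                   effect_ok = NA, p_ok = NA,
                   passes_filter = FALSE, reason = NA_character_)
    if (!reads_ok) { base$reason <- "low_reads"; return(base) }
    a <- ev |> filter(.data$sample_id %in% group_a, !is.na(.data$psi))
    b <- ev |> filter(.data$sample_id %in% group_b, !is.na(.data$psi))
    if (nrow(a) < 2L || nrow(b) < 2L) {
      base$reason <- "insufficient_replicates"; return(base)
    }
    mean_a <- mean(a$psi); mean_b <- mean(b$psi)
    delta <- mean_b - mean_a
    da <- mean(a$inc_density); db <- mean(b$inc_density)
    fc <- if (da > 0) db / da else if (db > 0) Inf else NA_real_
    # inclusive bounds with a float-safe epsilon (0.10 must pass)
    effect_ok <- abs(delta) >= dpsi_min - 1e-9 ||
      (!is.na(fc) && .fc_passes(fc, fc_min, fc_scale))
    p <- two_sided_t_test(a$psi, b$psi, variant = t_variant)$p.value
    p_ok <- p <= p_max
    base$mean_psi_a <- mean_a; base$mean_psi_b <- mean_b
    base$delta_psi <- delta; base$fold_change <- fc
    base$p_value <- p; base$effect_ok <- effect_ok; base$p_ok <- p_ok
    base$passes_filter <- reads_ok && effect_ok && p_ok
    base
  })
  out <- bind_rows(res)
  if (!is.null(nmd_role)) {
    out <- out |> left_join(nmd_role |> select("event_id", "nmd_role"),
                            by = "event_id")
  } else {
    out$nmd_role <- NA_character_
  }
  out <- out |>
    mutate(direction = dplyr::case_when(
      !.data$passes_filter | is.na(.data$nmd_role) ~ "none",
      .data$nmd_role == "inclusion" & .data$delta_psi > 0 ~ "nmd_up",
      .data$nmd_role == "inclusion" & .data$delta_psi < 0 ~ "nmd_down",
      .data$nmd_role == "exclusion" & .data$delta_psi > 0 ~ "nmd_down",
      .data$nmd_role == "exclusion" & .data$delta_psi < 0 ~ "nmd_up",
      TRUE ~ "none"
    ))
  class(out) <- c("nmd_diff", class(out))
  out
}

.fc_passes <- function(fc, fc_min, fc_scale) {
  if (fc_scale == "linear") max(fc, 1 / fc) >= fc_min
  else abs(log2(fc)) >= fc_min
}

#' Summarize NMD-substrate burden of differential splicing
#'
#' Counts, per alternative-splicing event type, the significant events in
#' which the NMD-substrate isoform is increased versus decreased in the test
#' condition. Restricted to NMD-relevant events arising from U2-type (major)
#' introns; each event is counted at most once.
#'
#' @param results `nmd_diff` tibble from [test_differential()].
#' @param events Event catalog with `event_id`, `event_type`,
#'   `intron_class`, `nmd_relevant`, and `nmd_role` columns (see
#'   [annotate_events()]).
#' @return A tibble of class `nmd_burden` with one row per event type
#'   (`SE`, `RI`, `A5SS`, `A3SS`, `MXE`) and columns `nmd_up`, `nmd_down`,
#'   `total`, zero-filled.
#' @export
summarize_nmd_burden <- function(results, events) {
  event_types <- c("SE", "RI", "A5SS", "A3SS", "MXE")
  joined <- as_tibble(results) |>
    select(-dplyr::any_of("nmd_role")) |>
    inner_join(events, by = "event_id") |>
    filter(.data$nmd_relevant, .data$intron_class == "U2",
           .data$passes_filter, !is.na(.data$nmd_role))
  joined <- joined |>
    mutate(direction = dplyr::case_when(
      .data$nmd_role == "inclusion" & .data$delta_psi > 0 ~ "nmd_up",
      .data$nmd_role == "inclusion" & .data$delta_psi < 0 ~ "nmd_down",
      .data$nmd_role == "exclusion" & .data$delta_psi > 0 ~ "nmd_down",
      .data$nmd_role == "exclusion" & .data$delta_psi < 0 ~ "nmd_up",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$direction))
  tab <- joined |>
    dplyr::count(.data$event_type, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("nmd_up", "nmd_down")) {
    if (!col %in% names(tab)) tab[[col]] <- 0L
  }
  out <- tibble(event_type = event_types) |>
    left_join(tab, by = "event_type") |>
    mutate(nmd_up = dplyr::coalesce(.data$nmd_up, 0L),
           nmd_down = dplyr::coalesce(.data$nmd_down, 0L),
           total = .data$nmd_up + .data$nmd_down) |>
    select("event_type", "nmd_up", "nmd_down", "total")
  class(out) <- c("nmd_burden", class(out))
  out
}

#' @rdname test_differential
#' @param x An `nmd_diff` tibble.
#' @param ... Unused.
#' @export
glance.nmd_diff <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_significant = sum(x$passes_filter),
    n_low_reads = sum(!is.na(x$reason) & x$reason == "low_reads"),
    n_insufficient = sum(!is.na(x$reason) &
                           x$reason == "insufficient_replicates")
  )
}
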