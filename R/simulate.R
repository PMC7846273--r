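# Synthetic-data generators. Every generator is seeded, deterministic under
# a fixed seed, and returns a machine-readable truth table alongside the
# files/tibbles it produces, so each pipeline stage can be tested against
# known ground truth with no external downloads.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# sample() treats a length-1 numeric as 1:x; this does not
.sample_from <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random sequence guaranteed free of ATG (start-codon-free 5' UTRs)
.rand_seq_no_atg <- function(n) {
  if (n == 0L) return("")
  s <- .rand_seq(n)
  while (grepl("ATG", s, fixed = TRUE)) s <- sub("ATG", "ACG", s, fixed = TRUE)
  s
}

.NONSTOP_CODONS <- {
  all_codons <- as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

#' Simulate transcript models with known NMD-substrate status
#'
#' Builds random multi-exon transcript models whose spliced sequence is
#' constructed mRNA-first: a start-codon-free 5' UTR, an AUG, a run of
#' stop-free codons, and a termination codon placed at a *chosen* spliced
#' distance from the final exon-exon junction. The NMD status of each model
#' is therefore known by construction (truth = distance > 50 nt), including
#' exact-boundary models at 50 and 51 nt; the classifier and any
#' sequence-level oracle can both be scored against it.
#'
#' @param n Number of transcripts.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param n_exons Range of exon counts to sample from (default `1:6`;
#'   single-exon models exercise the no-junction rule).
#' @param exon_len,intron_len Ranges for exon and intron lengths (nt).
#' @param cds_fraction Fraction of transcripts that carry an annotated CDS
#'   in the model (the rest must have their ORF derived from sequence).
#' @param boundary_prob Probability that a multi-exon transcript is forced
#'   to an exact boundary distance of 50 or 51 nt.
#' @param minus_prob Probability of placing a transcript on the minus
#'   strand.
#' @return A list with `models` (exon table; CDS extent includes the stop
#'   codon), `genome` (named character vector, one contig per transcript),
#'   and `truth` (`transcript_id`, `n_exons`, `stop_codon_tx_pos`,
#'   `last_junction_tx_pos`, `distance_nt`, `is_nmd_substrate`).
#' @export
sim_transcripts <- function(n, seed = NULL, n_exons = 1:6,
                            exon_len = 30:180, intron_len = 60:200,
                            cds_fraction = 1, boundary_prob = 0.1,
                            minus_prob = 0.3) {
  .with_seed(seed, {
    models <- list(); genome <- character(0); truth <- list()
    for (i in seq_len(n)) {
      tx_id <- sprintf("tx%04d", i)
      gene_id <- sprintf("g%04d", i)
      chrom <- sprintf("chr_%s", tx_id)
      strand <- if (runif(1) < minus_prob) "-" else "+"
      n_ex <- .sample_from(n_exons)
      w <- .sample_from(exon_len, n_ex, replace = TRUE)
      L <- sum(w)
      last_junc <- if (n_ex >= 2L) L - w[n_ex] else NA_integer_
      # choose the spliced position of the stop codon's last base
      if (n_ex >= 2L) {
        d_hi <- min(last_junc - 8L, 120L)
        d_lo <- max(-w[n_ex] + 3L, -80L)
        d <- if (runif(1) < boundary_prob && d_hi >= 51L) {
          .sample_from(c(50L, 51L))
        } else .sample_from(seq.int(d_lo, d_hi))
        stop_tx <- last_junc - d
      } else {
        stop_tx <- .sample_from(seq.int(8L, L - 3L))
      }
      # ORF start (AUG) in frame with the stop codon, short UTR
      m_max <- (stop_tx - 5L - 1L) %/% 3L
      m <- .sample_from(seq.int(0L, min(m_max, 40L)))
      a <- stop_tx - 5L - 3L * m
      utr5 <- .rand_seq_no_atg(a - 1L)
      mid <- paste(sample(.NONSTOP_CODONS, m, replace = TRUE), collapse = "")
      stopc <- sample(c("TAA", "TAG", "TGA"), 1)
      tail_seq <- .rand_seq(L - stop_tx)
      mrna <- paste0(utr5, "ATG", mid, stopc, tail_seq)
      stopifnot(nchar(mrna) == L)
      # lay the mRNA on a genomic contig with GT..AG introns
      pad <- 25L
      layout_start <- integer(n_ex); layout_end <- integer(n_ex)
      pieces <- character(0); cursor <- 0L
      add <- function(s) { pieces <<- c(pieces, s); cursor <<- cursor + nchar(s) }
      add(.rand_seq(pad))
      off <- cumsum(c(0L, w))
      for (e in seq_len(n_ex)) {
        layout_start[e] <- cursor + 1L
        add(substr(mrna, off[e] + 1L, off[e + 1L]))
        layout_end[e] <- cursor
        if (e < n_ex) {
          il <- .sample_from(intron_len)
          add(paste0("GT", .rand_seq(il - 4L), "AG"))
        }
      }
      add(.rand_seq(pad))
      layout <- paste(pieces, collapse = "")
      glen <- nchar(layout)
      if (strand == "+") {
        gseq <- layout
        ex_start <- layout_start; ex_end <- layout_end
      } else {
        gseq <- .revcomp(layout)
        ex_start <- glen - layout_end + 1L
        ex_end <- glen - layout_start + 1L
      }
      ex <- tibble(gene_id = gene_id, transcript_id = tx_id, chrom = chrom,
                   strand = strand, start = ex_start, end = ex_end)
      ex <- ex[order(ex$start, decreasing = (strand == "-")), ]
      has_cds <- runif(1) < cds_fraction
      if (has_cds) {
        g1 <- .tx_to_genomic(a, as.data.frame(ex))
        g2 <- .tx_to_genomic(stop_tx, as.data.frame(ex))
        ex$cds_start <- min(g1, g2); ex$cds_end <- max(g1, g2)
      } else {
        ex$cds_start <- NA_integer_; ex$cds_end <- NA_integer_
      }
      models[[i]] <- ex
      genome[chrom] <- gseq
      dist <- if (n_ex >= 2L) as.integer(last_junc - stop_tx) else NA_integer_
      truth[[i]] <- tibble(
        transcript_id = tx_id, n_exons = n_ex,
        stop_codon_tx_pos = as.integer(stop_tx),
        last_junction_tx_pos = if (n_ex >= 2L) as.integer(last_junc)
                               else NA_integer_,
        distance_nt = dist,
        is_nmd_substrate = !is.na(dist) && dist > NMD_DISTANCE_NT
      )
    }
    list(models = bind_rows(models), genome = genome,
         truth = bind_rows(truth))
  })
}

# exon templates for one two-isoform event of each class, as transcript-order
# block lists (start, end) on a plus-strand layout; cassette length `cl`
.event_template <- function(type, cl = 80L) {
  inc <- exc <- NULL
  if (type == "SE") {
    inc <- rbind(c(1, 100), c(201, 200 + cl), c(401, 520))
    exc <- rbind(c(1, 100), c(401, 520))
  } else if (type == "RI") {
    inc <- rbind(c(1, 300), c(401, 520))
    exc <- rbind(c(1, 100), c(201, 300), c(401, 520))
  } else if (type == "A5SS") {
    inc <- rbind(c(1, 140), c(301, 420), c(521, 640))
    exc <- rbind(c(1, 100), c(301, 420), c(521, 640))
  } else if (type == "A3SS") {
    inc <- rbind(c(1, 100), c(201, 320), c(421, 540))
    exc <- rbind(c(1, 100), c(241, 320), c(421, 540))
  } else if (type == "MXE") {
    inc <- rbind(c(1, 100), c(201, 200 + cl), c(501, 620))
    exc <- rbind(c(1, 100), c(301, 300 + cl), c(501, 620))
  } else stop("unknown event type: ", type)
  list(inclusion = inc, exclusion = exc)
}

#' Simulate an alternative-splicing event catalog with known NMD truth
#'
#' Generates two-isoform gene models for cassette-exon (SE),
#' retained-intron (RI), alternative 5'/3' splice-site (A5SS/A3SS), and
#' mutually-exclusive-exon (MXE) events. Each child's CDS is placed so that
#' its stop codon sits at a chosen spliced distance from its last junction,
#' fixing the NMD status of every child by construction; the per-event NMD
#' pattern (which child, if any, is the substrate) is drawn from
#' `pattern_weights`.
#'
#' @param n_events Number of events.
#' @param seed Integer seed.
#' @param types Event classes to cycle through.
#' @param pattern_weights Named weights for the per-event NMD pattern over
#'   `c(inclusion, exclusion, both, neither)`; only `inclusion`/`exclusion`
#'   patterns are NMD-relevant.
#' @param u12_fraction,unknown_fraction Fractions of events assigned minor
#'   (U12) or unclassifiable intron termini; these are excluded from burden
#'   summaries downstream.
#' @param minus_prob Probability of a minus-strand gene.
#' @return A list: `models` (exon table for all child isoforms), `children`
#'   (`event_id`, `transcript_id`, `role`), `events` (`event_id`,
#'   `event_type`, `gene_id`, `chrom`, `strand`, `intron_class`), and
#'   `truth` (per-child planted distances and NMD status, plus the event's
#'   `nmd_relevant`/`nmd_role`).
#' @export
sim_splicing_events <- function(n_events, seed = NULL,
                                types = c("SE", "RI", "A5SS", "A3SS", "MXE"),
                                pattern_weights = c(inclusion = 0.35,
                                                    exclusion = 0.35,
                                                    both = 0.1,
                                                    neither = 0.2),
                                u12_fraction = 0.02,
                                unknown_fraction = 0.02,
                                minus_prob = 0.25) {
  .with_seed(seed, {
    models <- list(); children <- list(); events <- list(); truth <- list()
    patterns <- names(pattern_weights)
    for (i in seq_len(n_events)) {
      type <- types[(i - 1L) %% length(types) + 1L]
      ev_id <- sprintf("ev%04d", i)
      gene_id <- sprintf("evg%04d", i)
      chrom <- sprintf("chr_%s", ev_id)
      strand <- if (runif(1) < minus_prob) "-" else "+"
      cl <- .sample_from(c(60L, 80L, 100L))  # frame-agnostic: no sequence here
      tmpl <- .event_template(type, cl)
      pattern <- sample(patterns, 1, prob = pattern_weights)
      span <- max(unlist(tmpl))
      for (role in c("inclusion", "exclusion")) {
        blocks <- tmpl[[role]]
        tx_id <- paste0(ev_id, "_", substr(role, 1, 3))
        if (strand == "+") {
          st <- blocks[, 1]; en <- blocks[, 2]
        } else {
          st <- span - blocks[, 2] + 1L; en <- span - blocks[, 1] + 1L
        }
        ex <- tibble(gene_id = gene_id, transcript_id = tx_id,
                     chrom = chrom, strand = strand,
                     start = as.integer(st), end = as.integer(en))
        ex <- ex[order(ex$start, decreasing = (strand == "-")), ]
        exd <- as.data.frame(ex)
        w <- .exon_widths(.tx_order(exd))
        L <- sum(w); last_junc <- L - w[length(w)]
        child_nmd <- pattern == "both" || pattern == role
        d <- if (child_nmd) .sample_from(60:min(110L, last_junc - 4L))
             else .sample_from(-30:35)
        stop_tx <- last_junc - d
        stopifnot(stop_tx >= 4L, stop_tx <= L)
        cds_tx_start <- max(1L, stop_tx - 3L * sample(5:15, 1) + 1L)
        g1 <- .tx_to_genomic(cds_tx_start, .tx_order(exd))
        g2 <- .tx_to_genomic(stop_tx, .tx_order(exd))
        ex$cds_start <- min(g1, g2); ex$cds_end <- max(g1, g2)
        models[[length(models) + 1L]] <- ex
        children[[length(children) + 1L]] <- tibble(
          event_id = ev_id, transcript_id = tx_id, role = role)
        truth[[length(truth) + 1L]] <- tibble(
          event_id = ev_id, transcript_id = tx_id, role = role,
          planted_distance_nt = as.integer(d),
          is_nmd_substrate = child_nmd)
      }
      u <- runif(1)
      intron_class <- if (u < u12_fraction) "U12"
        else if (u < u12_fraction + unknown_fraction) "unknown" else "U2"
      events[[i]] <- tibble(
        event_id = ev_id, event_type = type, gene_id = gene_id,
        chrom = chrom, strand = strand, intron_class = intron_class,
        nmd_pattern = pattern,
        nmd_relevant = pattern %in% c("inclusion", "exclusion"),
        nmd_role = ifelse(pattern %in% c("inclusion", "exclusion"),
                          pattern, NA_character_))
    }
    list(models = bind_rows(models), children = bind_rows(children),
         events = bind_rows(events), truth = bind_rows(truth))
  })
}

#' Simulate per-sample informative read counts for splicing events
#'
#' Draws informative reads binomially: each event/sample receives `depth`
#' informative reads, and a read is an inclusion read with probability
#' implied by the true PSI and the two isoforms' informative-position
#' counts, \eqn{p = \Psi p_i / (\Psi p_i + (1-\Psi) p_e)} -- the inverse of
#' the length-normalized PSI estimator, so [estimate_psi()] is unbiased for
#' the planted truth.
#'
#' @param plan Tibble with `event_id`, `psi_a`, `psi_b` (true PSI per
#'   group), and optionally `positions_inclusion`, `positions_exclusion`
#'   (defaults 2 and 1, the cassette-exon junction geometry).
#' @param samples_a,samples_b Sample ids for the two groups.
#' @param depth Informative reads per event and sample.
#' @param seed Integer seed.
#' @return A long counts tibble (`event_id`, `sample_id`, `role`, `reads`,
#'   `positions`) ready for [estimate_psi()].
#' @export
sim_event_counts <- function(plan, samples_a, samples_b, depth = 200L,
                             seed = NULL) {
  if (!"positions_inclusion" %in% names(plan)) plan$positions_inclusion <- 2L
  if (!"positions_exclusion" %in% names(plan)) plan$positions_exclusion <- 1L
  .with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(plan)), function(i) {
      pi_ <- plan$positions_inclusion[i]; pe <- plan$positions_exclusion[i]
      one_group <- function(psi, samples) {
        p_inc <- psi * pi_ / (psi * pi_ + (1 - psi) * pe)
        inc <- rbinom(length(samples), depth, p_inc)
        tibble(event_id = plan$event_id[i],
               sample_id = rep(samples, 2L),
               role = rep(c("inclusion", "exclusion"),
                          each = length(samples)),
               reads = c(inc, depth - inc),
               positions = rep(c(pi_, pe), each = length(samples)))
      }
      bind_rows(one_group(plan$psi_a[i], samples_a),
                one_group(plan$psi_b[i], samples_b))
    })
    bind_rows(rows)
  })
}

# ---- alignment-level simulation -------------------------------------------

#' Toy target loci for pileup simulations
#'
#' Two small loci standing in for the UPF1 and KRAS target regions of the
#' matched tumor-normal reanalysis, each its own contig.
#'
#' @param locus_length Length of each locus (nt).
#' @return A loci tibble (`name`, `chrom`, `start`, `end`).
#' @export
sim_target_loci <- function(locus_length = 400L) {
  tibble(name = c("UPF1", "KRAS"),
         chrom = c("upf1_locus", "kras_locus"),
         start = c(1L, 1L), end = c(locus_length, locus_length))
}

#' Simulate a reference genome for a set of loci
#'
#' @param loci Loci tibble (`chrom`, `end` define contig sizes).
#' @param seed Integer seed.
#' @param path Optional FASTA output path.
#' @return Named character vector of contig sequences (and the FASTA file
#'   when `path` is given).
#' @export
sim_reference <- function(loci, seed = NULL, path = NULL) {
  .with_seed(seed, {
    contigs <- vapply(split(loci, loci$chrom), function(l) {
      .rand_seq(max(l$end))
    }, character(1))
    if (!is.null(path)) {
      writeLines(unlist(lapply(names(contigs), function(ch) {
        c(paste0(">", ch), contigs[[ch]])
      })), path)
    }
    contigs
  })
}

.write_sam <- function(reads, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(contigs), "\tLN:", nchar(contigs)))
  reads <- reads[order(match(reads$chrom, names(contigs)), reads$pos), ,
                 drop = FALSE]
  body <- if (nrow(reads) == 0L) character(0) else paste(
    reads$qname, 0L, reads$chrom, reads$pos, 60L, reads$cigar,
    "*", 0L, 0L, reads$seq, "*", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate aligned reads over loci with planted variants
#'
#' Tiles fixed-length reads over each locus (uniform random starts at the
#' requested mean depth) and plants single-nucleotide variants: each read
#' covering a planted position carries the alternate base with probability
#' `vaf`, so pileup allele counts are Binomial(coverage, vaf). An optional
#' per-base substitution error rate stresses the minimum-alt-read
#' threshold; it is off by default so that the thresholds themselves are
#' the object under test.
#'
#' @param reference Named character vector from [sim_reference()].
#' @param loci Loci tibble.
#' @param variants Tibble `chrom`, `pos`, `alt`, `vaf` (may be empty).
#' @param depth Mean coverage.
#' @param read_length Read length (default 50 nt).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Integer seed.
#' @param path SAM output path.
#' @return `path`, invisibly.
#' @export
sim_locus_sam <- function(reference, loci, variants, depth = 60L,
                          read_length = 50L, error_rate = 0,
                          seed = NULL, path) {
  if (nrow(variants) > 0) {
    if (any(variants$vaf > 1 | variants$vaf < 0)) stop("vaf must be in [0,1]")
    ok <- vapply(seq_len(nrow(variants)), function(i) {
      any(loci$chrom == variants$chrom[i] &
            loci$start <= variants$pos[i] & loci$end >= variants$pos[i])
    }, logical(1))
    if (!all(ok)) stop("planted variant position outside all loci")
  }
  .with_seed(seed, {
    all_reads <- purrr::map(seq_len(nrow(loci)), function(i) {
      ch <- loci$chrom[i]
      L <- loci$end[i] - loci$start[i] + 1L
      n_reads <- max(1L, round(depth * L / read_length))
      starts <- loci$start[i] +
        sample.int(L - read_length + 1L, n_reads, replace = TRUE) - 1L
      seqs <- substring(reference[[ch]], starts, starts + read_length - 1L)
      vv <- variants[variants$chrom == ch, , drop = FALSE]
      if (nrow(vv) > 0 || error_rate > 0) {
        mat <- strsplit(seqs, "", fixed = TRUE)
        if (nrow(vv) > 0) {
          for (v in seq_len(nrow(vv))) {
            cover <- which(starts <= vv$pos[v] &
                             starts + read_length - 1L >= vv$pos[v])
            carry <- cover[runif(length(cover)) < vv$vaf[v]]
            for (r in carry) mat[[r]][vv$pos[v] - starts[r] + 1L] <- vv$alt[v]
          }
        }
        if (error_rate > 0) {
          for (r in seq_along(mat)) {
            err <- which(runif(read_length) < error_rate)
            for (e in err) {
              mat[[r]][e] <- sample(setdiff(c("A", "C", "G", "T"),
                                            mat[[r]][e]), 1)
            }
          }
        }
        seqs <- vapply(mat, paste, character(1), collapse = "")
      }
      tibble(qname = sprintf("%s_r%06d", ch, seq_len(n_reads)),
             chrom = ch, pos = starts,
             cigar = paste0(read_length, "M"), seq = seqs)
    })
    .write_sam(bind_rows(all_reads), reference, path)
  })
}

#' Simulate a matched tumor/normal pair with planted variants
#'
#' Plants germline variants in both samples and somatic variants in the
#' tumor only, then writes one SAM per sample. The downstream caller should
#' recover every somatic plant and subtract every germline plant.
#'
#' @param variant_plan Tibble `chrom`, `pos`, `alt`, `vaf`, `is_germline`.
#' @param reference Named character vector from [sim_reference()].
#' @param loci Loci tibble.
#' @param depth Mean coverage per sample.
#' @param read_length,error_rate Passed to [sim_locus_sam()].
#' @param dir Output directory.
#' @param prefix File-name prefix (e.g. a patient id).
#' @param seed Integer seed.
#' @return A list with `tumor_sam`, `normal_sam`, and the validated
#'   `variant_plan` (with `ref` filled in from the reference).
#' @export
sim_tumor_normal_pair <- function(variant_plan, reference, loci,
                                  depth = 60L, read_length = 50L,
                                  error_rate = 0, dir = tempdir(),
                                  prefix = "patient", seed = NULL) {
  variant_plan$ref <- vapply(seq_len(nrow(variant_plan)), function(i) {
    substring(reference[[variant_plan$chrom[i]]],
              variant_plan$pos[i], variant_plan$pos[i])
  }, character(1))
  if (any(variant_plan$ref == variant_plan$alt)) {
    stop("planted alt equals the reference base; choose a different alt")
  }
  tumor <- file.path(dir, paste0(prefix, "_tumor.sam"))
  normal <- file.path(dir, paste0(prefix, "_normal.sam"))
  s1 <- if (is.null(seed)) NULL else seed
  s2 <- if (is.null(seed)) NULL else seed + 1L
  sim_locus_sam(reference, loci, variant_plan, depth, read_length,
                error_rate, seed = s1, path = tumor)
  sim_locus_sam(reference, loci,
                variant_plan[variant_plan$is_germline, , drop = FALSE],
                depth, read_length, error_rate, seed = s2, path = normal)
  list(tumor_sam = tumor, normal_sam = normal, variant_plan = variant_plan)
}

#' Write a SAM of event-supporting junction reads
#'
#' Emits gapped alignments that are informative for each child isoform of
#' the simulated events (read starts drawn uniformly from that child's
#' informative start positions), plus optional uninformative reads placed
#' in shared exons. Used to test informative-read counting against exact
#' planted counts.
#'
#' @param sim Output of [sim_splicing_events()].
#' @param reads_per_child Named vector, e.g.
#'   `c(inclusion = 7, exclusion = 3)`.
#' @param n_uninformative Reads placed entirely within a shared exon.
#' @param read_length Read length.
#' @param path SAM output path.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
sim_event_sam <- function(sim, reads_per_child, n_uninformative = 0L,
                          read_length = 50L, path, seed = NULL) {
  .with_seed(seed, {
    reads <- list()
    contig_len <- integer(0)
    for (ev in split(sim$children, sim$children$event_id)) {
      child_tx <- lapply(ev$transcript_id, function(tx) {
        .tx_order(as.data.frame(
          sim$models[sim$models$transcript_id == tx, ]))
      })
      chrom <- child_tx[[1]]$chrom[1]
      contig_len[chrom] <- max(unlist(lapply(child_tx,
                                             function(e) e$end))) + 100L
      for (ci in seq_along(child_tx)) {
        ex <- child_tx[[ci]]
        L <- sum(.exon_widths(ex))
        inf_starts <- integer(0)
        for (s in seq_len(max(L - read_length + 1L, 0L))) {
          bl <- .tx_interval_blocks(s, s + read_length - 1L, ex)
          if (nrow(bl) > 1L) {
            is_ <- bl$end[-nrow(bl)] + 1L; ie <- bl$start[-1] - 1L
          } else { is_ <- integer(0); ie <- integer(0) }
          compat <- vapply(child_tx, function(other) {
            .read_compatible(bl$start, bl$end, is_, ie, other)
          }, logical(1))
          if (sum(compat) == 1L && compat[ci]) {
            inf_starts <- c(inf_starts, s)
          }
        }
        n_r <- reads_per_child[[ev$role[ci]]]
        if (n_r > 0L && length(inf_starts) > 0L) {
          starts <- .sample_from(inf_starts, n_r, replace = TRUE)
          for (k in seq_along(starts)) {
            bl <- .tx_interval_blocks(starts[k], starts[k] + read_length - 1L,
                                      ex)
            cig <- .blocks_to_cigar(bl)
            reads[[length(reads) + 1L]] <- tibble(
              qname = sprintf("%s_%s_%03d", ev$event_id[1], ev$role[ci], k),
              chrom = chrom, pos = bl$start[1], cigar = cig,
              seq = strrep("A", read_length))
          }
        }
      }
      if (n_uninformative > 0L) {
        # place reads inside the genomic intersection of every child's
        # 5'-most exon, where they distinguish nothing
        firsts <- do.call(rbind, lapply(child_tx, function(e) {
          c(e$start[1], e$end[1])
        }))
        s0 <- max(firsts[, 1]); e0 <- min(firsts[, 2])
        if (e0 - s0 + 1L >= read_length) {
          for (k in seq_len(n_uninformative)) {
            s <- s0 + sample.int(e0 - s0 - read_length + 2L, 1) - 1L
            reads[[length(reads) + 1L]] <- tibble(
              qname = sprintf("%s_shared_%03d", ev$event_id[1], k),
              chrom = chrom, pos = s, cigar = paste0(read_length, "M"),
              seq = strrep("A", read_length))
          }
        }
      }
    }
    contigs <- vapply(contig_len, function(l) strrep("N", l), character(1))
    .write_sam(bind_rows(reads), contigs, path)
  })
}

.blocks_to_cigar <- function(bl) {
  parts <- character(0)
  for (k in seq_len(nrow(bl))) {
    parts <- c(parts, paste0(bl$end[k] - bl$start[k] + 1L, "M"))
    if (k < nrow(bl)) {
      parts <- c(parts, paste0(bl$start[k + 1L] - bl$end[k] - 1L, "N"))
    }
  }
  paste(parts, collapse = "")
}

#' Simulate reported mutations across a patient cohort
#'
#' Draws distinct single-nucleotide "reported mutations" on a toy locus and
#' assigns them to patients so that every patient carries at least one.
#'
#' @param n_mutations,n_patients Cohort dimensions (e.g. 40 mutations over
#'   18 patients).
#' @param chrom Contig name.
#' @param region_length Positions are drawn from `1:region_length`.
#' @param intronic_fraction Fraction labeled `intronic` (rest `exonic`).
#' @param seed Integer seed.
#' @return A mutations tibble (`patient_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `context`, `label`).
#' @export
sim_reported_mutations <- function(n_mutations = 40L, n_patients = 18L,
                                   chrom = "upf1_locus",
                                   region_length = 2000L,
                                   intronic_fraction = 0.6,
                                   seed = NULL) {
  stopifnot(n_mutations >= n_patients)
  .with_seed(seed, {
    pos <- sort(sample.int(region_length, n_mutations))
    ref <- sample(c("A", "C", "G", "T"), n_mutations, replace = TRUE)
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1))
    patients <- sprintf("P%02d", seq_len(n_patients))
    assign <- c(patients,
                .sample_from(patients, n_mutations - n_patients, replace = TRUE))
    assign <- sample(assign)
    tibble(
      patient_id = assign, chrom = chrom, pos = pos, ref = ref, alt = alt,
      context = sample(c("intronic", "exonic"), n_mutations, replace = TRUE,
                       prob = c(intronic_fraction, 1 - intronic_fraction)),
      label = sprintf("g.%d%s>%s", pos, ref, alt)
    )
  })
}

#' Generate a population-variant catalog VCF with controlled overlap
#'
#' Writes a toy catalog engineered so that exactly
#' `round(overlap_fraction * n)` of the supplied mutations have exact-allele
#' entries, a further `position_only_fraction` of the remainder have an
#' entry at the same position with a *different* alternate allele, and
#' `n_padding` unrelated entries pad the file. Ground truth (which mutation
#' indices were matched) is returned.
#'
#' @param mutations Mutations tibble (see [sim_reported_mutations()]).
#' @param overlap_fraction Target exact-match fraction.
#' @param position_only_fraction Fraction of unmatched mutations given
#'   position-only entries.
#' @param n_padding Unrelated catalog entries.
#' @param match_idx Optional explicit row indices to match exactly
#'   (overrides `overlap_fraction`).
#' @param path VCF output path.
#' @param source Catalog name written into the file.
#' @param seed Integer seed.
#' @return A list: `path`, `exact_idx`, `position_only_idx`, and the
#'   catalog tibble as written.
#' @export
sim_variant_catalog <- function(mutations, overlap_fraction = 0.45,
                                position_only_fraction = 0.2,
                                n_padding = 10L, match_idx = NULL,
                                path, source = "synthetic_catalog",
                                seed = NULL) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  .with_seed(seed, {
    n <- nrow(mutations)
    if (is.null(match_idx)) {
      k <- round(overlap_fraction * n)
      match_idx <- sort(sample.int(n, k))
    }
    rest <- setdiff(seq_len(n), match_idx)
    pos_idx <- sort(.sample_from(rest, round(position_only_fraction * length(rest))))
    entries <- list()
    if (length(match_idx) > 0) {
      entries$exact <- mutations[match_idx, ] |>
        select("chrom", "pos", "ref", "alt")
    }
    if (length(pos_idx) > 0) {
      mm <- mutations[pos_idx, , drop = FALSE]
      other_alt <- vapply(seq_len(nrow(mm)), function(j) {
        sample(setdiff(c("A", "C", "G", "T"), c(mm$ref[j], mm$alt[j])), 1)
      }, character(1))
      entries$pos_only <- mm |>
        mutate(alt = other_alt) |>
        select("chrom", "pos", "ref", "alt")
    }
    if (n_padding > 0) {
      used <- unique(mutations$pos)
      pool <- setdiff(seq_len(max(mutations$pos) + 5000L), used)
      pad_pos <- sort(sample(pool, n_padding))
      pad_ref <- sample(c("A", "C", "G", "T"), n_padding, replace = TRUE)
      entries$pad <- tibble(
        chrom = mutations$chrom[1], pos = pad_pos, ref = pad_ref,
        alt = vapply(pad_ref, function(r) {
          sample(setdiff(c("A", "C", "G", "T"), r), 1)
        }, character(1)))
    }
    cat_tbl <- bind_rows(entries) |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      arrange(.data$chrom, .data$pos) |>
      mutate(source = source, af = round(runif(n(), 0.0005, 0.2), 5))
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##source=", source),
             "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- paste(cat_tbl$chrom, cat_tbl$pos, ".", cat_tbl$ref, cat_tbl$alt,
                  ".", "PASS", sprintf("AF=%g", cat_tbl$af), sep = "\t")
    writeLines(c(hdr, body), path)
    list(path = path, exact_idx = match_idx, position_only_idx = pos_idx,
         catalog = cat_tbl)
  })
}
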