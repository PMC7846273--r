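# Independent brute-force oracles. These deliberately share no code with the
# package internals: sequences are spelled out base by base, codons scanned
# in a loop, junction pairs enumerated with a double loop.

# NMD status from raw sequence: spell the spliced mRNA, find the 5'-most AUG,
# walk codons to the first in-frame stop, and measure the distance from the
# stop codon's last base to the final junction directly.
oracle_nmd <- function(exons, genome_vec) {
  strand <- exons$strand[1]
  chrom <- exons$chrom[1]
  ord <- exons[order(exons$start), , drop = FALSE]
  chars <- strsplit(genome_vec[[chrom]], "", fixed = TRUE)[[1]]
  plus_seq <- unlist(lapply(seq_len(nrow(ord)), function(i) {
    chars[ord$start[i]:ord$end[i]]
  }))
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    mrna <- rev(unname(comp[plus_seq]))
  } else {
    mrna <- plus_seq
  }
  L <- length(mrna)
  w <- ord$end - ord$start + 1L
  if (strand == "-") w <- rev(w)
  multi <- length(w) >= 2L
  last_junc <- if (multi) sum(w) - w[length(w)] else NA_integer_
  a <- NA_integer_
  for (i in seq_len(max(L - 2L, 0L))) {
    if (mrna[i] == "A" && mrna[i + 1L] == "T" && mrna[i + 2L] == "G") {
      a <- i; break
    }
  }
  if (is.na(a)) {
    return(list(is_nmd = FALSE, distance = NA_integer_, status = "no_orf"))
  }
  stop_last <- NA_integer_
  i <- a + 3L
  while (i + 2L <= L) {
    cod <- paste0(mrna[i], mrna[i + 1L], mrna[i + 2L])
    if (cod %in% c("TAA", "TAG", "TGA")) { stop_last <- i + 2L; break }
    i <- i + 3L
  }
  if (is.na(stop_last)) {
    return(list(is_nmd = FALSE, distance = NA_integer_, status = "no_orf"))
  }
  d <- if (multi) last_junc - stop_last else NA_integer_
  list(is_nmd = !is.na(d) && d > 50L, distance = d, status = "ok")
}

# All co-linear donor/acceptor pairs of one gene by explicit double loop.
oracle_junctions <- function(gene_models) {
  donors <- integer(0); acceptors <- integer(0)
  strand <- gene_models$strand[1]
  for (tx in split(gene_models, gene_models$transcript_id)) {
    o <- tx[order(tx$start), , drop = FALSE]
    if (nrow(o) < 2L) next
    if (strand == "+") {
      donors <- c(donors, o$end[-nrow(o)])
      acceptors <- c(acceptors, o$start[-1])
    } else {
      donors <- c(donors, o$start[-1])
      acceptors <- c(acceptors, o$end[-nrow(o)])
    }
  }
  donors <- unique(donors); acceptors <- unique(acceptors)
  out <- matrix(integer(0), ncol = 2)
  for (d in donors) {
    for (a in acceptors) {
      ok <- if (strand == "+") a > d else a < d
      if (ok) out <- rbind(out, c(d, a))
    }
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Textbook pooled two-sample t-test p-value.
oracle_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}

# Exact two-sided Fisher p by enumerating all 2x2 tables with the observed
# margins and summing probabilities no larger than the observed table's.
oracle_fisher_p <- function(k1, n1, k2, n2) {
  k_total <- k1 + k2
  lo <- max(0L, k_total - n2); hi <- min(n1, k_total)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(n1, x) + lchoose(n2, k_total - x) -
          lchoose(n1 + n2, k_total))
  }, numeric(1))
  obs <- probs[k1 - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Minimal hand-written SAM file.
write_test_sam <- function(path, contigs, records) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(contigs), "\tLN:", contigs))
  writeLines(c(hdr, records), path)
  path
}

# Mirror a gene's coordinates around a point and flip its strand; the
# transcript's spliced structure (and hence every classification) must be
# unchanged.
mirror_models <- function(models, m = max(models$end) + 17L) {
  out <- models
  out$start <- m - models$end
  out$end <- m - models$start
  out$strand <- ifelse(models$strand == "+", "-", "+")
  if ("cds_start" %in% names(models)) {
    out$cds_start <- m - models$cds_end
    out$cds_end <- m - models$cds_start
  }
  out[order(out$transcript_id, out$start), ]
}
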