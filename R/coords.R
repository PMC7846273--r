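# Internal coordinate helpers.
#
# All genomic coordinates in this package are 1-based and closed, the native
# convention of R/Bioconductor containers and of GTF/SAM/VCF once imported
# through rtracklayer/Rsamtools/vcfR. Transcript ("spliced") coordinates are
# 1-based offsets along the mature mRNA, 5'->3'.

# order exon rows of one transcript 5'->3' in transcript orientation
.tx_order <- function(exons) {
  stopifnot(length(unique(exons$strand)) == 1L)
  if (exons$strand[1] == "+") {
    exons[order(exons$start), , drop = FALSE]
  } else {
    exons[order(exons$start, decreasing = TRUE), , drop = FALSE]
  }
}

.exon_widths <- function(exons) exons$end - exons$start + 1L

# map a genomic position to its spliced (transcript) coordinate;
# exons must already be in transcript order. NA when not exonic.
.genomic_to_tx <- function(pos, exons) {
  w <- .exon_widths(exons)
  before <- cumsum(c(0L, w[-length(w)]))
  hit <- which(pos >= exons$start & pos <= exons$end)
  if (length(hit) == 0L) return(NA_integer_)
  hit <- hit[1]
  off <- if (exons$strand[1] == "+") pos - exons$start[hit] + 1L
         else exons$end[hit] - pos + 1L
  as.integer(before[hit] + off)
}

# map a spliced coordinate back to genomic; exons in transcript order
.tx_to_genomic <- function(txpos, exons) {
  w <- .exon_widths(exons)
  ends <- cumsum(w)
  hit <- which(txpos <= ends)[1]
  if (is.na(hit)) return(NA_integer_)
  before <- c(0L, ends)[hit]
  off <- txpos - before
  if (exons$strand[1] == "+") as.integer(exons$start[hit] + off - 1L)
  else as.integer(exons$end[hit] - off + 1L)
}

# genomic blocks covered by a spliced interval [tx_start, tx_end]
# (used to lay a read of given length over an isoform); returns a data frame
# of genomic start/end in genomic (left-to-right) order
.tx_interval_blocks <- function(tx_start, tx_end, exons) {
  w <- .exon_widths(exons)
  ends <- cumsum(w)
  starts <- c(0L, ends[-length(ends)]) + 1L
  keep <- which(ends >= tx_start & starts <= tx_end)
  blocks <- lapply(keep, function(i) {
    s <- max(tx_start, starts[i]) - starts[i] + 1L  # offset within exon i
    e <- min(tx_end, ends[i]) - starts[i] + 1L
    if (exons$strand[1] == "+") {
      c(exons$start[i] + s - 1L, exons$start[i] + e - 1L)
    } else {
      c(exons$end[i] - e + 1L, exons$end[i] - s + 1L)
    }
  })
  m <- do.call(rbind, blocks)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

# introns of one transcript as a data frame with donor/acceptor genomic
# coordinates (donor = last exonic base of the upstream exon in transcript
# orientation, acceptor = first exonic base of the downstream exon)
.tx_introns <- function(exons) {
  ex <- .tx_order(exons)
  n <- nrow(ex)
  if (n < 2L) {
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      left = integer(0), right = integer(0)))
  }
  if (ex$strand[1] == "+") {
    donor <- ex$end[-n]
    acceptor <- ex$start[-1]
    data.frame(donor = donor, acceptor = acceptor,
               left = donor, right = acceptor)
  } else {
    donor <- ex$start[-n]
    acceptor <- ex$end[-1]
    data.frame(donor = donor, acceptor = acceptor,
               left = acceptor, right = donor)
  }
}

# fetch a genome as a named list of character strings from a FASTA path,
# DNAStringSet, or named character vector
.load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    names(ss) <- sub("\\s.*$", "", names(ss))
    return(stats::setNames(as.character(ss), names(ss)))
  }
  if (methods::is(genome, "DNAStringSet")) {
    return(stats::setNames(as.character(genome), sub("\\s.*$", "", names(genome))))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("`genome` must be a FASTA path, a DNAStringSet, or a named character vector")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# spliced mRNA sequence of a transcript given a loaded genome
.spliced_seq <- function(exons, genome) {
  ex <- .tx_order(exons)
  chrom <- ex$chrom[1]
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' absent from the supplied genome")
  }
  seqs <- substring(genome[[chrom]], ex$start, ex$end)
  if (ex$strand[1] == "+") paste(seqs, collapse = "")
  else paste(vapply(seqs, .revcomp, character(1)), collapse = "")
}

# coerce a SAM (or BAM) path to an indexed BAM, converting in tempdir
.as_indexed_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}
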