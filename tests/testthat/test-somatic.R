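toy_loci <- function(len = 60L) {
  tibble::tibble(name = "L", chrom = "c", start = 1L, end = len)
}

test_that("pileup counts planted alternate bases and excludes deletion-spanning reads", {
  ref <- c(c = strrep("G", 60))
  loci <- toy_loci()
  # 12 full-match 20M reads over pos 10; 3 carry G->A at pos 10;
  # 1 extra read whose deletion spans pos 10
  recs <- character(0)
  for (i in 1:12) {
    seq <- strrep("G", 20)
    if (i <= 3) substr(seq, 10, 10) <- "A"
    recs <- c(recs, paste("r", i, sep = "", collapse = "") |>
                paste(0, "c", 1, 60, "20M", "*", 0, 0, seq, "*", sep = "\t"))
  }
  recs <- c(recs, paste("rdel", 0, "c", 5, 60, "4M3D13M", "*", 0, 0,
                        strrep("G", 17), "*", sep = "\t"))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, c(c = 60L), recs)
  p <- pileup_region(sam, loci, ref)
  at10 <- p[p$pos == 10L, ]
  expect_equal(at10$depth, 12L)  # deletion read contributes nothing at 10
  expect_equal(at10$A, 3L)
  expect_equal(at10$G, 9L)
  at12 <- p[p$pos == 12L, ]     # deletion read back in at 12 (resumes at 12)
  expect_equal(at12$depth, 13L)
  expect_equal(nrow(p), 60L)    # every locus position present
})

test_that("reference must cover the locus", {
  sam <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(sam, c(c = 60L), character(0))
  expect_error(pileup_region(sam, toy_loci(), c(c = strrep("A", 10))),
               "cover")
})

test_that("calling thresholds behave exactly at the decision boundary", {
  mk <- function(depth, altc) {
    tibble::tibble(locus = "L", chrom = "c", pos = 1L, ref = "G",
                   A = altc, C = 0L, G = depth - altc, T = 0L, depth = depth)
  }
  expect_equal(nrow(call_variants(mk(9L, 2L))), 1L)   # both at equality
  expect_equal(nrow(call_variants(mk(8L, 3L))), 0L)   # depth 8
  expect_equal(nrow(call_variants(mk(9L, 1L))), 0L)   # single alt read
  expect_equal(nrow(call_variants(mk(100L, 1L))), 0L)
  got <- call_variants(mk(9L, 2L))
  expect_equal(got$vaf, 2 / 9)
  # multiple alts evaluated independently
  multi <- tibble::tibble(locus = "L", chrom = "c", pos = 1L, ref = "G",
                          A = 3L, C = 2L, G = 10L, T = 1L, depth = 16L)
  expect_equal(sort(call_variants(multi)$alt), c("A", "C"))
})

test_that("raising thresholds never increases the number of calls", {
  sim <- sim_reference(toy_loci(400L), seed = 71)
  pile <- tibble::tibble(
    locus = "L", chrom = "c", pos = 1:400,
    ref = "G",
    A = rpois(400, 1.2), C = rpois(400, 0.6), G = 30L, T = rpois(400, 0.3))
  pile$depth <- pile$A + pile$C + pile$G + pile$T
  base <- nrow(call_variants(pile, 9L, 2L))
  for (md in c(9L, 15L, 25L)) {
    for (ma in c(2L, 3L, 5L)) {
      expect_lte(nrow(call_variants(pile, md, ma)), base)
    }
  }
  # VAF of every call within [min_alt/depth, 1]
  calls <- call_variants(pile, 9L, 2L)
  expect_true(all(calls$vaf >= 2 / calls$depth - 1e-12 & calls$vaf <= 1))
})

test_that("matched-normal subtraction distinguishes somatic, germline, and low-coverage sites", {
  tcalls <- tibble::tibble(locus = "L", chrom = "c", pos = c(10L, 20L, 30L),
                           ref = "G", alt = "A", depth = 50L,
                           alt_count = 15L, vaf = 0.3)
  npile <- tibble::tibble(
    locus = "L", chrom = "c", pos = c(10L, 20L, 30L), ref = "G",
    A = c(0L, 20L, 1L), C = 0L, G = c(50L, 30L, 3L), T = 0L,
    depth = c(50L, 50L, 4L))
  out <- subtract_matched_normal(tcalls, npile, patient_id = "p7")
  expect_equal(out$normal_status, c("absent", "present", "low_coverage"))
  expect_equal(out$is_somatic, c(TRUE, FALSE, TRUE))
  expect_error(subtract_matched_normal(tcalls, NULL), "normal")
})

test_that("planted somatic variants are recovered and germline variants subtracted", {
  loci <- sim_target_loci(300L)
  ref <- sim_reference(loci, seed = 81)
  n_pat <- 15L
  n_somatic_found <- 0L; n_germ_leaked <- 0L; n_control <- 0L
  for (p in seq_len(n_pat)) {
    alt_at <- function(ch, pos) {
      setdiff(c("A", "C", "G", "T"),
              substring(ref[[ch]], pos, pos))[1]
    }
    plan <- tibble::tibble(
      chrom = c("upf1_locus", "upf1_locus", "kras_locus"),
      pos = c(50L + p, 200L, 100L),
      vaf = c(0.3, 0.5, 0.4),
      is_germline = c(FALSE, TRUE, FALSE))
    plan$alt <- vapply(seq_len(3), function(i) alt_at(plan$chrom[i], plan$pos[i]),
                       character(1))
    pair <- sim_tumor_normal_pair(plan, ref, loci, depth = 40L,
                                  dir = withr::local_tempdir(),
                                  prefix = paste0("p", p), seed = 900 + p)
    tp <- pileup_region(pair$tumor_sam, loci, ref)
    np <- pileup_region(pair$normal_sam, loci, ref)
    sc <- subtract_matched_normal(call_variants(tp), np,
                                  patient_id = paste0("p", p))
    som <- sc[sc$is_somatic, ]
    planted_som <- plan[!plan$is_germline, ]
    n_somatic_found <- n_somatic_found +
      sum(paste(planted_som$chrom, planted_som$pos, planted_som$alt) %in%
            paste(som$chrom, som$pos, som$alt))
    germ <- plan[plan$is_germline, ]
    n_germ_leaked <- n_germ_leaked +
      sum(paste(germ$chrom, germ$pos, germ$alt) %in%
            paste(som$chrom, som$pos, som$alt))
    n_control <- n_control + any(som$chrom == "kras_locus" & som$pos == 100L)
  }
  expect_equal(n_somatic_found, 2L * n_pat)  # every somatic plant recovered
  expect_equal(n_germ_leaked, 0L)            # no germline leakage
  expect_equal(n_control, n_pat)             # control variant seen everywhere
})

test_that("sensitivity calibration names failing samples and validates control sites", {
  calls <- tibble::tibble(chrom = "kras_locus", pos = 100L, alt = "A",
                          is_somatic = TRUE, patient_id = "p1")
  loci <- sim_target_loci(300L)
  sites <- tibble::tibble(chrom = "kras_locus", pos = 100L)
  cal <- calibrate_sensitivity(calls, sites, samples = c("p1", "p2"),
                               loci = loci)
  expect_false(attr(cal, "overall_pass"))
  expect_equal(glance(cal)$failed_samples, "p2")
  cal1 <- calibrate_sensitivity(calls, sites, samples = "p1", loci = loci)
  expect_true(attr(cal1, "overall_pass"))
  expect_error(calibrate_sensitivity(calls, sites, samples = character(0)),
               "empty")
  expect_error(
    calibrate_sensitivity(calls, tibble::tibble(chrom = "nowhere", pos = 1L),
                          samples = "p1", loci = loci),
    "outside")
})

test_that("per-gene VAF medians use the midpoint convention", {
  calls <- tibble::tibble(
    locus = c("UPF1", "UPF1", "UPF1", "KRAS"),
    vaf = c(0.1, 0.2, 0.3, 0.34), is_somatic = TRUE)
  s <- summarize_af(calls)
  expect_equal(s$median_vaf[s$gene == "UPF1"], 0.2)
  expect_equal(s$median_vaf[s$gene == "KRAS"], 0.34)
  even <- tibble::tibble(locus = "UPF1", vaf = c(0.1, 0.3), is_somatic = TRUE)
  expect_equal(summarize_af(even)$median_vaf, 0.2)
  expect_warning(summarize_af(calls[0, ]), "no somatic")
})

test_that("somatic VCF output round-trips through a standard VCF reader", {
  calls <- tibble::tibble(
    locus = "UPF1", chrom = "chr19", pos = c(18941000L, 18950000L),
    ref = c("G", "C"), alt = c("A", "T"), depth = c(25L, 40L),
    alt_count = c(5L, 12L), vaf = c(0.2, 0.3),
    normal_status = c("absent", "low_coverage"), is_somatic = TRUE)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_somatic_vcf(calls, vcf)
  back <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(back, getINFO = TRUE)
  expect_equal(as.integer(fix[, "POS"]), calls$pos)
  expect_equal(fix[, "REF"], calls$ref, ignore_attr = TRUE)
  expect_equal(fix[, "ALT"], calls$alt, ignore_attr = TRUE)
  expect_match(fix[1, "INFO"], "DP=25;ALTC=5;VAF=0.2;NORMAL_STATUS=absent")
})
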