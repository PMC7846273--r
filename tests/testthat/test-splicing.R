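make_counts <- function(event_id, inc_reads, exc_reads, samples,
                        pos_inc = 1L, pos_exc = 1L) {
  tibble::tibble(
    event_id = event_id,
    sample_id = rep(samples, 2L),
    role = rep(c("inclusion", "exclusion"), each = length(samples)),
    reads = c(inc_reads, exc_reads),
    positions = rep(c(pos_inc, pos_exc), each = length(samples)))
}

test_that("informative-read counting recovers planted junction reads and ignores shared-exon reads", {
  ev <- sim_splicing_events(2, seed = 11, minus_prob = 0.5)
  sam <- withr::local_tempfile(fileext = ".sam")
  sim_event_sam(ev, reads_per_child = c(inclusion = 7, exclusion = 3),
                n_uninformative = 5, path = sam, seed = 12)
  cts <- suppressMessages(
    count_informative_reads(sam, ev$models, ev$children))
  expect_equal(nrow(cts), 4L)
  expect_equal(cts$reads[cts$role == "inclusion"], c(7L, 7L))
  expect_equal(cts$reads[cts$role == "exclusion"], c(3L, 3L))
  expect_true(all(cts$positions >= 1L))
})

test_that("junction-level read support matches planted reads", {
  ev <- sim_splicing_events(1, seed = 21, types = "SE", minus_prob = 0)
  sam <- withr::local_tempfile(fileext = ".sam")
  sim_event_sam(ev, reads_per_child = c(inclusion = 6, exclusion = 4),
                path = sam, seed = 22)
  jx <- enumerate_junctions(ev$models)
  support <- count_junction_reads(sam, jx)
  # the skipping junction (largest span) carries exactly the 4 exclusion reads
  skip <- support[which.max(abs(support$acceptor - support$donor)), ]
  expect_equal(skip$reads, 4L)
  # total junction-read incidences: inclusion reads cross one of 2 junctions,
  # exclusion reads cross the skip junction
  expect_equal(sum(support$reads), 6L + 4L)
})

test_that("PSI estimator follows the length-normalized count-ratio formula", {
  # all reads inclusion -> psi 1
  p1 <- estimate_psi(make_counts("e", 25L, 0L, "s"))
  expect_equal(p1$psi, 1)
  # symmetric counts and positions -> 0.5
  p2 <- estimate_psi(make_counts("e", 10L, 10L, "s"))
  expect_equal(p2$psi, 0.5)
  # inc 30 over 3 positions vs exc 10 over 1 position -> densities equal
  p3 <- estimate_psi(make_counts("e", 30L, 10L, "s", pos_inc = 3L))
  expect_equal(p3$psi, 0.5)
  # zero reads: undefined and flagged
  p0 <- estimate_psi(make_counts("e", 0L, 0L, "s"))
  expect_true(is.na(p0$psi))
  expect_equal(p0$status, "no_reads")
})

test_that("PSI recovery: mean estimate within 0.03 of truth across the PSI range", {
  truths <- seq(0.1, 0.9, by = 0.2)
  plan <- tibble::tibble(event_id = sprintf("t%02d", seq_along(truths)),
                         psi_a = truths, psi_b = truths)
  samples_a <- sprintf("a%03d", 1:50)
  counts <- sim_event_counts(plan, samples_a, "b_unused", depth = 200L,
                             seed = 31)
  est <- estimate_psi(counts) |>
    dplyr::filter(.data$sample_id %in% samples_a) |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(mean_psi = mean(.data$psi))
  expect_true(all(abs(est$mean_psi - truths) < 0.03))
})

test_that("the informative-read floor excludes events before testing", {
  samples <- c("a1", "a2", "a3", "b1", "b2", "b3")
  # one sample with 19 informative reads: excluded regardless of effect size
  counts <- make_counts("low", c(19L, 30L, 30L, 5L, 25L, 25L),
                        c(0L, 0L, 0L, 25L, 5L, 5L), samples)
  counts$reads[counts$sample_id == "a1" & counts$role == "inclusion"] <- 19L
  res <- test_differential(estimate_psi(counts), samples[1:3], samples[4:6])
  expect_false(res$passes_filter)
  expect_equal(res$reason, "low_reads")
  expect_true(is.na(res$p_value))
  # the same counts pass under the summed scope
  res2 <- test_differential(estimate_psi(counts), samples[1:3], samples[4:6],
                            min_reads_scope = "total")
  expect_false(is.na(res2$p_value))
})

test_that("a 10-percentage-point PSI change at small p passes; identical groups never do", {
  samples <- c("a1", "a2", "a3", "b1", "b2", "b3")
  counts <- make_counts("e", c(40L, 41L, 39L, 50L, 51L, 49L),
                        c(60L, 59L, 61L, 50L, 49L, 51L), samples)
  res <- test_differential(estimate_psi(counts), samples[1:3], samples[4:6])
  expect_equal(res$delta_psi, 0.10, tolerance = 1e-12)
  expect_true(res$p_value < 0.05)
  expect_true(res$passes_filter)

  same <- make_counts("e", rep(40L, 6), rep(60L, 6), samples)
  res0 <- test_differential(estimate_psi(same), samples[1:3], samples[4:6])
  expect_false(res0$passes_filter)
  expect_equal(res0$p_value, 1)
})

test_that("swapping group labels negates delta, inverts fold change, keeps p and verdict", {
  plan <- tibble::tibble(event_id = sprintf("s%02d", 1:10),
                         psi_a = 0.5, psi_b = c(rep(0.25, 5), rep(0.5, 5)))
  a <- sprintf("a%d", 1:3); b <- sprintf("b%d", 1:3)
  counts <- sim_event_counts(plan, a, b, depth = 150L, seed = 41)
  psi <- estimate_psi(counts)
  fwd <- test_differential(psi, a, b) |> dplyr::arrange(event_id)
  rev <- test_differential(psi, b, a) |> dplyr::arrange(event_id)
  expect_equal(fwd$delta_psi, -rev$delta_psi, tolerance = 1e-12)
  expect_equal(fwd$fold_change, 1 / rev$fold_change, tolerance = 1e-9)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  expect_equal(fwd$passes_filter, rev$passes_filter)
})

test_that("fold-change criterion is configurable between linear and log2 readings", {
  # delta psi below 0.10 but a >2x inclusion-density change
  samples <- c("a1", "a2", "a3", "b1", "b2", "b3")
  counts <- make_counts("e", c(4L, 5L, 4L, 11L, 12L, 12L),
                        c(96L, 95L, 96L, 89L, 88L, 88L), samples,
                        pos_inc = 1L, pos_exc = 1L)
  psi <- estimate_psi(counts)
  lin <- test_differential(psi, samples[1:3], samples[4:6], min_reads = 20L,
                           min_reads_scope = "total")
  expect_true(lin$fold_change > 2)
  expect_true(lin$effect_ok)
  # log2 reading requires |log2 fc| >= 2, i.e. a 4x change: not met here
  log2r <- test_differential(psi, samples[1:3], samples[4:6],
                             min_reads = 20L, min_reads_scope = "total",
                             fc_scale = "log2")
  expect_false(log2r$effect_ok)
})

test_that("null calibration: raw p <= 0.05 in about 5% of null events", {
  plan <- tibble::tibble(event_id = sprintf("n%04d", 1:500),
                         psi_a = 0.5, psi_b = 0.5)
  a <- sprintf("a%d", 1:3); b <- sprintf("b%d", 1:3)
  counts <- sim_event_counts(plan, a, b, depth = 100L, seed = 51)
  res <- test_differential(estimate_psi(counts), a, b)
  fpr <- mean(res$p_value <= 0.05, na.rm = TRUE)
  expect_gt(fpr, 0.02)
  expect_lt(fpr, 0.09)
})

test_that("burden table counts significant NMD-relevant U2 events once each, oriented by the NMD child", {
  events <- tibble::tibble(
    event_id = c("e1", "e2", "e3", "e4"),
    event_type = c("SE", "SE", "RI", "MXE"),
    intron_class = c("U2", "U2", "U2", "U12"),
    nmd_relevant = c(TRUE, TRUE, TRUE, TRUE),
    nmd_role = c("inclusion", "exclusion", "inclusion", "inclusion"))
  results <- tibble::tibble(
    event_id = c("e1", "e2", "e3", "e4"),
    delta_psi = c(0.3, 0.3, -0.2, 0.4),
    passes_filter = c(TRUE, TRUE, TRUE, TRUE))
  tab <- summarize_nmd_burden(results, events)
  expect_equal(tab$nmd_up[tab$event_type == "SE"], 1L)    # e1
  expect_equal(tab$nmd_down[tab$event_type == "SE"], 1L)  # e2: exclusion-NMD up
  expect_equal(tab$nmd_down[tab$event_type == "RI"], 1L)  # e3
  expect_equal(sum(tab$total), 3L)                        # e4 is U12: excluded

  empty <- summarize_nmd_burden(results[0, ], events)
  expect_equal(sum(empty$total), 0L)
  expect_equal(nrow(empty), 5L)
})

test_that("planted 3:1 down:up NMD shifts are recovered at the burden level", {
  ev <- sim_splicing_events(40, seed = 61, types = "SE",
                            pattern_weights = c(inclusion = 1, exclusion = 0,
                                                both = 0, neither = 0),
                            u12_fraction = 0, unknown_fraction = 0)
  # 30 events shift the (NMD) inclusion isoform down, 10 up
  plan <- tibble::tibble(
    event_id = ev$events$event_id,
    psi_a = 0.5,
    psi_b = c(rep(0.2, 30), rep(0.8, 10)))
  a <- sprintf("a%d", 1:3); b <- sprintf("b%d", 1:3)
  counts <- sim_event_counts(plan, a, b, depth = 200L, seed = 62)
  ann <- classify_nmd(ev$models)
  events <- annotate_events(ev$events |>
                              dplyr::select(-"nmd_relevant", -"nmd_role"),
                            ev$children, ann)
  res <- test_differential(estimate_psi(counts), a, b)
  tab <- summarize_nmd_burden(res, events)
  expect_equal(sum(tab$total), sum(res$passes_filter))
  expect_equal(tab$nmd_down[tab$event_type == "SE"], 30L)
  expect_equal(tab$nmd_up[tab$event_type == "SE"], 10L)
})
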