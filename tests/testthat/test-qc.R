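test_that("length filter applies inclusive marker bounds", {
  cnt <- matrix(100L, 5, 2, dimnames = list(NULL, c("p1", "p2")))
  x <- toy_table(cnt, lengths = c(50, 65, 131, 200, 201))
  r <- filter_length(x, 65, 200)
  expect_setequal(r$table$motus$length, c(65, 131, 200))
  expect_equal(r$report$motus_removed, 2)
  # Chlo02 bounds retain only the 65 bp MOTU
  b <- marker_length_bounds("Chlo02")
  r2 <- filter_length(x, b[1], b[2])
  expect_equal(r2$table$motus$length, 65)
  expect_equal(r2$report$motus_removed, 4)
  # 64 bp is out; missing length info rejected
  r3 <- filter_length(toy_table(cnt[1, , drop = FALSE], lengths = 64))
  expect_equal(nrow(r3$table$counts), 0)
  no_len <- motu_table(data.frame(motu_id = "m1"),
                       matrix(1L, 1, 1, dimnames = list("m1", "p1")))
  expect_error(filter_length(no_len), "length")
})

test_that("rare-variant filter uses a strict per-PCR peak threshold", {
  cnt <- rbind(c(0L, 0L), c(5L, 2L), c(10L, 10L), c(11L, 0L), c(1000L, 3L))
  colnames(cnt) <- c("p1", "p2")
  x <- toy_table(cnt)
  r <- filter_rare(x)
  expect_equal(nrow(r$table$counts), 2)   # peaks 11 and 1000 survive
  expect_setequal(r$table$motus$motu_id, c("m04", "m05"))
})

test_that("clade restriction keeps descendants of the target clade", {
  cnt <- matrix(50L, 3, 1, dimnames = list(NULL, "p1"))
  x <- toy_table(cnt, clades = c(
    "Eukaryota;Fungi;Agaricus",
    "Eukaryota;Chlorophyta;Chlorophyceae;GenusA",
    "Eukaryota;Chlorophyta"))
  r <- restrict_clade(x, "Chlorophyta")
  expect_setequal(r$table$motus$motu_id, c("m02", "m03"))
})

test_that("contaminant rule compares blank and sample maxima", {
  # m1: blanks only; m2: samples only; m3: higher rel freq in blank
  cnt <- rbind(c(0L, 0L, 30L), c(500L, 400L, 0L), c(20L, 10L, 40L))
  colnames(cnt) <- c("s1", "s2", "b1")
  x <- toy_table(cnt)
  pcrs <- toy_pcrs(c("s1", "s2", "b1"),
                   control_type = c("sample", "sample", "extraction_blank"))
  r <- remove_contaminants(x, pcrs)
  expect_setequal(unlist(r$report$details), c("m01", "m03"))
  # raw-read metric keeps m3 (20 sample reads < 40 blank reads still flags;
  # use a case where metrics disagree: m3 has more raw reads in sample)
  cnt2 <- rbind(c(900L, 0L), c(50L, 10L))
  colnames(cnt2) <- c("s1", "b1")
  x2 <- toy_table(cnt2)
  pcrs2 <- toy_pcrs(c("s1", "b1"),
                    control_type = c("sample", "pcr_blank"))
  raw <- remove_contaminants(x2, pcrs2, metric = "raw_reads")
  rel <- remove_contaminants(x2, pcrs2, metric = "rel_freq")
  expect_equal(raw$report$motus_removed, 0)    # 50 > 10 raw reads
  expect_equal(unlist(rel$report$details), "m02")  # 5% < 100% rel freq
  # no negative controls: warning and no-op
  pcrs3 <- toy_pcrs(c("s1", "b1"))
  expect_warning(r3 <- remove_contaminants(x2, pcrs3), "no negative")
  expect_equal(r3$report$motus_removed, 0)
})

test_that("failed-PCR rejection treats thresholds as minima", {
  cnt <- matrix(0L, 2, 4, dimnames = list(NULL, paste0("p", 1:4)))
  cnt[1, ] <- c(150L, 199L, 200L, 5000L)
  x <- toy_table(cnt)
  pcrs <- toy_pcrs(paste0("p", 1:4), marker = "Chlo01")
  r <- reject_failed_pcrs(x, pcrs)
  expect_setequal(colnames(r$table$counts), c("p3", "p4"))
  expect_equal(r$report$pcrs_removed, 2)
  # Euka03: 999 reads is below the 1,000 minimum
  cnt2 <- matrix(c(999L, 1000L), 1, 2,
                 dimnames = list(NULL, c("q1", "q2")))
  x2 <- toy_table(cnt2)
  pcrs2 <- toy_pcrs(c("q1", "q2"), marker = "Euka03")
  r2 <- reject_failed_pcrs(x2, pcrs2)
  expect_equal(colnames(r2$table$counts), "q2")
  # all rejected is a hard error
  expect_error(reject_failed_pcrs(x2, pcrs2, min_reads = 10000),
               "all .* rejected")
})

test_that("replicate distances use the Hellinger barycenter geometry", {
  # three identical replicates: all distances zero
  cnt <- matrix(rep(c(10L, 30L), 3), 2, 3,
                dimnames = list(NULL, paste0("r", 1:3)))
  x <- toy_table(cnt)
  pcrs <- toy_pcrs(paste0("r", 1:3), sample_ids = rep("sA", 3))
  d <- replicate_outliers(x, pcrs)
  expect_equal(d$distance, rep(0, 3))
  expect_false(any(d$flagged))
  # two replicates are equidistant from their midpoint
  cnt2 <- cbind(c(100L, 0L), c(0L, 100L))
  colnames(cnt2) <- c("r1", "r2")
  x2 <- toy_table(cnt2)
  pcrs2 <- toy_pcrs(c("r1", "r2"), sample_ids = c("sA", "sA"))
  d2 <- replicate_outliers(x2, pcrs2)
  expect_equal(d2$distance[1], d2$distance[2])
  # a replicate from a different community is the farthest and flagged
  set.seed(4)
  base <- c(60, 30, 10)
  good <- t(sapply(1:11, function(i) rmultinom(1, 2000, base / 100)[, 1]))
  odd <- rmultinom(1, 2000, c(5, 5, 90) / 100)[, 1]
  cnt3 <- t(rbind(good, odd))
  storage.mode(cnt3) <- "integer"
  colnames(cnt3) <- paste0("r", 1:12)
  x3 <- toy_table(cnt3)
  pcrs3 <- toy_pcrs(paste0("r", 1:12),
                    sample_ids = rep(paste0("s", 1:4), each = 3))
  d3 <- replicate_outliers(x3, pcrs3)
  expect_equal(d3$pcr_id[which.max(d3$distance)], "r12")
  expect_true(d3$flagged[d3$pcr_id == "r12"])
})

test_that("replicate aggregation averages relative frequencies", {
  cnt <- cbind(c(20L, 80L), c(40L, 60L), c(60L, 40L))
  colnames(cnt) <- paste0("r", 1:3)
  x <- toy_table(cnt)
  pcrs <- toy_pcrs(paste0("r", 1:3), sample_ids = rep("sA", 3))
  M <- aggregate_replicates(x, pcrs)
  expect_equal(unname(M["sA", ]), c(0.4, 0.6))
  # single replicate: aggregate equals its relative frequencies
  M1 <- aggregate_replicates(x, pcrs, exclude = c("r2", "r3"))
  expect_equal(unname(M1["sA", ]), c(0.2, 0.8))
  # disjoint replicates average to the midpoint
  cnt2 <- cbind(c(50L, 0L), c(0L, 70L))
  colnames(cnt2) <- c("r1", "r2")
  x2 <- toy_table(cnt2)
  pcrs2 <- toy_pcrs(c("r1", "r2"), sample_ids = c("sA", "sA"))
  expect_equal(unname(aggregate_replicates(x2, pcrs2)["sA", ]), c(0.5, 0.5))
})

test_that("filters are idempotent and reports reconcile with dimensions", {
  st <- simulate_study(small_config(seed = 21))
  f1 <- filter_length(st$table, 65, 200)
  f2 <- filter_length(f1$table, 65, 200)
  expect_identical(f1$table$counts, f2$table$counts)
  r1 <- filter_rare(st$table)
  r2 <- filter_rare(r1$table)
  expect_identical(r1$table$counts, r2$table$counts)
  c1 <- restrict_clade(st$table)
  expect_identical(restrict_clade(c1$table)$table$counts, c1$table$counts)
  expect_equal(nrow(st$table$counts) - f1$report$motus_removed,
               nrow(f1$table$counts))
  expect_equal(sum(st$table$counts) - f1$report$reads_removed,
               sum(f1$table$counts))
})

test_that("QC chain recovers planted contaminants and failures exactly", {
  st <- simulate_study(generator_config(seed = 31))
  qc <- suppressWarnings(suppressMessages(qc_pipeline(st$table, st$pcrs)))
  # contaminants: removed set equals the spiked set
  expect_setequal(unlist(qc$reports$contaminants$details),
                  st$truth$contaminants)
  # failures: every forced low-depth PCR is rejected
  rejected <- unlist(qc$reports$failed_pcrs$details)
  expect_true(all(st$truth$failed_pcrs %in% rejected))
  # rare artefacts all caught by the rarity filter
  expect_true(all(st$truth$rare %in% unlist(qc$reports$rare$details)))
  # off-target MOTUs absent from the final table
  expect_length(intersect(st$truth$offtarget,
                          qc$table$motus$motu_id), 0)
  # aggregated rows sum to one
  expect_true(all(abs(rowSums(qc$community) - 1) < 1e-12))
})
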