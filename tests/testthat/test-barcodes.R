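test_that("anchor search finds barcodes and respects the mismatch budget", {
  lib <- gen_barcode_library(3, seed = 41)
  bc <- lib$sequences[1]
  mk_read <- function(seq, id = "c1:AAAACCCCGGGG:1")
    structure(data.frame(read_id = id, cell_id = "c1", umi = "AAAACCCCGGGG",
                         sequence = seq, stringsAsFactors = FALSE),
              class = c("fastq_reads", "data.frame"))

  # exact anchor + barcode
  out <- extract_barcodes(mk_read(paste0(DEFAULT_ANCHOR, bc)))
  expect_equal(out$sequence, bc)
  expect_equal(out$umi_count, 1L)

  # read without the anchor
  out <- extract_barcodes(mk_read(paste0(strrep("A", 22), bc)))
  expect_equal(nrow(out), 0)
  expect_equal(unname(attr(out, "skip_log")["no_anchor"]), 1L)

  # 1-substitution anchor: found at max_anchor_mismatch = 1, not at 0;
  # cross-checked against a brute-force sliding-window Hamming scan
  anchor_mut <- DEFAULT_ANCHOR
  substr(anchor_mut, 5, 5) <- ifelse(substr(anchor_mut, 5, 5) == "A", "T", "A")
  read <- paste0("ACGT", anchor_mut, bc)  # offset start
  expect_equal(oracle_anchor_scan(read, DEFAULT_ANCHOR, 1), 5L)
  expect_true(is.na(oracle_anchor_scan(read, DEFAULT_ANCHOR, 0)))
  out1 <- extract_barcodes(mk_read(read), max_anchor_mismatch = 1)
  expect_equal(out1$sequence, bc)
  out0 <- extract_barcodes(mk_read(read), max_anchor_mismatch = 0)
  expect_equal(nrow(out0), 0)

  # too short after the hit -> skipped and logged
  out <- extract_barcodes(mk_read(paste0(DEFAULT_ANCHOR, substr(bc, 1, 50))))
  expect_equal(nrow(out), 0)
  expect_equal(unname(attr(out, "skip_log")["too_short"]), 1L)
})

test_that("UMI collapsing counts distinct UMIs per cell-barcode pair", {
  lib <- gen_barcode_library(2, seed = 42)
  bc <- lib$sequences[1]
  reads <- data.frame(
    read_id = sprintf("c1:%s:%d", c("U1", "U1", "U2"), 1:3),
    cell_id = "c1", umi = c("U1", "U1", "U2"),
    sequence = paste0(DEFAULT_ANCHOR, bc), stringsAsFactors = FALSE)
  out <- extract_barcodes(reads)
  expect_equal(out$read_count, 3L)
  expect_equal(out$umi_count, 2L)
})

test_that("clustering merges low-count neighbors into dominant barcodes", {
  map <- cluster_barcodes(c(AAAA = 100, AAAT = 3), max_dist = 1, merge_ratio = 5)
  expect_equal(unname(map[c("AAAA", "AAAT")]), c("AAAA", "AAAA"))

  map <- cluster_barcodes(c(AAAA = 100, TTTT = 90), max_dist = 1, merge_ratio = 5)
  expect_equal(unname(map[c("AAAA", "TTTT")]), c("AAAA", "TTTT"))

  # ratio condition blocks a merge even at distance 1
  map <- cluster_barcodes(c(AAAA = 10, AAAT = 9), max_dist = 1, merge_ratio = 5)
  expect_equal(unname(map[c("AAAA", "AAAT")]), c("AAAA", "AAAT"))

  expect_length(cluster_barcodes(numeric(0)), 0)
})

test_that("clustering equals the brute-force oracle on chained neighbors", {
  # 12 sequences forming chains of 1-edit neighbors with varied counts
  base <- c("ACGTACGT", "TTTTCCCC", "GGGGAAAA")
  seqs <- c(base,
            "ACGTACGA", "ACGAACGA", "ACGTACGC",
            "TTTTCCCA", "TTTACCCA", "TTTTCCCG",
            "GGGGAAAT", "GGGGAATT", "CGGGAAAA")
  counts <- setNames(c(500, 400, 300, 40, 5, 3, 30, 4, 2, 25, 6, 1), seqs)
  for (md in 1:2) {
    got <- cluster_barcodes(counts, max_dist = md, merge_ratio = 5)
    want <- oracle_cluster(counts, max_dist = md, merge_ratio = 5)
    expect_identical(got[names(want)], want)
  }
})

test_that("clustering is idempotent on its canonical output", {
  set.seed(43)
  lib <- gen_barcode_library(8, length = 30, seed = 43)
  # build noisy variants
  vars <- unlist(lapply(lib$sequences, function(s) {
    v <- s
    substr(v, 3, 3) <- "A"
    c(s, v)
  }))
  counts <- setNames(c(rbind(runif(8, 100, 200), runif(8, 1, 5))), vars)
  map <- cluster_barcodes(counts, max_dist = 5, merge_ratio = 5)
  canon_counts <- tapply(counts, map[names(counts)], sum)
  map2 <- cluster_barcodes(setNames(as.numeric(canon_counts),
                                    names(canon_counts)))
  expect_true(all(map2[names(map2)] == names(map2)))
})

test_that("lineage assignment applies sharing-design and size filters", {
  # toy table: 6 lineages with sizes 1,2,3,3,5,9
  sizes <- c(1, 2, 3, 3, 5, 9)
  lin <- rep(sprintf("BC%d", 1:6), sizes)
  cells <- data.frame(cell_id = sprintf("c%02d", seq_along(lin)),
                      sequence = lin, umi_count = 2L,
                      stringsAsFactors = FALSE)
  samples <- setNames(rep("A", nrow(cells)), cells$cell_id)
  asg <- assign_lineages(cells, samples, "independent_samples", min_cells = 3)
  kept <- asg[is.na(asg$drop_reason), ]
  expect_length(unique(kept$lineage_id), 4)
  expect_true(all(table(kept$lineage_id) >= 3))

  # cross-sample barcode removed under independent_samples, kept under
  # shared_split
  cells2 <- data.frame(cell_id = sprintf("c%02d", 1:6),
                       sequence = rep("BCX", 6), umi_count = 1L)
  samples2 <- setNames(rep(c("A", "B"), each = 3), cells2$cell_id)
  a1 <- assign_lineages(cells2, samples2, "independent_samples")
  expect_true(all(a1$drop_reason == "cross_sample"))
  a2 <- assign_lineages(cells2, samples2, "shared_split")
  expect_true(all(is.na(a2$drop_reason)))

  expect_error(assign_lineages(cells2, samples2[1:3], "shared_split"),
               "unknown sample")
})

test_that("multi-barcode combinations resolve by the >= 2 cells rule", {
  res <- resolve_multibarcode(list(c1 = c("b2", "b1"), c2 = c("b1", "b2"),
                                   c3 = c("b1", "b3")))
  expect_equal(res$lineage_id[res$cell_id %in% c("c1", "c2")],
               rep("b1+b2", 2))
  expect_true(is.na(res$lineage_id[res$cell_id == "c3"]))
  expect_equal(res$drop_reason[res$cell_id == "c3"], "ambiguous_combination")

  # 3 combinations over 7 cells: compare to exhaustive grouping
  sets <- list(c1 = c("a", "b"), c2 = c("a", "b"), c3 = c("a", "c"),
               c4 = c("a", "c"), c5 = c("a", "c"), c6 = c("b", "c"),
               c7 = c("a", "b"))
  res <- resolve_multibarcode(sets)
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "+"), "")
  expected <- ifelse(as.vector(table(keys)[keys] >= 2), keys, NA)
  expect_equal(res$lineage_id, unname(expected))
})

test_that("oversize filter removes lineages above slack * 2^doublings", {
  lin <- c(rep("big", 40), rep("ok", 30))
  asg <- data.frame(cell_id = sprintf("c%02d", seq_along(lin)),
                    sample_id = "A", lineage_id = lin,
                    n_supporting_umis = 1L, drop_reason = NA_character_,
                    stringsAsFactors = FALSE)
  out <- filter_oversized(asg, doublings = 4, slack = 2)  # threshold 32
  expect_true(all(out$drop_reason[out$lineage_id == "big"] == "oversized"))
  expect_true(all(is.na(out$drop_reason[out$lineage_id == "ok"])))
  expect_equal(attr(out, "oversize_report")$size, 40L)

  # infinite slack is the identity
  out2 <- filter_oversized(asg, doublings = 4, slack = Inf)
  expect_true(all(is.na(out2$drop_reason)))
})

test_that("oversize filter rarely touches true lineages in simulated data", {
  p <- study_params()
  pop <- simulate_population(p, c(S = 300), stop = list(target_doublings = 4),
                             seed = 44)
  asg <- data.frame(cell_id = pop$cells$cell_id, sample_id = "A",
                    lineage_id = as.character(pop$cells$lineage_id),
                    n_supporting_umis = 1L, drop_reason = NA_character_,
                    stringsAsFactors = FALSE)
  out <- filter_oversized(asg, doublings = 4)
  removed <- nrow(attr(out, "oversize_report"))
  expect_lt(removed / 300, 0.01)
})

test_that("filters only remove and never reassign lineages", {
  lin <- rep(sprintf("BC%d", 1:5), times = c(2, 3, 4, 5, 40))
  cells <- data.frame(cell_id = sprintf("c%02d", seq_along(lin)),
                      sequence = lin, umi_count = 1L)
  samples <- setNames(rep("A", nrow(cells)), cells$cell_id)
  asg <- assign_lineages(cells, samples, "independent_samples", min_cells = 3)
  out <- filter_oversized(asg, doublings = 4, slack = 2)
  expect_identical(out$lineage_id, asg$lineage_id)
  # every drop reason set by filters corresponds to a removal, not a rewrite
  expect_true(all(out$lineage_id == lin[match(out$cell_id, cells$cell_id)]))
})

test_that("reads round-trip to >= 99% correct lineage assignment", {
  set.seed(45)
  n_lin <- 25
  n_cells <- 150
  lib <- gen_barcode_library(n_lin, 100, seed = 45)
  cells <- sprintf("cell%03d", seq_len(n_cells))
  truth <- setNames(sample(lib$sequences, n_cells, replace = TRUE), cells)
  cfg <- synth_config(read_error_rate = 0.01)
  reads <- gen_reads(lib, truth, reads_per_cell = 8, cfg, seed = 46)
  bc <- extract_barcodes(reads)
  map <- cluster_barcodes(bc)
  bc$sequence <- unname(map[bc$sequence])
  samples <- setNames(rep("A", n_cells), cells)
  asg <- assign_lineages(bc, samples, "independent_samples", min_cells = 1)
  hit <- asg$lineage_id[match(cells, asg$cell_id)] == unname(truth)
  expect_gte(mean(hit, na.rm = TRUE), 0.99)
  expect_gte(sum(hit, na.rm = TRUE) / n_cells, 0.99)
})
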