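#' Extract lineage barcodes from reads by anchor search
#'
#' Scans each read for the anchor (the constant sequence immediately
#' preceding the lineage barcode) allowing up to `max_anchor_mismatch`
#' substitutions, and on a hit emits the following `barcode_length`
#' nucleotides. Reads lacking the anchor, or too short to contain a full
#' barcode after it, are skipped and counted. Barcodes are then
#' UMI-collapsed per (cell, sequence).
#'
#' @param reads a `fastq_reads` data.frame (see [gen_reads()] /
#'   [read_fastq()]) with columns `read_id`, `cell_id`, `umi`, `sequence`.
#' @param anchor anchor sequence (length >= 10).
#' @param max_anchor_mismatch maximum substitutions tolerated in the anchor.
#' @param barcode_length length of the lineage barcode to extract.
#' @return data.frame with columns `cell_id`, `sequence`, `read_count`,
#'   `umi_count`; attribute `skip_log` holds counts of skipped reads.
#' @export
extract_barcodes <- function(reads, anchor = DEFAULT_ANCHOR,
                             max_anchor_mismatch = 1L,
                             barcode_length = 100L) {
  stopifnot(nchar(anchor) >= 10)
  if (nrow(reads) == 0) {
    out <- data.frame(cell_id = character(), sequence = character(),
                      read_count = integer(), umi_count = integer())
    attr(out, "skip_log") <- c(no_anchor = 0L, too_short = 0L)
    return(out)
  }
  subj <- Biostrings::DNAStringSet(reads$sequence)
  hits <- Biostrings::vmatchPattern(anchor, subj,
                                    max.mismatch = max_anchor_mismatch,
                                    with.indels = FALSE)
  starts <- Biostrings::startIndex(hits)
  first <- vapply(starts, function(s) if (is.null(s)) NA_integer_ else s[1],
                  integer(1))
  has_hit <- !is.na(first)
  bc_start <- first + nchar(anchor)
  long_enough <- has_hit &
    (bc_start + barcode_length - 1L) <= nchar(reads$sequence)
  skip_log <- c(no_anchor = sum(!has_hit),
                too_short = sum(has_hit & !long_enough))
  keep <- which(long_enough)
  bc <- substr(reads$sequence[keep], bc_start[keep],
               bc_start[keep] + barcode_length - 1L)
  df <- data.frame(cell_id = reads$cell_id[keep], sequence = bc,
                   umi = reads$umi[keep], stringsAsFactors = FALSE)
  # UMI collapse per (cell, sequence)
  key <- paste(df$cell_id, df$sequence, sep = "\r")
  read_count <- as.integer(table(key)[unique(key)])
  uniq <- !duplicated(key)
  umi_count <- as.integer(tapply(df$umi, key, function(u) length(unique(u)))[
    unique(key)])
  out <- data.frame(cell_id = df$cell_id[uniq], sequence = df$sequence[uniq],
                    read_count = read_count, umi_count = umi_count,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_id, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skip_log") <- skip_log
  out
}

#' Cluster barcode sequences into canonical barcodes
#'
#' Greedy error-correction clustering in the style of message-less sphere
#' clustering: sequences are visited in descending total read count (ties
#' broken lexicographically); a sequence merges into an already-canonical
#' sequence when their Levenshtein distance is at most `max_dist` and the
#' canonical's count is at least `merge_ratio` times the sequence's count;
#' otherwise the sequence becomes canonical itself. When several canonicals
#' qualify, the closest one wins (ties by higher count, then lexicographic).
#' The returned map is idempotent: every canonical maps to itself.
#'
#' @param counts a barcode-count data.frame (from [extract_barcodes()]),
#'   aggregated over cells by total `read_count`; or a named numeric vector
#'   of counts per sequence.
#' @param max_dist maximum Levenshtein distance for a merge.
#' @param merge_ratio minimum canonical/member count ratio for a merge.
#' @return named character vector mapping each input sequence to its
#'   canonical sequence.
#' @export
cluster_barcodes <- function(counts, max_dist = 5L, merge_ratio = 5) {
  if (is.data.frame(counts)) {
    agg <- tapply(counts$read_count, counts$sequence, sum)
    counts <- setNames(as.numeric(agg), names(agg))
  }
  if (length(counts) == 0) return(setNames(character(0), character(0)))
  ord <- order(-counts, names(counts))
  seqs <- names(counts)[ord]
  cnts <- unname(counts[ord])
  canon <- character(0)
  canon_cnt <- numeric(0)
  map <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    assigned <- NA_character_
    if (length(canon) > 0) {
      cand <- which(canon_cnt >= merge_ratio * cnts[i] &
                      abs(nchar(canon) - nchar(s)) <= max_dist)
      if (length(cand)) {
        d <- as.integer(adist(s, canon[cand]))
        ok <- which(d <= max_dist)
        if (length(ok)) {
          sel <- cand[ok]
          # closest; ties -> higher count, then lexicographic
          o <- order(d[ok], -canon_cnt[sel], canon[sel])[1]
          assigned <- canon[sel[o]]
        }
      }
    }
    if (is.na(assigned)) {
      canon <- c(canon, s)
      canon_cnt <- c(canon_cnt, cnts[i])
      map[i] <- s
    } else {
      map[i] <- assigned
    }
  }
  setNames(map, seqs)
}

#' Assign cells to lineages with cross-sample and size filters
#'
#' Builds one lineage call per cell from canonicalised barcode counts. A
#' cell with a single best barcode (highest UMI count) is assigned to it;
#' cells with several tied best barcodes are resolved through the
#' barcode-combination rule (see [resolve_multibarcode()]) and dropped as
#' ambiguous when that fails. Under the `independent_samples` design any
#' barcode observed in more than one sample is removed entirely (separate
#' wells cannot share a founder), while the `shared_split` design (one
#' barcoded pool split across condition plates) keeps cross-sample
#' lineages. Lineages with fewer than `min_cells` cells are dropped.
#'
#' @param cells canonicalised barcode counts: data.frame with `cell_id`,
#'   `sequence`, `umi_count` (e.g. [extract_barcodes()] output with
#'   sequences replaced through the [cluster_barcodes()] map).
#' @param samples named character vector mapping cell id to sample id.
#' @param sharing_design `"independent_samples"` or `"shared_split"`.
#' @param min_cells minimum cells per retained lineage.
#' @return data.frame with columns `cell_id`, `sample_id`, `lineage_id`,
#'   `n_supporting_umis`, `drop_reason` (NA when retained). Attribute
#'   `filter_log` holds per-filter removal counts.
#' @export
assign_lineages <- function(cells, samples,
                            sharing_design = c("independent_samples", "shared_split"),
                            min_cells = 3L) {
  sharing_design <- match.arg(sharing_design)
  unknown <- setdiff(unique(cells$cell_id), names(samples))
  if (length(unknown))
    stop("unknown sample id for cells: ", paste(head(unknown, 5), collapse = ", "))

  # error-correction may map several raw sequences of a cell to the same
  # canonical barcode: aggregate UMI support first
  key <- paste(cells$cell_id, cells$sequence, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(cells$umi_count, key)
    first <- !duplicated(key)
    cells <- data.frame(cell_id = cells$cell_id[first],
                        sequence = cells$sequence[first],
                        umi_count = as.integer(agg[key[first], 1]),
                        stringsAsFactors = FALSE)
  }

  per_cell <- split(seq_len(nrow(cells)), cells$cell_id)
  n <- length(per_cell)
  cell_id <- names(per_cell)
  lineage <- rep(NA_character_, n)
  umis <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)

  multi <- list()
  for (i in seq_len(n)) {
    rows <- per_cell[[i]]
    u <- cells$umi_count[rows]
    sq <- cells$sequence[rows]
    best <- which(u == max(u))
    if (length(rows) == 1L || length(best) == 1L) {
      lineage[i] <- sq[best[1]]
      umis[i] <- u[best[1]]
    } else {
      multi[[cell_id[i]]] <- sort(unique(sq))
      umis[i] <- sum(u)
    }
  }
  if (length(multi)) {
    res <- resolve_multibarcode(multi)
    m <- match(res$cell_id, cell_id)
    lineage[m] <- res$lineage_id
    reason[m] <- res$drop_reason
  }

  out <- data.frame(cell_id = cell_id,
                    sample_id = unname(samples[cell_id]),
                    lineage_id = lineage,
                    n_supporting_umis = umis,
                    drop_reason = reason,
                    stringsAsFactors = FALSE)
  log <- c(ambiguous_multibarcode = sum(!is.na(reason)))

  live <- is.na(out$drop_reason)
  if (sharing_design == "independent_samples") {
    tab <- unique(out[live, c("lineage_id", "sample_id")])
    shared <- names(which(table(tab$lineage_id) > 1))
    hit <- live & out$lineage_id %in% shared
    out$drop_reason[hit] <- "cross_sample"
    log <- c(log, cross_sample = sum(hit))
    live <- is.na(out$drop_reason)
  } else {
    log <- c(log, cross_sample = 0L)
  }

  sizes <- table(out$lineage_id[live])
  small <- names(sizes)[sizes < min_cells]
  hit <- live & out$lineage_id %in% small
  out$drop_reason[hit] <- "too_few_cells"
  log <- c(log, too_few_cells = sum(hit))

  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  out
}

#' Resolve cells carrying multiple lineage barcodes
#'
#' A sorted combination of barcodes observed in at least two cells is taken
#' as a real multi-integration lineage and keyed by the joined sorted set;
#' a combination seen in exactly one cell is ambiguous and dropped.
#'
#' @param cells_with_multiple_barcodes named list mapping cell id to a
#'   character vector of >= 2 barcode sequences.
#' @return data.frame with `cell_id`, `lineage_id` (combination key or NA),
#'   `drop_reason`.
#' @export
resolve_multibarcode <- function(cells_with_multiple_barcodes) {
  stopifnot(all(vapply(cells_with_multiple_barcodes, length, 1L) >= 2))
  keys <- vapply(cells_with_multiple_barcodes,
                 function(b) paste(sort(unique(b)), collapse = "+"), "")
  counts <- table(keys)
  ok <- counts[keys] >= 2
  data.frame(cell_id = names(cells_with_multiple_barcodes),
             lineage_id = ifelse(ok, keys, NA_character_),
             drop_reason = ifelse(ok, NA_character_, "ambiguous_combination"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove lineages larger than the expansion time allows
#'
#' A lineage founded by one cell reaches `2^doublings` cells in
#' expectation over the allotted expansion; lineages exceeding `slack`
#' times that are artifacts (e.g. barcode collisions merging several real
#' lineages) and are dropped. Under stochastic exponential growth a
#' lineage's size is approximately geometric with mean `2^doublings`, so
#' the probability a real lineage exceeds `slack` times its expected size
#' is about `exp(-slack)`; the default slack of 7 corresponds to a 0.1%
#' upper-tail cutoff (a factor of 2 would discard roughly a tenth of
#' genuine lineages).
#'
#' @param assignments a lineage-assignment data.frame ([assign_lineages()]).
#' @param doublings number of population doublings cells were given.
#' @param slack multiplicative tolerance on the expected size.
#' @return the assignments with oversized lineages marked with drop reason
#'   `"oversized"`; attribute `oversize_report` lists removed lineages.
#' @export
filter_oversized <- function(assignments, doublings, slack = 7.0) {
  stopifnot(doublings >= 1)
  threshold <- slack * 2^doublings
  live <- is.na(assignments$drop_reason)
  sizes <- table(assignments$lineage_id[live])
  big <- names(sizes)[sizes > threshold]
  hit <- live & assignments$lineage_id %in% big
  assignments$drop_reason[hit] <- "oversized"
  attr(assignments, "oversize_report") <-
    data.frame(lineage_id = big,
               size = as.integer(sizes[big]),
               threshold = rep(threshold, length(big)),
               row.names = NULL, stringsAsFactors = FALSE)
  assignments
}
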