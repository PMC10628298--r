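#' Default anchor sequence preceding the lineage barcode in a read
#'
#' The constant "known sequence" used to locate the transcribed lineage
#' barcode within a read. Real libraries carry a vector-specific anchor;
#' here it is a configuration value with this 22-nt default.
#' @export
DEFAULT_ANCHOR <- "GCTAGCGGATCCTTAAGCTTCA"

#' Configuration for synthetic lineage-barcoded single-cell data
#'
#' Bundles the parameters of the synthetic-data generators: population size,
#' gene panel, the primed-cell fraction, negative-binomial expression
#' parameters, the marker fold change distinguishing the two states, the
#' per-base sequencing error rate, and the fraction of cells carrying a
#' lineage barcode.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (marker genes are included in this total).
#' @param primed_fraction fraction of cells in the primed (P) state.
#' @param marker_up_primed gene names upregulated in primed cells.
#' @param marker_up_susceptible gene names upregulated in drug-susceptible
#'   cells.
#' @param nb_mean_base baseline negative-binomial mean per gene.
#' @param nb_dispersion NB dispersion; variance = mu + dispersion * mu^2.
#' @param marker_fold_change multiplicative effect on the mean of a state's
#'   marker genes in cells of that state.
#' @param read_error_rate per-base substitution probability in reads.
#' @param infected_fraction fraction of cells carrying a lineage barcode.
#' @param seed optional integer seed recorded in the config.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_cells = 2000L,
                         n_genes = 1000L,
                         primed_fraction = 0.02,
                         marker_up_primed = c("NT5E", "EGFR", "AXL", "FN1", "SERPINE2"),
                         marker_up_susceptible = c("SOX10", "MITF"),
                         nb_mean_base = 1,
                         nb_dispersion = 0.5,
                         marker_fold_change = 8,
                         read_error_rate = 0.01,
                         infected_fraction = 0.2,
                         seed = NULL) {
  stopifnot(n_cells >= 1, n_genes >= 1,
            primed_fraction >= 0, primed_fraction <= 1,
            nb_mean_base > 0, nb_dispersion > 0, marker_fold_change > 0,
            read_error_rate >= 0, read_error_rate <= 1,
            infected_fraction >= 0, infected_fraction <= 1)
  if (length(intersect(marker_up_primed, marker_up_susceptible)) > 0)
    stop("marker sets must be disjoint")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 primed_fraction = primed_fraction,
                 marker_up_primed = marker_up_primed,
                 marker_up_susceptible = marker_up_susceptible,
                 nb_mean_base = nb_mean_base,
                 nb_dispersion = nb_dispersion,
                 marker_fold_change = marker_fold_change,
                 read_error_rate = read_error_rate,
                 infected_fraction = infected_fraction,
                 seed = seed),
            class = "synth_config")
}

.BASES <- c("A", "C", "G", "T")
.W <- c("A", "T")
.S <- c("G", "C")

#' Generate a WSN-patterned lineage barcode library
#'
#' Semi-random barcodes built from WSN repeats (W = A/T, S = G/C,
#' N = any base), the pattern used for transcribed lineage barcodes to
#' maximise library complexity. Position i (0-based) holds W when
#' i mod 3 = 0, S when i mod 3 = 1, and N when i mod 3 = 2.
#'
#' The canonical barcode is 100 nt, a truncated 34th repeat; any positive
#' length is accepted and follows the same position rule.
#'
#' @param n number of barcodes.
#' @param length barcode length in nucleotides.
#' @param seed optional integer seed.
#' @return object of class `barcode_library`: list with `sequences`
#'   (character vector, unique) and `length`.
#' @export
gen_barcode_library <- function(n, length = 100L, seed = NULL) {
  stopifnot(n >= 1)
  len <- as.integer(length)
  if (len < 1L) stop("barcode length must be positive")
  .check_seed(seed)
  draw <- function(k) {
    pos <- seq_len(len) - 1L
    m <- matrix("", nrow = len, ncol = k)
    m[pos %% 3L == 0L, ] <- sample(.W, sum(pos %% 3L == 0L) * k, replace = TRUE)
    m[pos %% 3L == 1L, ] <- sample(.S, sum(pos %% 3L == 1L) * k, replace = TRUE)
    m[pos %% 3L == 2L, ] <- sample(.BASES, sum(pos %% 3L == 2L) * k, replace = TRUE)
    apply(m, 2, paste, collapse = "")
  }
  seqs <- unique(draw(n))
  while (base::length(seqs) < n)  # resample collisions (rare at 100 nt)
    seqs <- unique(c(seqs, draw(n - base::length(seqs))))
  structure(list(sequences = seqs[seq_len(n)], length = len),
            class = "barcode_library")
}

# substitute characters of a character matrix i.i.d. at rate `rate`
.mutate_chars <- function(m, rate) {
  if (rate <= 0) return(m)
  idx <- which(runif(length(m)) < rate)
  if (length(idx)) {
    cur <- match(m[idx], .BASES)
    off <- sample.int(3L, length(idx), replace = TRUE)
    m[idx] <- .BASES[((cur - 1L + off) %% 4L) + 1L]
  }
  m
}

#' Generate synthetic barcode reads
#'
#' Emulates the barcode-side sequencing reaction: each read is the anchor
#' sequence followed by the cell's lineage barcode, with i.i.d. base
#' substitutions at the configured error rate over the whole read. The read
#' name encodes the cell id and a random UMI
#' (`cell_id:UMI:read_index`).
#'
#' @param library a `barcode_library`.
#' @param cell_assignments named character vector mapping cell id to
#'   barcode sequence (each must be in the library). Cells not present get
#'   no reads.
#' @param reads_per_cell reads generated per assigned cell.
#' @param config a `synth_config` (uses `read_error_rate`).
#' @param anchor anchor sequence prepended to each read.
#' @param umi_length UMI length in nt.
#' @param seed optional integer seed.
#' @return data.frame of class `fastq_reads` with columns `read_id`,
#'   `cell_id`, `umi`, `sequence`.
#' @export
gen_reads <- function(library, cell_assignments, reads_per_cell,
                      config = synth_config(), anchor = DEFAULT_ANCHOR,
                      umi_length = 12L, seed = NULL) {
  stopifnot(inherits(library, "barcode_library"))
  if (!all(cell_assignments %in% library$sequences))
    stop("every assigned barcode must be in the library")
  .check_seed(seed)
  if (reads_per_cell == 0L) {
    warning("reads_per_cell is 0; returning no reads")
    out <- data.frame(read_id = character(), cell_id = character(),
                      umi = character(), sequence = character())
    class(out) <- c("fastq_reads", "data.frame")
    return(out)
  }
  n_cells <- length(cell_assignments)
  cells <- rep(names(cell_assignments), each = reads_per_cell)
  bcs <- rep(unname(cell_assignments), each = reads_per_cell)
  n_reads <- length(cells)
  umis <- vapply(seq_len(n_reads), function(i)
    paste(sample(.BASES, umi_length, replace = TRUE), collapse = ""), "")
  # mutate anchor + barcode together
  L <- nchar(anchor) + library$length
  m <- matrix("", nrow = L, ncol = n_reads)
  m[seq_len(nchar(anchor)), ] <- strsplit(anchor, "")[[1]]
  bc_chars <- matrix(unlist(strsplit(bcs, ""), use.names = FALSE),
                     nrow = library$length)
  m[(nchar(anchor) + 1L):L, ] <- bc_chars
  m <- .mutate_chars(m, config$read_error_rate)
  seqs <- apply(m, 2, paste, collapse = "")
  out <- data.frame(
    read_id = paste0(cells, ":", umis, ":", seq_len(n_reads)),
    cell_id = cells, umi = umis, sequence = seqs,
    stringsAsFactors = FALSE)
  class(out) <- c("fastq_reads", "data.frame")
  out
}

#' Generate a two-state negative-binomial count matrix
#'
#' Counts are drawn from a negative binomial with mean `nb_mean_base` and
#' dispersion `nb_dispersion` (variance = mu + dispersion * mu^2). Marker
#' genes of a cell's state have their mean multiplied by
#' `marker_fold_change`; all other genes are state-independent.
#'
#' @param states named character vector mapping cell id to state
#'   ("S" or "P").
#' @param config a `synth_config`.
#' @param seed optional integer seed.
#' @return sparse genes x cells count matrix (`dgCMatrix`) with gene and
#'   cell names.
#' @export
gen_counts <- function(states, config = synth_config(), seed = NULL) {
  stopifnot(all(states %in% c("S", "P")))
  .check_seed(seed)
  n_cells <- length(states)
  markers <- c(config$marker_up_primed, config$marker_up_susceptible)
  if (length(markers) == 0)
    warning("empty marker sets: generating a plain NB matrix")
  n_other <- config$n_genes - length(markers)
  stopifnot(n_other >= 0)
  genes <- c(markers,
             sprintf("GENE%04d", seq_len(n_other)))
  mu <- matrix(config$nb_mean_base, nrow = config$n_genes, ncol = n_cells,
               dimnames = list(genes, names(states)))
  is_p <- states == "P"
  if (any(is_p) && length(config$marker_up_primed))
    mu[config$marker_up_primed, is_p] <-
      mu[config$marker_up_primed, is_p, drop = FALSE] * config$marker_fold_change
  if (any(!is_p) && length(config$marker_up_susceptible))
    mu[config$marker_up_susceptible, !is_p] <-
      mu[config$marker_up_susceptible, !is_p, drop = FALSE] * config$marker_fold_change
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   nrow = config$n_genes, dimnames = dimnames(mu))
  Matrix::Matrix(counts, sparse = TRUE)
}

#' Generate flow-cytometry-like intensity data
#'
#' A two-component lognormal mixture over single-event intensities: the
#' primed component's location is shifted by `shift` on the natural-log
#' scale. The latent state label of each event is returned alongside the
#' intensity.
#'
#' @param n_events number of events.
#' @param primed_fraction mixture weight of the primed component.
#' @param shift log-scale location shift of the primed component.
#' @param seed optional integer seed.
#' @param condition condition label stamped on every event.
#' @param meanlog,sdlog baseline lognormal parameters.
#' @return data.frame with columns `event_id`, `condition`, `intensity`,
#'   `latent_primed` (logical).
#' @export
gen_flow <- function(n_events, primed_fraction, shift, seed = NULL,
                     condition = "untreated", meanlog = 4, sdlog = 0.5) {
  stopifnot(n_events >= 1)
  if (primed_fraction < 0 || primed_fraction > 1)
    stop("primed_fraction must be in [0, 1]")
  .check_seed(seed)
  primed <- runif(n_events) < primed_fraction
  intens <- rlnorm(n_events, meanlog = meanlog + shift * primed, sdlog = sdlog)
  data.frame(event_id = sprintf("%s_ev%06d", condition, seq_len(n_events)),
             condition = condition,
             intensity = intens,
             latent_primed = primed,
             stringsAsFactors = FALSE)
}
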