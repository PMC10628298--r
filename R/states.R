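#' Log-normalize a count matrix
#'
#' Library-size normalization followed by a natural-log transform:
#' `log(1 + scale * count / column_sum)`. Zero counts remain zero, so
#' sparsity is preserved.
#'
#' @param counts genes x cells count matrix (base or `Matrix`).
#' @param scale library-size scale factor.
#' @return normalized matrix of the same class and dimnames.
#' @export
lognormalize <- function(counts, scale = 10000) {
  cs <- Matrix::colSums(counts)
  if (any(cs == 0)) {
    bad <- colnames(counts)[cs == 0] %||% which(cs == 0)
    stop("all-zero cell(s): ", paste(head(bad, 5), collapse = ", "))
  }
  if (inherits(counts, "Matrix")) {
    norm <- counts %*% Matrix::Diagonal(x = scale / cs)
    dimnames(norm) <- dimnames(counts)
    log1p(norm)
  } else {
    log1p(sweep(counts, 2, cs / scale, "/"))
  }
}

#' Rank-based gene-signature score per cell
#'
#' For each cell, all genes are ranked by decreasing expression (ties get
#' average ranks) and ranks beyond `rmax` are clipped to `rmax + 1`. With
#' `m` signature genes, the Mann-Whitney-style statistic
#' `U = sum(signature ranks) - m(m+1)/2` yields the score
#' `1 - U / (m * rmax)`, clipped to `[0, 1]`: 1 when the signature genes
#' occupy the top `m` ranks, near 0 when they all rank beyond `rmax`.
#' Because it is rank-based, the score is invariant to any monotone
#' transform of the expression values.
#'
#' @param normalized genes x cells expression matrix.
#' @param gene_set character vector of signature gene names.
#' @param rmax rank cap.
#' @param name label stored in the `gene_set_name` column.
#' @return data.frame with `cell_id`, `score`, `gene_set_name`.
#' @export
signature_score <- function(normalized, gene_set, rmax = 1500L,
                            name = "signature") {
  present <- intersect(gene_set, rownames(normalized))
  if (length(present) == 0)
    stop("no signature gene present in the matrix")
  missing <- setdiff(gene_set, present)
  if (length(missing))
    warning("signature genes absent from matrix (scored over the rest): ",
            paste(missing, collapse = ", "))
  m <- length(present)
  rmax <- min(rmax, nrow(normalized))
  x <- as.matrix(normalized)
  sig_idx <- match(present, rownames(x))
  scores <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(-x[, j], ties.method = "average")
    r[r > rmax] <- rmax + 1
    u <- sum(r[sig_idx]) - m * (m + 1) / 2
    min(max(1 - u / (m * rmax), 0), 1)
  }, numeric(1))
  data.frame(cell_id = colnames(x) %||% as.character(seq_len(ncol(x))),
             score = scores, gene_set_name = name,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call primed vs drug-susceptible states from signature scores
#'
#' Either fits a two-component Gaussian mixture to the scores and labels
#' the higher-mean component primed (boundary at the equal-posterior
#' point), or labels the top `q` fraction of scores primed. Replaces graph
#' clustering with a reproducible one-dimensional decision on the primed
#' signature score; the method used is recorded in the result's
#' `method` attribute.
#'
#' @param scores a signature-score data.frame ([signature_score()]) or a
#'   named numeric vector of scores per cell.
#' @param method `"mixture"` or `"quantile"`.
#' @param q quantile for the quantile method (fraction labeled primed).
#' @return named character vector mapping cell id to `"S"` or `"P"`, with
#'   attribute `method`.
#' @export
call_states <- function(scores, method = c("mixture", "quantile"), q = 0.02) {
  method <- match.arg(method)
  if (is.data.frame(scores))
    scores <- setNames(scores$score, scores$cell_id)
  if (is.null(names(scores)))
    names(scores) <- as.character(seq_along(scores))
  stopifnot(length(scores) >= 20)
  out <- setNames(rep("S", length(scores)), names(scores))
  if (max(scores) - min(scores) < .Machine$double.eps^0.5) {
    warning("constant scores: labeling all cells drug-susceptible")
    attr(out, "method") <- method
    return(out)
  }
  if (method == "quantile") {
    k <- ceiling(q * length(scores))
    if (k > 0) {
      top <- order(-scores, names(scores))[seq_len(k)]
      out[top] <- "P"
    }
  } else {
    fit <- mclust::Mclust(scores, G = 2, modelNames = c("E", "V"),
                          verbose = FALSE)
    hi <- which.max(fit$parameters$mean)
    out[fit$classification == hi] <- "P"
  }
  attr(out, "method") <- method
  out
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Two-sided rank-sum test per gene (exact when both groups have at most
#' 10 cells and there are no ties; normal approximation with tie
#' correction otherwise), Bonferroni correction over the genes actually
#' tested, and a log2 fold change of mean normalized expression with
#' pseudocount 1. Genes detected in fewer than 10% of cells in both
#' groups, or with zero variance across the two groups, are excluded
#' before testing and reported with NA statistics.
#'
#' @param normalized genes x cells expression matrix.
#' @param groupA,groupB character vectors of cell ids (columns).
#' @param alpha significance level on the Bonferroni-adjusted p-value.
#' @param lfc_cutoff absolute log2 fold-change cutoff for significance.
#' @return data.frame with `gene`, `log2_fold_change`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
de_wilcoxon <- function(normalized, groupA, groupB,
                        alpha = 0.05, lfc_cutoff = 0.25) {
  groupA <- intersect(groupA, colnames(normalized))
  groupB <- intersect(groupB, colnames(normalized))
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("groups do not intersect the matrix columns")
  stopifnot(length(groupA) >= 3, length(groupB) >= 3)
  xa <- as.matrix(normalized[, groupA, drop = FALSE])
  xb <- as.matrix(normalized[, groupB, drop = FALSE])
  detA <- rowMeans(xa > 0)
  detB <- rowMeans(xb > 0)
  novar <- apply(cbind(xa, xb), 1, function(v) max(v) == min(v))
  testable <- which(!(detA < 0.1 & detB < 0.1) & !novar)
  n_tested <- length(testable)
  exact <- length(groupA) <= 10 && length(groupB) <= 10
  p <- rep(NA_real_, nrow(normalized))
  for (g in testable) {
    p[g] <- suppressWarnings(
      wilcox.test(xa[g, ], xb[g, ], alternative = "two.sided",
                  exact = exact, correct = TRUE)$p.value)
  }
  lfc <- log2((rowMeans(xa) + 1) / (rowMeans(xb) + 1))
  padj <- pmin(1, p * n_tested)
  data.frame(gene = rownames(normalized),
             log2_fold_change = lfc,
             p_value = p,
             p_adjusted = padj,
             significant = padj < alpha & abs(lfc) >= lfc_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive the primed gene set from a differential-expression table
#'
#' All significantly differentially expressed genes with a positive log2
#' fold change, computed with the primed cells as group A.
#'
#' @param de a [de_wilcoxon()] result.
#' @return character vector of gene names.
#' @export
derive_primed_geneset <- function(de) {
  genes <- de$gene[!is.na(de$significant) & de$significant &
                     de$log2_fold_change > 0]
  if (length(genes) == 0)
    warning("no significant upregulated genes; returning an empty set")
  genes
}

#' Label intermediate-state cells within the drug-susceptible population
#'
#' Scores all cells against the crossing-lineage up-regulated gene set and
#' relabels the top `q` fraction of drug-susceptible cells (by score) as
#' intermediate (`"I"`). Primed labels are never changed. With any
#' drug-susceptible cells present and `q > 0`, at least one cell is
#' labeled intermediate.
#'
#' @param normalized genes x cells expression matrix.
#' @param states named character vector of `"S"`/`"P"` per cell.
#' @param crossing_up_genes non-empty gene set upregulated in crossing
#'   lineages.
#' @param q fraction of drug-susceptible cells to relabel.
#' @return named character vector over `{"S","P","I"}`.
#' @export
intermediate_call <- function(normalized, states, crossing_up_genes,
                              q = 0.02) {
  stopifnot(length(crossing_up_genes) > 0)
  sc <- signature_score(normalized, crossing_up_genes, name = "crossing")
  s_cells <- names(states)[states == "S"]
  s_cells <- intersect(s_cells, sc$cell_id)
  if (length(s_cells) == 0 || q <= 0) return(states)
  k <- max(1L, ceiling(q * length(s_cells)))
  sv <- setNames(sc$score, sc$cell_id)[s_cells]
  top <- s_cells[order(-sv, s_cells)][seq_len(min(k, length(s_cells)))]
  states[top] <- "I"
  states
}

#' Flow-cytometry primed gate calibrated on untreated cells
#'
#' Sets the intensity threshold at the `ceiling(q * N)`-th largest
#' untreated (control) value, so that exactly that many control events lie
#' at or above it; an event is called primed iff its intensity is greater
#' than or equal to the threshold. Returns the percent primed per
#' condition.
#'
#' @param control_intensities numeric vector of untreated intensities.
#' @param treated named list of numeric intensity vectors, one per treated
#'   condition (may be empty).
#' @param q calibration fraction.
#' @return list with `threshold` and `percent_primed` (named numeric, in
#'   percent, including `"control"`).
#' @export
flow_gate <- function(control_intensities, treated = list(), q = 0.02) {
  n <- length(control_intensities)
  stopifnot(n >= 1 / q)
  k <- ceiling(q * n)
  threshold <- sort(control_intensities, decreasing = TRUE)[k]
  pct <- function(x) {
    if (length(x) == 0) {
      warning("empty condition; returning NA")
      return(NA_real_)
    }
    100 * mean(x >= threshold)
  }
  res <- c(control = pct(control_intensities),
           vapply(treated, pct, numeric(1)))
  list(threshold = threshold, percent_primed = res)
}
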