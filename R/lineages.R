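#' Classify lineages into the four memory categories
#'
#' Each lineage is placed in one of four categories from its founder state
#' and its endpoint composition: `PURE_S` (founder drug-susceptible, all
#' cells drug-susceptible), `PURE_P` (founder primed, all cells primed),
#' `S_TO_P` (founder drug-susceptible, lineage contains primed cells), and
#' `P_TO_S` (founder primed, lineage contains drug-susceptible cells).
#' Intermediate (`"I"`) cells count as drug-susceptible here, since the
#' intermediate state is a subpopulation of the drug-susceptible state.
#' The categories partition the lineages.
#'
#' @param table a cell table: data.frame with `cell_id`, `lineage_id`,
#'   `state` (in `{"S","P","I"}`); rows with NA lineage are ignored.
#' @param founder_states named vector mapping lineage id to founder state
#'   (`"S"` or `"P"`). Lineages missing from it are excluded with a
#'   warning.
#' @return data.frame with `lineage_id`, `founder_state`, `category`,
#'   `size`, `primed_fraction`.
#' @export
classify_lineages <- function(table, founder_states) {
  tb <- table[!is.na(table$lineage_id), , drop = FALSE]
  lin <- as.character(tb$lineage_id)
  ids <- unique(lin)
  known <- ids %in% names(founder_states)
  if (any(!known)) {
    warning(sum(!known), " lineage(s) without a known founder state excluded")
    keep <- lin %in% ids[known]
    tb <- tb[keep, , drop = FALSE]
    lin <- lin[keep]
    ids <- ids[known]
  }
  f <- factor(lin, levels = ids)
  size <- tabulate(f, nbins = length(ids))
  is_p <- tb$state == "P"
  n_p <- tabulate(f[is_p], nbins = length(ids))
  founder <- unname(founder_states[ids])
  category <- ifelse(founder == "S",
                     ifelse(n_p == 0, "PURE_S", "S_TO_P"),
                     ifelse(n_p == size, "PURE_P", "P_TO_S"))
  data.frame(lineage_id = ids, founder_state = founder, category = category,
             size = size, primed_fraction = n_p / size,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell sets for the crossing-lineage differential expression
#'
#' Selects the two cell sets compared to reveal the intermediate state:
#' A = drug-susceptible cells from lineages that are entirely
#' drug-susceptible (`PURE_S`), and B = the drug-susceptible cells only
#' from lineages that switched from drug-susceptible to primed (`S_TO_P`);
#' the primed cells of switching lineages are excluded from B.
#'
#' @param table a cell table (see [classify_lineages()]).
#' @param classes a [classify_lineages()] result.
#' @return list with character vectors `A` and `B` of cell ids.
#' @export
crossing_de_inputs <- function(table, classes) {
  pure_s <- classes$lineage_id[classes$category == "PURE_S"]
  s_to_p <- classes$lineage_id[classes$category == "S_TO_P"]
  if (length(pure_s) == 0 || length(s_to_p) == 0)
    stop("need both PURE_S and S_TO_P lineages")
  s_like <- table$state %in% c("S", "I")
  A <- table$cell_id[s_like & table$lineage_id %in% pure_s]
  B <- table$cell_id[s_like & table$lineage_id %in% s_to_p]
  if (length(B) == 0)
    stop("no drug-susceptible cells in switching lineages")
  list(A = A, B = B)
}

#' Primed fractions of matched lineages across conditions
#'
#' For the split-plate design in which each lineage is represented in every
#' condition, selects reference-condition lineages by state — either
#' 100% in `ref_state` (`selection = "pure"`, the default) or containing
#' at least one `ref_state` cell (`"containing"`) — and reports each
#' one's primed fraction in every condition (NA where a lineage is
#' absent from a condition).
#'
#' @param tables named list of cell tables, one per condition.
#' @param reference name of the reference condition.
#' @param ref_state `"S"` or `"P"`: the state required in the reference.
#' @param selection `"pure"` (lineage entirely in `ref_state`) or
#'   `"containing"` (any cell in `ref_state`).
#' @return data.frame: one row per selected lineage, one column per
#'   condition holding the primed fraction, plus `lineage_id`.
#' @export
matched_lineage_fractions <- function(tables, reference,
                                      ref_state = c("S", "P"),
                                      selection = c("pure", "containing")) {
  ref_state <- match.arg(ref_state)
  selection <- match.arg(selection)
  if (!reference %in% names(tables))
    stop("reference condition not in tables: ", reference)
  pf <- function(tb) {
    tb <- tb[!is.na(tb$lineage_id), , drop = FALSE]
    st <- ifelse(tb$state == "P", 1, 0)  # I counts as S
    tapply(st, as.character(tb$lineage_id), mean)
  }
  fr <- lapply(tables, pf)
  ref <- fr[[reference]]
  sel <- if (selection == "pure") {
    target <- if (ref_state == "P") 1 else 0
    names(ref)[ref == target]
  } else {
    if (ref_state == "P") names(ref)[ref > 0] else names(ref)[ref < 1]
  }
  out <- data.frame(lineage_id = sel, stringsAsFactors = FALSE)
  for (cond in names(tables))
    out[[cond]] <- as.vector(fr[[cond]][sel])
  out
}

#' Proportion of lineages with a reduced primed fraction under treatment
#'
#' Over lineages present in both conditions, the proportion whose primed
#' fraction is strictly lower in `condition` than in `reference`; ties
#' count as not reduced.
#'
#' @param fractions a [matched_lineage_fractions()] result.
#' @param condition,reference condition column names to compare.
#' @return proportion in `[0, 1]`, or NA if no lineage is comparable.
#' @export
fraction_reduced <- function(fractions, condition, reference) {
  a <- fractions[[condition]]
  b <- fractions[[reference]]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  mean(a[ok] < b[ok])
}

#' Moment estimator of the per-division switch probability from purity
#'
#' In a complete binary tree of `d` doublings there are `2 (2^d - 1)`
#' daughter draws; under the per-daughter switching convention and
#' ignoring back-switching, the probability a lineage stays pure is
#' `(1 - p)^(2 (2^d - 1))`, which this estimator inverts:
#' `p_hat = 1 - purity^(1 / (2 (2^d - 1)))`. A small-p approximation;
#' purity 0 carries no information and returns NA.
#'
#' @param purity fraction of lineages with no switched cell, in `(0, 1]`.
#' @param doublings number of doublings `d >= 1`.
#' @return estimated per-daughter, per-division switch probability.
#' @export
estimate_switch_prob_from_purity <- function(purity, doublings) {
  stopifnot(doublings >= 1, purity >= 0, purity <= 1)
  if (purity == 0) return(NA_real_)
  draws <- 2 * (2^doublings - 1)
  1 - purity^(1 / draws)
}

#' Per-gene expression memory as an intraclass correlation
#'
#' Quantifies how much of each gene's expression variance lies between
#' lineages rather than within them, via the one-way intraclass
#' correlation ICC(1) with lineage as the grouping factor (unequal group
#' sizes handled with the standard average-group-size correction), clipped
#' to `[0, 1]`. A gene whose expression is heritable through divisions
#' scores near `sigma_b^2 / (sigma_b^2 + sigma_w^2)`; an i.i.d. gene
#' scores near 0. Zero-variance genes score 0.
#'
#' @param normalized genes x cells expression matrix.
#' @param table cell table with `cell_id` and `lineage_id`.
#' @return named numeric vector of per-gene memory scores.
#' @export
gene_memory_icc <- function(normalized, table) {
  tb <- table[!is.na(table$lineage_id) & table$cell_id %in% colnames(normalized), ]
  sizes <- base::table(as.character(tb$lineage_id))
  keep <- names(sizes)[sizes >= 2]
  if (length(keep) < 10)
    stop("need at least 10 lineages with >= 2 cells")
  tb <- tb[tb$lineage_id %in% keep, ]
  x <- as.matrix(normalized[, tb$cell_id, drop = FALSE])
  g <- factor(as.character(tb$lineage_id))
  a <- nlevels(g)
  n_i <- tabulate(g)
  N <- sum(n_i)
  # group sums via indicator crossprod
  gsum <- t(rowsum(t(x), g))                # genes x lineages
  gmean <- sweep(gsum, 2, n_i, "/")
  grand <- rowMeans(x)
  ssb <- rowSums(sweep(gmean - grand, 2, n_i, "*") * (gmean - grand))
  sst <- rowSums((x - grand)^2)
  ssw <- sst - ssb
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  k0 <- (N - sum(n_i^2) / N) / (a - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  icc[sst < .Machine$double.eps] <- 0
  icc[!is.finite(icc)] <- 0
  setNames(pmin(pmax(icc, 0), 1), rownames(x))
}
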