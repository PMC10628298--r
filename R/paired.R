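# matched-lineage (paired) statistics across two conditions of a
# split-plate design: cells with the same barcode on different plates act
# as copies of the same founder, so state switching and cell killing leave
# different signatures on a lineage's treated twin.

.PAIRED_NAMES <- c(
  "pp_exit_frac",   # primed-dominated reference lineages whose twin lost
                    # primed majority
  "pp_pf_med",      # median twin primed fraction of those lineages
  "pp_size_lr",     # median log2 twin/reference size ratio (pseudocount 1)
  "pp_absent_frac", # primed-dominated reference lineages missing from the
                    # twin plate
  "sp_entry_frac",  # pure-susceptible reference lineages whose twin has
                    # any P cell
  "sp_pf_med",
  "sp_size_lr",
  "sp_absent_frac")

.pf_by_lineage <- function(is_p, lineage) {
  ok <- !is.na(lineage)
  lin <- as.character(lineage[ok])
  ids <- unique(lin)
  f <- factor(lin, levels = ids)
  size <- tabulate(f, nbins = length(ids))
  n_p <- tabulate(f[is_p[ok] == 1], nbins = length(ids))
  list(ids = ids, size = size, pf = n_p / pmax(size, 1))
}

.paired_core <- function(u_isp, u_lin, t_isp, t_lin) {
  u <- .pf_by_lineage(u_isp, u_lin)
  t <- .pf_by_lineage(t_isp, t_lin)
  out <- setNames(numeric(length(.PAIRED_NAMES)), .PAIRED_NAMES)
  side <- function(sel, prefix, cross_name, cross_fun) {
    ids <- u$ids[sel]
    if (length(ids) == 0) return()
    m <- match(ids, t$ids)
    present <- !is.na(m)
    out[paste0(prefix, "_absent_frac")] <<- mean(!present)
    if (any(present)) {
      tpf <- t$pf[m[present]]
      tsz <- t$size[m[present]]
      usz <- u$size[sel][present]
      out[cross_name] <<- cross_fun(tpf)
      out[paste0(prefix, "_pf_med")] <<- median(tpf)
      out[paste0(prefix, "_size_lr")] <<- median(log2((tsz + 1) / (usz + 1)))
    }
  }
  side(u$pf >= 0.5, "pp", "pp_exit_frac", function(pf) mean(pf < 0.5))
  side(u$pf == 0, "sp", "sp_entry_frac", function(pf) mean(pf > 0))
  out
}

#' Matched-lineage statistics between two conditions
#'
#' For lineages observed in a reference (untreated) condition, compares
#' each lineage to its twin (same barcode) in another condition of a
#' split-plate design. Reported for the lineages that are primed-dominated
#' (primed fraction >= 0.5, `pp_*`) and pure drug-susceptible (`sp_*`) in
#' the reference: the fraction whose twin changed side
#' (`pp_exit_frac` / `sp_entry_frac`),
#' the median twin primed fraction, the median log2 size ratio
#' (pseudocount 1), and the fraction of twins absent from the other
#' condition. State switching flips a twin's states while preserving its
#' size; selective killing shrinks or deletes the twin — so these
#' components separate mechanisms that look alike in per-plate summaries.
#' Intermediate (`"I"`) cells count as drug-susceptible. Components with
#' no eligible lineage are 0.
#'
#' @param untreated reference-condition cell table (`lineage_id`, `state`).
#' @param treated other-condition cell table.
#' @return named numeric vector of 8 components.
#' @export
paired_lineage_stats <- function(untreated, treated) {
  .paired_core(as.integer(untreated$state == "P"), untreated$lineage_id,
               as.integer(treated$state == "P"), treated$lineage_id)
}
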