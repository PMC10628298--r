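# shared in-code fixtures and independent oracles

# cell table builder
make_cell_table <- function(lineage, state, cell_id = NULL,
                            condition = "untreated") {
  n <- length(state)
  data.frame(cell_id = cell_id %||% sprintf("c%04d", seq_len(n)),
             condition = condition,
             lineage_id = lineage,
             state = state,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force sliding-window Hamming scan for an anchor in a read
oracle_anchor_scan <- function(read, anchor, max_mm) {
  la <- nchar(anchor)
  a <- strsplit(anchor, "")[[1]]
  for (s in seq_len(nchar(read) - la + 1)) {
    w <- strsplit(substr(read, s, s + la - 1), "")[[1]]
    if (sum(w != a) <= max_mm) return(s)
  }
  NA_integer_
}

# independent greedy clustering oracle (different data structures and
# control flow from the implementation): repeatedly processes the
# highest-count unassigned sequence
oracle_cluster <- function(counts, max_dist, merge_ratio) {
  remaining <- counts
  canon <- c()
  map <- character(0)
  while (length(remaining) > 0) {
    o <- order(-remaining, names(remaining))
    s <- names(remaining)[o[1]]
    cnt <- remaining[[s]]
    target <- NA
    if (length(canon) > 0) {
      ds <- sapply(names(canon), function(k) drop(utils::adist(s, k)))
      elig <- names(canon)[ds <= max_dist & canon >= merge_ratio * cnt]
      if (length(elig)) {
        de <- ds[elig]
        ce <- canon[elig]
        pick <- elig[order(de, -ce, elig)][1]
        target <- pick
      }
    }
    if (is.na(target)) {
      canon[s] <- cnt
      map[s] <- s
    } else {
      map[s] <- target
    }
    remaining <- remaining[names(remaining) != s]
  }
  map
}

# default two-state parameters used by the study-condition simulations:
# one S->P event per 177 divisions, one P->S event per 6.3 divisions,
# primed cells dividing at half the susceptible rate, no death
study_params <- function() {
  two_state_params(r_S = 1, r_P = 0.5,
                   p_on = divisions_to_prob(177),
                   p_off = divisions_to_prob(6.3))
}
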