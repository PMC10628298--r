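test_that("lognormalize matches the closed form and the formula oracle", {
  m <- matrix(c(0, 7), nrow = 2, dimnames = list(c("g1", "g2"), "c1"))
  out <- lognormalize(m)
  expect_equal(out["g1", "c1"], 0)
  expect_equal(out["g2", "c1"], log(1 + 10000))

  set.seed(51)
  m <- matrix(rpois(1000, 2), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:20)))
  out <- lognormalize(m)
  cs <- colSums(m)
  oracle <- log(1 + 10000 * sweep(m, 2, cs, "/"))
  expect_equal(unname(as.matrix(out)), unname(oracle), tolerance = 1e-12)

  # sparse input stays sparse and agrees
  sp <- lognormalize(Matrix::Matrix(m, sparse = TRUE))
  expect_s4_class(sp, "Matrix")
  expect_equal(unname(as.matrix(sp)), unname(oracle), tolerance = 1e-12)

  m[, 3] <- 0
  expect_error(lognormalize(m), "c03")
})

test_that("signature score follows the capped rank-sum formula", {
  # signature genes at the very top -> score 1
  x <- matrix(c(10, 9, 8, seq(7, 1, length.out = 7)), ncol = 1,
              dimnames = list(sprintf("g%02d", 1:10), "c1"))
  s <- signature_score(x, c("g01", "g02", "g03"), rmax = 5)
  expect_equal(s$score, 1)

  # all m = 10 signature genes beyond rmax = 1500:
  # U = 10 * 1501 - 55 = 14955, score = 1 - 14955 / 15000 = 0.003
  n_genes <- 2000
  expr <- seq(n_genes, 1)
  x <- matrix(expr, ncol = 1,
              dimnames = list(sprintf("g%04d", 1:n_genes), "c1"))
  sig <- sprintf("g%04d", 1991:2000)  # the 10 lowest-expressed genes
  s <- signature_score(x, sig, rmax = 1500)
  expect_equal(s$score, 1 - 14955 / 15000)

  # permuting non-signature expression values leaves the score unchanged
  # (rank invariance), as does a monotone transform
  set.seed(52)
  x2 <- matrix(runif(500), ncol = 1,
               dimnames = list(sprintf("g%03d", 1:500), "c1"))
  sig <- sprintf("g%03d", c(3, 77, 200))
  s1 <- signature_score(x2, sig, rmax = 100)$score
  x3 <- x2
  nonsig <- setdiff(rownames(x2), sig)
  x3[nonsig, 1] <- sample(x3[nonsig, 1])  # permute values across genes
  r1 <- rank(-x2[, 1])[sig]
  r3 <- rank(-x3[, 1])[sig]
  # permutation preserves the signature genes' rank multiset
  expect_equal(sort(unname(r1)), sort(unname(r3)))
  expect_equal(signature_score(x3, sig, rmax = 100)$score, s1)
  expect_equal(signature_score(exp(3 * x2), sig, rmax = 100)$score, s1)

  expect_error(signature_score(x2, c("nope1", "nope2")), "no signature gene")
  expect_warning(signature_score(x2, c(sig, "absent"), rmax = 100), "absent")
})

test_that("state calling separates bimodal scores and handles edge cases", {
  set.seed(53)
  truth <- rep(c("S", "P"), c(900, 100))
  sc <- setNames(rnorm(1000, ifelse(truth == "P", 0.8, 0.2), 0.05),
                 sprintf("c%04d", 1:1000))
  called <- call_states(sc, method = "mixture")
  expect_gte(mean(called == truth), 0.99)

  q <- call_states(sc, method = "quantile", q = 0.02)
  expect_equal(sum(q == "P"), 20)

  expect_warning(all_s <- call_states(setNames(rep(0.5, 30), 1:30)),
                 "constant")
  expect_true(all(all_s == "S"))
})

test_that("rank-sum DE reproduces the exact null and the cutoffs", {
  # complete separation, 5 vs 5: two-sided exact p = 2 / choose(10, 5)
  x <- matrix(c(1:5, 101:105), nrow = 1,
              dimnames = list("g1", sprintf("c%02d", 1:10)))
  x <- rbind(x, g2 = rep(5, 10))  # constant gene -> excluded, NA
  x <- rbind(x, g3 = c(2, 3, 1, 5, 4, 3.5, 2.5, 1.5, 4.5, 0.5))
  de <- de_wilcoxon(x, sprintf("c%02d", 6:10), sprintf("c%02d", 1:5))
  expect_equal(de$p_value[de$gene == "g1"], 2 / 252)
  expect_true(is.na(de$p_value[de$gene == "g2"]))
  expect_true(de$significant[de$gene == "g1"])
  expect_equal(de$log2_fold_change[de$gene == "g1"],
               log2((mean(101:105) + 1) / (mean(1:5) + 1)))

  # identical groups: nothing significant
  set.seed(54)
  m <- matrix(rpois(200 * 12, 3), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:12)))
  de0 <- de_wilcoxon(m, sprintf("c%02d", 1:6), sprintf("c%02d", 1:6))
  expect_false(any(de0$significant, na.rm = TRUE))
})

test_that("rank-sum p-values are uniform under label permutation", {
  set.seed(55)
  n_genes <- 400
  cfg <- synth_config(n_cells = 60, n_genes = n_genes)
  st <- setNames(rep("S", 60), sprintf("c%02d", 1:60))
  m <- lognormalize(gen_counts(st, cfg, seed = 55) + 0)
  pvals <- c()
  for (i in 1:5) {
    grp <- sample(colnames(m))
    de <- de_wilcoxon(m, grp[1:30], grp[31:60])
    pvals <- c(pvals, de$p_value[!is.na(de$p_value)])
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("primed gene set derivation keeps significant upregulated genes", {
  de <- data.frame(gene = sprintf("g%d", 1:6),
                   log2_fold_change = c(1, 2, -1, 0.5, -2, 3),
                   p_value = 1, p_adjusted = 1,
                   significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_setequal(derive_primed_geneset(de), c("g1", "g2", "g6"))
  de$significant <- FALSE
  expect_warning(out <- derive_primed_geneset(de), "empty")
  expect_length(out, 0)

  # on synthetic two-state data, the planted primed markers are recovered
  cfg <- synth_config(n_cells = 300, n_genes = 100)
  st <- setNames(rep(c("P", "S"), c(60, 240)), sprintf("c%03d", 1:300))
  norm <- lognormalize(gen_counts(st, cfg, seed = 56))
  de2 <- de_wilcoxon(norm, names(st)[st == "P"], names(st)[st == "S"])
  gs <- derive_primed_geneset(de2)
  expect_true(all(cfg$marker_up_primed %in% gs))
})

test_that("intermediate relabeling takes the top scoring S cells only", {
  set.seed(57)
  cfg <- synth_config(n_cells = 1050, n_genes = 100)
  cells <- sprintf("c%04d", 1:1050)
  st <- setNames(rep(c("S", "P"), c(1000, 50)), cells)
  norm <- lognormalize(gen_counts(st, cfg, seed = 57))
  out <- intermediate_call(norm, st, cfg$marker_up_primed, q = 0.02)
  expect_equal(sum(out == "I"), 20)  # exactly 2% of 1000 S cells
  expect_true(all(out[st == "P"] == "P"))  # P labels never change
  out0 <- intermediate_call(norm, st, cfg$marker_up_primed, q = 0)
  expect_true(all(out0 == st))
})

test_that("intermediate calls enrich for a planted transition population", {
  # plant intermediates as S cells with partial activation of a
  # realistically sized crossing gene set (half the primed fold change);
  # the real crossing signature has hundreds of genes, so 25 is modest
  set.seed(58)
  n_s <- 800; n_i <- 40; n_p <- 40
  cells <- sprintf("c%04d", seq_len(n_s + n_i + n_p))
  truth <- rep(c("S", "I", "P"), c(n_s, n_i, n_p))
  crossing <- sprintf("CR%02d", 1:25)
  cfg <- synth_config(n_cells = n_s + n_i + n_p, n_genes = 150,
                      marker_up_primed = crossing,
                      marker_up_susceptible = character(0),
                      marker_fold_change = 8)
  st_gen <- setNames(ifelse(truth == "P", "P", "S"), cells)
  counts <- gen_counts(st_gen, cfg, seed = 58)
  half <- synth_config(n_cells = n_i, n_genes = 150,
                       marker_up_primed = crossing,
                       marker_up_susceptible = character(0),
                       marker_fold_change = 4)
  counts[, truth == "I"] <-
    gen_counts(setNames(rep("P", n_i), cells[truth == "I"]), half, seed = 59)
  norm <- lognormalize(counts)
  states <- setNames(ifelse(truth == "P", "P", "S"), cells)
  out <- intermediate_call(norm, states, crossing, q = n_i / (n_s + n_i))
  hit <- mean(names(out)[out == "I"] %in% cells[truth == "I"])
  expect_gte(hit, 0.7)
})

test_that("flow gate reproduces the calibration fraction exactly", {
  set.seed(59)
  control <- sample(seq_len(1000))  # 1000 distinct values
  res <- flow_gate(control, q = 0.02)
  expect_equal(sum(control >= res$threshold), 20)
  expect_equal(unname(res$percent_primed["control"]), 2.0)

  # constant upward shift raises the treated percentage
  res2 <- flow_gate(control, list(up = control + 100), q = 0.02)
  expect_gt(unname(res2$percent_primed["up"]), 2.0)

  expect_warning(res3 <- flow_gate(control, list(empty = numeric(0))),
                 "empty")
  expect_true(is.na(res3$percent_primed["empty"]))
})

test_that("treated percent matches the closed-form mixture tail", {
  # gate calibrated on untreated (2% primed); treated at 20% primed with a
  # 3-log-unit shift. Expected percent above the threshold: mixture tail
  # computed from the lognormal components.
  n <- 20000
  ctrl <- gen_flow(n, 0.02, 3, seed = 60, condition = "untreated")
  trt <- gen_flow(n, 0.20, 3, seed = 61, condition = "treated")
  res <- flow_gate(ctrl$intensity, list(treated = trt$intensity), q = 0.02)
  thr <- log(res$threshold)
  expected <- 100 * (0.20 * stats::pnorm(thr, 7, 0.5, lower.tail = FALSE) +
                     0.80 * stats::pnorm(thr, 4, 0.5, lower.tail = FALSE))
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / n)
  expect_lt(abs(unname(res$percent_primed["treated"]) - expected), 3 * se)
})
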