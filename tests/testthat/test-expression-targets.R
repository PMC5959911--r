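test_that("low-signal filter requires both clauses (conjunction)", {
  set.seed(1)
  m <- matrix(20 + rnorm(40 * 8, sd = 0.01), 40, 8,
              dimnames = list(sprintf("g%02d", 1:40),
                              sprintf("s%d", 1:8)))
  groups <- rep(c("control", "mimic"), each = 4)
  # g01: low abundance in both groups, near-zero variance -> removed
  m["g01", ] <- 0.5 + 1e-7 * (1:8)
  # g02: low abundance but variance above the pooled median -> retained
  m["g02", ] <- rep(c(0.1, 0.9), 4)
  de <- data.frame(gene_id = rownames(m))
  v <- apply(m, 1, var)
  expect_true(v[["g02"]] > median(v))
  out <- filter_low_signal(de, m, groups)
  expect_false("g01" %in% out$gene_id)
  expect_true("g02" %in% out$gene_id)
  expect_true(all(out$gene_id %in% de$gene_id))
  expect_error(filter_low_signal(data.frame(gene_id = "nope"), m, groups),
               "absent")
})

test_that("filter removes exactly the planted both-clause genes", {
  sim <- simulate_expression(n_genes = 100, n_planted_down = 0,
                             noise_cv = 0.15, frac_low_signal = 0.1,
                             seed = 21)
  de <- data.frame(gene_id = rownames(sim$matrix))
  # independent direct scan of the two printed clauses
  m <- sim$matrix
  g1 <- rowMeans(m[, sim$groups == "control"])
  g2 <- rowMeans(m[, sim$groups == "mimic"])
  v <- apply(m, 1, var)
  expected_removed <- rownames(m)[g1 < 1 & g2 < 1 & v < median(v)]
  out <- filter_low_signal(de, m, sim$groups)
  expect_setequal(attr(out, "removed_genes"), expected_removed)
  expect_true(all(sim$low_signal %in% attr(out, "removed_genes")))
  # idempotent when the median is taken on the original matrix
  out2 <- filter_low_signal(out, m, sim$groups)
  expect_equal(out2$gene_id, out$gene_id)
})

test_that("downregulated set uses strict alpha and the down direction", {
  de <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    fold_change = c(0.5, 0.6, 2.0, 0.7),
    p_value = c(0.001, 0.02, 0.001, 0.03),
    adjusted_p = c(0.01, 0.05, 0.01, 0.04),
    direction = c("down", "down", "up", "down"))
  expect_equal(downregulated_set(de), c("a", "d"))  # 0.05 excluded (strict)
  de$adjusted_p <- rep(1, 4)
  expect_length(downregulated_set(de), 0)
})

test_that("planted downregulation is recovered from a 4 vs 4 design", {
  sim <- simulate_expression(n_genes = 200, n_planted_down = 20,
                             fold_range_down = c(0.4, 0.6),
                             noise_cv = 0.1, frac_low_signal = 0.1,
                             seed = 31)
  de <- de_from_expression(sim$matrix, sim$groups, ref = "control")
  de <- filter_low_signal(de, sim$matrix, sim$groups)
  down <- downregulated_set(de, alpha = 0.05)
  expect_gte(mean(sim$planted %in% down), 0.90)
  # null design: no planted genes -> essentially no calls
  sim0 <- simulate_expression(n_genes = 200, n_planted_down = 0,
                              noise_cv = 0.1, frac_low_signal = 0,
                              seed = 32)
  de0 <- de_from_expression(sim0$matrix, sim0$groups, ref = "control")
  expect_lte(length(downregulated_set(de0)), 2)
})

test_that("overlap summary reports symmetric counts and rounded percentages", {
  a <- sprintf("a%d", 1:20)
  b <- c(a[1:5], sprintf("b%d", 1:15))
  o <- overlap_summary(a, b)
  expect_equal(o$n_common, 5)
  expect_equal(o$pct_of_a, 25)
  expect_equal(overlap_summary(b, a)$n_common, o$n_common)
  same <- overlap_summary(a, a)
  expect_equal(c(same$pct_of_a, same$pct_of_b), c(100, 100))
  dis <- overlap_summary(a, sprintf("c%d", 1:7))
  expect_equal(c(dis$n_common, dis$pct_of_a, dis$pct_of_b), c(0, 0, 0))
})

test_that("target annotation classifies evidence with experimental priority", {
  genes <- sprintf("g%03d", 1:100)
  ev <- rbind(
    data.frame(mirna_id = "miR-x", gene_id = genes[1:10], source = "tarbase",
               evidence_class = "experimental"),
    data.frame(mirna_id = "miR-x", gene_id = genes[8:30],
               source = "targetscan", evidence_class = "predicted"),
    data.frame(mirna_id = "miR-y", gene_id = genes[40:50], source = "mirdb",
               evidence_class = "predicted"))
  ann <- annotate_targets(genes, ev, "miR-x")
  st <- setNames(ann$annotation$status, ann$annotation$gene_id)
  expect_equal(sum(st == "experimental"), 10)  # overlap counts as experimental
  expect_equal(sum(st == "predicted"), 20)
  expect_equal(ann$summary$pct_experimental, 10)
  expect_equal(ann$summary$pct_predicted, 20)
  # miR-y evidence must not leak into the miR-x annotation
  expect_true(all(st[genes[40:50]] == "unsupported"))
  empty <- annotate_targets(genes, ev[0, ], "miR-x")
  expect_equal(empty$summary$n_unsupported, 100)
  expect_equal(empty$summary$pct_experimental, 0)
})

test_that("prediction aggregation honours union / intersection / k-of-n", {
  pair <- function(g) data.frame(mirna_id = "m", gene_id = g,
                                 stringsAsFactors = FALSE)
  tabs <- list(
    tarbase = pair(c("g1", "g2")),
    targetscan = pair(c("g2", "g3")),
    mirdb = pair(c("g2", "g3", "g4")))
  u <- aggregate_predictions(tabs, "union")
  i <- aggregate_predictions(tabs, "intersection")
  k2 <- aggregate_predictions(tabs, "k_of_n", k = 2)
  expect_setequal(u$gene_id, c("g1", "g2", "g3", "g4"))
  expect_setequal(i$gene_id, "g2")
  expect_setequal(k2$gene_id, c("g2", "g3"))
  # nesting: union >= k_of_n >= intersection
  expect_true(all(i$gene_id %in% k2$gene_id))
  expect_true(all(k2$gene_id %in% u$gene_id))
  # tarbase support marks the pair experimental
  expect_equal(u$evidence_class[u$gene_id == "g1"], "experimental")
  expect_equal(u$evidence_class[u$gene_id == "g3"], "predicted")
  expect_error(aggregate_predictions(list(foo = pair("g1")), "union"),
               "unknown source")
  expect_error(aggregate_predictions(tabs, "k_of_n", k = 5), "k must be")
})

test_that("k-of-n aggregation matches a brute-force bitmap filter", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:30)
  sources <- c("tarbase", "starbase", "mirtarbase", "targetscan", "mirdb")
  member <- matrix(runif(30 * 5) < 0.4, 30, 5,
                   dimnames = list(genes, sources))
  tabs <- lapply(setNames(nm = sources), function(s)
    data.frame(mirna_id = "m", gene_id = genes[member[, s]],
               stringsAsFactors = FALSE))
  for (k in 1:5) {
    got <- aggregate_predictions(tabs, "k_of_n", k = k)
    expect_setequal(got$gene_id, genes[rowSums(member) >= k])
  }
})
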