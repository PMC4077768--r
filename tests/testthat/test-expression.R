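test_that("fold changes are 1 with p near 1 for identical groups", {
  vals <- matrix(rep(c(8, 8.1, 7.9), 2), nrow = 1)
  x <- expression_table(vals, rep(c("control", "treated"), each = 3),
                        genes = "g1")
  fc <- fold_changes(x)
  expect_equal(fc$fold, 1, tolerance = 1e-9)
  expect_gt(fc$p, 0.9)
})

test_that("a planted fold change is estimated with significance", {
  set.seed(1)
  base <- 8 + rnorm(3, 0, 0.01)
  vals <- rbind(c(base, base + log2(5) + rnorm(3, 0, 0.01)))
  x <- expression_table(vals, rep(c("control", "treated"), each = 3),
                        genes = "g1")
  fc <- fold_changes(x)
  expect_equal(fc$fold, 5, tolerance = 0.05)
  expect_lt(fc$p, 0.05)
})

test_that("swapping condition labels inverts the fold change", {
  set.seed(2)
  vals <- matrix(rnorm(12, 8, 0.5), nrow = 2)
  cond <- rep(c("control", "treated"), each = 3)
  f1 <- fold_changes(expression_table(vals, cond))
  f2 <- fold_changes(expression_table(vals, rev(cond)))
  expect_equal(f1$fold, 1 / f2$fold, tolerance = 1e-9)
})

test_that("zero-variance equal-mean genes get p = 1 by convention", {
  vals <- matrix(8, nrow = 1, ncol = 6)
  x <- expression_table(vals, rep(c("control", "treated"), each = 3))
  expect_equal(fold_changes(x)$p, 1)
})

test_that("the DE filter applies inclusive fold and p thresholds", {
  res <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    fold = c(3.0, 2.9, 1 / 3, 5, 0.1),
                    p = c(0.05, 0.01, 0.05, 0.2, 0.01))
  out <- de_filter(res)
  expect_setequal(out$up, "a")          # fold exactly 3, p exactly 0.05
  expect_setequal(out$down, c("c", "e"))  # d fails on p
  empty <- de_filter(res[0, ])
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})

test_that("planted DE genes are recovered exactly at low noise", {
  sim <- gen_expression_matrix(n_genes = 1000, planted_up = c(10, 8),
                               planted_down = c(5, 8), noise_sd = 0.2,
                               n_reps = 3, seed = 0L)
  out <- de_filter(fold_changes(sim$table))
  expect_setequal(out$up, sim$truth$gene[sim$truth$status == "up"])
  expect_setequal(out$down, sim$truth$gene[sim$truth$status == "down"])
})

test_that("DE recovery attains high sensitivity and low false discovery", {
  sim <- gen_expression_matrix(n_genes = 2000, planted_up = c(40, 8),
                               planted_down = c(20, 8), noise_sd = 0.2,
                               n_reps = 3, seed = 7L)
  out <- de_filter(fold_changes(sim$table))
  called <- c(out$up, out$down)
  truth <- sim$truth$gene[sim$truth$status != "null"]
  sens <- length(intersect(called, truth)) / length(truth)
  fdr <- if (length(called)) {
    length(setdiff(called, truth)) / length(called)
  } else 0
  expect_gte(sens, 0.95)
  expect_lte(fdr, 0.1)
})

test_that("ddCt quantification matches its closed forms", {
  expect_equal(ddct_fold_change(gen_ct_table(1, sd = 0))$fold, 1)
  expect_equal(ddct_fold_change(gen_ct_table(8, sd = 0))$fold, 8)
  # a global +1 cycle shift in treated samples cancels through the reference
  ct <- gen_ct_table(1, sd = 0)
  ct$ct[ct$condition == "treated"] <- ct$ct[ct$condition == "treated"] + 1
  expect_equal(ddct_fold_change(ct)$fold, 1)
})

test_that("ddCt is invariant to per-sample additive shifts", {
  ct <- gen_ct_table(17.37, sd = 0.1, seed = 3L)
  ref <- ddct_fold_change(ct)$fold
  shifts <- stats::setNames(runif(length(unique(ct$sample)), -2, 2),
                            unique(ct$sample))
  ct$ct <- ct$ct + shifts[ct$sample]
  expect_equal(ddct_fold_change(ct)$fold, ref, tolerance = 1e-9)
})

test_that("ddCt requires the reference gene in every sample", {
  ct <- gen_ct_table(2, sd = 0)
  ct <- ct[!(ct$gene == "reference" & ct$sample == "treated_1"), ]
  expect_error(ddct_fold_change(ct), "reference")
})

test_that("SRM ratios sum peptides and normalise to the Cat sums", {
  areas <- data.frame(protein = rep(c("target", "control"), each = 2),
                      peptide = c("t1", "t2", "c1", "c2"),
                      area = c(100, 200, 150, 150),
                      replicate = 1L)
  out <- srm_protein_ratio(areas)
  expect_equal(out$mean, 1)
  areas0 <- areas
  areas0$area[areas0$protein == "target"] <- 0
  expect_equal(srm_protein_ratio(areas0)$mean, 0)
  # global rescaling leaves the ratio unchanged
  scaled <- areas
  scaled$area <- scaled$area * 10
  expect_equal(srm_protein_ratio(scaled)$mean, out$mean)
})

test_that("SRM uses the highest-intensity transition per peptide", {
  areas <- data.frame(protein = rep(c("target", "control"), each = 4),
                      peptide = rep(c("t1", "t1", "c1", "c1"), each = 2),
                      transition = rep(c("y4", "y5"), 4),
                      area = c(50, 300, 10, 20, 100, 150, 100, 150),
                      replicate = 1L)
  # target peptide t1 contributes 300 (its best transition), Cat 150 + ...
  out <- srm_protein_ratio(areas)
  expect_equal(out$mean, 300 / 150)
  zero_cat <- data.frame(protein = c("target", "control"),
                         peptide = c("t1", "c1"), area = c(10, 0),
                         replicate = 1L)
  expect_error(srm_protein_ratio(zero_cat), "Cat")
})

test_that("promoter ranking assigns tiers by descending fold with stable ties", {
  r <- rank_promoters(c(ydfO = 116.61, ydfA = 47.69, marR = 17.37))
  expect_equal(r$gene, c("ydfO", "ydfA", "marR"))
  expect_equal(r$tier, c("high", "medium", "low"))
  ties <- rank_promoters(c(b = 5, a = 5, c = 5))
  expect_equal(ties$gene, c("a", "b", "c"))
  single <- rank_promoters(c(only = 2), tiers = "high")
  expect_equal(single$tier, "high")
})
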