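test_that("two-way ANOVA matches a from-scratch sums-of-squares partition", {
  set.seed(3)
  fx <- expand.grid(gene = c("g1", "g2", "g3"),
                    reference_gene = c("RpL32", "RpS18"), rep = 1:4,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gene_eff <- c(g1 = 0, g2 = 2, g3 = -1)
  ref_eff <- c(RpL32 = 0, RpS18 = 1)
  fx$delta_cq <- gene_eff[fx$gene] + ref_eff[fx$reference_gene] +
    0.5 * (fx$gene == "g2" & fx$reference_gene == "RpS18") + rnorm(nrow(fx), 0, 0.4)

  res <- two_way_anova(fx)

  # independent balanced-design SS partition
  y <- fx$delta_cq; gm <- mean(y)
  mg <- tapply(y, fx$gene, mean); mr <- tapply(y, fx$reference_gene, mean)
  mc <- tapply(y, interaction(fx$gene, fx$reference_gene), mean)
  ss_g <- 8 * sum((mg - gm)^2)
  ss_r <- 12 * sum((mr - gm)^2)
  ss_cells <- 4 * sum((mc - gm)^2)
  ss_int <- ss_cells - ss_g - ss_r
  ss_res <- sum((y - mc[interaction(fx$gene, fx$reference_gene)])^2)
  f_oracle <- c(ss_g / 2, ss_r / 1, ss_int / 2) / (ss_res / 18)
  expect_equal(res$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$df_num, c(2L, 1L, 2L))
  expect_equal(res$df_den, rep(18L, 3))
  expect_equal(res$p_value, pf(f_oracle, c(2, 1, 2), 18, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("two-way ANOVA handles degenerate and malformed inputs", {
  fx <- expand.grid(gene = c("a", "b"), reference_gene = c("r1", "r2"),
                    rep = 1:3, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fx$delta_cq <- 1
  res <- two_way_anova(fx)
  expect_equal(res$f_statistic, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
  expect_error(two_way_anova(fx[!(fx$gene == "b" & fx$reference_gene == "r2"), ]),
               "empty cell")
})

test_that("additive reference offsets produce no interaction signal", {
  genes <- data.frame(gene = c("g1", "g2", "g3"), sample_class = "c1",
                      mean_dcq = c(-2, -6, -9))
  below <- 0
  for (s in 1:200) {
    sc <- expression_scenario(genes, replicate_sd = 0.3, n_replicates = 4,
                              reference_offset = 1.5, seed = s)
    dcq <- compute_delta_cq(generate_cq_table(sc))
    res <- two_way_anova(dcq)
    int <- res[res$effect == "gene:reference_gene", ]
    below <- below + (int$f_statistic < qf(0.95, int$df_num, int$df_den))
  }
  expect_gte(below / 200, 0.9)
})

test_that("per-gene one-way ANOVA agrees with textbook sums of squares", {
  # three classes, hand-checkable layout
  d <- data.frame(sample_class = rep(c("a", "b", "c"), each = 4),
                  reference_gene = "RpL32",
                  delta_cq = c(6, 8, 4, 5, 8, 12, 9, 11, 13, 9, 11, 8))
  m <- tapply(d$delta_cq, d$sample_class, mean)
  gm <- mean(d$delta_cq)
  ss_b <- 4 * sum((m - gm)^2)
  ss_w <- sum((d$delta_cq - m[d$sample_class])^2)
  f_oracle <- (ss_b / 2) / (ss_w / 9)
  fit <- anova_per_gene(d)
  expect_equal(fit$f_statistic, f_oracle, tolerance = 1e-12)
  expect_equal(fit$df_num, 2L)
  expect_equal(fit$df_den, 9L)
  expect_equal(fit$p_value, pf(f_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fit$mse, ss_w / 9, tolerance = 1e-12)
})

test_that("identical classes give F = 0 and reference pooling removes the offset", {
  d <- data.frame(sample_class = rep(c("a", "b"), each = 4),
                  reference_gene = rep(c("RpL32", "RpS18"), 4),
                  delta_cq = rep(c(1, 2), 4))  # pure reference offset
  fit <- anova_per_gene(d)
  expect_equal(fit$f_statistic, 0)
  expect_equal(fit$p_value, 1)
  # separate-reference mode returns one fit per reference
  fits <- anova_per_gene(d, pool_references = FALSE)
  expect_named(fits, c("RpL32", "RpS18"))
  expect_equal(fits$RpL32$f_statistic, 0)
  singleton <- rbind(d, data.frame(sample_class = "c",
                                   reference_gene = "RpL32", delta_cq = 1))
  expect_error(anova_per_gene(singleton), "fewer than 2")
})

test_that("Scheffe pairwise p-values match the hand-computed statistic", {
  d <- data.frame(sample_class = rep(c("a", "b", "c"), each = 4),
                  reference_gene = "RpL32",
                  delta_cq = c(6, 8, 4, 5, 8, 12, 9, 11, 13, 9, 11, 8))
  p <- scheffe_pairwise(d)
  fit <- anova_per_gene(d)
  m <- fit$group_means
  s_ab <- (m["a"] - m["b"])^2 / (fit$mse * (1 / 4 + 1 / 4) * 2)
  expect_equal(p["a", "b"], unname(pf(s_ab, 2, 9, lower.tail = FALSE)),
               tolerance = 1e-12)
  expect_true(isSymmetric(p))
  expect_equal(diag(p), setNames(rep(1, 3), c("a", "b", "c")))
})

test_that("with two groups Scheffe reduces to the pooled-variance F test", {
  set.seed(8)
  d <- data.frame(sample_class = rep(c("a", "b"), each = 6),
                  reference_gene = "RpL32", delta_cq = rnorm(12, c(0, 1)))
  p <- scheffe_pairwise(d)
  expect_equal(p["a", "b"], anova_per_gene(d)$p_value, tolerance = 1e-12)
})

test_that("Scheffe is conservative relative to the unadjusted pairwise F test", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    d <- data.frame(sample_class = rep(letters[1:k], each = 5),
                    reference_gene = "RpL32",
                    delta_cq = rnorm(5 * k, rep(rnorm(k, sd = 0.5), each = 5), 0.4))
    p <- scheffe_pairwise(d)
    fit <- anova_per_gene(d)
    m <- fit$group_means; N <- 5 * k
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      f_raw <- (m[i] - m[j])^2 / (fit$mse * (2 / 5))
      p_raw <- pf(f_raw, 1, N - k, lower.tail = FALSE)
      expect_gte(p[i, j], p_raw - 1e-12)
    }
  }
})

test_that("zero residual variance yields the documented degenerate p-values", {
  d <- data.frame(sample_class = rep(c("a", "b", "c"), each = 3),
                  reference_gene = "RpL32",
                  delta_cq = rep(c(1, 1, 2), each = 3))
  expect_warning(p <- scheffe_pairwise(d), "MSE")
  expect_equal(p["a", "b"], 1)  # equal means
  expect_equal(p["a", "c"], 0)  # unequal means, zero noise
})

test_that("BH q-values follow the step-up rule and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  # q >= p elementwise; lowering a p never raises any q
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(15)
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12))
    i <- sample(15, 1)
    p2 <- p; p2[i] <- p[i] / 2
    expect_true(all(bh_fdr(p2) <= q + 1e-12))
  }
})

test_that("letter display satisfies the sharing-iff-nonsignificant contract", {
  # all non-significant: single letter everywhere
  all_ns <- matrix(TRUE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(letter_display(all_ns)), rep("a", 3))
  # A|B significant, C compatible with both
  m <- matrix(TRUE, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- FALSE
  expect_equal(letter_display(m), c(A = "a", B = "b", C = "ab"))
  # all significant: distinct letters
  all_sig <- diag(4) == 1
  dimnames(all_sig) <- list(letters[1:4], letters[1:4])
  expect_equal(unname(letter_display(all_sig)), c("a", "b", "c", "d"))
  expect_error(letter_display(matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)),
               "symmetric")
})

test_that("letter display is sound and complete on random matrices up to 6 classes", {
  set.seed(17)
  for (rep in 1:60) {
    k <- sample(2:6, 1)
    m <- matrix(runif(k * k) > 0.45, k, k)
    m <- m | t(m); diag(m) <- TRUE
    dimnames(m) <- list(letters[1:k], letters[1:k])
    lets <- strsplit(letter_display(m), "")
    for (i in 1:k) for (j in 1:k) {
      shares <- length(intersect(lets[[i]], lets[[j]])) > 0
      expect_identical(shares, m[i, j],
                       info = sprintf("rep %d classes %d/%d", rep, i, j))
    }
  }
})

test_that("joint FDR correction spans all genes' pairwise comparisons", {
  set.seed(2)
  means <- expand.grid(gene = c("g1", "g2"), sample_class = c("a", "b", "c"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  means$mean_dcq <- c(-2, -2, -2, -5, -2.2, -5)
  sc <- expression_scenario(means, replicate_sd = 0.25, n_replicates = 4, seed = 9)
  dcq <- compute_delta_cq(generate_cq_table(sc))
  joint <- expression_significance(dcq, fdr_scope = "joint")
  per <- expression_significance(dcq, fdr_scope = "per_gene")
  # identical raw p-values, different families
  expect_equal(joint$g1$pairwise, per$g1$pairwise)
  all_p <- c(joint$g1$pairwise[upper.tri(joint$g1$pairwise)],
             joint$g2$pairwise[upper.tri(joint$g2$pairwise)])
  q_joint <- bh_fdr(all_p)
  expect_equal(joint$g1$qvalues[upper.tri(joint$g1$qvalues)], q_joint[1:3],
               tolerance = 1e-12)
  # every class is lettered, q >= p
  expect_true(all(nchar(unlist(lapply(joint, `[[`, "letters"))) >= 1))
  expect_true(all(joint$g2$qvalues >= joint$g2$pairwise - 1e-12))
})
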