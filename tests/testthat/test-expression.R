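test_that("normalization removes a planted cubic dye bias from null genes", {
  sim <- generate_experiment(n_genes = c(human = 500, mouse = 60),
                             category_props = c(null = 1),
                             dye_bias_coef = c(0.25, -0.1, 0.02, 0.015),
                             times_hr = 24, seed = 10)
  norm <- normalize_expression(sim$expression, sim$samples)
  hs <- norm$values[sim$truth$species == "human",
                    grepl("^hs", colnames(norm$values))]
  expect_lt(max(abs(colMeans(hs, na.rm = TRUE))), 0.05)
})

test_that("normalization is near-identity without bias and absorbs shifts", {
  sim <- generate_experiment(n_genes = c(human = 300, mouse = 60),
                             category_props = c(null = 1),
                             dye_bias_coef = c(0, 0, 0, 0),
                             times_hr = 24, n_reps = 1, seed = 11)
  sheet <- sim$samples
  norm <- normalize_expression(sim$expression, sheet)
  aid <- grep("^hs", unique(sheet$array_id), value = TRUE)[1]
  rows <- sheet[sheet$array_id == aid, ]
  trt <- rows$sample_id[rows$treatment == "TCDD"]
  ctl <- rows$sample_id[rows$treatment == "vehicle"]
  hs_rows <- sim$truth$species == "human"
  raw_M <- log2(sim$expression$values[hs_rows, trt] /
                  sim$expression$values[hs_rows, ctl])
  expect_lt(stats::median(abs(norm$values[hs_rows, aid] - raw_M)), 0.05)
  # a constant +0.5 shift on every probe is absorbed by the trend
  shifted <- sim$expression
  shifted$values[hs_rows, trt] <- shifted$values[hs_rows, trt] * 2^0.5
  norm2 <- normalize_expression(shifted, sheet)
  expect_lt(abs(mean(norm2$values[hs_rows, aid])), 0.05)
})

test_that("normalization refuses arrays too small for trend fitting", {
  sheet <- tiny_sheet()
  vals <- matrix(2^stats::rnorm(12, 10), 3, 4,
                 dimnames = list(NULL, sheet$sample_id))
  expr <- expression_table(vals, paste0("p", 1:3), paste0("g", 1:3))
  expect_error(normalize_expression(expr, sheet), "fewer than 20 probes")
})

test_that("dye-swap replicates come out sign-aligned after normalization", {
  sim <- generate_experiment(n_genes = c(human = 200, mouse = 60),
                             category_props = c(null = 0.8,
                                                conserved_up = 0.2),
                             times_hr = 24, seed = 12)
  norm <- normalize_expression(sim$expression, sim$samples)
  planted <- sim$truth$gene_id[sim$truth$species == "human" &
                                 sim$truth$effect_log2 > 0]
  fwd <- grep("^hs.*fwd$", colnames(norm$values), value = TRUE)
  swp <- grep("^hs.*swp$", colnames(norm$values), value = TRUE)
  expect_gt(min(rowMeans(norm$values[planted, fwd])), 1)
  expect_gt(min(rowMeans(norm$values[planted, swp])), 1)
})

test_that("empirical Bayes separates a large effect from tight nulls", {
  sim <- generate_experiment(n_genes = c(human = 300, mouse = 60),
                             category_props = c(null = 0.9,
                                                conserved_up = 0.1),
                             effect_log2 = 3, noise_sd = 0.1,
                             times_hr = 24, seed = 13)
  norm <- normalize_expression(sim$expression, sim$samples)
  fit <- fit_empirical_bayes(norm, species = "human", time_hr = 24)
  truth <- sim$truth[sim$truth$species == "human", ]
  m <- merge(fit, truth, by = "gene_id")
  expect_true(all(m$p1[m$effect_log2 == 3] > 0.999))
  expect_lt(mean(m$p1[m$effect_log2 == 0] > 0.999), 0.005)
})

test_that("P1 is monotone in |t| and invariant to replicate order", {
  # monotonicity of the two-component posterior (strict until the odds
  # saturate double precision)
  t_grid <- seq(0, 8, by = 0.25)
  p <- posterior_p1(t_grid, df = 9)
  expect_true(all(diff(p) > 0))
  expect_equal(posterior_p1(-t_grid, df = 9), p)  # symmetric in sign
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(posterior_p1(50, df = 9), 1)       # saturates cleanly
  # permuting replicate arrays leaves every statistic unchanged
  sim <- generate_experiment(n_genes = c(human = 100, mouse = 60),
                             times_hr = 24, seed = 14)
  norm <- normalize_expression(sim$expression, sim$samples)
  fit1 <- fit_empirical_bayes(norm, species = "human", time_hr = 24)
  ai <- array_info(norm)
  perm <- c(sample(which(ai$species == "human")),
            which(ai$species != "human"))
  norm_p <- norm
  norm_p$values <- norm_p$values[, ai$array_id[perm]]
  attr(norm_p, "array_info") <- ai[perm, ]
  fit2 <- fit_empirical_bayes(norm_p, species = "human", time_hr = 24)
  expect_equal(fit1[order(fit1$gene_id), c("m_bar", "t_mod", "p1")],
               fit2[order(fit2$gene_id), c("m_bar", "t_mod", "p1")],
               ignore_attr = TRUE)
})

test_that("two genes of equal variance order their P1 by |effect|", {
  sheet <- rbind(tiny_sheet(), within(tiny_sheet(), {
    sample_id <- sub("^a", "b", sample_id)
    array_id <- sub("^a", "b", array_id)
    replicate <- 2
  }))
  M <- rbind(g_small = c(0.1, 0.6, -0.4, 0.1),
             g_big = c(2.0, 2.5, 1.5, 2.0))
  arrays <- unique(sheet$array_id)
  vals <- matrix(NA_real_, 2, length(arrays),
                 dimnames = list(rownames(M), arrays))
  vals[] <- M
  expr <- expression_table(vals, rownames(M), rownames(M), "log2_ratio")
  attr(expr, "array_info") <- data.frame(
    array_id = arrays, species = "mouse", time_hr = 24, replicate = 1:4,
    contrast = "TCDD vs vehicle", stringsAsFactors = FALSE)
  fit <- fit_empirical_bayes(expr)
  expect_gt(fit$p1[fit$gene_id == "g_big"],
            fit$p1[fit$gene_id == "g_small"])
})

test_that("DE thresholds are strict at exactly P1 = 0.999 and |FC| = 1.4", {
  df <- data.frame(gene_id = paste0("g", 1:4), condition = "c",
                   n_arrays = 6,
                   m_bar = log2(c(1.5, 1.4, 5, 1.5)),
                   fc = c(1.5, 1.4, 5, 1.5),
                   t_mod = 10,
                   p1 = c(0.9995, 0.9995, 0.999, 0.999))
  calls <- call_de(df)
  expect_equal(calls$significant, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$direction, c("up", "ns", "ns", "ns"))
  down <- call_de(transform(df, fc = -fc, m_bar = -m_bar))
  expect_equal(down$direction, c("down", "ns", "ns", "ns"))
})

test_that("signed fold change has magnitude >= 1 with sign as direction", {
  expect_equal(signed_fold_change(1), 2)
  expect_equal(signed_fold_change(-log2(1.56)), -1.56)
  expect_equal(signed_fold_change(0), 1)
  x <- stats::rnorm(100)
  expect_true(all(abs(signed_fold_change(x)) >= 1))
  expect_equal(sign(signed_fold_change(x))[x != 0], sign(x)[x != 0])
})

test_that("profile clustering follows hand-computable Euclidean distances", {
  m <- matrix(c(0, 0, 0, 3, 4, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  tree <- cluster_de_profiles(m)
  # first merge joins gA and gB at distance 3
  expect_equal(tree$merge[1, ], c(-1, -2))
  expect_equal(tree$height[1], 3)
  # identical profiles merge at height 0
  m2 <- rbind(m, gD = c(0, 0))
  tree2 <- cluster_de_profiles(m2)
  expect_equal(tree2$height[1], 0)
  # permuting rows leaves the tree invariant (rows sorted internally)
  tree3 <- cluster_de_profiles(m[c(3, 1, 2), ])
  expect_identical(tree3$merge, tree$merge)
  expect_identical(tree3$height, tree$height)
  expect_error(cluster_de_profiles(m[1, , drop = FALSE]), "at least two")
  m_na <- m; m_na["gB", ] <- NA
  expect_error(cluster_de_profiles(m_na), "all-missing")
})

test_that("response percentages use round-half-up at one decimal", {
  expect_identical(response_percentage(691, 6995), 9.9)
  expect_identical(response_percentage(8, 3850), 0.2)
  expect_identical(response_percentage(0, 5000), 0)
  expect_identical(response_percentage(1, 800), 0.1)   # 0.125 rounds up
  expect_identical(response_percentage(1, 4000), 0)    # 0.025 rounds down
  expect_error(response_percentage(1, 0), "positive")
  expect_error(response_percentage(5, 4), "n_de")
})

test_that("moderated t ordering agrees with an independent implementation", {
  skip_if_not_installed("limma")
  sim <- generate_experiment(n_genes = c(human = 200, mouse = 60),
                             times_hr = 24, seed = 15)
  norm <- normalize_expression(sim$expression, sim$samples)
  fit <- fit_empirical_bayes(norm, species = "human", time_hr = 24)
  ai <- array_info(norm)
  cols <- ai$array_id[ai$species == "human" & ai$time_hr == 24]
  mat <- norm$values[fit$gene_id, cols]
  lf <- limma::eBayes(limma::lmFit(mat))
  expect_gt(stats::cor(fit$t_mod, lf$t[, 1], use = "complete.obs",
                       method = "spearman"), 0.99)
  expect_equal(fit$m_bar, unname(lf$coefficients[, 1]), tolerance = 1e-10)
})
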