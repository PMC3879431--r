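test_that("classify_gene agrees with the exhaustive 3x3 lookup", {
  lookup <- list(
    list("+", "+", "PP"), list("-", "-", "MM"), list("+", "-", "PM"),
    list("-", "+", "MP"), list("+", "=", "PE"), list("-", "=", "ME"),
    list("=", "+", "EP"), list("=", "-", "EM"), list("=", "=", "NR"))
  for (case in lookup)
    expect_equal(classify_gene(case[[1]], case[[2]]), case[[3]])
  expect_error(classify_gene("x", "+"), "sign calls")
})

test_that("classification partitions genes and is order-invariant", {
  sim <- simulate_master_table(sim_config(n_genes = 1200, seed = 21))
  cl <- classify_table(sim$master)
  expect_equal(nrow(cl), 1200L)
  expect_true(all(cl$memory_class %in% memory_classes()))
  # order invariance
  perm <- sample(nrow(sim$master))
  cl_perm <- classify_table(sim$master[perm, ])
  expect_identical(cl_perm$memory_class,
                   cl$memory_class[perm])
  # sign-consistency of every non-"=" symbol with thresholds
  lfc1 <- cl$lfc_s1w; lfc2 <- cl$lfc_s3s1
  expect_true(all(lfc1[cl$sign_s1w == "+"] >= 1))
  expect_true(all(lfc1[cl$sign_s1w == "-"] <= -1))
  expect_true(all(lfc2[cl$sign_s3s1 == "+"] >= 1))
  expect_true(all(lfc2[cl$sign_s3s1 == "-"] <= -1))
  expect_true(all(cl$q_s1w[cl$sign_s1w != "="] <= 0.05))
  # memory iff both calls significant
  mem <- cl$memory_class %in% c("PP", "MM", "PM", "MP")
  expect_identical(mem, cl$sign_s1w != "=" & cl$sign_s3s1 != "=")
})

test_that("all-zero expression and missing statistics give NR", {
  m <- data.frame(gene_id = c("a", "b"),
                  fpkm_w = c(0, 0), fpkm_s1 = c(0, 0), fpkm_s3 = c(0, 0),
                  lfc_s1w = c(0, 0), q_s1w = c(1, 1),
                  lfc_s3s1 = c(0, 0), q_s3s1 = c(1, 1))
  cl <- classify_table(m)
  expect_true(all(cl$memory_class == "NR"))

  m2 <- m[, c("gene_id", "fpkm_w", "fpkm_s1", "fpkm_s3")]
  m2$fpkm_s1 <- c(10, 20)
  # one missing-q warning per contrast
  expect_warning(expect_warning(cl2 <- classify_table(m2),
                                "missing q-value"), "missing q-value")
  expect_true(all(cl2$memory_class == "NR"))
})

test_that("replicate-only tables classify through the Welch path", {
  sim <- simulate_master_table(sim_config(
    n_genes = 300, n_replicates = 4, replicate_cv = 0.05, seed = 31))
  m <- sim$master[, setdiff(names(sim$master),
                            c("q_s1w", "q_s3s1", "lfc_s1w", "lfc_s3s1"))]
  cl <- classify_table(m)
  # with tiny replicate noise and 4 replicates the planted responsive
  # genes dominate; agreement should be near-perfect
  agree <- mean(cl$memory_class == sim$truth$planted_class)
  expect_gt(agree, 0.95)
})

test_that("class summary reproduces totals and partition invariants", {
  counts <- setNames(rep(1L, 9), memory_classes())
  s <- summarize_classes(make_classified(counts))
  expect_true(all(s$counts == 1L))
  expect_equal(s$memory_total, 4L)
  expect_equal(s$dehydration_responsive, 6L)
  expect_equal(s$late_total, 2L)

  s0 <- summarize_classes(make_classified(setNames(integer(9),
                                                   memory_classes())))
  expect_equal(s0$total_genes, 0L)
  expect_true(all(s0$counts == 0L))
})

test_that("scatter coordinates cover exactly the S1-responding genes", {
  m <- data.frame(gene_id = "g", fpkm_w = 1, fpkm_s1 = 4, fpkm_s3 = 8,
                  lfc_s1w = 2, q_s1w = 0.01, lfc_s3s1 = 1, q_s3s1 = 0.01)
  cl <- classify_table(m)
  xy <- figure_coordinates(cl, epsilon = 0)
  expect_equal(unlist(xy[, c("x", "y1", "y3")], use.names = FALSE),
               c(2, 2, 3))

  sim <- simulate_master_table(sim_config(n_genes = 2000, seed = 17))
  cl2 <- classify_table(sim$master)
  xy2 <- figure_coordinates(cl2)
  expect_setequal(xy2$gene_id, cl2$gene_id[cl2$sign_s1w != "="])
  # revised-response genes return toward watered levels: for PM genes
  # the S3/W ratio is much closer to 0 than the S1/W ratio
  pm <- xy2[xy2$memory_class == "PM", ]
  expect_true(all(pm$y1 >= 1))
  expect_true(all(abs(pm$y3) < abs(pm$y1)))
})
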