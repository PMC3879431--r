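test_that("degenerate proportions give an all-non-responsive table", {
  p <- setNames(rep(0, 9), memory_classes())
  p["NR"] <- 1
  sim <- simulate_master_table(sim_config(n_genes = 50,
                                          class_proportions = p, seed = 4))
  expect_true(all(sim$truth$planted_class == "NR"))
  expect_true(all(abs(sim$truth$planted_lfc_s1w) <= 0.5))
  expect_true(all(abs(sim$truth$planted_lfc_s3s1) <= 0.5))
})

test_that("identical configs produce identical tables", {
  cfg <- sim_config(n_genes = 900,
                    class_proportions = setNames(rep(1 / 9, 9),
                                                 memory_classes()),
                    seed = 1)
  a <- simulate_master_table(cfg)
  b <- simulate_master_table(cfg)
  expect_identical(a, b)
  c2 <- simulate_master_table(sim_config(n_genes = 900,
                                         class_proportions = cfg$class_proportions,
                                         seed = 2))
  expect_false(identical(a$master$fpkm_w, c2$master$fpkm_w))
})

test_that("planted classes are recovered exactly by the classifier", {
  cfg <- sim_config(n_genes = 9000,
                    class_proportions = setNames(rep(1 / 9, 9),
                                                 memory_classes()),
                    effect_lfc_min = 2, seed = 7)
  sim <- simulate_master_table(cfg)
  classified <- classify_table(sim$master)
  expect_identical(classified$memory_class, sim$truth$planted_class)
})

test_that("planted signs, magnitudes, q-values and floors are consistent", {
  sim <- simulate_master_table(sim_config(n_genes = 3000, seed = 9))
  m <- sim$master
  tr <- sim$truth
  sig1 <- tr$planted_lfc_s1w
  resp1 <- abs(sig1) >= 1
  expect_true(all(abs(sig1[resp1]) >= 2 & abs(sig1[resp1]) <= 4))
  expect_true(all(abs(sig1[!resp1]) <= 0.5))
  expect_true(all(m$q_s1w[resp1] <= 0.05))
  expect_true(all(m$q_s1w[!resp1] > 0.05))
  # per-sample means equal replicate means exactly (centred noise)
  expect_equal(rowMeans(cbind(m$fpkm_w_rep1, m$fpkm_w_rep2)), m$fpkm_w)
  # replicate CV near the configured value
  cv <- apply(cbind(m$fpkm_s1_rep1, m$fpkm_s1_rep2), 1, sd) / m$fpkm_s1
  expect_equal(mean(cv), 0.10, tolerance = 0.15)
})

test_that("planted class fractions match proportions within sampling error", {
  cfg <- sim_config(n_genes = 12000, seed = 13)
  sim <- simulate_master_table(cfg)
  obs <- table(factor(sim$truth$planted_class, levels = memory_classes()))
  exp_n <- cfg$n_genes * cfg$class_proportions[memory_classes()]
  se <- sqrt(exp_n * (1 - cfg$class_proportions[memory_classes()]))
  # largest-remainder apportionment is tighter than multinomial 3 SE
  expect_true(all(abs(as.integer(obs) - exp_n) <= pmax(3 * se, 1)))
})

test_that("simulation config invariants are enforced", {
  expect_error(sim_config(class_proportions = setNames(rep(0.2, 9),
                                                       memory_classes())),
               "sum to 1")
  expect_error(sim_config(effect_lfc_min = 0.5))
  expect_error(sim_config(null_lfc_max = 1.2))
  expect_error(sim_config(q_sig_max = 0.2))
  expect_warning(sim_config(n_genes = 10), "may be empty")
})

test_that("annotation simulation honours class-conditional probabilities", {
  sim <- simulate_master_table(sim_config(
    n_genes = 900,
    class_proportions = setNames(rep(1 / 9, 9), memory_classes()),
    seed = 1))
  # all-zero enrichment -> empty map
  ann0 <- simulate_annotation_map(sim$truth, "chloroplast", seed = 1)
  expect_equal(nrow(ann0), 0L)
  # probability 1 -> every planted [-/-] gene annotated
  ann1 <- simulate_annotation_map(sim$truth, "chloroplast",
                                  enrichment = list(MM = c(chloroplast = 1)),
                                  seed = 1)
  mm <- sim$truth$gene_id[sim$truth$planted_class == "MM"]
  expect_setequal(ann1$gene_id, mm)
  # binomial check at p = 0.24 on 10,000 genes of one class
  p <- setNames(rep(0, 9), memory_classes()); p["MM"] <- 1
  big <- simulate_master_table(sim_config(n_genes = 10000,
                                          class_proportions = p, seed = 2))
  ann <- simulate_annotation_map(big$truth, "chloroplast",
                                 enrichment = list(MM = c(chloroplast = 0.24)),
                                 seed = 3)
  frac <- nrow(ann) / 10000
  expect_lt(abs(frac - 0.24), 3 * sqrt(0.24 * 0.76 / 10000))
  expect_error(simulate_annotation_map(sim$truth, "x",
                                       enrichment = list(XX = c(x = 1))),
               "unknown class")
})

test_that("planted TF matrices are binary with block structure", {
  m <- simulate_tf_matrix(n_tfs = 12, n_groups = 3, seed = 5)
  expect_true(all(m %in% c(0L, 1L)))
  expect_identical(m, simulate_tf_matrix(n_tfs = 12, n_groups = 3, seed = 5))
})
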