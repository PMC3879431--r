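test_that("integer percentages use round-half-up", {
  expect_equal(format_percent(75, 310), 24L)
  expect_equal(format_percent(53, 310), 17L)
  expect_equal(format_percent(31, 310), 10L)
  expect_equal(format_percent(121, 857), 14L)
  expect_equal(format_percent(0, 310), 0L)
  expect_equal(format_percent(1, 200), 1L)   # 0.5% rounds up
  expect_equal(format_percent(c(1, 3), 4), c(25L, 75L))
  expect_error(format_percent(1, 0), "positive")
  expect_error(format_percent(5, 4), "class_total")
})

test_that("crosstab counts genes per (category, class) cell", {
  cl <- make_classified(c(PP = 1L, MM = 0L, PM = 0L, MP = 0L, PE = 2L,
                          ME = 0L, EP = 0L, EM = 0L, NR = 0L))
  ann <- data.frame(gene_id = cl$gene_id[1],
                    category = "LEA", stringsAsFactors = FALSE)
  xt <- crosstab(cl, ann)
  expect_equal(xt$counts["LEA", "PP"], 1L)
  expect_equal(xt$percent["LEA", "PP"], 100L)
  expect_equal(sum(xt$counts["LEA", ]), 1L)

  # a gene with two categories is counted once per category row
  ann2 <- rbind(ann, data.frame(gene_id = cl$gene_id[1],
                                category = "membrane"))
  xt2 <- crosstab(cl, ann2)
  expect_equal(xt2$counts["membrane", "PP"], 1L)
  expect_equal(xt2$counts["LEA", "PP"], 1L)

  expect_error(crosstab(cl, ann[0, ]), "no categories")
  # annotated genes missing from the table are ignored with a message
  ann3 <- rbind(ann, data.frame(gene_id = "ghost", category = "LEA"))
  expect_message(xt3 <- crosstab(cl, ann3), "absent")
  expect_equal(xt3$counts["LEA", "PP"], 1L)
})

test_that("crosstab category totals sum over classes correctly", {
  sim <- simulate_master_table(sim_config(n_genes = 2000, seed = 23))
  cl <- classify_table(sim$master)
  ann <- simulate_annotation_map(
    sim$truth, c("chloroplast", "membrane"),
    enrichment = list(MM = c(chloroplast = 0.5),
                      PE = c(membrane = 0.3)),
    base_prob = 0.05, seed = 24)
  xt <- crosstab(cl, ann)
  for (cat in rownames(xt$counts))
    expect_equal(sum(xt$counts[cat, ]),
                 length(unique(ann$gene_id[ann$category == cat])))
  expect_true(all(xt$counts <= matrix(xt$class_totals,
                                      nrow(xt$counts), 9, byrow = TRUE)))
})

test_that("planted enrichment reappears as the expected percentage", {
  p <- setNames(rep(0, 9), memory_classes())
  p["MM"] <- 0.5; p["NR"] <- 0.5
  sim <- simulate_master_table(sim_config(n_genes = 8000,
                                          class_proportions = p, seed = 25))
  cl <- classify_table(sim$master)
  ann <- simulate_annotation_map(sim$truth, "chloroplast",
                                 enrichment = list(MM = c(chloroplast = 0.24)),
                                 seed = 26)
  xt <- crosstab(cl, ann)
  n_mm <- xt$class_totals[["MM"]]
  se_pct <- 100 * 3 * sqrt(0.24 * 0.76 / n_mm)
  expect_lt(abs(xt$percent["chloroplast", "MM"] - 24), se_pct + 0.5)
})

test_that("venn regions obey inclusion-exclusion and class disjointness", {
  cl <- make_classified(c(PP = 5L, MM = 0L, PM = 3L, MP = 0L, PE = 4L,
                          ME = 0L, EP = 0L, EM = 0L, NR = 8L))
  v <- venn_sets(cl, category = "ALL", classes = c("PP", "PM", "PE"))
  expect_equal(v$regions[["PP"]], 5L)
  expect_equal(v$regions[["PM"]], 3L)
  expect_equal(v$regions[["PE"]], 4L)
  # classes partition genes: all intersections empty
  expect_true(all(v$regions[grep("&", names(v$regions))] == 0L))

  # brute-force enumeration oracle on overlapping hand-built sets
  ann <- data.frame(
    gene_id = c(cl$gene_id[1:3], cl$gene_id[6:7]),
    category = "salt", stringsAsFactors = FALSE)
  v2 <- venn_sets(cl, ann, "salt", c("PP", "PM"))
  in_cat <- ann$gene_id
  pp <- intersect(cl$gene_id[cl$memory_class == "PP"], in_cat)
  pm <- intersect(cl$gene_id[cl$memory_class == "PM"], in_cat)
  expect_equal(v2$regions[["PP"]], length(setdiff(pp, pm)))
  expect_equal(v2$regions[["PM"]], length(setdiff(pm, pp)))
  expect_equal(v2$regions[["PP&PM"]], length(intersect(pp, pm)))

  expect_error(venn_sets(cl, category = "ALL",
                         classes = c("PP", "PM", "PE", "ME")), "2 or 3")
  expect_error(venn_sets(cl, category = "ALL", classes = c("PP", "PP")),
               "distinct")
})

test_that("the bundled reference category table is internally consistent", {
  ref <- reference_go_table()
  expect_equal(unname(ref$class_totals),
               c(362L, 310L, 857L, 434L, 2177L, 2439L, 798L, 573L))
  expect_true(all(ref$counts <= matrix(ref$class_totals,
                                       nrow(ref$counts), 8, byrow = TRUE)))
  expect_equal(format_percent(ref$counts["Chloroplast", "MM"],
                              ref$class_totals[["MM"]]), 24L)
})
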