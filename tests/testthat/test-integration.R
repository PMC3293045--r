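test_that("tissue filtering is exact set restriction", {
  tp <- target_pairs(c("m1", "m1"), c("g1", "g2"))
  expect_message(out <- filter_tissue_specific(tp, "g1"), "1 of 2")
  expect_equal(out$gene, "g1")

  expect_message(ident <- filter_tissue_specific(tp, c("g1", "g2", "g3")))
  expect_equal(nrow(ident), 2L)

  expect_warning(expect_message(
    none <- filter_tissue_specific(tp, character())), "empty")
  expect_equal(nrow(none), 0L)

  set.seed(13)
  big <- target_pairs(sample(sprintf("m%02d", 1:20), 1000, TRUE),
                      sample(sprintf("g%03d", 1:300), 1000, TRUE))
  tissue <- sample(sprintf("g%03d", 1:300), 80)
  expect_message(res <- filter_tissue_specific(big, tissue))
  expect_identical(paste(res$mirna, res$gene),
                   paste(big$mirna, big$gene)[big$gene %in% tissue])
})

test_that("coordinate pairs keep exactly the inverse-direction predictions", {
  tp <- target_pairs(c("hsa-miR-29c", "hsa-miR-18a", "m3", "m4"),
                     c("NDST1", "ATM", "g3", "g4"))
  mir <- c("hsa-miR-29c" = "down", "hsa-miR-18a" = "up", m3 = "up")
  gene <- c(NDST1 = "up", ATM = "down", g3 = "up", g4 = "down")
  out <- coordinate_pairs(tp, mir, gene)
  expect_setequal(paste(out$mirna, out$gene),
                  c("hsa-miR-29c NDST1", "hsa-miR-18a ATM"))
  # same-direction pair dropped, uncalled miRNA dropped
  expect_false("m3 g3" %in% paste(out$mirna, out$gene))
  expect_false("m4 g4" %in% paste(out$mirna, out$gene))
  # output is always a subset of the predicted pairs
  expect_true(all(paste(out$mirna, out$gene) %in% paste(tp$mirna, tp$gene)))

  expect_error(coordinate_pairs(tp, c(m1 = "UP"), gene), "up.*down")
})

test_that("the printed coordinate table is a fixed point of the overlay", {
  # The overlay is run per direction stratum (up-miRNAs against
  # down-genes, then the converse), as the printed table itself assigns a
  # handful of genes (e.g. NOTCH2) opposite directions in the two halves.
  t2 <- load_fixture_table("table2")
  out <- do.call(rbind, lapply(c("up", "down"), function(dir) {
    half <- t2[t2$mirna_direction == dir, ]
    coordinate_pairs(target_pairs(half$mirna, half$gene),
                     tapply(half$mirna_direction, half$mirna, `[`, 1),
                     tapply(half$gene_direction, half$gene, `[`, 1))
  }))
  expect_setequal(paste(out$mirna, out$gene), paste(t2$mirna, t2$gene))
  expect_true(all(out$mirna_direction != out$gene_direction))
})

test_that("tissue filter and direction overlay commute", {
  set.seed(14)
  tp <- target_pairs(sample(sprintf("m%d", 1:10), 200, TRUE),
                     sample(sprintf("g%d", 1:50), 200, TRUE))
  tissue <- sprintf("g%d", sample(1:50, 20))
  mir <- setNames(sample(c("up", "down"), 10, TRUE), sprintf("m%d", 1:10))
  gene <- setNames(sample(c("up", "down"), 50, TRUE), sprintf("g%d", 1:50))
  suppressMessages({
    a <- coordinate_pairs(filter_tissue_specific(tp, tissue), mir, gene)
    b0 <- coordinate_pairs(tp, mir, gene)
    b <- b0[b0$gene %in% tissue, ]
  })
  expect_setequal(paste(a$mirna, a$gene), paste(b$mirna, b$gene))
})

test_that("correlation filter keeps planted anti-correlation, drops noise and self", {
  set.seed(15)
  samples <- paste0("s", 1:20)
  m <- rnorm(20)
  gene_anti <- -m + rnorm(20, 0, 0.3)   # r about -0.95
  gene_null <- rnorm(20)
  mm <- rbind(mirA = m, mirSelf = m); colnames(mm) <- samples
  me <- expression_matrix(mm, "miRNA")
  gg <- rbind(gAnti = gene_anti, gNull = gene_null, gSelf = m)
  colnames(gg) <- samples
  ge <- expression_matrix(gg, "mRNA")
  cands <- data.frame(mirna = c("mirA", "mirA", "mirSelf"),
                      gene = c("gAnti", "gNull", "gSelf"))
  out <- correlation_filter(cands, me, ge, r_max = -0.3)
  expect_identical(out$gene, "gAnti")
  expect_lt(out$correlation, -0.6)

  out0 <- correlation_filter(cands[3, ], me, ge, r_max = 0)
  expect_equal(nrow(out0), 0L)  # r = +1 never passes

  tiny <- expression_matrix(matrix(1:4, 2, 2,
                                   dimnames = list(c("a", "b"),
                                                   c("s1", "s2"))), "mRNA")
  expect_error(correlation_filter(cands, me, tiny), ">= 3 shared")
})

test_that("independent profiles rarely pass an anti-correlation threshold", {
  set.seed(16)
  dropped <- 0L
  for (i in 1:40) {
    me <- expression_matrix(matrix(rnorm(22), 1, 22,
                                   dimnames = list("m", paste0("s", 1:22))),
                            "miRNA")
    ge <- expression_matrix(matrix(rnorm(22), 1, 22,
                                   dimnames = list("g", paste0("s", 1:22))),
                            "mRNA")
    out <- correlation_filter(data.frame(mirna = "m", gene = "g"),
                              me, ge, r_max = -0.3)
    if (nrow(out) == 0L) dropped <- dropped + 1L
  }
  expect_gte(dropped / 40, 0.95)
})
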