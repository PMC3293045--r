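test_that("bipartite network counts degrees and handles empty input", {
  tp <- target_pairs(rep("m1", 3), c("g1", "g2", "g3"))
  net <- build_bipartite_network(tp)
  deg <- setNames(net$nodes$degree, net$nodes$id)
  expect_equal(deg[["m1"]], 3L)
  expect_equal(unname(deg[c("g1", "g2", "g3")]), rep(1L, 3))
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))

  empty <- build_bipartite_network(target_pairs(character(), character()))
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("the printed coordinate table yields the printed hub degree", {
  t2 <- load_fixture_table("table2")
  net <- build_bipartite_network(target_pairs(t2$mirna, t2$gene))
  deg <- setNames(net$nodes$degree, net$nodes$id)
  expect_equal(deg[["hsa-miR-34c-5p"]], 21L)
})

test_that("hub calling equals a brute-force degree filter", {
  star <- target_pairs(rep("hub", 12), sprintf("g%02d", 1:12))
  h <- hub_nodes(build_bipartite_network(star), min_degree = 10)
  expect_identical(h$id, "hub")
  expect_equal(nrow(hub_nodes(build_bipartite_network(star),
                              min_degree = 13)), 0L)
  # strict mode excludes ties at the threshold
  ten <- build_bipartite_network(
    target_pairs(rep("m", 10), sprintf("g%02d", 1:10)))
  expect_identical(hub_nodes(ten, 10)$id, "m")
  expect_equal(nrow(hub_nodes(ten, 10, strict = TRUE)), 0L)

  set.seed(19)
  rnd <- unique(data.frame(m = sample(sprintf("m%02d", 1:15), 200, TRUE),
                           g = sample(sprintf("g%02d", 1:40), 200, TRUE)))
  net <- build_bipartite_network(target_pairs(rnd$m, rnd$g))
  got <- hub_nodes(net, min_degree = 5)
  all_ids <- c(rnd$m, rnd$g)
  brute <- sort(names(which(table(all_ids) >= 5)))
  expect_setequal(got$id, brute)
  expect_true(all(diff(got$degree) <= 0))  # ranked by degree
})

test_that("motif scanning finds planted and degenerate sites exactly", {
  set.seed(20)
  prom <- random_seq(200)
  substr(prom, 38, 43) <- "GGGCGG"  # 0-based offset 37
  # guard against a chance second occurrence in the random backdrop
  hits <- scan_promoters(c(mirX = prom), c(TFa = "GGGCGG"),
                         max_mismatch = 0, both_strands = FALSE)
  expect_true(any(hits$position == 37 & hits$strand == "+"))
  expect_identical(hits$match[hits$position == 37], "GGGCGG")

  none <- scan_promoters(c(mirX = "ATATATATAT"), c(TFa = "GGGCGG"))
  expect_equal(nrow(none), 0L)

  iupac <- scan_promoters(c(m = "ACG"), c(tf = "RYGA"))
  expect_equal(nrow(iupac), 0L)  # motif longer than sequence
  hit <- scan_promoters(c(m = "ACGT"), c(tf = "RYGW"),
                        both_strands = FALSE)
  expect_equal(hit$position, 0L)  # R~A, Y~C, W~T by IUPAC expansion

  expect_error(scan_promoters(c(m = "ACGT"), c(tf = "GGXCGG")), "X")
})

test_that("scanning matches the naive sliding-window oracle", {
  set.seed(22)
  codes <- c("A", "C", "G", "T", "R", "Y", "N")
  for (i in 1:25) {
    seqs <- setNames(lapply(1:4, function(j) random_seq(60)),
                     paste0("m", 1:4))
    motif <- paste(sample(codes, 5, replace = TRUE, prob =
                            c(3, 3, 3, 3, 1, 1, 1) / 15), collapse = "")
    mm <- sample(0:1, 1)
    got <- scan_promoters(unlist(seqs), setNames(motif, "tf"),
                          max_mismatch = mm)
    want <- naive_scan(seqs, list(tf = motif), max_mismatch = mm)
    expect_identical(paste(got$mirna, got$position, got$strand),
                     paste(want$mirna, want$position, want$strand))
  }
})

test_that("strand handling is reverse-complement symmetric", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_seq(80)
    rc <- revcomp_chr(s)
    motif <- c(tf = paste(sample(c("A", "C", "G", "T", "R"), 6, TRUE),
                          collapse = ""))
    h1 <- scan_promoters(c(m = s), motif)
    h2 <- scan_promoters(c(m = rc), motif)
    expect_equal(nrow(h1), nrow(h2))
    # positions map p -> len - L - p with strands swapped
    remap <- sort(80 - 6 - h2$position)
    expect_equal(sort(h1$position), remap)
  }
})

test_that("TF-miRNA network edges carry Pearson regulatory ability", {
  hits <- data.frame(tf = rep(c("TFa", "TFb"), each = 3),
                     mirna = rep(c("m1", "m2", "m3"), 2))
  net <- build_tf_mirna_network(hits)
  expect_equal(nrow(net$edges), 6L)
  deg <- setNames(net$nodes$degree, net$nodes$id)
  expect_equal(unname(deg[c("TFa", "TFb")]), c(3L, 3L))

  samples <- paste0("s", 1:6)
  tfm <- matrix(c(1, 2, 3, 4, 5, 6, 6, 4, 5, 1, 2, 3), 2, byrow = TRUE,
                dimnames = list(c("TFa", "TFb"), samples))
  mim <- matrix(c(1, 2, 3, 4, 5, 6, 2, 1, 4, 3, 6, 5), 2, byrow = TRUE,
                dimnames = list(c("m1", "m2"), samples))
  net2 <- build_tf_mirna_network(hits[hits$mirna %in% c("m1", "m2"), ],
                                 expression_matrix(tfm, "mRNA"),
                                 expression_matrix(mim, "miRNA"))
  w <- net2$edges
  expect_equal(w$weight[w$from == "TFa" & w$to == "m1"], 1.0)
  for (i in seq_len(nrow(w)))
    expect_equal(w$weight[i], cor(tfm[w$from[i], ], mim[w$to[i], ]))

  short <- expression_matrix(matrix(1:4, 2, 2,
                                    dimnames = list(c("TFa", "TFb"),
                                                    c("s1", "s2"))), "mRNA")
  expect_error(build_tf_mirna_network(hits, short,
                                      expression_matrix(mim, "miRNA")),
               ">= 3 shared")
})

test_that("core TF ranking equals brute-force degree counting", {
  set.seed(24)
  hits <- unique(data.frame(tf = sample(sprintf("TF%02d", 1:12), 300, TRUE),
                            mirna = sample(sprintf("m%02d", 1:40), 300,
                                           TRUE)))
  net <- build_tf_mirna_network(hits)
  got <- core_tfs(net, min_degree = 12)
  brute <- table(hits$tf)
  expect_setequal(got$id, names(brute)[brute >= 12])
  expect_equal(got$degree, as.integer(brute[got$id]))
  expect_true(all(diff(got$degree) <= 0))
})

test_that("feedback-loop mining equals the brute-force double loop", {
  set.seed(25)
  tfs <- sprintf("TF%02d", 1:8); mirs <- sprintf("m%02d", 1:20)
  hits <- unique(data.frame(tf = sample(tfs, 60, TRUE),
                            mirna = sample(mirs, 60, TRUE)))
  pairs <- target_pairs(sample(mirs, 80, TRUE),
                        sample(c(tfs, sprintf("g%02d", 1:30)), 80, TRUE))
  net <- build_tf_mirna_network(hits)
  got <- find_feedback_loops(net, pairs)
  brute <- list()
  for (tf in tfs) for (m in mirs)
    if (any(hits$tf == tf & hits$mirna == m) &&
        any(pairs$mirna == m & pairs$gene == tf))
      brute[[length(brute) + 1L]] <- paste(tf, m)
  expect_setequal(paste(got$tf, got$mirna), unlist(brute))
  expect_identical(got$target_gene, got$tf)

  disjoint <- target_pairs("m01", "geneZ")
  expect_equal(nrow(find_feedback_loops(net, disjoint)), 0L)
})

test_that("typed-edge invariants are enforced", {
  nodes <- data.frame(id = c("TFa", "m1", "g1"),
                      type = c("TF", "miRNA", "gene"))
  bad <- data.frame(from = "m1", to = "TFa", type = "tf_binds_mirna")
  expect_error(regulatory_network(nodes, bad), "TF -> miRNA")
  ok <- regulatory_network(nodes,
                           data.frame(from = c("TFa", "m1"),
                                      to = c("m1", "g1"),
                                      type = c("tf_binds_mirna",
                                               "mirna_targets_gene")))
  expect_equal(sum(ok$nodes$degree), 2 * nrow(ok$edges))
})
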