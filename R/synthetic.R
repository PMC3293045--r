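#' Stage-mean trajectory of a planted dynamic pattern
#'
#' Offsets (log2 units, reference stage at 0) describing each of the six
#' dynamic patterns over an ordered 5-stage design: 1 gradual decrease,
#' 2 early decrease then plateau, 3 down-then-up, 4 up-then-down,
#' 5 gradual increase, 6 flat then metastasis spike.
#'
#' @param pattern Integer in 1..6.
#' @param effect_size Total trajectory span in log2 units (> 0).
#' @param n_stages Number of stages (currently fixed at 5).
#' @return Numeric vector of per-stage offsets.
#' @export
pattern_trajectory <- function(pattern, effect_size, n_stages = 5L) {
  if (n_stages != 5L) stop("pattern trajectories are defined for 5 stages")
  if (effect_size <= 0) stop("effect_size must be > 0")
  E <- effect_size
  switch(pattern,
         seq(0, -E, length.out = 5L),
         c(0, -E, -E, -E, -E),
         c(0, -E, -E, -E, 0),
         c(0, E, E, E, 0),
         seq(0, E, length.out = 5L),
         c(0, 0, 0, 0, E),
         stop("pattern must be in 1..6"))
}

#' Simulate staged expression with planted differential features
#'
#' Generates a log2 feature-by-sample matrix under the exact statistical
#' assumptions the moderated-F screen makes: per-feature true variances
#' are inverse-gamma (reciprocals gamma with the prior's shape and
#' scale), noise is Gaussian on the log2 scale, null features share one
#' mean across stages, and each planted differential feature follows one
#' of the six dynamic-pattern trajectories scaled to `effect_size`.
#'
#' Defaults mirror the targeted study: 766 detected miRNAs, 48 of them
#' differential, over the 22-sample 6/4/4/4/4 staged design.
#'
#' @param n_features Number of features (default 766).
#' @param design A [stage_design] (default [npc_stage_design()]).
#' @param prior An [rvm_prior] for the variance model (default
#'   `rvm_prior(2, 1.5)`).
#' @param n_de Number of planted differential features (default 48).
#' @param pattern_mix Proportions over patterns 1..6 (must sum to 1).
#' @param effect_size Trajectory span in log2 units (default 3.5, about
#'   an 11-fold overall change — the magnitude of array changes that
#'   validate cleanly by qPCR).
#' @param baseline_mean,baseline_sd Distribution of feature baseline
#'   log2 intensities (defaults 8 and 2).
#' @param seed Integer seed; same seed gives a bit-identical matrix.
#' @return List with `matrix` (an [expression_matrix]) and `truth`
#'   (class `synthetic_truth`): `de` data.frame (`feature_id`, `pattern`,
#'   per-stage `offset_*` columns), `sigma2`, `prior`, `seed`.
#' @export
generate_staged_expression <- function(n_features = 766L,
                                       design = npc_stage_design(),
                                       prior = rvm_prior(2, 1.5),
                                       n_de = 48L,
                                       pattern_mix = rep(1 / 6, 6),
                                       effect_size = 3.5,
                                       baseline_mean = 8,
                                       baseline_sd = 2,
                                       seed = 1L) {
  if (n_de > n_features) stop("n_de exceeds n_features")
  if (abs(sum(pattern_mix) - 1) > 1e-8 || any(pattern_mix < 0))
    stop("pattern_mix must be non-negative proportions summing to 1")
  if (effect_size <= 0) stop("effect_size must be > 0")
  set.seed(seed)
  ids <- sprintf("syn-miR-%04d", seq_len(n_features))
  g <- design_factor(design, names(design$samples))
  n <- length(g)

  sigma2 <- 1 / stats::rgamma(n_features, shape = prior$a,
                              scale = prior$b)
  baseline <- stats::rnorm(n_features, baseline_mean, baseline_sd)
  de_idx <- sort(sample.int(n_features, n_de))
  # largest-remainder apportionment of n_de over the pattern mix
  quota <- pattern_mix * n_de
  counts <- floor(quota)
  rem <- n_de - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  patterns <- rep(seq_len(6L), counts)

  offsets <- matrix(0, n_features, nlevels(g),
                    dimnames = list(ids, levels(g)))
  for (j in seq_along(de_idx))
    offsets[de_idx[j], ] <- pattern_trajectory(patterns[j], effect_size)

  vals <- baseline + offsets[, as.integer(g)] +
    matrix(stats::rnorm(n_features * n, 0, sqrt(sigma2)), n_features, n)
  colnames(vals) <- names(design$samples)
  rownames(vals) <- ids

  de <- data.frame(feature_id = ids[de_idx], pattern = patterns,
                   stringsAsFactors = FALSE)
  for (s in levels(g)) de[[paste0("offset_", s)]] <- offsets[de_idx, s]
  truth <- structure(list(de = de, sigma2 = stats::setNames(sigma2, ids),
                          prior = prior, seed = seed),
                     class = "synthetic_truth")
  list(matrix = expression_matrix(vals, "miRNA"), truth = truth)
}

#' Simulate a regulome: targets, promoters, motifs and feedback loops
#'
#' Generates paired miRNA/mRNA/TF expression over the staged design, a
#' predicted target-pair set, TF consensus motifs, upstream promoter
#' sequences, and plants exactly `loop_count` TF-miRNA feedback loops:
#' for each loop the TF's motif is written into that miRNA's promoter and
#' the miRNA's target set gains the TF's own gene. Planted miRNA-target
#' pairs are anti-correlated by construction (generative Pearson r of
#' about -0.8, always below -0.6); background promoter sequence is
#' i.i.d. uniform ACGT and background genes are expression noise.
#'
#' Every planted-regulome miRNA carries a monotone stage trend (up or
#' down) so that direction-overlay integration is exercised end to end.
#'
#' @param n_mirnas,n_genes,n_tfs Node counts (defaults 30, 200, 8).
#' @param loop_count Number of planted feedback loops (default 3, as in
#'   the targeted study's three self-repressing TFs); must not exceed
#'   `min(n_tfs, n_mirnas)`.
#' @param promoter_bp Upstream window length in bp (default 1000).
#' @param design A [stage_design].
#' @param targets_per_mirna Predicted targets per miRNA including the
#'   planted anti-correlated ones (default 8).
#' @param anticorr_per_mirna Planted anti-correlated targets per miRNA
#'   (default 2).
#' @param effect_size Stage-trend span for miRNAs, log2 units.
#' @param motif_length Length of the (non-degenerate) TF consensus
#'   motifs (default 10).
#' @param seed Integer seed.
#' @return List with `pairs` ([target_pairs]), `motifs` ([motif_set]),
#'   `promoters` ([promoter_set]), `mirna_expr`, `mrna_expr` (includes
#'   one row per TF gene), `tf_expr`, and `truth` (class
#'   `synthetic_truth`) holding `loops`, `motif_sites`, `anticorr_pairs`
#'   and `seed`.
#' @export
generate_regulome <- function(n_mirnas = 30L, n_genes = 200L, n_tfs = 8L,
                              loop_count = 3L, promoter_bp = 1000L,
                              design = npc_stage_design(),
                              targets_per_mirna = 8L,
                              anticorr_per_mirna = 2L,
                              effect_size = 3.5, motif_length = 10L,
                              seed = 1L) {
  if (loop_count > min(n_tfs, n_mirnas))
    stop("loop_count exceeds min(n_tfs, n_mirnas)")
  if (promoter_bp < motif_length)
    stop("promoter window shorter than the motif length")
  if (anticorr_per_mirna * n_mirnas > n_genes)
    stop("not enough genes for the requested anti-correlated pairs")
  set.seed(seed)
  mirnas <- sprintf("syn-miR-%03d", seq_len(n_mirnas))
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  g <- design_factor(design, names(design$samples))
  n <- length(g)
  samples <- names(design$samples)

  # miRNA expression: monotone up or down stage trend + noise
  mir_dir <- sample(c(-1, 1), n_mirnas, replace = TRUE)
  mir_expr <- matrix(0, n_mirnas, n, dimnames = list(mirnas, samples))
  for (i in seq_len(n_mirnas)) {
    traj <- pattern_trajectory(if (mir_dir[i] < 0) 1L else 5L, effect_size)
    mir_expr[i, ] <- 8 + traj[as.integer(g)] + stats::rnorm(n, 0, 0.7)
  }

  # planted anti-correlated targets: gene profile = mirrored miRNA + noise
  anti_gene <- function(x) {
    x_c <- x - mean(x)
    8 - x_c + stats::rnorm(length(x), 0, 0.75 * stats::sd(x))
  }
  mrna_expr <- matrix(stats::rnorm(n_genes * n, 8, 1.2), n_genes, n,
                      dimnames = list(genes, samples))
  anticorr <- data.frame(mirna = character(), gene = character(),
                         stringsAsFactors = FALSE)
  pool <- sample(genes)  # disjoint planted genes across miRNAs
  taken <- 0L
  pair_m <- character(); pair_g <- character()
  for (i in seq_len(n_mirnas)) {
    planted <- pool[taken + seq_len(anticorr_per_mirna)]
    taken <- taken + anticorr_per_mirna
    for (gg in planted) mrna_expr[gg, ] <- anti_gene(mir_expr[i, ])
    anticorr <- rbind(anticorr,
                      data.frame(mirna = mirnas[i], gene = planted,
                                 stringsAsFactors = FALSE))
    background <- sample(setdiff(genes, planted),
                         max(0L, targets_per_mirna - anticorr_per_mirna))
    pair_m <- c(pair_m, rep(mirnas[i], length(planted) + length(background)))
    pair_g <- c(pair_g, planted, background)
  }

  # TF motifs and promoters; loops pair TF i with a distinct random miRNA
  motifs <- motif_set(stats::setNames(
    vapply(seq_len(n_tfs), function(i)
      paste(sample(c("A", "C", "G", "T"), motif_length, replace = TRUE),
            collapse = ""), character(1)), tfs))
  promoters <- vapply(seq_len(n_mirnas), function(i)
    paste(sample(c("A", "C", "G", "T"), promoter_bp, replace = TRUE),
          collapse = ""), character(1))
  names(promoters) <- mirnas
  loop_mirnas <- sample(mirnas, loop_count)
  motif_sites <- data.frame(tf = character(), mirna = character(),
                            position = integer(), stringsAsFactors = FALSE)
  tf_expr <- matrix(stats::rnorm(n_tfs * n, 8, 1), n_tfs, n,
                    dimnames = list(tfs, samples))
  for (j in seq_len(loop_count)) {
    tf <- tfs[j]; m <- loop_mirnas[j]
    pos <- sample.int(promoter_bp - motif_length + 1L, 1L) - 1L  # 0-based
    substr(promoters[m], pos + 1L, pos + motif_length) <- motifs[[tf]]
    motif_sites <- rbind(motif_sites,
                         data.frame(tf = tf, mirna = m, position = pos,
                                    stringsAsFactors = FALSE))
    pair_m <- c(pair_m, m); pair_g <- c(pair_g, tf)
    tf_expr[tf, ] <- anti_gene(mir_expr[m, ])
  }
  mrna_expr <- rbind(mrna_expr, tf_expr)

  truth <- structure(list(
    loops = data.frame(tf = tfs[seq_len(loop_count)],
                       mirna = loop_mirnas, stringsAsFactors = FALSE),
    motif_sites = motif_sites,
    anticorr_pairs = anticorr,
    mirna_direction = stats::setNames(ifelse(mir_dir < 0, "down", "up"),
                                      mirnas),
    seed = seed), class = "synthetic_truth")
  list(pairs = target_pairs(pair_m, pair_g, "synthetic regulome"),
       motifs = motifs,
       promoters = promoter_set(promoters, promoter_bp),
       mirna_expr = expression_matrix(mir_expr, "miRNA"),
       mrna_expr = expression_matrix(mrna_expr, "mRNA"),
       tf_expr = expression_matrix(tf_expr, "mRNA"),
       truth = truth)
}

#' Simulate a qPCR Ct table from true fold changes
#'
#' Inverts the comparative-Ct model: for each assayed target the
#' calibrator group sits at a baseline dCt and the case group at
#' `dCt - log2(fold)`, so that noiseless records recover `true_folds`
#' exactly through [qpcr_fold_changes]. Gaussian cycle noise of
#' `ct_noise_sd` is added independently to every Ct measurement;
#' each condition is measured in `n_replicates`.
#'
#' @param true_folds Named numeric vector: target id -> true fold change
#'   (case vs calibrator), all positive.
#' @param ct_noise_sd Per-measurement Ct noise in cycles (default 0.2).
#' @param n_replicates Replicates per condition (default 3).
#' @param reference_id Normalizer assay name (default "U6").
#' @param seed Integer seed.
#' @return data.frame in [qpcr_fold_changes] layout, with groups
#'   `"calibrator"` and `"case"`.
#' @export
generate_ct_table <- function(true_folds, ct_noise_sd = 0.2,
                              n_replicates = 3L, reference_id = "U6",
                              seed = 1L) {
  if (any(true_folds <= 0)) stop("fold changes must be positive")
  if (is.null(names(true_folds))) stop("'true_folds' must be named")
  set.seed(seed)
  rows <- lapply(names(true_folds), function(t) {
    base_ref <- 20; base_tgt <- 27
    mk <- function(group, tgt_mean) data.frame(
      sample_id = sprintf("%s_%s_%d", t, group, seq_len(n_replicates)),
      group = group, target_id = t, reference_id = reference_id,
      ct_target = tgt_mean + stats::rnorm(n_replicates, 0, ct_noise_sd),
      ct_reference = base_ref + stats::rnorm(n_replicates, 0, ct_noise_sd),
      stringsAsFactors = FALSE)
    rbind(mk("calibrator", base_tgt),
          mk("case", base_tgt - log2(true_folds[[t]])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_folds") <- true_folds
  out
}
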