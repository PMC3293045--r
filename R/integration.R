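#' Restrict predicted target pairs to tissue-specific genes
#'
#' First step of the data-reduction strategy: keep only predicted
#' miRNA-target pairs whose target gene is expressed in the tissue of
#' interest (e.g. a nasopharyngeal-specific gene list).
#'
#' @param pairs A [target_pairs] set.
#' @param tissue_genes Character vector of tissue-specific gene ids.
#' @return The filtered [target_pairs]; counts before/after are reported
#'   via `message()`. An empty tissue list returns an empty set with a
#'   warning.
#' @export
filter_tissue_specific <- function(pairs, tissue_genes) {
  if (!length(tissue_genes))
    warning("empty tissue-specific gene list; all pairs removed")
  keep <- pairs$gene %in% tissue_genes
  message("tissue filter: ", sum(keep), " of ", nrow(pairs),
          " predicted pairs retained")
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(pairs, "provenance"),
            class = class(pairs))
}

#' Inverse-direction (coordinate) miRNA-target pairs
#'
#' Second step of the data reduction: of the predicted pairs, retain those
#' whose miRNA and target-gene differential directions are opposite
#' (miRNA up with target down, or miRNA down with target up) — the
#' signature of repression visible in paired expression profiles.
#'
#' @param pairs A [target_pairs] set (already tissue-filtered or not; the
#'   two restrictions commute).
#' @param mirna_calls,gene_calls Named character vectors of `"up"`/`"down"`
#'   calls (e.g. from [overall_direction_calls]); features without a call
#'   are treated as non-significant and their pairs dropped.
#' @return data.frame of class `coordinate_pairs` with columns `mirna`,
#'   `mirna_direction`, `gene`, `gene_direction`, ordered by miRNA then
#'   gene (the printed-table shape).
#' @export
coordinate_pairs <- function(pairs, mirna_calls, gene_calls) {
  check_calls <- function(x, what) {
    if (length(x) && (is.null(names(x)) || !all(x %in% c("up", "down"))))
      stop(what, " must be a named vector of 'up'/'down' calls")
  }
  check_calls(mirna_calls, "mirna_calls")
  check_calls(gene_calls, "gene_calls")
  md <- mirna_calls[pairs$mirna]
  gd <- gene_calls[pairs$gene]
  keep <- !is.na(md) & !is.na(gd) & md != gd
  out <- data.frame(mirna = pairs$mirna[keep],
                    mirna_direction = unname(md[keep]),
                    gene = pairs$gene[keep],
                    gene_direction = unname(gd[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("coordinate_pairs", "data.frame"))
}

#' Expression anti-correlation filter for coordinate pairs
#'
#' Optional third restriction available when paired miRNA and mRNA
#' expression matrices share samples: keep pairs whose Pearson correlation
#' across the shared samples is at most `r_max` (default 0, i.e. any
#' anti-correlation). The correlation is recorded on each retained pair.
#'
#' @param cands A `coordinate_pairs` data.frame (or any data.frame with
#'   `mirna` and `gene` columns).
#' @param mirna_expr,mrna_expr Expression matrices containing the paired
#'   features; at least 3 shared samples are required.
#' @param r_max Maximum Pearson r to retain (default 0).
#' @return The filtered data.frame with a `correlation` column added.
#' @export
correlation_filter <- function(cands, mirna_expr, mrna_expr, r_max = 0) {
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) < 3L)
    stop("need >= 3 shared samples to correlate, got ", length(shared))
  r <- rep(NA_real_, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    m <- cands$mirna[i]; g <- cands$gene[i]
    if (m %in% rownames(mirna_expr) && g %in% rownames(mrna_expr))
      r[i] <- stats::cor(mirna_expr[m, shared], mrna_expr[g, shared])
  }
  keep <- !is.na(r) & r <= r_max
  out <- cands[keep, , drop = FALSE]
  out$correlation <- r[keep]
  rownames(out) <- NULL
  out
}
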