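#' Typed regulatory network
#'
#' Directed network over typed nodes (`TF`, `miRNA`, `gene`) with two edge
#' types: `tf_binds_mirna` (TF -> miRNA promoter) and
#' `mirna_targets_gene` (miRNA -> target gene). Edges may carry a Pearson
#' correlation weight ("regulatory ability").
#'
#' @param nodes data.frame with columns `id`, `type`
#'   (`TF`/`miRNA`/`gene`).
#' @param edges data.frame with columns `from`, `to`, `type`
#'   (`tf_binds_mirna`/`mirna_targets_gene`) and optional `weight`.
#' @return Object of class `regulatory_network`: list with `nodes`
#'   (including a `degree` column) and `edges`.
#' @export
regulatory_network <- function(nodes, edges) {
  nodes$id <- as.character(nodes$id); nodes$type <- as.character(nodes$type)
  if (anyDuplicated(nodes$id))
    stop("duplicated node id: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (!all(nodes$type %in% c("TF", "miRNA", "gene")))
    stop("node types must be TF, miRNA or gene")
  if (is.null(edges$weight)) edges$weight <- NA_real_
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (!all(edges$type %in% c("tf_binds_mirna", "mirna_targets_gene")))
    stop("edge types must be tf_binds_mirna or mirna_targets_gene")
  ntype <- stats::setNames(nodes$type, nodes$id)
  bad <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(bad))
    stop("edge endpoint not a node: ", paste(bad, collapse = ", "))
  tb <- edges$type == "tf_binds_mirna"
  if (any(tb & (ntype[edges$from] != "TF" | ntype[edges$to] != "miRNA")))
    stop("tf_binds_mirna edges must run TF -> miRNA")
  mt <- edges$type == "mirna_targets_gene"
  if (any(mt & (ntype[edges$from] != "miRNA" | ntype[edges$to] != "gene")))
    stop("mirna_targets_gene edges must run miRNA -> gene")
  if (anyDuplicated(edges[c("from", "to", "type")]))
    stop("duplicated edges")
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$id))
  nodes$degree <- as.integer(deg[nodes$id])
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat("regulatory_network:", nrow(x$edges), "edges over",
      paste(sprintf("%d %s", tt, names(tt)), collapse = ", "), "nodes\n")
  invisible(x)
}

# build a network from an edge table alone, inferring node types
regulatory_network_from_edges <- function(edges) {
  tf <- unique(edges$from[edges$type == "tf_binds_mirna"])
  mir <- unique(c(edges$to[edges$type == "tf_binds_mirna"],
                  edges$from[edges$type == "mirna_targets_gene"]))
  gene <- unique(edges$to[edges$type == "mirna_targets_gene"])
  nodes <- data.frame(id = c(tf, mir, setdiff(gene, c(tf, mir))),
                      type = c(rep("TF", length(tf)),
                               rep("miRNA", length(mir)),
                               rep("gene", length(setdiff(gene, c(tf, mir))))),
                      stringsAsFactors = FALSE)
  regulatory_network(nodes, edges)
}

#' Build the bipartite miRNA-target network
#'
#' One node per distinct miRNA and gene, one `mirna_targets_gene` edge per
#' predicted (or coordinate) pair; correlation weights are carried over
#' when the input provides them.
#'
#' @param pairs A [target_pairs] set or a `coordinate_pairs` data.frame.
#' @return A [regulatory_network].
#' @export
build_bipartite_network <- function(pairs) {
  w <- if ("correlation" %in% colnames(pairs)) pairs$correlation else
    rep(NA_real_, nrow(pairs))
  ed <- unique(data.frame(from = pairs$mirna, to = pairs$gene,
                          type = rep("mirna_targets_gene", nrow(pairs)),
                          weight = w, stringsAsFactors = FALSE))
  mir <- unique(ed$from); gene <- unique(ed$to)
  overlap <- intersect(mir, gene)
  if (length(overlap))
    stop("id used as both miRNA and target gene: ",
         paste(overlap, collapse = ", "))
  nodes <- data.frame(id = c(mir, gene),
                      type = rep(c("miRNA", "gene"),
                                 c(length(mir), length(gene))),
                      stringsAsFactors = FALSE)
  regulatory_network(nodes, ed)
}

#' Hub nodes of a network
#'
#' Nodes whose degree reaches the hub threshold (the study's core-node
#' criterion, degree >= 10 by default), sorted by degree descending then
#' id.
#'
#' @param network A [regulatory_network].
#' @param min_degree Hub threshold (default 10).
#' @param strict If `TRUE`, require degree strictly greater than
#'   `min_degree`.
#' @return data.frame `id`, `type`, `degree`.
#' @export
hub_nodes <- function(network, min_degree = 10L, strict = FALSE) {
  nd <- network$nodes
  keep <- if (strict) nd$degree > min_degree else nd$degree >= min_degree
  out <- nd[keep, c("id", "type", "degree"), drop = FALSE]
  out <- out[order(-out$degree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan promoter sequences for IUPAC consensus motifs
#'
#' Slides each TF consensus along each upstream sequence and reports every
#' window matching with at most `max_mismatch` mismatches; IUPAC
#' degeneracy codes in the motif are expanded (e.g. `R` matches `A` or
#' `G`), while promoter bases are taken literally. With
#' `both_strands = TRUE` the reverse complement of the motif is also
#' scanned, and hits are reported on the `-` strand at the position of the
#' window on the forward sequence.
#'
#' @param promoters A [promoter_set] (or named character vector of DNA
#'   sequences).
#' @param motifs A [motif_set] (or named character vector of IUPAC
#'   consensi).
#' @param max_mismatch Mismatch budget per window (default 0).
#' @param both_strands Scan the minus strand too (default TRUE).
#' @return data.frame of class `motif_hits`: `tf`, `mirna`, `position`
#'   (0-based offset of the window start on the forward sequence),
#'   `strand` (`+`/`-`), `match` (the forward-sequence window), sorted by
#'   miRNA, position, strand.
#' @export
scan_promoters <- function(promoters, motifs, max_mismatch = 0L,
                           both_strands = TRUE) {
  seqs <- if (inherits(promoters, "promoter_set")) promoters$sequences
          else toupper(promoters)
  motifs <- if (inherits(motifs, "motif_set")) motifs else motif_set(motifs)
  rows <- list()
  for (tf in names(motifs)) {
    pat_f <- Biostrings::DNAString(motifs[[tf]])
    pat_r <- Biostrings::reverseComplement(pat_f)
    L <- length(pat_f)
    for (m in names(seqs)) {
      subj <- Biostrings::DNAString(seqs[[m]])
      if (length(subj) < L) next
      strands <- if (both_strands) c("+", "-") else "+"
      for (st in strands) {
        pat <- if (st == "+") pat_f else pat_r
        hits <- Biostrings::matchPattern(
          pat, subj, max.mismatch = max_mismatch,
          fixed = c(pattern = FALSE, subject = TRUE))
        # drop partial matches hanging over the sequence ends
        inb <- Biostrings::start(hits) >= 1L &
          Biostrings::end(hits) <= length(subj)
        hits <- hits[inb]
        if (length(hits))
          rows[[length(rows) + 1L]] <- data.frame(
            tf = tf, mirna = m,
            position = Biostrings::start(hits) - 1L, strand = st,
            match = as.character(hits), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(), mirna = character(),
               position = integer(), strand = character(),
               match = character(), stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$position, out$strand, out$tf), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("motif_hits", "data.frame"))
}

#' Build the TF-miRNA regulatory network from motif hits
#'
#' Motif hits are collapsed to distinct (TF, miRNA) pairs, each becoming a
#' `tf_binds_mirna` edge. When TF and miRNA expression matrices sharing at
#' least three samples are both supplied, every edge is weighted by the
#' Pearson correlation of the two profiles — the TF's "regulatory
#' ability" on that miRNA.
#'
#' @param hits A `motif_hits` data.frame from [scan_promoters] (or any
#'   data.frame with `tf` and `mirna` columns).
#' @param tf_expr,mirna_expr Optional expression matrices indexed by TF /
#'   miRNA id.
#' @return A [regulatory_network] of TF and miRNA nodes.
#' @export
build_tf_mirna_network <- function(hits, tf_expr = NULL,
                                   mirna_expr = NULL) {
  ed <- unique(data.frame(from = hits$tf, to = hits$mirna,
                          type = rep("tf_binds_mirna", nrow(hits)),
                          stringsAsFactors = FALSE))
  ed$weight <- rep(NA_real_, nrow(ed))
  if (!is.null(tf_expr) && !is.null(mirna_expr)) {
    shared <- intersect(colnames(tf_expr), colnames(mirna_expr))
    if (length(shared) < 3L)
      stop("need >= 3 shared samples for edge weighting, got ",
           length(shared))
    for (i in seq_len(nrow(ed)))
      if (ed$from[i] %in% rownames(tf_expr) &&
          ed$to[i] %in% rownames(mirna_expr))
        ed$weight[i] <- stats::cor(tf_expr[ed$from[i], shared],
                                   mirna_expr[ed$to[i], shared])
  }
  tf <- unique(ed$from); mir <- unique(ed$to)
  nodes <- data.frame(id = c(tf, mir),
                      type = rep(c("TF", "miRNA"),
                                 c(length(tf), length(mir))),
                      stringsAsFactors = FALSE)
  regulatory_network(nodes, ed)
}

#' Core transcription factors of a TF-miRNA network
#'
#' TFs whose degree (number of miRNAs they bind) reaches the threshold,
#' ranked by degree descending then name — the network's regulatory
#' centres.
#'
#' @inheritParams hub_nodes
#' @return data.frame `id`, `degree` restricted to TF nodes.
#' @export
core_tfs <- function(network, min_degree = 10L, strict = FALSE) {
  h <- hub_nodes(network, min_degree, strict)
  out <- h[h$type == "TF", c("id", "degree"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine TF-miRNA-target negative feedback loops
#'
#' A loop is a pair (TF, miRNA) where the TF binds the miRNA's promoter
#' (a `tf_binds_mirna` edge) and that miRNA in turn targets the TF's own
#' transcript (the pair (miRNA, TF) is in the target set): the TF is
#' predicted to repress its own translation through the miRNA it induces.
#'
#' @param tf_net A [regulatory_network] holding `tf_binds_mirna` edges.
#' @param pairs A [target_pairs] set (gene ids must use the same naming as
#'   the TFs for identity to be detected).
#' @return data.frame of class `feedback_loops`: `tf`, `mirna`,
#'   `target_gene` (equal to `tf`), sorted by TF then miRNA.
#' @export
find_feedback_loops <- function(tf_net, pairs) {
  ed <- tf_net$edges[tf_net$edges$type == "tf_binds_mirna", , drop = FALSE]
  key <- paste(pairs$mirna, pairs$gene, sep = "\r")
  hit <- paste(ed$to, ed$from, sep = "\r") %in% key
  out <- data.frame(tf = ed$from[hit], mirna = ed$to[hit],
                    target_gene = ed$from[hit], stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("feedback_loops", "data.frame"))
}

#' Convert a regulatory network to an igraph object
#' @param network A [regulatory_network].
#' @return An `igraph` directed graph with node `type` and edge `type`,
#'   `weight` attributes.
#' @export
as_igraph <- function(network) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("as_igraph needs the igraph package")
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}
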