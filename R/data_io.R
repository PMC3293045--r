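#' Predicted miRNA-target pairs
#'
#' A de-duplicated set of predicted (miRNA, gene) pairs, e.g. a TargetScan
#' export. Duplicate rows collapse to one pair.
#'
#' @param mirna,gene Character vectors of equal length; ids must be non-empty.
#' @param provenance Free-text note on where the predictions came from.
#' @return Object of class `target_pairs`: a data.frame with columns
#'   `mirna`, `gene` and attribute `provenance`.
#' @export
target_pairs <- function(mirna, gene, provenance = "") {
  mirna <- as.character(mirna); gene <- as.character(gene)
  if (length(mirna) != length(gene))
    stop("'mirna' and 'gene' must have equal length")
  if (any(!nzchar(mirna)) || any(!nzchar(gene)))
    stop("empty miRNA or gene id in target pairs")
  df <- unique(data.frame(mirna = mirna, gene = gene,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("target_pairs", "data.frame"))
}

#' Read predicted miRNA-target pairs from TSV
#'
#' Two tab-separated columns (miRNA id, gene id), with or without a header
#' line containing the words "mirna"/"gene".
#'
#' @param path File path.
#' @param provenance Passed to [target_pairs].
#' @export
read_target_pairs_tsv <- function(path, provenance = path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stop("target pair table needs 2 columns")
  if (nrow(df) && grepl("mir", tolower(df[1, 1])) &&
      grepl("gene|target", tolower(df[1, 2])))
    df <- df[-1L, , drop = FALSE]
  target_pairs(df[[1L]], df[[2L]], provenance)
}

#' Read a gene-set annotation file in GMT format
#'
#' One term per line: `term_id TAB description TAB gene TAB gene ...`.
#' Genes are de-duplicated within each term.
#'
#' @param path Path to a GMT file.
#' @return Object of class `annotation_set`: list with `terms` (named list,
#'   term id -> list(name, genes)) and `background` (NULL unless set later).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(annotation_set(list()))
  }
  terms <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, " lists no genes")
    terms[[fields[1L]]] <- list(name = fields[2L], genes = genes)
  }
  annotation_set(terms)
}

#' Construct an annotation set
#'
#' @param terms Named list; each element a list with `name` (character) and
#'   `genes` (non-empty character vector).
#' @param background Optional gene universe; when given it must contain
#'   every gene of every term used in testing (checked at test time).
#' @export
annotation_set <- function(terms, background = NULL) {
  if (length(terms)) {
    if (is.null(names(terms)) || any(!nzchar(names(terms))))
      stop("terms must be named by term id")
    empty <- vapply(terms, function(t) length(t$genes) == 0L, logical(1))
    if (any(empty))
      stop("term with empty gene set: ",
           paste(names(terms)[empty], collapse = ", "))
  }
  structure(list(terms = terms, background = background),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$terms), "terms")
  if (!is.null(x$background))
    cat(",", length(x$background), "background genes")
  cat("\n")
  invisible(x)
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path File path. Blank lines and `#` comments are ignored.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Transcription factor consensus motifs
#'
#' @param motifs Named character vector: TF name -> IUPAC consensus
#'   (codes ACGTRYSWKMBDHVN), each of length >= 4.
#' @return Object of class `motif_set` (the validated named vector).
#' @export
motif_set <- function(motifs) {
  if (is.null(names(motifs)) || any(!nzchar(names(motifs))))
    stop("motifs must be named by TF")
  motifs <- toupper(motifs)
  bad <- gsub("[ACGTRYSWKMBDHVN]", "", motifs)
  if (any(nzchar(bad)))
    stop("invalid IUPAC character '", substr(bad[nzchar(bad)][1], 1, 1),
         "' in motif of ", names(motifs)[nzchar(bad)][1])
  if (any(nchar(motifs) < 4L))
    stop("motif shorter than 4 nt: ",
         paste(names(motifs)[nchar(motifs) < 4L], collapse = ", "))
  structure(motifs, class = "motif_set")
}

#' Read a TF motif table (TSV: tf_name TAB IUPAC consensus)
#' @param path File path.
#' @export
read_motifs_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stop("motif table needs 2 columns")
  if (nrow(df) && grepl("tf|name", tolower(df[1, 1])) &&
      grepl("motif|consensus|iupac", tolower(df[1, 2])))
    df <- df[-1L, , drop = FALSE]
  motif_set(stats::setNames(df[[2L]], df[[1L]]))
}

#' Upstream (promoter) sequences of pre-miRNA loci
#'
#' @param sequences Named character vector: miRNA id -> DNA string over
#'   `A,C,G,T,N` (lower case accepted, normalized to upper).
#' @param window_bp Declared window length; sequences may be shorter (e.g.
#'   truncated at a contig edge), in which case they are flagged.
#' @return Object of class `promoter_set`: list with `sequences`,
#'   `window_bp`, `truncated` (logical vector).
#' @export
promoter_set <- function(sequences, window_bp = max(nchar(sequences))) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("promoter sequences must be named by miRNA id")
  sequences <- toupper(sequences)
  bad <- gsub("[ACGTN]", "", sequences)
  if (any(nzchar(bad)))
    stop("non-ACGTN character in promoter of ",
         names(sequences)[nzchar(bad)][1])
  if (any(nchar(sequences) > window_bp))
    stop("sequence longer than declared window_bp")
  structure(list(sequences = sequences, window_bp = window_bp,
                 truncated = nchar(sequences) < window_bp),
            class = "promoter_set")
}

#' Read promoter sequences from FASTA
#' @param path FASTA file; record names are taken up to the first whitespace.
#' @param window_bp Declared window length; defaults to the longest record.
#' @export
read_promoters_fasta <- function(path, window_bp = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  x <- stats::setNames(as.character(seqs),
                       sub("\\s.*$", "", names(seqs)))
  if (is.null(window_bp)) window_bp <- max(nchar(x))
  promoter_set(x, window_bp)
}

#' Load a packaged literature table fixture
#'
#' The package ships, as plain TSV fixtures under `extdata/`, the printed
#' stage-wise miRNA calls (`table1`), the inverse miRNA/target direction
#' pairs (`table2`), the per-stage core transcription factors (`table5`)
#' and the TF-miRNA-target feedback loops (`table6`) of the source study,
#' transcribed verbatim (including the anomalous id token
#' `hsa-miR-17-5p:9.1`, stored as-is).
#'
#' @param name One of `"table1"`, `"table2"`, `"table5"`, `"table6"`.
#' @return `table1`: named list, stage -> `list(down=, up=)` character
#'   vectors. `table2`: data.frame `mirna, mirna_direction, gene,
#'   gene_direction` (rows as printed, duplicates preserved). `table5`:
#'   named list, stage -> character vector of TFs. `table6`: data.frame
#'   `tf, mirna, target_gene`.
#' @examples
#' lengths(load_fixture_table("table1")[["I-II"]])
#' @export
load_fixture_table <- function(name) {
  valid <- c("table1", "table2", "table5", "table6")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".tsv"), package = "mirstage",
                      mustWork = TRUE)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          quote = "", check.names = FALSE)
  switch(name,
    table1 = {
      stages <- unique(df$stage)
      out <- lapply(stages, function(s) {
        list(down = df$mirna[df$stage == s & df$direction == "down"],
             up = df$mirna[df$stage == s & df$direction == "up"])
      })
      stats::setNames(out, stages)
    },
    table2 = df,
    table5 = {
      stages <- unique(df$stage)
      stats::setNames(lapply(stages, function(s) df$tf[df$stage == s]),
                      stages)
    },
    table6 = df)
}

#' Write a regulatory network as a tab-separated edge list
#'
#' Columns `source, target, edge_type, weight`; rows sorted
#' lexicographically by source then target then type, so output is
#' byte-identical regardless of edge insertion order. Optionally also
#' writes GraphML (requires the igraph package).
#'
#' @param network A [regulatory_network].
#' @param path Output TSV path.
#' @param graphml Optional path for a GraphML export.
#' @export
write_network_edgelist <- function(network, path, graphml = NULL) {
  ed <- network$edges
  ed <- ed[order(ed$from, ed$to, ed$type), , drop = FALSE]
  out <- data.frame(source = ed$from, target = ed$to, edge_type = ed$type,
                    weight = ifelse(is.na(ed$weight), "NA",
                                    format(ed$weight, digits = 17)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("GraphML export needs the igraph package")
    igraph::write_graph(as_igraph(network), graphml, format = "graphml")
  }
  invisible(path)
}

#' Read a regulatory network written by [write_network_edgelist]
#' @param path Edge-list TSV path.
#' @export
read_network_edgelist <- function(path) {
  df <- utils::read.delim(path, header = TRUE, quote = "",
                          colClasses = "character")
  if (!nrow(df))
    return(regulatory_network(
      nodes = data.frame(id = character(), type = character()),
      edges = data.frame(from = character(), to = character(),
                         type = character(), weight = numeric())))
  regulatory_network_from_edges(
    data.frame(from = df$source, to = df$target, type = df$edge_type,
               weight = suppressWarnings(as.numeric(df$weight))))
}
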