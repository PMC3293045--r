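#' Hypergeometric gene-set over-representation analysis
#'
#' For each annotation term, tests whether the gene list hits it more
#' often than expected by sampling without replacement from the
#' background universe: `p = P(X >= count)` with `X` hypergeometric on
#' population `|background|`, successes `|term (intersect) background|`
#' and draws `|list|`. The output mirrors the familiar
#' Term/Count/%/PValue/FDR table layout of annotation servers.
#'
#' @param gene_list Character vector of genes of interest.
#' @param annotation An [annotation_set].
#' @param background Gene universe; defaults to the union of all term
#'   genes (plus the annotation's own background, if recorded). Genes of
#'   the list outside the background are dropped with a message. Terms are
#'   intersected with the background before testing; terms falling
#'   entirely outside it are skipped with a message.
#' @param min_count Minimum overlap for a term to be reported (default 2).
#' @param method `"standard"` plain hypergeometric upper tail, or
#'   `"ease"` for the conservative jackknifed variant that computes the
#'   tail at `count - 1` (the EASE score of the DAVID server).
#' @param adjust Multiple-testing correction across tested terms:
#'   `"BH"` (default) or `"bonferroni"`.
#' @return data.frame of class `enrichment_table`, sorted by p-value,
#'   with columns `term_id`, `term_name`, `count`, `percent`
#'   (`100 * count / |list|`), `p_value`, `fdr`.
#' @examples
#' ann <- annotation_set(list(T1 = list(name = "set", genes = letters[1:5])))
#' hypergeometric_enrichment(letters[1:4], ann, background = letters[1:10],
#'                           min_count = 1)
#' @export
hypergeometric_enrichment <- function(gene_list, annotation,
                                      background = NULL, min_count = 2L,
                                      method = c("standard", "ease"),
                                      adjust = c("BH", "bonferroni")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (!length(gene_list)) stop("empty gene list")
  if (is.null(background))
    background <- unique(c(unlist(lapply(annotation$terms,
                                         function(t) t$genes)),
                           annotation$background))
  if (!length(background)) stop("empty background universe")
  background <- unique(background)
  genes <- unique(gene_list)
  outside <- setdiff(genes, background)
  if (length(outside)) {
    message(length(outside), " list genes outside the background dropped")
    genes <- setdiff(genes, outside)
  }
  if (!length(genes)) stop("no list genes in the background universe")
  N <- length(background); n <- length(genes)

  rows <- lapply(names(annotation$terms), function(id) {
    term <- annotation$terms[[id]]
    tg <- intersect(term$genes, background)
    if (!length(tg)) {
      message("term ", id, " entirely outside background; skipped")
      return(NULL)
    }
    count <- length(intersect(genes, tg))
    shift <- if (method == "ease") 2L else 1L
    p <- stats::phyper(count - shift, length(tg), N - length(tg), n,
                       lower.tail = FALSE)
    data.frame(term_id = id, term_name = term$name, count = count,
               percent = 100 * count / n, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(), term_name = character(),
                      count = integer(), percent = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  out$fdr <- if (adjust == "BH") bh_fdr(out$p_value) else
    pmin(out$p_value * nrow(out), 1)
  out <- out[out$count >= min_count, , drop = FALSE]
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, background_size = N, list_size = n,
            class = c("enrichment_table", "data.frame"))
}
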