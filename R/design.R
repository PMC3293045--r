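#' Stage design for an ordered clinical series
#'
#' Describes how samples map onto an ordered set of clinical stages, with a
#' designated reference stage (typically normal tissue). The stage order is
#' meaningful: trajectory classification and per-stage contrasts follow it.
#'
#' @param stages Character vector of stage labels in biological order,
#'   e.g. `c("normal", "I-II", "III", "IV", "MET")`.
#' @param sample_to_stage Named character vector mapping sample id to stage
#'   label. Every sample must map to exactly one stage present in `stages`.
#' @param reference_stage Label of the reference stage; must appear in
#'   `stages`. Defaults to the first stage.
#'
#' @return An object of class `stage_design`: a list with elements `stages`,
#'   `samples` (named character vector, sample id -> stage) and `reference`.
#'
#' @details Each stage must contain at least two samples so that a
#'   within-group variance can be estimated.
#'
#' @examples
#' stage_design(c("normal", "tumor"),
#'              c(n1 = "normal", n2 = "normal", t1 = "tumor", t2 = "tumor"))
#' @export
stage_design <- function(stages, sample_to_stage, reference_stage = stages[1]) {
  stages <- as.character(stages)
  if (anyDuplicated(stages)) stop("duplicated stage labels")
  if (is.null(names(sample_to_stage)) || any(names(sample_to_stage) == ""))
    stop("'sample_to_stage' must be a named vector (sample id -> stage)")
  if (anyDuplicated(names(sample_to_stage)))
    stop("duplicated sample ids: ",
         paste(unique(names(sample_to_stage)[duplicated(names(sample_to_stage))]),
               collapse = ", "))
  unknown <- setdiff(unique(sample_to_stage), stages)
  if (length(unknown))
    stop("samples assigned to stages not in 'stages': ",
         paste(unknown, collapse = ", "))
  if (!reference_stage %in% stages)
    stop("reference stage '", reference_stage, "' not among stages")
  counts <- table(factor(sample_to_stage, levels = stages))
  if (any(counts < 2L))
    stop("every stage needs >= 2 samples for variance estimation; short: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  structure(list(stages = stages,
                 samples = sample_to_stage,
                 reference = reference_stage),
            class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  counts <- table(factor(x$samples, levels = x$stages))
  cat("Stage design:", length(x$samples), "samples over",
      length(x$stages), "stages\n")
  cat(paste(sprintf("  %s: %d%s", x$stages, counts,
                    ifelse(x$stages == x$reference, " (reference)", "")),
            collapse = "\n"), "\n")
  invisible(x)
}

#' The 22-sample staged design used throughout this package
#'
#' Six normal controls, four samples per primary stage (I-II, III, IV) and
#' four lymph-node metastases, the design of the nasopharyngeal carcinoma
#' progression series this pipeline targets.
#'
#' @param n_normal,n_stage,n_met Arm sizes; defaults 6, 4, 4.
#' @return A [stage_design] with stages `normal, I-II, III, IV, MET` and
#'   `normal` as reference.
#' @examples
#' npc_stage_design()
#' @export
npc_stage_design <- function(n_normal = 6L, n_stage = 4L, n_met = 4L) {
  stages <- c("normal", "I-II", "III", "IV", "MET")
  sizes <- c(n_normal, n_stage, n_stage, n_stage, n_met)
  short <- c("norm", "s12", "s3", "s4", "met")
  ids <- unlist(mapply(function(s, n) {
    sprintf("%s_%d", s, seq_len(n))
  }, short, sizes, SIMPLIFY = FALSE), use.names = FALSE)
  stage_design(stages, stats::setNames(rep(stages, sizes), ids))
}

# factor of stage membership for a set of sample ids, levels in design order
design_factor <- function(design, sample_ids) {
  missing <- setdiff(sample_ids, names(design$samples))
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  factor(design$samples[sample_ids], levels = design$stages)
}
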