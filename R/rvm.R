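#' Random-variance-model prior on gene-level variances
#'
#' The random variance model assumes the reciprocal of each feature's true
#' residual variance is drawn from a gamma distribution with shape `a` and
#' scale `b`, i.e. `1/sigma^2 ~ Gamma(a, scale = b)`. Under this model the
#' scaled observed residual variance `s^2 * a * b` follows an
#' `F(df, 2a)` distribution, which is what [fit_rvm_prior] maximizes.
#'
#' @param a,b Shape and scale of the gamma prior on the inverse variance;
#'   both must be positive and finite.
#' @param converged,loglik,n_used,n_excluded Optional fit metadata.
#' @return Object of class `rvm_prior`.
#' @export
rvm_prior <- function(a, b, converged = NA, loglik = NA_real_,
                      n_used = NA_integer_, n_excluded = NA_integer_) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("rvm_prior requires finite a > 0 and b > 0")
  structure(list(a = a, b = b, converged = converged, loglik = loglik,
                 n_used = n_used, n_excluded = n_excluded),
            class = "rvm_prior")
}

#' @export
print.rvm_prior <- function(x, ...) {
  cat(sprintf("rvm_prior: a = %.4g, b = %.4g (prior df = 2a = %.3g)\n",
              x$a, x$b, 2 * x$a))
  if (!is.na(x$converged))
    cat(sprintf("  fitted on %d variances (%d excluded), converged: %s\n",
                x$n_used, x$n_excluded, x$converged))
  invisible(x)
}

#' Fit the random-variance prior by maximum likelihood
#'
#' Fits the gamma prior on inverse variances by maximizing the likelihood
#' of the observed residual variances under the model
#' `s^2 * a * b ~ F(df, 2a)`. The optimization is deterministic: a fixed
#' moment-based starting point and quasi-Newton iterations on the log
#' parameters, with a Nelder-Mead fallback.
#'
#' @param residual_variances Per-feature pooled residual variances
#'   (positive reals). Non-positive or non-finite entries are excluded and
#'   counted; fitting on fewer than 50 features triggers a warning.
#' @param df Residual degrees of freedom each variance was estimated with
#'   (n - k for a k-group one-way layout).
#' @return An [rvm_prior] with fit metadata.
#' @examples
#' set.seed(1)
#' sigma2 <- 1 / rgamma(2000, shape = 2, scale = 1.5)
#' s2 <- sigma2 * rchisq(2000, 17) / 17
#' fit_rvm_prior(s2, df = 17)
#' @export
fit_rvm_prior <- function(residual_variances, df) {
  v <- residual_variances
  keep <- is.finite(v) & v > 0
  n_excluded <- sum(!keep)
  if (n_excluded)
    message(n_excluded, " zero/non-finite variances excluded from prior fit")
  v <- v[keep]
  if (length(v) < 2L) stop("need at least 2 positive variances")
  if (length(v) < 50L)
    warning("fitting the variance prior on only ", length(v),
            " features; estimates will be unstable")
  if (stats::sd(v) / mean(v) < 1e-10)
    stop("degenerate input: all residual variances are (numerically) ",
         "identical; the prior likelihood has no interior maximum")

  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    x <- v * a * b
    ll <- suppressWarnings(stats::df(x, df, 2 * a, log = TRUE))
    if (!all(is.finite(ll))) return(1e10)  # reject wild optimizer trials
    -sum(ll) - length(v) * (par[1] + par[2])
  }
  # moment start: E[s2] = 1/(b(a-1)) under the prior, anchored at a = 1.5
  start <- c(log(1.5), log(2 / mean(v)))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500))
  if (opt$convergence != 0)
    opt <- stats::optim(opt$par, nll, control = list(maxit = 2000))
  if (opt$convergence != 0)
    stop(sprintf(paste0("variance-prior fit did not converge ",
                        "(code %d; last iterate a = %.4g, b = %.4g, ",
                        "nll = %.6g)"),
                 opt$convergence, exp(opt$par[1]), exp(opt$par[2]),
                 opt$value))
  rvm_prior(exp(opt$par[1]), exp(opt$par[2]), converged = TRUE,
            loglik = -opt$value, n_used = length(v),
            n_excluded = n_excluded)
}

# negative log-likelihood of variances under an rvm_prior (used by tests)
rvm_prior_nll <- function(prior, residual_variances, df) {
  x <- residual_variances * prior$a * prior$b
  -sum(stats::df(x, df, 2 * prior$a, log = TRUE)) -
    length(residual_variances) * log(prior$a * prior$b)
}

#' Pooled within-stage residual variances
#'
#' One-way pooled variance per feature, `SS_within / (n - k)`, the input to
#' [fit_rvm_prior]. Features with any missing value across the design's
#' samples are returned as `NA`.
#'
#' @param x An [expression_matrix].
#' @param design A [stage_design]; its samples must all be columns of `x`.
#' @return Named numeric vector of residual variances.
#' @export
pooled_residual_variances <- function(x, design) {
  xs <- x[, names(design$samples), drop = FALSE]
  g <- design_factor(design, colnames(xs))
  ssw <- 0
  for (lev in levels(g)) {
    xi <- xs[, g == lev, drop = FALSE]
    ssw <- ssw + rowSums((xi - rowMeans(xi))^2)
  }
  stats::setNames(ssw / (ncol(xs) - nlevels(g)), rownames(xs))
}

#' Moderated multi-group F-test under the random variance model
#'
#' For each feature, the classical one-way statistic
#' `F = MS_between / s^2` is moderated by replacing the per-feature
#' residual variance with the posterior-shrunk
#' `sigma~^2 = ((n-k) s^2 + 2/b) / ((n-k) + 2a)`, a strictly convex
#' combination of the observed variance and the prior scale. The moderated
#' statistic is referred to an `F(k-1, n-k+2a)` null distribution; the
#' prior contributes `2a` extra denominator degrees of freedom, which is
#' where the method's small-sample power comes from.
#'
#' @param x An [expression_matrix] containing every sample of `design`.
#' @param design A [stage_design] with k >= 2 stages.
#' @param prior An [rvm_prior], typically from [fit_rvm_prior] on
#'   [pooled_residual_variances].
#' @return A data.frame of class `differential_table` with columns
#'   `feature_id`, `f_raw`, `f_rvm`, `df1`, `df2`, `p_value`, `q_value`
#'   (Benjamini-Hochberg), one `lfc_<stage>` column per non-reference stage
#'   (stage mean minus reference mean, log2 units) and `flag`
#'   (`"ok"`, `"zero_variance"` for features flat in every sample, or
#'   `"missing"` for features dropped because of missing values).
#'   Features flagged `zero_variance` get `p = 1` by convention.
#' @export
rvm_f_test <- function(x, design, prior) {
  if (length(design$stages) < 2L) stop("need k >= 2 stages")
  missing_samples <- setdiff(names(design$samples), colnames(x))
  if (length(missing_samples))
    stop("design samples absent from matrix: ",
         paste(missing_samples, collapse = ", "))
  xs <- x[, names(design$samples), drop = FALSE]
  g <- design_factor(design, colnames(xs))
  n <- ncol(xs); k <- nlevels(g)
  complete <- rowSums(is.na(xs)) == 0L
  if (any(!complete))
    message(sum(!complete), " features with missing values dropped from test")

  gm <- sapply(levels(g), function(lev)
    rowMeans(xs[, g == lev, drop = FALSE]))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1, dimnames = list(rownames(xs), levels(g)))
  sizes <- as.vector(table(g))
  grand <- as.vector(gm %*% sizes) / n
  ssb <- as.vector((gm - grand)^2 %*% sizes)
  ssw <- 0
  for (lev in levels(g)) {
    xi <- xs[, g == lev, drop = FALSE]
    ssw <- ssw + rowSums((xi - rowMeans(xi))^2)
  }
  s2 <- ssw / (n - k)
  msb <- ssb / (k - 1)
  sigma_mod <- ((n - k) * s2 + 2 / prior$b) / ((n - k) + 2 * prior$a)
  f_raw <- msb / s2
  f_rvm <- msb / sigma_mod
  df2 <- n - k + 2 * prior$a
  p <- stats::pf(f_rvm, k - 1, df2, lower.tail = FALSE)

  flag <- rep("ok", nrow(xs))
  zero <- complete & ssw == 0 & ssb == 0
  flag[zero] <- "zero_variance"
  p[zero] <- 1
  flag[!complete] <- "missing"
  p[!complete] <- NA_real_
  f_raw[!complete] <- f_rvm[!complete] <- NA_real_

  out <- data.frame(feature_id = rownames(xs), f_raw = f_raw, f_rvm = f_rvm,
                    df1 = k - 1, df2 = df2, p_value = p,
                    q_value = bh_fdr(p), stringsAsFactors = FALSE)
  ref <- design$reference
  for (s in setdiff(design$stages, ref))
    out[[paste0("lfc_", s)]] <- gm[, s] - gm[, ref]
  out$flag <- flag
  rownames(out) <- NULL
  structure(out, design = design, prior = prior,
            class = c("differential_table", "data.frame"))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin, input-checked wrapper
#' over [stats::p.adjust()] that preserves input order and `NA`s.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return q-values in the same order.
#' @export
bh_fdr <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-stage direction calls (printed-table shape)
#'
#' Applies the global screening gate (moderated-F p and q below their
#' cut-offs) and then, for each non-reference stage, a per-stage contrast
#' rule: either a Welch two-sample test of stage versus reference
#' (`stage_rule = "welch"`, default) or an absolute log2-fold-change
#' threshold (`"foldchange"`). Features passing both gates are labelled
#' `up` if the stage mean exceeds the reference mean, else `down`.
#'
#' @param x,design Matrix and design the table was computed on.
#' @param diff A `differential_table` from [rvm_f_test].
#' @param p_cut,q_cut Global gate on `p_value` and `q_value`; defaults 0.05.
#' @param stage_rule `"welch"` or `"foldchange"`.
#' @param stage_p Welch p cut-off (default 0.05).
#' @param lfc_cut Absolute log2-fold-change cut-off for the
#'   fold-change rule (default 1).
#' @return Named list, stage -> `list(down = , up = )` of feature ids
#'   (the shape of the study's stage table), with a long-format data.frame
#'   (`stage`, `direction`, `feature_id`) in attribute `"long"`.
#' @export
stage_direction_calls <- function(x, design, diff, p_cut = 0.05,
                                  q_cut = 0.05,
                                  stage_rule = c("welch", "foldchange"),
                                  stage_p = 0.05, lfc_cut = 1) {
  stage_rule <- match.arg(stage_rule)
  xs <- x[diff$feature_id, names(design$samples), drop = FALSE]
  g <- design_factor(design, colnames(xs))
  ref <- design$reference
  pass_global <- !is.na(diff$p_value) & !is.na(diff$q_value) &
    diff$p_value < p_cut & diff$q_value < q_cut
  xref <- xs[, g == ref, drop = FALSE]

  out <- list()
  long <- data.frame(stage = character(), direction = character(),
                     feature_id = character(), stringsAsFactors = FALSE)
  for (s in setdiff(design$stages, ref)) {
    lfc <- diff[[paste0("lfc_", s)]]
    if (stage_rule == "welch") {
      xstg <- xs[, g == s, drop = FALSE]
      pw <- vapply(seq_len(nrow(xs)), function(i) {
        if (!pass_global[i]) return(NA_real_)
        stats::t.test(xstg[i, ], xref[i, ])$p.value
      }, numeric(1))
      pass_stage <- !is.na(pw) & pw < stage_p
    } else {
      pass_stage <- abs(lfc) >= lfc_cut
    }
    sel <- pass_global & pass_stage
    out[[s]] <- list(down = diff$feature_id[sel & lfc < 0],
                     up = diff$feature_id[sel & lfc > 0])
    if (any(sel))
      long <- rbind(long, data.frame(
        stage = s, direction = ifelse(lfc[sel] > 0, "up", "down"),
        feature_id = diff$feature_id[sel], stringsAsFactors = FALSE))
  }
  attr(out, "long") <- long
  out
}

#' Overall direction calls for significant features
#'
#' Collapses the per-stage log2 fold changes of features passing the
#' global gate into a single `up`/`down` call (sign of the mean fold
#' change across non-reference stages), the form consumed by the
#' miRNA/mRNA integration step.
#'
#' @inheritParams stage_direction_calls
#' @return Named character vector (`"up"`/`"down"`) over significant
#'   features; features whose mean fold change is exactly zero are dropped.
#' @export
overall_direction_calls <- function(diff, p_cut = 0.05, q_cut = 0.05) {
  lfc_cols <- grep("^lfc_", colnames(diff), value = TRUE)
  sig <- !is.na(diff$p_value) & !is.na(diff$q_value) &
    diff$p_value < p_cut & diff$q_value < q_cut
  m <- rowMeans(as.matrix(diff[sig, lfc_cols, drop = FALSE]))
  calls <- ifelse(m > 0, "up", "down")[m != 0]
  stats::setNames(calls, diff$feature_id[sig][m != 0])
}
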