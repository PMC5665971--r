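#' Fit the entrainment analysis to a set of tapping blocks
#'
#' The package's central fitting function. Given tap-event series and their
#' matching stimulus envelopes it runs the complete inference pipeline:
#'
#' 1. envelope phase at every finger drop, Rao's spacing U per block
#'    ([phases_and_U_per_block()]);
#' 2. 2.5 x IQR outlier exclusion at the block level, then at the subject
#'    level ([exclude_outliers()]);
#' 3. block-averaged U per subject x condition, rank-transformed pooled
#'    over all cells ([average_and_rank()]);
#' 4. linear mixed model on the ranks with condition fixed and subject
#'    random intercepts, condition effect tested by likelihood ratio
#'    ([fit_condition_model()]);
#' 5. paired permutation contrasts of mean U between each non-baseline
#'    condition and baseline ([permutation_contrast()]);
#' 6. optionally, the mini-block time-course analysis
#'    ([miniblock_analysis()]).
#'
#' @param taps list of [tap_series()] (main blocks).
#' @param envelopes named list of [make_envelope()] results keyed by
#'   `block_id`.
#' @param n_iter permutation iterations (default 5000).
#' @param seed integer seed for the permutation null.
#' @param n_miniblocks if non-`NULL`, also run the mini-block analysis with
#'   this many segments.
#' @param exclude apply the outlier-exclusion rule (default `TRUE`).
#' @param aware_filter `"all"` keeps every subject; `"unaware_only"` drops
#'   subjects whose `aware` questionnaire flag is set before any analysis.
#' @param random_slopes passed to [fit_condition_model()].
#' @return an object of class `"entrain_fit"`; see [print.entrain_fit()],
#'   [summary.entrain_fit()], [coef.entrain_fit()], [plot.entrain_fit()].
#' @export
entrain_fit <- function(taps, envelopes, n_iter = 5000, seed = 1,
                        n_miniblocks = NULL, exclude = TRUE,
                        aware_filter = c("all", "unaware_only"),
                        random_slopes = FALSE) {
  aware_filter <- match.arg(aware_filter)
  stopifnot(is.list(taps), length(taps) > 0)
  n_total <- length(unique(vapply(taps, `[[`, "", "subject_id")))
  if (aware_filter == "unaware_only")
    taps <- Filter(function(s) !s$aware, taps)
  if (length(taps) == 0)
    stop("entrain_fit: no blocks left after the awareness filter",
         call. = FALSE)
  utable <- phases_and_U_per_block(taps, envelopes)
  log <- list(blocks_in = length(taps),
              taps_in = sum(utable$n_taps),
              subjects_in = length(unique(utable$subject_id)),
              subjects_total = n_total)
  if (exclude) {
    utable <- exclude_outliers(utable, "block")
    utable <- exclude_outliers(utable, "subject")
  }
  log$blocks_excluded <- sum(utable$excluded)
  ranked <- average_and_rank(utable)
  conditions <- unique(ranked$condition)
  model <- if (length(conditions) >= 2 &&
               length(unique(ranked$subject_id)) >= 5)
    fit_condition_model(ranked, random_slopes = random_slopes)
  else NULL
  contrasts <- list()
  if ("baseline" %in% conditions) {
    for (cond in setdiff(conditions, "baseline")) {
      contrasts[[cond]] <- permutation_contrast(
        ranked, cond, "baseline", n_iter = n_iter,
        seed = derive_seed(seed, "contrast", cond))
    }
  }
  miniblocks <- NULL
  miniblock_model <- NULL
  if (!is.null(n_miniblocks)) {
    mb <- miniblock_analysis(taps, envelopes, n_miniblocks)
    if (!is.null(mb) && nrow(mb) > 0) {
      mb$rank <- rank(mb$U, ties.method = "average")
      miniblocks <- mb
      if (length(unique(mb$condition)) >= 2 &&
          length(unique(mb$subject_id)) >= 5)
        miniblock_model <- fit_condition_model(mb, random_slopes = TRUE,
                                               miniblock = "miniblock")
    }
  }
  structure(list(u_table = utable, ranked = ranked, model = model,
                 contrasts = contrasts, miniblocks = miniblocks,
                 miniblock_model = miniblock_model, log = log,
                 n_iter = n_iter, seed = seed,
                 aware_filter = aware_filter),
            class = "entrain_fit")
}

#' @export
print.entrain_fit <- function(x, ...) {
  cat("Entrainment analysis fit\n")
  cat(sprintf("  %d subjects, %d blocks (%d excluded), %d taps\n",
              x$log$subjects_in, x$log$blocks_in, x$log$blocks_excluded,
              x$log$taps_in))
  mu <- condition_means(x)
  for (i in seq_len(nrow(mu)))
    cat(sprintf("  %-9s mean U = %7.2f deg (n = %d subjects)\n",
                mu$condition[i], mu$mean_U[i], mu$n[i]))
  if (!is.null(x$model))
    cat(sprintf("  condition effect (LRT): chisq = %.2f, p = %.4g\n",
                x$model$lrt$statistic, x$model$lrt$p))
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("  %s - baseline: diff = %.2f deg, permutation p = %.4g\n",
                nm, ct$observed_diff, ct$p))
  }
  invisible(x)
}

# group mean of subject-level mean U per condition
condition_means <- function(x) {
  agg <- stats::aggregate(mean_U ~ condition, data = x$ranked, FUN = mean)
  agg$n <- as.vector(table(x$ranked$condition)[agg$condition])
  agg
}

#' Summary of an entrainment fit
#'
#' @param object an [entrain_fit()] result.
#' @param ... unused.
#' @return a list with `condition_means`, the mixed-model `lrt` and
#'   Satterthwaite `f_test`, the permutation `contrasts` table, the
#'   mini-block LRT (if run) and the audit `log`.
#' @export
summary.entrain_fit <- function(object, ...) {
  ct <- do.call(rbind, lapply(names(object$contrasts), function(nm) {
    c0 <- object$contrasts[[nm]]
    data.frame(contrast = paste(nm, "- baseline"),
               diff = c0$observed_diff, p = c0$p, n_iter = c0$n_iter)
  }))
  out <- list(condition_means = condition_means(object),
              lrt = if (!is.null(object$model)) object$model$lrt,
              f_test = if (!is.null(object$model)) object$model$f_test,
              contrasts = ct,
              miniblock_lrt = if (!is.null(object$miniblock_model))
                object$miniblock_model$miniblock_lrt,
              log = object$log)
  class(out) <- "summary.entrain_fit"
  out
}

#' @export
print.summary.entrain_fit <- function(x, ...) {
  cat("Entrainment analysis summary\n\nCondition means (deg):\n")
  print(x$condition_means, row.names = FALSE)
  if (!is.null(x$lrt))
    cat(sprintf("\nCondition effect: LRT chisq = %.2f (df = %d), p = %.4g\n",
                x$lrt$statistic, x$lrt$df, x$lrt$p))
  if (!is.null(x$contrasts)) {
    cat("\nPermutation contrasts:\n")
    print(x$contrasts, row.names = FALSE)
  }
  if (!is.null(x$miniblock_lrt))
    cat(sprintf("\nMini-block effect: LRT chisq = %.2f, p = %.4g\n",
                x$miniblock_lrt$statistic, x$miniblock_lrt$p))
  invisible(x)
}

#' @export
coef.entrain_fit <- function(object, ...) {
  if (is.null(object$model)) return(NULL)
  object$model$coefficients
}

#' Boxplot of block-averaged U-values by condition
#'
#' @param x an [entrain_fit()] result.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.entrain_fit <- function(x, ...) {
  graphics::boxplot(mean_U ~ condition, data = x$ranked,
                    ylab = "mean U (deg)", xlab = "condition", ...)
  invisible(x)
}
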