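#' Per-block tap phases and Rao U-values
#'
#' For every rhythmic block, evaluates the envelope phase at each finger
#' drop and computes Rao's spacing U on those phases. Single-tap blocks are
#' pooled per subject and condition into one phase sample (one row with
#' `block_id = "pooled"`). Blocks with fewer than 2 drops are kept as rows
#' flagged `excluded` with a reason.
#'
#' @param taps list of [tap_series()] objects.
#' @param envelopes named list of [make_envelope()] results, keyed by
#'   `block_id`; every block must have a matching envelope. For pooled
#'   single-tap rows each contributing block still needs its own envelope.
#' @return a `UTable`: data.frame with columns `subject_id`, `condition`,
#'   `block_id`, `U`, `n_taps`, `excluded`, `reason`, plus a `"phases"`
#'   attribute (named list of the per-row phase samples).
#' @export
phases_and_U_per_block <- function(taps, envelopes) {
  stopifnot(is.list(taps), is.list(envelopes))
  for (s in taps) {
    stopifnot(inherits(s, "tap_series"))
    if (is.null(envelopes[[s$block_id]]))
      stop(sprintf("phases_and_U_per_block: no envelope for block '%s'",
                   s$block_id), call. = FALSE)
  }
  rows <- list()
  phases_out <- list()
  rhythmic <- Filter(function(s) s$task == "rhythmic", taps)
  single <- Filter(function(s) s$task == "single_tap", taps)

  block_phases <- function(s) {
    env <- envelopes[[s$block_id]]
    d <- drop_times(s)
    d <- d[d < env$spec$duration]
    phase_at(env, d)
  }
  add_row <- function(subject, condition, block, ph) {
    key <- paste(subject, condition, block, sep = "|")
    if (length(ph) >= 2) {
      rows[[key]] <<- data.frame(subject_id = subject, condition = condition,
                                 block_id = block, U = rao_spacing_U(ph),
                                 n_taps = length(ph), excluded = FALSE,
                                 reason = "")
    } else {
      rows[[key]] <<- data.frame(subject_id = subject, condition = condition,
                                 block_id = block, U = NA_real_,
                                 n_taps = length(ph), excluded = TRUE,
                                 reason = "fewer than 2 taps")
    }
    phases_out[[key]] <<- ph
  }
  for (s in rhythmic)
    add_row(s$subject_id, s$condition, s$block_id, block_phases(s))
  if (length(single) > 0) {
    keys <- vapply(single, function(s)
      paste(s$subject_id, s$condition, sep = "|"), "")
    for (k in unique(keys)) {
      grp <- single[keys == k]
      ph <- unlist(lapply(grp, block_phases))
      add_row(grp[[1]]$subject_id, grp[[1]]$condition, "pooled", ph)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "phases") <- phases_out
  class(out) <- c("u_table", "data.frame")
  out
}

# the 2.5 x IQR rule: TRUE where |x - median| > 2.5 * IQR; degenerate IQR
# excludes nothing
iqr_outlier <- function(x, mult = 2.5) {
  iqr <- stats::IQR(x, type = 7)
  if (iqr == 0) {
    warning("outlier rule: IQR is 0, nothing excluded in this group")
    return(rep(FALSE, length(x)))
  }
  abs(x - stats::median(x)) > mult * iqr
}

#' Exclude outlying U-values
#'
#' Applies the rule "absolute distance from the median greater than 2.5
#' times the interquartile range" (quartiles by linear interpolation).
#' `scope = "block"` applies it within each subject x condition cell at the
#' block level; `scope = "subject"` applies the same rule across subjects to
#' each subject's mean of remaining block U-values, excluding all rows of
#' flagged subjects. Groups with zero IQR exclude nothing (with a warning).
#'
#' @param table a `UTable` from [phases_and_U_per_block()].
#' @param scope `"block"` or `"subject"`.
#' @param mult multiplier on the IQR (default 2.5).
#' @return the table with `excluded`/`reason` updated.
#' @export
exclude_outliers <- function(table, scope = c("block", "subject"),
                             mult = 2.5) {
  scope <- match.arg(scope)
  ok <- !table$excluded
  if (scope == "block") {
    grp <- interaction(table$subject_id, table$condition, drop = TRUE)
    for (g in levels(grp)) {
      i <- which(ok & grp == g)
      if (length(i) < 3) next
      bad <- iqr_outlier(table$U[i], mult)
      table$excluded[i[bad]] <- TRUE
      table$reason[i[bad]] <- "block-level IQR outlier"
    }
  } else {
    means <- tapply(table$U[ok], table$subject_id[ok], mean)
    if (length(means) >= 3) {
      bad <- iqr_outlier(as.numeric(means), mult)
      bad_subj <- names(means)[bad]
      hit <- table$subject_id %in% bad_subj
      table$excluded[hit] <- TRUE
      table$reason[hit] <- "subject-level IQR outlier"
    }
  }
  table
}

#' Block-averaged U-values with pooled ranks
#'
#' Averages the non-excluded block U-values within each subject x condition
#' cell, then rank-transforms the means pooled over all cells (midranks for
#' ties). Cells whose blocks were all excluded are dropped with a warning.
#'
#' @param table a `UTable`, exclusions already applied.
#' @return a `RankedUTable`: data.frame with columns `subject_id`,
#'   `condition`, `mean_U`, `rank`.
#' @export
average_and_rank <- function(table) {
  ok <- table[!table$excluded, , drop = FALSE]
  all_cells <- unique(table[c("subject_id", "condition")])
  agg <- stats::aggregate(U ~ subject_id + condition, data = ok, FUN = mean)
  names(agg)[names(agg) == "U"] <- "mean_U"
  dropped <- nrow(all_cells) - nrow(agg)
  if (dropped > 0)
    warning(sprintf("average_and_rank: %d subject x condition cell(s) had ",
                    dropped), "all blocks excluded and were dropped")
  agg$rank <- rank(agg$mean_U, ties.method = "average")
  agg <- agg[order(agg$subject_id, agg$condition), ]
  rownames(agg) <- NULL
  class(agg) <- c("ranked_u_table", "data.frame")
  agg
}

#' Mixed-effects model for the condition effect on ranked U
#'
#' Fits a linear mixed model with the pooled U-value ranks as the response,
#' condition as a fixed effect, and per-subject random intercepts
#' (optionally per-subject random slopes, and a mini-block covariate for
#' time-course analyses). The condition effect is tested primarily by a
#' likelihood-ratio test between nested maximum-likelihood fits; a
#' Satterthwaite-approximate F-test is reported as a secondary readout. A
#' singular random-slope fit is automatically refit with intercepts only and
#' flagged.
#'
#' @param table a `RankedUTable`, or any data.frame with columns
#'   `subject_id`, `condition`, `rank` (and optionally `miniblock`).
#' @param random_slopes add per-subject random slopes for condition (and
#'   mini-block, when present)?
#' @param miniblock optional name of a numeric mini-block column to include
#'   as a fixed covariate.
#' @return an object of class `"condition_model"`: list with the fitted
#'   `model`, `lrt` (statistic, df, p), `f_test` (Satterthwaite ANOVA
#'   table), `miniblock_lrt` (when applicable), `coefficients`, and
#'   `singular_refit`.
#' @export
fit_condition_model <- function(table, random_slopes = FALSE,
                                miniblock = NULL) {
  df <- as.data.frame(table)
  stopifnot(all(c("subject_id", "condition", "rank") %in% names(df)))
  if (length(unique(df$condition)) < 2)
    stop("fit_condition_model: need >= 2 conditions", call. = FALSE)
  if (length(unique(df$subject_id)) < 5)
    stop("fit_condition_model: need >= 5 subjects", call. = FALSE)
  df$condition <- factor(df$condition)
  df$subject_id <- factor(df$subject_id)
  fixed <- "condition"
  if (!is.null(miniblock)) {
    stopifnot(miniblock %in% names(df))
    df$.mb <- as.numeric(df[[miniblock]])
    fixed <- c(fixed, ".mb")
  }
  ran <- if (random_slopes)
    sprintf("(1 + %s | subject_id)", paste(fixed, collapse = " + "))
  else "(1 | subject_id)"
  form <- function(terms) stats::as.formula(
    paste("rank ~", paste(c(terms, ran), collapse = " + ")))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_ml <- function(f) suppressWarnings(suppressMessages(
    lmerTest::lmer(f, data = df, REML = FALSE, control = ctrl)))
  full <- fit_ml(form(fixed))
  singular_refit <- FALSE
  if (random_slopes && lme4::isSingular(full, tol = 1e-4)) {
    ran <- "(1 | subject_id)"
    full <- fit_ml(form(fixed))
    singular_refit <- TRUE
  }
  reduced <- fit_ml(form(setdiff(fixed, "condition")))
  an <- stats::anova(reduced, full)
  lrt <- list(statistic = an$Chisq[2], df = an$Df[2],
              p = an[["Pr(>Chisq)"]][2])
  ftab <- tryCatch(stats::anova(full, type = 3), error = function(e) NULL)
  mb_lrt <- NULL
  if (!is.null(miniblock)) {
    red_mb <- fit_ml(form(setdiff(fixed, ".mb")))
    an2 <- stats::anova(red_mb, full)
    mb_lrt <- list(statistic = an2$Chisq[2], df = an2$Df[2],
                   p = an2[["Pr(>Chisq)"]][2])
  }
  structure(list(model = full, lrt = lrt, f_test = ftab,
                 miniblock_lrt = mb_lrt,
                 coefficients = lme4::fixef(full),
                 singular_refit = singular_refit),
            class = "condition_model")
}

#' @export
print.condition_model <- function(x, ...) {
  cat("Mixed model on ranked U-values\n")
  cat(sprintf("  condition LRT: chisq = %.3f, df = %d, p = %.4g\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p))
  if (!is.null(x$miniblock_lrt))
    cat(sprintf("  mini-block LRT: chisq = %.3f, df = %d, p = %.4g\n",
                x$miniblock_lrt$statistic, x$miniblock_lrt$df,
                x$miniblock_lrt$p))
  if (x$singular_refit)
    cat("  note: random slopes were singular; refit with intercepts only\n")
  invisible(x)
}

#' Paired permutation contrast between two conditions
#'
#' The observed statistic is the group mean of the per-subject difference in
#' block-averaged U-values between the two conditions. The null is built by
#' independently swapping the two condition labels within each subject
#' (equivalent to sign-flipping the paired differences); the two-sided
#' p-value counts null draws whose absolute mean difference meets or exceeds
#' the observed one, with the +1 finite-sample correction. Subjects missing
#' either condition are dropped pairwise with a warning.
#'
#' @param means a `RankedUTable` (or data.frame with `subject_id`,
#'   `condition`, `mean_U`).
#' @param condition_a,condition_b condition labels to contrast
#'   (`observed_diff` is a minus b).
#' @param n_iter number of label shuffles (default 5000).
#' @param seed integer seed.
#' @return an object of class `"condition_contrast"`.
#' @export
permutation_contrast <- function(means, condition_a, condition_b,
                                 n_iter = 5000, seed = 1) {
  df <- as.data.frame(means)
  a <- df[df$condition == condition_a, c("subject_id", "mean_U")]
  b <- df[df$condition == condition_b, c("subject_id", "mean_U")]
  common <- intersect(a$subject_id, b$subject_id)
  n_drop <- length(union(a$subject_id, b$subject_id)) - length(common)
  if (n_drop > 0)
    warning(sprintf("permutation_contrast: %d subject(s) missing a ",
                    n_drop), "condition were dropped")
  if (length(common) < 2)
    stop("permutation_contrast: need >= 2 subjects with both conditions",
         call. = FALSE)
  d <- a$mean_U[match(common, a$subject_id)] -
       b$mean_U[match(common, b$subject_id)]
  obs <- mean(d)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_iter * length(d), replace = TRUE),
                  nrow = n_iter)
  null <- as.vector(signs %*% d) / length(d)
  p <- (sum(abs(null) >= abs(obs)) + 1) / (n_iter + 1)
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 observed_diff = obs, p = p, n_iter = n_iter, seed = seed,
                 n_subjects = length(common), null = null),
            class = "condition_contrast")
}

#' @export
print.condition_contrast <- function(x, ...) {
  cat(sprintf("Permutation contrast %s - %s: diff = %.3f deg, p = %.4g ",
              x$condition_a, x$condition_b, x$observed_diff, x$p))
  cat(sprintf("(%d subjects, %d shuffles)\n", x$n_subjects, x$n_iter))
  invisible(x)
}

#' Mini-block time course of U-values
#'
#' Splits each rhythmic block's drops, in temporal order, into
#' `n_miniblocks` contiguous segments of equal tap count (any remainder
#' spread over the earliest segments) and computes Rao U within each
#' segment. The result feeds [fit_condition_model()] with the mini-block
#' index as a covariate to test whether entrainment changes over the course
#' of a block. Blocks too short for at least 2 taps per segment are skipped
#' with a warning.
#'
#' @param taps list of rhythmic [tap_series()].
#' @param envelopes named list of envelopes keyed by `block_id`.
#' @param n_miniblocks number of segments (default 10, i.e. 10% of the taps
#'   each).
#' @return data.frame with columns `subject_id`, `condition`, `block_id`,
#'   `miniblock`, `U`, `n_taps`.
#' @export
miniblock_analysis <- function(taps, envelopes, n_miniblocks = 10) {
  stopifnot(n_miniblocks >= 2)
  out <- list()
  for (s in taps) {
    if (s$task != "rhythmic") next
    env <- envelopes[[s$block_id]]
    if (is.null(env))
      stop(sprintf("miniblock_analysis: no envelope for block '%s'",
                   s$block_id), call. = FALSE)
    d <- drop_times(s)
    d <- d[d < env$spec$duration]
    if (floor(length(d) / n_miniblocks) < 2) {
      warning(sprintf("miniblock_analysis: block '%s' has too few taps; ",
                      s$block_id), "skipped")
      next
    }
    sizes <- miniblock_sizes(length(d), n_miniblocks)
    idx <- rep(seq_len(n_miniblocks), times = sizes)
    ph <- phase_at(env, d)
    for (m in seq_len(n_miniblocks)) {
      pm <- ph[idx == m]
      out[[length(out) + 1]] <- data.frame(
        subject_id = s$subject_id, condition = s$condition,
        block_id = s$block_id, miniblock = m,
        U = rao_spacing_U(pm), n_taps = length(pm))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# contiguous equal-count partition sizes; remainder goes to the earliest
# segments: 23 taps over 10 -> 3 3 3 2 2 2 2 2 2 2
miniblock_sizes <- function(n, k) {
  base <- n %/% k
  rem <- n %% k
  base + (seq_len(k) <= rem)
}
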