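# Evaluation statistics for the 2 (region) x 3 (age group) x 3 (task) mixed
# design: descriptives, split-plot ANOVA with Mauchly/Greenhouse-Geisser
# sphericity handling, LSD post hoc, SUS scoring, Likert summaries.

.canonical_tasks <- function(x) {
  lv <- unique(as.character(x))
  pref <- c("ST", "DT", "FW")
  if (setequal(lv, pref)) pref else sort(lv)
}

# data -> list(Y [n x k wide matrix], between data.frame, k, tasks, n_excluded)
.rm_wide <- function(data, metric = NULL) {
  req <- c("subject_id", "region", "age_group", "task", "value")
  if (!all(req %in% names(data))) {
    abort_gait(sprintf("cohort data must have columns %s",
                       paste(req, collapse = ", ")),
               "gait_format_error")
  }
  if (!is.null(metric) && "metric" %in% names(data)) {
    data <- data[data$metric == metric, , drop = FALSE]
    if (!nrow(data)) {
      abort_gait(sprintf("no rows for metric '%s'", metric), "gait_data_error")
    }
  }
  tasks <- .canonical_tasks(data$task)
  k <- length(tasks)
  ids <- unique(data$subject_id)
  complete <- vapply(ids, function(id) {
    tt <- data$task[data$subject_id == id]
    !anyDuplicated(tt) && setequal(tt, tasks)
  }, logical(1))
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("excluding %d subject(s) with incomplete task data",
                    n_excluded))
  }
  ids <- ids[complete]
  if (length(ids) < 2L) {
    abort_gait("need at least 2 complete subjects", "gait_data_error")
  }
  Y <- matrix(NA_real_, nrow = length(ids), ncol = k,
              dimnames = list(ids, tasks))
  between <- data.frame(region = character(length(ids)),
                        age_group = character(length(ids)),
                        stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rows <- data[data$subject_id == ids[i], ]
    Y[i, ] <- rows$value[match(tasks, rows$task)]
    if (length(unique(rows$region)) > 1L ||
        length(unique(rows$age_group)) > 1L) {
      abort_gait(sprintf("subject %s has inconsistent between-subject factors",
                         ids[i]),
                 "gait_data_error")
    }
    between$region[i] <- rows$region[1L]
    between$age_group[i] <- rows$age_group[1L]
  }
  between$region <- factor(between$region)
  between$age_group <- factor(between$age_group)
  list(Y = Y, between = between, k = k, tasks = tasks,
       n_excluded = n_excluded)
}

# orthonormal contrasts spanning the space orthogonal to the unit vector
.orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# pooled within-group covariance of the k repeated measures
.pooled_cov <- function(Y, groups = NULL) {
  n <- nrow(Y)
  if (is.null(groups)) groups <- factor(rep(1L, n))
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  if (n - g < ncol(Y)) {
    abort_gait("too few subjects to estimate the within-cell covariance",
               "gait_data_error")
  }
  S <- matrix(0, ncol(Y), ncol(Y))
  for (lv in levels(groups)) {
    Yg <- Y[groups == lv, , drop = FALSE]
    if (nrow(Yg) > 1L) {
      S <- S + crossprod(scale(Yg, center = TRUE, scale = FALSE))
    }
  }
  list(S = S / (n - g), df = n - g)
}

#' Mauchly test of sphericity
#'
#' Tests whether the covariance of the orthonormal contrasts of the repeated
#' measures is proportional to the identity (sphericity), using the pooled
#' within-group covariance when a grouping factor is supplied. W is the
#' ratio of the geometric to the arithmetic mean (to the power k-1) of the
#' contrast-covariance eigenvalues; the p value uses the standard chi-square
#' approximation.
#'
#' @param Y Numeric matrix, subjects x k repeated measures (k >= 3).
#' @param groups Optional between-subject grouping factor (length nrow(Y)).
#' @return List with `W`, `statistic` (chi-square), `df`, `p`.
#' @export
mauchly_test <- function(Y, groups = NULL) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  if (k < 3L) abort_gait("need k >= 3 within-subject levels", "gait_parameter_error")
  if (nrow(Y) < k) abort_gait("need at least k subjects", "gait_data_error")
  pc <- .pooled_cov(Y, groups)
  Cm <- .orthonormal_contrasts(k)
  Sc <- t(Cm) %*% pc$S %*% Cm
  lambda <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(mean(diag(pc$S)), .Machine$double.xmin)
  if (min(lambda) <= tol) {
    abort_gait("singular contrast covariance: Mauchly W undefined",
               "gait_degenerate_error")
  }
  p1 <- k - 1L
  W <- prod(lambda) / mean(lambda)^p1
  d <- pc$df
  f <- 1 - (2 * p1^2 + p1 + 2) / (6 * p1 * d)
  X2 <- -f * d * log(W)
  df <- k * (k - 1) / 2 - 1
  list(W = W, statistic = X2, df = df,
       p = stats::pchisq(X2, df, lower.tail = FALSE))
}

#' Greenhouse-Geisser epsilon
#'
#' `epsilon = (sum(lambda))^2 / ((k - 1) * sum(lambda^2))` over the
#' eigenvalues of the orthonormal-contrast covariance; equals 1 under exact
#' sphericity and is bounded below by `1/(k - 1)`. Within-subject F-test
#' degrees of freedom are multiplied by epsilon when sphericity is violated.
#'
#' @inheritParams mauchly_test
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(Y, groups = NULL) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  if (k < 3L) abort_gait("need k >= 3 within-subject levels", "gait_parameter_error")
  pc <- .pooled_cov(Y, groups)
  Cm <- .orthonormal_contrasts(k)
  Sc <- t(Cm) %*% pc$S %*% Cm
  lambda <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  if (all(lambda <= 0)) {
    abort_gait("degenerate contrast covariance", "gait_degenerate_error")
  }
  sum(lambda)^2 / ((k - 1) * sum(lambda^2))
}

# Type III sums of squares by model comparison on effect-coded design
# matrices: SS(term) = RSS(model without the term's columns) - RSS(full).
.rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), rank = fit$rank)
}

.type3_ss <- function(formula, data, y) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X <- stats::model.matrix(formula, data)
  asg <- attr(X, "assign")
  labels <- attr(stats::terms(formula), "term.labels")
  full <- .rss(X, y)
  ss <- vapply(seq_along(labels), function(ti) {
    .rss(X[, asg != ti, drop = FALSE], y)$rss - full$rss
  }, numeric(1))
  names(ss) <- labels
  df <- vapply(seq_along(labels), function(ti) sum(asg == ti), numeric(1))
  list(ss = ss, df = df, rss = full$rss, df_resid = nrow(X) - full$rank)
}

#' Mixed repeated-measures ANOVA
#'
#' Univariate split-plot ANOVA for the 2 (region) x 3 (age group) between x
#' 3 (task) within design: partitioned sums of squares with two error
#' strata — subjects within groups for the between effects, task x subjects
#' within groups for the within effects. Sums of squares are Type III
#' (effect-coded model comparison), which coincides with the classical
#' marginal-means decomposition for balanced data and handles unequal cell
#' sizes. Sphericity of the within factor is assessed with
#' [mauchly_test()]; when violated (p < alpha, the default policy) the
#' within-subject F tests use Greenhouse-Geisser corrected degrees of
#' freedom (both numerator and denominator scaled by [gg_epsilon()]).
#' Subjects with missing task rows are excluded listwise (with a message).
#'
#' @param data Long-format cohort `data.frame` with columns `subject_id`,
#'   `region`, `age_group`, `task`, `value` (and optionally `metric`).
#' @param metric If the table holds several metrics, which one to analyse.
#' @param gg `"auto"` (correct when Mauchly p < alpha), `"always"`, or
#'   `"never"`.
#' @param alpha Significance threshold used by the `"auto"` policy and
#'   reported for convenience (default 0.05).
#' @return A `data.frame` of class `rm_anova`: one row per term (`region`,
#'   `age_group`, `region:age_group`, `task`, `task:region`, `task:age_group`,
#'   `task:region:age_group`) with `SS`, `df_num`, `df_den`, `F`, `epsilon`,
#'   `corrected`, `p`. Attributes: `mauchly` (list), `epsilon`, `error`
#'   (per-stratum error SS/df/MS), `n_subjects`, `n_excluded`, `k`, `tasks`,
#'   `ss_total`.
#' @export
mixed_rm_anova <- function(data, metric = NULL, gg = c("auto", "always", "never"),
                           alpha = 0.05) {
  gg <- match.arg(gg)
  w <- .rm_wide(data, metric)
  Y <- w$Y
  k <- w$k
  n <- nrow(Y)
  btw <- w$between
  g <- nrow(unique(btw))

  # ---- between stratum (on subject means; SS scaled back by k) ----
  m <- rowMeans(Y)
  b3 <- .type3_ss(~ region * age_group, btw, m)
  ss_b <- k * b3$ss
  df_b <- b3$df
  ss_subj <- k * b3$rss
  df_subj <- b3$df_resid
  ms_subj <- ss_subj / df_subj
  F_b <- (ss_b / df_b) / ms_subj
  p_b <- stats::pf(F_b, df_b, df_subj, lower.tail = FALSE)

  # ---- within stratum (subject-centred data) ----
  d <- Y - m
  long <- data.frame(
    task = factor(rep(w$tasks, each = n), levels = w$tasks),
    region = rep(btw$region, times = k),
    age_group = rep(btw$age_group, times = k)
  )
  yv <- as.numeric(d)           # column-major: task blocks
  # full factorial on subject-centred data: between-only blocks have
  # identically zero SS there (deviations sum to 0 within subject), while
  # the task-involving blocks keep their marginality-correct column counts
  w3 <- .type3_ss(~ task * region * age_group, long, yv)
  keep <- grepl("task", names(w3$ss))
  ss_w <- w3$ss[keep]
  df_w <- w3$df[keep]
  names(df_w) <- names(ss_w)
  ss_err <- w3$rss
  df_err <- (k - 1) * (n - g)
  ms_err <- ss_err / df_err
  F_w <- (ss_w / df_w) / ms_err

  # ---- sphericity ----
  grp <- interaction(btw$region, btw$age_group, drop = TRUE)
  mt <- tryCatch(mauchly_test(Y, grp), gait_error = function(e) NULL)
  eps <- tryCatch(gg_epsilon(Y, grp), gait_error = function(e) NA_real_)
  correct <- switch(gg,
    auto = !is.null(mt) && is.finite(eps) && mt$p < alpha,
    always = is.finite(eps),
    never = FALSE
  )
  df1_w <- df_w * if (correct) eps else 1
  df2_w <- rep(df_err * if (correct) eps else 1, length(ss_w))
  p_w <- stats::pf(F_w, df1_w, df2_w, lower.tail = FALSE)

  res <- data.frame(
    term = c(names(ss_b), names(ss_w)),
    SS = c(ss_b, ss_w),
    df_num = c(df_b, df1_w),
    df_den = c(rep(df_subj, length(ss_b)), df2_w),
    F = c(F_b, F_w),
    epsilon = c(rep(NA_real_, length(ss_b)),
                rep(if (correct) eps else NA_real_, length(ss_w))),
    corrected = c(rep(FALSE, length(ss_b)), rep(correct, length(ss_w))),
    p = c(p_b, p_w),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(res) <- c("rm_anova", "data.frame")
  attr(res, "mauchly") <- mt
  attr(res, "epsilon") <- eps
  attr(res, "error") <- list(
    between = list(SS = ss_subj, df = df_subj, MS = ms_subj),
    within = list(SS = ss_err, df = df_err, MS = ms_err)
  )
  attr(res, "n_subjects") <- n
  attr(res, "n_excluded") <- w$n_excluded
  attr(res, "k") <- k
  attr(res, "tasks") <- w$tasks
  attr(res, "Y") <- Y
  attr(res, "between") <- btw
  attr(res, "ss_total") <- sum((as.numeric(Y) - mean(Y))^2)
  attr(res, "alpha") <- alpha
  res
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA (%d subjects", attr(x, "n_subjects")))
  if (attr(x, "n_excluded") > 0) {
    cat(sprintf(", %d excluded", attr(x, "n_excluded")))
  }
  cat(")\n")
  mt <- attr(x, "mauchly")
  if (!is.null(mt)) {
    cat(sprintf("Mauchly W = %.4f, p = %.4g; GG epsilon = %.4f%s\n",
                mt$W, mt$p, attr(x, "epsilon"),
                if (any(x$corrected)) " (correction applied)" else ""))
  }
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 5); df$F <- signif(df$F, 5)
  df$df_num <- signif(df$df_num, 4); df$df_den <- signif(df$df_den, 5)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Descriptive cell table: mean and 95% CI per factor level
#'
#' Means with two-sided t-based confidence intervals (n-1 degrees of
#' freedom), in the style of the study's descriptive tables. `factors` may
#' contain single factor names or character vectors for interaction cells,
#' e.g. `list("task", c("region", "task"))`. Empty cells are reported as
#' missing rows, not errors.
#'
#' @param data Long-format cohort `data.frame` (see [mixed_rm_anova()]).
#' @param metric Optional metric filter.
#' @param factors List of factor name(s) to summarise over.
#' @param conf Confidence level (default 0.95).
#' @return `data.frame` with `factor`, `level`, `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
cell_descriptives <- function(data, metric = NULL,
                              factors = list("region", "age_group", "task"),
                              conf = 0.95) {
  if (!is.null(metric) && "metric" %in% names(data)) {
    data <- data[data$metric == metric, , drop = FALSE]
  }
  if (is.character(factors)) factors <- as.list(factors)
  out <- list()
  for (fct in factors) {
    if (!all(fct %in% names(data))) {
      abort_gait(sprintf("unknown factor column(s): %s",
                         paste(setdiff(fct, names(data)), collapse = ", ")),
                 "gait_parameter_error")
    }
    key <- interaction(data[fct], sep = ":", drop = FALSE)
    for (lv in levels(key)) {
      vals <- data$value[key == lv]
      n <- length(vals)
      if (n == 0L) {
        row <- data.frame(factor = paste(fct, collapse = ":"), level = lv,
                          n = 0L, mean = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, stringsAsFactors = FALSE)
      } else {
        m <- mean(vals)
        half <- if (n > 1L) {
          stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(vals) / sqrt(n)
        } else NA_real_
        row <- data.frame(factor = paste(fct, collapse = ":"), level = lv,
                          n = n, mean = m, ci_lo = m - half, ci_hi = m + half,
                          stringsAsFactors = FALSE)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' LSD post hoc pairwise comparisons
#'
#' Fisher's least significant difference: all pairwise t tests on level
#' means, using the error mean square (and its degrees of freedom) from the
#' ANOVA stratum the factor belongs to — subjects-within-groups for between
#' factors, task x subjects for the within factor. Deliberately applies no
#' multiplicity adjustment: LSD controls error only through the preceding
#' omnibus F test.
#'
#' @param data Long-format cohort `data.frame`.
#' @param metric Optional metric filter.
#' @param factor One of `"task"`, `"region"`, `"age_group"`.
#' @return `data.frame` with `level_a`, `level_b`, `diff` (a - b), `se`,
#'   `t`, `df`, `p`.
#' @export
lsd_posthoc <- function(data, metric = NULL,
                        factor = c("task", "region", "age_group")) {
  factor <- match.arg(factor)
  fit <- mixed_rm_anova(data, metric = metric)
  Y <- attr(fit, "Y")
  btw <- attr(fit, "between")
  err <- attr(fit, "error")
  k <- attr(fit, "k")
  if (factor == "task") {
    means <- colMeans(Y)
    ns <- rep(nrow(Y), k)
    ms <- err$within$MS
    df <- err$within$df
  } else {
    m <- rowMeans(Y)
    f <- btw[[factor]]
    means <- tapply(m, f, mean)
    ns <- as.numeric(table(f))
    ms <- err$between$MS / k      # on the subject-means scale
    df <- err$between$df
  }
  lv <- names(means)
  pairs <- utils::combn(seq_along(lv), 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(ms * (1 / ns[i] + 1 / ns[j]))
    dm <- means[i] - means[j]
    tt <- dm / se
    data.frame(level_a = lv[i], level_b = lv[j], diff = as.numeric(dm),
               se = se, t = as.numeric(tt), df = df,
               p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' System Usability Scale score
#'
#' Standard SUS scoring of the 10 alternating-polarity 5-point items:
#' `2.5 * (sum(odd items - 1) + sum(5 - even items))`, giving a score from 0
#' ("worst imaginable") to 100 ("best imaginable").
#'
#' @param response Integer vector of the 10 item scores (each 1–5), or a
#'   matrix/data.frame with one respondent per row and 10 item columns.
#' @return Numeric score(s) in `[0, 100]`.
#' @export
sus_score <- function(response) {
  if (is.data.frame(response)) response <- as.matrix(response)
  if (is.matrix(response)) {
    if (ncol(response) != 10L) {
      abort_gait("SUS needs exactly 10 items", "gait_parameter_error")
    }
    return(apply(response, 1, sus_score))
  }
  if (length(response) != 10L) {
    abort_gait("SUS needs exactly 10 items", "gait_parameter_error")
  }
  if (anyNA(response) || any(response != round(response)) ||
      any(response < 1) || any(response > 5)) {
    abort_gait("SUS items must be integers in 1..5", "gait_parameter_error")
  }
  odd <- response[c(1, 3, 5, 7, 9)]
  even <- response[c(2, 4, 6, 8, 10)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' Likert summaries per acceptance measure
#'
#' Mean and SD (n-1 denominator) of 5-point Likert responses grouped into
#' acceptance measures (e.g. perceived ease of use, perceived usefulness,
#' ease of learning, intention to use), optionally split by a grouping
#' column such as the app function being rated.
#'
#' @param responses Wide `data.frame` with one respondent per row and item
#'   columns (values 1–5), plus optionally the `by` column.
#' @param measure_map Named character vector mapping item column names to
#'   measure names.
#' @param by Optional name of a grouping column in `responses`.
#' @return `data.frame` with (`by`,) `measure`, `n`, `mean`, `sd`. Measures
#'   with no observations yield an `NA` row.
#' @export
likert_summary <- function(responses, measure_map, by = NULL) {
  if (!is.character(measure_map) || is.null(names(measure_map))) {
    abort_gait("`measure_map` must be a named character vector (item -> measure)",
               "gait_parameter_error")
  }
  missing_items <- setdiff(names(measure_map), names(responses))
  if (length(missing_items)) {
    abort_gait(sprintf("items not in responses: %s",
                       paste(missing_items, collapse = ", ")),
               "gait_format_error")
  }
  groups <- if (is.null(by)) factor(rep("all", nrow(responses)))
            else factor(responses[[by]])
  measures <- unique(unname(measure_map))
  out <- list()
  for (gl in levels(groups)) {
    for (ms in measures) {
      items <- names(measure_map)[measure_map == ms]
      vals <- unlist(responses[groups == gl, items, drop = FALSE],
                     use.names = FALSE)
      vals <- vals[!is.na(vals)]
      n <- length(vals)
      row <- data.frame(
        measure = ms, n = n,
        mean = if (n) mean(vals) else NA_real_,
        sd = if (n > 1) stats::sd(vals) else NA_real_,
        stringsAsFactors = FALSE
      )
      if (!is.null(by)) {
        row <- cbind(stats::setNames(data.frame(gl, stringsAsFactors = FALSE),
                                     by), row)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
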