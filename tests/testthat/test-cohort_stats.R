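make_cells <- function(values_by_cell) {
  # tiny long-format builder for hand fixtures
  do.call(rbind, lapply(names(values_by_cell), function(k) {
    parts <- strsplit(k, "\\|")[[1]]
    data.frame(subject_id = parts[1], region = parts[2], age_group = parts[3],
               task = parts[4], value = values_by_cell[[k]],
               stringsAsFactors = FALSE)
  }))
}

test_that("cell descriptives use t-based confidence intervals", {
  d <- data.frame(
    subject_id = rep(c("a", "b", "c"), each = 3),
    region = "R1", age_group = "60-69",
    task = rep(c("ST", "DT", "FW"), 3),
    value = c(2, 2, 2, 2, 2, 2, 2, 2, 2)
  )
  out <- cell_descriptives(d, factors = list("task"))
  expect_true(all(out$mean == 2))
  expect_true(all(out$ci_lo == 2 & out$ci_hi == 2))

  d2 <- data.frame(subject_id = c("a", "b", "c"), region = "R1",
                   age_group = "60-69", task = "ST", value = c(1, 2, 3))
  out2 <- cell_descriptives(d2, factors = list("task"))
  half <- qt(0.975, 2) * 1 / sqrt(3)    # sd({1,2,3}) = 1
  expect_equal(out2$mean, 2)
  expect_equal(out2$ci_hi - out2$mean, half, tolerance = 1e-12)

  # interaction cells and empty levels
  d2$task <- factor(d2$task, levels = c("ST", "DT"))
  out3 <- cell_descriptives(d2, factors = list(c("region", "task")))
  expect_identical(nrow(out3), 2L)
  expect_true(is.na(out3$mean[out3$level == "R1:DT"]))
})

test_that("confidence intervals achieve near-nominal coverage on null cohorts", {
  hits <- 0L; total <- 0L
  for (seed in 1:200) {
    coh <- generate_cohort(5, grand_mean = 2, subject_sd = 0.1,
                           noise_sd = 0.1, seed = seed)
    out <- cell_descriptives(coh, factors = list("task"))
    hits <- hits + sum(out$ci_lo <= 2 & out$ci_hi >= 2)
    total <- total + nrow(out)
  }
  # subject intercepts induce slight dependence between rows of a task cell,
  # so allow a modest band around 95%
  expect_gt(hits / total, 0.88)
  expect_lte(hits / total, 1)
})

test_that("Mauchly W is 1 under exact compound symmetry and < 1 otherwise", {
  cs <- 0.5 * diag(3) + 0.5
  Y <- matrix_with_cov(40, cs, seed = 2)
  m <- mauchly_test(Y)
  expect_equal(m$W, 1, tolerance = 1e-9)
  expect_gt(m$p, 0.999)

  het <- diag(c(4, 1, 0.25))
  Yh <- matrix_with_cov(40, het, seed = 3)
  expect_lt(mauchly_test(Yh)$W, 1)
})

test_that("Mauchly matches stats::mauchly.test on single-group data", {
  for (seed in 1:20) {
    set.seed(seed)
    Y <- matrix(rnorm(15 * 3), 15, 3) %*% matrix(c(1, .3, 0, .3, 1.5, .2,
                                                   0, .2, 0.7), 3)
    m <- mauchly_test(Y)
    ref <- stats::mauchly.test(lm(Y ~ 1), X = ~1)
    expect_equal(m$W, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(m$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(mauchly_test(matrix(rnorm(20), 10, 2)),
               class = "gait_parameter_error")
  degenerate <- cbind(1:10, 1:10, 1:10)
  expect_error(mauchly_test(degenerate), class = "gait_degenerate_error")
})

test_that("Greenhouse-Geisser epsilon respects its closed forms and bounds", {
  cs <- 0.3 * diag(3) + 0.7
  expect_equal(gg_epsilon(matrix_with_cov(30, cs, seed = 4)), 1,
               tolerance = 1e-9)

  # rank-1 contrast covariance: epsilon at the lower bound 1/(k-1)
  set.seed(5)
  z <- rnorm(20)
  Y1 <- outer(z, c(1, 0, -1)) + rnorm(20)  # subject offsets are contrast-free
  expect_equal(gg_epsilon(Y1), 0.5, tolerance = 1e-9)

  # eigenvalue-formula oracle with an independently built contrast basis
  for (seed in 1:20) {
    set.seed(seed)
    A <- matrix(rnorm(16), 4)
    S <- crossprod(A) + diag(4)
    Y <- matrix_with_cov(25, S, seed = seed + 100)
    k <- 4
    Cb <- qr.Q(qr(cbind(1, diag(k))))[, 2:k]   # any orthonormal complement of 1
    lam <- eigen(t(Cb) %*% cov(Y) %*% Cb, symmetric = TRUE)$values
    eps_oracle <- sum(lam)^2 / ((k - 1) * sum(lam^2))
    eps <- gg_epsilon(Y)
    expect_equal(eps, eps_oracle, tolerance = 1e-10)
    expect_gte(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1 + 1e-12)
  }
})

test_that("mixed ANOVA matches the classical split-plot oracle when balanced", {
  coh <- generate_cohort(2, grand_mean = 2,
                         region_effects = c("Beijing-like" = 0.1,
                                            "Chongqing-like" = -0.1),
                         task_effects = c(ST = 0, DT = -0.2, FW = 0.25),
                         subject_sd = 0.2, noise_sd = 0.1, seed = 11)
  fit <- mixed_rm_anova(coh, gg = "never")
  oracle <- splitplot_oracle(coh)
  for (term in fit$term) {
    expect_equal(fit$SS[fit$term == term], unname(oracle$ss[term]),
                 tolerance = 1e-8, info = term)
    expect_equal(fit$F[fit$term == term], unname(oracle$F[term]),
                 tolerance = 1e-8, info = term)
  }
  err <- attr(fit, "error")
  expect_equal(err$between$SS, oracle$ss_subj, tolerance = 1e-8)
  expect_equal(err$within$SS, oracle$ss_err_w, tolerance = 1e-8)
  # total SS conservation
  expect_equal(attr(fit, "ss_total"),
               sum(fit$SS) + err$between$SS + err$within$SS,
               tolerance = 1e-8)
})

test_that("mixed ANOVA agrees with car's univariate mixed-model table", {
  coh <- generate_cohort(4, task_effects = c(ST = 0, DT = -0.14, FW = 0.19),
                         seed = 5)
  fit <- mixed_rm_anova(coh, gg = "never")
  w <- gaitacc:::.rm_wide(coh, NULL)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mlm <- lm(w$Y ~ region * age_group, data = w$between)
  idata <- data.frame(task = factor(colnames(w$Y), levels = colnames(w$Y)))
  u <- suppressWarnings(summary(
    car::Anova(mlm, idata = idata, idesign = ~task, type = 3),
    multivariate = FALSE
  ))$univariate.tests
  map <- c(region = "region", age_group = "age_group",
           `region:age_group` = "region:age_group", task = "task",
           `region:task` = "task:region", `age_group:task` = "task:age_group",
           `region:age_group:task` = "task:region:age_group")
  for (car_term in names(map)) {
    mine <- fit[fit$term == map[[car_term]], ]
    expect_equal(mine$SS, u[car_term, "Sum Sq"], tolerance = 1e-10,
                 info = car_term)
    expect_equal(mine$F, u[car_term, "F value"], tolerance = 1e-10,
                 info = car_term)
  }
})

test_that("GG correction is applied under the Mauchly p < .05 policy", {
  # strongly non-spherical within-subject covariance
  set.seed(17)
  n <- 36
  base <- expand.grid(region = c("Beijing-like", "Chongqing-like"),
                      age_group = c("60-69", "70-79", "80-89"),
                      stringsAsFactors = FALSE)
  btw <- base[rep(1:6, each = 6), ]
  S <- matrix(c(1, 0.95, 0.1, 0.95, 1, 0.1, 0.1, 0.1, 0.05), 3)
  Y <- matrix_with_cov(n, S, seed = 18) + 2
  coh <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:n), times = 3),
    region = rep(btw$region, times = 3),
    age_group = rep(btw$age_group, times = 3),
    task = rep(c("ST", "DT", "FW"), each = n),
    value = as.numeric(Y)
  )
  fit <- mixed_rm_anova(coh)
  expect_lt(attr(fit, "mauchly")$p, 0.05)
  task_row <- fit[fit$term == "task", ]
  expect_true(task_row$corrected)
  expect_lt(task_row$df_num, 2)
  expect_equal(task_row$df_num, 2 * task_row$epsilon)
  # forcing "never" leaves integer df
  fit2 <- mixed_rm_anova(coh, gg = "never")
  expect_identical(fit2$df_num[fit2$term == "task"], 2)
})

test_that("subjects with missing task rows are excluded listwise", {
  coh <- generate_cohort(3, seed = 7)
  drop_row <- which(coh$subject_id == coh$subject_id[1] & coh$task == "FW")
  coh2 <- coh[-drop_row, ]
  expect_message(fit <- mixed_rm_anova(coh2), "excluding 1 subject")
  expect_identical(attr(fit, "n_subjects"),
                   length(unique(coh$subject_id)) - 1L)
  expect_identical(attr(fit, "n_excluded"), 1L)
})

test_that("LSD post hoc matches the hand formula and detects task shifts", {
  coh <- generate_cohort(2, task_effects = c(ST = 0, DT = -0.2, FW = 0.25),
                         subject_sd = 0.2, noise_sd = 0.1, seed = 11)
  oracle <- splitplot_oracle(coh)
  res <- suppressMessages(lsd_posthoc(coh, factor = "task"))
  n_subj <- length(unique(coh$subject_id))
  task_means <- tapply(coh$value, coh$task, mean)
  i <- which(res$level_a == "ST" & res$level_b == "DT")
  t_hand <- (task_means[["ST"]] - task_means[["DT"]]) /
    sqrt(2 * oracle$ms_err_w / n_subj)
  expect_equal(res$t[i], unname(t_hand), tolerance = 1e-8)
  expect_equal(res$df[i], oracle$df_err_w)
  expect_equal(res$p[i], 2 * pt(abs(t_hand), oracle$df_err_w, lower.tail = FALSE),
               tolerance = 1e-8)

  # cohort emulating the printed task pattern: all three pairs significant
  coh2 <- generate_cohort(12, grand_mean = 1.99,
                          task_effects = c(ST = 0, DT = -0.14, FW = 0.19),
                          subject_sd = 0.15, noise_sd = 0.08, seed = 21)
  res2 <- lsd_posthoc(coh2, factor = "task")
  expect_true(all(res2$p < 0.05))

  # identical level means give p ~ 1
  d <- make_cells(list(
    `a|R1|60-69|ST` = 1, `a|R1|60-69|DT` = 2, `a|R1|60-69|FW` = 1.5,
    `b|R1|60-69|ST` = 2, `b|R1|60-69|DT` = 1, `b|R1|60-69|FW` = 1.5,
    `c|R2|70-79|ST` = 1.2, `c|R2|70-79|DT` = 2.2, `c|R2|70-79|FW` = 1.7,
    `d|R2|70-79|ST` = 2.2, `d|R2|70-79|DT` = 1.2, `d|R2|70-79|FW` = 1.7
  ))
  res3 <- lsd_posthoc(d, factor = "task")
  i3 <- which(res3$level_a == "ST" & res3$level_b == "DT")
  expect_equal(res3$diff[i3], 0, tolerance = 1e-12)
  expect_gt(res3$p[i3], 0.999)
})

test_that("between-factor LSD uses the subject-within-groups error stratum", {
  coh <- generate_cohort(8, region_effects = c("Beijing-like" = 0.3,
                                               "Chongqing-like" = -0.3),
                         subject_sd = 0.1, noise_sd = 0.1, seed = 13)
  res <- lsd_posthoc(coh, factor = "region")
  expect_identical(nrow(res), 1L)
  expect_lt(res$p, 0.01)
  expect_equal(res$diff, 0.6, tolerance = 0.15)
  fit <- mixed_rm_anova(coh)
  expect_equal(res$df, attr(fit, "error")$between$df)
})

test_that("SUS scoring hits the anchor points and stays in [0, 100]", {
  expect_equal(sus_score(rep(3, 10)), 50)
  expect_equal(sus_score(rep(c(5, 1), 5)), 100)
  expect_equal(sus_score(rep(c(1, 5), 5)), 0)
  # lattice sample
  set.seed(19)
  for (i in 1:200) {
    r <- sample(1:5, 10, replace = TRUE)
    s <- sus_score(r)
    expect_gte(s, 0)
    expect_lte(s, 100)
  }
  # matrix input vectorises
  m <- rbind(rep(3, 10), rep(c(5, 1), 5))
  expect_equal(sus_score(m), c(50, 100))
  expect_error(sus_score(c(rep(3, 9), 6)), class = "gait_parameter_error")
  expect_error(sus_score(rep(3, 9)), class = "gait_parameter_error")
})

test_that("Likert summaries aggregate items into measures", {
  resp <- data.frame(item1 = c(4, 4), item2 = c(4, 4), item3 = c(3, 5),
                     item4 = c(4, 4))
  map <- c(item1 = "ease_of_use", item2 = "ease_of_use",
           item3 = "usefulness", item4 = "usefulness")
  out <- likert_summary(resp, map)
  eou <- out[out$measure == "ease_of_use", ]
  expect_equal(eou$mean, 4)
  expect_equal(eou$sd, 0)

  resp2 <- data.frame(item1 = c(3, 4, 5))
  out2 <- likert_summary(resp2, c(item1 = "m"))
  expect_equal(out2$mean, 4)
  expect_equal(out2$sd, 1)

  # sampling check against a known generating mean of 3.7
  p <- c(0.05, 0.05, 0.2, 0.55, 0.15)   # mean 3.7 on the 1-5 scale
  sv <- generate_survey(200, response_model = p, n_items = 4, seed = 23)
  map4 <- setNames(rep("m", 4), names(sv))
  out3 <- likert_summary(sv, map4)
  se <- out3$sd / sqrt(out3$n)
  expect_lt(abs(out3$mean - 3.7), 3 * se)

  # grouping column
  sv$fn <- rep(c("gait_test", "report"), each = 100)
  out4 <- likert_summary(sv, map4, by = "fn")
  expect_identical(nrow(out4), 2L)
  expect_true(all(c("fn", "measure", "n", "mean", "sd") %in% names(out4)))
})
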