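# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# literal two-loop unbiased autocorrelation, normalized by the lag-0 value
acf_oracle <- function(x, max_lag) {
  n <- length(x)
  out <- numeric(max_lag + 1)
  for (tau in 0:max_lag) {
    s <- 0
    for (t in seq_len(n - tau)) s <- s + x[t] * x[t + tau]
    out[tau + 1] <- s / (n - tau)
  }
  out / out[1]
}

# classical balanced split-plot sums-of-squares decomposition, computed
# literally from cell and marginal means of the long-format table
splitplot_oracle <- function(data) {
  y <- data$value
  gm <- mean(y)
  agg <- function(...) tapply(y, list(...), mean)
  r_m <- agg(data$region); a_m <- agg(data$age_group); t_m <- agg(data$task)
  ra_m <- agg(data$region, data$age_group)
  tr_m <- agg(data$task, data$region)
  ta_m <- agg(data$task, data$age_group)
  tra_m <- agg(data$task, data$region, data$age_group)
  subj_m <- tapply(y, data$subject_id, mean)
  subj_cell <- tapply(data$region, data$subject_id, function(z) z[1])
  subj_age <- tapply(data$age_group, data$subject_id, function(z) z[1])
  k <- length(t_m); r <- length(r_m); a <- length(a_m)
  n_subj <- length(subj_m)
  n_cell <- n_subj / (r * a)            # balanced by construction

  ss_region <- a * n_cell * k * sum((r_m - gm)^2)
  ss_age <- r * n_cell * k * sum((a_m - gm)^2)
  ss_ra <- n_cell * k * sum((ra_m - outer(r_m, rep(1, a)) -
                               outer(rep(1, r), a_m) + gm)^2)
  cell_of_subj <- paste(subj_cell, subj_age)
  cell_mean <- tapply(subj_m, cell_of_subj, mean)
  ss_subj <- k * sum((subj_m - cell_mean[cell_of_subj])^2)

  ss_task <- r * a * n_cell * sum((t_m - gm)^2)
  ss_tr <- a * n_cell * sum((tr_m - outer(t_m, rep(1, r)) -
                               outer(rep(1, k), r_m) + gm)^2)
  ss_ta <- r * n_cell * sum((ta_m - outer(t_m, rep(1, a)) -
                               outer(rep(1, k), a_m) + gm)^2)
  ss_tra <- 0
  for (ti in seq_len(k)) for (ri in seq_len(r)) for (ai in seq_len(a)) {
    ss_tra <- ss_tra + n_cell * unname(
      (tra_m[ti, ri, ai] - tr_m[ti, ri] - ta_m[ti, ai] - ra_m[ri, ai] +
         t_m[ti] + r_m[ri] + a_m[ai] - gm)^2)
  }
  # within error: y_ij - subj mean - (cell task mean - cell mean)
  cellkey <- paste(data$region, data$age_group)
  celltask_mean <- tapply(y, list(data$task, cellkey), mean)
  cell_mean_all <- tapply(y, cellkey, mean)
  resid <- y - subj_m[as.character(data$subject_id)] -
    celltask_mean[cbind(as.character(data$task), cellkey)] +
    cell_mean_all[cellkey]
  ss_err_w <- sum(resid^2)

  df_subj <- n_subj - r * a
  df_err_w <- (k - 1) * (n_subj - r * a)
  ms_subj <- ss_subj / df_subj
  ms_err_w <- ss_err_w / df_err_w
  list(
    ss = c(region = ss_region, age_group = ss_age, `region:age_group` = ss_ra,
           task = ss_task, `task:region` = ss_tr, `task:age_group` = ss_ta,
           `task:region:age_group` = ss_tra),
    F = c(region = (ss_region / (r - 1)) / ms_subj,
          age_group = (ss_age / (a - 1)) / ms_subj,
          `region:age_group` = (ss_ra / ((r - 1) * (a - 1))) / ms_subj,
          task = (ss_task / (k - 1)) / ms_err_w,
          `task:region` = (ss_tr / ((k - 1) * (r - 1))) / ms_err_w,
          `task:age_group` = (ss_ta / ((k - 1) * (a - 1))) / ms_err_w,
          `task:region:age_group` =
            (ss_tra / ((k - 1) * (r - 1) * (a - 1))) / ms_err_w),
    ss_subj = ss_subj, ss_err_w = ss_err_w,
    ms_subj = ms_subj, ms_err_w = ms_err_w,
    df_subj = df_subj, df_err_w = df_err_w
  )
}

# a strictly uniform synthetic recording written to CSV, for CLI tests
write_recording_csv <- function(rec, path) {
  utils::write.csv(data.frame(t = rec$t, ax = rec$ax, ay = rec$ay, az = rec$az),
                   path, row.names = FALSE, quote = FALSE)
  path
}

# Y matrix with its pooled sample covariance forced to exactly `target`
# (n x k, single group): whiten the empirical covariance, re-colour.
matrix_with_cov <- function(n, target, seed = 1) {
  k <- ncol(target)
  set.seed(seed)
  Z <- matrix(rnorm(n * k), n, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  S <- crossprod(Z) / (n - 1)
  Z %*% solve(chol(S)) %*% chol(target)
}

analyze_sim <- function(seed, ...) {
  sim <- generate_walk(synthetic_gait_spec(seed = seed, ...))
  analyze_recording(sim$recording)
}
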