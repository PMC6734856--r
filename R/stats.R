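#' Long-format results table
#'
#' The evaluation statistics operate on a balanced long table: one row per
#' subject x repetition cell of a chosen metric.
#'
#' @param data data.frame with columns `subject`, `group`, `repetition`,
#'   `value` (or a cohort results table plus `metric`).
#' @param metric `"collisions"` or `"completion_time"`; used when `data` is
#'   a cohort results table.
#' @return a validated data.frame of class `long_table` with attribute
#'   `metric`.
#' @export
long_table <- function(data, metric = c("collisions", "completion_time")) {
  metric <- match.arg(metric)
  if (all(c("trainee_id", "n_collisions") %in% names(data))) {
    data <- data.frame(
      subject = data$trainee_id, group = data$group,
      repetition = data$repetition,
      value = if (metric == "collisions") data$n_collisions else data$completion_time_s)
  }
  need <- c("subject", "group", "repetition", "value")
  if (!all(need %in% names(data)))
    stop("long table needs columns: ", paste(need, collapse = ", "))
  tab <- table(data$subject, data$repetition)
  if (any(tab != 1))
    stop("unbalanced design: every subject needs every repetition exactly once")
  grp_per_subj <- tapply(as.character(data$group), data$subject,
                         function(g) length(unique(g)))
  if (any(grp_per_subj != 1)) stop("each subject must belong to one group")
  structure(data[, need], metric = metric, class = c("long_table", "data.frame"))
}

# wide subject x repetition matrix + group factor, repetitions in order
long_to_wide <- function(table) {
  reps <- sort(unique(table$repetition))
  subjects <- unique(table$subject)
  Y <- matrix(NA_real_, length(subjects), length(reps),
              dimnames = list(subjects, reps))
  idx <- cbind(match(table$subject, subjects), match(table$repetition, reps))
  Y[idx] <- table$value
  groups <- factor(table$group[match(subjects, table$subject)])
  list(Y = Y, groups = groups)
}

#' Per-group summary of a long table
#'
#' Arithmetic mean and sd over all subject x repetition cells of each group.
#'
#' @param table a [long_table()].
#' @return data.frame with columns `group`, `n_subjects`, `mean`, `sd`.
#' @export
group_summary <- function(table) {
  table <- long_table(table, attr(table, "metric") %||% "collisions")
  groups <- unique(as.character(table$group))
  if (any(vapply(groups, function(g) sum(table$group == g) == 0, logical(1))))
    stop("missing group")
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- table$value[table$group == g]
    data.frame(group = g,
               n_subjects = length(unique(table$subject[table$group == g])),
               mean = mean(v), sd = sd(v))
  }))
  rownames(out) <- NULL
  out
}

#' Mixed-design repeated-measures ANOVA
#'
#' The classical balanced decomposition with one between-subject factor
#' (group) and one within-subject factor (repetition): the group effect is
#' tested against the subjects-within-groups mean square, the repetition and
#' group x repetition effects against the within-subject error mean square.
#' Implemented from the sums-of-squares definitions (no model-fitting
#' library), with an optional Greenhouse-Geisser correction of the
#' within-subject degrees of freedom computed from the pooled within-group
#' covariance of the repeated measures.
#'
#' @param table a balanced [long_table()] with >= 2 subjects per group and
#'   >= 2 repetitions.
#' @param gg_correction apply the Greenhouse-Geisser epsilon to the
#'   within-subject tests?
#' @return an object of class `rm_anova`: `$table` (effect, ss, df, ms, F,
#'   p), `$gg_epsilon`, `$grand_mean`, and `$p_gg` when requested.
#' @export
rm_anova <- function(table, gg_correction = FALSE) {
  table <- long_table(table, attr(table, "metric") %||% "collisions")
  w <- long_to_wide(table)
  Y <- w$Y; groups <- w$groups
  if (anyNA(Y)) stop("unbalanced design")
  g <- nlevels(groups)
  m <- ncol(Y)
  N <- nrow(Y)
  if (m < 2) stop("need >= 2 repetitions")
  if (any(tabulate(groups) < 2)) stop("need >= 2 subjects per group")
  if (length(unique(tabulate(groups))) != 1)
    stop("unbalanced design: unequal group sizes")
  n <- N / g

  GM <- mean(Y)
  subj_means <- rowMeans(Y)
  rep_means <- colMeans(Y)
  grp_means <- tapply(subj_means, groups, mean)
  cell_means <- rowsum(Y, groups) / n          # g x m matrix of group x rep means

  ss_total <- sum((Y - GM)^2)
  ss_between_subj <- m * sum((subj_means - GM)^2)
  ss_group <- n * m * sum((grp_means - GM)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_rep <- N * sum((rep_means - GM)^2)
  inter <- sweep(sweep(cell_means, 1, grp_means, "-"), 2, rep_means, "-") + GM
  ss_inter <- n * sum(inter^2)
  ss_err <- ss_total - ss_between_subj - ss_rep - ss_inter

  df_group <- g - 1
  df_subj <- g * (n - 1)
  df_rep <- m - 1
  df_inter <- (g - 1) * (m - 1)
  df_err <- g * (n - 1) * (m - 1)

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  ms_group <- ms(ss_group, df_group); ms_subj <- ms(ss_subj_within, df_subj)
  ms_rep <- ms(ss_rep, df_rep); ms_inter <- ms(ss_inter, df_inter)
  ms_err <- ms(ss_err, df_err)

  f_group <- ms_group / ms_subj
  f_rep <- ms_rep / ms_err
  f_inter <- ms_inter / ms_err
  p_group <- pf(f_group, df_group, df_subj, lower.tail = FALSE)
  p_rep <- pf(f_rep, df_rep, df_err, lower.tail = FALSE)
  p_inter <- pf(f_inter, df_inter, df_err, lower.tail = FALSE)

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  centered <- Y - cell_means[as.integer(groups), , drop = FALSE]
  S <- crossprod(centered) / (N - g)
  sbar <- mean(S); dbar <- mean(diag(S)); rbar <- rowMeans(S)
  denom <- (m - 1) * (sum(S^2) - 2 * m * sum(rbar^2) + m^2 * sbar^2)
  eps <- if (denom > 0) (m^2 * (dbar - sbar)^2) / denom else 1
  eps <- min(1, max(1 / (m - 1), eps))

  tab <- data.frame(
    effect = c("group", "subjects_within_groups", "repetition",
               "group_by_repetition", "within_error"),
    ss = c(ss_group, ss_subj_within, ss_rep, ss_inter, ss_err),
    df = c(df_group, df_subj, df_rep, df_inter, df_err),
    ms = c(ms_group, ms_subj, ms_rep, ms_inter, ms_err),
    F = c(f_group, NA, f_rep, f_inter, NA),
    p = c(p_group, NA, p_rep, p_inter, NA))
  out <- list(table = tab, gg_epsilon = eps, grand_mean = GM,
              n_subjects = N, n_repetitions = m, groups = levels(groups),
              ss_total = ss_total)
  if (gg_correction) {
    out$p_gg <- c(
      repetition = pf(f_rep, df_rep * eps, df_err * eps, lower.tail = FALSE),
      group_by_repetition = pf(f_inter, df_inter * eps, df_err * eps,
                               lower.tail = FALSE))
  }
  structure(out, class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Mixed-design repeated-measures ANOVA (", x$n_subjects, "subjects x",
      x$n_repetitions, "repetitions)\n")
  print(transform(x$table, ss = signif(ss, 6), ms = signif(ms, 6),
                  F = signif(F, 5), p = signif(p, 4)), row.names = FALSE)
  cat("Greenhouse-Geisser epsilon:", signif(x$gg_epsilon, 4), "\n")
  if (!is.null(x$p_gg)) {
    cat("GG-corrected p: repetition", signif(x$p_gg[1], 4),
        "| interaction", signif(x$p_gg[2], 4), "\n")
  }
  invisible(x)
}

#' Compare the two training groups
#'
#' Packages the group effect of [rm_anova()] with the direction of effect.
#' Significance threshold defaults to a two-sided 0.05.
#'
#' @param table a balanced [long_table()].
#' @param alpha significance level.
#' @return list: `p`, `F`, `means` (named per group), `direction` (string),
#'   `significant`.
#' @export
compare_groups <- function(table, alpha = 0.05) {
  fit <- rm_anova(table)
  gs <- group_summary(table)
  p <- fit$table$p[fit$table$effect == "group"]
  means <- setNames(gs$mean, gs$group)
  ord <- order(means)
  direction <- if (length(means) == 2 && diff(range(means)) > 0)
    paste(names(means)[ord[2]], ">", names(means)[ord[1]]) else "no difference"
  list(p = p, F = fit$table$F[fit$table$effect == "group"], means = means,
       direction = direction, significant = is.finite(p) && p < alpha)
}

#' Fit an exponential learning curve
#'
#' Least-squares fit of `y_k = b + a * exp(-lambda * (k - 1))` by profiling:
#' for each candidate `lambda` on a grid the conditionally linear `(a, b)`
#' are solved in closed form; the best grid cell is then refined by
#' one-dimensional optimization. A flat series returns `lambda = 0`, `a = 0`
#' without failure.
#'
#' @param y per-repetition metric values (>= 4 repetitions).
#' @param repetitions repetition numbers (default `seq_along(y)`).
#' @param lambda_max upper end of the decay-rate grid.
#' @return list `(a, b, lambda, rss, fitted)`.
#' @export
fit_learning_curve <- function(y, repetitions = seq_along(y), lambda_max = 3) {
  y <- as.numeric(y)
  if (length(y) < 4) stop("need >= 4 repetitions to fit a learning curve")
  k <- as.numeric(repetitions) - min(repetitions)
  if (sd(y) == 0)
    return(list(a = 0, b = y[1], lambda = 0, rss = 0, fitted = y))
  solve_ab <- function(lambda) {
    x <- exp(-lambda * k)
    vx <- sum((x - mean(x))^2)
    if (vx < 1e-12) {             # x ~ constant: flat model
      return(list(a = 0, b = mean(y), rss = sum((y - mean(y))^2)))
    }
    a <- sum((x - mean(x)) * (y - mean(y))) / vx
    b <- mean(y) - a * mean(x)
    list(a = a, b = b, rss = sum((y - b - a * x)^2))
  }
  grid <- seq(0, lambda_max, length.out = 61)
  rss <- vapply(grid, function(l) solve_ab(l)$rss, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(l) solve_ab(l)$rss, c(lo, hi), tol = 1e-10)
  cand <- list(opt$minimum, grid[i])
  best <- cand[[which.min(c(opt$objective, rss[i]))]]
  ab <- solve_ab(best)
  if (abs(ab$a) < 1e-12) best <- 0
  list(a = ab$a, b = ab$b, lambda = best, rss = ab$rss,
       fitted = ab$b + ab$a * exp(-best * k))
}

#' Power-analysis specification
#'
#' @param alpha significance level (0 < alpha < 1).
#' @param effect_size_f Cohen's f (>= 0).
#' @param n_total total subjects across groups.
#' @param groups number of groups.
#' @param measurements repeated measurements per subject.
#' @param correlation assumed correlation among repeated measures
#'   (0 <= rho < 1).
#' @param nonsphericity nonsphericity correction epsilon (0 < eps <= 1).
#' @return an object of class `power_spec`.
#' @export
power_spec <- function(alpha = 0.05, effect_size_f = 0.3, n_total = 16,
                       groups = 2, measurements = 20, correlation = 0.5,
                       nonsphericity = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (effect_size_f < 0) stop("effect size f must be >= 0")
  if (correlation < 0 || correlation >= 1) stop("correlation must be in [0,1)")
  if (nonsphericity <= 0 || nonsphericity > 1) stop("nonsphericity in (0,1]")
  structure(list(alpha = alpha, effect_size_f = effect_size_f,
                 n_total = n_total, groups = groups,
                 measurements = measurements, correlation = correlation,
                 nonsphericity = nonsphericity), class = "power_spec")
}

#' Analytic power of the mixed-design repeated-measures ANOVA
#'
#' Noncentral-F power with the conventional noncentrality parameters:
#' `lambda = f^2 N m / (1 + (m-1) rho)` for the between-group effect and
#' `lambda = f^2 N m eps / (1 - rho)` for the within and interaction
#' effects, with the matching (epsilon-corrected) degrees of freedom. At
#' `f = 0` the power equals `alpha` exactly.
#'
#' @param spec a [power_spec()].
#' @param effect `"between"`, `"within"`, or `"interaction"`.
#' @return power in (0, 1).
#' @export
power_rm_anova <- function(spec, effect = c("between", "within", "interaction")) {
  effect <- match.arg(effect)
  f2 <- spec$effect_size_f^2
  N <- spec$n_total; g <- spec$groups; m <- spec$measurements
  rho <- spec$correlation; eps <- spec$nonsphericity
  if (effect == "between") {
    df1 <- g - 1
    df2 <- N - g
    ncp <- f2 * N * m / (1 + (m - 1) * rho)
  } else {
    df1 <- if (effect == "within") (m - 1) * eps else (g - 1) * (m - 1) * eps
    df2 <- (N - g) * (m - 1) * eps
    ncp <- f2 * N * m * eps / (1 - rho)
  }
  crit <- qf(1 - spec$alpha, df1, df2)
  pf(crit, df1, df2, ncp = ncp, lower.tail = FALSE)
}
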