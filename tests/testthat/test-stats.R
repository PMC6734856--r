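toy_table <- function() {
  # 2 subjects x 2 repetitions per group; hand-checked means 4.5 / 2.0
  long_table(data.frame(
    subject = rep(c("b1", "b2", "e1", "e2"), each = 2),
    group = rep(c("beginner", "expert"), each = 4),
    repetition = rep(1:2, 4),
    value = c(3, 5, 4, 6, 1, 2, 2, 3)))
}

test_that("long_table validates balance and group membership", {
  expect_error(long_table(data.frame(subject = "a", group = "g",
                                     repetition = c(1, 1), value = 1:2)),
               "balanced|exactly once")
  df <- toy_table()
  df2 <- df[-1, ]
  expect_error(long_table(df2), "unbalanced|exactly once")
})

test_that("group_summary: constants, the hand-computed toy table, and a streaming recount", {
  const <- long_table(data.frame(subject = rep(c("b1", "b2", "e1", "e2"), each = 2),
                                 group = rep(c("beginner", "expert"), each = 4),
                                 repetition = rep(1:2, 4), value = 2))
  gs <- group_summary(const)
  expect_equal(gs$mean, c(2, 2))
  expect_equal(gs$sd, c(0, 0))

  gs2 <- group_summary(toy_table())
  expect_equal(gs2$mean[gs2$group == "beginner"], 4.5)
  expect_equal(gs2$mean[gs2$group == "expert"], 2.0)

  # independent one-pass accumulation
  tab <- random_long_table(5, 6, effect = 1, seed = 2)
  gs3 <- group_summary(tab)
  for (g in unique(tab$group)) {
    s <- 0; s2 <- 0; n <- 0
    for (i in seq_len(nrow(tab))) {
      if (tab$group[i] == g) { s <- s + tab$value[i]; s2 <- s2 + tab$value[i]^2; n <- n + 1 }
    }
    expect_equal(gs3$mean[gs3$group == g], s / n)
    expect_equal(gs3$sd[gs3$group == g], sqrt((s2 - s^2 / n) / (n - 1)))
  }
})

test_that("rm_anova matches the definitional oracle and aov on the toy table", {
  tab <- toy_table()
  fit <- rm_anova(tab)
  orc <- oracle_rm_anova(tab)
  got <- setNames(fit$table$ss, fit$table$effect)
  expect_equal(unname(got["group"]), orc$ss_group, tolerance = 1e-12)
  expect_equal(unname(got["subjects_within_groups"]), orc$ss_subj, tolerance = 1e-12)
  expect_equal(unname(got["repetition"]), orc$ss_rep, tolerance = 1e-12)
  expect_equal(unname(got["group_by_repetition"]), orc$ss_int, tolerance = 1e-12)
  expect_equal(unname(got["within_error"]), orc$ss_err, tolerance = 1e-12)
  # the printed toy table is exactly additive within subjects, so the
  # within-error SS must be zero (and the within F ratios degenerate)
  expect_equal(unname(got["within_error"]), 0, tolerance = 1e-20)
  # group effect cross-check against stats::aov with an Error stratum
  df <- as.data.frame(tab)
  df$repetition <- factor(df$repetition)
  a <- summary(stats::aov(value ~ group * repetition + Error(subject), data = df))
  between <- a[["Error: subject"]][[1]]
  expect_equal(unname(got["group"]), between["group", "Sum Sq"], tolerance = 1e-10)
  expect_equal(fit$table$F[fit$table$effect == "group"],
               between["group", "F value"], tolerance = 1e-10)
})

test_that("rm_anova F ratios match stats::aov on random tables", {
  for (seed in c(2, 7, 19)) {
    tab <- random_long_table(4, 5, effect = 0.5, seed = seed)
    fit <- rm_anova(tab)
    df <- as.data.frame(tab)
    df$repetition <- factor(df$repetition)
    a <- summary(stats::aov(value ~ group * repetition + Error(subject), data = df))
    between <- a[["Error: subject"]][[1]]
    within <- a[["Error: Within"]][[1]]
    expect_equal(fit$table$F[fit$table$effect == "group"],
                 between["group", "F value"], tolerance = 1e-8)
    expect_equal(fit$table$F[fit$table$effect == "repetition"],
                 within["repetition", "F value"], tolerance = 1e-8)
    expect_equal(fit$table$F[fit$table$effect == "group_by_repetition"],
                 within["group:repetition", "F value"], tolerance = 1e-8)
  }
})

test_that("rm_anova SS/df identities and invariances hold on random tables", {
  for (seed in 1:8) {
    tab <- random_long_table(n_per_group = 3 + seed %% 3, m = 3 + seed %% 4,
                             effect = runif(1), seed = seed)
    fit <- rm_anova(tab)
    ss <- fit$table$ss
    expect_lt(abs(sum(ss) - fit$ss_total), 1e-8 * max(1, fit$ss_total))
    expect_equal(sum(fit$table$df), nrow(tab) - 1)
    orc <- oracle_rm_anova(tab)
    expect_equal(ss, unname(unlist(orc[1:5])), tolerance = 1e-8)
    # invariance: subject relabeling and adding a constant leave F unchanged
    tab2 <- tab
    tab2$value <- tab2$value + 100
    perm <- sample(unique(tab$subject))
    tab2$subject <- perm[match(tab2$subject, unique(tab$subject))]
    fit2 <- rm_anova(long_table(as.data.frame(tab2)))
    expect_equal(fit$table$F, fit2$table$F, tolerance = 1e-8)
  }
})

test_that("interaction SS of an additive table is zero; m=2 reduces to one-way on subject means", {
  tab <- random_long_table(4, 5, seed = 3)
  # make it exactly additive: value = group effect + repetition effect
  tab$value <- ifelse(tab$group == "beginner", 2, 5) + 0.7 * tab$repetition
  fit <- rm_anova(long_table(as.data.frame(tab)))
  expect_lt(fit$table$ss[fit$table$effect == "group_by_repetition"], 1e-20)
  expect_lt(fit$table$ss[fit$table$effect == "within_error"], 1e-20)

  tab2 <- random_long_table(6, 2, effect = 0.8, seed = 9)
  fit2 <- rm_anova(tab2)
  w <- long_to_wide_oracle(tab2)
  one_way <- summary(stats::aov(means ~ group,
                                data = data.frame(means = rowMeans(w$Y),
                                                  group = w$groups)))[[1]]
  expect_equal(fit2$table$F[fit2$table$effect == "group"],
               one_way["group", "F value"], tolerance = 1e-10)
})

test_that("greenhouse-geisser epsilon is sane and m=2 gives epsilon 1", {
  tab <- random_long_table(6, 2, seed = 4)
  expect_equal(rm_anova(tab)$gg_epsilon, 1)
  tab2 <- random_long_table(8, 6, seed = 5)
  fit <- rm_anova(tab2, gg_correction = TRUE)
  expect_gte(fit$gg_epsilon, 1 / 5)
  expect_lte(fit$gg_epsilon, 1)
  # corrected p is the noncentral-free F tail at epsilon-scaled df
  f_rep <- fit$table$F[fit$table$effect == "repetition"]
  expect_equal(fit$p_gg[["repetition"]],
               pf(f_rep, 5 * fit$gg_epsilon, (16 - 2) * 5 * fit$gg_epsilon,
                  lower.tail = FALSE))
})

test_that("compare_groups: null, direction, and permutation calibration", {
  tab <- toy_table()
  cg <- compare_groups(tab)
  expect_identical(cg$direction, "beginner > expert")
  expect_true(cg$means[["beginner"]] > cg$means[["expert"]])
  # identical groups: F = 0, p = 1
  same <- long_table(data.frame(
    subject = rep(c("b1", "b2", "e1", "e2"), each = 2),
    group = rep(c("beginner", "expert"), each = 4),
    repetition = rep(1:2, 4), value = c(1, 2, 3, 4, 1, 2, 3, 4)))
  cg2 <- compare_groups(same)
  expect_equal(cg2$F, 0)
  expect_equal(cg2$p, 1)
  # permutation of group labels on a null table: p approximately uniform
  set.seed(6)
  base <- random_long_table(4, 4, effect = 0, seed = 6)
  w <- long_to_wide_oracle(base)
  ps <- replicate(400, {
    g <- sample(w$groups)
    df <- data.frame(subject = rep(rownames(w$Y), ncol(w$Y)),
                     group = rep(as.character(g), ncol(w$Y)),
                     repetition = rep(seq_len(ncol(w$Y)), each = nrow(w$Y)),
                     value = as.vector(w$Y))
    compare_groups(long_table(df))$p
  })
  expect_gt(mean(ps < 0.2), 0.10)
  expect_lt(mean(ps < 0.2), 0.35)
  expect_gt(min(ps), 0); expect_lte(max(ps), 1)
})

test_that("fit_learning_curve: exact recovery, degenerate flat series", {
  k <- 1:20
  y <- 1 + 4 * exp(-0.3 * (k - 1))
  fit <- fit_learning_curve(y)
  expect_lt(abs(fit$a - 4), 1e-6)
  expect_lt(abs(fit$b - 1), 1e-6)
  expect_lt(abs(fit$lambda - 0.3), 1e-6)
  flat <- fit_learning_curve(rep(3.5, 10))
  expect_identical(flat$lambda, 0)
  expect_identical(flat$a, 0)
  expect_equal(flat$b, 3.5)
  expect_error(fit_learning_curve(1:3), ">= 4")
})

test_that("lambda is recovered from noisy series (simulation recovery)", {
  set.seed(14)
  errs <- replicate(120, {
    y <- 1 + 4 * exp(-0.3 * (0:19)) + rnorm(20, sd = 0.5)
    abs(fit_learning_curve(y)$lambda - 0.3)
  })
  expect_lt(median(errs), 0.1)
})

test_that("power_rm_anova: null equals alpha, monotone, G*Power-style conventions", {
  sp0 <- power_spec(alpha = 0.05, effect_size_f = 0)
  for (eff in c("between", "within", "interaction"))
    expect_equal(power_rm_anova(sp0, eff), 0.05)
  # monotone in N and f
  for (eff in c("between", "within")) {
    pN <- vapply(c(8, 16, 32, 64), function(N)
      power_rm_anova(power_spec(n_total = N, measurements = 5), eff), numeric(1))
    expect_true(all(diff(pN) > 0))
    pf_ <- vapply(c(0.1, 0.25, 0.4, 0.6), function(f)
      power_rm_anova(power_spec(effect_size_f = f, measurements = 5), eff), numeric(1))
    expect_true(all(diff(pf_) > 0))
  }
  expect_error(power_spec(alpha = 1.2), "alpha")
  expect_error(power_spec(correlation = 1), "correlation")
})

test_that("analytic between-group power matches Monte-Carlo simulation", {
  # model of the power convention: compound symmetry, total variance 1,
  # correlation rho, group means +/- f
  sp <- power_spec(alpha = 0.05, effect_size_f = 0.3, n_total = 16, groups = 2,
                   measurements = 5, correlation = 0.5)
  analytic <- power_rm_anova(sp, "between")
  set.seed(77)
  nsim <- 2500
  rej <- 0L
  n <- 8; m <- 5; rho <- 0.5
  for (i in seq_len(nsim)) {
    subj_eff <- rnorm(2 * n, sd = sqrt(rho))
    mu <- rep(c(0.3, -0.3), each = n)
    Y <- matrix(rnorm(2 * n * m, sd = sqrt(1 - rho)), 2 * n, m) + subj_eff + mu
    df <- data.frame(subject = rep(sprintf("s%02d", 1:(2 * n)), m),
                     group = rep(rep(c("beginner", "expert"), each = n), m),
                     repetition = rep(1:m, each = 2 * n),
                     value = as.vector(Y))
    p <- compare_groups(long_table(df))$p
    if (p < 0.05) rej <- rej + 1L
  }
  phat <- rej / nsim
  ci <- 1.96 * sqrt(phat * (1 - phat) / nsim)
  expect_gt(analytic, phat - ci)
  expect_lt(analytic, phat + ci)
})

test_that("end-to-end: cohort statistics detect the group and beginner learning effects", {
  cfg <- session_config()
  pr <- default_profiles()
  grp_rej <- 0L; det_beginner <- 0L; det_expert <- 0L
  for (r in 1:12) {
    env <- generate_environment(derive_seed(1000 + r, "env"))
    res <- simulate_cohort(cohort_design(8, 20, "free", 1000 + r),
                           pr$beginner, pr$expert, cfg, env)
    if (compare_groups(long_table(res, "collisions"))$p < 0.05)
      grp_rej <- grp_rej + 1L
    p_rep <- function(g) {
      fit <- rm_anova(long_table(res[res$group == g, ], "collisions"))
      fit$table$p[fit$table$effect == "repetition"]
    }
    pb <- p_rep("beginner"); pe <- p_rep("expert")
    if (is.finite(pb) && pb < 0.05) det_beginner <- det_beginner + 1L
    if (is.finite(pe) && pe < 0.05) det_expert <- det_expert + 1L
  }
  expect_gt(grp_rej, 6)                      # majority of 12 replicates
  expect_gt(det_beginner, det_expert)        # learning shows only in beginners
})
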