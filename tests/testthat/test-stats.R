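test_that("within-subject SEMs remove additive subject offsets", {
  m <- rbind(c(10, 12), c(20, 22))
  cm <- cousineau_morey(m)
  expect_equal(cm$mean, c(15, 17))
  expect_equal(cm$within_subject_sem, c(0, 0))

  expect_error(cousineau_morey(matrix(1:4, ncol = 1)), "conditions")
  expect_error(cousineau_morey(rbind(c(1, NA), c(2, 3))), "complete")
})

test_that("within-subject SEMs match a hand-computed oracle", {
  set.seed(14)
  m <- matrix(rnorm(9, 10, 3), nrow = 3)
  # by-definition computation
  norm <- m
  for (i in 1:3) norm[i, ] <- m[i, ] - mean(m[i, ]) + mean(m)
  expected <- apply(norm, 2, sd) / sqrt(3) * sqrt(3 / 2)
  expect_equal(cousineau_morey(m)$within_subject_sem, expected,
               tolerance = 1e-12)

  # invariant to adding any per-subject constant (exact)
  shifted <- m + c(100, -250, 3)
  expect_equal(cousineau_morey(shifted)$within_subject_sem,
               cousineau_morey(m)$within_subject_sem)
})

test_that("split-plot ANOVA agrees with the brute-force SS oracle", {
  cases <- expand.grid(n_per_group = 2:4, seed = 1:3)
  count <- 0
  for (i in seq_len(nrow(cases))) {
    for (sizes in list(c(2, 3), c(3, 2), c(2, 2))) {
      d <- random_split_plot(cases$n_per_group[i], 2, sizes,
                             seed = 100 * i + sizes[1])
      got <- mixed_rm_anova(d, dv = "value", within = c("w1", "w2"),
                            between = "group")
      want <- oracle_split_plot(d, "value", "subject", c("w1", "w2"), "group")
      expect_equal(attr(want, "ss_accounted"), attr(want, "ss_total"),
                   tolerance = 1e-9)
      for (eff in want$effect) {
        g <- got[got$effect == eff, ]
        w <- want[want$effect == eff, ]
        expect_equal(nrow(g), 1)
        expect_equal(g$df_num, w$df_num)
        expect_equal(g$df_den, w$df_den)
        expect_equal(g$F, w$F, tolerance = 1e-9)
        expect_equal(g$p, w$p, tolerance = 1e-9)
      }
      count <- count + 1
    }
  }
  expect_gte(count, 20)
})

test_that("one-within-factor ANOVA squares the paired t (classical identity)", {
  set.seed(31)
  for (rep_i in 1:5) {
    n <- 6
    x <- rnorm(n); y <- rnorm(n, 0.5)
    d <- data.frame(subject = factor(rep(1:n, 2)),
                    cond = factor(rep(c("a", "b"), each = n)),
                    value = c(x, y))
    a <- mixed_rm_anova(d, dv = "value", within = "cond")
    t_res <- paired_t(x, y)
    expect_equal(a$F[a$effect == "cond"], t_res$t^2, tolerance = 1e-9)
    expect_equal(a$p[a$effect == "cond"], t_res$p, tolerance = 1e-9)
  }
})

test_that("degenerate and invalid designs are handled explicitly", {
  d <- random_split_plot(3, 2, c(2, 3), seed = 5)
  d$value <- 7
  a <- mixed_rm_anova(d, dv = "value", within = c("w1", "w2"), between = "group")
  expect_true(all(a$F == 0))
  expect_true(all(a$p == 1))

  unb <- random_split_plot(3, 2, c(2, 3), seed = 6)[-1, ]
  expect_error(mixed_rm_anova(unb, dv = "value", within = c("w1", "w2"),
                              between = "group"), "balanced")
  miss <- random_split_plot(3, 2, c(2, 3), seed = 7)
  miss$value[4] <- NA
  expect_error(mixed_rm_anova(miss, dv = "value", within = c("w1", "w2"),
                              between = "group"), "missing")
})

test_that("t tests match the closed-form formulas and edge rules", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(0.8, 2.9, 2.6, 4.2, 3.3)
  res <- paired_t(x, y)
  d <- x - y
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$df, 4L)
  expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)

  same <- paired_t(x, x)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  z <- c(1, 2, 3, 4, 5)
  expect_warning(inf <- paired_t(z, z + 1), "zero variance")
  expect_equal(inf$p, 0)

  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 9)
  res2 <- two_sample_t(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  expect_equal(res2$t, (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  expect_equal(res2$df, 6L)
  expect_equal(two_sample_t(a, a)$t, 0)
})

test_that("degrees of freedom reproduce the balanced-design patterns", {
  # 10 + 10 subjects, 2 x 3 within design
  d <- random_split_plot(10, 2, c(2, 3), seed = 8)
  a <- mixed_rm_anova(d, dv = "value", within = c("w1", "w2"), between = "group")
  task_like <- a[a$effect == "w2", ]
  expect_equal(c(task_like$df_num, task_like$df_den), c(2, 36))
  gt <- a[a$effect == "group x w1", ]
  expect_equal(c(gt$df_num, gt$df_den), c(1, 18))
  expect_equal(paired_t(rnorm(20), rnorm(20))$df, 19L)
  expect_equal(two_sample_t(rnorm(10), rnorm(10))$df, 18L)
})

test_that("difference scores equal the Task 4 percent change", {
  rows <- expand.grid(subject = c("S1", "S2"), time = c("pre", "post"),
                      task_level = 2:4)
  rows$pct_change_from_task2 <- ifelse(rows$task_level == 2, 0,
                                       ifelse(rows$task_level == 4, 2.74, 0.11))
  ds <- difference_score(rows)
  expect_equal(nrow(ds), 4)
  expect_true(all(ds$difference_pct == 2.74))

  neg <- rows; neg$pct_change_from_task2[neg$task_level == 4] <- -0.06
  expect_true(all(difference_score(neg)$difference_pct == -0.06))

  expect_error(difference_score(rows[rows$task_level != 4, ]), "Task")
})
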