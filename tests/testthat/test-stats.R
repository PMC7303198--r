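test_that("contrast-score F values match the GLM oracle to 1e-9", {
  cases <- list(list(n = 3, k = 2), list(n = 8, k = 2), list(n = 24, k = 2),
                list(n = 5, k = 3), list(n = 12, k = 4))
  for (cs in cases) {
    factors <- paste0("f", seq_len(cs$k))
    tbl <- random_cell_table(cs$n, factors, seed = cs$n * 10 + cs$k)
    fit <- rm_anova_2k(tbl, "value", "subject", factors)
    oracle <- aov_oracle(tbl, "value", factors)
    for (i in seq_len(nrow(fit$table))) {
      key <- fit$table$effect[i]
      expect_equal(fit$table$statistic[i], oracle[[key]],
                   tolerance = 1e-9,
                   label = paste("F for", key, "n =", cs$n))
      expect_equal(fit$table$df2[i], cs$n - 1L)
    }
  }
})

test_that("main-effect F equals the squared paired t on collapsed means", {
  tbl <- random_cell_table(9, c("f1", "f2"), seed = 42)
  fit <- rm_anova_2k(tbl, "value", "subject", c("f1", "f2"))
  coll <- dplyr::summarise(dplyr::group_by(tbl, subject, f1),
                           value = mean(value), .groups = "drop")
  tt <- stats::t.test(value ~ f1, data = coll, paired = TRUE)
  expect_equal(fit$table$statistic[fit$table$effect == "f1"],
               unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(fit$table$p_value[fit$table$effect == "f1"],
               tt$p.value, tolerance = 1e-9)
})

test_that("results are label-driven, not row-order-driven", {
  tbl <- random_cell_table(6, c("f1", "f2", "f3"), seed = 7)
  fit1 <- rm_anova_2k(tbl, "value", "subject", c("f1", "f2", "f3"))
  withr::with_seed(1, {
    shuf <- tbl[sample.int(nrow(tbl)), ]
  })
  fit2 <- rm_anova_2k(shuf, "value", "subject", c("f1", "f2", "f3"))
  expect_equal(fit1$table, fit2$table, tolerance = 1e-12)
})

test_that("degenerate zero-variance contrasts are flagged, not errors", {
  tbl <- tidyr::expand_grid(subject = 1:6, cond = c("Deviant", "Standard"))
  tbl$value <- ifelse(tbl$cond == "Deviant", -1, 0)    # exact -1 uV shift
  fit <- rm_anova_2k(tbl, "value", "subject", "cond")
  row <- fit$table[fit$table$effect == "cond", ]
  expect_true(row$degenerate)
  expect_equal(row$p_value, 0)
  tbl2 <- tidyr::expand_grid(subject = 1:6, a = c("x", "y"), b = c("u", "v"))
  tbl2$value <- ifelse(tbl2$a == "x", -1, 0)
  fit2 <- rm_anova_2k(tbl2, "value", "subject", c("a", "b"))
  null_row <- fit2$table[fit2$table$effect == "b", ]
  expect_true(null_row$degenerate)
  expect_equal(null_row$statistic, 0)
  expect_equal(null_row$p_value, 1)
})

test_that("incomplete or undersized tables are rejected", {
  tbl <- random_cell_table(4, c("f1", "f2"), seed = 1)
  expect_error(rm_anova_2k(tbl[-1, ], "value", "subject", c("f1", "f2")),
               "missing cell")
  one <- tbl[tbl$subject == 1, ]
  expect_error(rm_anova_2k(one, "value", "subject", c("f1", "f2")),
               "2 subjects")
  tbl3 <- tbl
  tbl3$f1[tbl3$subject == 2 & tbl3$f1 == "a"] <- "c"
  expect_error(rm_anova_2k(tbl3, "value", "subject", c("f1", "f2")),
               "2 levels")
})

test_that("Holm adjustment matches the step-down definition", {
  # hand-applied step-down: (0.01, 0.02, 0.04) -> (0.03, 0.04, 0.04)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  # input order restored
  expect_equal(holm_adjust(c(0.04, 0.01, 0.02)), c(0.04, 0.03, 0.04))
  # family larger than the supplied set
  expect_equal(holm_adjust(c(0.01, 0.02), m = 5), c(0.05, 0.08))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm output is monotone and never below the raw p-values", {
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- stats::runif(7)
      adj <- holm_adjust(p)
      expect_true(all(adj >= p))
      ord <- order(p)
      expect_true(all(diff(adj[ord]) >= -1e-15))
      expect_true(all(adj <= 1))
    }
  })
})

test_that("post-hoc paired t-tests match the textbook formula", {
  tbl <- tidyr::expand_grid(subject = 1:4, phonprob = c("HPP", "LPP"))
  tbl$value <- c(1.2, 0.8, -0.5, -0.1, 2.0, 1.1, 0.3, 0.9)
  out <- posthoc_paired_t(tbl, dv = "value", group = "phonprob")
  d <- tbl$value[tbl$phonprob == "HPP"] - tbl$value[tbl$phonprob == "LPP"]
  t_manual <- mean(d) / (stats::sd(d) / sqrt(4))
  p_manual <- 2 * stats::pt(-abs(t_manual), df = 3)
  expect_equal(out$statistic, t_manual, tolerance = 1e-9)
  expect_equal(out$p_value, p_manual, tolerance = 1e-9)
  expect_equal(out$df, 3)
})

test_that("identical paired vectors give t = 0, p = 1", {
  tbl <- tidyr::expand_grid(subject = 1:5, g = c("x", "y"))
  tbl$value <- rep(rnorm(5), each = 2)
  out <- posthoc_paired_t(tbl, dv = "value", group = "g")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
})

test_that("Bonferroni across ROI strata doubles p-values capped at one", {
  withr::with_seed(9, {
    tbl <- tidyr::expand_grid(subject = 1:6, phonprob = c("HPP", "LPP"),
                              roi = c("FC", "CP"))
    tbl$value <- stats::rnorm(nrow(tbl))
  })
  out <- posthoc_paired_t(tbl, dv = "value", group = "phonprob", by = "roi")
  expect_equal(nrow(out), 2L)
  expect_equal(out$p_adjusted, pmin(1, out$p_value * 2))
})

test_that("type-I error is calibrated at the nominal level", {
  cal <- type1_calibration(
    factors = list(a = c("1", "2"), b = c("1", "2")),
    n_subjects = 12, n_reps = 400, seed = 5)
  expect_equal(nrow(cal), 3L)
  expect_true(all(cal$rate > 0.01 & cal$rate < 0.10))
})

test_that("the hypothesis report supports exactly the simulated effects", {
  withr::with_seed(21, {
    amp_tbl <- tidyr::expand_grid(subject = 1:24,
                                  phonprob = c("HPP", "LPP"),
                                  sylstr = c("SylStr1", "SylStr2"),
                                  cond = c("Standard", "Deviant"),
                                  roi = c("FC", "CP"))
    # a pure condition effect: deviants 2 uV more negative everywhere
    amp_tbl$value <- stats::rnorm(nrow(amp_tbl), sd = 0.5) +
      ifelse(amp_tbl$cond == "Deviant", -2, 0)
    lat_tbl <- tidyr::expand_grid(subject = 1:24,
                                  phonprob = c("HPP", "LPP"),
                                  sylstr = c("SylStr1", "SylStr2"))
    lat_tbl$latency_ms <- stats::rnorm(nrow(lat_tbl), 200, 10)
  })
  amp <- rm_anova_2k(amp_tbl, "value", "subject",
                     c("phonprob", "sylstr", "cond", "roi"))
  lat <- rm_anova_latency(lat_tbl)
  rep <- hypothesis_report(amp, lat, deviant_type = "FD")
  expect_equal(nrow(rep), 5L)
  expect_equal(unique(rep$family_size), 5L)
  h1 <- rep[rep$hypothesis == "H1: MMN elicited", ]
  expect_true(h1$supported)
  expect_equal(h1$direction, "deviant more negative")
  expect_false(any(rep$supported[rep$hypothesis != "H1: MMN elicited"]))
  expect_true(all(rep$p_holm >= rep$p_raw))
})

test_that("a latency shift is reported with its direction", {
  withr::with_seed(22, {
    lat_tbl <- tidyr::expand_grid(subject = 1:24,
                                  phonprob = c("HPP", "LPP"),
                                  sylstr = c("SylStr1", "SylStr2"))
    lat_tbl$latency_ms <- stats::rnorm(nrow(lat_tbl), 200, 8) +
      ifelse(lat_tbl$phonprob == "HPP", -40, 0)
    amp_tbl <- tidyr::expand_grid(subject = 1:24,
                                  phonprob = c("HPP", "LPP"),
                                  sylstr = c("SylStr1", "SylStr2"),
                                  cond = c("Standard", "Deviant"),
                                  roi = c("FC", "CP"))
    amp_tbl$value <- stats::rnorm(nrow(amp_tbl))
  })
  rep <- hypothesis_report(
    rm_anova_2k(amp_tbl, "value", "subject",
                c("phonprob", "sylstr", "cond", "roi")),
    rm_anova_latency(lat_tbl), deviant_type = "FD")
  h2lat <- rep[rep$measure == "latency" & rep$effect == "phonprob", ]
  expect_true(h2lat$supported)
  expect_equal(h2lat$direction, "HPP earlier")
})

test_that("an empty effect list yields an empty report", {
  empty <- structure(list(table = tibble::tibble()), class = "rm_anova")
  rep <- hypothesis_report(empty, empty, deviant_type = "FD")
  expect_equal(nrow(rep), 0L)
})

test_that("tidy and glance methods expose the fitted tables", {
  tbl <- random_cell_table(6, c("f1", "f2"), seed = 2)
  fit <- rm_anova_2k(tbl, "value", "subject", c("f1", "f2"))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 3L)
  expect_equal(glance(fit)$n_subjects, 6L)
})
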