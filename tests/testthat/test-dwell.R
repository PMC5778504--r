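test_that("dwell extraction converts category runs with censoring flags", {
  cmap <- c("closed", "open")
  # C C C O O O C C: one interior open dwell, censored flanks
  d <- extract_dwells(c(1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L), cmap, 0.01)
  expect_equal(nrow(d), 3L)
  expect_equal(d$duration_s, c(0.03, 0.03, 0.02))
  expect_equal(d$left_censored, c(TRUE, FALSE, FALSE))
  expect_equal(d$right_censored, c(FALSE, FALSE, TRUE))

  # constant path: one doubly-censored dwell
  d <- extract_dwells(rep(1L, 50), cmap, 0.01)
  expect_equal(nrow(d), 1L)
  expect_true(d$left_censored && d$right_censored)
  expect_equal(d$duration_s, 0.5)

  # alternation every frame: all single-frame dwells, interior uncensored
  d <- extract_dwells(rep(c(1L, 2L), 10), cmap, 0.01)
  expect_equal(nrow(d), 20L)
  expect_true(all(d$duration_s == 0.01))
  expect_equal(sum(!d$left_censored & !d$right_censored), 18L)

  # totals tile the analysed duration
  set.seed(1)
  z <- sample(1:2, 300, replace = TRUE)
  d <- extract_dwells(z, cmap, 0.01)
  expect_equal(sum(d$duration_s), 3.0)

  expect_equal(nrow(extract_dwells(integer(0), cmap, 0.01)), 0L)
})

test_that("two open substates merge into one category dwell", {
  sc <- dynamic_bubble_scheme()
  ev <- simulate_state_path(sc, 50, seed = 3)
  td <- bubbleFRET:::true_dwells_from_events(ev)
  expect_true(all(td$category %in% c("closed", "open")))
  expect_true(all(diff(match(td$category, c("closed", "open"))) != 0))
})

test_that("shifted-exponential MLE has its closed form and analytic spread", {
  # degenerate data: all dwells equal tau -> tau_hat = tau - t_min
  d <- make_dwells(rep(0.25, 40), t_min = 0.01)
  f <- fit_exponential(d, n_boot = 0)
  expect_equal(f$tau, 0.24)

  # large-sample recovery within 3 analytic standard errors (tau / sqrt(n))
  set.seed(2)
  x <- 0.01 + rexp(1e4, 1 / 0.15)
  f <- fit_exponential(make_dwells(x, t_min = 0.01), n_boot = 0)
  expect_lt(abs(f$tau - 0.15), 3 * 0.15 / sqrt(1e4))

  # truncation correction vanishes as t_min -> 0
  d0 <- make_dwells(x, t_min = 1e-12)
  f0 <- fit_exponential(d0, t_min = 1e-12, n_boot = 0)
  expect_equal(f0$tau, mean(x), tolerance = 1e-9)

  # insufficient data guard
  f <- fit_exponential(make_dwells(rexp(5, 5)), n_boot = 0)
  expect_true(f$insufficient_data)
})

test_that("MLE error stays within 3 analytic SE across a tau / n grid", {
  set.seed(4)
  ok <- 0L; total <- 0L
  for (tau in c(0.05, 0.15, 0.5, 1.0)) {
    for (n in c(100, 1000)) {
      for (r in 1:15) {
        x <- 0.01 + rexp(n, 1 / tau)
        f <- fit_exponential(make_dwells(x, t_min = 0.01), n_boot = 0)
        ok <- ok + (abs(f$tau - tau) <= 3 * tau / sqrt(n))
        total <- total + 1L
      }
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("bootstrap CI covers the truth and censoring handling is stable", {
  # dwells accumulated inside a fixed observation window per molecule; the
  # window-end dwell is right-censored (the mechanism bleaching produces)
  set.seed(5)
  rows <- list()
  for (m in 1:40) {
    t_tot <- 0
    repeat {
      x <- 0.01 + rexp(1, 1 / 0.15)
      if (t_tot + x >= 5) {
        rows[[length(rows) + 1L]] <- data.frame(
          molecule_id = paste0("m", m), category = "closed",
          duration_s = 5 - t_tot, left_censored = FALSE,
          right_censored = TRUE)
        break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = paste0("m", m), category = "closed",
        duration_s = x, left_censored = FALSE, right_censored = FALSE)
      t_tot <- t_tot + x
    }
  }
  d <- do.call(rbind, rows)
  attr(d, "frame_period_s") <- 0.01
  f_ex <- fit_exponential(d, n_boot = 400, seed = 1)
  expect_true(f_ex$ci[1] <= 0.15 && 0.15 <= f_ex$ci[2])
  f_in <- fit_exponential(d, n_boot = 0, use_censored = TRUE)
  expect_lt(abs(f_in$tau - f_ex$tau), diff(f_ex$ci))
})

test_that("EM recovers a separated bi-exponential dwell mixture", {
  set.seed(6)
  comp <- sample(c(0.22, 1.0), 5000, replace = TRUE)
  x <- 0.01 + rexp(5000, 1 / comp)
  f <- fit_biexponential(make_dwells(x, t_min = 0.01), seed = 1)
  expect_equal(f$tau[1], 0.22, tolerance = 0.10)
  expect_equal(f$tau[2], 1.00, tolerance = 0.10)
  expect_equal(f$weights[1], 0.5, tolerance = 0.06)

  # coincident components collapse to the fallback flag
  x1 <- 0.01 + rexp(2000, 1 / 0.3)
  f1 <- fit_biexponential(make_dwells(x1, t_min = 0.01), seed = 2)
  expect_true(f1$collapsed || f1$tau[2] / f1$tau[1] < 3)
})

test_that("BIC chooses parsimony for single-exponential truth", {
  set.seed(7)
  one_hits <- 0L
  for (r in 1:8) {
    x <- 0.01 + rexp(1000, 1 / 0.3)
    cmp <- compare_exp_models(make_dwells(x, t_min = 0.01), seed = r)
    one_hits <- one_hits + (cmp$n_components == 1L)
  }
  expect_gte(one_hits, 7L)

  # well-separated mixture: two components win
  comp <- sample(c(0.22, 1.0), 1000, replace = TRUE)
  x <- 0.01 + rexp(1000, 1 / comp)
  cmp <- compare_exp_models(make_dwells(x, t_min = 0.01), seed = 1)
  expect_equal(cmp$n_components, 2L)

  # tiny samples fall back to one component
  cmp <- compare_exp_models(make_dwells(0.01 + rexp(15, 1 / 0.3)), seed = 1)
  expect_equal(cmp$n_components, 1L)
})

test_that("kinetics report summarizes categories and fold changes", {
  set.seed(8)
  mk_cond <- function(tau_c, tau_o, n = 800) {
    d <- rbind(make_dwells(0.01 + rexp(n, 1 / tau_c), "closed", 0.01,
                           paste0("m", rep(1:20, length.out = n))),
               make_dwells(0.01 + rexp(n, 1 / tau_o), "open", 0.01,
                           paste0("m", rep(1:20, length.out = n))))
    attr(d, "frame_period_s") <- 0.01
    d
  }
  rep_wt <- kinetics_report(mk_cond(0.156, 0.61), "wt", n_boot = 100)
  expect_setequal(rep_wt$category, c("closed", "open"))
  k_open <- rep_wt$rate_per_s[rep_wt$category == "closed"]
  expect_equal(k_open, 1 / 0.156, tolerance = 0.1)

  rep_m <- kinetics_report(mk_cond(0.156 / 3, 0.61 / 3), "x3", n_boot = 100)
  ratio <- rep_m$rate_per_s / rep_wt$rate_per_s
  expect_equal(unname(ratio), c(3, 3), tolerance = 0.25)
})
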