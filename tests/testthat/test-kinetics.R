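test_that("initial rate is the OLS slope over frame mid-times", {
  t0 <- seq(0, 60, 5)
  tc <- make_tc(t0, 0.12 * (t0 + 2.5))  # exact line through mid-times
  # lm warns about an essentially perfect fit on these exact fixtures
  r <- suppressWarnings(initial_rate(tc, "lactate"))
  expect_equal(r[["rate"]], 0.12, tolerance = 1e-10)
  expect_lt(r[["se"]], 1e-10)
  const <- make_tc(t0, rep(0.7, length(t0)))
  expect_equal(suppressWarnings(initial_rate(const, "lactate"))[["rate"]],
               0, tolerance = 1e-10)
  expect_error(initial_rate(tc, "lactate", window = c(0, 5)),
               "at least 2")
  expect_error(initial_rate(tc, "nope"), "no such")
})

test_that("window average matches closed-form oracles", {
  t0 <- seq(0, 60, 5)
  const <- make_tc(t0, rep(0.7, length(t0)))
  a <- window_average(const, "lactate")
  expect_identical(unname(a["mean"]), 0.7)
  expect_equal(unname(a["n_frames"]), 9)  # starts 20..60
  # linear ramp over symmetric frames: mean at the window midpoint
  ramp <- make_tc(t0, 0.3 + 0.01 * t0)
  expect_equal(window_average(ramp, "lactate")[["mean"]],
               0.3 + 0.01 * 40, tolerance = 1e-12)
  # saturating curve with plateau 1.08, rate 0.12: the 20-65 min
  # average is within 5% of the plateau (closed-form integral oracle)
  k <- 0.12 / 1.08
  curve <- function(t) 1.08 * (1 - exp(-k * t))
  sat <- make_tc(t0, curve(t0 + 2.5))
  got <- window_average(sat, "lactate")[["mean"]]
  oracle <- 1.08 * (1 - (exp(-k * 20) - exp(-k * 65)) / (k * 45))
  expect_lt(abs(got - 1.08) / 1.08, 0.05)
  expect_lt(abs(got - oracle) / oracle, 0.01)
  expect_error(window_average(const, "lactate", window = c(90, 95)),
               "empty")
})

test_that("subtype scoring is antisymmetric with an indeterminate band", {
  expect_identical(subtype_score(1, 1)$label, "indeterminate")
  expect_identical(subtype_score(1.4, 0.8)$label, "glycolytic")
  expect_identical(subtype_score(0.8, 1.4)$label, "mitochondrial")
  # swapping lactate and Glx inverts the call
  s <- subtype_score(1.3, 0.7)
  s_sw <- subtype_score(0.7, 1.3)
  expect_true(s$label == "glycolytic" && s_sw$label == "mitochondrial")
  expect_equal(s$score, 1 / s_sw$score, tolerance = 1e-12)
  z <- subtype_score(1, 0)
  expect_identical(z$label, "indeterminate")
  expect_true(is.na(z$score))
})

test_that("percent change reproduces printed reductions and scales", {
  expect_equal(round(percent_change(1.08, 0.56)), 48)
  expect_equal(round(percent_change(1.16, 0.49)), 58)
  expect_equal(percent_change(5, 5), 0)
  expect_identical(format_percent_change(percent_change(1.08, 0.56)),
                   "48%")
  # scale invariance
  set.seed(10)
  for (i in 1:20) {
    k <- runif(1, 0.1, 10); pre <- runif(1, 0.2, 3)
    post <- runif(1, 0, 3)
    expect_equal(percent_change(k * pre, k * post),
                 percent_change(pre, post), tolerance = 1e-12)
  }
  expect_error(percent_change(0, 1), "pre")
})

test_that("group comparison matches a from-scratch sum-of-squares oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(7, 8, 9))
  res <- compare_groups(g)
  # hand ANOVA: SSB = sum n_i (mi - m)^2, SSW = sum (x - mi)^2
  m <- mean(unlist(g))
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - m)^2,
                    numeric(1)))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$f, f_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_false(res$degenerate)
  expect_equal(nrow(res$tukey), 3)
  # two identical groups: F = 0, p = 1
  same <- compare_groups(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$f, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
})

test_that("paired test matches hand computation and flags degeneracy", {
  pre <- c(1.2, 1.0, 1.4, 1.1)
  post <- c(0.7, 0.6, 0.9, 0.5)
  res <- paired_test(pre, post)
  d <- pre - post
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  # constant shift: zero within-pair variance
  deg <- paired_test(c(1, 2, 3), c(0.5, 1.5, 2.5))
  expect_true(deg$degenerate)
  expect_identical(deg$t, Inf)
  expect_identical(deg$p, 0)
  ident <- paired_test(c(1, 2), c(1, 2))
  expect_true(ident$degenerate)
  expect_identical(ident$p, 1)
})

test_that("response analysis reports paired pre/post percent changes", {
  set.seed(77)
  pre <- data.frame(lactate = rnorm(6, 1.08, 0.05),
                    glx = rnorm(6, 0.80, 0.05))
  post <- data.frame(lactate = pre$lactate * 0.52,
                     glx = pre$glx + rnorm(6, 0, 0.08))
  res <- response_analysis(pre, post)
  lac <- res[res$metabolite == "lactate", ]
  expect_equal(lac$pct_change, 48, tolerance = 1)
  expect_lt(lac$p, 0.001)
  expect_gt(res[res$metabolite == "glx", ]$p, 0.05)
  expect_equal(lac$n, 6)
})

test_that("kinetics summary assembles rates, averages and the call", {
  truth <- simulate_timecourses(subtype_preset("glycolytic"),
                                seq(0, 65, 5))
  tc <- do.call(rbind, lapply(c("glucose", "glx", "lactate"),
                              function(m) make_tc(truth$time_min,
                                                  truth$conc[[m]], m)))
  attr(tc, "frame_duration_min") <- 5
  class(tc) <- c("dmi_timecourse", "data.frame")
  ks <- kinetics_summary(tc)
  expect_setequal(ks$metabolite, c("glucose", "glx", "lactate"))
  expect_true(all(ks$rate > 0))
  st <- attr(ks, "subtype")
  expect_identical(st$label, "glycolytic")
})
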