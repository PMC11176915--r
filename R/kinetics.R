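#' Initial metabolite production rate
#'
#' Ordinary least-squares slope of concentration versus frame mid-time
#' over the early uptake window (default the first 20 minutes after
#' injection, which includes the 10-minute infusion period). The
#' standard error comes from the regression.
#'
#' @param tc A `dmi_timecourse`.
#' @param metabolite Metabolite name.
#' @param window Length-2 window in minutes from injection; frames
#'   whose mid-times fall in `[window[1], window[2])` are used.
#' @return Named numeric: `rate` (mmol/L/min) and `se`.
#' @export
initial_rate <- function(tc, metabolite, window = c(0, 20)) {
  stopifnot(inherits(tc, "dmi_timecourse"))
  d <- tc[tc$metabolite == metabolite, ]
  if (!nrow(d)) stop("initial_rate: no such metabolite: ", metabolite)
  fd <- attr(tc, "frame_duration_min")
  if (is.null(fd)) fd <- diff(sort(unique(d$time_min)))[1]
  mid <- d$time_min + fd / 2
  keep <- mid >= window[1] & mid < window[2]
  if (sum(keep) < 2)
    stop("initial_rate: need at least 2 frames inside the window")
  f <- stats::lm(mmol_per_l ~ mid, data = data.frame(
    mmol_per_l = d$mmol_per_l[keep], mid = mid[keep]))
  s <- summary(f)$coefficients
  c(rate = unname(s["mid", "Estimate"]),
    se = unname(s["mid", "Std. Error"]))
}

#' Steady-window average concentration
#'
#' Unweighted mean (and SD) of the per-frame concentrations whose
#' frame start times fall in the window — by default 20 to 65 minutes
#' after injection, where the labeled-glucose curve has peaked and
#' lactate/Glx labeling has approached its plateau.
#'
#' @param tc A `dmi_timecourse`.
#' @param metabolite Metabolite name.
#' @param window Length-2 window, min; frames with start time in
#'   `[window[1], window[2])` are averaged.
#' @return Named numeric: `mean` (mmol/L), `sd`, `n_frames`.
#' @export
window_average <- function(tc, metabolite, window = c(20, 65)) {
  stopifnot(inherits(tc, "dmi_timecourse"))
  d <- tc[tc$metabolite == metabolite, ]
  if (!nrow(d)) stop("window_average: no such metabolite: ", metabolite)
  keep <- d$time_min >= window[1] & d$time_min < window[2]
  if (!any(keep)) stop("window_average: empty window")
  v <- d$mmol_per_l[keep]
  c(mean = mean(v), sd = stats::sd(v), n_frames = sum(keep))
}

#' Score a tumor as glycolytic or mitochondrial
#'
#' Operationalizes the subtype contrast — glycolytic tumors label
#' lactate strongly and Glx weakly, mitochondrial tumors the reverse —
#' as the ratio `score = lactate_avg / glx_avg` of steady-window
#' averages. The label is `"glycolytic"` when the score exceeds
#' `threshold * (1 + margin)`, `"mitochondrial"` below
#' `threshold * (1 - margin)`, and `"indeterminate"` between. The
#' interface defaults are the neutral threshold 1 with a 10\% margin;
#' the pipeline's calibrated values (see [classify_subtype()]) are
#' threshold 0.90 — the geometric midpoint of the noiseless scores of
#' the default glycolytic (1.35) and mitochondrial (0.60) presets —
#' with a 2\% margin.
#'
#' @param lactate_avg,glx_avg Steady-window averages, mmol/L (>= 0).
#' @param threshold Decision threshold on the score.
#' @param margin Relative width of the indeterminate band.
#' @return A `dmi_subtype_call`: list with `score`, `label`,
#'   `lactate_avg`, `glx_avg`, `threshold`, `margin`.
#' @export
subtype_score <- function(lactate_avg, glx_avg, threshold = 1.0,
                          margin = 0.1) {
  stopifnot(lactate_avg >= 0, glx_avg >= 0, threshold > 0,
            margin >= 0)
  if (glx_avg == 0) {
    score <- NA_real_
    label <- "indeterminate"
  } else {
    score <- lactate_avg / glx_avg
    label <- if (score > threshold * (1 + margin)) "glycolytic"
    else if (score < threshold * (1 - margin)) "mitochondrial"
    else "indeterminate"
  }
  structure(list(score = score, label = label,
                 lactate_avg = lactate_avg, glx_avg = glx_avg,
                 threshold = threshold, margin = margin),
            class = "dmi_subtype_call")
}

#' @export
print.dmi_subtype_call <- function(x, ...) {
  cat(sprintf("subtype call: %s (lactate/Glx score %.3g; lac %.3g, Glx %.3g mmol/L)\n",
              x$label, x$score, x$lactate_avg, x$glx_avg))
  invisible(x)
}

#' Calibrated subtype classification of a concentration time course
#'
#' Convenience wrapper: computes the lactate and Glx steady-window
#' averages of a time course and applies [subtype_score()] with the
#' package's calibrated threshold/margin.
#'
#' @param tc A `dmi_timecourse`.
#' @param window Averaging window, min.
#' @param threshold,margin Calibrated decision constants.
#' @return A `dmi_subtype_call`.
#' @export
classify_subtype <- function(tc, window = c(20, 65), threshold = 0.90,
                             margin = 0.02) {
  lac <- window_average(tc, "lactate", window)[["mean"]]
  glx <- window_average(tc, "glx", window)[["mean"]]
  subtype_score(lac, glx, threshold = threshold, margin = margin)
}

#' Percent change between pre- and post-treatment means
#'
#' `100 * (pre - post) / pre`: positive values are reductions. Full
#' precision is returned; display rounding (nearest integer by
#' default) is left to [format_percent_change()] and the print
#' methods.
#'
#' @param pre,post Concentrations, mmol/L (`pre > 0`).
#' @return Percent change (numeric, full precision).
#' @examples
#' percent_change(1.08, 0.56)  # the 48-percent lactate reduction
#' @export
percent_change <- function(pre, post) {
  if (any(pre <= 0)) stop("percent_change: pre must be > 0")
  100 * (pre - post) / pre
}

#' @rdname percent_change
#' @param x Percent change value(s).
#' @param digits Rounding digits for display.
#' @export
format_percent_change <- function(x, digits = 0) {
  paste0(round(x, digits), "%")
}

#' One-way ANOVA across groups with Tukey post-hoc tests
#'
#' Standard one-way fixed-effects ANOVA (via [stats::aov()]) over a
#' named list of per-group samples, followed by Tukey HSD all-pairs
#' comparisons (configurable to none). Zero residual variance is
#' flagged as degenerate.
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param posthoc `"tukey"` or `"none"`.
#' @return List with `f`, `p`, `df`, `anova` (the aov fit), `tukey`
#'   (pairwise table or `NULL`), `degenerate`.
#' @export
compare_groups <- function(groups, posthoc = c("tukey", "none")) {
  posthoc <- match.arg(posthoc)
  stopifnot(is.list(groups), length(groups) >= 2,
            !is.null(names(groups)))
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  degenerate <- tab["Residuals", "Mean Sq"] <= 0 ||
    !is.finite(tab["group", "F value"])
  tk <- if (posthoc == "tukey" && !degenerate)
    stats::TukeyHSD(fit)$group else NULL
  list(f = unname(tab["group", "F value"]),
       p = unname(tab["group", "Pr(>F)"]),
       df = unname(tab[, "Df"]), anova = fit, tukey = tk,
       degenerate = degenerate)
}

#' Paired Student t test with a degenerate-difference guard
#'
#' Wraps [stats::t.test()] (paired). When the within-pair differences
#' have zero variance the t statistic is unbounded: the result is
#' returned with `t = +/-Inf`, `p = 0` (or `t = 0`, `p = 1` for
#' identical vectors) and flagged `degenerate`.
#'
#' @param pre,post Equal-length numeric vectors (n >= 2).
#' @return List with `t`, `p`, `df`, `mean_difference`, `n`,
#'   `degenerate`.
#' @export
paired_test <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- pre - post
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0,
                df = length(d) - 1, mean_difference = md,
                n = length(d), degenerate = TRUE))
  }
  ht <- stats::t.test(pre, post, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = mean(d),
       n = length(d), degenerate = FALSE)
}

#' Treatment-response analysis of paired pre/post measurements
#'
#' For each metabolite: pre and post means, the percent change of the
#' means, and a paired t test across animals.
#'
#' @param pre,post Data frames with one row per animal and one column
#'   per metabolite (matched rows = same animal), or named numeric
#'   vectors of group means (then no test is possible and only percent
#'   changes are reported).
#' @return A `dmi_response`: one row per metabolite with `pre_mean`,
#'   `post_mean`, `pct_change`, `t`, `p`, `n`.
#' @export
response_analysis <- function(pre, post) {
  if (is.numeric(pre) && !is.null(names(pre))) {
    pre <- as.data.frame(as.list(pre))
    post <- as.data.frame(as.list(post))
  }
  pre <- as.data.frame(pre); post <- as.data.frame(post)
  mets <- intersect(names(pre), names(post))
  if (!length(mets)) stop("response_analysis: no shared metabolites")
  rows <- lapply(mets, function(m) {
    pm <- mean(pre[[m]]); qm <- mean(post[[m]])
    if (nrow(pre) >= 2 && nrow(pre) == nrow(post)) {
      ht <- paired_test(pre[[m]], post[[m]])
      tv <- ht$t; pv <- ht$p
    } else {
      tv <- NA_real_; pv <- NA_real_
    }
    data.frame(metabolite = m, pre_mean = pm, post_mean = qm,
               pct_change = percent_change(pm, qm), t = tv, p = pv,
               n = nrow(pre), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dmi_response", "data.frame")
  out
}

#' @export
print.dmi_response <- function(x, ...) {
  cat("treatment response (paired pre/post):\n")
  y <- as.data.frame(x)
  y$pct_change <- format_percent_change(y$pct_change)
  print(y, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Summarize a concentration time course into kinetic statistics
#'
#' Initial rates (first 20 min) and steady-window averages (20-65 min)
#' for every metabolite, plus the subtype call.
#'
#' @param tc A `dmi_timecourse`.
#' @param rate_window,avg_window Windows in minutes.
#' @param metabolites Metabolites to summarize (default: all but
#'   water).
#' @return A `dmi_kinetics`: data frame with one row per metabolite
#'   (`rate`, `rate_se`, `window_avg`, `window_sd`) and the subtype
#'   call in attribute `"subtype"`.
#' @export
kinetics_summary <- function(tc, rate_window = c(0, 20),
                             avg_window = c(20, 65),
                             metabolites = NULL) {
  stopifnot(inherits(tc, "dmi_timecourse"))
  if (is.null(metabolites))
    metabolites <- setdiff(unique(tc$metabolite), "water")
  rows <- lapply(metabolites, function(m) {
    r <- initial_rate(tc, m, rate_window)
    a <- window_average(tc, m, avg_window)
    data.frame(metabolite = m, rate = r[["rate"]],
               rate_se = r[["se"]], window_avg = a[["mean"]],
               window_sd = a[["sd"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(c("lactate", "glx") %in% metabolites))
    attr(out, "subtype") <- classify_subtype(tc, avg_window)
  class(out) <- c("dmi_kinetics", "data.frame")
  out
}

#' @export
print.dmi_kinetics <- function(x, ...) {
  cat("kinetic summary (rates mmol/L/min, averages mmol/L):\n")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  st <- attr(x, "subtype")
  if (!is.null(st)) print(st)
  invisible(x)
}
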