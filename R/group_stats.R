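#' Normality-gated choice of statistical test
#'
#' Shapiro-Wilk normality (gate alpha 0.05) decides between parametric and
#' rank tests: paired data use a paired Student's t test when normal and
#' the Wilcoxon signed-rank test otherwise; independent groups use an
#' unpaired (pooled-variance) Student's t test when both groups are normal
#' and the Mann-Whitney test otherwise.  For paired data the gate is
#' applied to the paired differences by default (`gate_on =
#' "differences"`); distribution comparisons use the Kolmogorov-Smirnov
#' test regardless of normality.
#'
#' @param x,y Numeric samples (n >= 3 each; equal length when paired).
#' @param paired Logical.
#' @param gate_on For paired data, `"differences"` (default) or
#'   `"groups"`.
#' @param alpha Gate significance level.
#' @param distribution If `TRUE`, return `"ks"` (distribution comparison).
#' @return One of `"paired_t"`, `"wilcoxon_signed_rank"`, `"unpaired_t"`,
#'   `"mann_whitney"`, `"ks"`, with attribute `normal`.
#' @examples
#' set.seed(1)
#' choose_test(rnorm(10), rnorm(10), paired = FALSE)
#' @export
choose_test <- function(x, y, paired, gate_on = c("differences", "groups"),
                        alpha = 0.05, distribution = FALSE) {
  gate_on <- match.arg(gate_on)
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 observations per group")
  if (distribution) return(structure("ks", normal = NA))
  normal <- if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    if (gate_on == "differences") shapiro_ok(x - y, alpha)
    else shapiro_ok(x, alpha) && shapiro_ok(y, alpha)
  } else {
    shapiro_ok(x, alpha) && shapiro_ok(y, alpha)
  }
  test <- if (paired) {
    if (normal) "paired_t" else "wilcoxon_signed_rank"
  } else {
    if (normal) "unpaired_t" else "mann_whitney"
  }
  structure(test, normal = normal)
}

shapiro_ok <- function(x, alpha = 0.05) {
  if (stats::sd(x) == 0) return(FALSE)  # degenerate: treat as non-normal
  stats::shapiro.test(x)$p.value >= alpha
}

#' Run one test of the statistical battery
#'
#' Two-tailed p-values.  Rank tests are exact for n <= 12 (no ties) and
#' use the normal approximation with continuity correction otherwise; the
#' unpaired t test uses the pooled-variance (Student's) form.  Welch's
#' unpaired t is available as `"welch_t"`.
#'
#' @param test Test name as returned by [choose_test()].
#' @param x,y Numeric samples.
#' @return List with `p`, `statistic`, `test`.
#' @examples
#' run_test("mann_whitney", c(1, 2), c(3, 4))$p  # exact 1/3
#' @export
run_test <- function(test, x, y) {
  exact_limit <- 12
  res <- switch(
    test,
    paired_t = {
      if (stats::sd(x - y) == 0) stop("zero variance of differences")
      stats::t.test(x, y, paired = TRUE)
    },
    unpaired_t = {
      if (stats::sd(c(x - mean(x), y - mean(y))) == 0)
        stop("zero within-group variance")
      stats::t.test(x, y, var.equal = TRUE)
    },
    welch_t = stats::t.test(x, y, var.equal = FALSE),
    wilcoxon_signed_rank = {
      n_eff <- sum(x - y != 0)
      suppressWarnings(stats::wilcox.test(
        x, y, paired = TRUE, exact = n_eff <= exact_limit,
        correct = TRUE))
    },
    mann_whitney = {
      suppressWarnings(stats::wilcox.test(
        x, y, exact = max(length(x), length(y)) <= exact_limit,
        correct = TRUE))
    },
    ks = suppressWarnings(stats::ks.test(x, y)),
    stop("unknown test: ", test)
  )
  list(p = unname(res$p.value), statistic = unname(res$statistic),
       test = test)
}

#' Post hoc power from the noncentral t distribution
#'
#' Two-tailed power at significance level `alpha` for the observed effect
#' size: for a two-sample comparison `d = |m1 - m2| / sd_pooled` with
#' noncentrality `d * sqrt(n1 n2 / (n1 + n2))` on `n1 + n2 - 2` df; for a
#' paired comparison `dz = mean(diff) / sd(diff)` with noncentrality
#' `dz * sqrt(n)` on `n - 1` df.  Rows gated to a rank test are given the
#' same noncentral-t power computed from the observed effect size (the
#' usual parametric approximation for post hoc reporting).
#'
#' @param d Effect size (Cohen's d, or dz for paired).
#' @param n1 Sample size (first group, or number of pairs).
#' @param n2 Second group size (two-sample only).
#' @param type `"two.sample"` or `"paired"`.
#' @param alpha Two-tailed significance level.
#' @return Power in \[0, 1\].
#' @examples
#' posthoc_power(1, 8, 8)                  # two-sample d = 1
#' posthoc_power(0, 8, 8)                  # null: equals alpha
#' @export
posthoc_power <- function(d, n1, n2 = NULL,
                          type = c("two.sample", "paired"),
                          alpha = 0.05) {
  type <- match.arg(type)
  if (!is.finite(d)) stop("effect size is undefined")
  d <- abs(d)
  if (type == "two.sample") {
    if (is.null(n2)) n2 <- n1
    df <- n1 + n2 - 2
    ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  } else {
    df <- n1 - 1
    ncp <- d * sqrt(n1)
  }
  if (df < 1) stop("not enough observations for the test")
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
}

#' @rdname posthoc_power
#' @param x,y Samples from which to compute the observed effect size.
#' @param paired Logical.
#' @export
posthoc_power_from_data <- function(x, y, paired, alpha = 0.05) {
  if (paired) {
    dd <- x - y
    s <- stats::sd(dd)
    if (s == 0) stop("zero pooled SD; effect size undefined")
    posthoc_power(mean(dd) / s, length(dd), type = "paired",
                  alpha = alpha)
  } else {
    n1 <- length(x); n2 <- length(y)
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                 (n1 + n2 - 2))
    if (sp == 0) stop("zero pooled SD; effect size undefined")
    posthoc_power((mean(x) - mean(y)) / sp, n1, n2,
                  type = "two.sample", alpha = alpha)
  }
}

#' Build a statistical report from a metric table
#'
#' One row per requested comparison, in the shape of a summary table:
#' groups, n, mean, SD, normality flag, test used, two-tailed p, and post
#' hoc power at alpha = 0.05.  Comparison types: `"paired"`
#' (within-nucleus control vs drug), `"unpaired"` (between-nucleus on a
#' per-neuron metric such as a percent reduction), `"ks"` (distribution
#' comparison).  No multiple-testing correction is applied; each row is
#' tested at face value.
#'
#' @param metrics A [metric_table()].
#' @param plan Data frame with columns `label`, `parameter`, `metric`,
#'   `type` (`"paired"`, `"unpaired"`, `"ks"`), and either `nucleus` plus
#'   `group1`/`group2` condition labels (paired) or `condition` plus
#'   implicit PHN-vs-INC grouping (unpaired/ks).
#' @param alpha Significance level used for gating and power.
#' @return Data frame of class `stats_report`, one row per comparison;
#'   rows with missing cells are flagged `incomplete`.
#' @examples
#' coh <- generate_cohort(4, sim_config(trace_duration = 6),
#'                        drug_effect("NAS", 0.6, 0.4), seed = 1)
#' m <- quantify_cohort(coh, use_truth = TRUE)
#' plan <- data.frame(label = "A", parameter = "Duration (s)",
#'                    metric = "duration_s", type = "paired",
#'                    nucleus = "PHN", group1 = "control", group2 = "NAS")
#' build_report(m, plan)
#' @export
build_report <- function(metrics, plan, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(plan)), function(r) {
    p <- plan[r, ]
    if (p$type == "paired") {
      sub <- metrics[metrics$metric == p$metric &
                       metrics$nucleus == p$nucleus, ]
      g1 <- sub[sub$condition == p$group1, ]
      g2 <- sub[sub$condition == p$group2, ]
      ids <- intersect(g1$neuron_id, g2$neuron_id)
      x <- g1$value[match(ids, g1$neuron_id)]
      y <- g2$value[match(ids, g2$neuron_id)]
      names12 <- c(p$group1, p$group2)
    } else {
      sub <- metrics[metrics$metric == p$metric, ]
      if (!is.null(p$condition) && !is.na(p$condition))
        sub <- sub[sub$condition == p$condition, ]
      x <- sub$value[sub$nucleus == "PHN"]
      y <- sub$value[sub$nucleus == "INC"]
      names12 <- c("PHN", "INC")
    }
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    incomplete <- length(x) < 3 || length(y) < 3
    if (incomplete) {
      return(data.frame(
        label = p$label, parameter = p$parameter, group1 = names12[1],
        group2 = names12[2], n1 = length(x), n2 = length(y),
        mean1 = NA_real_, sd1 = NA_real_, mean2 = NA_real_,
        sd2 = NA_real_, normality = NA_character_,
        test = NA_character_, p_value = NA_real_, power = NA_real_,
        incomplete = TRUE, stringsAsFactors = FALSE))
    }
    paired <- p$type == "paired"
    test <- choose_test(x, y, paired = paired, alpha = alpha,
                        distribution = p$type == "ks")
    res <- tryCatch(run_test(as.character(test), x, y),
                    error = function(e)
                      list(p = NA_real_, statistic = NA_real_,
                           test = as.character(test)))
    pow <- tryCatch(
      posthoc_power_from_data(x, y, paired = paired, alpha = alpha),
      error = function(e) NA_real_)
    data.frame(
      label = p$label, parameter = p$parameter, group1 = names12[1],
      group2 = names12[2], n1 = length(x), n2 = length(y),
      mean1 = mean(x), sd1 = stats::sd(x), mean2 = mean(y),
      sd2 = stats::sd(y),
      normality = if (isTRUE(attr(test, "normal"))) "normal"
                  else if (isFALSE(attr(test, "normal"))) "non-normal"
                  else NA_character_,
      test = res$test, p_value = res$p, power = pow,
      incomplete = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stats_report", "data.frame")
  out
}

#' Default comparison plan for one antagonist experiment
#'
#' Mirrors the standard report layout: paired control-vs-drug comparisons
#' of duration and post-burst frequency within each nucleus, and unpaired
#' PHN-vs-INC comparisons of the per-neuron percent reductions.
#'
#' @param drug Drug condition label.
#' @return Plan data frame for [build_report()].
#' @export
drug_comparison_plan <- function(drug) {
  data.frame(
    label = c("A", "B", "C", "D", "E", "F"),
    parameter = c("Duration of PHN neurons (s)",
                  "Duration of INC neurons (s)",
                  "EPSC rate of PHN neurons (events/s)",
                  "EPSC rate of INC neurons (events/s)",
                  sprintf("Reduction in duration by %s (%%)", drug),
                  sprintf("Reduction in EPSC rate by %s (%%)", drug)),
    metric = c("duration_s", "duration_s", "post_rate_1s", "post_rate_1s",
               "duration_s_reduction_pct", "post_rate_1s_reduction_pct"),
    type = c("paired", "paired", "paired", "paired", "unpaired",
             "unpaired"),
    nucleus = c("PHN", "INC", "PHN", "INC", NA, NA),
    group1 = c("control", "control", "control", "control", NA, NA),
    group2 = c(drug, drug, drug, drug, NA, NA),
    condition = c(NA, NA, NA, NA, drug, drug),
    stringsAsFactors = FALSE
  )
}

#' Simulate and analyze one antagonist experiment end to end
#'
#' Generates paired control/drug cohorts for both nuclei with the default
#' calibrated effect of `drug`, detects EPSCs on every trace, computes the
#' sustained-response metrics and per-neuron reductions, and builds the
#' statistical report.
#'
#' @param drug `"NAS"`, `"APV"` or `"FFA"`.
#' @param config A [sim_config()].
#' @param n_neurons Neurons per nucleus (default 8).
#' @param seed Seed for the whole experiment.
#' @param use_truth Bypass the detector (for speed or calibration checks).
#' @return List with `metrics` (the [metric_table()]) and `report` (the
#'   `stats_report`).
#' @examples
#' \donttest{
#' res <- run_drug_experiment("NAS", sim_config(trace_duration = 8),
#'                            n_neurons = 4, seed = 1, use_truth = TRUE)
#' res$report[, c("parameter", "p_value")]
#' }
#' @export
run_drug_experiment <- function(drug, config = sim_config(),
                                n_neurons = 8, seed = NULL,
                                use_truth = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cohorts <- lapply(c("PHN", "INC"), function(nuc) {
    eff <- default_effect(drug, nuc, config)
    generate_cohort(n_neurons, config, eff, nucleus = nuc)
  })
  metrics <- do.call(rbind, lapply(cohorts, quantify_cohort,
                                   use_truth = use_truth))
  metrics <- metric_table(metrics$neuron_id, metrics$nucleus,
                          metrics$condition, metrics$metric,
                          metrics$value, metrics$units)
  metrics <- add_reduction_metrics(metrics, drug)
  list(metrics = metrics,
       report = build_report(metrics, drug_comparison_plan(drug)))
}
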