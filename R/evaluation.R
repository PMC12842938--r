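# Metrics and reporting: the six standard binary-classification metrics,
# significance comparison across repeated runs, robustness sweeps under
# perturbation specs, computation-path usage, and attention-map export.

#' Compute the six-metric classification report
#'
#' Accuracy, precision, recall and F1 for the positive class (class 1),
#' unweighted accuracy (UA, the mean of per-class recalls) and weighted
#' average F1 (WF1, the support-weighted mean of per-class F1 scores). When
#' no positive predictions exist, precision is reported as 0 and the report
#' carries a warning flag.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return A \code{metrics_report} list: the six metrics, \code{n_samples},
#'   per-class \code{support}, and \code{undefined_precision}.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be non-empty and equal length")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be 0/1")
  tp <- sum(y_true == 1 & y_pred == 1); fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0); tn <- sum(y_true == 0 & y_pred == 0)
  undefined <- (tp + fp) == 0L
  prec1 <- if (undefined) 0 else tp / (tp + fp)
  rec1 <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1_1 <- if (prec1 + rec1 == 0) 0 else 2 * prec1 * rec1 / (prec1 + rec1)
  prec0 <- if (tn + fn == 0L) 0 else tn / (tn + fn)
  rec0 <- if (tn + fp == 0L) 0 else tn / (tn + fp)
  f1_0 <- if (prec0 + rec0 == 0) 0 else 2 * prec0 * rec0 / (prec0 + rec0)
  support <- c(`0` = tn + fp, `1` = tp + fn)
  n <- length(y_true)
  structure(list(accuracy = (tp + tn) / n, precision = prec1, recall = rec1,
                 f1 = f1_1, ua = (rec0 + rec1) / 2,
                 wf1 = (support[["0"]] * f1_0 + support[["1"]] * f1_1) / n,
                 n_samples = n, support = support,
                 undefined_precision = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  ",
                     "ua %.4f  wf1 %.4f  (n = %d)\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$ua, x$wf1,
              x$n_samples))
  invisible(x)
}

#' Significance comparison of two accuracy distributions
#'
#' Two-sided independent-samples t-test with pooled variance, Cohen's d from
#' the pooled standard deviation, and a Bonferroni-adjusted p-value
#' (\code{min(1, p * n_comparisons)}).
#'
#' @param acc_a,acc_b Numeric vectors of per-run scores (length >= 2 each).
#' @param n_comparisons Number of simultaneous comparisons for the
#'   correction.
#' @return A \code{significance_report}: mean_diff, cohens_d, t, df, p_raw,
#'   p_adjusted, n_comparisons.
#' @export
significance_compare <- function(acc_a, acc_b, n_comparisons = 1L) {
  if (length(acc_a) < 2L || length(acc_b) < 2L)
    stop("each group needs at least two runs")
  n1 <- length(acc_a); n2 <- length(acc_b)
  sp2 <- ((n1 - 1) * stats::var(acc_a) + (n2 - 1) * stats::var(acc_b)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled variance is zero; Cohen's d undefined")
  tt <- stats::t.test(acc_a, acc_b, var.equal = TRUE)
  structure(list(mean_diff = mean(acc_a) - mean(acc_b),
                 cohens_d = (mean(acc_a) - mean(acc_b)) / sqrt(sp2),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_adjusted = min(1, tt$p.value * n_comparisons),
                 n_comparisons = n_comparisons),
            class = "significance_report")
}

#' Robustness sweep over perturbation specs
#'
#' Evaluates the model on the unperturbed dataset and on a perturbed copy per
#' spec, reporting the six metrics plus the percentage degradation of
#' accuracy and F1 relative to baseline
#' (100 * (baseline - perturbed) / baseline).
#'
#' @param fit A fitted model ([train_model()] result or model).
#' @param samples Evaluation samples.
#' @param specs List of [perturbation_spec()] (may be empty for a
#'   baseline-only table).
#' @return Data frame: one row per condition (first row \code{baseline}).
#' @export
robustness_sweep <- function(fit, samples, specs = list()) {
  eval_set <- function(ss) {
    pr <- predict_model(fit, ss)
    compute_metrics(pr$label, pr$pred)
  }
  base <- eval_set(samples)
  row <- function(name, m, spec = NULL) {
    data.frame(condition = name,
               kind = spec$kind %||% "none", target = spec$target %||% "none",
               sigma = spec$sigma %||% 0, rate = spec$rate %||% 0,
               accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1, ua = m$ua, wf1 = m$wf1,
               degradation_acc = if (base$accuracy > 0)
                 100 * (base$accuracy - m$accuracy) / base$accuracy else NA_real_,
               degradation_f1 = if (base$f1 > 0)
                 100 * (base$f1 - m$f1) / base$f1 else NA_real_)
  }
  out <- list(row("baseline", base))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    perturbed <- lapply(samples, apply_perturbation, spec = sp)
    out[[length(out) + 1L]] <-
      row(sprintf("%s_%s_%g", sp$kind, sp$target,
                  if (sp$kind == "gaussian_noise") sp$sigma else sp$rate),
          eval_set(perturbed), sp)
  }
  do.call(rbind, out)
}

#' Computation-path usage and cost report
#'
#' Runs the model in hard mode over a dataset and reports the fraction of
#' samples routed to each of the four expert paths (fractions sum to 1), the
#' mean nominal cost per sample, and the mean analytic elementary-op count
#' per sample.
#'
#' @param fit A fitted model or model.
#' @param samples Non-empty list of samples.
#' @return List with \code{fractions} (named length-4), \code{counts},
#'   \code{mean_nominal_cost}, \code{mean_analytic_flops}.
#' @export
path_distribution <- function(fit, samples) {
  if (length(samples) == 0L) stop("empty dataset")
  model <- if (inherits(fit, "dynfuse_fit")) fit$model else fit
  flop_counter_reset()
  pr <- predict_model(model, samples)
  flops <- flop_counter_read() / length(samples)
  counts <- vapply(1:4, function(k) sum(pr$path == k), numeric(1))
  names(counts) <- paste0("path", 1:4)
  list(fractions = counts / length(samples), counts = counts,
       mean_nominal_cost = mean(pr$cost), mean_analytic_flops = flops)
}

#' Export attention maps for one sample
#'
#' Runs a hard-mode forward pass with attention recording and returns every
#' attention weight matrix (one per layer/head actually executed), each
#' row-stochastic: rows sum to 1 over the positions the head was allowed to
#' attend to, and banded maps are exactly zero outside the window.
#'
#' @param fit A fitted model or model.
#' @param sample A [multimodal_sample()].
#' @return Named list of row-stochastic matrices; names identify the module,
#'   layer and head.
#' @export
attention_maps <- function(fit, sample) {
  model <- if (inherits(fit, "dynfuse_fit")) fit$model else fit
  rec <- new.env(parent = emptyenv())
  rec$maps <- list()
  model_forward(model, sample, mode = "hard", record = rec)
  maps <- rec$maps
  names(maps) <- vapply(maps, function(m) attr(m, "label"), character(1))
  lapply(maps, function(m) { attributes(m)$label <- NULL; m })
}
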