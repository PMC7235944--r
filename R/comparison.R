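# Agreement analysis between algorithm variants: per-sample percent
# differences, Bland-Altman limits of agreement and ordinary least squares
# regression, reported per (parameter, variant pair) the way software
# comparison studies tabulate them.

#' Per-sample percent difference between two paired series
#'
#' `100 * (a - b) / denom`, with the denominator per `normalization`:
#' `ref_b` (default, the second series is the reference), `ref_a`, or
#' `pair_mean` (`(a + b) / 2`, antisymmetric under swapping). Samples with a
#' zero denominator are excluded with a warning.
#'
#' @param a,b Equal-length numeric vectors, paired by sample.
#' @param normalization `"ref_b"`, `"ref_a"` or `"pair_mean"`.
#' @return Percent differences; excluded samples are `NA`.
#' @export
percent_difference <- function(a, b, normalization = c("ref_b", "ref_a",
                                                       "pair_mean")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("`a` and `b` must be paired (same length)")
  denom <- switch(normalization, ref_b = b, ref_a = a,
                  pair_mean = (a + b) / 2)
  out <- ifelse(denom != 0, 100 * (a - b) / denom, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " sample(s) excluded: zero denominator")
  out
}

#' Bland-Altman agreement statistics
#'
#' Mean and standard deviation (n-1 denominator) of the per-sample percent
#' differences, with limits of agreement at mean +/- 1.96 SD.
#'
#' @inheritParams percent_difference
#' @return List: `mean_diff_pct`, `sd_diff_pct`, `loa_low`, `loa_high`, `n`,
#'   `normalization`, and the per-sample `diff_pct`.
#' @export
bland_altman <- function(a, b, normalization = c("ref_b", "ref_a",
                                                 "pair_mean")) {
  normalization <- match.arg(normalization)
  d <- percent_difference(a, b, normalization)
  d <- d[!is.na(d)]
  if (length(d) < 3) stop("insufficient data: Bland-Altman needs n >= 3")
  m <- mean(d)
  s <- sd(d)
  list(mean_diff_pct = m, sd_diff_pct = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n = length(d), normalization = normalization, diff_pct = d)
}

#' Ordinary least squares of b on a
#'
#' @param a,b Paired numeric vectors, `n >= 3`; `a` must vary.
#' @return Named numeric: `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation).
#' @export
linear_regression <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired (same length)")
  if (length(a) < 3) stop("insufficient data: regression needs n >= 3")
  if (sd(a) == 0) stop("degenerate regressor: `a` has zero variance")
  fit <- lm(b ~ a)
  c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = cor(a, b)^2)
}

#' Compare algorithm variants across a morphometry results table
#'
#' Takes a long-format results table (columns `sample`, `parameter`,
#' `variant_label`, `value`) and, for each parameter and each requested pair
#' of variant labels, computes the mean percent difference +/- SD,
#' Bland-Altman limits of agreement and the regression of the first label on
#' the second. Samples missing either value are dropped (count reported).
#'
#' @param results Data frame in long format.
#' @param pairs List of length-2 character vectors `c(label_A, label_B)`.
#' @param normalization Passed to [percent_difference()]; default `ref_b`
#'   (the second label is the reference).
#' @param parameters Optional subset of parameters to report.
#' @return A `comparison_report` data frame, one row per (parameter, pair):
#'   `parameter`, `label_a`, `label_b`, `n`, `n_dropped`, `mean_diff_pct`,
#'   `sd_diff_pct`, `loa_low`, `loa_high`, `slope`, `intercept`,
#'   `r_squared`, `normalization`. The regression puts the second
#'   (reference) label on the x-axis, so a variant running 5% high has
#'   slope 1.05.
#' @export
compare_variants <- function(results, pairs,
                             normalization = c("ref_b", "ref_a", "pair_mean"),
                             parameters = NULL) {
  normalization <- match.arg(normalization)
  need <- c("sample", "parameter", "variant_label", "value")
  if (!all(need %in% names(results)))
    stop("`results` must have columns: ", paste(need, collapse = ", "))
  if (!is.list(pairs)) pairs <- list(pairs)
  params <- parameters %||% unique(results$parameter)
  rows <- list()
  for (param in params) {
    sub <- results[results$parameter == param, , drop = FALSE]
    for (pr in pairs) {
      va <- sub[sub$variant_label == pr[1], c("sample", "value")]
      vb <- sub[sub$variant_label == pr[2], c("sample", "value")]
      if (nrow(va) == 0 || nrow(vb) == 0) next
      mg <- merge(va, vb, by = "sample", suffixes = c("_a", "_b"))
      ok <- is.finite(mg$value_a) & is.finite(mg$value_b)
      dropped <- length(unique(c(va$sample, vb$sample))) - sum(ok)
      if (dropped > 0)
        message(sprintf("%s %s:%s -- %d sample(s) dropped (missing values)",
                        param, pr[1], pr[2], dropped))
      if (sum(ok) < 3) next
      a <- mg$value_a[ok]; b <- mg$value_b[ok]
      ba <- bland_altman(a, b, normalization)
      reg <- linear_regression(b, a)   # first label on the reference scale
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, label_a = pr[1], label_b = pr[2], n = ba$n,
        n_dropped = dropped, mean_diff_pct = ba$mean_diff_pct,
        sd_diff_pct = ba$sd_diff_pct, loa_low = ba$loa_low,
        loa_high = ba$loa_high, slope = reg[["slope"]],
        intercept = reg[["intercept"]], r_squared = reg[["r_squared"]],
        normalization = normalization, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(0))
  class(out) <- c("comparison_report", class(out))
  out
}

#' @export
print.comparison_report <- function(x, digits = 2, ...) {
  if (nrow(x) == 0) {
    cat("<comparison_report> empty\n")
    return(invisible(x))
  }
  df <- data.frame(
    parameter = x$parameter,
    pair = paste(x$label_a, "-", x$label_b),
    `diff +/- sd [%]` = sprintf(paste0("%.", digits, "f +/- %.", digits, "f"),
                                x$mean_diff_pct, x$sd_diff_pct),
    R2 = sprintf(paste0("%.", digits, "f"), x$r_squared),
    n = x$n, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Regression and Bland-Altman agreement plot
#'
#' Two base-graphics panels: the regression of `a` on reference `b` with the
#' identity and fitted lines, and the Bland-Altman plot of percent
#' differences against pair means with a solid mean line and dashed
#' mean +/- 1.96 SD limits.
#'
#' @inheritParams percent_difference
#' @param parameter Label used in the axis titles.
#' @return The [bland_altman()] statistics, invisibly.
#' @export
plot_agreement <- function(a, b, parameter = "value",
                           normalization = c("ref_b", "ref_a", "pair_mean")) {
  normalization <- match.arg(normalization)
  ba <- bland_altman(a, b, normalization)
  reg <- linear_regression(b, a)   # a regressed on reference b
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(b, a, xlab = paste(parameter, "(reference)"), ylab = parameter,
       main = sprintf("slope %.3f, R2 = %.3f",
                      reg[["slope"]], reg[["r_squared"]]))
  abline(0, 1, col = "grey60")
  abline(reg[["intercept"]], reg[["slope"]], col = "red3")
  means <- (a + b) / 2
  d <- percent_difference(a, b, normalization)
  plot(means, d, xlab = paste("mean", parameter), ylab = "difference [%]",
       main = sprintf("%.2f +/- %.2f %%", ba$mean_diff_pct, ba$sd_diff_pct))
  abline(h = ba$mean_diff_pct)
  abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}
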