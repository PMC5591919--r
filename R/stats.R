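#' One-way fixed-effects analysis of variance
#'
#' Textbook decomposition `SS_total = SS_between + SS_within` with the F test
#' on `(k - 1, N - k)` degrees of freedom. The experimental unit is whatever
#' one row of `data` represents — in the study pipeline, one syncytium.
#'
#' @param data Data frame with one observation per row.
#' @param value Column holding the metric (tidy-eval).
#' @param group Column holding the group label (tidy-eval).
#' @return An object of class `lsd_anova`: group table, sums of squares,
#'   pooled error variance `ms_within`, `F`, `p`. Use [lsd_pairwise()],
#'   [tidy.lsd_anova()], [glance.lsd_anova()].
#' @export
one_way_anova <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- as.character(g[ok])
  counts <- table(g)
  if (length(counts) < 2) abort("need at least 2 groups")
  if (any(counts < 2)) abort("each group needs at least 2 observations")
  k <- length(counts); N <- length(v)
  grand <- mean(v)
  means <- tapply(v, g, mean)
  ss_between <- sum(counts * (means - grand)^2)
  ss_within <- sum((v - means[g])^2)
  df_b <- k - 1; df_w <- N - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ms_w == 0) {
    warn("zero within-group variance in every group")
    Fstat <- if (ss_between > 0) Inf else 0
    p <- if (ss_between > 0) 0 else 1
  } else {
    Fstat <- ms_b / ms_w
    p <- pf(Fstat, df_b, df_w, lower.tail = FALSE)
  }
  groups <- tibble(group = names(counts), n = as.integer(counts),
                   mean = as.numeric(means))
  structure(list(groups = groups, grand_mean = grand,
                 ss_between = ss_between, ss_within = ss_within,
                 df_between = df_b, df_within = df_w,
                 ms_within = ms_w, F = Fstat, p = p,
                 values = v, labels = g),
            class = "lsd_anova")
}

#' @export
print.lsd_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$groups)
  invisible(x)
}

#' Fisher least-significant-difference pairwise comparisons
#'
#' All `k (k - 1) / 2` unadjusted pairwise comparisons using the pooled
#' within-group variance of the omnibus ANOVA — that is what the LSD test
#' means; no multiplicity adjustment is applied, by design. The confidence
#' half-width for pair `(i, j)` is
#' `t(1 - alpha/2, df_within) * sqrt(ms_within * (1/n_i + 1/n_j))`, and a
#' pair is significant exactly when its interval excludes zero.
#'
#' @param fit An [one_way_anova()] fit.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `group1`, `group2`, `delta` (mean of `group1` minus
#'   mean of `group2`), `ci_low`, `ci_high`, `p` and `significant`.
#' @export
lsd_pairwise <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lsd_anova"))
  if (fit$df_within < 1) abort("LSD comparisons need df_within >= 1")
  g <- fit$groups
  pairs <- utils::combn(seq_len(nrow(g)), 2)
  tcrit <- qt(1 - alpha / 2, fit$df_within)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    delta <- g$mean[i] - g$mean[j]
    se <- sqrt(fit$ms_within * (1 / g$n[i] + 1 / g$n[j]))
    h <- tcrit * se
    tstat <- if (se > 0) delta / se else if (delta == 0) 0 else sign(delta) * Inf
    tibble(group1 = g$group[i], group2 = g$group[j], delta = delta,
           ci_low = delta - h, ci_high = delta + h,
           p = 2 * pt(abs(tstat), fit$df_within, lower.tail = FALSE),
           significant = abs(delta) > h)
  })
  attr(out, "alpha") <- alpha
  out
}

#' Significance pattern of the four arms against control
#'
#' For each non-reference arm, reports the direction of the mean difference
#' and whether the LSD interval excludes zero; additionally reports the
#' ISO vs ISO+EMF contrast, the comparison used to ask whether the field
#' blunts the beta-adrenergic response.
#'
#' @param comparisons Output of [lsd_pairwise()].
#' @param reference Reference arm (default `"CTRL"`).
#' @return Tibble with `contrast`, `delta`, `direction` (`"+"`/`"-"`),
#'   `significant`, `label` (e.g. `"ISO up *"`, `"EMF down ns"`).
#' @export
significance_pattern <- function(comparisons, reference = "CTRL") {
  arms <- unique(c(comparisons$group1, comparisons$group2))
  others <- setdiff(arms, reference)
  want <- purrr::map_dfr(others, function(a) tibble(a = a, b = reference))
  if (all(c("ISO", "ISO+EMF") %in% arms) && reference != "ISO")
    want <- dplyr::bind_rows(want, tibble(a = "ISO+EMF", b = "ISO"))
  purrr::map_dfr(seq_len(nrow(want)), function(i) {
    a <- want$a[i]; b <- want$b[i]
    row <- comparisons[(comparisons$group1 == a & comparisons$group2 == b) |
                         (comparisons$group1 == b & comparisons$group2 == a), ]
    if (nrow(row) == 0) return(tibble())
    delta <- if (row$group1[1] == a) row$delta[1] else -row$delta[1]
    dir <- if (delta >= 0) "+" else "-"
    tibble(
      contrast = paste(a, "vs", b), delta = delta, direction = dir,
      significant = row$significant[1],
      label = paste0(a, if (dir == "+") " up " else " down ",
                     if (row$significant[1]) "*" else "ns")
    )
  })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style tidiers for `lsd_anova` fits
#'
#' `tidy()` returns the pairwise LSD comparisons; `glance()` the one-row
#' omnibus summary.
#'
#' @param x An [one_way_anova()] fit.
#' @param alpha Significance level passed to [lsd_pairwise()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lsd_anova <- function(x, alpha = 0.05, ...) lsd_pairwise(x, alpha)

#' @rdname tidy.lsd_anova
#' @export
glance.lsd_anova <- function(x, ...) {
  tibble(statistic = x$F, p.value = x$p, df = x$df_between,
         df.residual = x$df_within, ms.within = x$ms_within,
         ss.between = x$ss_between, ss.within = x$ss_within)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Bar plot of group means with LSD confidence half-widths
#'
#' Bars show group means; error bars show plus/minus half the LSD 95%
#' confidence interval for a difference against that group (so two groups
#' with nonoverlapping bars differ significantly, as in the figure
#' convention of the modelled study).
#'
#' @param object An [one_way_anova()] fit.
#' @param alpha Significance level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lsd_anova <- function(object, alpha = 0.05, ...) {
  g <- object$groups
  tcrit <- qt(1 - alpha / 2, object$df_within)
  g$half <- tcrit * sqrt(object$ms_within * 2 / g$n) / 2
  g$group <- factor(g$group, levels = intersect(ARM_LEVELS, g$group))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", color = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$half,
                                        ymax = .data$mean + .data$half),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "group mean",
                  caption = "error bars: half LSD 95% CI for a difference between means (unadjusted)") +
    ggplot2::theme_classic()
}
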