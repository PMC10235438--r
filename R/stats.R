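#' Normality-gated choice of statistical family
#'
#' Shapiro-Wilk tests on every group; the comparison family is
#' nonparametric as soon as any group rejects normality at `alpha`
#' (nonparametric summaries are then median and interquartile range).
#' Groups smaller than 3 make the gate indeterminate and the caller must
#' choose explicitly.
#'
#' @param data Data frame with one value column and one grouping column.
#' @param value,group Column names (tidy-eval).
#' @param alpha Rejection level for the normality tests (default 0.05).
#' @return A list with `decision` (`"parametric"`, `"nonparametric"` or
#'   `"indeterminate"`) and `shapiro` (tibble: `group`, `n`, `W`, `p`).
#' @export
normality_gate <- function(data, value, group, alpha = 0.05) {
  vals <- dplyr::pull(data, {{ value }})
  grps <- dplyr::pull(data, {{ group }})
  sp <- purrr::map_dfr(split(vals, grps), function(v) {
    if (length(v) < 3) return(tibble(n = length(v), W = NA_real_, p = NA_real_))
    if (var(v) == 0) {
      # degenerate sample: normality untestable and implausible
      return(tibble(n = length(v), W = NA_real_, p = 0))
    }
    s <- shapiro.test(v)
    tibble(n = length(v), W = unname(s$statistic), p = s$p.value)
  }, .id = "group")
  decision <- if (anyNA(sp$p)) "indeterminate" else
    if (any(sp$p < alpha)) "nonparametric" else "parametric"
  list(decision = decision, shapiro = sp)
}

group_summaries <- function(vals, grps) {
  purrr::map_dfr(split(vals, grps), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(n = length(v), mean = mean(v), sd = sd(v),
      sem = sd(v) / sqrt(length(v)), median = q[2], iqr_lo = q[1],
      iqr_hi = q[3])
  }, .id = "group")
}

#' Two-group comparison with normality-gated test selection
#'
#' Compares two groups with a two-tailed test: Student's two-sample t test
#' for parametric data, the two-sample Kolmogorov-Smirnov test for
#' nonparametric data, or a ratio paired t test (one-sample t on log
#' ratios) for paired positive data. `mode = "auto"` selects t vs KS via
#' [normality_gate()] and sets the summary convention accordingly
#' (mean +/- SEM, or median +/- IQR when normality is rejected).
#'
#' @param data Data frame with a value column, a two-level group column,
#'   and (for the paired mode) a pair-identifier column.
#' @param value,group,pair Column names (tidy-eval); `pair` only for
#'   `mode = "ratio_paired_t"`.
#' @param mode `"auto"`, `"t"`, `"ks"` or `"ratio_paired_t"`.
#' @param alpha Gate level for `mode = "auto"`.
#' @return A `pk_test` object; see [tidy.pk_test()].
#' @export
compare_two <- function(data, value, group, pair = NULL,
                        mode = c("auto", "t", "ks", "ratio_paired_t"),
                        alpha = 0.05) {
  mode <- match.arg(mode)
  vals <- dplyr::pull(data, {{ value }})
  grps <- as.character(dplyr::pull(data, {{ group }}))
  levs <- unique(grps)
  if (length(levs) != 2) stop("`group` must have exactly 2 levels", call. = FALSE)
  v1 <- vals[grps == levs[1]]
  v2 <- vals[grps == levs[2]]
  gate <- NULL
  if (mode == "auto") {
    gate <- normality_gate(data, {{ value }}, {{ group }}, alpha = alpha)
    if (gate$decision == "indeterminate") {
      stop("groups too small for the normality gate; choose `mode` explicitly",
        call. = FALSE)
    }
    mode <- if (gate$decision == "parametric") "t" else "ks"
  }
  if (mode == "t") {
    ht <- t.test(v1, v2, var.equal = TRUE)
    res <- list(method = "two-sample t", statistic = unname(ht$statistic),
      df = unname(ht$parameter), p_value = ht$p.value,
      summary_mode = "mean_sem")
  } else if (mode == "ks") {
    ht <- suppressWarnings(ks.test(v1, v2))
    res <- list(method = "two-sample KS", statistic = unname(ht$statistic),
      df = NA_real_, p_value = ht$p.value, summary_mode = "median_iqr")
  } else {
    pr <- rlang::enquo(pair)
    if (rlang::quo_is_null(pr)) {
      stop("ratio paired t test needs a `pair` column", call. = FALSE)
    }
    pid <- as.character(dplyr::pull(data, !!pr))
    p1 <- pid[grps == levs[1]]; p2 <- pid[grps == levs[2]]
    if (length(v1) != length(v2) || !setequal(p1, p2)) {
      stop("paired mode requires equal n with matching pair ids", call. = FALSE)
    }
    r <- v1[order(p1)] / v2[order(p2)]
    if (any(r <= 0)) stop("ratio paired t test requires positive values",
      call. = FALSE)
    if (sd(log(r)) == 0) {
      # all ratios identical: no evidence either way (t is 0/0 otherwise)
      res <- list(method = "ratio paired t",
        statistic = if (all(r == 1)) 0 else sign(mean(log(r))) * Inf,
        df = length(r) - 1,
        p_value = if (all(r == 1)) 1 else 0, summary_mode = "mean_sem")
    } else {
      ht <- t.test(log(r))
      res <- list(method = "ratio paired t", statistic = unname(ht$statistic),
        df = unname(ht$parameter), p_value = ht$p.value,
        summary_mode = "mean_sem")
    }
  }
  res$groups <- levs
  res$n <- c(length(v1), length(v2))
  res$summaries <- group_summaries(vals, grps)
  res$gate <- gate
  structure(res, class = "pk_test")
}

#' @export
print.pk_test <- function(x, ...) {
  cat(sprintf("<pk_test> %s: statistic = %.4g%s, p = %.4g (two-tailed)\n",
    x$method, x$statistic,
    if (is.finite(x$df)) sprintf(", df = %.4g", x$df) else "", x$p_value))
  cat("  summary convention:",
    if (x$summary_mode == "mean_sem") "mean +/- SEM" else "median +/- IQR", "\n")
  invisible(x)
}

#' Tidy a two-group comparison
#'
#' @param x A `pk_test`.
#' @param ... Unused.
#' @return One-row tibble with method, statistic, df, p value, group sizes
#'   and the summary convention used.
#' @method tidy pk_test
#' @export
tidy.pk_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, df = x$df,
    n1 = x$n[1], n2 = x$n[2], p_value = x$p_value,
    summary_mode = x$summary_mode)
}

#' @method glance pk_test
#' @export
glance.pk_test <- function(x, ...) tidy(x)

#' Multiple-comparison p-value adjustment
#'
#' Implements the Benjamini-Hochberg step-up FDR adjustment, the Holm and
#' Holm-Sidak step-down familywise adjustments, and the Bonferroni
#' correction. Adjusted values are monotonicity-enforced and capped at 1;
#' every method returns values no smaller than the raw p values.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param method `"BH"`, `"holm_sidak"`, `"holm"` or `"bonferroni"`.
#' @return Adjusted p values, same order as the input.
#' @export
adjust_p <- function(p, method = c("BH", "holm_sidak", "holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m <= 1) return(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- switch(method,
    bonferroni = pmin(1, m * ps),
    BH = {
      raw <- ps * m / seq_len(m)
      pmin(1, rev(cummin(rev(raw))))
    },
    holm = pmin(1, cummax(ps * (m - seq_len(m) + 1))),
    holm_sidak = pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

gg_epsilon <- function(wide, groups) {
  # pooled within-group covariance of the subject x within-level matrix
  k <- ncol(wide)
  centered <- wide
  for (g in unique(groups)) {
    idx <- groups == g
    centered[idx, ] <- sweep(wide[idx, , drop = FALSE], 2,
      colMeans(wide[idx, , drop = FALSE]))
  }
  S <- crossprod(as.matrix(centered)) / (nrow(wide) - length(unique(groups)))
  Cmat <- contr.helmert(k)
  Cmat <- qr.Q(qr(Cmat))          # orthonormal within-subject contrasts
  M <- t(Cmat) %*% S %*% Cmat
  sum(diag(M))^2 / ((k - 1) * sum(M^2))
}

#' Two-factor ANOVA with optional repeated measures
#'
#' Between-subjects two-way ANOVA, or a split-plot design with one
#' between-subjects factor and one within-subjects (repeated) factor. For
#' the repeated design the within-subject effects are reported with
#' Greenhouse-Geisser sphericity correction (fractional corrected degrees
#' of freedom), alongside the uncorrected test. Post hoc options: Tukey
#' HSD (between designs) or per-within-level group comparisons with
#' Benjamini-Hochberg adjustment (repeated designs).
#'
#' @param data Data frame in long format.
#' @param value,factor1,factor2 Column names (tidy-eval); `factor1` is the
#'   between-subjects factor, `factor2` the within-subjects factor when
#'   `repeated = TRUE`.
#' @param subject Subject-identifier column; required when
#'   `repeated = TRUE`.
#' @param repeated Logical.
#' @param posthoc `"none"`, `"tukey"` or `"per_level_bh"`.
#' @return A `pk_anova` object with a `table` tibble (term, df, F, p, and
#'   for within effects `df1_gg`, `df2_gg`, `p_gg`, `epsilon`) and an
#'   optional `posthoc` tibble.
#' @export
anova_factorial <- function(data, value, factor1, factor2, subject = NULL,
                            repeated = FALSE,
                            posthoc = c("none", "tukey", "per_level_bh")) {
  posthoc <- match.arg(posthoc)
  df <- tibble(
    value = dplyr::pull(data, {{ value }}),
    A = factor(dplyr::pull(data, {{ factor1 }})),
    B = factor(dplyr::pull(data, {{ factor2 }})))
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  if (!repeated) {
    fit <- aov(value ~ A * B, data = df)
    tab <- summary(fit)[[1]]
    terms <- trimws(rownames(tab))
    out <- tibble(term = terms, df = tab$Df, sumsq = tab$`Sum Sq`,
      F = tab$`F value`, p = tab$`Pr(>F)`)
    ph <- NULL
    if (posthoc == "tukey") {
      tk <- TukeyHSD(fit, "A:B")[[1]]
      ph <- tibble(contrast = rownames(tk), diff = tk[, "diff"],
        p_adj = tk[, "p adj"])
    }
    return(structure(list(table = out, posthoc = ph, repeated = FALSE),
      class = "pk_anova"))
  }
  sq <- rlang::enquo(subject)
  if (rlang::quo_is_null(sq)) {
    stop("repeated design requires a `subject` column", call. = FALSE)
  }
  df$S <- factor(dplyr::pull(data, !!sq))
  counts <- table(df$S, df$B)
  if (any(counts != 1)) {
    stop("repeated design requires exactly one observation per subject and within level",
      call. = FALSE)
  }
  fit <- aov(value ~ A * B + Error(S / B), data = df)
  sm <- summary(fit)
  between <- sm[["Error: S"]][[1]]
  within <- sm[["Error: S:B"]][[1]]
  get_row <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    c(df1 = tab$Df[i], F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  df2_b <- between$Df[match("Residuals", trimws(rownames(between)))]
  df2_w <- within$Df[match("Residuals", trimws(rownames(within)))]
  wide <- tidyr::pivot_wider(df[, c("S", "B", "value")], names_from = "B",
    values_from = "value")
  groups <- df$A[match(wide$S, df$S)]
  eps <- gg_epsilon(as.data.frame(wide[, -1]), groups)
  a <- get_row(between, "A"); b <- get_row(within, "B")
  ab <- get_row(within, "A:B")
  out <- tibble(
    term = c("A", "B", "A:B"),
    df1 = c(a["df1"], b["df1"], ab["df1"]),
    df2 = c(df2_b, df2_w, df2_w),
    F = c(a["F"], b["F"], ab["F"]),
    p = c(a["p"], b["p"], ab["p"]),
    epsilon = c(NA, eps, eps),
    df1_gg = c(NA, b["df1"] * eps, ab["df1"] * eps),
    df2_gg = c(NA, df2_w * eps, df2_w * eps))
  out$p_gg <- ifelse(is.na(out$epsilon), NA,
    pf(out$F, out$df1_gg, out$df2_gg, lower.tail = FALSE))
  ph <- NULL
  if (posthoc == "per_level_bh") {
    ph <- purrr::map_dfr(levels(df$B), function(lev) {
      sub <- df[df$B == lev, ]
      ht <- t.test(value ~ A, data = sub, var.equal = TRUE)
      tibble(level = lev, statistic = unname(ht$statistic), p = ht$p.value)
    })
    ph$p_adj <- adjust_p(ph$p, "BH")
  }
  structure(list(table = out, posthoc = ph, repeated = TRUE),
    class = "pk_anova")
}

#' @export
print.pk_anova <- function(x, ...) {
  cat(sprintf("<pk_anova> %s design\n",
    if (x$repeated) "repeated-measures (split-plot)" else "between-subjects"))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @method tidy pk_anova
#' @export
tidy.pk_anova <- function(x, ...) x$table

#' @method glance pk_anova
#' @export
glance.pk_anova <- function(x, ...) {
  tibble(repeated = x$repeated, n_terms = nrow(x$table),
    min_p = min(x$table$p, na.rm = TRUE))
}
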