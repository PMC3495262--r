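## Group-comparison statistics: two-way ANOVA (with and without repeated
## measures), Bonferroni adjustment, and the star-coding convention.

#' Two-way ANOVA with optional repeated measures
#'
#' Classical two-way factorial ANOVA of `value ~ factor_a * factor_b`.
#' Balanced designs use the standard sequential decomposition (which is
#' unique there); unbalanced designs use type-II sums of squares.  With
#' `repeated = TRUE`, `subject` identifies the blocking unit (e.g. vessel)
#' observed across the levels of `factor_b` (e.g. dose), and the model is
#' fitted with a subject error stratum.
#'
#' @param data data frame.
#' @param value,factor_a,factor_b column names (strings).
#' @param repeated logical; repeated-measures across `factor_b`.
#' @param subject column naming the blocking unit (required when
#'   `repeated = TRUE`).
#' @return object of class `group_comparison`: list with `anova`
#'   (tibble: term, df, sumsq, statistic, p_value, stars), `cell_means`
#'   (tibble with mean, sem, n per factor combination) and `pairwise`
#'   (Bonferroni-adjusted factor_a contrasts within each level of
#'   factor_b).
#' @export
two_way_anova <- function(data, value, factor_a, factor_b,
                          repeated = FALSE, subject = NULL) {
  data <- as.data.frame(data)
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  y <- data[[value]]
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("design error: each factor needs at least two levels")
  df <- data.frame(y = y, A = a, B = b)
  if (repeated) {
    if (is.null(subject))
      stop("repeated-measures ANOVA requires a subject column")
    df$S <- factor(data[[subject]])
    fit <- stats::aov(y ~ A * B + Error(S/B), data = df)
    tabs <- summary(fit)
    rows <- do.call(rbind, lapply(tabs, function(s) {
      d <- as.data.frame(s[[1]])
      d$term <- trimws(rownames(d))
      d
    }))
  } else {
    counts <- table(a, b)
    balanced <- length(unique(as.vector(counts))) == 1L
    if (balanced) {
      fit <- stats::aov(y ~ A * B, data = df)
      rows <- as.data.frame(summary(fit)[[1]])
      rows$term <- trimws(rownames(summary(fit)[[1]]))
    } else {
      fit <- stats::lm(y ~ A * B, data = df)
      tab <- car::Anova(fit, type = 2)
      rows <- as.data.frame(tab)
      names(rows)[names(rows) == "Sum Sq"] <- "Sum Sq"
      rows$term <- rownames(tab)
      rows$Df <- rows$Df
      rows[["F value"]] <- rows[["F value"]]
      rows[["Pr(>F)"]] <- rows[["Pr(>F)"]]
    }
  }
  relabel <- function(term) {
    term <- sub("^A$", factor_a, term)
    term <- sub("^B$", factor_b, term)
    sub("^A:B$", paste(factor_a, factor_b, sep = ":"), term)
  }
  anova_tbl <- tibble::tibble(
    term = relabel(rows$term),
    df = rows$Df,
    sumsq = rows[["Sum Sq"]],
    statistic = rows[["F value"]],
    p_value = rows[["Pr(>F)"]]
  )
  ## a constant response carries no evidence for any effect: define F = 0,
  ## p = 1 rather than propagating the 0/0 (or floating-point fuzz) of an
  ## all-zero decomposition
  if (sum(anova_tbl$sumsq, na.rm = TRUE) < 1e-18 * max(1, sum(y^2))) {
    eff <- anova_tbl$term != "Residuals"
    anova_tbl$statistic[eff] <- 0
    anova_tbl$p_value[eff] <- 1
  }
  anova_tbl$stars <- ifelse(is.na(anova_tbl$p_value), "",
                            star_code(anova_tbl$p_value))
  cell_means <- df |>
    dplyr::group_by(.data$A, .data$B) |>
    dplyr::summarise(mean = mean(.data$y), sem = sem(.data$y),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::rename(!!factor_a := "A", !!factor_b := "B")
  pairwise <- pairwise_bonferroni(df, factor_a, factor_b)
  structure(list(anova = anova_tbl, cell_means = cell_means,
                 pairwise = pairwise,
                 factors = c(factor_a, factor_b), repeated = repeated),
            class = "group_comparison")
}

## factor_a contrasts within each level of factor_b, Bonferroni over the
## whole family of comparisons
pairwise_bonferroni <- function(df, factor_a, factor_b) {
  lev_a <- levels(df$A); lev_b <- levels(df$B)
  combos <- utils::combn(lev_a, 2, simplify = FALSE)
  rows <- list()
  for (bl in lev_b) for (cp in combos) {
    y1 <- df$y[df$A == cp[1] & df$B == bl]
    y2 <- df$y[df$A == cp[2] & df$B == bl]
    if (length(y1) < 2L || length(y2) < 2L) next
    p <- tryCatch(stats::t.test(y1, y2)$p.value, error = function(e) NA_real_)
    rows[[paste(bl, cp[1], cp[2])]] <- tibble::tibble(
      level_b = bl, group1 = cp[1], group2 = cp[2], p_raw = p)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$p_adjusted <- bonferroni_adjust(out$p_raw, nrow(out))
    out$stars <- ifelse(is.na(out$p_adjusted), "",
                        star_code(out$p_adjusted))
    names(out)[names(out) == "level_b"] <- factor_b
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", paste(x$factors, collapse = " x "),
      if (x$repeated) " (repeated measures)", "\n", sep = "")
  print(x$anova)
  invisible(x)
}

#' Bonferroni adjustment
#'
#' adjusted p = min(1, p * k) for a family of k comparisons.
#'
#' @param p_values raw p-values.
#' @param k number of comparisons in the family (>= 1).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, k) {
  stopifnot(k >= 1)
  pmin(1, p_values * k)
}

#' Significance star codes
#'
#' `"***"` for p < 0.001, `"**"` for 0.001 < p < 0.01, `"*"` for
#' 0.01 < p < 0.05, `""` otherwise; a p exactly on a boundary maps to the
#' less significant code (the intervals are open).
#'
#' @param p p-values in \[0, 1\].
#' @return character vector of star codes.
#' @export
star_code <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("contract violation: p must lie in [0, 1]")
  out <- character(length(p))
  out[p < 0.05 & p >= 0.01] <- "*"    # boundary 0.01 -> weaker code "*"
  out[p < 0.01 & p >= 0.001] <- "**"  # boundary 0.001 -> weaker code "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- ""
  out
}
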