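## Duncan's multiple range test (DMRT) with compact letter display.
##
## For a stretch of p adjacent means in the descending order, the critical
## range is R_p = q(1 - alpha_p, p, df_error) * sqrt(MS_error / n_h), where
## alpha_p = 1 - (1 - alpha)^(p - 1) is Duncan's protected level, q is the
## studentized-range quantile, and n_h the harmonic mean group size. Two means
## differ when their gap exceeds R_p for their separation, with the usual
## protection that a range inside a non-significant wider range is not
## declared significant.

duncan_critical_ranges <- function(k, alpha, ms_error, df_error, n_h) {
  p <- 2:k
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  q <- stats::qtukey(1 - alpha_p, nmeans = p, df = df_error)
  c(0, q * sqrt(ms_error / n_h)) # index by span length, R[1] = 0 (single mean)
}

## Insert-and-absorb compact letter display over descending means: each
## starting position extends to the farthest mean whose full span is
## homogeneous; maximal spans get letters.
cld_from_ranges <- function(means_desc, ranges) {
  k <- length(means_desc)
  reach <- integer(k)
  for (i in seq_len(k)) {
    reach[i] <- i
    for (j in seq(k, i)) {
      if (means_desc[i] - means_desc[j] <= ranges[j - i + 1] +
          1e-12 * max(1, abs(means_desc[i]))) {
        reach[i] <- j
        break
      }
    }
  }
  spans <- data.frame(from = seq_len(k), to = reach)
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && spans$from[j] <= spans$from[i] && spans$to[i] <= spans$to[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  spans <- spans[keep, , drop = FALSE]
  spans <- spans[order(spans$from), , drop = FALSE]
  letters_out <- character(k)
  for (s in seq_len(nrow(spans))) {
    idx <- spans$from[s]:spans$to[s]
    letters_out[idx] <- paste0(letters_out[idx], letters[s])
  }
  letters_out
}

#' Duncan's multiple range test with compact letter display
#'
#' Runs a one-way ANOVA and then Duncan's test at protected significance
#' levels, assigning compact-display letters to the group means (sorted
#' descending; groups sharing a letter are not significantly different at
#' `alpha`). Unequal group sizes are handled through the harmonic mean n,
#' standard DMRT practice, and noted in the result.
#'
#' @param values Numeric response vector (omit when `summary` is given).
#' @param groups Group labels.
#' @param alpha Significance level, default 0.05.
#' @param summary Optional summary-only input instead of raw values: a data
#'   frame with columns `group`, `n`, `mean`, `sd`. The residual mean square
#'   is then pooled from the group SDs. Published tables often provide only
#'   these summaries.
#' @return A `mean_comparison` list: `groups` (group, n, mean, sd, letter;
#'   sorted by descending mean), ANOVA `statistic` and `p_value`, `ms_error`,
#'   `df_error`, `alpha`, `critical_ranges`, and `harmonic_n`.
#' @export
duncan_mrt <- function(values = NULL, groups = NULL, alpha = 0.05,
                       summary = NULL) {
  if (is.null(summary)) {
    av <- one_way_anova(values, groups)
    gstats <- av$groups
    ms_error <- av$ms_error
    df_error <- av$df_error
  } else {
    stopifnot(all(c("group", "n", "mean", "sd") %in% names(summary)))
    gstats <- as.data.frame(summary)[c("group", "n", "mean", "sd")]
    if (nrow(gstats) < 2) stop("need at least 2 groups", call. = FALSE)
    if (any(gstats$n < 2)) stop("summary groups need n >= 2", call. = FALSE)
    df_error <- sum(gstats$n - 1)
    ms_error <- sum((gstats$n - 1) * gstats$sd^2) / df_error
    grand <- sum(gstats$n * gstats$mean) / sum(gstats$n)
    ss_b <- sum(gstats$n * (gstats$mean - grand)^2)
    df_b <- nrow(gstats) - 1
    fval <- if (ms_error == 0) {
      if (ss_b == 0) 0 else Inf
    } else (ss_b / df_b) / ms_error
    av <- list(statistic = fval, df = c(df_b, df_error),
               p_value = stats::pf(fval, df_b, df_error, lower.tail = FALSE))
  }
  if (df_error < 1) stop("error degrees of freedom below 1", call. = FALSE)

  k <- nrow(gstats)
  n_h <- k / sum(1 / gstats$n)
  unequal <- length(unique(gstats$n)) > 1
  ord <- order(gstats$mean, decreasing = TRUE)
  gstats <- gstats[ord, , drop = FALSE]
  ranges <- if (ms_error == 0) rep(0, k) else
    duncan_critical_ranges(k, alpha, ms_error, df_error, n_h)
  gstats$letter <- cld_from_ranges(gstats$mean, ranges)
  rownames(gstats) <- NULL

  structure(list(groups = gstats, statistic = av$statistic, df = av$df,
                 p_value = av$p_value, ms_error = ms_error,
                 df_error = df_error, alpha = alpha,
                 critical_ranges = ranges, harmonic_n = n_h,
                 unequal_n = unequal,
                 method = "Duncan's multiple range test"),
            class = "mean_comparison")
}

#' @export
print.mean_comparison <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic) && is.finite(x$statistic)) {
    cat(sprintf("  statistic = %.4g, p = %s\n", x$statistic,
                format_pvalue(x$p_value)))
  }
  print(x$groups, row.names = FALSE)
  invisible(x)
}

# report rendering convention: three decimals, tiny values as "<0.001"
format_pvalue <- function(p) {
  ifelse(p < 0.0005, "<0.001", sprintf("%.3f", p))
}
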