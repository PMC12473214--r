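#' Standardize the six traits to z-scores
#'
#' Centers and scales each trait by the mean and sample SD of a reference
#' population. When `reference` is omitted the table standardizes against
#' itself, so each column of the result has mean 0 and sample SD 1.
#' Standardizing one generation against another (e.g. F2 records against the
#' F1 center/scale) puts both on the scale the selection index was built on.
#'
#' @param table A [trait_table()] (or a data frame of the six trait columns).
#' @param reference Optional [trait_table()] supplying the center and scale.
#' @return An object of class `standardized_matrix`: a list with `z` (an
#'   n x 6 matrix, row names the ids), `center`, `scale` and `ids`.
#' @export
standardize <- function(table, reference = NULL) {
  x <- as.matrix(as.data.frame(table)[trait_names()])
  ref <- if (is.null(reference)) x else
    as.matrix(as.data.frame(reference)[trait_names()])
  if (nrow(ref) < 2) stop("reference needs at least 2 records", call. = FALSE)
  center <- colMeans(ref)
  scale <- apply(ref, 2, stats::sd)
  degenerate <- trait_names()[scale == 0 | !is.finite(scale)]
  if (length(degenerate) > 0) {
    stop("degenerate trait(s) with zero SD: ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  ids <- if ("id" %in% names(table)) as.character(table$id) else
    as.character(seq_len(nrow(x)))
  rownames(z) <- ids
  structure(list(z = z, center = center, scale = scale, ids = ids),
            class = "standardized_matrix")
}

#' Invert a standardization
#'
#' @param zmat A `standardized_matrix`.
#' @return The matrix of original-scale trait values.
#' @export
unstandardize <- function(zmat) {
  sweep(sweep(zmat$z, 2, zmat$scale, "*"), 2, zmat$center, "+")
}

#' Pairwise trait correlations with significance
#'
#' Product-moment (Pearson, default) or rank (Spearman) correlations between
#' the six traits, with two-sided p-values from the t transform
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom. Traits with
#' zero variance get `NA` rows/columns and a warning rather than an error, so
#' a constant trait does not abort a report.
#'
#' @param table A [trait_table()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `correlation_report`: `r` and `p` (6 x 6 matrices)
#'   and `n`.
#' @export
pearson_correlations <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(as.data.frame(table)[trait_names()])
  n <- nrow(x)
  if (n < 3) stop("need at least 3 records for correlation", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning("zero-variance trait(s), correlations undefined: ",
            paste(trait_names()[constant], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(x, method = method))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- ifelse(constant, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- ifelse(constant, NA_real_, 0)
  structure(list(r = r, p = p, n = n, method = method),
            class = "correlation_report")
}

#' Two-sample t-test
#'
#' Student's pooled-variance test is the default (matching SPSS-style
#' reporting); Welch's unequal-variance form is available. Degenerate inputs
#' are handled explicitly: two constant, equal samples give t = 0, p = 1, and
#' a single constant group is pooled against the other group's variance.
#'
#' @param a,b Numeric vectors (each of length at least 2).
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return A list of class `mean_comparison` with `groups` (n, mean, sd per
#'   group), `statistic`, `df`, `p_value`, `method`.
#' @export
two_sample_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  groups <- data.frame(
    group = c("a", "b"), n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b))
  )
  pooled_var <- ((length(a) - 1) * stats::var(a) +
                 (length(b) - 1) * stats::var(b)) / (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    # both samples constant: equal means are indistinguishable, unequal means
    # are separated with certainty under the model
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2,
                p_value = if (equal) 1 else 0)
  } else if (variant == "student") {
    se <- sqrt(pooled_var * (1 / length(a) + 1 / length(b)))
    tt <- (mean(a) - mean(b)) / se
    df <- length(a) + length(b) - 2
    res <- list(statistic = tt, df = df,
                p_value = 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
  } else {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  structure(c(list(groups = groups), res,
              list(method = paste0(variant, " t-test"))),
            class = "mean_comparison")
}

#' One-way analysis of variance
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`; at least two groups,
#'   each with at least two observations.
#' @return A list of class `mean_comparison` with per-group summaries, the F
#'   `statistic`, numerator/denominator `df`, `p_value`, and the residual mean
#'   square `ms_error` with `df_error` (consumed by [duncan_mrt()]).
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("length mismatch", call. = FALSE)
  ns <- table(groups)
  if (length(ns) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(ns)[ns < 2], collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(values ~ factor(groups))
  av <- stats::anova(fit)
  gstats <- data.frame(
    group = names(ns), n = as.integer(ns),
    mean = tapply(values, groups, mean)[names(ns)],
    sd = tapply(values, groups, stats::sd)[names(ns)],
    row.names = NULL
  )
  fval <- av$`F value`[1]
  pval <- av$`Pr(>F)`[1]
  if (av$`Mean Sq`[2] == 0) { # all groups internally constant
    equal <- length(unique(gstats$mean)) == 1
    fval <- if (equal) 0 else Inf
    pval <- if (equal) 1 else 0
  }
  structure(list(groups = gstats, statistic = fval,
                 df = c(av$Df[1], av$Df[2]), p_value = pval,
                 ms_error = av$`Mean Sq`[2], df_error = av$Df[2],
                 method = "one-way ANOVA"),
            class = "mean_comparison")
}

#' Signed percent change
#'
#' `100 * (value - reference) / reference`, the convention behind reported
#' gains such as "+15.56% dry weight".
#'
#' @param value,reference Numeric; `reference` must be nonzero.
#' @return Signed percentage.
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("undefined: reference is 0", call. = FALSE)
  100 * (value - reference) / reference
}
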