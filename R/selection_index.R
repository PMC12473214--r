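#' Build the composite selection index from a PCA
#'
#' Each trait's index weight is the variance-weighted combination of its
#' component coefficients over the retained components, normalized by the
#' total retained variance:
#' w_j = sum_k(c_jk * v_k) / sum_k(v_k), k = 1..K. The composite score of an
#' individual is then Y_i = sum_j w_j * z_ij on standardized traits, which is
#' algebraically identical to combining its component scores with the same
#' variance weights.
#'
#' @param pca A `pca_result`, or a coefficient matrix (traits x components)
#'   when `variance_pct` is supplied directly.
#' @param variance_pct Variance percentages of the retained components (only
#'   when `pca` is a plain coefficient matrix).
#' @param k Override for the number of retained components (defaults to the
#'   PCA's own retention).
#' @param scoring_scale `"standardized"` (z-scores; default) or `"centered"`
#'   (mean-deviations without scaling). The centered mode scores raw trait
#'   deviations, so magnitude is dominated by the widest-ranging trait.
#' @return An object of class `index_model`: named `weights` (one per trait),
#'   the retained `coefficients` and `variance_pct`, `k`, `scoring_scale`.
#' @export
build_index <- function(pca, variance_pct = NULL, k = NULL,
                        scoring_scale = c("standardized", "centered")) {
  scoring_scale <- match.arg(scoring_scale)
  if (inherits(pca, "pca_result")) {
    k <- if (is.null(k)) pca$k_retained else as.integer(k)
    if (k < 1) stop("no components retained; cannot build an index", call. = FALSE)
    coef <- pca$coefficients[, seq_len(k), drop = FALSE]
    v <- pca$variance_pct[seq_len(k)]
  } else {
    coef <- as.matrix(pca)
    v <- variance_pct
    if (is.null(v)) stop("variance_pct required with a plain coefficient matrix",
                         call. = FALSE)
    if (length(v) != ncol(coef)) stop("one variance share per component required",
                                      call. = FALSE)
    k <- ncol(coef)
  }
  if (any(v <= 0)) stop("retained variance shares must be positive", call. = FALSE)
  w <- drop(coef %*% v) / sum(v)
  names(w) <- rownames(coef)
  structure(list(weights = w, coefficients = coef, variance_pct = v,
                 k = k, scoring_scale = scoring_scale),
            class = "index_model")
}

#' Composite index scores
#'
#' @param model An `index_model`.
#' @param z A `standardized_matrix` (for the default standardized scale) whose
#'   trait order matches the model weights. For `scoring_scale = "centered"`
#'   the z-matrix scale is undone, leaving raw mean-deviations.
#' @return Data frame `id`, `score`.
#' @export
composite_scores <- function(model, z) {
  if (ncol(z$z) != length(model$weights)) {
    stop("dimension mismatch between weights and trait columns", call. = FALSE)
  }
  zm <- z$z
  if (identical(model$scoring_scale, "centered")) {
    zm <- sweep(zm, 2, z$scale, "*") # back to raw deviations from the center
  }
  data.frame(id = z$ids, score = drop(zm %*% model$weights),
             stringsAsFactors = FALSE)
}

#' Selection rules
#'
#' `select_threshold(t)` keeps scores strictly greater than `t`;
#' `select_top_fraction(f)` and `select_top_n(n)` keep the best individuals,
#' retaining every individual tied at the boundary (the realized fraction is
#' recorded in the result).
#'
#' @param t Score threshold.
#' @param f Fraction in (0, 1].
#' @param n Positive count.
#' @return A selection-rule object for [rank_and_select()].
#' @export
select_threshold <- function(t) structure(list(type = "threshold", value = t),
                                          class = "selection_rule")

#' @rdname select_threshold
#' @export
select_top_fraction <- function(f) {
  if (f <= 0 || f > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  structure(list(type = "top_fraction", value = f), class = "selection_rule")
}

#' @rdname select_threshold
#' @export
select_top_n <- function(n) {
  if (n < 1) stop("n must be positive", call. = FALSE)
  structure(list(type = "top_n", value = as.integer(n)), class = "selection_rule")
}

#' Rank individuals and select elites
#'
#' Scores are sorted descending (ties broken by id for reproducibility) and
#' given dense ranks (1 = best; equal scores share a rank). The threshold rule
#' selects scores strictly above the threshold; fraction and count rules keep
#' all individuals tied at the boundary score and record the realized
#' fraction.
#'
#' @param scores Data frame `id`, `score` from [composite_scores()].
#' @param rule A selection rule from [select_threshold()],
#'   [select_top_fraction()] or [select_top_n()].
#' @return An object of class `selection_result`: `ranking` (id, score, rank,
#'   selected), `selected_ids`, `rule`, `threshold` (realized boundary),
#'   `fraction` (realized).
#' @export
rank_and_select <- function(scores, rule) {
  if (nrow(scores) == 0) stop("empty scores", call. = FALSE)
  if (!inherits(rule, "selection_rule")) stop("not a selection rule", call. = FALSE)
  ord <- order(-scores$score, scores$id)
  ranking <- scores[ord, , drop = FALSE]
  ranking$rank <- match(ranking$score, unique(ranking$score)) # dense, 1 = best
  n <- nrow(ranking)

  if (rule$type == "threshold") {
    sel <- ranking$score > rule$value
  } else {
    target <- if (rule$type == "top_fraction") ceiling(rule$value * n) else
      min(rule$value, n)
    if (target < 1) stop("selection target below 1 individual", call. = FALSE)
    boundary <- ranking$score[target]
    sel <- ranking$score >= boundary # absorb ties at the boundary
  }
  ranking$selected <- sel
  rownames(ranking) <- NULL
  realized <- mean(sel)
  if (rule$type != "threshold" && sum(sel) != min(n, ceiling(
        if (rule$type == "top_fraction") rule$value * n else rule$value))) {
    message(sprintf("boundary ties kept: realized selection fraction %.3f",
                    realized))
  }
  structure(list(ranking = ranking,
                 selected_ids = ranking$id[sel],
                 rule = rule,
                 threshold = if (rule$type == "threshold") rule$value else
                   if (any(sel)) min(ranking$score[sel]) else NA_real_,
                 fraction = realized),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection: %d of %d individuals (%.1f%%), rule %s\n",
              length(x$selected_ids), nrow(x$ranking), 100 * x$fraction,
              x$rule$type))
  invisible(x)
}
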