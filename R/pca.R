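#' Correlation-matrix principal component analysis
#'
#' Eigendecomposition of the 6 x 6 Pearson correlation matrix of the
#' standardized traits. Loadings are eigenvectors scaled by the square root of
#' their eigenvalue (so squared loadings in a column sum to the eigenvalue);
#' component coefficients are the unit eigenvectors (loadings divided by
#' sqrt(eigenvalue)), the multipliers applied to z-scores when computing
#' component scores. Variance percentages are 100 * eigenvalue / p for p
#' traits. Components are retained by the Kaiser rule (eigenvalue > 1) by
#' default.
#'
#' Eigenvector sign is arbitrary; each component is oriented so that its
#' largest-absolute-loading trait loads positively, a fixed convention that
#' makes results reproducible across platforms.
#'
#' @param z A `standardized_matrix` from [standardize()].
#' @param retention `"kaiser"` (eigenvalue > 1, default), `"fixed_k"` or
#'   `"cumvar"`.
#' @param k Number of components when `retention = "fixed_k"`.
#' @param cum_threshold Retained cumulative variance percentage when
#'   `retention = "cumvar"` (components are added until the threshold is
#'   reached), default 70.
#' @return An object of class `pca_result`: `eigenvalues`, `variance_pct`,
#'   `cumulative_pct`, `loadings`, `coefficients` (traits x components),
#'   `k_retained`, `correlation` (the input correlation matrix) and
#'   `n` (observations used).
#' @export
pca_correlation <- function(z, retention = c("kaiser", "fixed_k", "cumvar"),
                            k = NULL, cum_threshold = 70) {
  retention <- match.arg(retention)
  zm <- z$z
  p <- ncol(zm)
  if (nrow(zm) <= p) {
    stop("need more observations than traits for a stable PCA", call. = FALSE)
  }
  R <- stats::cor(zm)
  if (any(!is.finite(R))) {
    stop("correlation matrix undefined (zero-variance trait upstream)",
         call. = FALSE)
  }
  eig <- eigen(R, symmetric = TRUE)
  lambda <- eig$values
  near_zero <- lambda < 1e-10
  if (any(near_zero & lambda < -1e-8)) {
    warning("negative eigenvalue(s) beyond numerical tolerance clamped to 0")
  }
  lambda[near_zero] <- 0
  vectors <- eig$vectors
  # orientation: dominant trait of each component loads positive
  for (j in seq_len(p)) {
    dom <- which.max(abs(vectors[, j]))
    if (vectors[dom, j] < 0) vectors[, j] <- -vectors[, j]
  }
  loadings <- sweep(vectors, 2, sqrt(lambda), "*")
  dimnames(loadings) <- list(colnames(zm), paste0("PC", seq_len(p)))
  coefficients <- vectors
  dimnames(coefficients) <- dimnames(loadings)

  variance_pct <- 100 * lambda / p
  cumulative_pct <- cumsum(variance_pct)
  k_retained <- switch(retention,
    kaiser = sum(lambda > 1),
    fixed_k = {
      if (is.null(k) || k < 1 || k > p) stop("fixed_k needs k in 1..p", call. = FALSE)
      as.integer(k)
    },
    cumvar = max(1L, which(cumulative_pct >= cum_threshold)[1])
  )
  if (is.na(k_retained)) k_retained <- p

  structure(list(eigenvalues = lambda, variance_pct = variance_pct,
                 cumulative_pct = cumulative_pct, loadings = loadings,
                 coefficients = coefficients, k_retained = k_retained,
                 retention = retention, correlation = R, n = nrow(zm),
                 flagged_zero = which(near_zero)),
            class = "pca_result")
}

#' Component coefficients from loadings and eigenvalues
#'
#' Divides each loading column by the square root of its eigenvalue, turning
#' correlation-scaled loadings back into unit-eigenvector coefficients — the
#' construction used to write component-score formulas from a published
#' loading matrix.
#'
#' @param loadings Traits x components matrix of loadings.
#' @param eigenvalues Vector of eigenvalues, one per column; all must be
#'   positive.
#' @return Matrix of coefficients, same shape as `loadings`.
#' @export
component_coefficients <- function(loadings, eigenvalues) {
  loadings <- as.matrix(loadings)
  if (length(eigenvalues) != ncol(loadings)) {
    stop("one eigenvalue per loading column required", call. = FALSE)
  }
  if (any(eigenvalues <= 0)) {
    stop("eigenvalues must be positive", call. = FALSE)
  }
  sweep(loadings, 2, sqrt(eigenvalues), "/")
}

#' Per-individual principal component scores
#'
#' Scores are the matrix product of the z-score matrix with the coefficient
#' matrix: PC_k(i) = sum_j c_jk * z_ij. On the population that defined the
#' standardization, every score column has mean 0.
#'
#' @param z A `standardized_matrix`.
#' @param coefficients Traits x components coefficient matrix (trait order
#'   must match the z columns).
#' @return n x K matrix of scores, rows named by individual id.
#' @export
component_scores <- function(z, coefficients) {
  coefficients <- as.matrix(coefficients)
  if (ncol(z$z) != nrow(coefficients)) {
    stop("dimension mismatch: ", ncol(z$z), " traits vs ",
         nrow(coefficients), " coefficient rows", call. = FALSE)
  }
  scores <- z$z %*% coefficients
  rownames(scores) <- z$ids
  scores
}

#' Variance-explained (scree) table
#'
#' @param result A `pca_result`.
#' @return Data frame with one row per component: `component`, `eigenvalue`,
#'   `variance_pct`, `cumulative_pct`.
#' @export
scree_table <- function(result) {
  data.frame(component = seq_along(result$eigenvalues),
             eigenvalue = result$eigenvalues,
             variance_pct = result$variance_pct,
             cumulative_pct = result$cumulative_pct)
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA (n = %d): %d of %d components retained (%s)\n",
              x$n, x$k_retained, length(x$eigenvalues), x$retention))
  print(round(scree_table(x), 3), row.names = FALSE)
  invisible(x)
}
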