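# Independent oracles, coded without reusing the implementation's paths.

# two-pass sample SD
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# brute-force one-way ANOVA from sums of squares
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  lev <- unique(groups)
  ss_b <- 0; ss_w <- 0; n <- length(values)
  for (g in lev) {
    x <- values[groups == g]
    ss_b <- ss_b + length(x) * (mean(x) - grand)^2
    ss_w <- ss_w + sum((x - mean(x))^2)
  }
  df_b <- length(lev) - 1; df_w <- n - length(lev)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(f = f, p = pf(f, df_b, df_w, lower.tail = FALSE),
       ms_error = ss_w / df_w, df_error = df_w)
}

# eigenpairs by power iteration with deflation (symmetric PSD input)
oracle_eigen <- function(A, tol = 1e-12, max_iter = 10000) {
  p <- ncol(A)
  values <- numeric(p)
  vectors <- matrix(0, p, p)
  M <- A
  for (k in seq_len(p)) {
    v <- rep(1 / sqrt(p), p) + seq_len(p) * 1e-3 # deterministic start
    v <- v / sqrt(sum(v^2))
    lam <- 0
    for (it in seq_len(max_iter)) {
      w <- M %*% v
      nw <- sqrt(sum(w^2))
      if (nw < tol) { lam <- 0; break }
      v_new <- drop(w / nw)
      lam_new <- drop(t(v_new) %*% M %*% v_new)
      if (max(abs(v_new - v)) < tol || max(abs(v_new + v)) < tol) {
        v <- v_new; lam <- lam_new; break
      }
      v <- v_new; lam <- lam_new
    }
    values[k] <- lam
    vectors[, k] <- v
    M <- M - lam * tcrossprod(v)
  }
  list(values = values, vectors = vectors)
}

# Duncan letters by a direct all-pairs construction: a pair of ordered means
# is non-significant iff some enclosing span is homogeneous; letters are the
# maximal intervals of mutual non-significance.
oracle_duncan_letters <- function(means_desc, ranges) {
  k <- length(means_desc)
  homo <- matrix(FALSE, k, k)
  for (a in seq_len(k)) for (b in a:k) {
    homo[a, b] <- (means_desc[a] - means_desc[b]) <=
      ranges[b - a + 1] + 1e-12 * max(1, abs(means_desc[a]))
  }
  nonsig <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    for (a in seq_len(i)) {
      for (b in j:k) if (homo[a, b]) { nonsig[i, j] <- TRUE; break }
      if (nonsig[i, j]) break
    }
  }
  # maximal intervals [i, j] with all enclosed pairs non-significant
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    intervals[[i]] <- c(i, j)
  }
  ivm <- unique(do.call(rbind, intervals))
  keep <- apply(ivm, 1, function(iv) {
    !any(ivm[, 1] <= iv[1] & ivm[, 2] >= iv[2] &
           (ivm[, 1] != iv[1] | ivm[, 2] != iv[2]))
  })
  ivm <- ivm[keep, , drop = FALSE]
  ivm <- ivm[order(ivm[, 1]), , drop = FALSE]
  lets <- character(k)
  for (s in seq_len(nrow(ivm))) {
    idx <- ivm[s, 1]:ivm[s, 2]
    lets[idx] <- paste0(lets[idx], letters[s])
  }
  lets
}

# letter partition as a canonical set of group-name sets (order-free compare)
letter_partition <- function(groups, lets) {
  all_letters <- unique(unlist(strsplit(lets, "")))
  part <- lapply(all_letters, function(l) sort(groups[grepl(l, lets)]))
  unname(part[order(vapply(part, paste, "", collapse = ","))])
}

# deterministic random trait table (values well inside biological bounds)
random_trait_table <- function(n, seed = 1, generation = "F1", group = "all") {
  set.seed(seed)
  trait_table(data.frame(
    id = sprintf("r%04d", seq_len(n)),
    generation = generation, group = group,
    height_cm = runif(n, 40, 120),
    branches = runif(n, 2, 15),
    fhr = runif(n, 2, 6),
    lsr = runif(n, 0.5, 3),
    mf_pct = runif(n, 5, 95),
    dry_weight_g = runif(n, 50, 250),
    stringsAsFactors = FALSE
  ))
}

ref_coef_matrix <- function() {
  ref <- alfalfa_reference()
  m <- as.matrix(ref$coefficients[, -1])
  rownames(m) <- ref$coefficients$trait
  m
}
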