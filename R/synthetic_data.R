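## Seeded generator of parental, F1 and F2 trait populations: multivariate
## normal draws with target moments and correlations, truncation selection on
## a composite index, and a per-trait breeder's-equation response
## (delta_mu_j = h2_j * S_j) in the F2 lineages.

#' Build a trait correlation matrix from pairwise entries
#'
#' Unspecified pairs default to 0. If the assembled matrix is not positive
#' semidefinite it is repaired by clipping negative eigenvalues at zero and
#' re-normalizing to unit diagonal; the largest absolute entry change is
#' reported in the `repair_delta` attribute.
#'
#' @param pairs Data frame with columns `trait_a`, `trait_b`, `rho`.
#' @return 6 x 6 correlation matrix (traits in canonical order).
#' @export
correlation_from_pairs <- function(pairs) {
  traits <- trait_names()
  R <- diag(length(traits))
  dimnames(R) <- list(traits, traits)
  for (i in seq_len(nrow(pairs))) {
    a <- as.character(pairs$trait_a[i]); b <- as.character(pairs$trait_b[i])
    if (!a %in% traits || !b %in% traits) {
      stop("unknown trait in correlation pair: ", a, " / ", b, call. = FALSE)
    }
    R[a, b] <- R[b, a] <- pairs$rho[i]
  }
  repair_correlation(R)
}

repair_correlation <- function(R) {
  eig <- eigen(R, symmetric = TRUE)
  if (min(eig$values) >= -1e-10) {
    attr(R, "repair_delta") <- 0
    return(R)
  }
  lam <- pmax(eig$values, 0)
  R2 <- eig$vectors %*% diag(lam) %*% t(eig$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  dimnames(R2) <- dimnames(R)
  delta <- max(abs(R2 - R))
  message(sprintf("correlation matrix repaired to PSD (max entry change %.4f)",
                  delta))
  attr(R2, "repair_delta") <- delta
  R2
}

#' Specify a trait population
#'
#' @param mean,sd Named numeric vectors over [trait_names()] (means and SDs on
#'   the raw trait scales). An SD of exactly 0 declares a constant trait (its
#'   correlations must then all be 0).
#' @param R 6 x 6 target correlation matrix (default: independence).
#' @param n Number of individuals.
#' @param generation,group Labels for the generated records.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(mean, sd, R = diag(6), n, generation,
                            group = "none") {
  traits <- trait_names()
  mean <- mean[traits]; sd <- sd[traits]
  if (any(is.na(mean)) || any(is.na(sd))) {
    stop("mean and sd must be named over all six traits", call. = FALSE)
  }
  if (any(sd < 0)) stop("negative SD", call. = FALSE)
  dimnames(R) <- list(traits, traits)
  const <- sd == 0
  if (any(const)) {
    off <- R[const, , drop = FALSE]
    diag_idx <- cbind(seq_len(sum(const)), which(const))
    off[diag_idx] <- 0
    if (any(abs(off) > 1e-12)) {
      stop("infeasible spec: constant trait(s) ",
           paste(traits[const], collapse = ", "),
           " carry nonzero correlations", call. = FALSE)
    }
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  generation <- match.arg(generation, generation_levels())
  group <- match.arg(group, group_levels())
  structure(list(mean = mean, sd = sd, R = repair_correlation(R), n = as.integer(n),
                 generation = generation, group = group),
            class = "population_spec")
}

#' Draw a population from a spec
#'
#' Multivariate normal draws with the spec's correlation structure (imposed
#' through the spectral factorization used by [MASS::mvrnorm()]), scaled by
#' the SDs and shifted by the means, then clamped to the biological bounds
#' (heights/branches/dry weight at 0, FHR at 1, multifoliolate frequency to
#' \[0, 100\]). The realized fraction of clamped values per trait is attached
#' as the `clamp_rate` attribute (and the spec's expected clamp probability as
#' `clamp_prob`); a spec placing more than 5% of its mass beyond the bounds
#' warns, because clamping then biases the realized moments.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; the same seed always reproduces the same table.
#'   `NULL` continues the current RNG stream (used inside scenario
#'   generation).
#' @param id_prefix Prefix for generated ids.
#' @return A [trait_table()] of `spec$n` records.
#' @export
generate_population <- function(spec, seed = NULL, id_prefix = NULL) {
  if (!inherits(spec, "population_spec")) stop("not a population_spec", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  traits <- trait_names()
  live <- spec$sd > 0
  x <- matrix(rep(spec$mean, each = spec$n), nrow = spec$n,
              dimnames = list(NULL, traits))
  if (any(live)) {
    z <- MASS::mvrnorm(spec$n, mu = rep(0, sum(live)),
                       Sigma = spec$R[live, live, drop = FALSE])
    z <- matrix(z, nrow = spec$n)
    x[, live] <- sweep(sweep(z, 2, spec$sd[live], "*"), 2, spec$mean[live], "+")
  }
  bounds <- trait_bounds()
  clamp_rate <- clamp_prob <- numeric(length(traits))
  names(clamp_rate) <- names(clamp_prob) <- traits
  for (tr in traits) {
    b <- bounds[[tr]]
    clamped <- x[, tr] < b[1] | x[, tr] > b[2]
    clamp_rate[tr] <- mean(clamped)
    x[, tr] <- pmin(pmax(x[, tr], b[1]), b[2])
    # tail mass of the spec beyond the bounds: the distortion is a property of
    # the spec, so the warning does not flicker with sampling noise
    if (spec$sd[tr] > 0) {
      clamp_prob[tr] <- stats::pnorm(b[1], spec$mean[tr], spec$sd[tr]) +
        stats::pnorm(b[2], spec$mean[tr], spec$sd[tr], lower.tail = FALSE)
    }
  }
  if (any(clamp_prob > 0.05)) {
    warning("spec places more than 5% of mass beyond the bounds for trait(s): ",
            paste(traits[clamp_prob > 0.05], collapse = ", "),
            " (realized moments are biased by clamping)")
  }
  if (is.null(id_prefix)) {
    id_prefix <- paste0(spec$generation,
                        if (spec$group != "none") paste0("_", spec$group), "_")
  }
  df <- data.frame(id = sprintf("%s%04d", id_prefix, seq_len(spec$n)),
                   generation = spec$generation, group = spec$group,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x))
  out <- trait_table(df)
  attr(out, "clamp_rate") <- clamp_rate
  attr(out, "clamp_prob") <- clamp_prob
  out
}

#' Default realized heritabilities
#'
#' Per-trait realized heritabilities calibrated from the bundled validation
#' summaries as (selected-F2 mean - all-F1 mean) / (selected-F1 mean - all-F1
#' mean), clamped to \[0, 1\]. These are calibration artifacts of the
#' generator, not measured genetic parameters; traits whose observed F2
#' response exceeded the selection differential (multifoliolate frequency in
#' particular) are clamped at 1 and will under-reproduce that response.
#'
#' @return Named numeric vector over [trait_names()].
#' @export
default_h2 <- function() {
  gs <- alfalfa_reference()$group_summaries
  gs <- gs[gs$source == "validation", ]
  h2 <- vapply(trait_names(), function(tr) {
    m <- function(gen, grp) gs$mean[gs$trait == tr & gs$generation == gen &
                                      gs$group == grp]
    s <- m("F1", "selected") - m("F1", "all")
    if (abs(s) < 1e-9) return(0)
    min(max((m("F2", "selected") - m("F1", "all")) / s, 0), 1)
  }, numeric(1))
  h2
}

#' Define a two-generation breeding scenario
#'
#' @param paternal,maternal,f1 [population_spec()]s for the two parents and
#'   the F1 population.
#' @param h2 Named vector of realized heritabilities in \[0, 1\], one per
#'   trait.
#' @param selection_rule How elites are picked from the F1 (default top 31.1%
#'   by composite index score).
#' @param n_f2 F2 individuals per lineage (selected-derived and
#'   non-selected-derived).
#' @param seed Integer seed governing every draw of the scenario.
#' @return An object of class `breeding_scenario`.
#' @export
breeding_scenario <- function(paternal, maternal, f1, h2 = default_h2(),
                              selection_rule = select_top_fraction(28 / 90),
                              n_f2 = 45, seed = 1) {
  h2 <- h2[trait_names()]
  if (any(is.na(h2)) || any(h2 < 0) || any(h2 > 1)) {
    stop("h2 must be named over all traits and lie in [0, 1]", call. = FALSE)
  }
  structure(list(paternal = paternal, maternal = maternal, f1 = f1, h2 = h2,
                 selection_rule = selection_rule, n_f2 = as.integer(n_f2),
                 seed = as.integer(seed)),
            class = "breeding_scenario")
}

#' The default alfalfa breeding scenario
#'
#' Parents and F1 at the bundled trial means and SDs (paternal multifoliolate
#' frequency declared constant at 0), F1 correlation structure from the five
#' bundled pairwise correlations (all other pairs 0), 45 plants per parental
#' line, 90 F1, top 31.1% index selection, 45 F2 per lineage, and the
#' calibrated [default_h2()] response.
#'
#' @param seed Integer seed.
#' @param n_parent,n_f1,n_f2 Population sizes.
#' @return A `breeding_scenario`.
#' @export
default_breeding_scenario <- function(seed = 1, n_parent = 45, n_f1 = 90,
                                      n_f2 = 45) {
  ref <- alfalfa_reference()
  gs <- ref$group_summaries[ref$group_summaries$source == "parent_progeny", ]
  stat <- function(gen, col) {
    sub <- gs[gs$generation == gen, ]
    stats::setNames(sub[[col]], sub$trait)[trait_names()]
  }
  R <- correlation_from_pairs(ref$correlations)
  R_pat <- R
  R_pat["mf_pct", ] <- 0; R_pat[, "mf_pct"] <- 0; diag(R_pat) <- 1
  paternal <- population_spec(stat("P_paternal", "mean"), stat("P_paternal", "sd"),
                              R_pat, n = n_parent, generation = "P_paternal")
  maternal <- population_spec(stat("P_maternal", "mean"), stat("P_maternal", "sd"),
                              R, n = n_parent, generation = "P_maternal")
  f1 <- population_spec(stat("F1", "mean"), stat("F1", "sd"), R, n = n_f1,
                        generation = "F1")
  breeding_scenario(paternal, maternal, f1, seed = seed, n_f2 = n_f2)
}

#' Generate the five labelled populations of a breeding scenario
#'
#' Draws the parents and the F1, scores the F1 with `index_model` (or, when
#' `NULL`, an index built on the fly by correlation PCA of the F1 itself),
#' splits selected/unselected by the scenario's rule, and generates the two F2
#' lineages with means shifted by the breeder's equation: for each trait,
#' delta_mu = h2 * S where S is the lineage's selection differential (mean of
#' its F1 parents minus the full F1 mean). Within-group correlations and SDs
#' are inherited from the F1 spec.
#'
#' @param scenario A [breeding_scenario()].
#' @param index_model Optional [build_index()] model used for selection.
#' @return A [trait_table()] with all populations (parents labelled group
#'   `none`; F1 split into `selected`/`unselected`; two F2 lineages). The
#'   index model, selection result and per-trait selection differentials are
#'   attached as attributes `index_model`, `selection` and `differentials`.
#' @export
generate_scenario <- function(scenario, index_model = NULL) {
  if (!inherits(scenario, "breeding_scenario")) {
    stop("not a breeding_scenario", call. = FALSE)
  }
  set.seed(scenario$seed)
  pat <- generate_population(scenario$paternal, seed = NULL, id_prefix = "P1_")
  mat <- generate_population(scenario$maternal, seed = NULL, id_prefix = "P2_")
  f1 <- generate_population(scenario$f1, seed = NULL, id_prefix = "F1_")

  z <- standardize(f1)
  if (is.null(index_model)) {
    index_model <- build_index(pca_correlation(z))
  }
  sel <- rank_and_select(composite_scores(index_model, z),
                         scenario$selection_rule)
  n_sel <- length(sel$selected_ids)
  if (n_sel == 0 || n_sel == nrow(f1)) {
    stop("selection rule selected ", n_sel, " of ", nrow(f1),
         " F1 individuals; both lineages need members", call. = FALSE)
  }
  is_sel <- f1$id %in% sel$selected_ids
  f1$group[is_sel] <- "selected"
  f1$group[!is_sel] <- "unselected"

  f1_means <- colMeans(as.data.frame(f1)[trait_names()])
  s_sel <- colMeans(as.data.frame(f1)[is_sel, trait_names()]) - f1_means
  s_unsel <- colMeans(as.data.frame(f1)[!is_sel, trait_names()]) - f1_means

  f2_spec <- function(shift, group) {
    population_spec(f1_means + scenario$h2 * shift, scenario$f1$sd,
                    scenario$f1$R, n = scenario$n_f2, generation = "F2",
                    group = group)
  }
  f2_sel <- generate_population(f2_spec(s_sel, "selected"), seed = NULL,
                                id_prefix = "F2s_")
  f2_unsel <- generate_population(f2_spec(s_unsel, "unselected"), seed = NULL,
                                  id_prefix = "F2u_")

  out <- trait_table(rbind(as.data.frame(pat), as.data.frame(mat),
                           as.data.frame(f1), as.data.frame(f2_sel),
                           as.data.frame(f2_unsel)))
  attr(out, "index_model") <- index_model
  attr(out, "selection") <- sel
  attr(out, "differentials") <- list(selected = s_sel, unselected = s_unsel)
  out
}
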