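## End-to-end wiring: simulate -> analyze -> report bundle, with a manifest
## recording config, seed and package version so a bundle can be reproduced.

write_manifest <- function(outdir, config) {
  manifest <- list(
    package = "alfaselect",
    version = as.character(utils::packageVersion("alfaselect")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Read a scenario configuration file
#'
#' JSON (always available) or YAML (when the yaml package is installed) with
#' fields: per-population `mean`/`sd` lists for `paternal`, `maternal`, `f1`;
#' `correlations` as a list of `(trait_a, trait_b, rho)` records; sizes
#' `n_parent`, `n_f1`, `n_f2`; `h2`; `selection` (`rule` of
#' threshold/top_fraction/top_n with `value`); `seed`. Missing fields fall
#' back to the defaults of [default_breeding_scenario()].
#'
#' @param path Config file path (`.json`, `.yaml`/`.yml`).
#' @return A [breeding_scenario()].
#' @export
read_scenario_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- default_breeding_scenario(
    seed = if (!is.null(cfg$seed)) cfg$seed else 1,
    n_parent = if (!is.null(cfg$n_parent)) cfg$n_parent else 45,
    n_f1 = if (!is.null(cfg$n_f1)) cfg$n_f1 else 90,
    n_f2 = if (!is.null(cfg$n_f2)) cfg$n_f2 else 45
  )
  R <- if (!is.null(cfg$correlations)) {
    correlation_from_pairs(as.data.frame(cfg$correlations))
  } else NULL
  for (pop in c("paternal", "maternal", "f1")) {
    if (is.null(cfg[[pop]]) && is.null(R)) next
    spec <- base[[pop]]
    mu <- if (!is.null(cfg[[pop]]$mean)) unlist(cfg[[pop]]$mean) else spec$mean
    sd <- if (!is.null(cfg[[pop]]$sd)) unlist(cfg[[pop]]$sd) else spec$sd
    Rp <- if (!is.null(R)) R else spec$R
    if (any(sd[trait_names()] == 0)) { # keep constant traits decorrelated
      const <- trait_names()[sd[trait_names()] == 0]
      Rp[const, ] <- 0; Rp[, const] <- 0; diag(Rp) <- 1
    }
    base[[pop]] <- population_spec(mu, sd, Rp, n = spec$n,
                                   generation = spec$generation,
                                   group = spec$group)
  }
  if (!is.null(cfg$h2)) base$h2 <- unlist(cfg$h2)[trait_names()]
  if (!is.null(cfg$selection)) {
    base$selection_rule <- switch(cfg$selection$rule,
      threshold = select_threshold(cfg$selection$value),
      top_fraction = select_top_fraction(cfg$selection$value),
      top_n = select_top_n(cfg$selection$value),
      stop("unknown selection rule: ", cfg$selection$rule, call. = FALSE))
  }
  breeding_scenario(base$paternal, base$maternal, base$f1, h2 = base$h2,
                    selection_rule = base$selection_rule, n_f2 = base$n_f2,
                    seed = base$seed)
}

#' Simulate a breeding scenario and write it out
#'
#' @param scenario A [breeding_scenario()] (default: the bundled default).
#' @param outdir Output directory (created if absent).
#' @return Path of the written trait CSV, invisibly; also writes
#'   `manifest.json`.
#' @export
run_simulation <- function(scenario = default_breeding_scenario(),
                           outdir = "results/simulation") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  table <- generate_scenario(scenario)
  path <- file.path(outdir, "population.csv")
  write_trait_table(table, path)
  write_manifest(outdir, list(
    stage = "simulate", seed = scenario$seed,
    n = c(parent = scenario$paternal$n, f1 = scenario$f1$n,
          f2_per_lineage = scenario$n_f2),
    h2 = as.list(scenario$h2),
    selection_rule = scenario$selection_rule[c("type", "value")]
  ))
  invisible(path)
}

#' Run the full analysis pipeline on a trait table
#'
#' Standardize, correlate, decompose, build the index, rank and select, and
#' (when F2 records are present) compare the five populations. Every output is
#' written as CSV in the shapes of the published tables and is round-trippable
#' through the package's own readers; a manifest records configuration and
#' seed.
#'
#' @param table A [trait_table()] with labelled generations (F1 required; F2
#'   required for the comparison stage).
#' @param outdir Output directory.
#' @param alpha Significance level for Duncan letters.
#' @param retention,k Component retention passed to [pca_correlation()].
#' @param rule Selection rule, default score threshold 1.
#' @param scoring_scale Passed to [build_index()].
#' @param compare If `TRUE` (default when F2 records exist) run the
#'   generation-comparison stage.
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list with the in-memory stage results: `correlations`,
#'   `pca`, `index`, `selection`, `comparison` (or `NULL`).
#' @export
run_analysis <- function(table, outdir = "results/analysis", alpha = 0.05,
                         retention = "kaiser", k = NULL,
                         rule = select_threshold(1),
                         scoring_scale = "standardized",
                         compare = any(table$generation == "F2"),
                         seed = NA) {
  table <- trait_table(table)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "trait_io"
  result <- tryCatch({
    f1 <- table[table$generation == "F1", , drop = FALSE]
    if (nrow(f1) < 7) stop("need at least 7 F1 records")

    stage <- "stats_basic"
    z <- standardize(f1)
    corr <- pearson_correlations(f1)
    utils::write.csv(data.frame(trait = trait_names(), round(corr$r, 4)),
                     file.path(outdir, "correlations.csv"), row.names = FALSE)
    utils::write.csv(data.frame(trait = trait_names(), round(corr$p, 4)),
                     file.path(outdir, "correlation_pvalues.csv"),
                     row.names = FALSE)

    stage <- "pca_engine"
    pca <- pca_correlation(z, retention = retention, k = k)
    utils::write.csv(round(scree_table(pca), 4),
                     file.path(outdir, "pca_variance.csv"), row.names = FALSE)
    utils::write.csv(data.frame(trait = trait_names(),
                                round(pca$loadings, 4)),
                     file.path(outdir, "pca_loadings.csv"), row.names = FALSE)

    stage <- "selection_index"
    index <- build_index(pca, scoring_scale = scoring_scale)
    utils::write.csv(data.frame(trait = trait_names(),
                                weight = round(index$weights, 4)),
                     file.path(outdir, "index_weights.csv"), row.names = FALSE)
    sel <- rank_and_select(composite_scores(index, z), rule)
    utils::write.csv(transform(sel$ranking, score = round(score, 4)),
                     file.path(outdir, "ranking.csv"), row.names = FALSE)
    writeLines(sel$selected_ids, file.path(outdir, "selected_ids.txt"))

    comparison <- NULL
    if (isTRUE(compare)) {
      stage <- "generation_compare"
      if (!any(table$generation == "F2")) {
        stop("comparison requested but no F2 records present")
      }
      cmp_table <- table
      cmp_table$group[cmp_table$generation == "F1" &
                        cmp_table$id %in% sel$selected_ids] <- "selected"
      cmp_table$group[cmp_table$generation == "F1" &
                        !cmp_table$id %in% sel$selected_ids] <- "unselected"
      comparison <- compare_generations(cmp_table, alpha = alpha)
      s <- comparison$summaries
      s$mean <- round(s$mean, 4); s$sd <- round(s$sd, 4)
      utils::write.csv(s, file.path(outdir, "comparison_summaries.csv"),
                       row.names = FALSE)
      ch <- comparison$changes
      ch$percent_change <- round(ch$percent_change, 2)
      utils::write.csv(ch[c("name", "trait", "value_pop", "ref_pop",
                            "percent_change")],
                       file.path(outdir, "comparison_changes.csv"),
                       row.names = FALSE)
    }
    list(correlations = corr, pca = pca, index = index, selection = sel,
         comparison = comparison)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  write_manifest(outdir, list(
    stage = "analyze", seed = seed, alpha = alpha, retention = retention,
    k = k, scoring_scale = scoring_scale,
    rule = rule[c("type", "value")]
  ))
  invisible(result)
}
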