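## Intergenerational validation: compare the five study populations
## (selected F1, all F1, selected-derived F2, non-selected-derived F2, all F2)
## trait by trait with ANOVA + Duncan letters and percent-change metrics.

comparison_populations <- function() {
  c("F1_selected", "F1_all", "F2_selected", "F2_unselected", "F2_all")
}

# membership is by generation x group; "all" pools both lineage groups of a
# generation, as in the study design (so populations overlap by construction)
population_rows <- function(table, population) {
  gen <- sub("_.*$", "", population)
  grp <- sub("^[^_]*_", "", population)
  in_gen <- table$generation == gen
  if (grp == "all") in_gen else in_gen & table$group == grp
}

#' Default percent-change comparisons
#'
#' The reported validation metrics: dry weight, multifoliolate frequency and
#' FHR of the selected-lineage F2 against the whole F1 generation, plus the
#' lineage yield declines (selected F2 vs selected F1; non-selected F2 vs all
#' F1). Each entry names the trait, the value population and the reference
#' (baseline) population.
#'
#' @return Data frame with columns `name`, `trait`, `value_pop`, `ref_pop`.
#' @export
default_comparison_pairs <- function() {
  data.frame(
    name = c("dw_gain", "mf_gain", "fhr_change",
             "decline_selected", "decline_unselected"),
    trait = c("dry_weight_g", "mf_pct", "fhr", "dry_weight_g", "dry_weight_g"),
    value_pop = c("F2_selected", "F2_selected", "F2_selected",
                  "F2_selected", "F2_unselected"),
    ref_pop = c("F1_all", "F1_all", "F1_all", "F1_selected", "F1_all"),
    stringsAsFactors = FALSE
  )
}

#' Compare the five breeding populations
#'
#' Accepts either a raw per-individual [trait_table()] containing labelled F1
#' and F2 records, or a summary-only data frame (columns `generation`,
#' `group`, `trait`, `n`, `mean`, `sd`) as published tables provide. For each
#' trait it runs a one-way ANOVA across the five populations followed by
#' Duncan's multiple range test at `alpha`, and computes the requested
#' percent-change metrics from the population means.
#'
#' @param x A [trait_table()] or a summary data frame.
#' @param pairs Percent-change definitions, see [default_comparison_pairs()].
#' @param alpha Significance level for Duncan letters.
#' @return An object of class `comparison_report`: `summaries` (population x
#'   trait: n, mean, sd, letter), `tests` (per-trait F, p), `changes` (the
#'   percent-change table), `alpha`.
#' @export
compare_generations <- function(x, pairs = default_comparison_pairs(),
                                alpha = 0.05) {
  pops <- comparison_populations()
  summary_mode <- all(c("trait", "mean", "sd", "n") %in% names(x)) &&
    !all(trait_names() %in% names(x))

  per_trait <- lapply(trait_names(), function(tr) {
    if (summary_mode) {
      sub <- x[x$trait == tr, , drop = FALSE]
      sub$population <- paste(sub$generation, sub$group, sep = "_")
      missing <- setdiff(pops, sub$population)
      if (length(missing) > 0) {
        stop("missing population(s) in summary input: ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      sub <- sub[match(pops, sub$population), , drop = FALSE]
      dm <- duncan_mrt(summary = data.frame(group = sub$population, n = sub$n,
                                            mean = sub$mean, sd = sub$sd),
                       alpha = alpha)
    } else {
      table <- trait_table(x)
      vals <- list()
      for (p in pops) {
        rows <- population_rows(table, p)
        if (sum(rows) < 2) {
          stop("population '", p, "' missing or has fewer than 2 records",
               call. = FALSE)
        }
        vals[[p]] <- table[[tr]][rows]
      }
      dm <- duncan_mrt(values = unlist(vals),
                       groups = rep(names(vals), lengths(vals)), alpha = alpha)
    }
    dm
  })
  names(per_trait) <- trait_names()

  summaries <- do.call(rbind, lapply(trait_names(), function(tr) {
    g <- per_trait[[tr]]$groups
    data.frame(trait = tr, population = g$group, n = g$n, mean = g$mean,
               sd = g$sd, letter = g$letter, stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(trait_names(), function(tr) {
    d <- per_trait[[tr]]
    data.frame(trait = tr, statistic = d$statistic, p_value = d$p_value)
  }))

  get_mean <- function(tr, pop) {
    m <- summaries$mean[summaries$trait == tr & summaries$population == pop]
    if (length(m) != 1) stop("population '", pop, "' absent for trait ", tr,
                             call. = FALSE)
    m
  }
  changes <- pairs
  changes$value <- mapply(get_mean, pairs$trait, pairs$value_pop)
  changes$reference <- mapply(get_mean, pairs$trait, pairs$ref_pop)
  changes$percent_change <- percent_change(changes$value, changes$reference)

  structure(list(summaries = summaries, tests = tests, changes = changes,
                 duncan = per_trait, alpha = alpha),
            class = "comparison_report")
}

#' Lineage yield decline
#'
#' Relative change of a trait mean from an F1 population to its descendant F2
#' population, 100 * (F2 - F1) / F1, per lineage. The lineage baselines are
#' configurable because published decline figures do not always state theirs.
#'
#' @param report A `comparison_report`.
#' @param trait Trait name, default dry weight.
#' @param lineages Named list of `c(F2_population, F1_population)` pairs.
#' @return Named numeric vector of signed percentages.
#' @export
yield_decline <- function(report, trait = "dry_weight_g",
                          lineages = list(
                            selected = c("F2_selected", "F1_selected"),
                            unselected = c("F2_unselected", "F1_all"))) {
  s <- report$summaries[report$summaries$trait == trait, , drop = FALSE]
  vapply(lineages, function(pair) {
    f2 <- s$mean[s$population == pair[1]]
    f1 <- s$mean[s$population == pair[2]]
    if (length(f2) != 1 || length(f1) != 1) {
      stop("lineage population(s) absent: ", paste(pair, collapse = ", "),
           call. = FALSE)
    }
    percent_change(f2, f1)
  }, numeric(1))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Generation comparison (Duncan letters at alpha =", x$alpha, ")\n")
  for (tr in unique(x$summaries$trait)) {
    s <- x$summaries[x$summaries$trait == tr, ]
    cat(sprintf("  %-13s %s\n", tr,
                paste(sprintf("%s %.2f+/-%.2f^%s", s$population, s$mean,
                              s$sd, s$letter), collapse = "  ")))
  }
  cat("Percent changes:\n")
  print(x$changes[c("name", "trait", "value_pop", "ref_pop", "percent_change")],
        row.names = FALSE)
  invisible(x)
}
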