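#' @keywords internal
"_PACKAGE"

## Fixed trait order: weight vectors, loading matrices and z-score columns are
## positional, so every module indexes traits through these constants.

#' Trait, generation and group vocabularies
#'
#' The six agronomic traits handled by the package, in their canonical order:
#' plant height (cm), primary branch number, fresh/hay yield ratio (FHR),
#' leaf/stem ratio (LSR), multifoliolate leaf frequency (percent of compound
#' leaves with four or more leaflets) and dry weight per plant (g). All
#' standardized matrices, loading matrices and weight vectors use this order.
#'
#' @return `trait_names()` returns a character vector of the six trait column
#'   names; `generation_levels()` and `group_levels()` return the admissible
#'   labels for the `generation` and `group` columns of a trait table.
#' @export
trait_names <- function() {
  c("height_cm", "branches", "fhr", "lsr", "mf_pct", "dry_weight_g")
}

#' @rdname trait_names
#' @export
generation_levels <- function() c("P_paternal", "P_maternal", "F1", "F2")

#' @rdname trait_names
#' @export
group_levels <- function() c("selected", "unselected", "all", "none")

trait_bounds <- function() {
  list(
    height_cm    = c(0, Inf),
    branches     = c(0, Inf),
    fhr          = c(1, Inf),   # fresh weight cannot be below dry weight
    lsr          = c(0, Inf),
    mf_pct       = c(0, 100),
    dry_weight_g = c(0, Inf)
  )
}

#' Construct a validated trait table
#'
#' A trait table is a data frame with one row per plant: an `id`, a
#' `generation` label, a `group` label and the six trait columns of
#' [trait_names()]. All trait values must be finite and within their
#' biological bounds (FHR at least 1, multifoliolate frequency in \[0, 100\],
#' the rest non-negative), and ids must be unique.
#'
#' @param df A data frame carrying the nine required columns.
#' @param drop_incomplete If `TRUE`, rows with missing trait values are
#'   dropped with a message giving the count; if `FALSE` (default) missing
#'   values are an error.
#' @return The validated data frame with class `trait_table`, trait columns
#'   coerced to numeric and column order normalised.
#' @export
trait_table <- function(df, drop_incomplete = FALSE) {
  required <- c("id", "generation", "group", trait_names())
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$id <- as.character(df$id)
  df$generation <- as.character(df$generation)
  df$group <- as.character(df$group)

  for (tr in trait_names()) {
    if (!is.numeric(df[[tr]])) {
      suppressWarnings(num <- as.numeric(df[[tr]]))
      bad <- which(is.na(num) & !is.na(df[[tr]]) & df[[tr]] != "")
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value in column '%s' at row(s) %s",
                     tr, paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      }
      df[[tr]] <- num
    }
  }

  incomplete <- !stats::complete.cases(df[trait_names()])
  if (any(incomplete)) {
    if (drop_incomplete) {
      message(sum(incomplete), " row(s) with missing trait values dropped")
      df <- df[!incomplete, , drop = FALSE]
    } else {
      stop(sprintf("missing trait value(s) at row(s) %s (set drop_incomplete = TRUE to drop them)",
                   paste(utils::head(which(incomplete), 5), collapse = ", ")),
           call. = FALSE)
    }
  }

  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    stop("duplicate id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  bad_gen <- setdiff(unique(df$generation), generation_levels())
  if (length(bad_gen) > 0) {
    stop("unknown generation label(s): ", paste(bad_gen, collapse = ", "),
         "; expected one of ", paste(generation_levels(), collapse = ", "),
         call. = FALSE)
  }
  bad_grp <- setdiff(unique(df$group), group_levels())
  if (length(bad_grp) > 0) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
         "; expected one of ", paste(group_levels(), collapse = ", "),
         call. = FALSE)
  }

  bounds <- trait_bounds()
  for (tr in trait_names()) {
    x <- df[[tr]]
    if (any(!is.finite(x))) {
      stop(sprintf("non-finite value in column '%s' at row(s) %s", tr,
                   paste(utils::head(which(!is.finite(x)), 5), collapse = ", ")),
           call. = FALSE)
    }
    b <- bounds[[tr]]
    out <- which(x < b[1] | x > b[2])
    if (length(out) > 0) {
      stop(sprintf("column '%s' outside [%s, %s] at row(s) %s", tr,
                   format(b[1]), format(b[2]),
                   paste(utils::head(out, 5), collapse = ", ")),
           call. = FALSE)
    }
  }

  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a trait table from CSV
#'
#' Expects a comma-separated, header-first file (RFC 4180 quoting, "." decimal
#' separator) with columns `id, generation, group` and the six traits of
#' [trait_names()]. Alternative column names can be mapped via `column_map`.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named character vector mapping required column
#'   names to the names used in the file, e.g. `c(height_cm = "PH")`.
#' @param drop_incomplete Passed to [trait_table()].
#' @return A validated [trait_table()].
#' @export
read_trait_table <- function(path, column_map = NULL, drop_incomplete = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(df)) {
        stop("column_map names absent column '", src, "'", call. = FALSE)
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  trait_table(df, drop_incomplete = drop_incomplete)
}

#' Write a trait table to CSV
#'
#' Values round-trip at full precision: [read_trait_table()] on the written
#' file reproduces the table exactly.
#'
#' @param table A [trait_table()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  table <- trait_table(table)
  out <- as.data.frame(table)
  # format() would truncate doubles; keep full precision for round-tripping
  for (tr in trait_names()) {
    out[[tr]] <- sprintf("%.17g", out[[tr]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Per-group descriptive statistics
#'
#' Computes n, mean and sample standard deviation (n - 1 denominator) of every
#' trait within each group of the table. Groups of a single record report the
#' SD as `NA` (undefined).
#'
#' @param table A [trait_table()].
#' @param by Character vector of grouping columns, default
#'   `c("generation", "group")`.
#' @return A data frame with one row per group and trait: columns from `by`,
#'   then `trait`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(table, by = c("generation", "group")) {
  table <- trait_table(table)
  if (nrow(table) == 0) stop("empty trait table", call. = FALSE)
  key <- interaction(table[by], drop = TRUE, lex.order = TRUE)
  res <- lapply(levels(key), function(k) {
    sub <- table[key == k, , drop = FALSE]
    do.call(rbind, lapply(trait_names(), function(tr) {
      x <- sub[[tr]]
      row <- sub[1, by, drop = FALSE]
      row$trait <- tr
      row$n <- length(x)
      row$mean <- mean(x)
      row$sd <- if (length(x) > 1) stats::sd(x) else NA_real_
      row
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
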