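# broom-style tidiers for the package's result objects

#' Tidy an overlap odds-ratio result
#'
#' @param x An `overlap_stats` object.
#' @param ... Unused.
#' @return A one-row tibble with the 2x2 cells, estimator, odds ratio,
#'   confidence bounds, p-value and overlap percentage.
#' @export
tidy.overlap_stats <- function(x, ...) {
  tibble(
    a = unname(x$table["a"]), b = unname(x$table["b"]),
    c = unname(x$table["c"]), d = unname(x$table["d"]),
    method = x$method, odds_ratio = x$odds_ratio,
    ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, overlap_pct = x$overlap_pct
  )
}

#' @rdname tidy.overlap_stats
#' @export
glance.overlap_stats <- function(x, ...) tidy(x)

#' Tidy a class-expression contrast
#'
#' @param x A `class_contrast` object.
#' @param ... Unused.
#' @return One row per class with pooled value summaries.
#' @export
tidy.class_contrast <- function(x, ...) {
  tibble(
    class = c("a", "b"),
    n_values = c(length(x$values_a), length(x$values_b)),
    mean = c(mean(x$values_a), mean(x$values_b)),
    median = c(stats::median(x$values_a), stats::median(x$values_b))
  )
}

#' @rdname tidy.class_contrast
#' @export
glance.class_contrast <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, t_p = x$t_p, wilcoxon_p = x$wilcoxon_p)
}

#' Tidy a stage profile
#'
#' @param x A `stage_profile` object.
#' @param ... Unused.
#' @return The per-stage tibble (count, percentage, cumulative percentage).
#' @export
tidy.stage_profile <- function(x, ...) {
  x$stages |> mutate(label = x$label, .before = 1)
}

#' @rdname tidy.stage_profile
#' @export
glance.stage_profile <- function(x, ...) {
  tibble(label = x$label, total = x$total, n_stages = nrow(x$stages))
}

#' Tidy an MCODE module set
#'
#' @param x An `mcode_result` object.
#' @param ... Unused.
#' @return One row per module member (`module_id`, `gene_id`) joined with
#'   the module's size, density and score.
#' @export
tidy.mcode_result <- function(x, ...) {
  module_members(x) |>
    left_join(x$modules |> select("module_id", "n_nodes", "density", "score"),
              by = "module_id")
}

#' @rdname tidy.mcode_result
#' @export
glance.mcode_result <- function(x, ...) {
  tibble(
    n_modules = nrow(x$modules),
    n_clustered_genes = sum(x$modules$n_nodes),
    max_score = if (nrow(x$modules) > 0) max(x$modules$score) else NA_real_
  )
}

#' Tidy a pipeline run
#'
#' @param x A `phylomark_run` object.
#' @param ... Unused.
#' @return `glance()` returns the headline summary as a one-row tibble;
#'   `tidy()` the per-stage profile of all dated genes.
#' @export
tidy.phylomark_run <- function(x, ...) tidy(x$profiles$all)

#' @rdname tidy.phylomark_run
#' @export
glance.phylomark_run <- function(x, ...) {
  s <- x$summary
  as_tibble(s[setdiff(names(s), "stage_counts")])
}
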