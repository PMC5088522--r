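#' Classify house-keeping genes
#'
#' House-keeping (HK) genes are the genes expressed in every sample of every
#' tissue (the `expressed_in_all_samples` call) that also appear in a curated
#' reference HK list.
#'
#' @param calls Expression calls from [detect_expressed()].
#' @param reference Character vector of reference HK gene ids (nonempty).
#' @return Character vector of HK gene ids (possibly empty, with a warning).
#' @export
classify_housekeeping <- function(calls, reference) {
  if (length(reference) == 0) abort("reference HK list is empty")
  expressed_all <- calls$gene_id[calls$expressed_in_all_samples]
  hk <- intersect(expressed_all, reference)
  if (length(hk) == 0) warn("no overlap between expressed-in-all genes and the HK reference")
  hk
}

#' Classify tissue-enriched genes
#'
#' Tissue-enriched (TE) genes are expressed (at least one replicate at or
#' above the FPKM threshold used for the calls) in at least one and at most
#' `max_tissues` tissues. The default of three tissues tolerates
#' physiologically linked tissues that share expression profiles (e.g. colon
#' and rectum).
#'
#' @param calls Expression calls from [detect_expressed()].
#' @param max_tissues Maximum number of tissues (default 3).
#' @return Character vector of TE gene ids.
#' @export
classify_tissue_enriched <- function(calls, max_tissues = 3L) {
  calls$gene_id[calls$tissues_expressed_in >= 1L &
                  calls$tissues_expressed_in <= max_tissues]
}

overlap_stats_new <- function(a, b, c, d, method, or, ci, p) {
  structure(
    list(
      table = c(a = a, b = b, c = c, d = d),
      method = method,
      odds_ratio = unname(or),
      ci_low = ci[1], ci_high = ci[2],
      p_value = unname(p),
      overlap_pct = 100 * a / (a + c)
    ),
    class = "overlap_stats"
  )
}

#' Overlap odds ratio from 2x2 counts
#'
#' Core estimator behind [overlap_odds_ratio()], taking the 2x2 table
#' directly: `a` genes in both sets, `b` in A only, `c` in B only, `d` in
#' neither. `method = "cmle"` (default) returns the conditional
#' maximum-likelihood odds ratio under the noncentral hypergeometric model
#' with its exact confidence interval and Fisher exact p-value (the
#' `fisher.test` estimator); `method = "sample"` returns the cross-product
#' ratio ad/bc with a Woolf log-normal interval, applying the Haldane 0.5
#' correction when any cell is zero.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param method `"cmle"` or `"sample"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `overlap_stats`; see [tidy.overlap_stats()].
#' @export
overlap_stats_from_counts <- function(a, b, c, d,
                                      method = c("cmle", "sample"),
                                      conf_level = 0.95) {
  method <- match.arg(method)
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be nonnegative")
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (method == "cmle") {
    ft <- fisher.test(tab, conf.level = conf_level)
    overlap_stats_new(a, b, c, d, method, ft$estimate, ft$conf.int, ft$p.value)
  } else {
    z <- -stats::qnorm((1 - conf_level) / 2)
    cells <- c(a, b, c, d)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-z, z) * se)
    p <- fisher.test(tab)$p.value
    overlap_stats_new(a, b, c, d, method, or, ci, p)
  }
}

#' Odds ratio of the overlap between two gene sets
#'
#' Tabulates two gene sets against a common universe and estimates the odds
#' ratio of their overlap. Reference genes outside the universe are dropped
#' before tabulation. `overlap_pct` is the percentage of set B recovered in
#' set A (100 * |A \eqn{\cap}{∩} B| / |B|).
#'
#' @param universe Either the universe size (a single count) or a character
#'   vector of universe gene ids.
#' @param set_a,set_b Character vectors of gene ids.
#' @param method `"cmle"` (default) or `"sample"`; see
#'   [overlap_stats_from_counts()].
#' @return An object of class `overlap_stats`.
#' @export
overlap_odds_ratio <- function(universe, set_a, set_b, method = c("cmle", "sample")) {
  method <- match.arg(method)
  if (is.character(universe)) {
    set_a <- intersect(set_a, universe)
    set_b <- intersect(set_b, universe)
    n_universe <- length(unique(universe))
  } else {
    n_universe <- as.integer(universe)
  }
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c <- length(setdiff(set_b, set_a))
  d <- n_universe - a - b - c
  if (d < 0) abort("universe smaller than |A union B|")
  overlap_stats_from_counts(a, b, c, d, method = method)
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "Overlap odds ratio (%s): OR = %.2f [%.2f, %.2f], p = %.3g\n",
    x$method, x$odds_ratio, x$ci_low, x$ci_high, x$p_value
  ))
  cat(sprintf("2x2 table (a,b,c,d): %s; overlap = %.1f%%\n",
              paste(x$table, collapse = ", "), x$overlap_pct))
  invisible(x)
}

#' Contrast the expression distributions of two gene classes
#'
#' Pools all gene-by-sample log2 expression values of each class and compares
#' them: mean difference (class A minus class B), two-sided Welch t-test and
#' Wilcoxon rank-sum test. With a single gene per class the tests are skipped
#' with a warning.
#'
#' @param expr Expression tibble on the log2 scale (see [log_transform()]).
#' @param hk,te Character vectors of gene ids for the two classes
#'   (conventionally house-keeping and tissue-enriched; both nonempty).
#' @return An object of class `class_contrast` with fields `mean_diff`,
#'   `t_p`, `wilcoxon_p`, and the per-class pooled value vectors.
#' @export
compare_class_expression <- function(expr, hk, te) {
  if (length(hk) == 0 || length(te) == 0) abort("both gene sets must be nonempty")
  if (!identical(expr_scale(expr), "log2")) {
    warn("expression does not carry the log2 scale marker; values used as-is")
  }
  m <- expr_as_matrix(expr)
  miss <- setdiff(c(hk, te), rownames(m))
  if (length(miss) > 0) abort(paste("genes absent from matrix:", paste(head(miss, 5), collapse = ", ")))
  va <- as.vector(m[hk, , drop = FALSE])
  vb <- as.vector(m[te, , drop = FALSE])
  mean_diff <- mean(va) - mean(vb)
  if (length(hk) < 2 || length(te) < 2) {
    warn("singleton gene set: significance tests skipped")
    t_p <- NA_real_
    w_p <- NA_real_
  } else {
    t_p <- tryCatch(t.test(va, vb)$p.value, error = function(e) {
      warn(paste("t-test unavailable:", conditionMessage(e)))
      NA_real_
    })
    w_p <- tryCatch(suppressWarnings(wilcox.test(va, vb)$p.value), error = function(e) {
      warn(paste("Wilcoxon test unavailable:", conditionMessage(e)))
      NA_real_
    })
  }
  structure(
    list(mean_diff = mean_diff, t_p = t_p, wilcoxon_p = w_p,
         values_a = va, values_b = vb),
    class = "class_contrast"
  )
}

#' @export
print.class_contrast <- function(x, ...) {
  cat(sprintf("Class contrast: mean log2 difference = %.3f (t p = %.3g, Wilcoxon p = %.3g)\n",
              x$mean_diff, x$t_p, x$wilcoxon_p))
  invisible(x)
}
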