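#' Pairwise contrast specification
#'
#' @param group_a,group_b Group labels to compare (`b` minus `a` on the log2
#'   scale).
#' @param name Contrast label; defaults to `"a_vs_b"`.
#' @param alpha Significance level (default 0.05).
#' @param two_sided Logical; two-sided test (default `TRUE`).
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(group_a, group_b, name = NULL, alpha = 0.05,
                          two_sided = TRUE) {
  if (identical(group_a, group_b)) stop_("group_a and group_b must differ")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_("alpha must lie in (0, 1)")
  structure(list(name = name %||% paste0(group_a, "_vs_", group_b),
                 group_a = group_a, group_b = group_b,
                 alpha = alpha, two_sided = isTRUE(two_sided)),
            class = "contrast_spec")
}

#' Per-protein two-group t-test for one contrast
#'
#' Two-sided Student's t-test with pooled variance on log2 fractions (the
#' classical statistics-package default); Welch's unequal-variance form is
#' available via `var_equal = FALSE`. When both groups are constant and
#' equal the convention t = 0, p = 1 is applied.
#'
#' @param norm A [normalize_areas()] result.
#' @param design Design data frame.
#' @param spec A [contrast_spec()].
#' @param var_equal Pooled variance (default `TRUE`) or Welch.
#' @return A data frame of class `contrast_result`: one row per protein
#'   with `mean_a`, `mean_b`, `log2_fold_change` (= mean_b - mean_a),
#'   `t_statistic`, `degrees_of_freedom`, `p_value` and `significant`.
#' @export
t_test_contrast <- function(norm, design, spec, var_equal = TRUE) {
  stopifnot(inherits(norm, "normalized_matrix"),
            inherits(spec, "contrast_spec"))
  runs <- colnames(norm$log2_values)
  design <- design[match(runs, design$run), , drop = FALSE]
  ia <- which(design$group == spec$group_a)
  ib <- which(design$group == spec$group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop_("both groups need >= 2 runs (", spec$group_a, ": ", length(ia),
          ", ", spec$group_b, ": ", length(ib), ")")
  xa <- norm$log2_values[, ia, drop = FALSE]
  xb <- norm$log2_values[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1L)
  vb <- rowSums((xb - mb)^2) / (nb - 1L)
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2L, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  }
  delta <- mb - ma
  t <- delta / se
  # degenerate: no variance at all
  zero_se <- se == 0
  t[zero_se & delta == 0] <- 0
  t[zero_se & delta != 0] <- Inf * sign(delta[zero_se & delta != 0])
  df[zero_se & delta == 0] <- na + nb - 2L
  p <- if (spec$two_sided) 2 * stats::pt(-abs(t), df) else
    stats::pt(t, df, lower.tail = FALSE)
  p[zero_se & delta == 0] <- 1
  p[zero_se & delta != 0] <- 0
  out <- data.frame(accession = rownames(norm$log2_values),
                    contrast = spec$name,
                    mean_a = ma, mean_b = mb,
                    log2_fold_change = delta,
                    t_statistic = t,
                    degrees_of_freedom = df,
                    p_value = p,
                    significant = p < spec$alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("contrast_result", class(out))
  attr(out, "spec") <- spec
  out
}

#' Adjust contrast p-values across proteins (optional)
#'
#' Raw per-protein p-values at the stated alpha drive significance by
#' default, matching common practice for small-replicate LFQ screens; this
#' helper adds a Benjamini-Hochberg adjusted column and re-flags
#' significance on it for users who want FDR control.
#'
#' @param result A [t_test_contrast()] result.
#' @param alpha Level applied to the adjusted values.
#' @return The result with columns `q_bh` and `significant` re-derived.
#' @export
adjust_contrast <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "contrast_result"))
  result$q_bh <- stats::p.adjust(result$p_value, method = "BH")
  result$significant <- result$q_bh < alpha
  result
}

#' Union of significant proteins across contrasts
#'
#' @param results A list of [t_test_contrast()] results (one per contrast).
#' @return A list with `union` (accessions significant in >= 1 contrast),
#'   `per_contrast` (named significant counts), and `membership` (logical
#'   matrix protein x contrast). Contrasts tested over different protein
#'   sets are intersected with a warning.
#' @export
significant_union <- function(results) {
  if (inherits(results, "contrast_result")) results <- list(results)
  if (length(results) == 0L) stop_("need at least one contrast result")
  accs <- lapply(results, `[[`, "accession")
  common <- Reduce(intersect, accs)
  if (!all(vapply(accs, function(a) setequal(a, common), logical(1))))
    warn_("contrasts cover different protein sets; ",
          "union computed over their intersection")
  names(results) <- vapply(results, function(r) r$contrast[1] %||% "contrast",
                           character(1))
  membership <- sapply(results, function(r) {
    r$significant[match(common, r$accession)]
  })
  membership <- matrix(membership, nrow = length(common),
                       dimnames = list(common, names(results)))
  list(union = common[rowSums(membership) > 0],
       per_contrast = colSums(membership),
       membership = membership)
}

#' Volcano-plot table
#'
#' @param result A [t_test_contrast()] result.
#' @return Data frame with `accession`, `log2_fold_change`, `neg_log10_p`
#'   and `significant`, one row per tested protein.
#' @export
volcano_table <- function(result) {
  stopifnot(inherits(result, "contrast_result"), nrow(result) > 0L)
  data.frame(accession = result$accession,
             log2_fold_change = result$log2_fold_change,
             neg_log10_p = -log10(result$p_value),
             significant = result$significant,
             stringsAsFactors = FALSE)
}

#' Volcano plot of one contrast
#'
#' @param x A [t_test_contrast()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.contrast_result <- function(x, ...) {
  v <- volcano_table(x)
  graphics::plot(v$log2_fold_change, v$neg_log10_p,
                 col = ifelse(v$significant, "red", "grey40"),
                 pch = 20, xlab = "log2 fold change",
                 ylab = "-log10 p", main = x$contrast[1], ...)
  spec <- attr(x, "spec")
  if (!is.null(spec)) graphics::abline(h = -log10(spec$alpha), lty = 2)
  invisible(x)
}
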