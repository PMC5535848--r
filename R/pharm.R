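#' Infarct volume as a percentage of the hemisphere
#'
#' Total infarct volume from serial coronal sections: the sum of the
#' per-slice infarct areas expressed as a percentage of the summed
#' left-hemisphere areas (constant slice thickness, so summed areas proxy
#' volumes). Scale-invariant under a common rescaling of all areas.
#'
#' @param infarct_areas Numeric vector of per-slice infarct areas (mm^2),
#'   conventionally 5 slices.
#' @param hemisphere_areas Per-slice left-hemisphere areas (mm^2), same
#'   length.
#' @param n_slices Expected slice count (default 5).
#' @return Infarct volume percentage in [0, 100].
#' @examples
#' infarct_percent(c(1, 2, 3, 2, 1), rep(10, 5))  # 18
#' @export
infarct_percent <- function(infarct_areas, hemisphere_areas, n_slices = 5L) {
  if (length(infarct_areas) != n_slices ||
      length(hemisphere_areas) != n_slices)
    stop_("expected ", n_slices, " slices")
  if (any(infarct_areas < 0) || any(hemisphere_areas < 0))
    stop_("areas must be non-negative")
  if (any(infarct_areas > hemisphere_areas))
    stop_("infarct area exceeds hemisphere area on some slice")
  tot <- sum(hemisphere_areas)
  if (tot <= 0) stop_("zero total hemisphere area")
  100 * sum(infarct_areas) / tot
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments,
# with mid-ranks for ties; two-sided as P(|U - n1 n2 / 2| >= |u_obs - ...|)
ranksum_exact <- function(ranks_a_idx, ranks, n1, n2) {
  u_from <- function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_from(ranks_a_idx)
  centre <- n1 * n2 / 2
  dev <- abs(u_obs - centre)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2L, u_from)
  mean(abs(us - centre) >= dev - 1e-9)
}

#' Wilcoxon-Mann-Whitney rank-sum test for ordinal scores
#'
#' Two-sample rank-sum test with mid-ranks for ties, as used for
#' neurological-deficit (Longa) scores. For small samples (both groups
#' <= 8) the two-sided p-value is computed by exact enumeration of all
#' rank assignments; otherwise the normal approximation with tie
#' correction and continuity correction is used. The statistic is
#' invariant under any strictly monotone transformation of the scores.
#'
#' @param a,b Numeric vectors of scores (each nonempty).
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) branch;
#'   `NULL` (default) picks exact when both groups have <= 8 observations.
#' @return List with `U` (Mann-Whitney statistic of `a`), `W` (rank sum of
#'   `a`), two-sided `p_value`, and `method`.
#' @export
rank_sum <- function(a, b, exact = NULL) {
  if (length(a) == 0L || length(b) == 0L)
    stop_("both groups must be nonempty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)  # mid-ranks for ties
  W <- sum(ranks[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  use_exact <- exact %||% (max(n1, n2) <= 8L)
  if (use_exact) {
    p <- ranksum_exact(seq_len(n1), ranks, n1, n2)
    method <- "exact enumeration (mid-ranks)"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, W = W, p_value = 1,
                                 method = "degenerate (all tied)"))
    dev <- abs(U - n1 * n2 / 2)
    z <- (dev - 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation with tie correction"
  }
  list(U = U, W = W, p_value = p, method = method)
}

#' One-way ANOVA with Newman-Keuls post-hoc comparisons
#'
#' Standard one-way fixed-effects ANOVA followed by the step-down
#' Student-Newman-Keuls (SNK) procedure: group means are sorted, each pair
#' is compared with the studentized-range critical value at the span of the
#' pair (number of means it straddles), stepping down from the widest span,
#' and any pair inside a non-significant span is declared non-significant
#' without testing (the blocking rule). Unequal group sizes use the
#' harmonic mean of the pair's sizes.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param alpha Family level for the SNK decisions (default 0.05).
#' @return List of class `anova_snk`: `F`, `df`, `p_value`, `ms_error`,
#'   `means`, and data frame `comparisons` with per-pair `span`, `q`,
#'   `q_crit`, `p_q` and `significant`. Zero within-group variance with
#'   unequal means yields infinite F, flagged via `degenerate`.
#' @export
anova_snk <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop_("need >= 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) stop_("every group needs >= 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  N <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  ms_between <- ss_between / df1
  ms_error <- ss_within / df2
  degenerate <- ms_error == 0 && ms_between > 0
  Fstat <- if (ms_error == 0) {
    if (ms_between == 0) 0 else Inf
  } else ms_between / ms_error
  p <- if (is.infinite(Fstat)) 0 else
    stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  ord <- order(means)
  sorted <- means[ord]
  nm <- names(sorted)
  pairs <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      pairs[[length(pairs) + 1L]] <- c(i = i, j = j, span = span)
    }
  }
  blocked <- matrix(FALSE, k, k)
  comp <- do.call(rbind, lapply(pairs, function(pr) {
    i <- pr["i"]; j <- pr["j"]; span <- pr["span"]
    nh <- 2 / (1 / sizes[ord][i] + 1 / sizes[ord][j])
    se <- sqrt(ms_error / nh)
    q <- if (se == 0) {
      if (sorted[j] - sorted[i] == 0) 0 else Inf
    } else (sorted[j] - sorted[i]) / se
    q_crit <- stats::qtukey(1 - alpha, nmeans = span, df = df2)
    p_q <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = span, df = df2, lower.tail = FALSE)
    sig <- q >= q_crit && !blocked[i, j]
    if (!sig) {
      # blocking: every pair nested inside a non-significant span is
      # declared non-significant without testing
      for (a in i:j) for (b in i:j) blocked[a, b] <<- TRUE
    }
    data.frame(group_low = nm[i], group_high = nm[j],
               span = as.integer(span), difference = sorted[j] - sorted[i],
               q = q, q_crit = q_crit, p_q = p_q,
               significant = sig, stringsAsFactors = FALSE)
  }))
  structure(list(F = Fstat, df = c(df1, df2), p_value = p,
                 ms_error = ms_error, means = means,
                 comparisons = comp, degenerate = degenerate,
                 alpha = alpha),
            class = "anova_snk")
}

#' @export
print.anova_snk <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df[1], ", ", x$df[2], ") = ",
      format(x$F, digits = 4), ", p = ", format(x$p_value, digits = 4),
      "\n", sep = "")
  if (x$degenerate) cat("  (zero within-group variance; F degenerate)\n")
  cat("Newman-Keuls pairwise decisions (alpha = ", x$alpha, "):\n", sep = "")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Reconstruct integer score multisets from a printed mean and SD
#'
#' Exhaustively enumerates all multisets of `n` integer scores on the
#' Longa 0--4 scale whose mean and population SD (divide-by-n formula,
#' which matches how such summaries are conventionally printed) round to
#' the given two-decimal values. Useful for rebuilding raw behavioural
#' scores from published summary tables.
#'
#' @param mean_value,sd_value Printed mean and SD (2 decimals).
#' @param n Number of animals in the group.
#' @param scores Allowed score values (default 0:4).
#' @return List of integer vectors (sorted decreasing), possibly empty
#'   when no multiset matches.
#' @examples
#' reconstruct_score_multiset(2.75, 0.43, 8)
#' @export
reconstruct_score_multiset <- function(mean_value, sd_value, n,
                                       scores = 0:4) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_("n must be >= 1")
  counts <- compositions(n, length(scores))
  out <- list()
  for (row in seq_len(nrow(counts))) {
    x <- rep(scores, counts[row, ])
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))  # population SD
    if (round(m, 2) == round(mean_value, 2) &&
        round(s, 2) == round(sd_value, 2)) {
      out[[length(out) + 1L]] <- sort(x, decreasing = TRUE)
    }
  }
  out
}

# all vectors of `parts` non-negative integers summing to n
compositions <- function(n, parts) {
  if (parts == 1L) return(matrix(n, ncol = 1L))
  do.call(rbind, lapply(0:n, function(i) {
    cbind(i, compositions(n - i, parts - 1L))
  }))
}
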