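#' Protein-by-run precursor-area matrix
#'
#' The entry point of the quantitative pipeline: one row per protein
#' accession, one column per MS run, cells holding non-negative precursor
#' areas with `NA` for missing (not detected). Zero areas are treated as
#' missing, since a zero precursor area is a non-detection.
#'
#' @param areas Numeric matrix with unique row (accession) and column (run)
#'   names; non-negative or `NA`.
#' @param unique_peptides Optional integer vector, one per protein: the
#'   number of unique identifying peptides, used by [filter_proteins()].
#' @param imputed Optional logical matrix flagging imputed cells (set by
#'   [impute_missing()]).
#' @return An object of class `area_matrix`.
#' @export
area_matrix <- function(areas, unique_peptides = NULL, imputed = NULL) {
  if (!is.matrix(areas) || !is.numeric(areas))
    stop_("areas must be a numeric matrix")
  if (is.null(rownames(areas)) || anyDuplicated(rownames(areas)))
    stop_("rows must be uniquely labelled by accession")
  if (is.null(colnames(areas)) || anyDuplicated(colnames(areas)))
    stop_("columns must be uniquely labelled by run id")
  if (any(areas < 0, na.rm = TRUE)) stop_("negative precursor areas")
  areas[!is.na(areas) & areas == 0] <- NA_real_
  if (!is.null(unique_peptides)) {
    if (length(unique_peptides) != nrow(areas))
      stop_("unique_peptides length must match the number of proteins")
    unique_peptides <- as.integer(unique_peptides)
  }
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(areas), ncol(areas),
                      dimnames = dimnames(areas))
  }
  structure(list(areas = areas, unique_peptides = unique_peptides,
                 imputed = imputed),
            class = "area_matrix")
}

#' @export
print.area_matrix <- function(x, ...) {
  cat("Precursor area matrix: ", nrow(x$areas), " proteins x ",
      ncol(x$areas), " runs\n", sep = "")
  nm <- sum(is.na(x$areas))
  cat("  missing cells: ", nm, " (",
      round(100 * nm / length(x$areas), 1), "%)\n", sep = "")
  if (any(x$imputed)) cat("  imputed cells: ", sum(x$imputed), "\n", sep = "")
  invisible(x)
}

#' @export
dim.area_matrix <- function(x) dim(x$areas)

check_design <- function(x, design) {
  runs <- colnames(x$areas)
  if (!setequal(runs, design$run) || length(runs) != nrow(design))
    stop_("design table and area matrix disagree on run ids")
  design[match(runs, design$run), , drop = FALSE]
}

#' Presence and unique-peptide filtering
#'
#' Retains proteins identified by at least `min_unique_peptides` unique
#' peptides (default 2, i.e. "more than one unique peptide") and observed
#' in at least `min_replicates_present` runs of at least one experimental
#' group (default 1: identified in at least one biological replicate of
#' some group). Row order is preserved.
#'
#' @param x An [area_matrix()].
#' @param design Design data frame (`run`, `group`, `replicate`).
#' @param min_replicates_present Minimum observed runs within some group.
#' @param min_unique_peptides Minimum unique-peptide count; ignored (with a
#'   message) when the matrix carries no unique-peptide annotation.
#' @return A filtered `area_matrix`, with attribute `"dropped"`: a data
#'   frame ledger of removed accessions and the reason.
#' @export
filter_proteins <- function(x, design, min_replicates_present = 1L,
                            min_unique_peptides = 2L) {
  stopifnot(inherits(x, "area_matrix"))
  design <- check_design(x, design)
  groups <- split(seq_len(ncol(x$areas)), design$group)
  obs <- !is.na(x$areas)
  present <- rep(FALSE, nrow(x$areas))
  for (idx in groups) {
    present <- present | rowSums(obs[, idx, drop = FALSE]) >=
      min_replicates_present
  }
  up_ok <- if (is.null(x$unique_peptides)) {
    if (min_unique_peptides > 1L)
      message("no unique-peptide annotation; unique-peptide filter skipped")
    rep(TRUE, nrow(x$areas))
  } else {
    x$unique_peptides >= min_unique_peptides
  }
  keep <- present & up_ok
  reason <- ifelse(!up_ok & !present, "unique_peptides+presence",
                   ifelse(!up_ok, "unique_peptides", "presence"))
  dropped <- data.frame(accession = rownames(x$areas)[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- area_matrix(x$areas[keep, , drop = FALSE],
                     unique_peptides = x$unique_peptides[keep],
                     imputed = x$imputed[keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Imputation parameters for below-detection-limit draws
#'
#' Missing precursor areas are assumed left-censored (below the detection
#' limit) and are replaced, per run, by draws from a normal distribution on
#' the log2 scale that is down-shifted from the run's observed distribution:
#' mean = run mean - `shift` x run SD, SD = `width` x run SD. The 1.8/0.3
#' defaults are the widely used down-shifted-normal convention.
#'
#' @param shift Down-shift in multiples of the per-run SD (default 1.8).
#' @param width Width in multiples of the per-run SD (default 0.3).
#' @param seed Integer seed for the draws, or `NULL` to use the session RNG.
#' @return An object of class `imputation_params`.
#' @export
imputation_params <- function(shift = 1.8, width = 0.3, seed = NULL) {
  if (!is.numeric(width) || width <= 0) stop_("width must be > 0")
  if (!is.numeric(shift) || shift < 0) stop_("shift must be >= 0")
  structure(list(shift = shift, width = width, seed = seed),
            class = "imputation_params")
}

#' Impute left-censored missing values
#'
#' Replaces each missing cell by a draw from the per-run down-shifted
#' normal distribution described in [imputation_params()], computed from
#' the run's observed log2 areas only. Observed cells are never altered.
#'
#' @param x An [area_matrix()].
#' @param params An [imputation_params()] object.
#' @return A complete `area_matrix` whose `imputed` field flags the filled
#'   cells.
#' @export
impute_missing <- function(x, params = imputation_params()) {
  stopifnot(inherits(x, "area_matrix"), inherits(params, "imputation_params"))
  areas <- x$areas
  miss <- is.na(areas)
  if (!any(miss)) return(x)
  filled <- with_seed(params$seed, {
    for (j in seq_len(ncol(areas))) {
      mj <- miss[, j]
      if (!any(mj)) next
      obs <- log2(areas[!mj, j])
      if (length(obs) == 0L)
        stop_("run '", colnames(areas)[j], "' has no observed values")
      if (length(obs) < 2L)
        stop_("run '", colnames(areas)[j],
              "' has a single observed value; per-run SD is undefined")
      mu <- mean(obs) - params$shift * stats::sd(obs)
      sigma <- params$width * stats::sd(obs)
      areas[mj, j] <- 2^stats::rnorm(sum(mj), mean = mu, sd = sigma)
    }
    areas
  })
  area_matrix(filled, unique_peptides = x$unique_peptides,
              imputed = x$imputed | miss)
}

#' Peptide-count and fraction-of-total normalization
#'
#' Divides each protein's precursor area by its theoretical peptide count,
#' then expresses each protein as its fraction of the run's total
#' peptide-normalized area, so each run's fractions sum to one. Statistics
#' downstream run on `log2` of these fractions.
#'
#' @param x A complete [area_matrix()] (impute first; see
#'   [impute_missing()]).
#' @param peptide_counts Data frame from [count_theoretical_peptides()].
#' @return An object of class `normalized_matrix` with fields `fractions`,
#'   `log2_values`, `imputed` (provenance flags) and `peptide_counts`.
#' @export
normalize_areas <- function(x, peptide_counts) {
  stopifnot(inherits(x, "area_matrix"))
  if (any(is.na(x$areas)))
    stop_("matrix still has missing cells; run impute_missing() first")
  idx <- match(rownames(x$areas), peptide_counts$accession)
  if (any(is.na(idx)))
    stop_("no peptide count for accession(s): ",
          paste(utils::head(rownames(x$areas)[is.na(idx)], 5), collapse = ", "))
  counts <- peptide_counts$n_theoretical_peptides[idx]
  zero <- counts < 1L
  if (any(zero)) {
    warn_(sum(zero), " protein(s) with zero theoretical peptides dropped ",
          "from normalization")
  }
  areas <- x$areas[!zero, , drop = FALSE]
  counts <- counts[!zero]
  imputed <- x$imputed[!zero, , drop = FALSE]
  value1 <- areas / counts
  totals <- colSums(value1)
  if (any(totals <= 0)) stop_("zero total normalized area in a run")
  fractions <- sweep(value1, 2L, totals, "/")
  structure(list(fractions = fractions,
                 log2_values = log2(fractions),
                 imputed = imputed,
                 peptide_counts = stats::setNames(counts, rownames(areas))),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("Normalized LFQ matrix: ", nrow(x$fractions), " proteins x ",
      ncol(x$fractions), " runs (fraction-of-total, peptide-count scaled)\n",
      sep = "")
  cat("  imputed cells: ", sum(x$imputed), "\n", sep = "")
  invisible(x)
}

#' Per-protein, per-group mean and SD of log2 fractions
#'
#' @param norm A [normalize_areas()] result.
#' @param design Design data frame.
#' @return Data frame keyed by (`accession`, `group`) with `mean`, `sd` and
#'   `n` of log2 fractions. Groups with a single run get `NA` SD and are
#'   flagged by `sd_defined = FALSE`.
#' @export
group_summary <- function(norm, design) {
  stopifnot(inherits(norm, "normalized_matrix"))
  runs <- colnames(norm$log2_values)
  if (!setequal(runs, design$run))
    stop_("design table and matrix disagree on run ids")
  design <- design[match(runs, design$run), , drop = FALSE]
  if (any(is.na(design$group))) stop_("unknown group label in design")
  out <- do.call(rbind, lapply(levels(design$group), function(g) {
    idx <- which(design$group == g)
    vals <- norm$log2_values[, idx, drop = FALSE]
    data.frame(accession = rownames(vals), group = g,
               mean = rowMeans(vals),
               sd = if (length(idx) >= 2L) apply(vals, 1L, stats::sd)
                    else NA_real_,
               n = length(idx),
               sd_defined = length(idx) >= 2L,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$group <- factor(out$group, levels = levels(design$group))
  out
}

#' Wide matrix of group means of log2 fractions
#'
#' Convenience reshaping of [group_summary()]: rows are proteins, columns
#' groups (in design order).
#' @inheritParams group_summary
#' @param groups Optional subset/ordering of group labels.
#' @return Numeric matrix of group means.
#' @export
group_mean_matrix <- function(norm, design, groups = NULL) {
  gs <- group_summary(norm, design)
  groups <- groups %||% levels(gs$group)
  acc <- rownames(norm$log2_values)
  m <- sapply(groups, function(g) {
    v <- gs[gs$group == g, ]
    v$mean[match(acc, v$accession)]
  })
  m <- matrix(m, nrow = length(acc), dimnames = list(acc, groups))
  m
}
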