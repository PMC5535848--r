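#' Pipeline configuration
#'
#' Collects every threshold and parameter of the end-to-end analysis with
#' the conventional defaults: unique peptides > 1, presence in >= 1
#' replicate of some group, down-shifted-normal imputation (shift 1.8,
#' width 0.3), raw p < 0.05 contrasts, k = 3 clusters for the injury part
#' and k = 4 for the repair part, trend tolerance 0.05. The master seed
#' fans out to derived per-stage seeds so stages can be rerun
#' independently yet reproducibly.
#'
#' @param groups Ordered group labels; contrasts default to consecutive
#'   pairs. The first three groups form the injury part, the last three
#'   the repair part.
#' @param contrasts Optional list of [contrast_spec()]s.
#' @param alpha Significance level for contrasts and enrichment (default
#'   0.05).
#' @param min_replicates_present,min_unique_peptides Filter thresholds
#'   (see [filter_proteins()]).
#' @param impute_shift,impute_width Imputation parameters (see
#'   [imputation_params()]).
#' @param k_injury,k_repair Cluster counts for the two parts.
#' @param trend_tolerance Relative trend tolerance.
#' @param localization_term Localization term required of candidates.
#' @param digest_mode `"counting"` or `"search"` peptide-count convention.
#' @param seed Master integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(groups = c("Naive", "Sham", "MCAO", "MCAO_DHI"),
                            contrasts = NULL,
                            alpha = 0.05,
                            min_replicates_present = 1L,
                            min_unique_peptides = 2L,
                            impute_shift = 1.8,
                            impute_width = 0.3,
                            k_injury = 3L,
                            k_repair = 4L,
                            trend_tolerance = 0.05,
                            localization_term = "extracellular_region",
                            digest_mode = "counting",
                            seed = 1L) {
  if (length(groups) < 3L)
    stop_("need >= 3 ordered groups for trend analysis")
  if (is.null(contrasts)) {
    contrasts <- lapply(seq_len(length(groups) - 1L), function(i) {
      contrast_spec(groups[i], groups[i + 1L], alpha = alpha)
    })
  }
  structure(list(groups = groups, contrasts = contrasts, alpha = alpha,
                 min_replicates_present = as.integer(min_replicates_present),
                 min_unique_peptides = as.integer(min_unique_peptides),
                 impute_shift = impute_shift, impute_width = impute_width,
                 k_injury = as.integer(k_injury),
                 k_repair = as.integer(k_repair),
                 trend_tolerance = trend_tolerance,
                 localization_term = localization_term,
                 digest_mode = digest_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full LFQ candidate-selection pipeline
#'
#' Executes, in order: theoretical-peptide counting of the proteome,
#' presence/unique-peptide filtering, left-censored imputation,
#' peptide-count + fraction-of-total normalization, per-protein pairwise
#' contrasts, trend classification and clustering over the injury
#' (first three groups) and repair (last three groups) parts, offline
#' hypergeometric enrichment of each part against the pathway fixture,
#' common-pathway intersection, the conjunctive candidate funnel, and
#' (when a validation table is supplied) orthogonal-trend concordance.
#' Identical inputs and seed give identical outputs.
#'
#' @param x An [area_matrix()], or a `synthetic_bundle` from
#'   [generate_bundle()] (which supplies everything else).
#' @param design Run design data frame (ignored for bundles).
#' @param proteome Named sequence vector (ignored for bundles).
#' @param cc_terms,kegg_terms [annotation_terms()] namespaces (ignored for
#'   bundles).
#' @param config A [pipeline_config()].
#' @param wb Optional [read_wb_tsv()] table for concordance scoring.
#' @param out_dir Optional directory; when given, TSV/JSON outputs are
#'   written there.
#' @return An object of class `lfq_run` holding every stage result plus a
#'   stage-count ledger (`report`).
#' @export
run_all <- function(x, design = NULL, proteome = NULL, cc_terms = NULL,
                    kegg_terms = NULL, config = pipeline_config(),
                    wb = NULL, out_dir = NULL) {
  if (inherits(x, "synthetic_bundle")) {
    design <- x$design
    proteome <- x$proteome
    cc_terms <- x$annotations$cc
    kegg_terms <- x$annotations$kegg
    bundle <- x
    x <- x$matrix
  } else bundle <- NULL
  stopifnot(inherits(x, "area_matrix"), inherits(config, "pipeline_config"))
  if (is.null(design) || is.null(proteome))
    stop_("design and proteome are required")
  ledger <- list(input_proteins = nrow(x$areas))

  pep <- count_theoretical_peptides(proteome, mode = config$digest_mode)
  filtered <- filter_proteins(x, design,
                              min_replicates_present =
                                config$min_replicates_present,
                              min_unique_peptides =
                                config$min_unique_peptides)
  ledger$dropped_filter <- nrow(attr(filtered, "dropped"))
  ledger$retained <- nrow(filtered$areas)

  imputed <- impute_missing(filtered,
                            imputation_params(shift = config$impute_shift,
                                              width = config$impute_width,
                                              seed = derive_seed(config$seed,
                                                                 "impute")))
  ledger$imputed_cells <- sum(imputed$imputed)

  norm <- normalize_areas(imputed, pep)
  ledger$normalized <- nrow(norm$fractions)

  results <- lapply(config$contrasts, function(sp) {
    t_test_contrast(norm, design, sp)
  })
  names(results) <- vapply(config$contrasts, `[[`, character(1), "name")
  sig <- significant_union(results)
  ledger$significant_per_contrast <- sig$per_contrast
  ledger$significant_union <- length(sig$union)

  groups <- config$groups
  inj_groups <- groups[1:3]
  rep_groups <- groups[(length(groups) - 2L):length(groups)]
  means_inj <- group_mean_matrix(norm, design, inj_groups)
  means_rep <- group_mean_matrix(norm, design, rep_groups)

  part_selection <- function(mean_mat, part_contrasts, wanted) {
    sig_part <- rowSums(sig$membership[, part_contrasts, drop = FALSE]) > 0
    acc <- rownames(sig$membership)[sig_part]
    labels <- apply(mean_mat[acc, , drop = FALSE], 1L, classify_trend,
                    tolerance = config$trend_tolerance)
    acc[labels %in% wanted]
  }
  n_contr <- length(config$contrasts)
  inj_contrasts <- names(results)[1:min(2L, n_contr)]
  rep_contrasts <- names(results)[max(1L, n_contr - 1L):n_contr]
  sel_inj <- part_selection(means_inj, inj_contrasts, c("up", "down"))
  sel_rep <- part_selection(means_rep, rep_contrasts,
                            c("up_down", "down_up"))
  ledger$selected_injury <- length(sel_inj)
  ledger$selected_repair <- length(sel_rep)

  cluster_part <- function(mean_mat, selection, k, stage) {
    if (length(selection) < max(k, 2L)) return(NULL)
    params <- clustering_params(k = k,
                                trend_tolerance = config$trend_tolerance,
                                seed = derive_seed(config$seed, stage))
    prof <- mean_mat[selection, , drop = FALSE]
    hc <- hierarchical_cluster(pearson_distance(prof), k = k)
    km <- kmeans_trends(prof, params)
    list(profiles = trend_profiles(prof, params, run_kmeans = FALSE),
         hierarchical = hc$clusters, kmeans = km$labels)
  }
  clust_inj <- suppressWarnings(
    cluster_part(means_inj, sel_inj, config$k_injury, "cluster_injury"))
  clust_rep <- suppressWarnings(
    cluster_part(means_rep, sel_rep, config$k_repair, "cluster_repair"))

  # enrichment universe per part: the common overlapping proteins, i.e.
  # those observed (pre-imputation) in at least one run of every group of
  # the part; selections are intersected with their universe
  obs <- !is.na(filtered$areas)
  obs <- obs[intersect(rownames(obs), rownames(norm$fractions)), ,
             drop = FALSE]
  part_background <- function(part_groups) {
    ok <- rep(TRUE, nrow(obs))
    for (g in part_groups) {
      runs_g <- design$run[design$group == g]
      ok <- ok & rowSums(obs[, runs_g, drop = FALSE]) >= 1L
    }
    rownames(obs)[ok]
  }
  bg_inj <- part_background(inj_groups)
  bg_rep <- part_background(rep_groups)
  ledger$background_injury <- length(bg_inj)
  ledger$background_repair <- length(bg_rep)
  enr <- list()
  if (!is.null(kegg_terms)) {
    enr$kegg_injury <- enrich(intersect(sel_inj, bg_inj), bg_inj,
                              kegg_terms)
    enr$kegg_repair <- enrich(intersect(sel_rep, bg_rep), bg_rep,
                              kegg_terms)
    common <- suppressWarnings(
      common_pathways(enr$kegg_injury, enr$kegg_repair,
                      alpha = config$alpha))
  } else common <- character(0)
  if (!is.null(cc_terms)) {
    enr$cc_injury <- enrich(intersect(sel_inj, bg_inj), bg_inj, cc_terms)
  }
  ledger$common_pathways <- length(common)

  trends <- data.frame(
    accession = rownames(norm$fractions),
    injury_trend = apply(means_inj, 1L, classify_trend,
                         tolerance = config$trend_tolerance),
    repair_trend = apply(means_rep, 1L, classify_trend,
                         tolerance = config$trend_tolerance),
    stringsAsFactors = FALSE, row.names = NULL)

  funnel <- if (!is.null(cc_terms) && !is.null(kegg_terms)) {
    candidate_funnel(sig, trends, cc_terms, kegg_terms, common,
                     localization_term = config$localization_term)
  } else NULL
  cand <- if (!is.null(funnel)) candidates(funnel) else character(0)
  ledger$candidates <- length(cand)

  conc <- NULL
  if (!is.null(wb)) {
    lf <- means_rep
    conc <- wb_concordance(wb, lf_means = lf,
                           tolerance = config$trend_tolerance)
  }

  run <- structure(list(config = config, design = design,
                        peptide_counts = pep, filtered = filtered,
                        normalized = norm, contrasts = results,
                        significant = sig,
                        group_means = list(injury = means_inj,
                                           repair = means_rep),
                        clusters = list(injury = clust_inj,
                                        repair = clust_rep),
                        selections = list(injury = sel_inj,
                                          repair = sel_rep),
                        enrichment = enr, common_pathways = common,
                        trends = trends, funnel = funnel,
                        candidates = cand, concordance = conc,
                        truth = if (!is.null(bundle)) bundle$truth,
                        report = ledger),
                   class = "lfq_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

check_ledger <- function(run) {
  l <- run$report
  ok <- l$input_proteins == l$retained + l$dropped_filter &&
    l$normalized <= l$retained &&
    l$significant_union <= l$normalized &&
    l$selected_injury <= l$significant_union &&
    l$selected_repair <= l$significant_union &&
    l$candidates <= l$significant_union
  isTRUE(ok)
}

#' @export
print.lfq_run <- function(x, ...) {
  l <- x$report
  cat("LFQ candidate-selection run\n")
  cat("  input proteins:        ", l$input_proteins, "\n")
  cat("  retained after filter: ", l$retained, " (", l$dropped_filter,
      " dropped)\n", sep = "")
  cat("  imputed cells:         ", l$imputed_cells, "\n")
  cat("  significant union:     ", l$significant_union, " (",
      paste(names(l$significant_per_contrast),
            l$significant_per_contrast, sep = ": ", collapse = ", "),
      ")\n", sep = "")
  cat("  part selections:       injury ", l$selected_injury, ", repair ",
      l$selected_repair, "\n", sep = "")
  cat("  common pathways:       ", l$common_pathways, "\n")
  cat("  candidates:            ", l$candidates, "\n")
  if (!is.null(x$concordance))
    cat("  WB concordant trends:  ", x$concordance$n_concordant, "/",
        x$concordance$n_compared, "\n", sep = "")
  invisible(x)
}

#' @export
summary.lfq_run <- function(object, ...) {
  print(object)
  if (length(object$common_pathways))
    cat("\nCommon pathways: ",
        paste(object$common_pathways, collapse = ", "), "\n", sep = "")
  if (length(object$candidates)) {
    cat("\nCandidates:\n")
    print(object$funnel[object$funnel$passes_funnel,
                        c("accession", "n_significant_contrasts",
                          "injury_trend", "repair_trend", "pathways")],
          row.names = FALSE)
  }
  invisible(object)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(run$contrasts)) {
    utils::write.table(run$contrasts[[nm]],
                       file.path(dir, paste0("contrast_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in names(run$enrichment)) {
    utils::write.table(run$enrichment[[nm]],
                       file.path(dir, paste0("enrichment_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$funnel))
    utils::write.table(run$funnel, file.path(dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$trends, file.path(dir, "trends.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(run$report,
      list(common_pathways = run$common_pathways,
           candidates = run$candidates,
           ledger_consistent = check_ledger(run))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
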