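#' Hypergeometric term enrichment against an offline annotation set
#'
#' For each term, tests over-representation of the selected proteins among
#' the background with the upper-tail hypergeometric probability
#' P(X >= k) where k = |selected & term|, K = |background & term|,
#' n = |selected|, N = |background|, then applies Benjamini-Hochberg
#' adjustment within the namespace. Annotation fixtures are user-supplied
#' GMT files; results are only as current as the fixture.
#'
#' @param selected Character vector of selected accessions (must be a
#'   subset of `background`).
#' @param background Character vector: the enrichment universe, typically
#'   the proteins quantified in all groups of the analysis part.
#' @param terms An [annotation_terms()] object.
#' @return Data frame of class `enrichment_table`, one row per term, sorted
#'   by `p_hyper`: `term_id`, `namespace`, `k`, `K`, `n`, `N`, `p_hyper`,
#'   `q_bh`.
#' @export
enrich <- function(selected, background, terms) {
  stopifnot(inherits(terms, "annotation_terms"))
  selected <- unique(selected)
  background <- unique(background)
  if (length(background) == 0L) stop_("background must be nonempty")
  outside <- setdiff(selected, background)
  if (length(outside))
    stop_("selected proteins outside the background: ",
          paste(utils::head(outside, 5), collapse = ", "),
          if (length(outside) > 5) " ...")
  n <- length(selected)
  N <- length(background)
  rows <- lapply(names(terms), function(id) {
    members <- intersect(terms[[id]], background)
    K <- length(members)
    k <- length(intersect(selected, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, namespace = attr(terms, "namespace"),
               k = k, K = K, n = n, N = N, p_hyper = p,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(0), namespace = character(0),
               k = integer(0), K = integer(0), n = integer(0),
               N = integer(0), p_hyper = numeric(0))
  out$q_bh <- stats::p.adjust(out$p_hyper, method = "BH")
  out <- out[order(out$p_hyper), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Pathways enriched in both analysis parts
#'
#' Intersects two enrichment tables over the same pathway namespace,
#' keeping terms with raw `p_hyper` below `alpha` in both (raw p drives
#' pathway selection; BH-adjusted values are reported alongside).
#'
#' @param part_one,part_two [enrich()] results over the same namespace.
#' @param alpha Raw-p threshold (default 0.05).
#' @return Character vector of common term ids (possibly empty, with a
#'   warning, in which case the candidate funnel returns no candidates).
#' @export
common_pathways <- function(part_one, part_two, alpha = 0.05) {
  stopifnot(inherits(part_one, "enrichment_table"),
            inherits(part_two, "enrichment_table"))
  ns1 <- unique(part_one$namespace)
  ns2 <- unique(part_two$namespace)
  if (length(ns1) && length(ns2) && !identical(ns1, ns2))
    stop_("enrichment tables are over different namespaces: ",
          ns1, " vs ", ns2)
  hits <- intersect(part_one$term_id[part_one$p_hyper < alpha],
                    part_two$term_id[part_two$p_hyper < alpha])
  if (length(hits) == 0L)
    warn_("no pathway enriched in both parts; funnel will be empty")
  hits
}

#' Candidate-protein funnel
#'
#' Applies the conjunctive selection rule: a protein is a candidate iff it
#' (1) is significant in at least one contrast, (2) shows a qualifying
#' expression trend -- monotone (`up`/`down`) across the injury part or
#' biphasic (`up_down`/`down_up`) across the repair part, (3) is annotated
#' to the extracellular-region localization term, and (4) belongs to at
#' least one pathway enriched in both parts.
#'
#' @param sig A [significant_union()] result.
#' @param trends Data frame with `accession` and trend labels
#'   `injury_trend` and/or `repair_trend` (either may be absent or NA).
#' @param cc_terms [annotation_terms()] holding the localization namespace;
#'   must contain `localization_term`.
#' @param kegg_terms [annotation_terms()] holding the pathway namespace.
#' @param common Character vector from [common_pathways()].
#' @param localization_term Term id required of candidates
#'   (default `"extracellular_region"`).
#' @return Data frame of class `candidate_table`, one row per protein in
#'   the tested universe, with the per-criterion flags and `passes_funnel`.
#' @export
candidate_funnel <- function(sig, trends, cc_terms, kegg_terms, common,
                             localization_term = "extracellular_region") {
  stopifnot(inherits(cc_terms, "annotation_terms"),
            inherits(kegg_terms, "annotation_terms"))
  if (!localization_term %in% names(cc_terms))
    stop_("localization term '", localization_term,
          "' missing from the annotation namespace")
  acc <- rownames(sig$membership)
  n_sig <- rowSums(sig$membership)
  inj <- trends$injury_trend[match(acc, trends$accession)] %||%
    rep(NA_character_, length(acc))
  rep_ <- trends$repair_trend[match(acc, trends$accession)] %||%
    rep(NA_character_, length(acc))
  trend_ok <- (!is.na(inj) & inj %in% c("up", "down")) |
    (!is.na(rep_) & rep_ %in% c("up_down", "down_up"))
  in_cc <- acc %in% cc_terms[[localization_term]]
  kegg_common <- unique(unlist(unclass(kegg_terms)[intersect(common,
                                                   names(kegg_terms))]))
  pathways <- vapply(acc, function(a) {
    paste(names(kegg_terms)[vapply(unclass(kegg_terms),
                                   function(m) a %in% m, logical(1))],
          collapse = ";")
  }, character(1))
  in_common <- acc %in% kegg_common
  out <- data.frame(accession = acc,
                    n_significant_contrasts = n_sig,
                    injury_trend = inj,
                    repair_trend = rep_,
                    qualifying_trend = trend_ok,
                    in_extracellular_region = in_cc,
                    pathways = unname(pathways),
                    in_common_pathway = in_common,
                    passes_funnel = n_sig > 0 & trend_ok & in_cc & in_common,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("candidate_table", class(out))
  out
}

#' Candidate accessions passing the funnel
#' @param candidates A [candidate_funnel()] result.
#' @return Character vector of candidate accessions.
#' @export
candidates <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_table"))
  candidates$accession[candidates$passes_funnel]
}

#' Read an orthogonal-validation (Western-blot style) mean table
#'
#' TSV with header columns `protein`, `group`, `mean`, `sd` and optional
#' `n_replicates` (default 5), holding relative densitometric levels per
#' protein and group.
#'
#' @param path TSV path.
#' @param groups Expected ordered group labels; every protein must have a
#'   complete set.
#' @return Data frame of class `wb_table`.
#' @export
read_wb_tsv <- function(path, groups = c("Sham", "MCAO", "DHI")) {
  if (!file.exists(path)) stop_("WB table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "group", "mean", "sd")
  if (!all(need %in% names(df)))
    stop_("WB table must have columns: ", paste(need, collapse = ", "))
  if (!"n_replicates" %in% names(df)) df$n_replicates <- 5L
  if (any(df$mean < 0)) stop_("negative WB means")
  bad <- names(which(table(df$protein) != length(groups)))
  if (length(bad))
    stop_("incomplete group set for protein(s): ",
          paste(bad, collapse = ", "))
  df$group <- factor(df$group, levels = groups)
  if (any(is.na(df$group))) stop_("unexpected group label in WB table")
  class(df) <- c("wb_table", class(df))
  df
}

#' Concordance between orthogonal validation and label-free trends
#'
#' Applies [classify_trend()] to each protein's orthogonal-validation
#' (e.g. Western blot) mean triple and to its label-free group-mean triple
#' over the same ordered groups; a protein is concordant when the two
#' trend labels agree. Also reports the count of proteins whose middle
#' (MCAO) validation mean strictly exceeds both flanking group means.
#'
#' @param wb A [read_wb_tsv()] table.
#' @param lf_means Numeric matrix of label-free group means: rows named by
#'   protein, 3 ordered group columns matching the WB groups. May cover a
#'   subset; unmapped proteins are listed and excluded from concordance
#'   counts.
#' @param tolerance Relative trend tolerance (see [classify_trend()]).
#' @return List with per-protein data frame `proteins` (WB trend, LF
#'   trend, `concordant`), `n_concordant`, `n_compared`,
#'   `n_mcao_elevated` (computed over the full WB table) and `unmapped`.
#' @export
wb_concordance <- function(wb, lf_means = NULL, tolerance = 0.05) {
  stopifnot(inherits(wb, "wb_table"))
  groups <- levels(wb$group)
  prot <- unique(wb$protein)
  wb_mat <- t(vapply(prot, function(p) {
    v <- wb[wb$protein == p, ]
    v$mean[match(groups, v$group)]
  }, numeric(length(groups))))
  rownames(wb_mat) <- prot
  wb_trend <- apply(wb_mat, 1L, classify_trend, tolerance = tolerance)
  elevated <- wb_mat[, 2] > wb_mat[, 1] & wb_mat[, 2] > wb_mat[, 3]
  unmapped <- character(0)
  res <- data.frame(protein = prot, wb_trend = unname(wb_trend),
                    mcao_elevated = unname(elevated),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(lf_means)) {
    unmapped <- setdiff(prot, rownames(lf_means))
    if (length(unmapped))
      warn_("protein(s) without label-free means excluded: ",
            paste(unmapped, collapse = ", "))
    res$lf_trend <- NA_character_
    mapped <- setdiff(prot, unmapped)
    res$lf_trend[match(mapped, res$protein)] <-
      apply(lf_means[mapped, , drop = FALSE], 1L, classify_trend,
            tolerance = tolerance)
    res$concordant <- res$wb_trend == res$lf_trend
  }
  list(proteins = res,
       n_concordant = if (!is.null(lf_means))
         sum(res$concordant, na.rm = TRUE) else NA_integer_,
       n_compared = if (!is.null(lf_means))
         sum(!is.na(res$lf_trend)) else 0L,
       n_mcao_elevated = sum(elevated),
       unmapped = unmapped)
}
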