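#' Configuration for the synthetic fixture generator
#'
#' Describes a designed LFQ experiment at desk scale: a 4-group (ischaemia
#' injury/repair style) by 3-replicate design of ~3,000 proteins with
#' log-normal abundances, planted group effects in three consecutive
#' contrasts, intensity-dependent (left-censored) missingness, and
#' annotation fixtures carrying an extracellular-region localization term
#' and WNT/MAPK/AMPK-style pathway terms.
#'
#' @param n_proteins Number of proteins (default 3000).
#' @param groups Ordered group labels (default Naive, Sham, MCAO,
#'   MCAO_DHI).
#' @param replicates_per_group Biological replicates per group (default 3).
#' @param base_log2_abundance_mean,base_log2_abundance_sd Mean and SD of
#'   the per-protein baseline log2 abundance (default 20 and 2, i.e. a
#'   log-normal abundance spanning several orders of magnitude).
#' @param replicate_log2_sd Within-group replicate noise on the log2 scale
#'   (default 0.3).
#' @param de_fraction_per_contrast Fraction of proteins planted as
#'   differential per contrast (default 0.04).
#' @param effect_log2 Planted shift size in log2 units (default 1).
#' @param censor_quantile Per-run fraction of lowest-intensity observations
#'   recorded missing (default 0.05); must be < 1.
#' @param annotation_term_count Number of background (decoy) terms per
#'   annotation namespace (default 10).
#' @param term_size_range Size range of background terms (default
#'   c(20, 100)); must not exceed `n_proteins`.
#' @param background_annotation_rate Probability that a background protein
#'   is annotated to each named term, independent of the planted truth
#'   (default 0.02).
#' @param kr_density Total K+R frequency of generated sequences (default
#'   0.11, near natural abundance); 0 yields cleavage-free sequences.
#' @param seed Integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 3000L,
                             groups = c("Naive", "Sham", "MCAO", "MCAO_DHI"),
                             replicates_per_group = 3L,
                             base_log2_abundance_mean = 20,
                             base_log2_abundance_sd = 2,
                             replicate_log2_sd = 0.3,
                             de_fraction_per_contrast = 0.04,
                             effect_log2 = 1,
                             censor_quantile = 0.05,
                             annotation_term_count = 10L,
                             term_size_range = c(20L, 100L),
                             background_annotation_rate = 0.02,
                             kr_density = 0.11,
                             seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  if (is.na(n_proteins) || n_proteins < 1L)
    stop_("n_proteins must be >= 1")
  if (length(groups) < 2L) stop_("need >= 2 groups")
  if (anyDuplicated(groups)) stop_("group labels must be unique")
  replicates_per_group <- as.integer(replicates_per_group)
  if (replicates_per_group < 1L) stop_("replicates_per_group must be >= 1")
  for (p in c(de_fraction_per_contrast, censor_quantile,
              background_annotation_rate, kr_density)) {
    if (!is.numeric(p) || p < 0 || p > 1)
      stop_("proportions must lie in [0, 1]")
  }
  if (replicate_log2_sd < 0 || base_log2_abundance_sd < 0)
    stop_("standard deviations must be >= 0")
  if (length(term_size_range) != 2L ||
      term_size_range[1] > term_size_range[2])
    stop_("term_size_range must be an increasing pair")
  if (term_size_range[2] > n_proteins)
    stop_("term_size_range exceeds n_proteins")
  structure(list(n_proteins = n_proteins, groups = groups,
                 replicates_per_group = replicates_per_group,
                 base_log2_abundance_mean = base_log2_abundance_mean,
                 base_log2_abundance_sd = base_log2_abundance_sd,
                 replicate_log2_sd = replicate_log2_sd,
                 de_fraction_per_contrast = de_fraction_per_contrast,
                 effect_log2 = effect_log2,
                 censor_quantile = censor_quantile,
                 annotation_term_count = as.integer(annotation_term_count),
                 term_size_range = as.integer(term_size_range),
                 background_annotation_rate = background_annotation_rate,
                 kr_density = kr_density,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a random proteome
#'
#' Random amino-acid sequences over the 20-letter alphabet with lengths
#' uniform on 50--600 and a controllable K/R density, so theoretical
#' tryptic peptide counts vary across proteins. Deterministic under the
#' configured seed.
#'
#' @param config A [synthetic_config()].
#' @return Named character vector of sequences (accessions `SYNP0001`, ...).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_proteins
  other <- setdiff(AA_ALPHABET20, c("K", "R"))
  probs <- c(rep(config$kr_density / 2, 2),
             rep((1 - config$kr_density) / length(other), length(other)))
  letters20 <- c("K", "R", other)
  with_seed(derive_seed(config$seed, "proteome"), {
    lens <- sample(50:600, n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(letters20, L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(seqs) <- sprintf("SYNP%04d", seq_len(n))
    seqs
  })
}

# Planted design: three consecutive contrasts over the ordered groups.
# Per-protein log2 offsets by class (e = effect_log2), over the 4 groups:
#   injury_up    (0,  e, 2e, 2e)   monotone rise through the injury part
#   injury_down  (0, -e,-2e,-2e)
#   cand_up      (0,  e, 2e,  0)   spike: rises into MCAO, reverts on DHI
#   cand_down    (0, -e,-2e,  0)
#   dhi_up       (0,  0,  0,  e)   treatment-only shift
#   dhi_down     (0,  0,  0, -e)
# Candidates are the spike classes: differential in contrasts 2 and 3,
# monotone across the injury part and biphasic across the repair part.
plant_offsets <- function(class, e) {
  switch(class,
         injury_up = c(0, e, 2 * e, 2 * e),
         injury_down = -c(0, e, 2 * e, 2 * e),
         cand_up = c(0, e, 2 * e, 0),
         cand_down = -c(0, e, 2 * e, 0),
         dhi_up = c(0, 0, 0, e),
         dhi_down = c(0, 0, 0, -e),
         c(0, 0, 0, 0))
}

assign_planted <- function(config, eligible) {
  n_de <- round(config$de_fraction_per_contrast * config$n_proteins)
  n_de <- min(n_de, floor(length(eligible) / 3))
  half <- function(m) 2L * (m %/% 2L)
  n_inj <- half(n_de)
  n_cand <- half(max(0, round(0.2 * n_de)))
  n_dhi <- half(n_de - n_cand)
  pool <- eligible
  take <- function(m) {
    out <- pool[seq_len(m)]
    pool <<- pool[-seq_len(m)]
    out
  }
  classes <- stats::setNames(rep("null", config$n_proteins), names(eligible))
  res <- list()
  if (n_inj >= 2L) {
    s <- take(n_inj)
    res$injury_up <- s[seq_len(n_inj / 2)]
    res$injury_down <- s[n_inj / 2 + seq_len(n_inj / 2)]
  }
  if (n_cand >= 2L) {
    s <- take(n_cand)
    res$cand_up <- s[seq_len(n_cand / 2)]
    res$cand_down <- s[n_cand / 2 + seq_len(n_cand / 2)]
  }
  if (n_dhi >= 2L) {
    s <- take(n_dhi)
    res$dhi_up <- s[seq_len(n_dhi / 2)]
    res$dhi_down <- s[n_dhi / 2 + seq_len(n_dhi / 2)]
  }
  res
}

#' Generate the precursor-area matrix with planted ground truth
#'
#' Per protein, the latent log2 abundance in each run is a baseline draw
#' plus the planted class offset for the run's group plus replicate noise;
#' the linear-scale area couples abundance to the protein's theoretical
#' peptide count (area = 2^log2 x count), so peptide-count normalization is
#' exactly invertible on noise-free data. Entries whose latent intensity
#' falls below the run's `censor_quantile` are recorded missing
#' (left-censoring: the missingness is purely intensity-dependent).
#'
#' @param config A [synthetic_config()].
#' @param proteome A [generate_proteome()] result (or any named sequence
#'   set).
#' @return List with `matrix` (an [area_matrix()] with unique-peptide
#'   counts), `design` (run design data frame) and `truth` (a
#'   `synthetic_truth` object: planted up/down sets per contrast,
#'   `planted_candidates`, per-run censor thresholds, the seed).
#' @export
generate_area_matrix <- function(config, proteome) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(proteome) == 0L) stop_("proteome must be nonempty")
  if (config$censor_quantile >= 1)
    stop_("censor_quantile = 1 would censor every observation")
  n <- length(proteome)
  groups <- config$groups
  reps <- config$replicates_per_group
  runs <- as.vector(outer(seq_len(reps), groups,
                          function(r, g) paste0(g, "_R", r)))
  run_group <- rep(groups, each = reps)
  design <- data.frame(run = runs,
                       group = factor(run_group, levels = groups),
                       replicate = rep(seq_len(reps), times = length(groups)),
                       stringsAsFactors = FALSE)
  pep <- count_theoretical_peptides(proteome)
  counts <- stats::setNames(pep$n_theoretical_peptides, pep$accession)

  res <- with_seed(derive_seed(config$seed, "areas"), {
    # unique identifying peptides: tied loosely to digestibility
    up <- pmin(pmax(counts, 1L), 1L + stats::rpois(n, lambda = 4))
    up <- pmax(up, ifelse(counts >= 2L,
                          stats::rbinom(n, 1L, 0.9) + 1L, 1L))
    eligible <- proteome[counts >= 1L & up >= 2L]
    eligible <- eligible[sample(length(eligible))]
    planted <- assign_planted(config, eligible)

    base <- stats::rnorm(n, config$base_log2_abundance_mean,
                         config$base_log2_abundance_sd)
    offsets <- matrix(0, n, length(groups),
                      dimnames = list(names(proteome), groups))
    for (cls in names(planted)) {
      offsets[names(planted[[cls]]), ] <-
        matrix(plant_offsets(cls, config$effect_log2),
               nrow = length(planted[[cls]]), ncol = length(groups),
               byrow = TRUE)
    }
    latent <- base + offsets[, match(run_group, groups), drop = FALSE] +
      matrix(stats::rnorm(n * length(runs), 0, config$replicate_log2_sd),
             n, length(runs))
    colnames(latent) <- runs
    areas <- 2^latent * pmax(counts, 1L)

    thresholds <- apply(log2(areas), 2L, stats::quantile,
                        probs = config$censor_quantile, names = FALSE)
    if (config$censor_quantile > 0) {
      for (j in seq_along(runs)) {
        areas[log2(areas[, j]) < thresholds[j], j] <- NA_real_
      }
    }
    if (all(is.na(areas))) stop_("censoring removed every observation")
    list(areas = areas, up = up, planted = planted, thresholds = thresholds)
  })

  cand <- unname(c(names(res$planted$cand_up), names(res$planted$cand_down)))
  nm <- function(x) unname(names(x)) %||% character(0)
  truth <- structure(list(
    planted_up = list(
      c1 = c(nm(res$planted$injury_up), nm(res$planted$cand_up)),
      c2 = c(nm(res$planted$injury_up), nm(res$planted$cand_up)),
      c3 = c(nm(res$planted$dhi_up), nm(res$planted$cand_down))),
    planted_down = list(
      c1 = c(nm(res$planted$injury_down), nm(res$planted$cand_down)),
      c2 = c(nm(res$planted$injury_down), nm(res$planted$cand_down)),
      c3 = c(nm(res$planted$dhi_down), nm(res$planted$cand_up))),
    planted_candidates = cand,
    planted_classes = lapply(res$planted, function(x) unname(names(x))),
    censor_threshold_per_run = stats::setNames(res$thresholds, runs),
    seed = config$seed), class = "synthetic_truth")

  list(matrix = area_matrix(res$areas,
                            unique_peptides = stats::setNames(res$up, NULL)),
       design = design, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth (seed ", x$seed, ")\n", sep = "")
  for (ct in names(x$planted_up)) {
    cat("  ", ct, ": ", length(x$planted_up[[ct]]), " up, ",
        length(x$planted_down[[ct]]), " down\n", sep = "")
  }
  cat("  planted candidates: ", length(x$planted_candidates), "\n", sep = "")
  invisible(x)
}

#' Generate annotation fixtures with planted memberships
#'
#' Emits a GO-CC style namespace with one `extracellular_region` term and a
#' KEGG style namespace with `WNT`, `MAPK` and `AMPK` pathway terms. Every
#' planted candidate is a member of `extracellular_region` and of at least
#' one of the three pathways; background memberships of the named terms are
#' assigned at `background_annotation_rate`, independent of the truth.
#' Each namespace additionally carries `annotation_term_count` background
#' terms with sizes drawn from `term_size_range`.
#'
#' @param config A [synthetic_config()].
#' @param proteome Named sequence set (accession universe).
#' @param truth The `synthetic_truth` from [generate_area_matrix()].
#' @return List with [annotation_terms()] elements `cc` and `kegg`.
#' @export
generate_annotations <- function(config, proteome, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  acc <- names(proteome)
  cand <- truth$planted_candidates
  rate <- config$background_annotation_rate
  with_seed(derive_seed(config$seed, "annotations"), {
    bg_members <- function(exclude) {
      pool <- setdiff(acc, exclude)
      pool[stats::runif(length(pool)) < rate]
    }
    cc <- list(extracellular_region = c(cand, bg_members(cand)))
    pathways <- c("WNT", "MAPK", "AMPK")
    primary <- if (length(cand)) {
      stats::setNames(pathways[(seq_along(cand) - 1L) %% 3L + 1L], cand)
    } else character(0)
    kegg <- lapply(pathways, function(pw) {
      planted <- names(primary)[primary == pw]
      extra <- cand[stats::runif(length(cand)) < 0.2]
      c(union(planted, extra), bg_members(cand))
    })
    names(kegg) <- pathways
    add_decoys <- function(lst, prefix) {
      for (i in seq_len(config$annotation_term_count)) {
        size <- sample(config$term_size_range[1]:config$term_size_range[2],
                       1L)
        lst[[sprintf("%s%02d", prefix, i)]] <- sample(acc, size)
      }
      lst
    }
    cc <- add_decoys(cc, "CC_TERM")
    kegg <- add_decoys(kegg, "PATHWAY")
    drop_empty <- function(lst) lst[vapply(lst, length, integer(1)) > 0L]
    list(cc = annotation_terms(drop_empty(cc), namespace = "GO-CC"),
         kegg = annotation_terms(drop_empty(kegg), namespace = "KEGG"))
  })
}

#' Generate and optionally write a complete fixture bundle
#'
#' Runs [generate_proteome()], [generate_area_matrix()] and
#' [generate_annotations()] under one configuration and, when `dir` is
#' given, writes the FASTA, area TSV, design TSV, GMT pair and a JSON
#' truth file into it. Identical config and seed give byte-identical
#' files.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory (created if needed).
#' @return List of class `synthetic_bundle`: `config`, `proteome`,
#'   `matrix`, `design`, `truth`, `annotations`, and `paths` when written.
#' @export
generate_bundle <- function(config = synthetic_config(), dir = NULL) {
  proteome <- generate_proteome(config)
  gm <- generate_area_matrix(config, proteome)
  ann <- generate_annotations(config, proteome, gm$truth)
  bundle <- structure(list(config = config, proteome = proteome,
                           matrix = gm$matrix, design = gm$design,
                           truth = gm$truth, annotations = ann),
                      class = "synthetic_bundle")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "proteome.fasta"),
                  areas = file.path(dir, "areas.tsv"),
                  design = file.path(dir, "design.tsv"),
                  cc = file.path(dir, "go_cc.gmt"),
                  kegg = file.path(dir, "kegg.gmt"),
                  truth = file.path(dir, "truth.json"))
    write_fasta(proteome, paths$fasta)
    write_area_tsv(gm$matrix, paths$areas)
    write_design_tsv(gm$design, paths$design)
    write_gmt(ann$cc, paths$cc)
    write_gmt(ann$kegg, paths$kegg)
    jsonlite::write_json(
      list(planted_up = gm$truth$planted_up,
           planted_down = gm$truth$planted_down,
           planted_candidates = gm$truth$planted_candidates,
           censor_threshold_per_run =
             as.list(gm$truth$censor_threshold_per_run),
           seed = gm$truth$seed),
      paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    bundle$paths <- paths
  }
  bundle
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic LFQ fixture bundle: ", length(x$proteome), " proteins, ",
      nrow(x$design), " runs (", length(levels(x$design$group)),
      " groups x ", x$config$replicates_per_group, " replicates)\n",
      sep = "")
  print(x$truth)
  invisible(x)
}
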