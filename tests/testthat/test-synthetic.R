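test_that("fixture bundles are byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_proteins = 120, seed = 5)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  generate_bundle(cfg, dir = d1)
  generate_bundle(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("proteome generation honours K/R density and the config contract", {
  cfg0 <- synthetic_config(n_proteins = 30, kr_density = 0,
                           term_size_range = c(2L, 10L), seed = 2)
  prot <- generate_proteome(cfg0)
  expect_false(any(grepl("[KR]", prot)))
  # without cleavage sites each chain yields at most one peptide
  counts <- count_theoretical_peptides(prot, mode = "search")
  expect_true(all(counts$n_theoretical_peptides <= 1L))

  # default density spreads digest counts over many distinct values
  cfg <- synthetic_config(n_proteins = 400, seed = 2)
  tab <- count_theoretical_peptides(generate_proteome(cfg))
  expect_gte(length(unique(tab$n_theoretical_peptides)), 10L)

  expect_error(synthetic_config(n_proteins = 0), "n_proteins")
  expect_error(synthetic_config(censor_quantile = 1.2), "proportions")
  expect_error(synthetic_config(n_proteins = 50,
                                term_size_range = c(10, 100)),
               "term_size_range")
})

test_that("censoring is left-censoring against the recorded run thresholds", {
  cfg <- synthetic_config(n_proteins = 200, censor_quantile = 0.15, seed = 9)
  gm <- generate_area_matrix(cfg, generate_proteome(cfg))
  areas <- gm$matrix$areas
  thr <- gm$truth$censor_threshold_per_run
  for (j in colnames(areas)) {
    obs <- log2(areas[!is.na(areas[, j]), j])
    expect_true(all(obs >= thr[[j]]))
  }
  miss_frac <- mean(is.na(areas))
  expect_equal(miss_frac, 0.15, tolerance = 0.15)

  # censor_quantile 0 leaves a complete matrix
  cfg0 <- synthetic_config(n_proteins = 100, censor_quantile = 0, seed = 9)
  gm0 <- generate_area_matrix(cfg0, generate_proteome(cfg0))
  expect_false(anyNA(gm0$matrix$areas))

  expect_error(generate_area_matrix(
    synthetic_config(n_proteins = 100, censor_quantile = 1, seed = 1),
    generate_proteome(cfg0)), "censor")
})

test_that("planted truth sets obey their structural invariants", {
  cfg <- synthetic_config(n_proteins = 600, seed = 13)
  gm <- generate_area_matrix(cfg, generate_proteome(cfg))
  truth <- gm$truth
  for (ct in names(truth$planted_up)) {
    expect_length(intersect(truth$planted_up[[ct]],
                            truth$planted_down[[ct]]), 0)
  }
  all_planted <- unique(c(unlist(truth$planted_up),
                          unlist(truth$planted_down)))
  expect_true(all(truth$planted_candidates %in% all_planted))
  # planted proteins survive the default unique-peptide filter
  up <- gm$matrix$unique_peptides
  names(up) <- rownames(gm$matrix$areas)
  expect_true(all(up[all_planted] >= 2L))
})

test_that("a null generator calibrates the downstream contrast test", {
  # effect 0: planted proteins behave as nulls, so rejections at
  # alpha = 0.05 should occur for about 5% of them across seeds
  rej <- unlist(lapply(1:20, function(s) {
    cfg <- synthetic_config(n_proteins = 250, effect_log2 = 0,
                            censor_quantile = 0,
                            de_fraction_per_contrast = 0.2, seed = s)
    b <- generate_bundle(cfg)
    pep <- count_theoretical_peptides(b$proteome)
    norm <- suppressWarnings(normalize_areas(b$matrix, pep))
    res <- t_test_contrast(norm, b$design,
                           contrast_spec("Sham", "MCAO"))
    planted <- intersect(c(b$truth$planted_up$c2, b$truth$planted_down$c2),
                         res$accession)
    res$significant[match(planted, res$accession)]
  }))
  expect_gt(length(rej), 500)
  expect_equal(mean(rej), 0.05, tolerance = 0.3)
})

test_that("planted effects land at the configured size after normalization", {
  # group-mean difference of normalized log2 values for planted proteins
  # in the first contrast, averaged over seeds, sits within 0.2 of the
  # planted 2.0 shift
  diffs <- unlist(lapply(1:30, function(s) {
    cfg <- synthetic_config(n_proteins = 400, effect_log2 = 2,
                            replicate_log2_sd = 0.3, censor_quantile = 0,
                            de_fraction_per_contrast = 0.01, seed = s)
    b <- generate_bundle(cfg)
    pep <- count_theoretical_peptides(b$proteome)
    norm <- suppressWarnings(normalize_areas(b$matrix, pep))
    gm <- group_mean_matrix(norm, b$design, c("Naive", "Sham"))
    up <- intersect(b$truth$planted_classes$injury_up, rownames(gm))
    gm[up, "Sham"] - gm[up, "Naive"]
  }))
  expect_gt(length(diffs), 50)
  expect_lt(abs(mean(diffs) - 2), 0.2)
})

test_that("annotation fixtures plant candidates and rate-driven background", {
  cfg <- synthetic_config(n_proteins = 1000, seed = 4,
                          background_annotation_rate = 0.1)
  prot <- generate_proteome(cfg)
  gm <- generate_area_matrix(cfg, prot)
  ann <- generate_annotations(cfg, prot, gm$truth)
  cand <- gm$truth$planted_candidates
  expect_gt(length(cand), 0)
  # every planted candidate is extracellular and in >= 1 pathway
  expect_true(all(cand %in% ann$cc$extracellular_region))
  pw <- unique(unlist(unclass(ann$kegg)[c("WNT", "MAPK", "AMPK")]))
  expect_true(all(cand %in% pw))
  # extracellular-region size is candidates + Binomial(n - cand, 0.1),
  # within 3 sigma of its expectation
  n_bg <- 1000 - length(cand)
  size <- length(ann$cc$extracellular_region)
  expect_lt(abs(size - length(cand) - 0.1 * n_bg),
            3 * sqrt(n_bg * 0.1 * 0.9))

  # background rate 0: only planted candidates are annotated to the
  # named terms
  cfg0 <- synthetic_config(n_proteins = 300, seed = 4,
                           background_annotation_rate = 0)
  prot0 <- generate_proteome(cfg0)
  gm0 <- generate_area_matrix(cfg0, prot0)
  ann0 <- generate_annotations(cfg0, prot0, gm0$truth)
  cand0 <- gm0$truth$planted_candidates
  expect_setequal(ann0$cc$extracellular_region, cand0)
  expect_true(all(unlist(unclass(ann0$kegg)[c("WNT", "MAPK", "AMPK")])
                  %in% cand0))
})
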