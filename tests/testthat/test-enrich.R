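test_that("hypergeometric enrichment matches the combinatorial closed form", {
  bg <- paste0("P", 1:20)
  terms <- annotation_terms(list(hit = bg[1:5], miss = bg[16:20]),
                            namespace = "KEGG")
  sel <- c(bg[1:4], bg[6])  # k = 4 of K = 5, n = 5, N = 20
  e <- enrich(sel, bg, terms)
  manual <- (choose(5, 4) * choose(15, 1) + choose(5, 5) * choose(15, 0)) /
    choose(20, 5)
  expect_equal(manual, 76 / 15504)
  expect_equal(e$p_hyper[e$term_id == "hit"], manual)
  # disjoint term: upper tail from k = 0 is 1
  expect_equal(e$p_hyper[e$term_id == "miss"], 1)
  expect_true(all(diff(e$p_hyper) >= 0))  # sorted by p
  expect_error(enrich(c(sel, "QX"), bg, terms), "QX")
})

test_that("enrichment p equals exhaustive selection enumeration for small N", {
  set.seed(8)
  for (rep in 1:4) {
    N <- sample(8:12, 1)
    bg <- paste0("P", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    term <- sample(bg, K)
    sel <- sample(bg, n)
    k_obs <- length(intersect(sel, term))
    e <- enrich(sel, bg, annotation_terms(list(t = term), "KEGG"))
    combos <- combn(N, n)
    overlaps <- apply(combos, 2, function(ix) {
      length(intersect(bg[ix], term))
    })
    expect_equal(e$p_hyper, mean(overlaps >= k_obs), tolerance = 1e-12)
  }
})

test_that("upper-tail probabilities and BH adjustment behave as a distribution", {
  # tail probabilities step down from 1 at k = 0 and the pmf sums to 1
  N <- 15; K <- 6; n <- 7
  pmf <- dhyper(0:min(K, n), K, N - K, n)
  expect_equal(sum(pmf), 1)
  bg <- paste0("P", 1:N)
  term <- bg[1:K]
  for (k in 1:min(K, n)) {
    sel <- c(term[seq_len(k)], setdiff(bg, term)[seq_len(n - k)])
    e <- enrich(sel, bg, annotation_terms(list(t = term), "KEGG"))
    expect_equal(e$p_hyper, sum(pmf[(k + 1):length(pmf)]))
  }
  # BH: q >= p, q <= 1, and q is monotone in p-rank
  set.seed(3)
  bg2 <- paste0("Q", 1:50)
  terms <- annotation_terms(
    stats::setNames(lapply(1:8, function(i) sample(bg2, 10)),
                    paste0("t", 1:8)), "KEGG")
  e2 <- enrich(sample(bg2, 12), bg2, terms)
  expect_true(all(e2$q_bh >= e2$p_hyper - 1e-12))
  expect_true(all(e2$q_bh <= 1))
  expect_true(all(diff(e2$q_bh) >= -1e-12))
})

test_that("common pathways require sub-alpha enrichment in both parts", {
  bg <- paste0("P", 1:60)
  terms <- annotation_terms(list(WNT = bg[1:8], MAPK = bg[9:16],
                                 AMPK = bg[17:24], decoy = bg[25:40]),
                            namespace = "KEGG")
  strong <- enrich(bg[c(1:6, 9:14, 17:22)], bg, terms)
  expect_setequal(common_pathways(strong, strong),
                  c("WNT", "MAPK", "AMPK"))
  weak <- enrich(bg[c(1:6, 41:46)], bg, terms)
  expect_identical(common_pathways(strong, weak), "WNT")
  expect_warning(empty <- common_pathways(strong, weak, alpha = 1e-12),
                 "empty")
  expect_length(empty, 0)
  expect_warning(none <- common_pathways(strong, strong, alpha = 0),
                 "empty")
  expect_length(none, 0)
})

test_that("the candidate funnel applies the conjunctive rule and is monotone", {
  acc <- paste0("P", 1:6)
  membership <- cbind(c1 = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
                      c2 = rep(FALSE, 6))
  rownames(membership) <- acc
  sig <- list(union = acc[rowSums(membership) > 0],
              per_contrast = colSums(membership), membership = membership)
  trends <- data.frame(accession = acc,
                       injury_trend = c("up", "up", "flat_mixed", "up",
                                        "up", "up"),
                       repair_trend = "flat_mixed",
                       stringsAsFactors = FALSE)
  cc <- annotation_terms(list(extracellular_region = acc[c(1, 3, 4, 6)]),
                         "GO-CC")
  kegg <- annotation_terms(list(WNT = acc[c(1, 2, 5)], MAPK = acc[6]),
                           "KEGG")
  fun <- candidate_funnel(sig, trends, cc, kegg, common = "WNT")
  # P1 passes everything; P2 lacks localization; P3 lacks a qualifying
  # trend; P4 is not significant; P5 lacks localization; P6 is in no
  # common pathway
  expect_identical(candidates(fun), "P1")
  expect_false(any(fun$passes_funnel & !fun$in_extracellular_region))

  # enlarging the localization term can only add candidates
  cc2 <- annotation_terms(list(extracellular_region = acc[c(1, 3, 4, 5, 6)]),
                          "GO-CC")
  fun2 <- candidate_funnel(sig, trends, cc2, kegg, common = "WNT")
  expect_true(all(candidates(fun) %in% candidates(fun2)))
  expect_setequal(candidates(fun2), c("P1", "P5"))

  # an empty common-pathway set yields no candidates
  fun0 <- candidate_funnel(sig, trends, cc, kegg, common = character(0))
  expect_length(candidates(fun0), 0)
  expect_error(candidate_funnel(sig, trends, kegg, kegg, common = "WNT"),
               "extracellular_region")
})

test_that("biphasic repair trends qualify for the funnel", {
  acc <- c("X1", "X2")
  membership <- cbind(c1 = c(TRUE, TRUE))
  rownames(membership) <- acc
  sig <- list(union = acc, per_contrast = 2, membership = membership)
  trends <- data.frame(accession = acc,
                       injury_trend = "flat_mixed",
                       repair_trend = c("up_down", "flat_mixed"),
                       stringsAsFactors = FALSE)
  cc <- annotation_terms(list(extracellular_region = acc), "GO-CC")
  kegg <- annotation_terms(list(AMPK = acc), "KEGG")
  fun <- candidate_funnel(sig, trends, cc, kegg, common = "AMPK")
  expect_identical(candidates(fun), "X1")
})

test_that("validation-table concordance counts MCAO-elevated proteins", {
  wb <- read_wb_tsv(system.file("extdata", "wb_relative_levels.tsv",
                                package = "lfqfunnel"))
  conc <- wb_concordance(wb)
  # 9 of the 12 validated proteins peak in the MCAO group
  expect_identical(conc$n_mcao_elevated, 9L)
  expect_identical(
    conc$proteins$wb_trend[conc$proteins$protein == "Gsk3b"], "up_down")

  # identical WB and label-free triples are concordant for every protein
  groups <- levels(wb$group)
  lf <- t(vapply(unique(wb$protein), function(p) {
    v <- wb[wb$protein == p, ]
    v$mean[match(groups, v$group)]
  }, numeric(3)))
  full <- wb_concordance(wb, lf_means = lf)
  expect_identical(full$n_concordant, full$n_compared)
  expect_identical(full$n_compared, 12L)

  # unmapped proteins are listed and excluded
  expect_warning(part <- wb_concordance(wb, lf_means = lf[1:10, ]),
                 "excluded")
  expect_identical(part$n_compared, 10L)
  expect_length(part$unmapped, 2L)
})
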