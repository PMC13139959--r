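test_that("allele-sharing distance takes its documented values", {
  g <- make_geno(rbind(rep(0L, 10),    # s1
                       rep(1L, 10),    # s2: het everywhere
                       rep(2L, 10),    # s3: opposite hom
                       rep(0L, 10)))   # s4 = s1
  d <- allele_sharing_distance(g)
  expect_equal(d["s1", "s4"], 0)
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 1)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(allele_sharing_distance(g[1, ]), "two samples")
  ## no shared loci -> NA with warning
  g2 <- make_geno(rbind(c(0L, NA), c(NA, 1L)))
  expect_warning(d2 <- allele_sharing_distance(g2), "no shared loci")
  expect_true(is.na(d2["s1", "s2"]))
})

test_that("allele sharing and Match Score are two views of one definition", {
  fr <- diverged_freqs(40, seed = 101)
  sim <- sim_genotypes(fr, n = c(3, 3, 3), missing_rate = 0.1, seed = 102)
  g <- as_geno_matrix(sim$genotypes)
  d <- allele_sharing_distance(sim$genotypes)
  for (pair in list(c(1, 2), c(3, 7), c(5, 9))) {
    ms <- match_score(g[pair[1], ], g[pair[2], ])
    expect_equal(d[pair[1], pair[2]], 1 - ms$match_score / 100)
  }
})

test_that("sharing assignment recovers controls and flags intermediates", {
  fr <- diverged_freqs(60, seed = 103)
  ctl <- sim_genotypes(fr, n = c(1, 1, 1), missing_rate = 0, seed = 104)
  ## an unknown identical to its group's only control shares 100%
  twin <- ctl$genotypes[1, ]
  twin$sample_id <- "twin"
  geno <- dplyr::bind_rows(ctl$genotypes, twin)
  res <- assign_by_sharing(geno, ctl$popmap)
  expect_equal(nrow(res), 1)
  expect_equal(res$assigned, ctl$popmap$group[1])
  expect_equal(max(res$share_A, res$share_B, res$share_C), 100)
  ctl <- sim_genotypes(fr, n = c(4, 4, 4), missing_rate = 0, seed = 104)

  ## a half-half admixed individual stays unassigned with two fractions
  adm <- sim_admixed(fr, c(0.5, 0.5, 0), "half", seed = 105)
  res2 <- assign_by_sharing(dplyr::bind_rows(ctl$genotypes, adm),
                            ctl$popmap)
  expect_equal(res2$assigned, "unassigned")
  expect_false(is.na(res2$second_share))
  expect_error(assign_by_sharing(adm, ctl$popmap), "control")
})

test_that("a strongly admixed 73/27 individual reports both source groups", {
  ## diagnostic-style panel loci: the two source species carry opposite
  ## near-fixed alleles at every locus, as an ascertained assay panel does
  fr <- tibble::tibble(
    locus_id = rep(sprintf("L%03d", 1:500), 2),
    fst = 0.95, p_anc = 0.5,
    pop = rep(c("A", "B"), each = 500),
    freq = rep(c(0.99, 0.01), each = 500)
  )
  ctl <- sim_genotypes(fr, n = c(4, 4), missing_rate = 0, seed = 107)
  adm <- sim_admixed(fr, c(0.73, 0.27), "mix", seed = 108)
  res <- assign_by_sharing(dplyr::bind_rows(ctl$genotypes, adm),
                           ctl$popmap)
  expect_equal(res$assigned, "unassigned")
  expect_equal(res$share_A, 73, tolerance = 6 / 73)
  expect_equal(res$second_group, "B")
  expect_equal(res$second_share, 27, tolerance = 6 / 27)
})

test_that("MLG matching counts unique and repeated genotypes", {
  g <- make_geno(rbind(c(0, 1, 2), c(0, 1, 2), c(2, 1, 0), c(1, 1, 1)))
  res <- multilocus_matches(g)
  expect_equal(res$summary$n_unique_mlg, 3)
  expect_equal(res$summary$n_repeated_mlg, 1)
  expect_equal(res$samples$mlg[1], res$samples$mlg[2])
  ## all distinct
  g2 <- make_geno(rbind(c(0, 1), c(1, 0), c(2, 2)))
  expect_equal(multilocus_matches(g2)$summary$n_unique_mlg, 3)
  ## planted duplicates match brute force
  fr <- diverged_freqs(30, seed = 109)
  sim <- sim_genotypes(fr, n = c(5, 5, 5), missing_rate = 0.05, seed = 110)
  gm <- as_geno_matrix(sim$genotypes)
  gm <- rbind(gm, dup1 = gm[2, ], dup2 = gm[7, ])
  res3 <- multilocus_matches(as_geno_tbl(gm))
  brute <- sum(!duplicated(apply(gm, 1, paste, collapse = ",")))
  expect_equal(res3$summary$n_unique_mlg, brute)
})

test_that("exact MLG mode distinguishes differing missing patterns", {
  g <- make_geno(rbind(c(0L, NA, 2L), c(0L, 1L, 2L)))
  expect_equal(multilocus_matches(g)$summary$n_unique_mlg, 2)
  expect_equal(multilocus_matches(g, missing_wildcard = TRUE)$
                 summary$n_unique_mlg, 1)
})

test_that("frequency assignment test places samples by likelihood", {
  fr <- diverged_freqs(80, seed = 111)
  ctl <- sim_genotypes(fr, n = c(10, 10, 10), missing_rate = 0, seed = 112)
  unk <- sim_genotypes(fr, n = c(3, 3, 3), missing_rate = 0, prefix = "u",
                       seed = 113)
  unk$popmap$role <- "unknown"
  geno <- dplyr::bind_rows(ctl$genotypes, unk$genotypes)
  pm <- dplyr::bind_rows(ctl$popmap, unk$popmap)
  res <- frequency_assignment_test(geno, pm)
  truth <- pm$group[match(res$sample_id, pm$sample)]
  expect_gte(mean(res$assigned == truth), 0.9)
  expect_false(any(res$tie[res$sample_id %in% unk$popmap$sample]))
})

test_that("uniform control frequencies produce flagged likelihood ties", {
  g <- make_geno(rbind(c(0, 2), c(2, 0), c(0, 2), c(2, 0), c(0, 2)),
                 samples = c("a1", "a2", "b1", "b2", "u"))
  pm <- pop_map(c("a1", "a2", "b1", "b2", "u"),
                c("ga", "ga", "gb", "gb", NA),
                c(rep("control", 4), "unknown"))
  res <- frequency_assignment_test(g, pm)
  expect_true(res$tie[res$sample_id == "u"])
})

test_that("leave-one-out never uses a control's own alleles", {
  ## group ga: two hom-alt controls. For a1 the LOO frequency comes from a2
  ## alone (p = 1, floored to 2/3 with n = 1), so its own-group likelihood
  ## is exactly 2 log(2/3); including a1's own alleles would give n = 2 and
  ## a floor of 4/5 instead.
  g <- make_geno(rbind(c(2L), c(2L), c(0L), c(0L)),
                 samples = c("a1", "a2", "b1", "b2"))
  pm <- pop_map(c("a1", "a2", "b1", "b2"), c("ga", "ga", "gb", "gb"),
                "control")
  res <- frequency_assignment_test(g, pm)
  expect_equal(res$loglik_ga[res$sample_id == "a1"], 2 * log(2 / 3))
})
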