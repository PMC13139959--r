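test_that("published panel rows reproduce from reconstructed compositions", {
  tab <- greyia_panel_stats()
  for (i in seq_len(nrow(tab))) {
    ls <- locus_summary(reconstruct_genotypes(tab$n[i], tab$maf[i],
                                              tab$h_o[i]))
    expect_equal(round(ls$h_s, 3), tab$h_s[i],
                 info = paste("h_s at", tab$assay[i]))
    expect_equal(round(ls$pic, 3), tab$pic[i],
                 info = paste("pic at", tab$assay[i]))
  }
})

test_that("locus summary handles monomorphic and empty loci", {
  g <- make_geno(rbind(c(0, 1, NA),
                       c(0, 1, NA),
                       c(0, 1, NA)))
  ls <- locus_summary(g)
  expect_equal(ls$h_o, c(0, 1, NA))
  expect_equal(ls$h_s[1], 0)          # monomorphic
  expect_equal(ls$pic[1], 0)
  expect_true(is.na(ls$h_s[3]))       # no calls
  ## all-heterozygous locus, n = 3: H_S = (6/5) * 0.5
  expect_equal(ls$h_s[2], 0.6)
  expect_equal(ls$pic[2], 0.375)
})

test_that("PIC is bounded by its algebraic relation to H_S", {
  fr <- sim_frequencies(200, n_pops = 1, fst = 0, maf_range = c(0.05, 0.5),
                        seed = 51)
  sim <- sim_genotypes(fr, n = 30, missing_rate = 0.05, seed = 52)
  ls <- locus_summary(sim$genotypes)
  ok <- ls$n > 0
  expect_true(all(ls$pic[ok] <=
                    ls$h_s[ok] * (2 * ls$n[ok] - 1) / (2 * ls$n[ok]) + 1e-12))
  expect_true(all(ls$pic[ok] <= 0.375 + 1e-12))
  expect_true(all(ls$maf[ok] >= 0 & ls$maf[ok] <= 0.5))
})

test_that("Weir-Cockerham theta equals hand-evaluated variance components", {
  ## group1: genotypes 0,1,2; group2: 0,0,0 -> a = b = c -> theta = 1/3
  g <- make_geno(rbind(0, 1, 2, 0, 0, 0))
  pm <- pop_map(paste0("s", 1:6), rep(c("g1", "g2"), each = 3))
  th <- wc_theta(g, pm)
  expect_equal(th$a, 1 / 12, tolerance = 1e-12)
  expect_equal(th$b, 1 / 12, tolerance = 1e-12)
  expect_equal(th$c, 1 / 12, tolerance = 1e-12)
  expect_equal(th$theta, 1 / 3, tolerance = 1e-12)

  ## group1: 0,1,2; group2: 0,0,1 -> a = 0 exactly
  g2 <- make_geno(rbind(0, 1, 2, 0, 0, 1))
  th2 <- wc_theta(g2, pm)
  expect_equal(th2$a, 0, tolerance = 1e-12)
  expect_equal(th2$theta, 0, tolerance = 1e-12)
})

test_that("fixed differences force theta = 1 and identity gives theta <= 0", {
  g <- make_geno(rbind(0, 0, 0, 0, 2, 2, 2, 2))
  pm <- pop_map(paste0("s", 1:8), rep(c("g1", "g2"), each = 4))
  expect_equal(wc_theta(g, pm)$theta, 1)
  ## identical genotype compositions in both groups
  g2 <- make_geno(rbind(0, 1, 2, 1, 0, 1, 2, 1))
  expect_lte(wc_theta(g2, pm)$theta, 0)
  expect_error(wc_theta(g, pm[pm$group == "g1", ]), "two groups")
})

test_that("theta is invariant to allele-label swap", {
  fr <- sim_frequencies(50, n_pops = 2, fst = 0.3, seed = 53)
  sim <- sim_genotypes(fr, n = c(10, 10), missing_rate = 0.05, seed = 54)
  th1 <- wc_theta(sim$genotypes, sim$popmap)
  flipped <- as_geno_matrix(sim$genotypes)
  flipped <- 2L - flipped
  th2 <- wc_theta(as_geno_tbl(flipped), sim$popmap)
  expect_equal(th1$theta, th2$theta)
})

test_that("multilocus pairwise F_ST recovers the generating divergence", {
  fr <- sim_frequencies(500, n_pops = 2, fst = 0.3, seed = 55)
  sim <- sim_genotypes(fr, n = c(40, 40), missing_rate = 0, seed = 56)
  res <- pairwise_wc_fst(sim$genotypes, sim$popmap, n_boot = 200, seed = 57)
  expect_equal(nrow(res), 1)
  expect_equal(res$theta, 0.3, tolerance = 0.07 / 0.3)
  expect_true(res$significant)
  expect_lte(res$ci_lower, res$ci_upper)
})

test_that("duplicating every locus leaves the point estimate unchanged", {
  fr <- sim_frequencies(40, n_pops = 2, fst = 0.4, seed = 58)
  sim <- sim_genotypes(fr, n = c(8, 8), missing_rate = 0, seed = 59)
  g <- as_geno_matrix(sim$genotypes)
  gg <- cbind(g, g)
  colnames(gg) <- paste0("L", seq_len(ncol(gg)))
  r1 <- pairwise_wc_fst(sim$genotypes, sim$popmap, n_boot = 10, seed = 1)
  r2 <- pairwise_wc_fst(as_geno_tbl(gg), sim$popmap, n_boot = 10, seed = 1)
  expect_equal(r1$theta, r2$theta)
  expect_error(pairwise_wc_fst(sim$genotypes, sim$popmap, n_boot = 1),
               "n_boot")
})

test_that("panmictic data yields CIs covering zero in most seeds", {
  hits <- vapply(1:20, function(s) {
    fr <- sim_frequencies(200, n_pops = 2, fst = 0, seed = 100 + s)
    sim <- sim_genotypes(fr, n = c(15, 15), missing_rate = 0,
                         seed = 200 + s)
    res <- pairwise_wc_fst(sim$genotypes, sim$popmap, n_boot = 199,
                           seed = 300 + s)
    res$ci_lower <= 0 && res$ci_upper >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Nei D_A distance matches hand computation and its fixed points", {
  freqs <- tibble::tibble(
    group = rep(c("x", "y"), each = 2),
    locus_id = rep(c("L1", "L2"), 2),
    p = c(0.2, 0.8, 0.6, 0.4)
  )
  d <- nei_da_distance(freqs)
  ## hand: per locus sqrt(.2*.6)+sqrt(.8*.4) = 0.9120956; D_A = 1 - mean
  expect_equal(d["x", "y"], 1 - (sqrt(0.12) + sqrt(0.32)), tolerance = 1e-9)
  expect_equal(diag(d), c(x = 0, y = 0))

  same <- tibble::tibble(group = rep(c("x", "y"), each = 2),
                         locus_id = rep(c("L1", "L2"), 2),
                         p = c(0.3, 0.7, 0.3, 0.7))
  expect_equal(nei_da_distance(same)["x", "y"], 0)
  opp <- tibble::tibble(group = rep(c("x", "y"), each = 2),
                        locus_id = rep(c("L1", "L2"), 2),
                        p = c(1, 1, 0, 0))
  expect_equal(nei_da_distance(opp)["x", "y"], 1)
})

test_that("Nei identity matches hand computation and its fixed points", {
  freqs <- tibble::tibble(
    group = rep(c("x", "y"), each = 2),
    locus_id = rep(c("L1", "L2"), 2),
    p = c(0.2, 0.8, 0.6, 0.4)
  )
  i <- nei_identity(freqs)
  expect_equal(i["x", "y"], 0.88 / sqrt(1.36 * 1.04), tolerance = 1e-9)
  expect_equal(diag(i), c(x = 1, y = 1))
  opp <- tibble::tibble(group = rep(c("x", "y"), each = 2),
                        locus_id = rep(c("L1", "L2"), 2),
                        p = c(1, 1, 0, 0))
  expect_equal(nei_identity(opp)["x", "y"], 0)
})

test_that("group blocks mirror the published table layout", {
  fr <- diverged_freqs(30, seed = 61)
  sim <- sim_genotypes(fr, n = c(5, 5, 5), missing_rate = 0, seed = 62)
  out <- locus_summary(sim$genotypes, sim$popmap, by_group = TRUE)
  expect_setequal(unique(out$group), c("all", "A", "B", "C"))
  expect_true(all(!is.na(out$theta[out$group == "all"]) |
                    is.na(out$theta[out$group == "all"])))
  expect_equal(sum(out$group == "all"), 30)
})
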