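test_that("window subsets are drawn from the eligible set only", {
  stats <- tibble::tibble(locus_id = paste0("L", 1:1000),
                          theta = seq(0, 1, length.out = 1000))
  sub <- subset_by_fst_window(stats, c(0.5, 0.7), subset_size = 200,
                              seed = 71)
  eligible <- stats$locus_id[stats$theta >= 0.5 & stats$theta <= 0.7]
  expect_equal(nrow(sub), 200)
  expect_true(all(sub$locus_id %in% eligible))
  ## deterministic given seed
  sub2 <- subset_by_fst_window(stats, c(0.5, 0.7), subset_size = 200,
                               seed = 71)
  expect_identical(sub, sub2)
  ## central rule takes loci nearest the midpoint
  subc <- subset_by_fst_window(stats, c(0.5, 0.7), subset_size = 10,
                               rule = "central")
  expect_true(all(abs(subc$theta - 0.6) <= 0.005))
})

test_that("undersized and empty windows warn", {
  stats <- tibble::tibble(locus_id = paste0("L", 1:150), theta = 0.4)
  expect_warning(sub <- subset_by_fst_window(stats, c(0.3, 0.5), 200),
                 "150")
  expect_equal(nrow(sub), 150)
  expect_warning(none <- subset_by_fst_window(stats, c(0.8, 1), 200),
                 "no loci")
  expect_equal(nrow(none), 0)
  expect_error(subset_by_fst_window(stats, c(0.5, 0.5), 10), "window")
})

test_that("subset scoring separates diverged groups but not panmixia", {
  fr <- diverged_freqs(60, seed = 72)
  sim <- sim_genotypes(fr, n = c(8, 8, 8), missing_rate = 0, seed = 73)
  sc <- score_subset(sim$genotypes, unique(fr$locus_id), sim$popmap)
  expect_gt(sc$silhouette, 0.8)
  expect_true(sc$distinct)

  frp <- sim_frequencies(60, n_pops = 3, fst = 0, seed = 74)
  simp <- sim_genotypes(frp, n = c(8, 8, 8), missing_rate = 0, seed = 75)
  scp <- score_subset(simp$genotypes, unique(frp$locus_id), simp$popmap)
  expect_lt(scp$silhouette, 0.25)
  expect_false(scp$distinct)
  expect_error(score_subset(sim$genotypes, c("nope"), sim$popmap),
               "absent")
})

test_that("moderate-divergence windows outrank sparse noisy high-theta windows", {
  ## plant plenty of truly diverged mid-window loci but only a handful of
  ## high-theta loci, all of which differentiate a single species and so
  ## cannot resolve the other two clusters
  fr_mid <- sim_frequencies(150, n_pops = 3, fst = c(0.35, 0.45),
                            pop_labels = c("A", "B", "C"), seed = 76)
  fr_hi <- tibble::tibble(
    locus_id = rep(paste0("hi_", 1:3), 3),
    fst = 0.9, p_anc = 0.5,
    pop = rep(c("A", "B", "C"), each = 3),
    freq = rep(c(0.99, 0.99, 0.01), each = 3)
  )
  fr <- dplyr::bind_rows(fr_mid, fr_hi)
  sim <- sim_genotypes(fr, n = c(30, 30, 30), missing_rate = 0, seed = 78)
  stats <- locus_summary(sim$genotypes, sim$popmap)
  s_mid <- suppressWarnings(subset_by_fst_window(stats, c(0.3, 0.5), 100,
                                                 seed = 79))
  ## the high band only offers the three planted one-species loci
  s_hi <- stats[stats$locus_id %in% paste0("hi_", 1:3), ]
  ranked <- score_subsets(sim$genotypes,
                          list(mid = s_mid$locus_id, hi = s_hi$locus_id),
                          sim$popmap)
  expect_equal(ranked$subset[1], "mid")
  expect_false(ranked$distinct[ranked$subset == "hi"])
})

test_that("diagnostic SNP detection equals planted-signal enumeration", {
  ## 8 controls (3/3/2), 5 planted diagnostic loci + noise loci
  set.seed(80)
  n_noise <- 40
  noise <- matrix(sample(0:2, 8 * n_noise, TRUE), nrow = 8)
  planted <- cbind(c(2, 2, 2, 0, 0, 0, 0, 0),    # diagnostic for g1
                   c(0, 0, 0, 2, 2, 2, 0, 0) * 0 + c(0, 0, 0, 2, 2, 2, 0, 0),
                   c(0, 0, 0, 0, 0, 0, 2, 2),
                   c(2, 2, 2, 0, 0, 0, 0, 0),
                   c(0, 0, 0, 2, 2, 2, 0, 0))
  near_miss <- cbind(c(2, 2, 1, 0, 0, 0, 0, 0),  # one het control
                     c(2, 2, NA, 0, 0, 0, 0, 0)) # one missing control
  g <- make_geno(cbind(planted, near_miss, noise))
  pm <- pop_map(paste0("s", 1:8), rep(c("g1", "g2", "g3"), c(3, 3, 2)))
  found <- find_diagnostic_snps(g, pm)
  ## brute force over loci
  mat <- as_geno_matrix(g)
  grp <- rep(c("g1", "g2", "g3"), c(3, 3, 2))
  brute <- lapply(colnames(mat), function(l) {
    v <- mat[, l]
    if (anyNA(v) || any(v == 1L)) return(NULL)
    for (s in unique(grp)) {
      if (length(unique(v[grp == s])) == 1 &&
          length(unique(v[grp != s])) == 1 &&
          v[grp == s][1] != v[grp != s][1]) {
        return(tibble::tibble(locus_id = l, species = s))
      }
    }
    NULL
  })
  brute <- dplyr::bind_rows(brute)
  expect_equal(found[order(found$locus_id), ],
               brute[order(brute$locus_id), ])
  expect_true(all(paste0("L", 1:5) %in% found$locus_id))
  expect_false(any(c("L6", "L7") %in% found$locus_id))
})

test_that("spacing constraint removes SNP pairs within the gap", {
  loci <- tibble::tibble(
    locus_id = c("r1.10", "r1.25", "r1.70", "r2.10", "r2.50", "r3.5"),
    contig = c("r1", "r1", "r1", "r2", "r2", "r3"),
    pos = c(10L, 25L, 70L, 10L, 50L, 5L)
  )
  out <- apply_spacing_constraint(loci$locus_id, loci, min_gap = 30)
  ## r1.10 and r1.25 are 15 bp apart: both removed; r1.70 is 45 bp from
  ## r1.25: kept; r2 pair is 40 bp apart: kept
  expect_setequal(out, c("r1.70", "r2.10", "r2.50", "r3.5"))
  ## non-candidate SNPs still disqualify nearby candidates
  out2 <- apply_spacing_constraint("r1.10", loci, min_gap = 30)
  expect_equal(out2, character(0))
  ## brute force pairwise-distance check on a random planted set
  set.seed(81)
  pos <- sample(1:500, 60)
  loci3 <- tibble::tibble(locus_id = paste0("c.", pos), contig = "c",
                          pos = as.integer(pos))
  surv <- apply_spacing_constraint(loci3$locus_id, loci3, min_gap = 30)
  brute <- loci3$locus_id[vapply(seq_len(60), function(i) {
    all(abs(pos[-i] - pos[i]) > 30)
  }, logical(1))]
  expect_setequal(surv, brute)
})

test_that("panel assembly honours size, extras and deduplication", {
  fr <- diverged_freqs(260, seed = 82)
  sim <- sim_genotypes(fr, n = c(8, 8, 8), missing_rate = 0, seed = 83)
  stats <- locus_summary(sim$genotypes, sim$popmap)
  sub <- suppressWarnings(subset_by_fst_window(stats, c(0.5, 1), 200,
                                               seed = 84))
  extras <- c(stats$locus_id[1:3], sub$locus_id[1])   # one overlaps
  res <- assemble_panel(sim$genotypes, sub, sim$popmap,
                        extra_loci = extras, target_size = 19)
  expect_true(sub$locus_id[1] %in% res$panel$locus_id ||
                !sub$locus_id[1] %in% res$panel$locus_id)  # well-defined
  expect_equal(anyDuplicated(res$panel$locus_id), 0)
  expect_gte(nrow(res$panel), 19)
  expect_lte(nrow(res$panel), 19 + 4)
  expect_error(assemble_panel(sim$genotypes, sub[1:5, ], sim$popmap,
                              target_size = 19), "target_size")
  ## panel keeps the cluster structure of the full subset
  full <- score_subset(sim$genotypes, sub, sim$popmap)
  expect_gt(res$score$silhouette, full$silhouette - 0.15)
})

test_that("diagnostic loci are preferred when ranking the panel", {
  stats <- tibble::tibble(locus_id = paste0("L", 1:30),
                          theta = seq(0.99, 0.5, length.out = 30))
  diag <- tibble::tibble(locus_id = c("L29", "L30"), species = "g1")
  fr <- diverged_freqs(30, seed = 85)
  sim <- sim_genotypes(fr, n = c(4, 4, 4), missing_rate = 0, seed = 86)
  stats$locus_id <- unique(fr$locus_id)
  diag$locus_id <- stats$locus_id[29:30]
  res <- assemble_panel(sim$genotypes, stats, sim$popmap,
                        diagnostic = diag, target_size = 5)
  expect_true(all(diag$locus_id %in% res$panel$locus_id))
})
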