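#' Simulate population allele frequencies under the Balding-Nichols model
#'
#' Draws, for each locus, an ancestral allele frequency uniformly from
#' `maf_range` and then one frequency per population from the
#' Balding-Nichols Beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose divergence parameter `F` is the
#' expected per-locus F_ST among populations. `F = 0` returns the ancestral
#' frequency unchanged (no divergence).
#'
#' @param n_loci number of loci.
#' @param n_pops number of populations `K`.
#' @param fst per-locus divergence: a single value, a length-2 range to draw
#'   from uniformly, or a vector of length `n_loci`. All values in `[0, 1)`.
#' @param maf_range interval in `(0, 0.5]` for the ancestral frequency.
#' @param pop_labels population labels (default `pop1..popK`).
#' @param seed optional integer seed.
#'
#' @return long tibble with columns `locus_id`, `fst`, `p_anc`, `pop`,
#'   `freq` (one row per population and locus).
#' @export
sim_frequencies <- function(n_loci, n_pops = 3,
                            fst = c(0.2, 0.7),
                            maf_range = c(0.1, 0.5),
                            pop_labels = paste0("pop", seq_len(n_pops)),
                            seed = NULL) {
  stopifnot(n_loci >= 1, n_pops >= 1, length(pop_labels) == n_pops,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  with_seed(seed, {
    f <- if (length(fst) == 1) rep(fst, n_loci)
         else if (length(fst) == 2 && n_loci != 2) runif(n_loci, fst[1], fst[2])
         else fst
    if (length(f) != n_loci) stop("`fst` must have length 1, 2 or n_loci")
    if (any(f < 0 | f >= 1)) stop("divergence values must lie in [0, 1)")
    p_anc <- runif(n_loci, maf_range[1], maf_range[2])
    freqs <- matrix(rep(p_anc, n_pops), nrow = n_loci)
    div <- f > 0
    if (any(div)) {
      a <- p_anc[div] * (1 - f[div]) / f[div]
      b <- (1 - p_anc[div]) * (1 - f[div]) / f[div]
      for (k in seq_len(n_pops)) {
        freqs[div, k] <- rbeta(sum(div), a, b)
      }
    }
    locus_id <- sprintf("locus_%04d.%d", seq_len(n_loci),
                        sample(30:150, n_loci, replace = TRUE))
    tibble::tibble(
      locus_id = rep(locus_id, n_pops),
      fst = rep(f, n_pops),
      p_anc = rep(p_anc, n_pops),
      pop = rep(pop_labels, each = n_loci),
      freq = as.vector(freqs)
    )
  })
}

freq_matrix <- function(freqs) {
  ## populations x loci matrix of allele frequencies, locus order preserved
  wide <- tidyr::pivot_wider(freqs[c("locus_id", "pop", "freq")],
                             names_from = "locus_id", values_from = "freq")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$pop
  m[, unique(freqs$locus_id), drop = FALSE]
}

#' Simulate genotypes from population allele frequencies
#'
#' Individuals are drawn in Hardy-Weinberg proportions: the genotype of an
#' individual from population `k` at locus `l` is `Binomial(2, p_kl)`.
#' Calls are independently set missing with probability `missing_rate`.
#'
#' @param freqs frequency table from [sim_frequencies()].
#' @param n sample sizes per population, in the order of the populations in
#'   `freqs` (recycled if length 1).
#' @param missing_rate probability a call is missing.
#' @param role role recorded in the returned population map.
#' @param prefix prefix for generated sample ids.
#' @inheritParams sim_frequencies
#' @return list with `genotypes` (genotype table) and `popmap` ([pop_map()]).
#' @export
sim_genotypes <- function(freqs, n = c(20, 20, 10), missing_rate = 0.02,
                          role = "control", prefix = "s", seed = NULL) {
  fm <- freq_matrix(freqs)
  pops <- rownames(fm)
  n <- rep_len(n, length(pops))
  stopifnot(all(n >= 1), missing_rate >= 0, missing_rate < 1)
  with_seed(seed, {
    rows <- lapply(seq_along(pops), function(k) {
      g <- matrix(rbinom(n[k] * ncol(fm), 2, rep(fm[k, ], each = n[k])),
                  nrow = n[k])
      g
    })
    g <- do.call(rbind, rows)
    if (missing_rate > 0) {
      g[runif(length(g)) < missing_rate] <- NA
    }
    storage.mode(g) <- "integer"
    rownames(g) <- sprintf("%s%03d_%s", prefix, seq_len(sum(n)),
                           rep(pops, n))
    colnames(g) <- colnames(fm)
    list(
      genotypes = as_geno_tbl(g),
      popmap = pop_map(rownames(g), rep(pops, n), role)
    )
  })
}

#' Simulate an admixed individual
#'
#' Each of the two allele copies at every locus is drawn from population `k`
#' with probability `q[k]`, then is the alternate allele with probability
#' `p_kl`. `q = (1, 0, ...)` reduces to an unadmixed draw from population 1.
#'
#' @param freqs frequency table from [sim_frequencies()].
#' @param q ancestry fractions over the populations (sums to 1).
#' @param sample_id id for the generated sample.
#' @inheritParams sim_genotypes
#' @return one-row genotype table.
#' @export
sim_admixed <- function(freqs, q, sample_id = "admixed1",
                        missing_rate = 0, seed = NULL) {
  fm <- freq_matrix(freqs)
  stopifnot(length(q) == nrow(fm))
  if (any(q < 0)) stop("ancestry fractions must be non-negative")
  if (abs(sum(q) - 1) > 1e-8) stop("ancestry fractions must sum to 1")
  with_seed(seed, {
    L <- ncol(fm)
    g <- integer(L)
    for (copy in 1:2) {
      src <- sample.int(nrow(fm), L, replace = TRUE, prob = q)
      p <- fm[cbind(src, seq_len(L))]
      g <- g + as.integer(runif(L) < p)
    }
    if (missing_rate > 0) g[runif(L) < missing_rate] <- NA
    m <- matrix(g, nrow = 1, dimnames = list(sample_id, colnames(fm)))
    as_geno_tbl(m)
  })
}

#' Simulate replicated genotyping runs with allelic error and dropout
#'
#' Emulates repeated allele-specific PCR genotyping of the same samples:
#' each of the two allele copies of every true genotype is independently
#' flipped with probability `allele_error`, and each call is independently
#' dropped (set missing) with probability `dropout_rate`. Per-allele (rather
#' than per-genotype) error gives the heterozygote-biased error profile seen
#' in real allele-specific PCR data.
#'
#' @param genotypes true genotype table.
#' @param n_replicates replicates per sample (default 4, matching
#'   quadruplicate assay runs).
#' @param allele_error probability an allele copy is mis-called.
#' @param dropout_rate probability a call is missing in a replicate.
#' @inheritParams sim_frequencies
#' @return replicate table: tibble with `sample_id`, `replicate`, then one
#'   column per locus.
#' @export
sim_replicates <- function(genotypes, n_replicates = 4, allele_error = 0.05,
                           dropout_rate = 0.02, seed = NULL) {
  stopifnot(n_replicates >= 1, allele_error >= 0, allele_error < 1,
            dropout_rate >= 0, dropout_rate < 1)
  g <- as_geno_matrix(genotypes)
  with_seed(seed, {
    out <- lapply(seq_len(n_replicates), function(r) {
      ## flip each allele copy: genotype g = (# alt copies); a flipped ref
      ## copy gains one alt, a flipped alt copy loses one.
      noisy <- g
      ok <- which(!is.na(g))
      gv <- g[ok]
      noisy[ok] <- gv + rbinom(length(gv), 2L - gv, allele_error) -
        rbinom(length(gv), gv, allele_error)
      noisy[runif(length(g)) < dropout_rate] <- NA
      m <- matrix(as.integer(noisy), nrow = nrow(g), dimnames = dimnames(g))
      dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(g), replicate = r),
        tibble::as_tibble(m)
      )
    })
    dplyr::arrange(dplyr::bind_rows(out), .data$sample_id, .data$replicate)
  })
}

#' Simulate a complete panel-design study
#'
#' Convenience wrapper generating all the pieces the pipeline consumes under
#' one seed: per-locus divergent frequencies for three populations,
#' control/unknown genotypes, optional admixed individuals, and replicated
#' assay runs. Defaults reflect the study conditions the package targets:
#' three populations, per-locus F_ST spread over 0.2-0.7, desk-scale 2000
#' discovery loci, 20/20/10 samples, ~98% call rate and 4 replicates with 5%
#' allelic error.
#'
#' @inheritParams sim_frequencies
#' @inheritParams sim_genotypes
#' @inheritParams sim_replicates
#' @param n_unknowns unknown samples per population (0 for none).
#' @param admixed_q optional list of ancestry-fraction vectors; one admixed
#'   unknown is generated per entry.
#' @param seed integer seed; per-stage substreams are derived from it so each
#'   component is independently reproducible.
#' @return list with `freqs`, `genotypes`, `popmap`, `replicates`.
#' @export
sim_study <- function(n_loci = 2000, n_pops = 3, fst = c(0.2, 0.7),
                      maf_range = c(0.1, 0.5),
                      pop_labels = c("GRA", "GSU", "GFL")[seq_len(n_pops)],
                      n = c(20, 20, 10), n_unknowns = 0, admixed_q = NULL,
                      missing_rate = 0.02, n_replicates = 4,
                      allele_error = 0.05, dropout_rate = 0.02,
                      seed = NULL) {
  seeds <- derive_seeds(seed, 5)
  freqs <- sim_frequencies(n_loci, n_pops, fst, maf_range, pop_labels,
                           seed = seeds[1])
  ctrl <- sim_genotypes(freqs, n, missing_rate, role = "control",
                        prefix = "ctl", seed = seeds[2])
  genotypes <- ctrl$genotypes
  popmap <- ctrl$popmap
  if (n_unknowns > 0) {
    unk <- sim_genotypes(freqs, rep(n_unknowns, n_pops), missing_rate,
                         role = "unknown", prefix = "unk", seed = seeds[3])
    genotypes <- dplyr::bind_rows(genotypes, unk$genotypes)
    popmap <- dplyr::bind_rows(popmap, unk$popmap)
  }
  if (!is.null(admixed_q)) {
    adm_seeds <- derive_seeds(seeds[4], length(admixed_q))
    for (i in seq_along(admixed_q)) {
      id <- sprintf("adm%03d", i)
      genotypes <- dplyr::bind_rows(
        genotypes,
        sim_admixed(freqs, admixed_q[[i]], id, missing_rate,
                    seed = adm_seeds[i])
      )
      popmap <- dplyr::bind_rows(popmap, pop_map(id, NA_character_,
                                                 role = "unknown"))
    }
  }
  replicates <- sim_replicates(genotypes, n_replicates, allele_error,
                               dropout_rate, seed = seeds[5])
  list(freqs = freqs, genotypes = genotypes, popmap = popmap,
       replicates = replicates)
}

## derive independent substream seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
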