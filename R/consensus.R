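#' Per-replicate call rates and exclusion flags
#'
#' The call rate of a replicate is the percentage of panel loci with a
#' genotype call. Replicates at or below `min_call_rate` percent are
#' flagged for exclusion before consensus building.
#'
#' @param reps replicate table (`sample_id`, `replicate`, then one column
#'   per locus), e.g. from [sim_replicates()] or [read_genotype_table()].
#' @param min_call_rate exclusion threshold in percent (default 85;
#'   replicates with `call_rate <= min_call_rate` are excluded).
#' @return tibble `sample_id`, `replicate`, `call_rate`, `excluded`.
#' @export
replicate_call_rates <- function(reps, min_call_rate = 85) {
  loci <- setdiff(names(reps), c("sample_id", "replicate"))
  g <- as.matrix(reps[loci])
  rate <- 100 * rowMeans(!is.na(g))
  tibble::tibble(sample_id = reps$sample_id, replicate = reps$replicate,
                 call_rate = rate, excluded = rate <= min_call_rate)
}

#' @rdname replicate_call_rates
#' @return `sample_call_rates()`: tibble `sample_id`, `mean_call_rate`,
#'   `n_replicates`, `n_excluded`, `failed` (all replicates excluded).
#' @export
sample_call_rates <- function(reps, min_call_rate = 85) {
  replicate_call_rates(reps, min_call_rate) %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(mean_call_rate = mean(.data$call_rate),
                     n_replicates = dplyr::n(),
                     n_excluded = sum(.data$excluded),
                     failed = all(.data$excluded), .groups = "drop")
}

#' Locus success filter over all reactions
#'
#' A locus is retained when it amplified (yielded a call) in at least
#' `min_success` of all sample-by-replicate reactions; weaker loci distort
#' replicate-concordance estimates and are removed before consensus.
#'
#' @inheritParams replicate_call_rates
#' @param min_success minimum success fraction (default 0.8, boundary
#'   inclusive).
#' @return tibble `locus_id`, `success`, `retained`.
#' @export
locus_success_filter <- function(reps, min_success = 0.8) {
  loci <- setdiff(names(reps), c("sample_id", "replicate"))
  g <- as.matrix(reps[loci])
  succ <- unname(colMeans(!is.na(g)))
  tibble::tibble(locus_id = loci, success = succ,
                 retained = succ >= min_success)
}

#' Consensus genotypes from replicated assay runs
#'
#' After excluding low-call-rate replicates, the consensus at each locus of
#' each sample follows majority logic over the remaining replicate calls:
#'
#' * two or more replicates missing: the locus is classed *insufficient*
#'   and the consensus is missing;
#' * otherwise the plurality genotype wins (three consistent homozygotes
#'   beat one heterozygote; two heterozygotes beat one each of the two
#'   contrasting homozygotes);
#' * an unresolved plurality tie (e.g. two homozygous-reference vs two
#'   homozygous-alternate calls with no heterozygote) yields a missing
#'   consensus, logged as class *tie*.
#'
#' Replicate concordance is summarised per sample as the Match Score (mean
#' percentage of allele copies agreeing over all replicate pairs, loci
#' missing in either member skipped) and the genotyping error rate,
#' defined as 100 minus the Match Score.
#'
#' @inheritParams replicate_call_rates
#' @return list with `genotypes` (consensus genotype table), `qc` (per
#'   sample: mean call rate, replicates used, match score, error rate,
#'   failed flag) and `agreement` (long tibble sample x locus with class
#'   `agree`/`disagree`/`insufficient`/`tie`).
#' @export
build_consensus <- function(reps, min_call_rate = 85) {
  loci <- setdiff(names(reps), c("sample_id", "replicate"))
  rates <- replicate_call_rates(reps, min_call_rate)
  keep <- !rates$excluded
  used <- reps[keep, , drop = FALSE]
  samples <- unique(reps$sample_id)
  cons <- matrix(NA_integer_, length(samples), length(loci),
                 dimnames = list(samples, loci))
  agreement <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    block <- as.matrix(used[used$sample_id == samples[i], loci,
                            drop = FALSE])
    res <- apply(block, 2, consensus_call)
    cons[i, ] <- vapply(res, `[[`, integer(1), "code")
    agreement[[i]] <- tibble::tibble(
      sample_id = samples[i], locus_id = loci,
      class = vapply(res, `[[`, character(1), "class"))
  }
  qc <- sample_call_rates(reps, min_call_rate)
  ms <- match_score(used)
  qc <- dplyr::left_join(qc, ms, by = "sample_id")
  list(genotypes = as_geno_tbl(cons), qc = qc,
       agreement = dplyr::bind_rows(agreement))
}

consensus_call <- function(calls) {
  n_miss <- sum(is.na(calls))
  obs <- calls[!is.na(calls)]
  if (length(calls) == 0 || n_miss >= 2 || length(obs) == 0) {
    return(list(code = NA_integer_, class = "insufficient"))
  }
  tab <- tabulate(obs + 1L, nbins = 3L)
  winners <- which(tab == max(tab)) - 1L
  if (length(winners) > 1L) {
    return(list(code = NA_integer_, class = "tie"))
  }
  list(code = as.integer(winners),
       class = if (length(unique(obs)) == 1L) "agree" else "disagree")
}

#' Match Score and genotyping error rate
#'
#' The Match Score of two genotype vectors is the percentage of allele
#' copies that agree over loci called in both (a heterozygote vs a
#' homozygote shares 1 of 2 copies). For a replicate table the per-sample
#' score is the mean over all replicate pairs. The error rate is exactly
#' `100 - match_score`.
#'
#' @param x replicate table, or a genotype vector (codes 0/1/2/NA).
#' @param y second genotype vector when `x` is a vector.
#' @return tibble with `match_score`, `error_rate`, `n_compared` (allele
#'   copies compared); per `sample_id` for a replicate table. Samples (or
#'   pairs) with no comparable loci get `NA` scores.
#' @export
match_score <- function(x, y = NULL) {
  if (!is.null(y)) {
    p <- pair_match(as.integer(x), as.integer(y))
    return(tibble::tibble(match_score = unname(p["score"]),
                          error_rate = unname(100 - p["score"]),
                          n_compared = unname(p["n"])))
  }
  loci <- setdiff(names(x), c("sample_id", "replicate"))
  x %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::group_modify(function(df, key) {
      g <- as.matrix(df[loci])
      if (nrow(g) < 2) {
        return(tibble::tibble(match_score = NA_real_, error_rate = NA_real_,
                              n_compared = 0))
      }
      prs <- utils::combn(nrow(g), 2)
      res <- apply(prs, 2, function(ij) pair_match(g[ij[1], ], g[ij[2], ]))
      score <- mean(res["score", ], na.rm = TRUE)
      tibble::tibble(match_score = score, error_rate = 100 - score,
                     n_compared = sum(res["n", ]))
    }) %>%
    dplyr::ungroup()
}

pair_match <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(c(score = NA_real_, n = 0))
  shared <- 2 - abs(a[ok] - b[ok])
  c(score = 100 * sum(shared) / (2 * sum(ok)), n = 2 * sum(ok))
}
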