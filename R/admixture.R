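#' Model-based ancestry estimation by EM (ADMIXTURE-style)
#'
#' Fits the binomial admixture model: each of the two allele copies of
#' individual `i` at locus `l` originates from cluster `k` with probability
#' `q_ik` and is then the alternate allele with probability `f_kl`, so the
#' genotype is `Binomial(2, m_il)` with `m_il = sum_k q_ik f_kl`. The
#' log-likelihood
#' \deqn{\ell = \sum_{i,l} g_{il} \log m_{il} + (2 - g_{il}) \log(1 - m_{il})}
#' is maximised by EM block updates of `Q` (rows on the simplex) and `F`
#' (clamped to `[1e-6, 1 - 1e-6]`); it is non-decreasing at every
#' iteration. Missing genotypes contribute nothing to the likelihood.
#' Individuals whose largest ancestry fraction is below `admixed_cutoff`
#' are flagged admixed.
#'
#' @param x genotype table or `snp_geno`.
#' @param K number of ancestral clusters (`K >= 1`).
#' @param seed optional integer seed for the random initialisation.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence threshold on the log-likelihood gain
#'   (default 1e-6).
#' @param admixed_cutoff flag a sample admixed when `max_k q_ik` is below
#'   this (default 0.8).
#' @return object of class `"admixture_fit"`: `Q` (samples x K), `F`
#'   (K x loci), `loglik`, `loglik_trace`, `K`, `converged`, `n_iter`,
#'   `admixed` (named logical).
#' @export
admixture_em <- function(x, K, seed = NULL, max_iter = 500, tol = 1e-6,
                         admixed_cutoff = 0.8) {
  stopifnot(K >= 1)
  g <- as_geno_matrix(x)
  mode(g) <- "double"
  fit <- with_seed(seed, admixture_em_fit(g, K, max_iter, tol))
  if (!fit$converged) {
    warning(sprintf("EM did not converge in %d iterations", max_iter))
  }
  fit$admixed <- apply(fit$Q, 1, max) < admixed_cutoff
  fit$admixed_cutoff <- admixed_cutoff
  structure(fit, class = "admixture_fit")
}

admixture_em_fit <- function(g, K, max_iter, tol) {
  eps <- 1e-6
  N <- nrow(g); L <- ncol(g)
  obs <- !is.na(g)
  g0 <- ifelse(obs, g, 0)                  # alt copies, 0 where missing
  r0 <- ifelse(obs, 2 - g, 0)              # ref copies
  L_i <- rowSums(obs)
  ## init: perturbed observed frequencies, near-uniform Q
  p_hat <- colSums(g0) / pmax(2 * colSums(obs), 1)
  Fm <- matrix(pmin(pmax(rep(p_hat, each = K) +
                           stats::runif(K * L, -0.1, 0.1), eps), 1 - eps),
               nrow = K)
  Q <- matrix(stats::rexp(N * K) + 1, nrow = N)
  Q <- Q / rowSums(Q)
  loglik <- function(M) sum(g0 * log(M) + r0 * log(1 - M))
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M <- Q %*% Fm
    M <- pmin(pmax(M, eps), 1 - eps)
    A_sum <- matrix(0, N, K)                 # expected copies per cluster
    F_num <- matrix(0, K, L)
    F_den <- matrix(0, K, L)
    for (k in seq_len(K)) {
      wk_alt <- (Q[, k] %o% Fm[k, ]) / M            # resp. of alt copies
      wk_ref <- (Q[, k] %o% (1 - Fm[k, ])) / (1 - M)
      Ea <- g0 * wk_alt
      Er <- r0 * wk_ref
      A_sum[, k] <- rowSums(Ea) + rowSums(Er)
      F_num[k, ] <- colSums(Ea)
      F_den[k, ] <- colSums(Ea) + colSums(Er)
    }
    Q <- A_sum / pmax(2 * L_i, 1)
    bad <- rowSums(Q) <= 0
    Q[bad, ] <- 1 / K
    Q <- Q / rowSums(Q)
    Fm <- ifelse(F_den > 0, F_num / F_den, Fm)
    Fm <- pmin(pmax(Fm, eps), 1 - eps)
    M <- pmin(pmax(Q %*% Fm, eps), 1 - eps)
    cur <- loglik(M)
    trace <- c(trace, cur)
    if (is.finite(prev) && cur - prev < tol) { converged <- TRUE; break }
    prev <- cur
  }
  dimnames(Q) <- list(rownames(g), paste0("cluster", seq_len(K)))
  dimnames(Fm) <- list(paste0("cluster", seq_len(K)), colnames(g))
  list(Q = Q, F = Fm, loglik = trace[length(trace)], loglik_trace = trace,
       K = K, converged = converged, n_iter = length(trace))
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("<admixture_fit> K = %d, %d samples, %d loci\n",
              x$K, nrow(x$Q), ncol(x$F)))
  cat(sprintf("  loglik %.2f after %d iterations (%s); %d admixed (q < %g)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged",
              sum(x$admixed), x$admixed_cutoff))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an admixture fit into a long ancestry table
#'
#' @param x an `"admixture_fit"`.
#' @param ... unused.
#' @return tibble `sample_id`, `cluster`, `q`, `admixed`.
#' @export
tidy.admixture_fit <- function(x, ...) {
  tibble::as_tibble(x$Q, rownames = "sample_id") %>%
    tidyr::pivot_longer(-"sample_id", names_to = "cluster",
                        values_to = "q") %>%
    dplyr::mutate(admixed = x$admixed[.data$sample_id])
}

#' @rdname tidy.admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, n_admixed = sum(x$admixed))
}

#' Ancestry bar plot for an admixture fit
#'
#' @param object an `"admixture_fit"`.
#' @param popmap optional [pop_map()] used to order samples by group.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.admixture_fit <- function(object, popmap = NULL, ...) {
  df <- tidy(object)
  if (!is.null(popmap)) {
    ord <- popmap$sample[order(popmap$group)]
    df$sample_id <- factor(df$sample_id,
                           levels = c(intersect(ord, df$sample_id),
                                      setdiff(unique(df$sample_id), ord)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$q,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry fraction q") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Choose the number of clusters by masked-entry cross-validation
#'
#' For each candidate `K` and each replicate, a fraction of the non-missing
#' genotype entries is masked, the admixture model is fitted to the masked
#' data, and the masked entries are predicted by their expected dosage
#' `2 * sum_k q_ik f_kl`. The CV error is the mean squared prediction error
#' on the masked entries; the best `K` minimises the mean CV error over
#' replicates.
#'
#' @inheritParams admixture_em
#' @param k_range candidate cluster numbers (default `1:6`).
#' @param cv_fraction fraction of non-missing entries masked per replicate
#'   (default 0.2).
#' @param n_replicates masking replicates per `K` (default 5).
#' @param max_iter,tol EM settings passed to the fits.
#' @return object of class `"k_selection"`: `cv` (tibble `k`, `replicate`,
#'   `cv_error`), `summary` (tibble `k`, `mean_cv`), `best_k`.
#' @export
select_k <- function(x, k_range = 1:6, cv_fraction = 0.2, n_replicates = 5,
                     seed = NULL, max_iter = 200, tol = 1e-4) {
  g <- as_geno_matrix(x)
  mode(g) <- "double"
  obs_idx <- which(!is.na(g))
  if (length(obs_idx) < 10) stop("too few non-missing genotypes to mask")
  seeds <- derive_seeds(seed, n_replicates)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    mask <- with_seed(seeds[[r]], sample(obs_idx,
                                         round(cv_fraction * length(obs_idx))))
    g_tr <- g
    g_tr[mask] <- NA
    if (all(is.na(g_tr))) next              # degenerate mask
    truth <- g[mask]
    for (k in k_range) {
      fit <- with_seed(seeds[[r]], admixture_em_fit(g_tr, k, max_iter, tol))
      pred <- 2 * (fit$Q %*% fit$F)[mask]
      rows[[length(rows) + 1]] <- tibble::tibble(
        k = k, replicate = r, cv_error = mean((truth - pred)^2))
    }
  }
  cv <- dplyr::bind_rows(rows)
  summary <- cv %>%
    dplyr::group_by(.data$k) %>%
    dplyr::summarise(mean_cv = mean(.data$cv_error), .groups = "drop")
  structure(list(cv = cv, summary = summary,
                 best_k = summary$k[which.min(summary$mean_cv)]),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> best K = %d\n", x$best_k))
  print(x$summary)
  invisible(x)
}

#' @rdname tidy.admixture_fit
#' @export
tidy.k_selection <- function(x, ...) x$cv

#' @rdname tidy.admixture_fit
#' @export
glance.k_selection <- function(x, ...) {
  tibble::tibble(best_k = x$best_k,
                 min_mean_cv = min(x$summary$mean_cv),
                 n_k = nrow(x$summary))
}

#' Cross-validation curve for K selection
#'
#' @param object a `"k_selection"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$k,
                                          y = .data$cv_error)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = object$summary,
                       ggplot2::aes(y = .data$mean_cv), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = 2) +
    ggplot2::labs(x = "K (clusters)", y = "masked-entry CV error") +
    ggplot2::theme_minimal()
}
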