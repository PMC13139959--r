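# small deterministic fixtures used across test files

# genotype table from a literal matrix (rows = samples)
make_geno <- function(codes, samples = NULL, loci = NULL) {
  m <- as.matrix(codes)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- loci %||% paste0("L", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  as_geno_tbl(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# replicate table from a named list sample -> matrix (replicates x loci)
make_reps <- function(blocks, loci = NULL) {
  out <- lapply(names(blocks), function(s) {
    m <- as.matrix(blocks[[s]])
    colnames(m) <- loci %||% paste0("L", seq_len(ncol(m)))
    dplyr::bind_cols(
      tibble::tibble(sample_id = s, replicate = seq_len(nrow(m))),
      tibble::as_tibble(m)
    )
  })
  dplyr::bind_rows(out)
}

# strongly diverged three-population frequency table (near-fixed loci)
diverged_freqs <- function(n_loci = 60, seed = 1) {
  sim_frequencies(n_loci, n_pops = 3, fst = c(0.9, 0.97),
                  maf_range = c(0.4, 0.5),
                  pop_labels = c("A", "B", "C"), seed = seed)
}
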