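# Small in-code fixtures shared across tests.

# One 10 kb chromosome with a single island at [4000, 5000) (BED).
tiny_islands <- function() {
  tibble::tibble(chr = "1", start = 4000L, end = 5000L, name = "CGI_1")
}

# A + strand gene on chromosome 1: transcript 3000..9000, two exons
# 3000..4000 and 6000..9000, CDS 3500..8000.
tiny_gene <- function(strand = "+") {
  if (strand == "+") {
    tibble::tibble(
      gene = "G1", chr = "1", strand = "+", start = 3000L, end = 9000L,
      tss = 3000L, cds_start = 3500L, cds_end = 8000L,
      exon_starts = "3000,6000", exon_ends = "4000,9000"
    )
  } else {
    tibble::tibble(
      gene = "G1", chr = "1", strand = "-", start = 3000L, end = 9000L,
      tss = 9000L, cds_start = 3500L, cds_end = 8000L,
      exon_starts = "3000,6000", exon_ends = "4000,9000"
    )
  }
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(
      n_probes = 600, n_islands = 40, n_genes = 60,
      chromosome_lengths = stats::setNames(rep(500000L, 4), as.character(1:4))
    ),
    list(...)
  )
  do.call(methcall::synth_config, args)
}

# Long signal tibble from explicit A/B matrices.
signals_from_matrices <- function(A, B, groups = NULL) {
  probes <- rownames(A) %||% paste0("p", seq_len(nrow(A)))
  samples <- colnames(A) %||% paste0("s", seq_len(ncol(A)))
  out <- tibble::tibble(
    probe_id = rep(probes, times = ncol(A)),
    sample_id = rep(samples, each = nrow(A)),
    A = as.vector(A), B = as.vector(B)
  )
  if (!is.null(groups)) {
    out$group <- rep(groups, each = nrow(A))
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
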