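# Internal helpers shared across modules.

# Single point of truth for the BED <-> probe coordinate convention:
# intervals on disk are 0-based half-open [start, end); probe positions and
# all in-memory interval columns are 1-based inclusive.
bed_to_1based <- function(start, end) {
  list(start = start + 1L, end = end)
}

onebased_to_bed <- function(start, end) {
  list(start = start - 1L, end = end)
}

# Chromosome names sort numerically where possible ("1" < "2" < "10"),
# falling back to lexicographic for non-numeric names. chrom_order() is the
# row permutation, chrom_rank() the per-element sort key (for arrange()).
chrom_order <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  order(is.na(num), num, chr)
}

chrom_rank <- function(chr) {
  u <- unique(chr)
  num <- suppressWarnings(as.numeric(u))
  match(chr, u[order(is.na(num), num, u)])
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(
      sprintf("`%s` must be a single number in [%s, %s].", name, min, max),
      class = "methcall_argument_error"
    )
  }
  invisible(x)
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s is missing required column(s): %s.",
        what, paste(missing, collapse = ", ")
      ),
      class = "methcall_argument_error"
    )
  }
  invisible(data)
}

# Long (probe_id, sample_id, value) -> probes x samples matrix, preserving
# first-appearance order of probes and samples.
long_to_matrix <- function(data, value) {
  probes <- unique(data$probe_id)
  samples <- unique(data$sample_id)
  mat <- matrix(
    NA_real_, nrow = length(probes), ncol = length(samples),
    dimnames = list(probes, samples)
  )
  mat[cbind(
    match(data$probe_id, probes),
    match(data$sample_id, samples)
  )] <- data[[value]]
  mat
}

matrix_to_long <- function(mat, value) {
  tibble(
    probe_id = rep(rownames(mat), times = ncol(mat)),
    sample_id = rep(colnames(mat), each = nrow(mat)),
    !!value := as.vector(mat)
  )
}
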