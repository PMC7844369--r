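# Synthetic 850K-style array generator: manifest, genomic features,
# two-channel signals with planted group effects, and ground truth.

# Autosome lengths proportional to the human genome, scaled to desk size
# (1/100 of Mb-scale lengths), chromosomes "1".."22".
default_chromosome_lengths <- function() {
  mb <- c(
    249, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135,
    133, 114, 107, 102, 90, 83, 80, 59, 64, 47, 51
  )
  setNames(as.integer(mb * 1e4), as.character(1:22))
}

#' Configuration for the synthetic methylation-array generator
#'
#' Bundles and validates every tunable of the generator. The defaults are
#' the package's reference study conditions: a 20,000-probe desk-scale
#' stand-in for an 850K array over 22 autosomes, 6 case vs 6 control
#' samples, 5% planted differentially methylated probes of which 14% are
#' hypermethylated in the case group (a hyper:hypo ratio of about 0.16),
#' and a target |delta-beta| of 0.35.
#'
#' @param n_probes Number of probes (0 allowed, yields empty outputs).
#' @param chromosome_lengths Named integer vector of chromosome lengths in
#'   bp; names are the chromosome names.
#' @param n_islands Number of CpG islands, allocated to chromosomes
#'   proportionally to length; non-overlapping within a chromosome.
#' @param island_length_range Length 2 numeric, min/max island length (bp).
#' @param n_genes Number of gene models (overlaps between genes permitted).
#' @param n_samples_per_group Samples in each of the case and control groups.
#' @param frac_dmp Fraction of probes with a planted group effect.
#' @param hyper_fraction Share of planted probes that are hypermethylated
#'   in the case group (the rest are hypomethylated).
#' @param effect_delta_beta Target |delta-beta| of planted probes. The shift
#'   is applied to the case-group mean on the logit scale (a probe-specific
#'   M-value offset chosen so the beta-scale difference equals this target),
#'   with means clipped to [0.01, 0.99].
#' @param beta_shapes1,beta_shapes2 Shape pairs of the two Beta components
#'   of the baseline methylation mixture; the defaults, `c(0.5, 8)` and
#'   `c(8, 0.5)` at equal weight, emulate the bimodal (mostly un- or mostly
#'   fully-methylated) beta landscape of methylation arrays.
#' @param beta_mix_weight Mixing weight of the low-methylation component.
#' @param intensity_scale Expected total intensity A + B per probe.
#' @param noise_sd Gaussian intensity noise SD per channel; noise may drive
#'   intensities negative on purpose (the beta formula guards with
#'   `max(., 0)`).
#' @param background_level Additive background on both channels.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_probes = 20000,
                         chromosome_lengths = default_chromosome_lengths(),
                         n_islands = 400,
                         island_length_range = c(500, 2000),
                         n_genes = 1000,
                         n_samples_per_group = 6,
                         frac_dmp = 0.05,
                         hyper_fraction = 0.14,
                         effect_delta_beta = 0.35,
                         beta_shapes1 = c(0.5, 8),
                         beta_shapes2 = c(8, 0.5),
                         beta_mix_weight = 0.5,
                         intensity_scale = 10000,
                         noise_sd = 300,
                         background_level = 200,
                         seed = 1L) {
  assert_scalar_number(n_probes, "n_probes", min = 0)
  assert_scalar_number(n_islands, "n_islands", min = 0)
  assert_scalar_number(n_genes, "n_genes", min = 0)
  assert_scalar_number(n_samples_per_group, "n_samples_per_group", min = 1)
  assert_scalar_number(frac_dmp, "frac_dmp", min = 0, max = 1)
  assert_scalar_number(hyper_fraction, "hyper_fraction", min = 0, max = 1)
  assert_scalar_number(effect_delta_beta, "effect_delta_beta", min = 0, max = 0.98)
  assert_scalar_number(beta_mix_weight, "beta_mix_weight", min = 0, max = 1)
  assert_scalar_number(intensity_scale, "intensity_scale", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(background_level, "background_level", min = 0)
  assert_scalar_number(seed, "seed", min = -2^31, max = 2^31 - 1)
  if (is.null(names(chromosome_lengths)) || any(chromosome_lengths <= 0)) {
    abort("`chromosome_lengths` must be a named vector of positive lengths.",
      class = "methcall_argument_error"
    )
  }
  if (length(island_length_range) != 2 ||
    island_length_range[1] > island_length_range[2] ||
    island_length_range[1] <= 0) {
    abort("`island_length_range` must be an increasing positive pair.",
      class = "methcall_argument_error"
    )
  }
  if (island_length_range[2] >= min(chromosome_lengths)) {
    abort("Island lengths must be shorter than every chromosome.",
      class = "methcall_argument_error"
    )
  }
  structure(
    list(
      n_probes = as.integer(n_probes),
      chromosome_lengths = chromosome_lengths,
      n_islands = as.integer(n_islands),
      island_length_range = island_length_range,
      n_genes = as.integer(n_genes),
      n_samples_per_group = as.integer(n_samples_per_group),
      frac_dmp = frac_dmp,
      hyper_fraction = hyper_fraction,
      effect_delta_beta = effect_delta_beta,
      beta_shapes1 = beta_shapes1,
      beta_shapes2 = beta_shapes2,
      beta_mix_weight = beta_mix_weight,
      intensity_scale = intensity_scale,
      noise_sd = noise_sd,
      background_level = background_level,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Allocate n features to chromosomes proportionally to length,
# deterministically (largest remainders).
allocate_by_length <- function(n, lengths) {
  if (n == 0) {
    return(setNames(integer(length(lengths)), names(lengths)))
  }
  frac <- lengths / sum(lengths) * n
  base <- floor(frac)
  rem <- n - sum(base)
  extra <- order(frac - base, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1
  setNames(as.integer(base), names(lengths))
}

# k non-overlapping intervals of the given lengths on [1, L]; errors when
# they do not fit.
place_nonoverlapping <- function(k, lens, L, chrom) {
  total <- sum(lens)
  free <- L - total
  if (k == 0) {
    return(tibble(start1 = integer(0), end1 = integer(0)))
  }
  if (free < 0) {
    abort(
      sprintf(
        "Cannot place %d features totalling %d bp on chromosome %s (%d bp).",
        k, total, chrom, L
      ),
      class = "methcall_sizing_error"
    )
  }
  offs <- sort(floor(runif(k, 0, free + 1)))
  start1 <- offs + cumsum(c(0, lens[-k])) + 1L
  tibble(start1 = as.integer(start1), end1 = as.integer(start1 + lens - 1L))
}

#' Generate a synthetic probe manifest, CpG islands and gene models
#'
#' Islands and genes are allocated to chromosomes proportionally to length;
#' islands are non-overlapping within a chromosome. About 30% of probes are
#' placed inside islands (emulating the CpG-dense targeting of array
#' designs), the rest uniformly. The returned probes are annotated with
#' gene regions and CpG-island context via [annotate_manifest()] and sorted
#' by (chromosome, position).
#'
#' @param config A [synth_config()].
#' @return A list of class `methyl_manifest` with tibbles `probes`
#'   (`probe_id`, `chr`, `pos`, `strand`, `gene`, `region`, `cgi_context`),
#'   `islands` (BED-convention `chr`, `start`, `end`, `name`), and `genes`
#'   (`gene`, `chr`, `strand`, `start`, `end`, `tss`, `cds_start`,
#'   `cds_end`, `exon_starts`, `exon_ends`).
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  lens <- config$chromosome_lengths
  chroms <- names(lens)

  n_isl <- allocate_by_length(config$n_islands, lens)
  islands <- purrr::map_dfr(chroms, function(cc) {
    k <- n_isl[[cc]]
    if (k == 0) {
      return(tibble(
        chr = character(0), start = integer(0),
        end = integer(0), name = character(0)
      ))
    }
    il <- as.integer(round(runif(
      k, config$island_length_range[1],
      config$island_length_range[2]
    )))
    pl <- place_nonoverlapping(k, il, lens[[cc]], cc)
    bed <- onebased_to_bed(pl$start1, pl$end1)
    tibble(chr = cc, start = bed$start, end = bed$end, name = NA_character_)
  })
  if (nrow(islands) > 0) {
    islands$name <- sprintf("CGI_%04d", seq_len(nrow(islands)))
  }

  n_gen <- allocate_by_length(config$n_genes, lens)
  genes <- purrr::map_dfr(chroms, function(cc) {
    k <- n_gen[[cc]]
    if (k == 0) return(NULL)
    span <- pmin(
      as.integer(round(runif(k, 5000, 50000))),
      lens[[cc]] - 2L
    )
    start <- as.integer(floor(runif(k, 1, lens[[cc]] - span)))
    tibble(
      chr = cc, strand = sample(c("+", "-"), k, replace = TRUE),
      start = start, end = start + span
    )
  })
  if (nrow(genes) > 0) {
    genes$gene <- sprintf("GENE%04d", seq_len(nrow(genes)))
    ex <- purrr::map2(genes$start, genes$end, sample_exons)
    genes$exon_starts <- purrr::map_chr(ex, ~ paste(.x$start, collapse = ","))
    genes$exon_ends <- purrr::map_chr(ex, ~ paste(.x$end, collapse = ","))
    first_len <- purrr::map_int(ex, ~ .x$end[1] - .x$start[1] + 1L)
    last_len <- purrr::map_int(ex, ~ .x$end[length(.x$end)] - .x$start[length(.x$start)] + 1L)
    genes$cds_start <- genes$start + as.integer(ceiling(0.5 * first_len))
    genes$cds_end <- genes$end - as.integer(ceiling(0.5 * last_len))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    genes <- genes[, c(
      "gene", "chr", "strand", "start", "end", "tss",
      "cds_start", "cds_end", "exon_starts", "exon_ends"
    )]
  } else {
    genes <- tibble(
      gene = character(0), chr = character(0), strand = character(0),
      start = integer(0), end = integer(0), tss = integer(0),
      cds_start = integer(0), cds_end = integer(0),
      exon_starts = character(0), exon_ends = character(0)
    )
  }

  n_pr <- allocate_by_length(config$n_probes, lens)
  probes <- purrr::map_dfr(chroms, function(cc) {
    k <- n_pr[[cc]]
    if (k == 0) return(NULL)
    isl <- islands[islands$chr == cc, , drop = FALSE]
    n_in_isl <- if (nrow(isl) > 0) rbinom(1, k, 0.3) else 0L
    pos_isl <- integer(0)
    if (n_in_isl > 0) {
      pick <- sample.int(nrow(isl), n_in_isl, replace = TRUE)
      coords <- bed_to_1based(isl$start[pick], isl$end[pick])
      pos_isl <- as.integer(floor(runif(n_in_isl, coords$start, coords$end + 1)))
    }
    pos_unif <- as.integer(ceiling(runif(k - n_in_isl, 0, lens[[cc]])))
    tibble(chr = cc, pos = c(pos_isl, pos_unif))
  })
  if (nrow(probes) > 0) {
    probes <- arrange(probes, chrom_rank(.data$chr), .data$pos)
    probes <- mutate(probes,
      probe_id = sprintf("cg%08d", dplyr::row_number()),
      strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)
    )
  } else {
    probes <- tibble(
      chr = character(0), pos = integer(0),
      probe_id = character(0), strand = character(0)
    )
  }
  probes <- annotate_manifest(probes, genes, islands)

  structure(
    list(probes = probes, islands = islands, genes = genes, config = config),
    class = "methyl_manifest"
  )
}

#' @importFrom stats rbinom
sample_exons <- function(start, end) {
  span <- end - start + 1L
  n_ex <- sample(2:6, 1)
  if (span < 4L * n_ex) {
    return(list(start = start, end = end))
  }
  pts <- sort(sample(seq(start + 1L, end - 1L), 2L * (n_ex - 1L)))
  list(
    start = as.integer(c(start, pts[seq(2, length(pts), by = 2)] + 1L)),
    end = as.integer(c(pts[seq(1, length(pts), by = 2)], end))
  )
}

#' @export
print.methyl_manifest <- function(x, ...) {
  cat(sprintf(
    "<methyl_manifest> %d probes, %d islands, %d genes on %d chromosomes\n",
    nrow(x$probes), nrow(x$islands), nrow(x$genes),
    length(x$config$chromosome_lengths)
  ))
  print(head(x$probes, 5))
  invisible(x)
}

#' Simulate two-channel intensities with planted group effects
#'
#' Draws a baseline methylation level per probe from a bimodal Beta
#' mixture, plants hyper-/hypomethylation effects in the case group for a
#' configured fraction of probes (shifting the case-group mean on the logit
#' scale so the beta-scale difference equals `effect_delta_beta`, clipped
#' to `[0.01, 0.99]`), and converts methylation levels to methylated (B)
#' and unmethylated (A) channel intensities with additive background and
#' Gaussian noise. Noise may drive intensities negative; downstream
#' [compute_beta()] guards with `max(., 0)`.
#'
#' Baselines for which the full effect cannot be realized inside the clip
#' bounds are re-drawn from the mixture (at most 100 retries per probe).
#'
#' @param manifest A `methyl_manifest` from [generate_manifest()].
#' @param config The same [synth_config()] used for the manifest.
#' @return A list of class `methyl_signals`: `signals` (long tibble
#'   `probe_id`, `sample_id`, `group`, `A`, `B`), `samples` (`sample_id`,
#'   `group`), and `truth` (`probe_id`, `is_dmp`, `direction`,
#'   `true_delta_beta`).
#' @export
simulate_signals <- function(manifest, config) {
  stopifnot(inherits(manifest, "methyl_manifest"), inherits(config, "synth_config"))
  probes <- manifest$probes
  if (nrow(probes) == 0) {
    abort("Manifest has no probes; nothing to simulate.",
      class = "methcall_argument_error"
    )
  }
  if (config$n_samples_per_group < 2) {
    abort("Need at least 2 samples per group.", class = "methcall_argument_error")
  }
  set.seed(config$seed + 1L)
  n <- nrow(probes)

  draw_baseline <- function(k) {
    comp <- runif(k) < config$beta_mix_weight
    ifelse(comp,
      rbeta(k, config$beta_shapes1[1], config$beta_shapes1[2]),
      rbeta(k, config$beta_shapes2[1], config$beta_shapes2[2])
    )
  }
  beta0 <- draw_baseline(n)

  n_dmp <- round(config$frac_dmp * n)
  n_hyper <- round(config$hyper_fraction * n_dmp)
  planted <- sample.int(n, n_dmp)
  direction <- rep("none", n)
  direction[planted] <- c(
    rep("hyper", n_hyper),
    rep("hypo", n_dmp - n_hyper)
  )

  delta <- config$effect_delta_beta
  lo <- 0.01
  hi <- 0.99
  # re-draw baselines that cannot carry the full planted shift
  for (dir in c("hyper", "hypo")) {
    idx <- which(direction == dir)
    if (length(idx) == 0) next
    ok <- function(b) {
      if (dir == "hyper") b >= lo & b + delta <= hi else b - delta >= lo & b <= hi
    }
    tries <- 0
    bad <- idx[!ok(beta0[idx])]
    while (length(bad) > 0 && tries < 100) {
      beta0[bad] <- draw_baseline(length(bad))
      bad <- bad[!ok(beta0[bad])]
      tries <- tries + 1
    }
    if (length(bad) > 0) {
      abort(
        sprintf(
          "Could not realize a |delta-beta| of %.3f for %d probe(s) after 100 retries.",
          delta, length(bad)
        ),
        class = "methcall_sizing_error"
      )
    }
  }

  beta_case <- beta0 +
    ifelse(direction == "hyper", delta, 0) -
    ifelse(direction == "hypo", delta, 0)
  planted_idx <- direction != "none"
  beta_case[planted_idx] <- pmin(pmax(beta_case[planted_idx], lo), hi)

  n_per <- config$n_samples_per_group
  samples <- tibble(
    sample_id = c(
      sprintf("case_%02d", seq_len(n_per)),
      sprintf("control_%02d", seq_len(n_per))
    ),
    group = rep(c("case", "control"), each = n_per)
  )

  beta_mat <- cbind(
    matrix(beta_case, n, n_per),
    matrix(beta0, n, n_per)
  )
  total <- config$intensity_scale
  noise_b <- matrix(rnorm(n * 2 * n_per, 0, config$noise_sd), n, 2 * n_per)
  noise_a <- matrix(rnorm(n * 2 * n_per, 0, config$noise_sd), n, 2 * n_per)
  B <- total * beta_mat + config$background_level + noise_b
  A <- total * (1 - beta_mat) + config$background_level + noise_a
  dimnames(A) <- dimnames(B) <- list(probes$probe_id, samples$sample_id)

  signals <- matrix_to_long(A, "A") |>
    mutate(B = as.vector(B)) |>
    left_join(samples, by = "sample_id") |>
    relocate("probe_id", "sample_id", "group")

  truth <- tibble(
    probe_id = probes$probe_id,
    is_dmp = direction != "none",
    direction = direction,
    true_delta_beta = beta_case - beta0
  )

  structure(
    list(signals = signals, samples = samples, truth = truth),
    class = "methyl_signals"
  )
}

#' @export
print.methyl_signals <- function(x, ...) {
  cat(sprintf(
    "<methyl_signals> %d probes x %d samples (%s); %d planted DMPs\n",
    length(unique(x$signals$probe_id)), nrow(x$samples),
    paste(table(x$samples$group), collapse = " vs "),
    sum(x$truth$is_dmp)
  ))
  invisible(x)
}
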