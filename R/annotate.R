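#' Classify probes by CpG-island context
#'
#' Assigns each probe position one of the four canonical CpG-island context
#' classes used on methylation arrays: `island` (inside an island), `shore`
#' (within 2 kb of an island boundary), `shelf` (2--4 kb away) and
#' `open_sea` (more than 4 kb away, or on a chromosome with no island).
#' Distance is measured in bp from the probe to the nearest island boundary,
#' symmetric upstream/downstream, with the shore and shelf bins closed on
#' the right: a probe exactly 2,000 bp away is a shore probe, exactly
#' 4,000 bp away a shelf probe.
#'
#' @param position Integer vector of 1-based probe positions.
#' @param chromosome Character vector of chromosome names, recycled against
#'   `position`.
#' @param islands A data frame of CpG islands with columns `chr`, `start`,
#'   `end` in BED convention (0-based half-open). Islands must not overlap
#'   within a chromosome.
#' @return A character vector, one of `"island"`, `"shore"`, `"shelf"`,
#'   `"open_sea"` per position.
#' @examples
#' islands <- tibble::tibble(chr = "1", start = 4000, end = 5000)
#' classify_cgi_context(c(4500, 5500, 8000, 9900), "1", islands)
#' @export
classify_cgi_context <- function(position, chromosome, islands) {
  assert_columns(islands, c("chr", "start", "end"), "`islands`")
  if (nrow(islands) > 0 && any(islands$start >= islands$end)) {
    bad <- which(islands$start >= islands$end)[1]
    abort(
      sprintf(
        "Malformed island interval at row %d: start (%s) >= end (%s).",
        bad, islands$start[bad], islands$end[bad]
      ),
      class = "methcall_format_error"
    )
  }
  chromosome <- rep_len(as.character(chromosome), length(position))
  d <- island_distance(position, chromosome, islands)
  dplyr::case_when(
    d == 0 ~ "island",
    d <= 2000 ~ "shore",
    d <= 4000 ~ "shelf",
    .default = "open_sea"
  )
}

# bp distance from 1-based positions to the nearest island boundary;
# 0 inside an island, Inf when the chromosome has none.
island_distance <- function(position, chromosome, islands) {
  d <- rep(Inf, length(position))
  if (nrow(islands) == 0) return(d)
  for (cc in unique(chromosome)) {
    idx <- which(chromosome == cc)
    isl <- islands[islands$chr == cc, , drop = FALSE]
    if (nrow(isl) == 0) next
    coords <- bed_to_1based(isl$start, isl$end)
    o <- order(coords$start)
    s1 <- coords$start[o]
    e1 <- coords$end[o]
    if (any(s1[-1] <= e1[-length(e1)])) {
      abort(
        sprintf("Islands overlap on chromosome %s.", cc),
        class = "methcall_format_error"
      )
    }
    pos <- position[idx]
    i <- findInterval(pos, s1)
    inside <- i >= 1 & pos <= e1[pmax(i, 1L)]
    d_prev <- ifelse(i >= 1, pos - e1[pmax(i, 1L)], Inf)
    d_next <- ifelse(i < length(s1), s1[pmin(i + 1L, length(s1))] - pos, Inf)
    d[idx] <- ifelse(inside, 0, pmin(d_prev, d_next))
  }
  d
}

#' Classify a probe position into a gene-region band
#'
#' Strand-aware assignment of the Illumina-style gene-region vocabulary:
#' `TSS200` (0--200 bp upstream of the transcription start site), `TSS1500`
#' (201--1,500 bp upstream), `1stExon`, `5UTR` (exonic between the TSS and
#' the CDS start, outside the first exon), `3UTR` (exonic between the CDS
#' end and the transcript end), and `Body` (anywhere else within the
#' transcript). When several bands apply to one position the precedence is
#' TSS200 > TSS1500 > 1stExon > 5UTR > 3UTR > Body.
#'
#' @param position Integer vector of 1-based probe positions on the gene's
#'   chromosome.
#' @param gene A one-row data frame (or list) with fields `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive transcript span),
#'   `cds_start`, `cds_end`, and `exon_starts`/`exon_ends` (comma-separated
#'   strings or numeric vectors of 1-based inclusive exon bounds).
#' @return Character vector of region labels, `NA` where the position falls
#'   outside all bands of this gene.
#' @export
classify_gene_region <- function(position, gene) {
  strand <- gene$strand[[1]]
  start <- gene$start[[1]]
  end <- gene$end[[1]]
  cds_start <- gene$cds_start[[1]]
  cds_end <- gene$cds_end[[1]]
  ex_s <- parse_bounds(gene$exon_starts[[1]])
  ex_e <- parse_bounds(gene$exon_ends[[1]])
  stopifnot(length(ex_s) == length(ex_e), all(ex_s <= ex_e))

  tss <- if (strand == "+") start else end
  updist <- if (strand == "+") tss - position else position - tss
  exonic <- vapply(
    position,
    function(p) any(p >= ex_s & p <= ex_e),
    logical(1)
  )
  first_i <- if (strand == "+") 1L else length(ex_s)
  in_first <- position >= ex_s[first_i] & position <= ex_e[first_i]
  in_tx <- position >= start & position <= end
  utr5 <- if (strand == "+") position < cds_start else position > cds_end
  utr3 <- if (strand == "+") position > cds_end else position < cds_start

  dplyr::case_when(
    updist >= 1 & updist <= 200 ~ "TSS200",
    updist >= 201 & updist <= 1500 ~ "TSS1500",
    in_tx & in_first ~ "1stExon",
    in_tx & exonic & utr5 ~ "5UTR",
    in_tx & exonic & utr3 ~ "3UTR",
    in_tx ~ "Body",
    .default = NA_character_
  )
}

parse_bounds <- function(x) {
  if (is.character(x)) as.integer(strsplit(x, ",", fixed = TRUE)[[1]]) else as.integer(x)
}

#' Annotate a probe table with gene regions and CpG-island context
#'
#' Every probe receives one CpG-island context label and all `(gene,
#' region)` pairs from gene models it overlaps (including their upstream
#' TSS1500 window); multi-gene annotations are retained. Probes overlapping
#' no gene are intergenic (`gene` and `region` are empty strings).
#' Annotations are stored as `;`-collapsed parallel strings in `gene` and
#' `region`, the manifest CSV convention.
#'
#' @param probes Data frame with columns `probe_id`, `chr`, `pos` (1-based),
#'   and optionally `strand`.
#' @param genes Data frame of gene models (see [classify_gene_region()] for
#'   fields, plus `gene` and `chr`). May have zero rows.
#' @param islands Data frame of CpG islands in BED convention (`chr`,
#'   `start`, `end`). May have zero rows.
#' @return A tibble: the input probes plus `gene`, `region` and
#'   `cgi_context` columns, sorted by (chromosome, position).
#' @export
annotate_manifest <- function(probes, genes, islands) {
  assert_columns(probes, c("probe_id", "chr", "pos"), "`probes`")
  probes <- as_tibble(probes)
  if (nrow(probes) == 0) {
    return(mutate(probes,
      gene = character(0), region = character(0), cgi_context = character(0)
    ))
  }
  unknown <- setdiff(unique(probes$chr), c(unique(genes$chr), unique(islands$chr)))
  if (length(unknown) > 0) {
    warn(sprintf(
      "Chromosome(s) %s carry probes but no islands or genes; their probes are annotated open_sea/intergenic.",
      paste(unknown, collapse = ", ")
    ))
  }

  probes$cgi_context <- classify_cgi_context(probes$pos, probes$chr, islands)

  ann <- probe_gene_annotations(probes, genes)
  collapsed <- ann |>
    group_by(.data$probe_id) |>
    summarise(
      gene = paste(.data$gene, collapse = ";"),
      region = paste(.data$region, collapse = ";"),
      .groups = "drop"
    )
  probes |>
    left_join(collapsed, by = "probe_id") |>
    mutate(
      gene = dplyr::coalesce(.data$gene, ""),
      region = dplyr::coalesce(.data$region, "")
    ) |>
    arrange(chrom_rank(.data$chr), .data$pos) |>
    relocate("probe_id", "chr", "pos")
}

# Long (probe_id, gene, region) table of every probe-gene hit.
probe_gene_annotations <- function(probes, genes) {
  out <- list()
  if (!is.null(genes) && nrow(genes) > 0) {
    for (cc in unique(probes$chr)) {
      p <- probes[probes$chr == cc, , drop = FALSE]
      g <- genes[genes$chr == cc, , drop = FALSE]
      if (nrow(g) == 0) next
      for (i in seq_len(nrow(g))) {
        gi <- g[i, ]
        lo <- if (gi$strand == "+") gi$start - 1500 else gi$start
        hi <- if (gi$strand == "+") gi$end else gi$end + 1500
        hit <- p$pos >= lo & p$pos <= hi
        if (!any(hit)) next
        reg <- classify_gene_region(p$pos[hit], gi)
        keep <- !is.na(reg)
        if (!any(keep)) next
        out[[length(out) + 1L]] <- tibble(
          probe_id = p$probe_id[hit][keep],
          gene = gi$gene,
          region = reg[keep]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(probe_id = character(0), gene = character(0), region = character(0)))
  }
  bind_rows(out)
}
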