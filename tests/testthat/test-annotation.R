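test_that("CpG-context distance bins classify the 10 kb fixture correctly", {
  islands <- tiny_islands()
  # island [4000,5000) BED = 4001..5000 1-based
  ctx <- classify_cgi_context(c(4500, 5500, 8000, 9900), "1", islands)
  expect_equal(ctx, c("island", "shore", "shelf", "open_sea"))
  # boundary inclusivity: exactly 2 kb away is still shore, 4 kb still shelf
  expect_equal(classify_cgi_context(7000, "1", islands), "shore")
  expect_equal(classify_cgi_context(9000, "1", islands), "shelf")
  expect_equal(classify_cgi_context(9001, "1", islands), "open_sea")
  # inside-island edges
  expect_equal(classify_cgi_context(c(4001, 5000), "1", islands), rep("island", 2))
  expect_equal(classify_cgi_context(c(4000, 5001), "1", islands), rep("shore", 2))
})

test_that("chromosomes without islands are open sea and bad intervals error", {
  expect_equal(classify_cgi_context(100, "2", tiny_islands()), "open_sea")
  expect_equal(
    classify_cgi_context(
      100, "1",
      tibble::tibble(chr = character(0), start = integer(0), end = integer(0))
    ),
    "open_sea"
  )
  expect_error(
    classify_cgi_context(100, "1", tibble::tibble(chr = "1", start = 500, end = 500)),
    class = "methcall_format_error"
  )
  expect_error(
    classify_cgi_context(
      100, "1",
      tibble::tibble(chr = "1", start = c(100, 150), end = c(200, 300))
    ),
    class = "methcall_format_error"
  )
})

test_that("CpG context is symmetric in distance and invariant to island order", {
  islands <- tibble::tibble(
    chr = "1", start = c(10000L, 40000L), end = c(11000L, 41000L),
    name = c("a", "b")
  )
  # mirrored offsets around the two boundaries of the first island
  offs <- c(1, 500, 2000, 2001, 4000, 4001)
  up <- classify_cgi_context(10001 - offs, "1", islands) # upstream of start
  dn <- classify_cgi_context(11000 + offs, "1", islands) # downstream of end
  expect_equal(up, dn)
  shuffled <- islands[c(2, 1), ]
  pos <- seq(1, 60000, by = 997)
  expect_equal(
    classify_cgi_context(pos, "1", islands),
    classify_cgi_context(pos, "1", shuffled)
  )
})

test_that("context bins partition every probe", {
  set.seed(42)
  islands <- tibble::tibble(
    chr = rep(c("1", "2"), each = 3),
    start = rep(c(5000L, 20000L, 60000L), 2)
  ) |>
    dplyr::mutate(end = start + 1000L, name = paste0("i", dplyr::row_number()))
  pos <- sample.int(80000, 500)
  chr <- sample(c("1", "2", "3"), 500, replace = TRUE)
  ctx <- classify_cgi_context(pos, chr, islands)
  expect_true(all(ctx %in% c("island", "shore", "shelf", "open_sea")))
  expect_length(ctx, 500)
})

test_that("gene-region bands are strand-aware with total precedence", {
  g <- tiny_gene("+")
  expect_equal(classify_gene_region(2900, g), "TSS200") # 100 bp upstream
  expect_equal(classify_gene_region(2800, g), "TSS200") # exactly 200 bp
  expect_equal(classify_gene_region(2000, g), "TSS1500") # 1000 bp upstream
  expect_equal(classify_gene_region(1500, g), "TSS1500") # exactly 1500 bp
  expect_equal(classify_gene_region(1499, g), NA_character_)
  expect_equal(classify_gene_region(3200, g), "1stExon")
  expect_equal(classify_gene_region(5000, g), "Body") # intron
  expect_equal(classify_gene_region(8500, g), "3UTR") # exonic past CDS end
  expect_equal(classify_gene_region(9100, g), NA_character_)

  gm <- tiny_gene("-")
  expect_equal(classify_gene_region(9100, gm), "TSS200") # upstream on minus
  expect_equal(classify_gene_region(10000, gm), "TSS1500")
  expect_equal(classify_gene_region(8500, gm), "1stExon") # last genomic exon
  expect_equal(classify_gene_region(3200, gm), "3UTR") # exonic below CDS start
  expect_equal(classify_gene_region(5000, gm), "Body")

  # exactly one region per (probe, gene) pair across the whole span
  pos <- seq(1400, 9600, by = 7)
  reg <- classify_gene_region(pos, g)
  in_scope <- pos >= 1500 & pos <= 9000
  expect_true(all(!is.na(reg[in_scope])))
  expect_true(all(is.na(reg[!in_scope])))
})

test_that("5UTR band covers exonic positions between TSS and CDS start", {
  # widen the gap between first-exon end and CDS start using a second exon
  g <- tibble::tibble(
    gene = "G2", chr = "1", strand = "+", start = 1000L, end = 9000L,
    tss = 1000L, cds_start = 5500L, cds_end = 8000L,
    exon_starts = "1000,5000", exon_ends = "2000,9000"
  )
  expect_equal(classify_gene_region(5200, g), "5UTR")
  expect_equal(classify_gene_region(1500, g), "1stExon") # precedence over 5UTR
  expect_equal(classify_gene_region(3000, g), "Body") # intronic
})

test_that("annotate_manifest retains multi-gene hits and flags unknown chromosomes", {
  probes <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    chr = c("1", "1", "9"),
    pos = c(2000L, 4500L, 100L),
    strand = "+"
  )
  # two + strand genes whose TSS1500 bands both cover position 2000
  genes <- dplyr::bind_rows(
    tiny_gene("+"),
    dplyr::mutate(tiny_gene("+"), gene = "G2", start = 3100L, tss = 3100L)
  )
  expect_warning(
    ann <- annotate_manifest(probes, genes, tiny_islands()),
    "9"
  )
  p1 <- ann[ann$probe_id == "p1", ]
  expect_setequal(strsplit(p1$gene, ";")[[1]], c("G1", "G2"))
  expect_equal(strsplit(p1$region, ";")[[1]], c("TSS1500", "TSS1500"))
  p3 <- ann[ann$probe_id == "p3", ]
  expect_equal(p3$cgi_context, "open_sea")
  expect_equal(p3$gene, "")
})

test_that("empty gene set yields an intergenic manifest", {
  probes <- tibble::tibble(probe_id = "p1", chr = "1", pos = 4500L, strand = "+")
  genes <- tiny_gene("+")[0, ]
  ann <- annotate_manifest(probes, genes, tiny_islands())
  expect_equal(ann$gene, "")
  expect_equal(ann$region, "")
  expect_equal(ann$cgi_context, "island")
})
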