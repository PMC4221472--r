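test_that("variant kinds follow the length rule", {
  expect_equal(classify_variant_kind("A", "G"), "SNP")
  expect_equal(classify_variant_kind("ATT", "A"), "DEL")
  expect_equal(classify_variant_kind("A", "ACGT"), "INS")
  expect_equal(classify_variant_kind("AT", "GC"), "MNV")
  expect_equal(classify_variant_kind(c("A", "AC"), c("T", "A")),
               c("SNP", "DEL"))
  expect_error(classify_variant_kind("", "A"), "non-empty")
})

test_that("interval span uses the end - start convention", {
  expect_equal(interval_span(genomic_interval("chr1", 5, 5)), 0)
  expect_equal(interval_span(genomic_interval("chr1", 10, 25)), 15)
  expect_error(genomic_interval("chr1", 10, 5), "start > end")
  # additivity over abutting intervals sharing an endpoint
  a <- genomic_interval("chr1", 100, 250)
  b <- genomic_interval("chr1", 250, 900)
  whole <- genomic_interval("chr1", 100, 900)
  expect_equal(interval_span(a) + interval_span(b), interval_span(whole))
})

test_that("region strings parse and format round-trip", {
  iv <- parse_region("chr2:86,110,000-86,850,000")
  expect_equal(iv$start, 86110000)
  expect_equal(interval_span(iv), 740000)
  expect_equal(format_region(iv), "chr2:86110000-86850000")
  expect_error(parse_region("chr2_86110000"), "cannot parse")
})

test_that("cohort design enforces phenotype/class consistency", {
  d <- default_design()
  expect_s3_class(d, "cohort_design")
  expect_error(cohort_design("S1", "AFFECTED", "HOM_REF"), "inconsistent")
  expect_error(cohort_design("S1", "UNAFFECTED", "HET"), "inconsistent")
  expect_error(cohort_design(c("S1", "S1"), rep("AFFECTED", 2),
                             rep("HET", 2)), "duplicate")
})

test_that("genotype classes derive from GT strings per retained alt", {
  expect_equal(gt_class_from_gt(c("0/0", "0/1", "1/1", "./.", "1|0", ".")),
               c("HOM_REF", "HET", "HOM_ALT", "MISSING", "HET", "MISSING"))
  # half-calls and garbage are MISSING
  expect_equal(gt_class_from_gt(c("./1", "garbage", NA)),
               rep("MISSING", 3))
  # multiallelic reclassification relative to alt 2
  expect_equal(gt_class_from_gt(c("1/2", "2/2", "0/2", "1/1"), alt_index = 2L),
               c("HET", "HOM_ALT", "HET", "HOM_REF"))
})

test_that("read_vcf maps one record to per-sample classes", {
  d <- default_design()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", d$sample_id), collapse = "\t"),
    paste("chr2", "500", ".", "A", "G", ".", ".", ".", "GT",
          "1/1", "1/1", "1/1", "0/1", "0/1", "0/0", sep = "\t")), vcf)
  v <- read_vcf(vcf, d)
  expect_equal(nrow(v), 1L)
  expect_equal(unlist(v[1, d$sample_id], use.names = FALSE),
               c("HOM_ALT", "HOM_ALT", "HOM_ALT", "HET", "HET", "HOM_REF"))
})

test_that("empty VCF body yields an empty variant table", {
  d <- default_design()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", d$sample_id), collapse = "\t")), vcf)
  v <- read_vcf(vcf, d)
  expect_equal(nrow(v), 0L)
  expect_true(all(d$sample_id %in% names(v)))
})

test_that("multiallelic records split into per-alt variants", {
  d <- cohort_design(c("S1", "S2", "S3"),
                     c("AFFECTED", "AFFECTED", "UNAFFECTED"),
                     c("HOM_ALT", "HET", "HOM_REF"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste("chr2", "700", ".", "A", "G,T", ".", ".", ".", "GT",
          "1/2", "0/2", "2/2", sep = "\t")), vcf)
  v <- read_vcf(vcf, d)
  expect_equal(nrow(v), 2L)
  expect_equal(v$alt, c("G", "T"))
  # hand oracle: for alt G (index 1): 1/2 -> HET, 0/2 -> HOM_REF, 2/2 -> HOM_REF
  expect_equal(unlist(v[1, c("S1", "S2", "S3")], use.names = FALSE),
               c("HET", "HOM_REF", "HOM_REF"))
  # for alt T (index 2): 1/2 -> HET, 0/2 -> HET, 2/2 -> HOM_ALT
  expect_equal(unlist(v[2, c("S1", "S2", "S3")], use.names = FALSE),
               c("HET", "HET", "HOM_ALT"))
})

test_that("a design sample missing from the VCF is fatal, by name", {
  d <- default_design()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", head(d$sample_id, -1)), collapse = "\t"),
    paste("chr2", "500", ".", "A", "G", ".", ".", ".", "GT",
          "1/1", "1/1", "1/1", "0/1", "0/1", sep = "\t")), vcf)
  expect_error(read_vcf(vcf, d), "ATL1")
})

test_that("malformed GT becomes MISSING with a warning", {
  d <- cohort_design(c("S1", "S2"), c("AFFECTED", "UNAFFECTED"),
                     c("HET", "HOM_REF"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste("chr2", "500", ".", "A", "G", ".", ".", ".", "GT",
          "0/x", "0/0", sep = "\t")), vcf)
  expect_warning(v <- read_vcf(vcf, d), "malformed")
  expect_equal(v$S1, "MISSING")
  expect_equal(v$S2, "HOM_REF")
})

test_that("write_vcf / read_vcf round-trips records and classes", {
  d <- default_design()
  set.seed(42)
  classes <- all_class_assignments(6)[sample.int(729, 20), ]
  v <- make_variants(classes, d, ref = "A", alt = "G")
  v$kind[3] <- "DEL"; v$ref[3] <- "AGT"; v$alt[3] <- "A"
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, path)
  v2 <- read_vcf(path, d)
  expect_equal(v2[order(v2$pos), names(v)], v[order(v$pos), ],
               ignore_attr = TRUE)
})

test_that("known-variant sets read from VCF and TSV with exact keys", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chr2\t100\tA\tG", "chr2\t100\tA\tG"),
             tsv)
  k <- read_known_variants(tsv)
  expect_equal(nrow(k), 1L)  # deduplicated
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr2\t100\t.\tA\tG,T\t.\t.\t."), vcf)
  k2 <- read_known_variants(vcf)
  expect_equal(nrow(k2), 2L)  # one key per alt
  expect_setequal(k2$alt, c("G", "T"))
})

test_that("gene models survive a GFF3 write/read round-trip", {
  genes <- tibble::tibble(
    gene_id = c("G1", "G2"), chrom = "chr2", strand = c("+", "-"),
    gene_start = c(1000, 9000), gene_end = c(5000, 12000),
    exons = list(tibble::tibble(start = c(1000, 3000), end = c(1500, 5000)),
                 tibble::tibble(start = 9000, end = 12000)))
  class(genes) <- c("gene_models", class(genes))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(genes, path)
  g2 <- read_gff3_genes(path)
  expect_equal(g2$gene_id, genes$gene_id)
  expect_equal(g2$gene_start, genes$gene_start)
  expect_equal(g2$exons[[1]], genes$exons[[1]])
})
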