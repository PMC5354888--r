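test_that("intervals enforce 1-based inclusive invariants", {
  iv <- genomic_interval("4", "143211964", 146188881)
  expect_equal(iv$chrom, "chr4")
  expect_equal(iv$start, 143211964L)
  expect_error(genomic_interval("chr1", 0, 10), "start must be >= 1")
  expect_error(genomic_interval("chr1", 10, 9), "end must be >= start")
  expect_error(genomic_interval("", 1, 2), "non-empty")
})

test_that("zero-based half-open conversion round-trips at the I/O boundary", {
  iv <- genomic_interval("chr1", c(1, 100), c(50, 100))
  expect_equal(from_zero_based(to_zero_based(iv)), iv)
  expect_equal(to_zero_based(iv)$start, c(0L, 99L))
})

test_that("chromosome labels normalize the chr prefix only", {
  expect_equal(normalize_chrom(c("4", "chrX", "CHRY", "contig_7")),
               c("chr4", "chrX", "chrY", "chrcontig_7"))
})

test_that("read_seg parses printed-style rows with thousands separators", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tvalue",
               "P\t4\t143,211,964\t146,188,881\t0.8"), f)
  seg <- read_seg(f)
  expect_equal(seg$chrom, "chr4")
  expect_equal(seg$start, 143211964L)
  expect_equal(seg$end, 146188881L)
  expect_equal(seg$value, 0.8)
})

test_that("read_seg returns an empty table for a header-only file", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines("sample\tchrom\tstart\tend\tvalue", f)
  expect_equal(nrow(read_seg(f)), 0)
})

test_that("read_seg rejects malformed and overlapping rows with line numbers", {
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tvalue",
               "P\tchr1\t1\t100\t0.5",
               "P\tchr1\tfifty\t200\t0.5"), f)
  expect_error(read_seg(f), "line 3")
  writeLines(c("sample\tchrom\tstart\tend\tvalue",
               "P\tchr1\t1\t100\t0.5",
               "Q\tchr1\t50\t200\t0.5",
               "P\tchr1\t50\t200\t0.5"), f)
  expect_error(read_seg(f), "overlapping segments within sample 'P'.*line 2.*line 4")
})

test_that("mutation tables parse, coerce flags, and reject invariant violations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("sample", "gene", "chrom", "position", "ref", "alt",
                 "region_class", "allele_frequency", "coverage", "alt_reads",
                 "in_dbsnp", "in_germline"), collapse = "\t")
  writeLines(c(hdr,
               "bile_duct\tTP53\tchr17\t7577538\tC\tT\texon\t0.156\t576\t90\tno\t0"),
             f)
  mut <- read_mutation_table(f)
  expect_equal(mut$gene, "TP53")
  expect_equal(mut$position, 7577538L)
  expect_false(mut$in_dbsnp)
  expect_false(mut$in_germline)

  writeLines(c(hdr,
               "s\tG\tchr1\t10\tA\tC\texon\t1.2\t200\t20\t0\t0"), f)
  expect_error(read_mutation_table(f), "allele_frequency outside")
  writeLines(c(hdr,
               "s\tG\tchr1\t10\tA\tC\texon\t0.5\t100\t150\t0\t0"), f)
  expect_error(read_mutation_table(f), "alt_reads.*exceeds coverage")
  writeLines(hdr, f)
  expect_equal(nrow(read_mutation_table(f)), 0)
})

test_that("mutation tables round-trip through write/read", {
  mut <- make_mutations(3)
  mut$position <- c(100L, 200L, 300L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(mut, f)
  expect_equal(read_mutation_table(f), mut)
})

test_that("region matrices round-trip losslessly through the TSV writer", {
  seg <- data.frame(sample = c("A", "B"), chrom = "chr1",
                    start = c(1, 51), end = c(100, 150),
                    value = c(0.8, -0.9))
  rm1 <- fill_matrix(seg, build_regions(seg))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_region_matrix(rm1, f)
  rm2 <- read_region_matrix(f)
  expect_equal(rm2$values, rm1$values)
  expect_equal(as.data.frame(rm2$regions), as.data.frame(rm1$regions))
  expect_equal(rm2$samples, rm1$samples)
  # a 2-region x 2-sample matrix writes 2 data rows and 5 columns
  tab <- read.delim(f)
  expect_equal(dim(tab), c(3, 5))
})

test_that("SEG writer/reader round-trips validated segments", {
  seg <- data.frame(sample = "P", chrom = "chr4", start = 143211964L,
                    end = 146188881L, value = 0.8,
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".seg")
  write_seg(seg, f)
  expect_equal(read_seg(f), seg)
})

test_that("cohort label and gene CNV tables are validated on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcancer_type", "s1\tPAAD", "s1\tCHOL"), f)
  expect_error(read_cohort_labels(f), "duplicated sample id")
  writeLines(c("sample\tgene\tdirection", "s1\tMDM2\tup"), f)
  expect_error(read_gene_cnv_table(f), "gain.*loss")
  writeLines(c("sample\tgene\tdirection\tlog2_ratio", "s1\tMDM2\tgain\t-0.9"), f)
  expect_error(read_gene_cnv_table(f), "contradicts")
})
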