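# Readers/writers, domain-type validation, coordinate conventions.

test_that("read_bed parses BED3+, skips non-data lines, preserves labels", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test",
               "# a comment",
               "chr3\t189349000\t189350200",
               "",
               "browser position chr3",
               "chr12\t100\t250\textra\tfields\tok"), f)
  pk <- read_bed(f, "bed3plus")
  expect_s3_class(pk, "peak_set")
  expect_equal(nrow(pk$intervals), 2)
  expect_equal(pk$intervals$chrom, c("chr3", "chr12"))
  expect_equal(pk$intervals$start[1], 189349000)
  expect_equal(pk$intervals$end[1], 189350200)
})

test_that("read_bed handles empty files and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f)
  expect_equal(length(read_bed(f)), 0)

  writeLines(c("chr1\t10\t20", "chr1\t30"), f)
  expect_error(read_bed(f), "line 2", class = "snpfunnel_parse_error")

  writeLines(c("chr1\t10\t20", "chr1\t50\t40"), f)
  expect_error(read_bed(f), "line 2",
               class = "snpfunnel_validation_error")
  writeLines("chr1\tx\t20", f)
  expect_error(read_bed(f), "line 1", class = "snpfunnel_parse_error")
})

test_that("narrowPeak dialect keeps signalValue and matches a second parser", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  set.seed(42)
  n <- 40
  s <- sort(sample(1:100000, n))
  lines <- sprintf("chr%d\t%d\t%d\tpeak%d\t%d\t.\t%.3f\t%.2f\t%.2f\t%d",
                   sample(1:5, n, TRUE), s, s + sample(50:500, n, TRUE),
                   1:n, sample(0:1000, n), runif(n, 0, 30),
                   runif(n, 0, 10), runif(n, 0, 10),
                   sample(10:100, n, TRUE))
  writeLines(c("track type=narrowPeak", lines), f)
  pk <- read_bed(f, "narrowpeak")
  oracle <- oracle_parse_narrowpeak(f)
  expect_equal(pk$intervals$chrom, oracle$chrom)
  expect_equal(pk$intervals$start, oracle$start)
  expect_equal(pk$intervals$end, oracle$end)
  expect_equal(pk$intervals$score, oracle$score)
  # 9-field line is malformed for this dialect
  writeLines(c(lines[1], sub("\t[0-9]+$", "", lines[2])), f)
  expect_error(read_bed(f, "narrowpeak"), "line 2",
               class = "snpfunnel_parse_error")
})

test_that("tag catalog tiering follows the significance bounds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tpos\tpvalue",
               "rs1\tchr1\t1000\t1e-9",
               "rs2\tchr2\t2000\t1e-6",
               "rs3\tchr3\t3000\t2e-5",
               "rs4\tchr4\t4000\t4.9e-8",
               "rs5\tchr5\t5000\t5e-8"), f)
  suppressMessages(cat <- read_tag_catalog(f))
  expect_equal(attr(cat, "n_dropped"), 1)      # rs3 above 1e-5
  expect_setequal(cat$rsid, c("rs1", "rs2", "rs4", "rs5"))
  expect_equal(cat$tier[cat$rsid == "rs1"], "genome_wide")
  expect_equal(cat$tier[cat$rsid == "rs4"], "genome_wide")  # < 5e-8
  expect_equal(cat$tier[cat$rsid == "rs5"], "subthreshold") # boundary
  expect_equal(cat$tier[cat$rsid == "rs2"], "subthreshold")

  writeLines(c("rsid\tchrom\tpos\tpvalue", "rs1\tchr1\t1\t0"), f)
  expect_error(read_tag_catalog(f), class = "snpfunnel_validation_error")
})

test_that("variant table invariants are enforced", {
  expect_error(variant_table("chr1", 0, "rs1"),
               class = "snpfunnel_validation_error")
  expect_error(variant_table("chr1", 5, ""),
               class = "snpfunnel_validation_error")
  expect_error(variant_table("chr1", 5, "rs1", ref = "A", alt = "A"),
               class = "snpfunnel_validation_error")
  expect_error(variant_table(c("chr1", "chr1"), c(5, 6), c("rs1", "rs1")),
               class = "snpfunnel_validation_error")
})

test_that("genotype TSV round-trips randomized matrices, phased and not", {
  set.seed(7)
  for (phased in c(FALSE, TRUE)) {
    n <- 13; k <- 5
    v <- variant_table(sample(paste0("chr", 1:3), k, TRUE),
                       sort(sample(1e6, k)), sprintf("rs%d", 1:k),
                       ref = rep("T", k), alt = rep("C", k))
    if (phased) {
      h1 <- matrix(rbinom(n * k, 1, 0.4), n)
      h2 <- matrix(rbinom(n * k, 1, 0.4), n)
      gm <- genotype_matrix(h1 + h2, v, sprintf("S%02d", 1:n),
                            phased = TRUE, hap1 = h1, hap2 = h2)
    } else {
      codes <- matrix(sample(c(0:2, NA), n * k, TRUE), n)
      gm <- genotype_matrix(codes, v, sprintf("S%02d", 1:n))
    }
    f <- withr::local_tempfile(fileext = ".tsv")
    write_genotypes(gm, f)
    gm2 <- read_genotypes(f, "tsv")
    expect_equal(gm2$codes, gm$codes)
    expect_equal(gm2$samples, gm$samples)
    expect_equal(as.data.frame(gm2$variants),
                 as.data.frame(gm$variants))
    expect_equal(gm2$phased, phased)
    if (phased) expect_equal(gm2$hap1, gm$hap1)
  }
})

test_that("VCF intake maps GT to dosage, missing and phasing correctly", {
  f <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2")
  writeLines(c(hdr,
               "chr1\t100\trs1\tG\tA\t.\t.\t.\tGT\t0/1\t1/1",
               "chr1\t200\trs2\tT\tC\t.\t.\t.\tGT\t./.\t0/0"), f)
  gm <- read_genotypes(f, "vcf")
  expect_false(gm$phased)   # "/" separators present
  expect_equal(unname(gm$codes["S1", ]), c(1L, NA))
  expect_equal(unname(gm$codes["S2", ]), c(2L, 0L))
  expect_equal(gm$variants$pos, c(100L, 200L))
  expect_equal(gm$variants$alt, c("A", "C"))

  writeLines(c(hdr,
               "chr1\t100\trs1\tG\tA\t.\t.\t.\tGT\t0|1\t1|1"), f)
  gm <- read_genotypes(f, "vcf")
  expect_true(gm$phased)
  expect_equal(unname(gm$hap1["S1", ]), 0L)
  expect_equal(unname(gm$hap2["S1", ]), 1L)
  expect_equal(unname(gm$codes["S2", ]), 2L)
})

test_that("genotype TSV rejects ragged rows; matrix rejects bad codes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\trs1\trs2", "S1\t0\t1", "S2\t2"), f)
  expect_error(read_genotypes(f, "tsv"), "row 2",
               class = "snpfunnel_parse_error")
  v <- variant_table("chr1", 5, "rs1")
  expect_error(genotype_matrix(matrix(3L, 1, 1), v, "S1"),
               class = "snpfunnel_validation_error")
})

test_that("phenotype table validates and round-trips", {
  ph <- make_phen(5, 6)
  pt <- phenotype_table(ph)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(pt, f)
  pt2 <- read_phenotypes(f)
  expect_equal(as.data.frame(pt2), as.data.frame(pt))
  # histology on a control is invalid
  bad <- ph; bad$histology[bad$status == "control"][1] <- "adeno"
  expect_error(phenotype_table(bad), class = "snpfunnel_validation_error")
  bad <- rbind(ph, ph[1, ])
  expect_error(phenotype_table(bad), class = "snpfunnel_validation_error")
})

test_that("1-based/BED coordinate rule matches brute force on random data", {
  set.seed(11)
  for (rep in 1:5) {
    n_int <- 60
    s <- sample(0:5000, n_int, TRUE)
    ints <- data.frame(chrom = sample(c("chr1", "2"), n_int, TRUE),
                       start = s, end = s + sample(1:300, n_int, TRUE))
    pk <- peak_set(ints$chrom, ints$start, ints$end)
    idx <- build_index(pk, autosomes_only = FALSE)
    pos <- sample(1:5300, 200, TRUE)
    chs <- sample(c("chr1", "chr2", "1", "2"), 200, TRUE)
    for (i in seq_along(pos)) {
      v <- variant_table(chs[i], pos[i], "rsX")
      got <- variant_in_peaks(v, idx)
      want <- brute_overlap(chs[i], pos[i], ints)
      expect_equal(got$hit, length(want) > 0)
      expect_equal(nrow(got$intervals), length(want))
    }
  }
})
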