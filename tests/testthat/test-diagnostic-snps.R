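make_call <- function(chrom = "chr01", pos, qual = 50, dp = 30, idv = 0L,
                      is_indel = FALSE, ref = "A", alt = "C") {
  structure(
    data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
               qual = qual, dp = dp, idv = as.integer(idv),
               is_indel = is_indel, gt = "1/1", stringsAsFactors = FALSE),
    class = c("variant_calls", "data.frame")
  )
}

bind_calls <- function(...) {
  out <- do.call(rbind, list(...))
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

test_that("the QUAL threshold is a hard >= 35 boundary", {
  calls <- bind_calls(make_call(pos = 10, qual = 34.9),
                      make_call(pos = 20, qual = 35),
                      make_call(pos = 30, qual = 35.1))
  out <- filter_variants(calls, filter_config())
  expect_equal(out$pos, c(20L, 30L))
})

test_that("SNPs within 100 bp of a credible indel are excluded, boundary included", {
  calls <- bind_calls(
    make_call(pos = 1000, idv = 3, is_indel = TRUE),
    make_call(pos = 1100),  # exactly 100 bp away -> excluded
    make_call(pos = 1101),  # 101 bp away -> retained
    make_call(pos = 900)    # exactly 100 bp on the other side -> excluded
  )
  out <- filter_variants(calls, filter_config())
  expect_equal(out$pos, 1101L)
})

test_that("indels below the IDV threshold do not trigger the gap rule", {
  calls <- bind_calls(
    make_call(pos = 1000, idv = 1, is_indel = TRUE),  # not credible
    make_call(pos = 1050)
  )
  out <- filter_variants(calls, filter_config())
  expect_equal(out$pos, 1050L)
})

test_that("depth and indel-record exclusion follow the configuration", {
  calls <- bind_calls(make_call(pos = 10, dp = 4),
                      make_call(pos = 2000, dp = 5),
                      make_call(pos = 5000, idv = 4, is_indel = TRUE, qual = 80))
  out <- filter_variants(calls, filter_config())
  expect_equal(out$pos, 2000L)
  out2 <- filter_variants(calls, filter_config(exclude_indels = FALSE))
  expect_setequal(out2$pos, c(2000L, 5000L))
})

test_that("filtering matches an exhaustive per-call predicate oracle", {
  for (seed in c(1, 2, 3)) {
    calls <- random_calls(200, seed = seed)
    cfg <- filter_config()
    expect_equal(filter_variants(calls, cfg), brute_filter(calls, cfg))
  }
})

test_that("filtering is idempotent and monotone in its thresholds", {
  calls <- random_calls(200, seed = 9)
  cfg <- filter_config()
  once <- filter_variants(calls, cfg)
  expect_equal(filter_variants(once, cfg), once)
  base_n <- nrow(once)
  for (stricter in list(filter_config(qual_min = 60),
                        filter_config(dp_min = 20),
                        filter_config(snp_gap = 500),
                        filter_config(idv_min = 1))) {
    out <- filter_variants(calls, stricter)
    expect_lte(nrow(out), base_n)
    ## and every kept call was kept by the looser configuration too,
    ## except when idv_min drops (more indels become credible anchors)
    if (stricter$idv_min >= cfg$idv_min) {
      expect_true(all(out$pos %in% once$pos))
    }
  }
})

test_that("unsorted calls are rejected", {
  calls <- bind_calls(make_call(pos = 100), make_call(pos = 50))
  calls <- calls[c(2, 1), ]  # undo the sort
  expect_error(filter_variants(calls, filter_config()),
               class = "musapaint_malformed_input")
})

test_that("a clean B accession recovers exactly the filter-surviving truth sites", {
  pair <- generate_subgenomes(23, n_chrom = 1, chrom_length = 50000)
  acc <- compose_genotype(pair, genotype_spec("BB"))
  pile <- simulate_pileup(acc, 30, error_rate = 0, seed = 5)
  calls <- call_variants(pile, error_rate = 0.005)
  kept <- filter_variants(calls, filter_config())
  snps <- identify_informative_snps(kept, pile, hom_fraction = 0.9)
  ## every diagnostic site is a truth site with the right alleles
  truth_key <- paste(pair$truth_sites$chrom, pair$truth_sites$pos,
                     pair$truth_sites$a_allele, pair$truth_sites$b_allele)
  snp_key <- paste(snps$chrom, snps$pos, snps$a_allele, snps$b_allele)
  expect_true(all(snp_key %in% truth_key))
  ## and the only losses are the depth filter and indel-gap exclusions
  expect_gt(nrow(snps) / nrow(pair$truth_sites), 0.9)
})

test_that("within-B heterozygous sites are not informative", {
  call <- make_call(pos = 500, qual = 90)
  pile <- make_column(pos = 500L, ref = "A",
                      counts = c(A = 9L, C = 11L, G = 0L, T = 0L))
  expect_equal(nrow(identify_informative_snps(call, pile, 0.9)), 0)
  ## but a 95%-alternate site is
  pile2 <- make_column(pos = 500L, ref = "A",
                       counts = c(A = 1L, C = 19L, G = 0L, T = 0L))
  snps <- identify_informative_snps(call, pile2, 0.9)
  expect_equal(snps$b_allele, "C")
  expect_equal(snps$a_allele, "A")
})

test_that("empty filtered input yields an empty diagnostic set without error", {
  empty <- filter_variants(random_calls(50, 1), filter_config(qual_min = 1e6))
  pile <- make_column()
  out <- identify_informative_snps(empty, pile)
  expect_s3_class(out, "diagnostic_snps")
  expect_equal(nrow(out), 0)
})

test_that("calls lacking a pileup column raise a consistency error", {
  call <- make_call(pos = 123)
  pile <- make_column(pos = 999L, counts = c(A = 10L, C = 10L, G = 0L, T = 0L))
  expect_error(identify_informative_snps(call, pile),
               class = "musapaint_malformed_input")
})

test_that("diagnostic sets serialize to TSV and sites-only VCF and back", {
  snps <- structure(
    data.frame(chrom = c("chr01", "chr02"), pos = c(10L, 20L),
               a_allele = c("A", "G"), b_allele = c("T", "C"),
               stringsAsFactors = FALSE),
    class = c("diagnostic_snps", "data.frame"))
  tmp_tsv <- withr::local_tempfile(fileext = ".tsv")
  tmp_vcf <- withr::local_tempfile(fileext = ".vcf")
  write_diagnostic_snps(snps, tmp_tsv, "tsv")
  write_diagnostic_snps(snps, tmp_vcf, "vcf")
  expect_equal(as.data.frame(read_diagnostic_snps(tmp_tsv)),
               as.data.frame(snps), ignore_attr = TRUE)
  expect_equal(as.data.frame(read_diagnostic_snps(tmp_vcf)),
               as.data.frame(snps), ignore_attr = TRUE)
})

test_that("intersecting diagnostic sets keeps only allele-identical sites", {
  fx <- withr::local_tempfile(fileext = ".tsv")
  fy <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\ta_allele\tb_allele",
               "chr01\t10\tA\tT", "chr01\t20\tC\tG"), fx)
  writeLines(c("chrom\tpos\ta_allele\tb_allele",
               "chr01\t10\tA\tT", "chr01\t20\tC\tA"), fy)
  x <- read_diagnostic_snps(fx)
  y <- read_diagnostic_snps(fy)
  out <- intersect_diagnostic_snps(x, y)
  expect_equal(out$pos, 10L)
})
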