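test_that("zero divergence yields identical subgenomes and no truth sites", {
  pair <- generate_subgenomes(3, n_chrom = 2, chrom_length = 500,
                              divergence_rate = 0, indel_rate = 0)
  expect_identical(pair$a_seqs, pair$b_seqs)
  expect_equal(nrow(pair$truth_sites), 0)
  expect_equal(nrow(pair$indels), 0)
})

test_that("the same seed reproduces the subgenome pair byte for byte", {
  p1 <- generate_subgenomes(7, n_chrom = 2, chrom_length = 2000)
  p2 <- generate_subgenomes(7, n_chrom = 2, chrom_length = 2000)
  expect_identical(p1, p2)
  p3 <- generate_subgenomes(8, n_chrom = 2, chrom_length = 2000)
  expect_false(identical(p1$a_seqs, p3$a_seqs))
})

test_that("divergent-site counts follow binomial moments", {
  ## Binomial(1e5, 0.005): mean 500, sd = sqrt(1e5 * .005 * .995) = 22.3
  pair <- generate_subgenomes(11, n_chrom = 1, chrom_length = 100000,
                              divergence_rate = 0.005)
  expect_lt(abs(nrow(pair$truth_sites) - 500), 4 * sqrt(100000 * 0.005 * 0.995))
  ## sequences differ exactly at the truth sites
  a <- strsplit(pair$a_seqs[[1]], "")[[1]]
  b <- strsplit(pair$b_seqs[[1]], "")[[1]]
  expect_identical(which(a != b), as.integer(pair$truth_sites$pos))
  expect_true(all(pair$truth_sites$a_allele != pair$truth_sites$b_allele))
  expect_true(all(diff(pair$truth_sites$pos) > 0))
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(generate_subgenomes(1, chrom_length = 0),
               class = "musapaint_invalid_parameter")
  expect_error(generate_subgenomes(1, divergence_rate = 0.5),
               class = "musapaint_invalid_parameter")
  expect_error(genotype_spec("AXB"), class = "musapaint_invalid_parameter")
  expect_error(genotype_spec("A"), class = "musapaint_invalid_parameter")
  expect_error(genotype_spec("AABBA"), class = "musapaint_invalid_parameter")
})

test_that("composition determines truth B dosage", {
  pair <- generate_subgenomes(5, n_chrom = 1, chrom_length = 20000)
  for (case in list(list("AA", 0), list("BB", 1), list("AAB", 1 / 3),
                    list("ABB", 2 / 3))) {
    acc <- compose_genotype(pair, genotype_spec(case[[1]]))
    expect_true(all(acc$truth_b_dosage$dosage == case[[2]]),
                label = case[[1]])
  }
})

test_that("swapping A and B in the composition complements the dosage", {
  pair <- generate_subgenomes(6, n_chrom = 1, chrom_length = 20000)
  d1 <- compose_genotype(pair, genotype_spec("AAB"))$truth_b_dosage$dosage
  d2 <- compose_genotype(pair, genotype_spec("BBA"))$truth_b_dosage$dosage
  expect_equal(d2, 1 - d1)
})

test_that("a homeologous exchange rewrites dosage only inside the segment", {
  pair <- generate_subgenomes(9, n_chrom = 1, chrom_length = 20000)
  hx <- data.frame(chrom = "chr01", start = 5000L, end = 12000L,
                   donor = "A", copy = 3L)
  acc <- compose_genotype(pair, genotype_spec("AAB", hx))
  ts <- acc$truth_b_dosage
  inside <- ts$pos >= 5000 & ts$pos < 12000
  expect_true(all(ts$dosage[inside] == 0))
  expect_true(all(ts$dosage[!inside] == 1 / 3))
  ## direct haplotype inspection: the B copy carries A alleles inside
  hap3 <- strsplit(acc$haplotypes$chr01[3], "")[[1]]
  expect_identical(hap3[ts$pos[inside]], ts$a_allele[inside])
  expect_identical(hap3[ts$pos[!inside]], ts$b_allele[!inside])
})

test_that("overlapping exchange segments on one copy are rejected", {
  hx <- data.frame(chrom = "chr01", start = c(100L, 400L), end = c(500L, 900L),
                   donor = "A", copy = 3L)
  expect_error(genotype_spec("AAB", hx), class = "musapaint_invalid_parameter")
})

test_that("error-free pileup of a pure-A accession shows only reference bases", {
  pair <- generate_subgenomes(2, n_chrom = 1, chrom_length = 5000)
  acc <- compose_genotype(pair, genotype_spec("AA"))
  pile <- simulate_pileup(acc, 25, error_rate = 0, seed = 4)
  counts <- as.matrix(pile[, c("A", "C", "G", "T")])
  ref_count <- counts[cbind(seq_len(nrow(pile)), match(pile$ref, c("A", "C", "G", "T")))]
  expect_true(all(ref_count == pile$depth))
  expect_true(all(rowSums(counts) == pile$depth))
})

test_that("pileup depth is Poisson with the requested mean", {
  pair <- generate_subgenomes(2, n_chrom = 1, chrom_length = 10000)
  acc <- compose_genotype(pair, genotype_spec("AA"))
  pile <- simulate_pileup(acc, 30, 0.005, seed = 5)
  expect_equal(nrow(pile), 10000)
  expect_lt(abs(mean(pile$depth) - 30) / 30, 0.01)
  ## variance equals the mean for a Poisson draw (generous 10% window)
  expect_lt(abs(var(pile$depth) - 30) / 30, 0.10)
})

test_that("B-base fraction at divergent sites matches the error model", {
  ## expected B fraction = d (1 - e) + (1 - d) e / 3 at truth dosage d
  pair <- generate_subgenomes(13, n_chrom = 1, chrom_length = 100000,
                              divergence_rate = 0.01)
  acc <- compose_genotype(pair, genotype_spec("AAB"))
  err <- 0.01
  pile <- simulate_pileup(acc, 60, error_rate = err, seed = 6)
  ts <- acc$truth_b_dosage
  idx <- match(ts$pos, pile$pos)
  counts <- as.matrix(pile[idx, c("A", "C", "G", "T")])
  b_count <- counts[cbind(seq_len(nrow(ts)), match(ts$b_allele, c("A", "C", "G", "T")))]
  frac <- sum(b_count) / sum(pile$depth[idx])
  expected <- (1 / 3) * (1 - err) + (2 / 3) * err / 3
  se <- sqrt(expected * (1 - expected) / sum(pile$depth[idx]))
  expect_lt(abs(frac - expected), 3 * se)
  expect_gt(nrow(ts), 800)  # >= 1e4 read draws at divergent sites
})

test_that("pileup simulation is deterministic under a fixed seed", {
  pair <- generate_subgenomes(3, n_chrom = 1, chrom_length = 3000)
  acc <- compose_genotype(pair, genotype_spec("AAB"))
  p1 <- simulate_pileup(acc, 20, 0.01, seed = 9)
  p2 <- simulate_pileup(acc, 20, 0.01, seed = 9)
  expect_identical(p1, p2)
})

test_that("subgenome-private indels surface as indel support in pileups", {
  pair <- generate_subgenomes(21, n_chrom = 1, chrom_length = 50000,
                              indel_rate = 5e-4)
  expect_gt(nrow(pair$indels), 5)
  acc <- compose_genotype(pair, genotype_spec("BB"))
  pile <- simulate_pileup(acc, 30, 0, seed = 2)
  b_indels <- pair$indels[pair$indels$subgenome == "B", ]
  a_indels <- pair$indels[pair$indels$subgenome == "A", ]
  ## BB carries every B-private indel in all copies: support ~ depth
  expect_true(all(pile$indel_support[match(b_indels$pos, pile$pos)] ==
                    pile$depth[match(b_indels$pos, pile$pos)]))
  ## and no A-private indel
  expect_true(all(pile$indel_support[match(a_indels$pos, pile$pos)] == 0))
})

test_that("FASTA, truth-site and pileup files round-trip", {
  pair <- generate_subgenomes(4, n_chrom = 2, chrom_length = 400)
  tmp <- withr::local_tempdir()
  write_subgenome_fasta(pair, file.path(tmp, "a.fa"), file.path(tmp, "b.fa"))
  a_back <- Biostrings::readDNAStringSet(file.path(tmp, "a.fa"))
  expect_identical(as.character(a_back), pair$a_seqs)
  write_truth_sites(pair, file.path(tmp, "ts.tsv"))
  expect_equal(read_truth_sites(file.path(tmp, "ts.tsv")), pair$truth_sites,
               ignore_attr = TRUE)
  acc <- compose_genotype(pair, genotype_spec("AB"))
  pile <- simulate_pileup(acc, 15, 0.01, seed = 1)
  write_pileup(pile, file.path(tmp, "p.tsv"))
  expect_equal(as.data.frame(read_pileup(file.path(tmp, "p.tsv"))),
               as.data.frame(pile), ignore_attr = TRUE)
})
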