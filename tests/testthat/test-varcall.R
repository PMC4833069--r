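# Variant calling: the 90% haploid support rule, homology masking,
# matrix construction against planted truth, classification, densities.

test_that("haploid genotype call applies the 90% support rule inclusively", {
  th <- threshold_config()
  expect_equal(call_genotype(c(A = 950, G = 50), th)$allele, "A")
  r <- call_genotype(c(A = 880, G = 120), th)
  expect_true(r$missing)
  expect_true(is.na(r$allele))
  expect_false(r$no_coverage)
  ## boundary is inclusive
  expect_equal(call_genotype(c(A = 900, G = 100), th)$allele, "A")
  ## review band [0.90, 0.95)
  expect_true(call_genotype(c(A = 940, G = 60), th)$review)
  expect_false(call_genotype(c(A = 950, G = 50), th)$review)
  r0 <- call_genotype(c(A = 0, G = 0), th)
  expect_true(r0$no_coverage)
  expect_true(r0$missing)
})

test_that("nuclear-homology search recovers planted tracts and honours thresholds", {
  set.seed(77)
  q <- random_dna(5000)
  tract <- substr(q, 2001, 2150)          # 150 bp exact copy
  decoy_exact <- paste0(random_dna(1000), tract, random_dna(1000))
  hit <- find_homologous_regions(q, decoy_exact)
  expect_equal(nrow(hit), 1L)
  expect_lte(hit$start[1], 2000L)
  expect_gte(hit$end[1], 2150L)
  ## 150 bp at 85% identity: below the identity threshold
  tc <- seqinr::s2c(tract)
  mut <- sample(150, 23)
  tc[mut] <- vapply(tc[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  decoy_diverged <- paste0(random_dna(1000), paste(tc, collapse = ""),
                           random_dna(1000))
  expect_equal(nrow(find_homologous_regions(q, decoy_diverged)), 0L)
  ## 90 bp exact copy: below the length threshold
  decoy_short <- paste0(random_dna(1000), substr(q, 2001, 2090),
                        random_dna(1000))
  expect_equal(nrow(find_homologous_regions(q, decoy_short)), 0L)
})

test_that("samples identical to the reference give an empty matrix", {
  ref <- "ACGTACGTACGTACGTACGT"
  rows <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(s)
    do.call(rbind, lapply(0:19, function(p)
      pileup_row(s, p, A = 0, C = 0, G = 0, T = 0) |>
        (\(r) { r[[substr(ref, p + 1, p + 1)]] <- 1500; r$depth <- 1500; r })()))))
  vm <- build_variant_matrix(rows, ref)
  expect_equal(length(vm$positions), 0L)
})

test_that("matrix rows match planted truth with high recall and precision", {
  dat <- toy8_data()
  vm <- build_variant_matrix(dat$pileup, dat$reference$sequence,
                             dat$reference$mask)
  ## no matrix row lies inside the mask
  expect_false(any(in_intervals(vm$positions, dat$reference$mask)))
  ## expand deletion runs into per-position truth
  tv <- dat$truth$variants
  truth_pos <- unique(unlist(lapply(seq_len(nrow(tv)), function(i) {
    if (tv$alt[i] == "-") tv$pos0[i] + 0:(nchar(tv$ref[i]) - 1L)
    else tv$pos0[i]
  })))
  truth_pos <- truth_pos[!in_intervals(truth_pos, dat$reference$mask)]
  recall <- mean(truth_pos %in% vm$positions)
  precision <- mean(vm$positions %in% truth_pos)
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
  ## every non-missing call satisfies the support rule (re-check from pileup)
  pk <- data.table::as.data.table(dat$pileup)
  idx <- sample(seq_along(vm$positions), 25)
  for (i in idx) {
    p <- vm$positions[i]
    for (s in vm$samples) {
      cl <- vm$calls[i, s]
      if (is.na(cl) || startsWith(cl, "+")) next
      row <- pk[pk$sample == s & pk$pos0 == p]
      cnts <- c(A = row$A, C = row$C, G = row$G, T = row$T, "-" = row$del)
      expect_gte(cnts[[cl]] / sum(cnts), 0.90)
    }
  }
})

test_that("a position with three sample alleles is triallelic", {
  ref <- paste(rep("A", 120), collapse = "")
  mk <- function(s, allele) {
    rows <- do.call(rbind, lapply(0:119, function(p) pileup_row(s, p, A = 1500)))
    rows[rows$pos0 == 50, c("A", "C", "G", "T")] <- 0
    rows[rows$pos0 == 50, allele] <- 1500
    rows
  }
  pk <- rbind(mk("s1", "A"), mk("s2", "G"), mk("s3", "T"))
  vm <- build_variant_matrix(pk, ref)
  expect_equal(vm$positions, 50)
  expect_equal(vm$n_alleles, 3L)
  expect_equal(vm$type, "SNV")
})

test_that("classification distinguishes frameshift, duplication and intergenic", {
  ## gene g1 at [30, 60), plus strand; reference has AAGGCC at [36,42)
  ref <- paste0(random_dna(30), "ATGAAAAAGGCCTTTGACGAAGACCCTTAC", random_dna(40))
  genes <- data.frame(gene = "g1", strand = "+", exon = 1L,
                      start = 30L, end = 60L)
  base <- function(s) {
    do.call(rbind, lapply(0:99, function(p) {
      b <- substr(ref, p + 1, p + 1)
      r <- pileup_row(s, p)
      r[[b]] <- 2000; r$depth <- 2000; r
    }))
  }
  p1 <- base("s1")
  p2 <- base("s2")
  ## s2: 1-bp deletion inside the exon at pos 45
  p2[p2$pos0 == 45, c("A", "C", "G", "T")] <- 0
  p2[p2$pos0 == 45, "del"] <- 2000
  p2[p2$pos0 == 45, "depth"] <- 2000
  ## s2: 6-bp duplication of [36,42) anchored at pos 41 (in frame)
  p2$ins[p2$pos0 == 41] <- paste0(substr(ref, 37, 42), ":2000")
  ## s2: intergenic SNV at pos 5
  b5 <- substr(ref, 6, 6); alt5 <- setdiff(c("A", "C", "G", "T"), b5)[1]
  p2[p2$pos0 == 5, c("A", "C", "G", "T")] <- 0
  p2[p2$pos0 == 5, alt5] <- 2000
  vm <- build_variant_matrix(rbind(p1, p2), ref)
  ann <- classify_variants(vm, genes, ref)
  expect_equal(ann$effect[ann$pos0 == 45], "frameshift")
  expect_equal(ann$region[ann$pos0 == 45], "exon")
  expect_equal(ann$effect[ann$pos0 == 41], "duplication")
  expect_equal(ann$indel_len[ann$pos0 == 41], 6L)
  expect_equal(ann$region[ann$pos0 == 5], "intergenic")
  vm2 <- vm
  vm2$positions[1] <- 5000L   # beyond the 100-bp reference
  expect_error(classify_variants(vm2, genes, ref), "outside reference")
})

test_that("variant density excludes masked bases from the denominator", {
  vm <- structure(list(positions = as.integer(seq(0, 990, by = 110))[1:10],
                       mask = data.frame(start = integer(0), end = integer(0))),
                  class = "variant_matrix")
  d <- variant_density(vm, windows = data.frame(start = 0L, end = 1000L))
  expect_equal(d$density_per_kb, 10)
  d2 <- variant_density(vm, windows = data.frame(start = 0L, end = 1000L),
                        mask = data.frame(start = 500L, end = 1000L))
  expect_equal(d2$n, 10L)           # counts keep all matrix rows
  expect_equal(d2$unmasked_bp, 500L)
  ## 5 variants over 0.5 kb unmasked -> 10 per kb
  vm5 <- structure(list(positions = c(10L, 20L, 30L, 40L, 50L),
                        mask = data.frame(start = 500L, end = 1000L)),
                   class = "variant_matrix")
  d3 <- variant_density(vm5, windows = data.frame(start = 0L, end = 1000L))
  expect_equal(d3$density_per_kb, 10)
  expect_error(variant_density(vm5, windows = data.frame(start = 5L, end = 5L)),
               "zero-length")
  ## conservation: window counts sum to the matrix row count
  dat <- toy8_data()
  vmt <- build_variant_matrix(dat$pileup, dat$reference$sequence,
                              dat$reference$mask)
  dd <- variant_density(vmt, window_size = 100L, L = 20000L)
  expect_equal(sum(dd$n), length(vmt$positions))
})

test_that("variant accounting reproduces totals and intergenic fractions", {
  acct <- variant_accounting(10, 4, 3)
  expect_equal(acct$total, 14)
  expect_equal(acct$pct_indel_intergenic, 75)
  ann <- data.frame(type = c("SNV", "SNV", "indel", "indel", "indel"),
                    region = c("exon", "intergenic", "intergenic",
                               "intergenic", "exon"))
  acct2 <- variant_accounting(ann)
  expect_equal(acct2$n_snv, 2)
  expect_equal(acct2$pct_indel_intergenic, 67)
})
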