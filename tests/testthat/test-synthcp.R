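# Simulator: reference structure, determinism, event calibration, pileups.

test_that("reference structure and mask arithmetic are as configured", {
  cfg <- sim_config(genome_length = 160129L,
                    ir_intervals = list(c(88000L, 114000L),
                                        c(133000L, 160000L)),
                    seed = 11L)
  ref <- generate_reference(cfg)
  expect_equal(nchar(ref$sequence), 160129L)
  expect_equal(sum(ref$mask$end - ref$mask$start), 53000L)
  ## IRb is the reverse complement of IRa
  ira <- substr(ref$sequence, 88001, 114000)
  irb <- substr(ref$sequence, 133001, 159000)
  expect_identical(irb, revcomp(ira))
  ## adding a homolog tract outside the IRs grows the mask by its length
  cfg2 <- sim_config(genome_length = 160129L,
                     ir_intervals = list(c(88000L, 114000L),
                                         c(133000L, 160000L)),
                     homolog_tracts = list(c(1000L, 1200L)), seed = 11L)
  ref2 <- generate_reference(cfg2)
  expect_equal(sum(ref2$mask$end - ref2$mask$start), 53200L)
  ## exons are in frame and non-overlapping
  for (g in split(ref$genes, ref$genes$gene))
    expect_equal(sum(g$end - g$start) %% 3L, 0L)
  iv <- ref$genes[order(ref$genes$start), ]
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
})

test_that("configuration errors are caught", {
  expect_error(sim_config(genome_length = 5000L), "10 kb")
  expect_error(sim_config(ir_intervals = list(c(0, 1000), c(500, 1500)),
                          genome_length = 20000L), "disjoint")
  expect_error(sim_config(homolog_tracts = list(c(150000, 170000))),
               "out of genome bounds")
  expect_error(sim_config(hybrid_events = list(
    list(recipient = "a", donor = "b", leakage = 0.6))), "leakage")
})

test_that("identical config and seed give byte-identical output", {
  cfg <- toy8_config(seed = 5L)
  d1 <- simulate_dataset(cfg, positions = "variants")
  d2 <- simulate_dataset(toy8_config(seed = 5L), positions = "variants")
  expect_identical(d1$reference$sequence, d2$reference$sequence)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(as.data.frame(d1$pileup), as.data.frame(d2$pileup))
  d3 <- simulate_dataset(toy8_config(seed = 6L), positions = "variants")
  expect_false(identical(d1$sequences, d3$sequences))
})

test_that("zero-length branch leaves the child genome identical to its parent", {
  cfg <- sim_config(genome_length = 10000L,
                    ir_intervals = list(c(6000L, 7000L), c(8000L, 9000L)),
                    tree = "(a:0,b:4);", subst_rate = 5e-4,
                    indel_rate = 1e-4, seed = 3L)
  ref <- generate_reference(cfg)
  ev <- evolve_genomes(cfg, ref)
  ## root is the reference; a's branch has length zero
  expect_identical(ev$sequences[["a"]], ref$sequence)
  expect_false(identical(ev$sequences[["b"]], ref$sequence))
})

test_that("pairwise divergence matches the Poisson expectation", {
  ## 2 taxa separated by 2t; expected pairwise differences ~ 2 r t L
  r <- 5e-4; t <- 2; L <- 10000L
  diffs <- vapply(1:50, function(s) {
    cfg <- sim_config(genome_length = L,
                      ir_intervals = list(c(6000L, 7000L), c(8000L, 9000L)),
                      tree = sprintf("(a:%g,b:%g);", t, t),
                      subst_rate = r, indel_rate = 0, seed = 1000L + s)
    ref <- generate_reference(cfg)
    ev <- evolve_genomes(cfg, ref)
    rc <- seqinr::s2c(ref$sequence)
    sum(genome_allele_at(ev$genomes$a, 0:(L - 1L), rc) !=
        genome_allele_at(ev$genomes$b, 0:(L - 1L), rc))
  }, numeric(1))
  expected <- 2 * r * t * L
  se <- sqrt(expected / 50)  # Poisson SE of the mean
  expect_lt(abs(mean(diffs) - expected), 3 * se + 1)
})

test_that("a TCCT-flanked large deletion joins the two copies leaving one", {
  cfg <- toy8_config()
  dat <- toy8_data()
  sv <- dat$truth$sv
  expect_equal(nrow(sv), 1L)
  expect_equal(sv$sample, "t5")
  expect_equal(c(sv$start, sv$end), c(9324L, 9531L))
  ref <- dat$reference$sequence
  expect_identical(substr(ref, 9325, 9328), "TCCT")
  expect_identical(substr(ref, 9532, 9535), "TCCT")
  ## in the carrier the deleted region is gone: exactly one copy remains
  ## at the junction
  del_region <- substr(ref, 9325, 9531)
  expect_false(grepl(del_region, dat$sequences[["t5"]], fixed = TRUE))
  expect_true(grepl(del_region, dat$sequences[["t6"]], fixed = TRUE))
})

test_that("hybridization truth lists donor-discordant positions at the leakage fraction", {
  dat <- toy8_data()
  ref <- dat$reference$sequence
  ## identical genomes -> empty list
  empty <- apply_hybridization(dat$genomes$t1, dat$genomes$t1, 0.05, ref)
  expect_equal(nrow(empty), 0L)
  expect_error(apply_hybridization(dat$genomes$t1, dat$genomes$t2, 0.5, ref),
               "leakage")
  shp <- dat$truth$shp
  expect_true(all(shp$fraction == 0.05))
  rc <- seqinr::s2c(ref)
  expect_identical(shp$minor,
                   genome_allele_at(dat$genomes$t7, shp$pos0, rc))
  expect_identical(shp$major,
                   genome_allele_at(dat$genomes$t2, shp$pos0, rc))
  ## binomial tail: at 2000x and 5% leakage, >= 99% of SHPs clear the
  ## 5-read threshold
  expect_gt(1 - pbinom(4, 2000, 0.05), 0.99)
  pk2 <- dat$pileup[dat$pileup$sample == "t2" & dat$pileup$pos0 %in% shp$pos0, ]
  cm <- as.matrix(pk2[, c("A", "C", "G", "T")])
  minor_n <- cm[cbind(seq_len(nrow(cm)),
                      match(shp$minor[match(pk2$pos0, shp$pos0)],
                            c("A", "C", "G", "T")))]
  expect_gte(mean(minor_n >= 5), 0.99)
})

test_that("pileup depth, purity and minor-allele counts are calibrated", {
  cfg <- sim_config(genome_length = 10000L,
                    ir_intervals = list(c(6000L, 7000L), c(8000L, 9000L)),
                    seed = 21L)
  ref <- generate_reference(cfg)
  g <- list(sub = character(0), del = integer(0), ins = character(0))
  ## error 0, no SHP -> every position monoallelic
  pk0 <- simulate_pileup(g, ref$sequence, coverage = 100, error_rate = 0,
                         seed = 2L)
  cm <- as.matrix(pk0[, c("A", "C", "G", "T")])
  expect_true(all(rowSums(cm > 0) == 1L))
  ## mean depth within 2% of target at 2000x over 10 kb
  pk <- simulate_pileup(g, ref$sequence, coverage = 2000,
                        error_rate = 0.001, seed = 3L)
  expect_lt(abs(mean(pk$depth) - 2000) / 2000, 0.02)
  ## SHP fraction 0.10 at ~1000x: mean minor count within 3 SD of 100
  shp <- data.frame(pos0 = 0:1999, minor = "A", fraction = 0.10)
  shp$minor <- ifelse(seqinr::s2c(ref$sequence)[1:2000] == "A", "C", "A")
  pk1 <- simulate_pileup(g, ref$sequence, shp = shp, coverage = 1000,
                         error_rate = 0, seed = 4L, positions = 0:1999)
  cm <- as.matrix(pk1[, c("A", "C", "G", "T")])
  minor_n <- cm[cbind(1:2000, match(shp$minor, c("A", "C", "G", "T")))]
  frac <- minor_n / pk1$depth
  expect_lt(abs(mean(frac) - 0.10), 3 * sd(frac) / sqrt(2000))
})

test_that("empirical minor fraction converges to the leakage at deep coverage", {
  dat <- toy8_data()
  shp <- dat$truth$shp
  g <- dat$genomes$t2
  pk <- simulate_pileup(g, dat$reference$sequence, shp = shp,
                        coverage = 20000, error_rate = 0, seed = 8L,
                        positions = shp$pos0, sample = "t2")
  cm <- as.matrix(pk[, c("A", "C", "G", "T")])
  minor_n <- cm[cbind(seq_len(nrow(cm)),
                      match(shp$minor[match(pk$pos0, shp$pos0)],
                            c("A", "C", "G", "T")))]
  emp <- mean(minor_n / pk$depth)
  expect_lt(abs(emp - 0.05) / 0.05, 0.01)
})
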