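# Selection scan: codon alignment extraction, NG86 counting against an
# enumeration oracle, closed-form omega MLEs, LRT power and type-I error.

## hand-built reference with one 18-bp gene at [10, 28)
sel_ref <- function(strand = "+") {
  cds <- "ATGAAACCCGGGTTTAAC"
  genomic <- if (strand == "-") revcomp(cds) else cds
  list(sequence = paste0("GATTACAGAT", genomic, "ACCTGAGGTCAA"),
       genes = data.frame(gene = "g1", strand = strand, exon = 1L,
                          start = 10L, end = 28L),
       mask = NULL)
}

g_empty <- function() list(sub = character(0), del = integer(0),
                           ins = character(0))

test_that("codon alignment extraction is strand-aware and starts at ATG", {
  for (strand in c("+", "-")) {
    ref <- sel_ref(strand)
    aln <- extract_codon_alignment(list(s1 = g_empty(), s2 = g_empty()),
                                   ref, "g1")
    expect_equal(ncol(aln$codons), 6L)
    expect_equal(unname(aln$codons[1, 1]), "ATG")
    expect_identical(aln$codons["s1", ], aln$codons["s2", ])
    expect_equal(paste(aln$codons[1, ], collapse = ""),
                 "ATGAAACCCGGGTTTAAC")
  }
})

test_that("genes inside the inverted repeats are refused", {
  ref <- sel_ref()
  expect_error(extract_codon_alignment(list(s1 = g_empty()), ref, "g1",
                                       ir_intervals = list(c(5L, 40L))),
               "inverted-repeat|masked")
})

test_that("indels mask codons across rows or drop the offending sample", {
  ref <- sel_ref()
  ## 3-bp deletion of codon 3 (positions 16..18) in s2
  g_del <- g_empty(); g_del$del <- c(16L, 17L, 18L)
  aln <- extract_codon_alignment(list(s1 = g_empty(), s2 = g_del), ref, "g1")
  expect_equal(ncol(aln$codons), 5L)
  expect_false("CCC" %in% aln$codons[1, ])
  expect_identical(aln$codons["s1", ], aln$codons["s2", ])
  ## 6-bp duplication (insertion after codon boundary) masks the copied
  ## codon pair in every row
  g_dup <- g_empty()
  g_dup$ins <- stats::setNames(substr(ref$sequence, 14, 19), "18")
  aln2 <- extract_codon_alignment(list(s1 = g_empty(), s2 = g_dup), ref, "g1")
  expect_lt(ncol(aln2$codons), 6L)
  expect_identical(aln2$codons["s1", ], aln2$codons["s2", ])
  ## frame-violating insertion drops the sample
  g_bad <- g_empty()
  g_bad$ins <- stats::setNames("AC", "15")
  expect_warning(
    aln3 <- extract_codon_alignment(list(s1 = g_empty(), s2 = g_bad),
                                    ref, "g1"),
    "frame-violating")
  expect_equal(aln3$samples, "s1")
})

test_that("NG86 site counts split codon positions correctly", {
  ## TTT (Phe): only the third position has a synonymous change (TTC)
  s <- ng_sites("TTT")
  expect_equal(unname(s["S"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(s["N"] + s["S"]), 3)
  ## fourfold degenerate third position: GGG (Gly)
  expect_equal(unname(ng_sites("GGG")["S"]), 1, tolerance = 1e-12)
})

test_that("pathway-averaged counts match explicit enumeration for all codon pairs", {
  cods <- all_codons()
  cods <- cods[!cods %in% c("TAA", "TAG", "TGA")]
  set.seed(3)
  ## exhaustive over all ordered sense pairs
  for (c1 in cods) for (c2 in cods) {
    got <- ng_pathway(c1, c2)
    want <- oracle_pathway(c1, c2)
    if (!isTRUE(all.equal(unname(got), unname(want), tolerance = 1e-12)))
      fail(sprintf("pathway mismatch %s->%s", c1, c2))
  }
  succeed()
  expect_equal(unname(ng_pathway("AAA", "AAC")), c(1, 0))
  expect_equal(unname(ng_pathway("AAA", "AAA")), c(0, 0))
})

test_that("substitution counting is zero on identical rows and exact on a toy pair", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  aln <- structure(list(gene = "g", samples = c("a", "b"),
                        codons = matrix(c("AAA", "AAA", "AAA", "AAC"),
                                        nrow = 2,
                                        dimnames = list(c("a", "b"), NULL))),
                   class = "codon_alignment")
  cs <- count_substitutions(tr, aln)
  expect_equal(sum(cs$branch$n), 1)
  expect_equal(sum(cs$branch$s), 0)
  expect_equal(unname(cs$N + cs$S), 6)
  aln0 <- aln; aln0$codons[2, ] <- aln0$codons[1, ]
  cs0 <- count_substitutions(tr, aln0)
  expect_equal(cs0$total, 0)
  expect_error(count_substitutions(tr, structure(list(
    gene = "g", samples = c("a", "b"),
    codons = matrix(character(0), nrow = 2,
                    dimnames = list(c("a", "b"), NULL))),
    class = "codon_alignment")), "length 0")
})

test_that("global omega MLE is the closed-form ratio and matches optimize()", {
  N <- 300; S <- 100
  cs <- make_counts("g", n_b = c(12, 8), s_b = c(6, 10), N = N, S = S)
  r <- omega_lrt(cs, foreground = 1)
  n <- 20; s <- 16
  expect_equal(r$omega_global, (n / N) / (s / S), tolerance = 1e-12)
  ## dual route: numeric optimization of the binomial likelihood
  lnl <- function(w) {
    p <- w * N / (w * N + S)
    n * log(p) + s * log(1 - p)
  }
  opt <- stats::optimize(lnl, c(1e-4, 50), maximum = TRUE)
  expect_equal(r$omega_global, opt$maximum, tolerance = 1e-4)
})

test_that("verdicts follow the omega/LRT rules and the few-mutation filter", {
  N <- 300; S <- 100
  p1 <- N / (N + S)
  ## counts exactly at the neutral expectation -> omega 1, LRT 0
  cs <- make_counts("g", n_b = c(30, 45), s_b = c(10, 15), N = N, S = S)
  r <- omega_lrt(cs, foreground = 1)
  expect_equal(r$omega_fore, 1, tolerance = 1e-9)
  expect_equal(r$lrt, 0, tolerance = 1e-9)
  expect_equal(r$verdict, "neutral")
  ## 3 substitutions in total -> filtered
  cs3 <- make_counts("g", n_b = c(1, 1), s_b = c(0, 1), N = N, S = S)
  expect_equal(omega_lrt(cs3, foreground = 1)$verdict, "filtered")
  expect_error(omega_lrt(make_counts("g", 1, 1, 0, 10), 1), "positive")
})

test_that("foreground omega = 4 is detected with high power", {
  set.seed(99)
  N <- 300; S <- 100
  p4 <- 4 * N / (4 * N + S); p1 <- N / (N + S)
  hits <- 0L
  for (i in 1:100) {
    nf <- rbinom(1, 200, p4); sf <- 200 - nf
    nb <- rbinom(1, 150, p1); sb <- 150 - nb
    cs <- make_counts("g", n_b = c(nf, nb), s_b = c(sf, sb), N = N, S = S)
    if (omega_lrt(cs, foreground = 1)$verdict == "positive")
      hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("clade scan applies BH correction over gene x clade tests", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  set.seed(1)
  aln <- structure(list(gene = "g", samples = letters[1:4],
                        codons = matrix(sample(c("AAA", "AAC", "AAG"), 40,
                                               TRUE),
                                        nrow = 4,
                                        dimnames = list(letters[1:4], NULL))),
                   class = "codon_alignment")
  cs <- count_substitutions(tr, aln)
  scan <- scan_selection(tr, list(cs))
  expect_true(all(c("p", "q", "verdict") %in% names(scan)))
  expect_true(all(scan$q >= scan$p - 1e-12))
  expect_equal(nrow(scan), sum(tr$edge[, 2] > 4))
})
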