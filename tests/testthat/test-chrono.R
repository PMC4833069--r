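# Dating: Langley-Fitch recovery, PL limits (lambda -> 0 and infinity),
# grid oracle, cross-validated smoothing, CI aggregation, rate classes.

lf_tree <- function() ape::read.tree(text = "((a:2,b:2):3,(c:4,d:4):1);")

## noiseless clocklike counts: x_b = r * d_b exactly
lf_counts <- function(tree, r = 10) round(r * tree$edge.length)

test_that("Langley-Fitch recovers true ages from noiseless clock counts", {
  tr <- lf_tree()
  x <- lf_counts(tr, r = 10)
  fit <- fit_langley_fitch(tr, x, dating_constraints(5))
  ages <- fit$ages
  expect_equal(unname(ages[c("a", "b", "c", "d")]), rep(0, 4))
  ab <- ape::getMRCA(tr, c("a", "b")); cd <- ape::getMRCA(tr, c("c", "d"))
  expect_equal(unname(ages[paste0("node", ab)]), 2, tolerance = 1e-3)
  expect_equal(unname(ages[paste0("node", cd)]), 4, tolerance = 1e-3)
  expect_equal(fit$rates[1], 10, tolerance = 1e-3)
  ## doubling the counts doubles the rate, ages unchanged
  fit2 <- fit_langley_fitch(tr, 2 * x, dating_constraints(5))
  expect_equal(fit2$rates[1], 2 * fit$rates[1], tolerance = 1e-3)
  expect_equal(unname(fit2$ages), unname(fit$ages), tolerance = 1e-3)
})

test_that("all-zero counts give the degenerate midpoint solution", {
  tr <- lf_tree()
  expect_warning(fit <- fit_langley_fitch(tr, rep(0L, nrow(tr$edge)),
                                          dating_constraints(5)),
                 "zero")
  expect_equal(fit$rates, rep(0, nrow(tr$edge)))
  expect_equal(fit$objective, 0)
  ## feasible: parent older than child
  a <- unname(fit$ages)
  expect_true(all(a[tr$edge[, 1]] > a[tr$edge[, 2]] - 1e-9))
})

test_that("infeasible constraints are rejected", {
  tr <- lf_tree()
  cons <- dating_constraints(5, nodes = data.frame(
    node = ape::getMRCA(tr, c("a", "b")), min = 7, max = 9))
  expect_error(fit_langley_fitch(tr, lf_counts(tr), cons), "infeasible")
})

test_that("PL with huge lambda matches Langley-Fitch; lambda 0 gives per-branch MLEs", {
  set.seed(5)
  tr <- lf_tree()
  x <- round(tr$edge.length * 10) + c(3, 0, 1, 0, 2, 1)  # mildly non-clock
  cons <- dating_constraints(5)
  lf <- fit_langley_fitch(tr, x, cons)
  pl_inf <- fit_pl(tr, x, cons, 1e9)
  expect_lt(max(abs(pl_inf$ages - lf$ages) / pmax(lf$ages, 1e-6)), 1e-3)
  pl0 <- fit_pl(tr, x, cons, 0)
  d <- unname(pl0$ages)[tr$edge[, 1]] - unname(pl0$ages)[tr$edge[, 2]]
  mle <- x / d
  ok <- x > 0
  expect_equal(pl0$rates[ok], mle[ok], tolerance = 1e-3)
  expect_error(fit_pl(tr, x, cons, -1), "lambda")
})

test_that("PL optimum beats a coarse grid search", {
  tr <- lf_tree()
  x <- c(28, 21, 24, 9, 44, 37)
  lam <- 1
  cons <- dating_constraints(5)
  fit <- fit_pl(tr, x, cons, lam)
  ## brute-force objective over a coarse grid of the two free ages and six
  ## rates, using the same penalized-likelihood definition
  edge <- tr$edge
  parent_edge <- match(edge[, 1], edge[, 2])
  obj <- function(ages, rates) {
    d <- ages[edge[, 1]] - ages[edge[, 2]]
    if (any(d <= 0)) return(-Inf)
    ll <- sum(ifelse(x > 0, x * log(rates * d), 0) - rates * d)
    pen <- 0
    for (b in seq_len(nrow(edge))) {
      if (!is.na(parent_edge[b]))
        pen <- pen + (rates[b] - rates[parent_edge[b]])^2
    }
    pen <- pen + stats::var(rates[is.na(parent_edge)])
    ll - lam * pen
  }
  ntip <- 4L
  ab <- ape::getMRCA(tr, c("a", "b")); cd <- ape::getMRCA(tr, c("c", "d"))
  best <- -Inf
  rate_grid <- c(4, 7, 10, 14)
  rg <- as.matrix(do.call(expand.grid, rep(list(rate_grid), 3)))
  for (t_ab in seq(0.5, 4.5, by = 1)) for (t_cd in seq(0.5, 4.5, by = 1)) {
    ages <- numeric(6)
    ages[ntip + 1L] <- 5; ages[ab] <- t_ab; ages[cd] <- t_cd
    for (i in seq_len(nrow(rg))) {
      ## tie terminal-pair rates to cut the grid dimension
      rates <- numeric(6)
      rates[parent_edge %in% NA] <- rg[i, 1]
      rates[edge[, 2] %in% c(match(c("a", "b"), tr$tip.label))] <- rg[i, 2]
      rates[edge[, 2] %in% c(match(c("c", "d"), tr$tip.label))] <- rg[i, 3]
      v <- obj(ages, rates)
      if (v > best) best <- v
    }
  }
  expect_gte(fit$objective, best - 1e-3)
})

test_that("cross-validation behaves on clocklike data and degenerate grids", {
  tr <- lf_tree()
  x <- lf_counts(tr, r = 10)
  cons <- dating_constraints(5)
  cv1 <- cross_validate_lambda(tr, x, cons, grid = 2.5)
  expect_equal(cv1$lambda, 2.5)
  grid <- 10^seq(-1, 2, by = 1)
  cv <- cross_validate_lambda(tr, x, cons, grid = grid)
  sc <- cv$table$score
  expect_true(all(diff(sc) <= 1e-3 * pmax(abs(sc[-length(sc)]), 1)))
  ## tie -> first entry
  cvt <- cross_validate_lambda(tr, x, cons, grid = c(10, 10))
  expect_equal(cvt$lambda, 10)
  tr3 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  expect_error(cross_validate_lambda(tr3, c(1, 1, 1, 1), cons), "4 leaves")
})

test_that("age summaries aggregate matched clades with 2-SD CIs", {
  tr <- lf_tree()
  mk <- function(t_ab, t_cd) {
    ages <- c(a = 0, b = 0, c = 0, d = 0, node5 = 5, node6 = t_ab,
              node7 = t_cd)
    structure(list(tree = tr, ages = ages, rates = rep(1, 6)),
              class = "dating_result")
  }
  s <- summarize_ages(list(mk(4, 6), mk(6, 4)))
  ## the (a,b) clade has ages 4 and 6 across the two results
  key_ab <- paste(sort(c("a", "b")), collapse = "|")
  row <- s[s$clade == key_ab, ]
  expect_equal(row$mean, 5)
  expect_equal(row$sd, sqrt(2), tolerance = 1e-9)
  expect_equal(row$ci_lo, 5 - 2 * sqrt(2))
  expect_equal(row$ci_hi, 5 + 2 * sqrt(2))
  s2 <- summarize_ages(list(mk(4, 6), mk(4, 6)))
  expect_equal(s2$sd[s2$clade == key_ab], 0)
  expect_error(summarize_ages(list(mk(4, 6))), "at least two")
})

test_that("CIs over jittered tree samples cover the true ages", {
  set.seed(31)
  tr <- lf_tree()
  cons <- dating_constraints(5)
  results <- lapply(1:40, function(i) {
    x <- rpois(nrow(tr$edge), 10 * tr$edge.length)
    fit_langley_fitch(tr, x, cons)
  })
  s <- summarize_ages(results)
  truth <- c("a|b" = 2, "c|d" = 4)
  for (k in names(truth)) {
    row <- s[s$clade == k, ]
    expect_lte(row$ci_lo, truth[[k]])
    expect_gte(row$ci_hi, truth[[k]])
  }
})

test_that("rate K-means classes are ordered and degenerate cases handled", {
  rc1 <- classify_rates(rep(2, 5), 1)
  expect_equal(rc1$k, 1L)
  rc <- classify_rates(c(1, 1, 1, 10, 10), 2, seed = 4)
  expect_equal(rc$labels, c(1, 1, 1, 2, 2))
  expect_equal(rc$means, c(1, 10))
  expect_message(rc3 <- classify_rates(c(1, 1, 10, 10), 3, seed = 4),
                 "distinct")
  expect_equal(rc3$k, 2L)
})

test_that("node ages are recovered within 10% on clock simulations", {
  ## 34 taxa, root 15 My, ~1,600 substitutions of signal, true root given
  cfg <- citrus34_config()
  tr <- ape::read.tree(text = cfg$tree)
  depths <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * 15 / max(depths)
  depths <- ape::node.depth.edgelength(tr)
  true_age <- max(depths) - depths
  r <- 1600 / sum(tr$edge.length)
  ntip <- length(tr$tip.label)
  idx <- (ntip + 1L):(ntip + tr$Nnode)
  meds <- vapply(1:5, function(s) {
    set.seed(100 + s)
    x <- rpois(nrow(tr$edge), r * tr$edge.length)
    fit <- fit_langley_fitch(tr, x, dating_constraints(15))
    median(abs(unname(fit$ages)[idx] - true_age[idx]) /
           pmax(true_age[idx], 0.5))
  }, numeric(1))
  expect_lte(median(meds), 0.10)
})
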