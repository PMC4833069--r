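# Divergence dating from branch substitution counts: Langley-Fitch global
# clock, penalized likelihood with autocorrelated rates, cross-validated
# smoothing, root-age scanning, CI aggregation over tree samples, and
# K-means branch-rate classes.
#
# The branch-count likelihood is Poisson: sum_b [ x_b ln(r_b d_b) - r_b d_b ]
# with d_b the branch duration implied by the node ages. Ages are
# reparameterized as proportions of the feasible interval between each
# node's floor (oldest child / minimum-age constraint) and ceiling (parent
# age / maximum-age constraint), which enforces parent > child and all
# constraints by construction.

#' Estimated substitution counts per branch
#'
#' @param tree `ape::phylo` with branch lengths in substitutions/site.
#' @param nsites alignment length the branch lengths refer to.
#' @return integer vector x_b aligned with `tree$edge` rows.
#' @export
branch_counts <- function(tree, nsites) {
  pmax(0L, as.integer(round(tree$edge.length * nsites)))
}

#' Dating constraints
#'
#' @param root_age fixed root age (My).
#' @param nodes optional constraint table: data.frame with columns
#'   `min`, `max` and either `node` (ape node number) or a list-column
#'   `tips` naming the clade (its MRCA is constrained).
#' @return list of class `dating_constraints`.
#' @export
dating_constraints <- function(root_age, nodes = NULL) {
  stopifnot(is.numeric(root_age), root_age > 0)
  if (!is.null(nodes)) stopifnot(all(c("min", "max") %in% names(nodes)),
                                 all(nodes$min <= nodes$max))
  structure(list(root_age = root_age, nodes = nodes),
            class = "dating_constraints")
}

prep_dating <- function(tree, constraints) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("dating requires a rooted tree")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nn <- ntip + tree$Nnode
  lo <- numeric(nn); hi <- rep(Inf, nn)
  hi[seq_len(ntip)] <- 0
  lo[root] <- hi[root] <- constraints$root_age
  if (!is.null(constraints$nodes)) {
    for (i in seq_len(nrow(constraints$nodes))) {
      row <- constraints$nodes[i, ]
      node <- if (!is.null(row$node) && !is.na(row$node)) row$node else
        ape::getMRCA(tree, unlist(row$tips))
      if (node > nn) stop("constrained node not in tree")
      lo[node] <- max(lo[node], row$min)
      hi[node] <- min(hi[node], row$max)
    }
  }
  po <- ape::postorder(tree)
  floor_ <- lo
  for (ei in po) {
    par <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    floor_[par] <- max(floor_[par], floor_[ch])
  }
  if (floor_[root] > constraints$root_age + 1e-9)
    stop("infeasible constraints: a minimum age exceeds the root age")
  if (any(hi < floor_ - 1e-9))
    stop("infeasible constraints: maximum age below a descendant minimum")
  pre <- rev(po)
  free <- integer(0)
  for (ei in pre) {
    ch <- tree$edge[ei, 2]
    if (ch > ntip) free <- c(free, ch)
  }
  list(tree = tree, ntip = ntip, root = root, nn = nn,
       lo = lo, hi = hi, floor = floor_, pre = pre, free = free)
}

ages_from_theta <- function(prep, theta) {
  age <- numeric(prep$nn)
  age[prep$root] <- prep$lo[prep$root]
  k <- 0L
  for (ei in prep$pre) {
    par <- prep$tree$edge[ei, 1]; ch <- prep$tree$edge[ei, 2]
    if (ch <= prep$ntip) next
    k <- k + 1L
    ceil <- min(age[par], prep$hi[ch])
    age[ch] <- prep$floor[ch] +
      stats::plogis(theta[k]) * max(ceil - prep$floor[ch], 0)
  }
  age
}

theta_from_ages <- function(prep, age) {
  th <- numeric(length(prep$free))
  k <- 0L
  for (ei in prep$pre) {
    par <- prep$tree$edge[ei, 1]; ch <- prep$tree$edge[ei, 2]
    if (ch <= prep$ntip) next
    k <- k + 1L
    ceil <- min(age[par], prep$hi[ch])
    u <- (age[ch] - prep$floor[ch]) / max(ceil - prep$floor[ch], 1e-12)
    th[k] <- stats::qlogis(min(max(u, 1e-6), 1 - 1e-6))
  }
  th
}

edge_durations <- function(prep, age) {
  age[prep$tree$edge[, 1]] - age[prep$tree$edge[, 2]]
}

poisson_term <- function(x, r, d) {
  rd <- r * d
  sum(ifelse(x > 0, x * log(pmax(rd, 1e-300)), 0) - rd)
}

dating_result <- function(prep, age, rates, lambda, objective, converged,
                          method) {
  names(age) <- c(prep$tree$tip.label,
                  paste0("node", (prep$ntip + 1L):prep$nn))
  structure(list(tree = prep$tree, ages = age, rates = rates,
                 lambda = lambda, objective = objective,
                 converged = converged, method = method),
            class = "dating_result")
}

#' Langley-Fitch global-clock dating
#'
#' Maximizes the Poisson branch-count likelihood over node ages and a
#' single global substitution rate (profiled in closed form given ages).
#'
#' @param tree rooted `ape::phylo`.
#' @param counts integer branch counts aligned with `tree$edge` (see
#'   [branch_counts()]).
#' @param constraints a [dating_constraints()] with fixed root age.
#' @return `dating_result` with equal per-branch rates.
#' @export
fit_langley_fitch <- function(tree, counts, constraints) {
  prep <- prep_dating(tree, constraints)
  x <- counts
  if (all(x == 0)) {
    warning("all branch counts are zero; returning constraint-midpoint ages")
    age <- ages_from_theta(prep, rep(0, length(prep$free)))
    return(dating_result(prep, age, rep(0, nrow(prep$tree$edge)), NA_real_,
                         0, TRUE, "LF"))
  }
  X <- sum(x)
  ob <- function(th) {
    age <- ages_from_theta(prep, th)
    d <- edge_durations(prep, age)
    if (any(d < -1e-9)) return(1e12)
    D <- sum(d)
    if (D <= 0) return(1e12)
    if (any(x > 0 & d <= 0)) return(1e12)
    -(sum(ifelse(x > 0, x * log(pmax(d, 1e-300)), 0)) + X * log(X / D) - X)
  }
  o <- stats::nlminb(rep(0, length(prep$free)), ob, lower = -12, upper = 12)
  age <- ages_from_theta(prep, o$par)
  d <- edge_durations(prep, age)
  r <- X / sum(d)
  dating_result(prep, age, rep(r, length(d)), NA_real_, -o$objective,
                o$convergence == 0, "LF")
}

pl_penalty <- function(prep, rates, included = NULL) {
  edge <- prep$tree$edge
  ne <- nrow(edge)
  if (is.null(included)) included <- rep(TRUE, ne)
  parent_edge <- match(edge[, 1], edge[, 2])  # NA for root-adjacent
  pen <- 0
  for (b in seq_len(ne)) {
    pe <- parent_edge[b]
    if (is.na(pe)) next
    if (included[b] && included[pe]) pen <- pen + (rates[b] - rates[pe])^2
  }
  ra <- which(is.na(parent_edge) & included)
  if (length(ra) >= 2L) pen <- pen + stats::var(rates[ra])
  pen
}

#' Penalized-likelihood dating with autocorrelated rates
#'
#' Maximizes the Poisson branch-count likelihood minus
#' `lambda * Phi(rates)`, where Phi sums squared rate differences between
#' each branch and its parent branch and adds the variance of the rates on
#' the root-adjacent branches. Ages and per-branch rates are optimized
#' jointly (bounded quasi-Newton on proportion-reparameterized ages and
#' log-rates), started from the Langley-Fitch solution so that large
#' `lambda` recovers the global clock.
#'
#' @param tree rooted `ape::phylo`.
#' @param counts branch counts aligned with `tree$edge`.
#' @param constraints a [dating_constraints()].
#' @param lambda smoothing parameter (>= 0).
#' @param exclude_edges edge indices removed from the likelihood and
#'   penalty (used by cross-validation).
#' @return `dating_result` with per-branch rates.
#' @export
fit_pl <- function(tree, counts, constraints, lambda,
                   exclude_edges = integer(0)) {
  if (lambda < 0) stop("lambda must be >= 0")
  prep <- prep_dating(tree, constraints)
  x <- counts
  ne <- nrow(prep$tree$edge)
  included <- !(seq_len(ne) %in% exclude_edges)
  lf <- fit_langley_fitch(tree, counts, constraints)
  rlf <- max(lf$rates[1], 1e-6)
  th0 <- theta_from_ages(prep, unname(lf$ages))
  d0 <- pmax(edge_durations(prep, unname(lf$ages)), 1e-6)
  r0 <- (x + rlf) / (d0 + 1)   # shrink per-branch MLEs toward the LF rate
  nfree <- length(prep$free)
  ob <- function(par) {
    age <- ages_from_theta(prep, par[seq_len(nfree)])
    d <- edge_durations(prep, age)
    if (any(d < -1e-9)) return(1e12)
    r <- exp(par[nfree + seq_len(ne)])
    ll <- poisson_term(x[included], r[included], d[included])
    if (!is.finite(ll)) return(1e12)
    -(ll - lambda * pl_penalty(prep, r, included))
  }
  par0 <- c(th0, log(pmax(r0, 1e-8)))
  o <- stats::nlminb(par0, ob,
                     lower = c(rep(-12, nfree), rep(log(1e-10), ne)),
                     upper = c(rep(12, nfree), rep(log(1e4), ne)))
  age <- ages_from_theta(prep, o$par[seq_len(nfree)])
  rates <- exp(o$par[nfree + seq_len(ne)])
  dating_result(prep, age, rates, lambda, -o$objective,
                o$convergence == 0, "PL")
}

#' Cross-validated choice of the smoothing parameter
#'
#' Leave-one-terminal-branch-out: for each terminal branch b, refit without
#' b, predict x_b as the fitted rate of its parent branch (mean of the
#' other root-adjacent rates when the parent is the root) times the
#' refitted duration d_b, and score sum (x_b - xhat_b)^2 / xhat_b. Returns
#' the grid argmin (first entry on ties).
#'
#' @param tree rooted `ape::phylo`.
#' @param counts branch counts aligned with `tree$edge`.
#' @param constraints a [dating_constraints()].
#' @param grid candidate lambdas (default 10^(-2..3), half-log steps).
#' @return list: lambda (best), table (lambda, score).
#' @export
cross_validate_lambda <- function(tree, counts, constraints,
                                  grid = 10^seq(-2, 3, by = 0.5)) {
  if (length(tree$tip.label) < 4L) stop("need at least 4 leaves")
  if (!length(grid)) stop("empty lambda grid")
  ntip <- length(tree$tip.label)
  terminals <- which(tree$edge[, 2] <= ntip)
  if (!is.null(tree$edge.length))
    terminals <- terminals[tree$edge.length[terminals] > 0]
  edge <- tree$edge
  parent_edge <- match(edge[, 1], edge[, 2])
  scores <- vapply(grid, function(lam) {
    sc <- 0
    for (b in terminals) {
      fit <- fit_pl(tree, counts, constraints, lam, exclude_edges = b)
      d <- edge_durations(list(tree = fit$tree), unname(fit$ages))
      pe <- parent_edge[b]
      rhat <- if (!is.na(pe)) fit$rates[pe] else {
        ra <- setdiff(which(is.na(parent_edge)), b)
        mean(fit$rates[ra])
      }
      xhat <- rhat * d[b]
      sc <- sc + (counts[b] - xhat)^2 / max(xhat, 1e-6)
    }
    sc
  }, numeric(1))
  list(lambda = grid[which.min(scores)],
       table = data.frame(lambda = grid, score = scores))
}

#' Root-age scan
#'
#' Refits PL over a grid of fixed root ages and reports each node's age
#' per root age plus a normalized stability measure (age range / mean).
#'
#' @param tree rooted `ape::phylo`.
#' @param counts branch counts.
#' @param lambda smoothing parameter.
#' @param root_ages grid of root ages (default 8..20 My, step 1).
#' @param nodes optional extra constraints (see [dating_constraints()]).
#' @return list: ages (node x root-age matrix), stability (per node).
#' @export
root_age_scan <- function(tree, counts, lambda, root_ages = 8:20,
                          nodes = NULL) {
  fits <- lapply(root_ages, function(ra)
    fit_pl(tree, counts, dating_constraints(ra, nodes), lambda))
  A <- vapply(fits, function(f) unname(f$ages), numeric(length(fits[[1]]$ages)))
  rownames(A) <- names(fits[[1]]$ages)
  colnames(A) <- root_ages
  stab <- apply(A, 1, function(a)
    if (mean(a) > 0) (max(a) - min(a)) / mean(a) else 0)
  list(ages = A, stability = stab, fits = fits)
}

clade_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "|"), character(1))
}

#' Aggregate node ages over a sample of dated trees
#'
#' Nodes are matched across results by the identity of their descendant
#' leaf sets; per node the mean, sample SD and the CI mean +/- 2 SD are
#' reported. Nodes absent from a given tree are skipped for that tree.
#'
#' @param results list of `dating_result` objects (>= 2).
#' @return data.frame: clade, n, mean, sd, ci_lo, ci_hi.
#' @export
summarize_ages <- function(results) {
  if (length(results) < 2L) stop("need at least two dating results")
  per <- lapply(results, function(res) {
    keys <- clade_keys(res$tree)
    ntip <- length(res$tree$tip.label)
    ages <- unname(res$ages)[(ntip + 1L):length(res$ages)]
    stats::setNames(ages, keys)
  })
  all_keys <- unique(unlist(lapply(per, names)))
  common <- all_keys[vapply(all_keys, function(k)
    sum(vapply(per, function(p) k %in% names(p), logical(1))) >= 2L,
    logical(1))]
  if (!length(common)) stop("no common nodes across results")
  rows <- lapply(common, function(k) {
    a <- unlist(lapply(per, function(p) p[k]))
    a <- a[!is.na(a)]
    m <- mean(a); s <- stats::sd(a)
    data.frame(clade = k, n = length(a), mean = m, sd = s,
               ci_lo = m - 2 * s, ci_hi = m + 2 * s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' K-means classes of branch rates
#'
#' One-dimensional K-means (50 random restarts, seeded) on the per-branch
#' rates; class labels are reordered by ascending class mean. When k
#' exceeds the number of distinct rates it falls back to that count.
#'
#' @param result a `dating_result` (or numeric rate vector).
#' @param k number of classes.
#' @param seed integer seed.
#' @return list of class `rate_classes`: k, labels (per branch), means.
#' @export
classify_rates <- function(result, k, seed = 1L) {
  r <- if (inherits(result, "dating_result")) result$rates else result
  stopifnot(k >= 1)
  ndist <- length(unique(r))
  if (k > ndist) {
    message("k exceeds distinct rate values; using k = ", ndist)
    k <- ndist
  }
  if (k == 1L) {
    return(structure(list(k = 1L, labels = rep(1L, length(r)),
                          means = mean(r)), class = "rate_classes"))
  }
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(matrix(r, ncol = 1), centers = k,
                                       nstart = 50))
  ord <- order(km$centers)
  relabel <- match(seq_len(k), ord)
  structure(list(k = k, labels = relabel[km$cluster],
                 means = as.numeric(km$centers[ord])),
            class = "rate_classes")
}
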