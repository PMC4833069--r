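# Concatenated variable-site alignment, NJ bootstrap tree, GTR likelihood
# (Felsenstein pruning) with and without a molecular clock, and the
# clocklikeness likelihood-ratio test.

#' Concatenate variable SNV sites into an alignment
#'
#' Keeps biallelic and triallelic SNV positions of the variant matrix
#' (indels excluded), propagating MISSING calls, and drops any column with
#' fewer than two distinct non-missing states.
#'
#' @param vm a `variant_matrix`.
#' @return list of class `snv_alignment`: samples, sites (0-based
#'   reference positions), states (samples x sites character matrix with
#'   NA for MISSING).
#' @export
concat_variable_sites <- function(vm) {
  if (length(vm$samples) < 3L) stop("need at least 3 samples")
  rows <- which(vm$type == "SNV")
  if (!length(rows)) stop("no variable SNV sites in the matrix")
  states <- t(vm$calls[rows, , drop = FALSE])
  states[!(states %in% BASES)] <- NA_character_
  keep <- apply(states, 2, function(x) length(unique(x[!is.na(x)])) >= 2L)
  structure(list(samples = vm$samples, sites = vm$positions[rows][keep],
                 states = states[, keep, drop = FALSE]),
            class = "snv_alignment")
}

#' Pairwise p-distances with pairwise deletion of MISSING
#'
#' @param aln an `snv_alignment` (or raw states matrix).
#' @return symmetric numeric matrix of mismatch proportions.
#' @export
p_distance <- function(aln) {
  st <- if (inherits(aln, "snv_alignment")) aln$states else aln
  n <- nrow(st)
  d <- matrix(0, n, n, dimnames = list(rownames(st), rownames(st)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(st[i, ]) & !is.na(st[j, ])
    if (!any(ok))
      stop(sprintf("no shared non-missing sites between %s and %s",
                   rownames(st)[i], rownames(st)[j]))
    d[i, j] <- d[j, i] <- mean(st[i, ok] != st[j, ok])
  }
  d
}

#' Neighbour-joining tree with site-resampled bootstrap supports
#'
#' NJ on p-distances (pairwise deletion); node supports are the percentage
#' of bootstrap replicates (columns resampled with replacement) whose NJ
#' tree contains each bipartition.
#'
#' @param aln an `snv_alignment`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed (deterministic output).
#' @return `ape::phylo` with `node.label` percent supports.
#' @export
nj_bootstrap_tree <- function(aln, n_boot = 100L, seed = 1L) {
  if (nrow(aln$states) < 3L) stop("need at least 3 samples")
  st <- aln$states
  rownames(st) <- aln$samples
  set.seed(seed)
  tr <- ape::nj(p_distance(st))
  if (n_boot > 0) {
    bts <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(st), replace = TRUE)
      bts[[b]] <- ape::nj(p_distance(st[, cols, drop = FALSE]))
    }
    cnt <- ape::prop.clades(tr, bts, rooted = FALSE)
    cnt[is.na(cnt)] <- n_boot
    tr$node.label <- round(100 * cnt / n_boot)
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## ---- GTR machinery -------------------------------------------------------

#' Build a normalized GTR rate matrix
#'
#' Q[i,j] = s_ij * pi_j off-diagonal, diagonal set so rows sum to zero,
#' scaled so the mean substitution rate -sum(pi_i Q_ii) equals 1.
#'
#' @param pi base frequencies (A,C,G,T).
#' @param rates 6 exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @return 4x4 rate matrix.
#' @export
gtr_q <- function(pi, rates) {
  R <- gtr_exchange_matrix(rates)
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(BASES, BASES)
  Q / sum(-diag(Q) * pi)
}

## eigen-decomposition of the reversible Q via its symmetrization
gtr_eigen <- function(pi, rates) {
  Q <- gtr_q(pi, rates)
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(vals = e$values, U = diag(1 / sp) %*% e$vectors,
       Uinv = t(e$vectors) %*% diag(sp), pi = pi, Q = Q)
}

gtr_pmat <- function(eig, t) {
  P <- eig$U %*% (exp(eig$vals * t) * eig$Uinv)
  P[P < 0] <- 0
  P
}

## site-pattern compression: returns list(tip_lik = list per sample of
## 4 x npat matrices, weights)
compress_patterns <- function(states) {
  key <- apply(states, 2, function(x) paste(ifelse(is.na(x), "?", x),
                                            collapse = ""))
  u <- !duplicated(key)
  w <- as.numeric(table(key)[key[u]])
  st <- states[, u, drop = FALSE]
  tip_lik <- lapply(seq_len(nrow(st)), function(i) {
    M <- matrix(1, 4, ncol(st), dimnames = list(BASES, NULL))
    for (b in BASES) {
      hit <- !is.na(st[i, ]) & st[i, ] == b
      M[, hit] <- 0
      M[b, hit] <- 1
    }
    M
  })
  names(tip_lik) <- rownames(st)
  list(tip_lik = tip_lik, weights = w, npat = ncol(st))
}

## pruning log-likelihood for an edge-length vector on a fixed topology;
## MISSING states are marginalized through all-ones tip partials
pruning_loglik <- function(tree, bl, pat, eig) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  npat <- pat$npat
  tree <- ape::reorder.phylo(tree, "postorder")
  bl <- bl[attr(tree, "order_map")]
  lik <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) lik[[i]] <- pat$tip_lik[[tree$tip.label[i]]]
  for (ei in seq_len(nrow(tree$edge))) {
    par <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    P <- gtr_pmat(eig, bl[ei])
    contrib <- P %*% lik[[ch]]
    lik[[par]] <- if (is.null(lik[[par]])) contrib else lik[[par]] * contrib
  }
  root <- ntip + 1L
  site_l <- colSums(eig$pi * lik[[root]])
  sum(pat$weights * log(site_l))
}

## reorder helper: pruning_loglik needs bl in the reordered edge order;
## precompute a map from the caller's edge order
with_order_map <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  pkey <- paste(po$edge[, 1], po$edge[, 2])
  attr(tree, "order_map") <- match(pkey, key)
  tree
}

clock_heights <- function(tree, theta, floors = NULL) {
  ## theta[1] = log root height; remaining map preorder internal nodes to
  ## proportions of their parent's height
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  h <- numeric(ntip + tree$Nnode)
  h[root] <- exp(theta[1])
  pre <- rev(ape::postorder(tree))
  k <- 1L
  for (ei in pre) {
    ch <- tree$edge[ei, 2]
    if (ch <= ntip) next
    k <- k + 1L
    h[ch] <- h[tree$edge[ei, 1]] * stats::plogis(theta[k])
  }
  h
}

#' Fit GTR branch lengths (free or clock-constrained) on a fixed topology
#'
#' Log-likelihood by the pruning recursion over unique site patterns, with
#' MISSING marginalized. The unconstrained mode optimizes free branch
#' lengths; the clock mode parameterizes node heights (all root-to-leaf
#' paths equal) and optimizes heights. Exchangeabilities are optionally
#' co-estimated by coordinate ascent (branch lengths | rates) until the
#' log-likelihood improves by less than `tol`.
#'
#' @param tree `ape::phylo` topology (rooted required for `clock = TRUE`);
#'   edge lengths, if present, are used as a starting point.
#' @param aln an `snv_alignment`.
#' @param clock constrain to a molecular clock?
#' @param gtr optional list(pi, rates) to hold fixed.
#' @param optimize_gtr co-estimate exchangeabilities (ignored when `gtr`
#'   supplied).
#' @param tol coordinate-ascent convergence tolerance on the
#'   log-likelihood.
#' @return list: logLik, tree (fitted edge lengths), gtr, clock, heights
#'   (clock mode), convergence.
#' @export
fit_gtr <- function(tree, aln, clock = FALSE, gtr = NULL,
                    optimize_gtr = is.null(gtr), tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(sort(tree$tip.label) == sort(aln$samples)))
    stop("tree leaves must match alignment samples")
  if (clock && !ape::is.rooted(tree))
    stop("clock mode requires a rooted tree")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  states <- aln$states
  rownames(states) <- aln$samples
  pat <- compress_patterns(states)
  cnt <- table(factor(states, levels = BASES))
  pi <- if (!is.null(gtr)) gtr$pi else {
    p <- (as.numeric(cnt) + 1) / (sum(cnt) + 4)
    stats::setNames(p, BASES)
  }
  rates <- if (!is.null(gtr)) gtr$rates else rep(1, 6)
  tree <- with_order_map(tree)
  ne <- nrow(tree$edge)
  bl <- tree$edge.length
  if (is.null(bl) || any(!is.finite(bl))) bl <- rep(0.05, ne)
  bl <- pmax(bl, 1e-7)

  ntip <- length(tree$tip.label)
  fit_branches <- function(rates, bl0) {
    eig <- gtr_eigen(pi, rates)
    if (!clock) {
      ob <- function(lb) -pruning_loglik(tree, exp(lb), pat, eig)
      o <- stats::nlminb(log(bl0), ob, lower = log(1e-8), upper = log(10))
      list(bl = exp(o$par), lnl = -o$objective, par = o$par,
           conv = o$convergence == 0)
    } else {
      nint <- tree$Nnode
      ob <- function(th) {
        h <- clock_heights(tree, th)
        d <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
        -pruning_loglik(tree, pmax(d, 1e-10), pat, eig)
      }
      ## init 1: ultrametricize the current branch lengths (mean tip path
      ## below each node); init 2: flat proportions
      hmean <- numeric(ntip + nint)
      ndesc <- numeric(ntip + nint)
      tmp <- ape::reorder.phylo(tree, "postorder")
      blp <- bl0[attr(tree, "order_map")]
      for (ei in seq_len(nrow(tmp$edge))) {
        par <- tmp$edge[ei, 1]; ch <- tmp$edge[ei, 2]
        nd <- if (ch <= ntip) 1 else ndesc[ch]
        hm <- if (ch <= ntip) 0 else hmean[ch]
        hmean[par] <- (hmean[par] * ndesc[par] +
                       (hm + blp[ei]) * nd) / (ndesc[par] + nd)
        ndesc[par] <- ndesc[par] + nd
      }
      th_of <- function(h) {
        th <- log(max(h[ntip + 1L], 1e-6))
        k <- 1L
        for (ei in rev(ape::postorder(tree))) {
          ch <- tree$edge[ei, 2]
          if (ch <= ntip) next
          k <- k + 1L
          u <- h[ch] / max(h[tree$edge[ei, 1]], 1e-12)
          th[k] <- stats::qlogis(min(max(u, 0.02), 0.98))
        }
        th
      }
      starts <- list(th_of(hmean),
                     c(log(max(sum(bl0) / ntip, 1e-4)),
                       rep(stats::qlogis(0.6), nint - 1L)))
      best <- NULL
      for (theta0 in starts) {
        o <- stats::nlminb(theta0, ob,
                           lower = c(log(1e-8), rep(-12, nint - 1L)),
                           upper = c(log(10), rep(12, nint - 1L)))
        if (is.null(best) || o$objective < best$objective) best <- o
      }
      h <- clock_heights(tree, best$par)
      list(bl = pmax(h[tree$edge[, 1]] - h[tree$edge[, 2]], 0),
           lnl = -best$objective, heights = h, conv = best$convergence == 0)
    }
  }

  res <- fit_branches(rates, bl)
  if (optimize_gtr) {
    for (it in 1:10) {
      lnl_prev <- res$lnl
      obr <- function(lr) {
        eig <- gtr_eigen(pi, c(exp(lr), 1))
        -pruning_loglik(tree, pmax(res$bl, 1e-10), pat, eig)
      }
      orates <- stats::optim(log(rates[1:5]), obr, method = "L-BFGS-B",
                             lower = -6, upper = 6)
      rates <- c(exp(orates$par), 1)
      res <- fit_branches(rates, pmax(res$bl, 1e-7))
      if (abs(res$lnl - lnl_prev) < tol) break
    }
  }
  tree$edge.length <- res$bl
  attr(tree, "order_map") <- NULL
  out <- list(logLik = res$lnl, tree = tree,
              gtr = list(pi = pi, rates = rates), clock = clock,
              convergence = res$conv)
  if (clock) out$heights <- res$heights
  out
}

#' Likelihood-ratio test of clocklike behaviour
#'
#' @param neg_lnl_unconstrained,neg_lnl_clock -lnL scores of the
#'   unconstrained and clock-constrained fits (clock >= unconstrained).
#' @param n_taxa number of taxa; df = n_taxa - 2.
#' @return list: chi2, df, p.
#' @export
clock_lrt <- function(neg_lnl_unconstrained, neg_lnl_clock, n_taxa) {
  chi2 <- 2 * (neg_lnl_clock - neg_lnl_unconstrained)
  if (chi2 < -1e-9)
    stop("clock -lnL is below the unconstrained -lnL; inputs swapped?")
  chi2 <- max(chi2, 0)
  df <- as.integer(n_taxa) - 2L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
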