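# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

## toy8 dataset with pileups restricted to variant positions (fast);
## simulated once per test run
toy8_data <- function() {
  if (is.null(.fixture_cache$toy8))
    .fixture_cache$toy8 <- simulate_dataset(toy8_config(),
                                            pileups = TRUE,
                                            positions = "variants")
  .fixture_cache$toy8
}

## hand-rolled pileup row builder
pileup_row <- function(sample, pos0, A = 0, C = 0, G = 0, T = 0, del = 0,
                       ins = "") {
  data.frame(sample = sample, pos0 = pos0, A = A, C = C, G = G, T = T,
             del = del, ins = ins, depth = A + C + G + T + del,
             stringsAsFactors = FALSE)
}

## simulate an SNV alignment directly from the GTR process along a tree
## (independent of the package's genome simulator)
sim_states <- function(tree, nsites, pi = c(A = .25, C = .25, G = .25, T = .25),
                       rates = rep(1, 6)) {
  B <- c("A", "C", "G", "T")
  Q <- gtr_q(pi, rates)
  ntip <- length(tree$tip.label)
  st <- matrix(NA_character_, ntip + tree$Nnode, nsites)
  root <- ntip + 1L
  st[root, ] <- sample(B, nsites, TRUE, prob = pi)
  ord <- order(-ape::node.depth(tree)[tree$edge[, 2]])
  for (ei in ord) {
    par <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    P <- as.matrix(Matrix::expm(Q * tree$edge.length[ei]))
    for (b in B) {
      sel <- st[par, ] == b
      if (any(sel))
        st[ch, sel] <- sample(B, sum(sel), TRUE, prob = P[match(b, B), ])
    }
  }
  out <- st[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

as_aln <- function(states) {
  keep <- apply(states, 2, function(x) length(unique(x[!is.na(x)])) >= 2L)
  structure(list(samples = rownames(states),
                 sites = which(keep) - 1L,
                 states = states[, keep, drop = FALSE]),
            class = "snv_alignment")
}

## brute-force GTR log-likelihood by enumerating all internal-node state
## assignments, with transition matrices from Matrix::expm (independent of
## the package's eigen-decomposition pruning path)
brute_force_lnl <- function(tree, states, pi, rates) {
  B <- c("A", "C", "G", "T")
  Q <- gtr_q(pi, rates)
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  grid <- do.call(expand.grid, rep(list(1:4), length(internal)))
  ll <- 0
  for (j in seq_len(ncol(states))) {
    tot <- 0
    for (gi in seq_len(nrow(grid))) {
      asg <- integer(ntip + tree$Nnode)
      asg[internal] <- as.integer(grid[gi, ])
      pr <- pi[asg[ntip + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        if (ch <= ntip) {
          obs <- states[tree$tip.label[ch], j]
          if (!is.na(obs))
            pr <- pr * P[[e]][asg[par], match(obs, B)]
        } else {
          pr <- pr * P[[e]][asg[par], asg[ch]]
        }
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  as.numeric(ll)
}

## independent NG86 pathway oracle: explicit enumeration of the orderings
## of the differing codon positions (hard-coded permutation lists)
oracle_pathway <- function(c1, c2) {
  tr <- function(cod) seqinr::translate(seqinr::s2c(cod))
  a <- seqinr::s2c(c1); b <- seqinr::s2c(c2)
  dif <- which(a != b)
  d <- length(dif)
  if (d == 0) return(c(n = 0, s = 0))
  orders <- switch(as.character(d),
                   "1" = list(dif),
                   "2" = list(dif, rev(dif)),
                   "3" = list(dif[c(1, 2, 3)], dif[c(1, 3, 2)],
                              dif[c(2, 1, 3)], dif[c(2, 3, 1)],
                              dif[c(3, 1, 2)], dif[c(3, 2, 1)]))
  res <- list()
  for (ord in orders) {
    cur <- a; n <- 0; s <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      if (tr(paste(nxt, collapse = "")) == "*") blocked <- TRUE
      if (tr(paste(cur, collapse = "")) == tr(paste(nxt, collapse = "")))
        s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    res[[length(res) + 1L]] <- c(n, s, blocked)
  }
  M <- do.call(rbind, res)
  ok <- M[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(M))
  c(n = mean(M[ok, 1]), s = mean(M[ok, 2]))
}

all_codons <- function() {
  B <- c("A", "C", "G", "T")
  apply(expand.grid(B, B, B, stringsAsFactors = FALSE), 1, paste,
        collapse = "")
}

## build a subst_counts object directly (for model-level tests)
make_counts <- function(gene, n_b, s_b, N, S) {
  ne <- length(n_b)
  structure(list(gene = gene,
                 branch = data.frame(parent = rep(1L, ne),
                                     child = seq_len(ne) + 1L,
                                     n = n_b, s = s_b),
                 N = N, S = S, total = sum(n_b) + sum(s_b)),
            class = "subst_counts")
}
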