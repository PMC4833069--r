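# Counting-based branch-omega selection scan: codon alignments from the
# gene model, Fitch parsimony ancestral codons, Nei-Gojobori (NG86)
# pathway-averaged synonymous/nonsynonymous counts and site totals, and the
# three-model (omega = 1 / global omega / two-ratio) likelihood-ratio
# design over a binomial model of per-branch nonsynonymous fractions.

the <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(the$codon_table)) {
    cods <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE)[, 3:1],
                  1, paste, collapse = "")
    aa <- vapply(cods, function(cd)
      seqinr::translate(seqinr::s2c(cd)), character(1))
    the$codon_table <- stats::setNames(aa, cods)
  }
  the$codon_table
}

is_stop <- function(codon) codon_table()[codon] == "*"

#' NG86 synonymous/nonsynonymous site counts of one codon
#'
#' Each codon position contributes the fraction of its three possible
#' changes that are synonymous to S (changes to stop codons count as
#' nonsynonymous).
#'
#' @param codon a 3-letter codon string.
#' @return c(N = nonsynonymous sites, S = synonymous sites); N + S = 3.
#' @export
ng_sites <- function(codon) {
  ct <- codon_table()
  ch <- seqinr::s2c(codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(BASES, ch[p])) {
      mut <- ch; mut[p] <- b
      mc <- paste(mut, collapse = "")
      if (ct[mc] != "*" && ct[mc] == ct[codon]) s <- s + 1 / 3
    }
  }
  c(N = 3 - s, S = s)
}

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

#' NG86 pathway-averaged substitution counts between two codons
#'
#' Averages the synonymous/nonsynonymous decomposition over all orderings
#' of the differing positions; paths passing through a stop codon are
#' excluded (all orderings are used if every path hits a stop).
#'
#' @param c1,c2 codon strings.
#' @return c(n = nonsynonymous, s = synonymous substitutions).
#' @export
ng_pathway <- function(c1, c2) {
  ct <- codon_table()
  a <- seqinr::s2c(c1); b <- seqinr::s2c(c2)
  dif <- which(a != b)
  if (!length(dif)) return(c(n = 0, s = 0))
  paths <- list()
  for (ord in perms(dif)) {
    cur <- a; n <- 0; s <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      ccur <- paste(cur, collapse = ""); cnxt <- paste(nxt, collapse = "")
      if (ct[cnxt] == "*") blocked <- TRUE
      if (ct[ccur] == ct[cnxt]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- c(n = n, s = s, blocked = blocked)
  }
  P <- do.call(rbind, paths)
  ok <- P[, "blocked"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(P))
  c(n = mean(P[ok, "n"]), s = mean(P[ok, "s"]))
}

#' Extract an in-frame codon alignment for one gene
#'
#' Concatenates the gene's exons for every sample (reverse-complemented for
#' minus-strand genes). Codons touched by a deletion in any sample are
#' removed across all samples; an in-frame insertion masks the reference
#' codons overlapping the tract it could duplicate; a frame-violating
#' (length not multiple of 3) insertion inside the CDS drops that sample
#' with a warning, as does an internal stop codon.
#'
#' @param genomes named list of edit-map genomes (see [evolve_genomes()]).
#' @param reference `cp_reference` (or list with `sequence` and `genes`).
#' @param gene_id gene to extract; must lie outside `ir_intervals`.
#' @param ir_intervals inverted-repeat intervals (defaults to the
#'   reference mask when present).
#' @return list of class `codon_alignment`: gene, samples, codons
#'   (samples x codons character matrix of 3-letter strings).
#' @export
extract_codon_alignment <- function(genomes, reference, gene_id,
                                    ir_intervals = NULL) {
  genes <- reference$genes
  g <- genes[genes$gene == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("unknown gene: ", gene_id)
  if (is.null(ir_intervals)) ir_intervals <- reference$mask
  if (!is.null(ir_intervals) &&
      any(in_intervals(c(g$start, g$end - 1L), ir_intervals)))
    stop("gene lies inside an excluded (inverted-repeat/masked) region")
  ref_chars <- seqinr::s2c(reference$sequence)
  g <- g[order(g$start), , drop = FALSE]
  gpos <- unlist(Map(function(s, e) s:(e - 1L), g$start, g$end))
  minus <- g$strand[1] == "-"
  cds_order <- if (minus) rev(gpos) else gpos  # genomic pos in CDS order
  ncod <- length(cds_order) %/% 3L
  codon_of <- function(genomic_pos) {
    ci <- (match(genomic_pos, cds_order) - 1L) %/% 3L + 1L
    ci[!is.na(ci)]
  }

  masked <- logical(ncod)
  keep_sample <- stats::setNames(rep(TRUE, length(genomes)), names(genomes))
  for (s in names(genomes)) {
    gm <- genomes[[s]]
    dl <- intersect(gm$del, gpos)
    if (length(dl)) masked[codon_of(dl)] <- TRUE
    ip <- as.integer(names(gm$ins))
    ip <- ip[ip %in% gpos[gpos < max(gpos)]]  # insertions inside the CDS
    for (p in ip) {
      l <- nchar(gm$ins[[as.character(p)]])
      if (l %% 3L != 0L) {
        warning(sprintf("sample %s dropped: frame-violating insertion in %s",
                        s, gene_id))
        keep_sample[s] <- FALSE
      } else {
        masked[codon_of(intersect((p - l):(p + 1L), gpos))] <- TRUE
      }
    }
  }

  rows <- list()
  for (s in names(genomes)[keep_sample]) {
    al <- genome_allele_at(genomes[[s]], cds_order, ref_chars)
    if (minus) al <- chartr("ACGT", "TGCA", al)
    al[al == "-"] <- "N"  # masked below via the deletion codons
    cods <- vapply(seq_len(ncod), function(i)
      paste(al[(3L * (i - 1L) + 1L):(3L * i)], collapse = ""), character(1))
    cods <- cods[!masked]
    aa <- codon_table()[cods]
    if (any(!is.na(aa) & aa == "*")) {
      warning(sprintf("sample %s dropped: internal stop codon in %s",
                      s, gene_id))
      next
    }
    rows[[s]] <- cods
  }
  if (!length(rows)) stop("no samples left for gene ", gene_id)
  codons <- do.call(rbind, rows)
  structure(list(gene = gene_id, samples = rownames(codons),
                 codons = codons), class = "codon_alignment")
}

## Fitch parsimony over codon states for one column; returns assigned
## codon per node (ties toward minimizing nonsynonymous changes vs the
## parent, then lexicographic)
fitch_column <- function(tree, tipstates) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- tipstates[tree$tip.label[i]]
  po <- ape::postorder(tree)
  for (ei in po) {
    par <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    sets[[par]] <- if (is.null(sets[[par]])) sets[[ch]] else {
      inter <- intersect(sets[[par]], sets[[ch]])
      if (length(inter)) inter else union(sets[[par]], sets[[ch]])
    }
  }
  assign <- character(nn)
  root <- ntip + 1L
  assign[root] <- sort(sets[[root]])[1]
  for (ei in rev(po)) {
    par <- tree$edge[ei, 1]; ch <- tree$edge[ei, 2]
    if (assign[par] %in% sets[[ch]]) {
      assign[ch] <- assign[par]
    } else {
      cand <- sort(unlist(sets[[ch]]))
      nn_cost <- vapply(cand, function(cd)
        ng_pathway(assign[par], cd)["n"], numeric(1))
      assign[ch] <- cand[which.min(nn_cost)]
    }
  }
  assign
}

#' Per-branch synonymous/nonsynonymous substitution counts
#'
#' Ancestral codons by Fitch parsimony per codon column; per-branch codon
#' differences are decomposed into synonymous and nonsynonymous
#' substitutions by NG86 pathway averaging; N and S site totals are NG86
#' site counts averaged over the leaf sequences.
#'
#' @param tree `ape::phylo`; leaves must be a subset of alignment rows.
#' @param aln a `codon_alignment`.
#' @return list of class `subst_counts`: gene, branch (edge table with n,
#'   s), N, S, total.
#' @export
count_substitutions <- function(tree, aln) {
  if (ncol(aln$codons) == 0L) stop("alignment of length 0")
  miss <- setdiff(tree$tip.label, aln$samples)
  if (length(miss)) stop("tree leaves absent from alignment: ",
                         paste(miss, collapse = ", "))
  ne <- nrow(tree$edge)
  n_b <- numeric(ne); s_b <- numeric(ne)
  for (j in seq_len(ncol(aln$codons))) {
    tip <- stats::setNames(aln$codons[tree$tip.label, j], tree$tip.label)
    if (length(unique(tip)) > 1L) {
      asg <- fitch_column(tree, tip)
      for (ei in seq_len(ne)) {
        a <- asg[tree$edge[ei, 1]]; b <- asg[tree$edge[ei, 2]]
        if (a != b) {
          ns <- ng_pathway(a, b)
          n_b[ei] <- n_b[ei] + ns["n"]; s_b[ei] <- s_b[ei] + ns["s"]
        }
      }
    }
  }
  sites <- rowMeans(vapply(aln$samples, function(s) {
    tot <- c(N = 0, S = 0)
    for (cd in aln$codons[s, ]) tot <- tot + ng_sites(cd)
    tot
  }, c(N = 0, S = 0)))
  structure(list(gene = aln$gene,
                 branch = data.frame(parent = tree$edge[, 1],
                                     child = tree$edge[, 2],
                                     n = n_b, s = s_b),
                 N = sites["N"], S = sites["S"],
                 total = sum(n_b) + sum(s_b)),
            class = "subst_counts")
}

binom_lnl <- function(n, s, p) {
  t1 <- if (n > 0) n * log(p) else 0
  t2 <- if (s > 0) s * log(1 - p) else 0
  t1 + t2
}

omega_mle <- function(n, s, N, S) {
  if (n + s == 0) return(1)
  p <- n / (n + s)
  if (p >= 1) return(Inf)
  (p / (1 - p)) * (S / N)
}

#' Branch-omega likelihood-ratio test for one foreground clade
#'
#' Per branch, the nonsynonymous count is Binomial(n_b + s_b, p(omega))
#' with p(omega) = omega N / (omega N + S). Three models are fitted in
#' closed form: omega = 1 everywhere; one global omega; and a two-ratio
#' model (foreground/background). The positive-selection LRT compares the
#' two-ratio model with the nested null fixing the foreground omega at 1
#' (background free), df = 1; the global-vs-neutral LRT (df = 1) is also
#' reported. Genes with fewer than `min_subs` total substitutions are
#' verdict "filtered".
#'
#' @param counts a `subst_counts`.
#' @param foreground edge indices (rows of the branch table) forming the
#'   foreground clade.
#' @param alpha significance level for the verdict.
#' @param min_subs minimum total substitutions (default 5).
#' @return list of class `sel_test`: gene, omegas, log-likelihoods, lrt,
#'   p, lrt_global, p_global, verdict.
#' @export
omega_lrt <- function(counts, foreground, alpha = 0.05, min_subs = 5) {
  N <- unname(counts$N); S <- unname(counts$S)
  if (N <= 0 || S <= 0) stop("N and S site totals must be positive")
  br <- counts$branch
  if (length(foreground) && (min(foreground) < 1 ||
                             max(foreground) > nrow(br)))
    stop("foreground edges outside the tree")
  fg <- seq_len(nrow(br)) %in% foreground
  nf <- sum(br$n[fg]); sf <- sum(br$s[fg])
  nb <- sum(br$n[!fg]); sb <- sum(br$s[!fg])
  p_of <- function(w) w * N / (w * N + S)
  p1 <- p_of(1)
  phat <- function(n, s) if (n + s > 0) n / (n + s) else p1

  lnl0 <- binom_lnl(nf + nb, sf + sb, p1)
  w_glob <- omega_mle(nf + nb, sf + sb, N, S)
  lnl1 <- binom_lnl(nf + nb, sf + sb, phat(nf + nb, sf + sb))
  w_fore <- omega_mle(nf, sf, N, S)
  w_back <- omega_mle(nb, sb, N, S)
  lnl2 <- binom_lnl(nf, sf, phat(nf, sf)) + binom_lnl(nb, sb, phat(nb, sb))
  lnl3 <- binom_lnl(nf, sf, p1) + binom_lnl(nb, sb, phat(nb, sb))

  lrt <- max(2 * (lnl2 - lnl3), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  lrt_g <- max(2 * (lnl1 - lnl0), 0)
  p_g <- stats::pchisq(lrt_g, df = 1, lower.tail = FALSE)

  total <- nf + sf + nb + sb
  verdict <- if (total < min_subs) "filtered"
  else if (w_fore > 1 && p < alpha) "positive"
  else if (w_fore < 1 && p < alpha) "negative"
  else "neutral"
  structure(list(gene = counts$gene, omega_global = w_glob,
                 omega_fore = w_fore, omega_back = w_back,
                 lnl_neutral = lnl0, lnl_global = lnl1,
                 lnl_two_ratio = lnl2, lnl_fore_neutral = lnl3,
                 lrt = lrt, p = p, lrt_global = lrt_g, p_global = p_g,
                 n_fore = nf, s_fore = sf, n_back = nb, s_back = sb,
                 total = total, verdict = verdict),
            class = "sel_test")
}

## stem edge + all descendant edges of the clade below `edge`
clade_edges <- function(tree, edge) {
  out <- edge
  stack <- tree$edge[edge, 2]
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    kids <- which(tree$edge[, 1] == nd)
    out <- c(out, kids)
    stack <- c(stack, tree$edge[kids, 2])
  }
  sort(unique(out))
}

#' Scan all genes and clades for selection
#'
#' Iterates [omega_lrt()] over every gene and every internal edge's clade,
#' reporting raw p-values and Benjamini-Hochberg q-values across all
#' gene x clade tests.
#'
#' @param tree `ape::phylo`.
#' @param counts_list list of `subst_counts`, one per gene.
#' @param alpha significance level.
#' @param min_subs few-mutation filter.
#' @param fdr FDR level for the `significant_fdr` column.
#' @return data.frame: gene, clade (tip set), omega_fore, omega_back,
#'   lrt, p, q, verdict, significant_fdr.
#' @export
scan_selection <- function(tree, counts_list, alpha = 0.05, min_subs = 5,
                           fdr = 0.05) {
  ntip <- length(tree$tip.label)
  internal_edges <- which(tree$edge[, 2] > ntip)
  rows <- list()
  for (counts in counts_list) {
    for (e in internal_edges) {
      fg <- clade_edges(tree, e)
      r <- omega_lrt(counts, fg, alpha = alpha, min_subs = min_subs)
      tips <- tree$tip.label[intersect(tree$edge[fg, 2], seq_len(ntip))]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = counts$gene, clade = paste(sort(tips), collapse = "|"),
        omega_fore = r$omega_fore, omega_back = r$omega_back,
        lrt = r$lrt, p = r$p, verdict = r$verdict,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant_fdr <- out$q < fdr & out$verdict %in% c("positive", "negative")
  out
}
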