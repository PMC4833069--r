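# Single heteroplasmic positions (SHPs), cluster sharing statistics, the
# biparental-inheritance compatibility ("maternity") test, and ancestral
# mapping of heteroplasmy origins onto a tree.

#' Call single heteroplasmic positions
#'
#' A position is heteroplasmic for a sample when its minor base allele is
#' supported by at least `min_minor` reads out of at least `min_depth`
#' covering reads. The search is restricted to the supplied candidate
#' positions (the nonredundant SNV set). The minor allele must be a single
#' consistent base: ties between two alleles with equal counts are broken
#' toward the highest count then alphabetically, and positions where two
#' distinct minor alleles both pass the read threshold are emitted once per
#' allele with an `ambiguous` flag.
#'
#' @param pileup allele-count table (one or more samples).
#' @param snv_positions 0-based candidate positions (the SNV set).
#' @param min_minor minimum minor-allele reads (default 5).
#' @param min_depth minimum covering reads (default 1000).
#' @return data.frame of class `shp_table`: sample, pos0, major, minor,
#'   minor_count, depth, fraction, ambiguous.
#' @export
call_shp <- function(pileup, snv_positions, min_minor = 5L,
                     min_depth = 1000L) {
  pk <- data.table::as.data.table(pileup)
  pk <- pk[pk$pos0 %in% snv_positions]
  cm <- as.matrix(pk[, c("A", "C", "G", "T"), with = FALSE])
  depth <- rowSums(cm)
  ord1 <- max.col(cm, ties.method = "first")
  major <- BASES[ord1]
  cm2 <- cm
  cm2[cbind(seq_len(nrow(cm2)), ord1)] <- -1L
  ord2 <- max.col(cm2, ties.method = "first")
  minor <- BASES[ord2]
  minor_n <- cm[cbind(seq_len(nrow(cm)), ord2)]
  ## a further allele tied with the minor at or above threshold -> ambiguous
  cm3 <- cm2
  cm3[cbind(seq_len(nrow(cm3)), ord2)] <- -1L
  third_n <- apply(cm3, 1, max)
  keep <- depth >= min_depth & minor_n >= min_minor &
    minor_n / depth < 0.5
  out <- data.frame(sample = pk$sample[keep], pos0 = pk$pos0[keep],
                    major = major[keep], minor = minor[keep],
                    minor_count = minor_n[keep],
                    depth = as.integer(depth[keep]),
                    fraction = minor_n[keep] / depth[keep],
                    ambiguous = third_n[keep] == minor_n[keep] &
                      third_n[keep] >= min_minor,
                    stringsAsFactors = FALSE)
  amb <- which(out$ambiguous)
  if (length(amb)) {
    extra <- out[amb, , drop = FALSE]
    for (k in seq_along(amb)) {
      i <- amb[k]
      row <- pk[keep][i, ]
      cnts <- c(A = row$A, C = row$C, G = row$G, T = row$T)
      cnts[out$major[i]] <- -1L
      cnts[out$minor[i]] <- -1L
      extra$minor[k] <- names(which.max(cnts))
      extra$minor_count[k] <- max(cnts)
    }
    out <- rbind(out, extra)
    out <- out[order(out$sample, out$pos0), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("shp_table", "data.frame")
  out
}

#' Cluster specification for heteroplasmy sharing
#'
#' @param name cluster label.
#' @param members sample names (>= 2).
#' @param min_sharing positions count as shared when heteroplasmic in at
#'   least this many members (default: all members).
#' @return list of class `cluster_spec`.
#' @export
cluster_spec <- function(name, members, min_sharing = length(members)) {
  if (length(members) < 2L)
    stop("a sharing cluster needs at least two members")
  if (min_sharing < 2L || min_sharing > length(members))
    stop("min_sharing must lie in [2, number of members]")
  structure(list(name = name, members = members,
                 min_sharing = as.integer(min_sharing)),
            class = "cluster_spec")
}

#' Shared-heteroplasmy statistics for a cluster
#'
#' The cluster total is the mean per-sample SHP count when the cluster has
#' four or more members, otherwise the minimum count; the shared count is
#' the number of positions heteroplasmic in at least `min_sharing` members;
#' the percentage is `round(100 * shared / total)` (NA when total is 0).
#'
#' @param shp_sets named list mapping each member sample to its vector of
#'   heteroplasmic positions (or an `shp_table` covering the members).
#' @param cluster a [cluster_spec()].
#' @return list: name, n_members, total, shared, percentage.
#' @export
sharing_stats <- function(shp_sets, cluster) {
  if (inherits(shp_sets, "shp_table") || is.data.frame(shp_sets))
    shp_sets <- split(shp_sets$pos0, shp_sets$sample)
  miss <- setdiff(cluster$members, names(shp_sets))
  for (s in miss) shp_sets[[s]] <- integer(0)
  sets <- lapply(shp_sets[cluster$members], unique)
  counts <- lengths(sets)
  total <- if (length(sets) >= 4L) mean(counts) else min(counts)
  tab <- table(unlist(sets))
  shared <- sum(tab >= cluster$min_sharing)
  pct <- if (total == 0) NA_integer_ else as.integer(round(100 * shared / total))
  list(name = cluster$name, n_members = length(sets), total = total,
       shared = shared, percentage = pct)
}

#' Compatibility ratio of a paternity comparison
#'
#' @param n_compatible,n_incompatible SHP counts.
#' @return n_compatible / (n_compatible + n_incompatible).
#' @export
compatibility_ratio <- function(n_compatible, n_incompatible) {
  n_compatible / (n_compatible + n_incompatible)
}

#' Biparental-inheritance compatibility test
#'
#' For each candidate paternal parent, a hybrid's SHP is compatible when
#' the candidate's called allele at that position equals the hybrid's minor
#' allele (either allele matches for ambiguous SHPs); positions where the
#' candidate call is MISSING are excluded from both counts. Known hybrids
#' are never used as candidates. Candidates are ranked by descending
#' ratio; only candidates with more than `min_compatible` compatible
#' positions carry the reported flag.
#'
#' @param hybrid_shp `shp_table` rows for the hybrid sample.
#' @param candidate_calls positions x samples character matrix of haploid
#'   calls (rownames = 0-based positions), e.g. built from a
#'   `variant_matrix` via `vm$calls` with `rownames(vm$calls) <- vm$positions`.
#' @param known_hybrids sample names excluded from the candidate pool.
#' @param hybrid name of the hybrid (excluded from candidates; defaults to
#'   the sample in `hybrid_shp`).
#' @param min_compatible reporting threshold (default 70).
#' @return data.frame ranked by ratio: candidate, n_compatible,
#'   n_incompatible, ratio, ratio_2dp, reported.
#' @export
paternity_test <- function(hybrid_shp, candidate_calls,
                           known_hybrids = character(0), hybrid = NULL,
                           min_compatible = 70L) {
  if (is.null(hybrid)) hybrid <- unique(hybrid_shp$sample)[1]
  if (nrow(hybrid_shp) == 0)
    return(data.frame(candidate = character(0), n_compatible = integer(0),
                      n_incompatible = integer(0), ratio = numeric(0),
                      ratio_2dp = numeric(0), reported = logical(0)))
  cands <- setdiff(colnames(candidate_calls), c(known_hybrids, hybrid))
  pos_chr <- as.character(hybrid_shp$pos0)
  res <- lapply(cands, function(cd) {
    call <- candidate_calls[match(pos_chr, rownames(candidate_calls)), cd]
    ok <- !is.na(call)
    compat <- ok & call == hybrid_shp$minor
    ## an ambiguous position counts once, as compatible if either of its
    ## tied minor alleles matches
    d <- data.frame(pos0 = hybrid_shp$pos0, ok = ok, compat = compat)
    agg <- stats::aggregate(cbind(ok, compat) ~ pos0, d, any)
    n_c <- sum(agg$compat[agg$ok])
    n_i <- sum(agg$ok) - n_c
    data.frame(candidate = cd, n_compatible = n_c, n_incompatible = n_i,
               ratio = compatibility_ratio(n_c, n_i))
  })
  out <- do.call(rbind, res)
  out$ratio[is.nan(out$ratio)] <- 0
  out <- out[order(-out$ratio, out$candidate), , drop = FALSE]
  out$ratio_2dp <- round(out$ratio, 2)
  out$reported <- out$n_compatible > min_compatible
  rownames(out) <- NULL
  out
}

#' Map heteroplasmy origins onto a tree
#'
#' Each distinct heteroplasmic position is assigned a single origin: the
#' most recent common ancestor of the leaves carrying it (the leaf itself
#' for private positions). Per-node counts therefore sum to the number of
#' distinct positions.
#'
#' @param tree `ape::phylo` whose tips include every SHP-bearing sample.
#' @param shp `shp_table` (or data.frame with sample, pos0).
#' @return data.frame: node (ape node number), label (tip label or
#'   "node<N>"), n_events; attribute "assignment" maps each position to its
#'   node.
#' @export
ancestral_origin_map <- function(tree, shp) {
  samples <- unique(shp$sample)
  bad <- setdiff(samples, tree$tip.label)
  if (length(bad))
    stop("sample(s) not in tree: ", paste(bad, collapse = ", "))
  carriers <- split(shp$sample, shp$pos0)
  node_of <- vapply(carriers, function(cs) {
    cs <- unique(cs)
    if (length(cs) == 1L) match(cs, tree$tip.label)
    else ape::getMRCA(tree, cs)
  }, integer(1))
  tab <- table(node_of)
  nodes <- as.integer(names(tab))
  lab <- ifelse(nodes <= length(tree$tip.label), tree$tip.label[nodes],
                paste0("node", nodes))
  out <- data.frame(node = nodes, label = lab, n_events = as.integer(tab))
  attr(out, "assignment") <- data.frame(pos0 = as.integer(names(carriers)),
                                        node = node_of)
  out
}
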