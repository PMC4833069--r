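# Seeded simulator of chloroplast-like genomes: reference with inverted
# repeats and nuclear-homologous tracts, genome evolution along a timed tree
# (GTR substitutions + indels + large deletions between homologous flanks),
# hybridization leakage producing heteroplasmy, and deep pileups.
#
# Leaf genomes are represented in the reference coordinate frame as sparse
# edit maps: list(sub = named character (0-based pos -> base),
# del = integer positions, ins = named character (pos -> inserted sequence,
# placed after that position)). This keeps every downstream stage (pileups,
# variant truth, codon alignments) positionally consistent by construction.

#' Default indel length distribution (1..36 bp)
#'
#' Geometric-decay weights with ratio 0.825 so that ~90% of indels are
#' shorter than 13 bp and 1-bp events are modal.
#'
#' @return named numeric vector of probabilities for lengths 1..36.
#' @export
default_indel_lengths <- function() {
  w <- 0.825^(0:35)
  stats::setNames(w / sum(w), 1:36)
}

#' Simulation configuration
#'
#' @param genome_length reference length in bp.
#' @param ir_intervals list of two equal-length 0-based half-open intervals;
#'   the second is written as the reverse complement of the first.
#' @param homolog_tracts list of intervals planted as nuclear-homologous
#'   (copied into the decoy nuclear sequence and masked).
#' @param tree newick string or `ape::phylo`; branch lengths in My.
#' @param subst_rate substitutions/site/My.
#' @param gtr list with `pi` (4 base frequencies, sums to 1) and `rates`
#'   (6 exchangeabilities in order AC, AG, AT, CG, CT, GT).
#' @param indel_rate indel events/site/My.
#' @param indel_length_dist categorical distribution over 1..36 bp.
#' @param insertion_fraction proportion of indel events that are insertions.
#' @param large_deletions list of `list(motif, start, end, leaf)`; the motif
#'   is planted at both flanks and the deletion applied on the terminal
#'   branch of `leaf` (default first leaf).
#' @param hybrid_events list of `list(recipient, donor, leakage)` with
#'   leakage in (0, 0.5); the paternal donor contributes the minor allele.
#' @param coverage mean pileup depth (reads/position).
#' @param error_rate per-base sequencing error probability.
#' @param seed master integer seed; per-stage streams are derived from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 160129L,
                       ir_intervals = list(c(85000L, 111000L),
                                           c(134129L, 160129L)),
                       homolog_tracts = list(),
                       tree = NULL,
                       subst_rate = 1.2e-4,
                       gtr = list(pi = c(A = 0.31, C = 0.19, G = 0.19, T = 0.31),
                                  rates = rep(1, 6)),
                       indel_rate = 2.5e-5,
                       indel_length_dist = default_indel_lengths(),
                       insertion_fraction = 0.59,
                       large_deletions = list(),
                       hybrid_events = list(),
                       coverage = 2000,
                       error_rate = 0.001,
                       seed = 1L) {
  L <- as.integer(genome_length)
  if (L < 10000L) stop("configuration error: genome_length must be >= 10 kb")
  ir <- intervals_df(ir_intervals)
  if (nrow(ir) != 2L) stop("configuration error: exactly two IR intervals required")
  if (any(ir$start < 0L) || any(ir$end > L) || any(ir$start >= ir$end))
    stop("configuration error: IR intervals out of genome bounds")
  if (diff(ir$start)[1] < 0) ir <- ir[order(ir$start), ]
  if (ir$end[1] > ir$start[2])
    stop("configuration error: IR intervals must be disjoint")
  ht <- intervals_df(homolog_tracts)
  if (nrow(ht) && (any(ht$start < 0L) || any(ht$end > L)))
    stop("configuration error: homolog tract out of genome bounds")
  if (abs(sum(gtr$pi) - 1) > 1e-8)
    stop("configuration error: GTR base frequencies must sum to 1")
  if (length(gtr$rates) != 6L || any(gtr$rates <= 0))
    stop("configuration error: 6 positive GTR exchangeabilities required")
  if (insertion_fraction < 0 || insertion_fraction > 1)
    stop("configuration error: insertion_fraction must lie in [0, 1]")
  for (h in hybrid_events)
    if (h$leakage <= 0 || h$leakage >= 0.5)
      stop("configuration error: hybrid leakage must lie in (0, 0.5)")
  for (ld in large_deletions)
    if (ld$start < 0 || ld$end > L || ld$start >= ld$end)
      stop("configuration error: large deletion interval out of bounds")
  structure(list(
    genome_length = L, ir_intervals = ir, homolog_tracts = ht, tree = tree,
    subst_rate = subst_rate, gtr = gtr, indel_rate = indel_rate,
    indel_length_dist = indel_length_dist,
    insertion_fraction = insertion_fraction,
    large_deletions = large_deletions, hybrid_events = hybrid_events,
    coverage = coverage, error_rate = error_rate, seed = as.integer(seed)),
    class = "sim_config")
}

sense_codons <- function() {
  cods <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                1, paste, collapse = "")
  setdiff(cods, c("TAA", "TAG", "TGA"))
}

## Tile non-overlapping genes over the unmasked genome. Single-exon genes on
## both strands; every 4th gene (plus strand only) carries one intron.
make_gene_model <- function(L, avoid) {
  avoid <- merge_intervals(avoid)
  pos <- 300L
  rows <- list()
  gi <- 0L
  repeat {
    glen <- sample(seq(300L, 900L, by = 3L), 1)
    if (pos + glen + 400L >= L) break
    hit <- which(avoid$start < pos + glen + 200L & avoid$end > pos - 50L)
    if (length(hit)) {
      pos <- max(avoid$end[hit]) + 60L
      next
    }
    gi <- gi + 1L
    strand <- if (gi %% 2L == 0L) "-" else "+"
    gene <- sprintf("g%03d", gi)
    if (gi %% 4L == 0L && strand == "+") {
      e1 <- 3L * sample(40:80, 1)
      intron <- sample(91:149, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, strand = strand, exon = 1:2,
        start = c(pos, pos + e1 + intron),
        end = c(pos + e1, pos + glen + intron))
      pos <- pos + glen + intron + sample(200:500, 1)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, strand = strand, exon = 1L, start = pos, end = pos + glen)
      pos <- pos + glen + sample(200:500, 1)
    }
  }
  do.call(rbind, rows)
}

#' Generate a chloroplast-like reference
#'
#' Draws a random sequence under the configured base composition, plants
#' stop-free CDSs for a tiled gene model, writes the second inverted repeat
#' as the reverse complement of the first, plants large-deletion flank
#' motifs, and builds a decoy nuclear sequence embedding the homolog tracts.
#'
#' @param cfg a [sim_config()].
#' @return list of class `cp_reference` with `sequence`, `genes` (gene-model
#'   data.frame), `mask` (IRs plus homolog tracts, merged), and
#'   `nuclear_decoy`.
#' @export
generate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, 1L))
  L <- cfg$genome_length
  chars <- sample(BASES, L, replace = TRUE, prob = cfg$gtr$pi)

  avoid <- rbind(cfg$ir_intervals, cfg$homolog_tracts,
                 intervals_df(lapply(cfg$large_deletions, function(ld)
                   c(ld$start - 30L, ld$end + 30L))))
  genes <- make_gene_model(L, avoid)

  cods <- sense_codons()
  for (g in unique(genes$gene)) {
    ex <- genes[genes$gene == g, , drop = FALSE]
    cds_len <- sum(ex$end - ex$start)
    ncod <- cds_len %/% 3L
    cds <- paste(c("ATG", sample(cods, ncod - 1L, replace = TRUE)),
                 collapse = "")
    if (ex$strand[1] == "-") cds <- revcomp(cds)
    off <- 0L
    for (i in seq_len(nrow(ex))) {
      len <- ex$end[i] - ex$start[i]
      piece <- substr(cds, off + 1L, off + len)
      chars[(ex$start[i] + 1L):ex$end[i]] <- seqinr::s2c(piece)
      off <- off + len
    }
  }

  ira <- cfg$ir_intervals[1, ]; irb <- cfg$ir_intervals[2, ]
  k <- min(ira$end - ira$start, irb$end - irb$start)
  chars[(irb$start + 1L):(irb$start + k)] <-
    rev(chartr("ACGT", "TGCA", chars[(ira$start + 1L):(ira$start + k)]))

  for (ld in cfg$large_deletions) {
    m <- seqinr::s2c(ld$motif)
    k <- length(m)
    if (ld$end + k > L) stop("configuration error: motif extends past genome")
    chars[(ld$start + 1L):(ld$start + k)] <- m
    chars[(ld$end + 1L):(ld$end + k)] <- m
  }

  seq <- paste(chars, collapse = "")
  decoy <- random_dna(2000, cfg$gtr$pi)
  if (nrow(cfg$homolog_tracts)) {
    for (i in seq_len(nrow(cfg$homolog_tracts))) {
      tr <- substr(seq, cfg$homolog_tracts$start[i] + 1L,
                   cfg$homolog_tracts$end[i])
      decoy <- paste0(decoy, tr, random_dna(150, cfg$gtr$pi))
    }
  }
  decoy <- paste0(decoy, random_dna(2000, cfg$gtr$pi))

  mask <- merge_intervals(rbind(cfg$ir_intervals, cfg$homolog_tracts))
  structure(list(sequence = seq, genes = genes, mask = mask,
                 nuclear_decoy = decoy),
            class = "cp_reference")
}

empty_genome <- function() list(sub = character(0), del = integer(0),
                                ins = character(0))

## Allele of an edit-map genome at 0-based positions ("-" where deleted).
#' Alleles of a simulated genome at given reference positions
#'
#' @param genome edit-map genome (as produced by [evolve_genomes()]).
#' @param pos integer vector of 0-based positions.
#' @param ref_chars reference sequence split into characters.
#' @return character vector of alleles; "-" where the position is deleted.
#' @export
genome_allele_at <- function(genome, pos, ref_chars) {
  a <- ref_chars[pos + 1L]
  if (length(genome$sub)) {
    hit <- match(as.character(pos), names(genome$sub))
    a[!is.na(hit)] <- genome$sub[hit[!is.na(hit)]]
  }
  a[pos %in% genome$del] <- "-"
  a
}

gtr_exchange_matrix <- function(rates) {
  R <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  R["A", "C"] <- R["C", "A"] <- rates[1]
  R["A", "G"] <- R["G", "A"] <- rates[2]
  R["A", "T"] <- R["T", "A"] <- rates[3]
  R["C", "G"] <- R["G", "C"] <- rates[4]
  R["C", "T"] <- R["T", "C"] <- rates[5]
  R["G", "T"] <- R["T", "G"] <- rates[6]
  R
}

#' Evolve genomes along a timed tree
#'
#' Substitution counts per branch are Poisson(subst_rate x L x duration)
#' with GTR-conditional replacement bases; indels are Poisson events with
#' lengths from the configured distribution, placed uniformly outside the
#' inverted repeats; configured large deletions are applied on the terminal
#' branch of their carrier leaf only where the flank motif is present on
#' both sides (otherwise skipped with a warning).
#'
#' @param cfg a [sim_config()] whose `tree` is set.
#' @param reference a `cp_reference` from [generate_reference()].
#' @return list with `tree` (phylo), `genomes` (edit maps per leaf),
#'   `sequences` (realized leaf genome strings), `true_variants`,
#'   `true_sv`, and `true_ages` (named node ages, My).
#' @export
evolve_genomes <- function(cfg, reference) {
  tree <- cfg$tree
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths (My)")
  set.seed(stage_seed(cfg$seed, 2L))
  L <- cfg$genome_length
  ref_chars <- seqinr::s2c(reference$sequence)
  R <- gtr_exchange_matrix(cfg$gtr$rates)
  pi <- cfg$gtr$pi
  lens <- as.integer(names(cfg$indel_length_dist))
  non_ir <- which(!in_intervals(0:(L - 1L), cfg$ir_intervals)) - 1L

  ntip <- length(tree$tip.label)
  genomes <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  genomes[[root]] <- empty_genome()
  ## parents before children
  eord <- order(-ape::node.depth(tree)[tree$edge[, 2]])

  sv_rows <- list()
  ld_by_leaf <- list()
  for (ld in cfg$large_deletions) {
    leaf <- if (is.null(ld$leaf)) tree$tip.label[1] else ld$leaf
    ld_by_leaf[[leaf]] <- c(ld_by_leaf[[leaf]], list(ld))
  }

  for (ei in eord) {
    par <- tree$edge[ei, 1]; child <- tree$edge[ei, 2]
    t <- tree$edge.length[ei]
    g <- genomes[[par]]

    nsub <- stats::rpois(1, cfg$subst_rate * L * t)
    if (nsub > 0) {
      pos <- sample.int(L, min(nsub, L)) - 1L
      cur <- genome_allele_at(g, pos, ref_chars)
      keep <- cur != "-"
      pos <- pos[keep]; cur <- cur[keep]
      new <- character(length(pos))
      for (b in BASES) {
        sel <- cur == b
        if (!any(sel)) next
        p <- R[b, ] * pi
        new[sel] <- sample(BASES, sum(sel), replace = TRUE, prob = p)
      }
      g$sub[as.character(pos)] <- new
      ## a substitution back to the reference base removes the edit
      backs <- new == ref_chars[pos + 1L]
      if (any(backs))
        g$sub <- g$sub[!(names(g$sub) %in% as.character(pos[backs]))]
    }

    nind <- stats::rpois(1, cfg$indel_rate * L * t)
    if (nind > 0) {
      pos <- sample(non_ir, nind, replace = TRUE)
      is_ins <- stats::runif(nind) < cfg$insertion_fraction
      ln <- sample(lens, nind, replace = TRUE, prob = cfg$indel_length_dist)
      for (i in seq_len(nind)) {
        if (is_ins[i]) {
          g$ins[as.character(pos[i])] <- random_dna(ln[i], pi)
        } else {
          g$del <- union(g$del, pos[i]:min(pos[i] + ln[i] - 1L, L - 1L))
        }
      }
    }

    if (child <= ntip) {
      leaf <- tree$tip.label[child]
      for (ld in ld_by_leaf[[leaf]]) {
        k <- nchar(ld$motif)
        lflank <- substr(reference$sequence, ld$start + 1L, ld$start + k)
        rflank <- substr(reference$sequence, ld$end + 1L, ld$end + k)
        if (lflank != ld$motif || rflank != ld$motif) {
          warning(sprintf("flank motif %s absent at [%d,%d); deletion skipped",
                          ld$motif, ld$start, ld$end))
          next
        }
        g$del <- union(g$del, ld$start:(ld$end - 1L))
        sv_rows[[length(sv_rows) + 1L]] <- data.frame(
          sample = leaf, start = ld$start, end = ld$end,
          motif = ld$motif, stringsAsFactors = FALSE)
      }
    }
    g$del <- sort(g$del)
    genomes[[child]] <- g
  }

  leaf_maps <- stats::setNames(genomes[seq_len(ntip)], tree$tip.label)
  seqs <- vapply(leaf_maps, realize_sequence, character(1),
                 ref_chars = ref_chars)
  tv <- do.call(rbind, c(lapply(tree$tip.label, function(s)
    truth_variants_one(leaf_maps[[s]], s, ref_chars)),
    list(make.row.names = FALSE)))
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths) - depths
  names(ages) <- c(tree$tip.label,
                   paste0("node", (ntip + 1L):(ntip + tree$Nnode)))
  list(tree = tree, genomes = leaf_maps, sequences = seqs,
       true_variants = tv,
       true_sv = if (length(sv_rows)) do.call(rbind, sv_rows) else
         data.frame(sample = character(0), start = integer(0),
                    end = integer(0), motif = character(0)),
       true_ages = ages)
}

truth_variants_one <- function(g, sample, ref_chars) {
  rows <- list()
  if (length(g$sub)) {
    pos <- as.integer(names(g$sub))
    rows[[1L]] <- data.frame(sample = sample, pos0 = pos,
                             ref = ref_chars[pos + 1L],
                             alt = unname(g$sub), type = "SNV",
                             stringsAsFactors = FALSE)
  }
  if (length(g$del)) {
    d <- sort(g$del)
    run_id <- cumsum(c(1L, diff(d) != 1L))
    for (r in split(d, run_id)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample, pos0 = r[1],
        ref = paste(ref_chars[r + 1L], collapse = ""), alt = "-",
        type = "indel", stringsAsFactors = FALSE)
    }
  }
  if (length(g$ins)) {
    pos <- as.integer(names(g$ins))
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample, pos0 = pos, ref = ref_chars[pos + 1L],
      alt = paste0("+", unname(g$ins)), type = "indel",
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sample = character(0), pos0 = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0)))
  do.call(rbind, rows)
}

#' Realize a leaf genome sequence from its edit map
#'
#' @param genome edit-map genome.
#' @param ref_chars reference characters.
#' @return the leaf genome as a single DNA string.
#' @export
realize_sequence <- function(genome, ref_chars) {
  y <- ref_chars
  if (length(genome$del)) y[genome$del + 1L] <- ""
  if (length(genome$ins)) {
    p <- as.integer(names(genome$ins))
    y[p + 1L] <- paste0(y[p + 1L], unname(genome$ins))
  }
  paste(y, collapse = "")
}

#' Heteroplasmy truth from a hybridization event
#'
#' Every position where the paternal donor genome differs from the maternal
#' recipient genome (both carrying a base) becomes a true single
#' heteroplasmic position with minor allele = donor allele and expected
#' minor fraction = leakage.
#'
#' @param recipient,donor edit-map genomes in the same coordinate frame.
#' @param leakage paternal chloroplast fraction, in (0, 0.5).
#' @param reference reference sequence string (or character vector).
#' @return data.frame with pos0, major, minor, fraction.
#' @export
apply_hybridization <- function(recipient, donor, leakage, reference) {
  if (leakage <= 0 || leakage >= 0.5)
    stop("leakage must lie in (0, 0.5): the donor allele is the minor allele")
  ref_chars <- if (length(reference) == 1L) seqinr::s2c(reference) else reference
  pos <- sort(unique(c(as.integer(names(recipient$sub)),
                       as.integer(names(donor$sub)))))
  if (!length(pos))
    return(data.frame(pos0 = integer(0), major = character(0),
                      minor = character(0), fraction = numeric(0)))
  a_r <- genome_allele_at(recipient, pos, ref_chars)
  a_d <- genome_allele_at(donor, pos, ref_chars)
  keep <- a_r != a_d & a_r != "-" & a_d != "-"
  if (!any(keep))
    return(data.frame(pos0 = integer(0), major = character(0),
                      minor = character(0), fraction = numeric(0)))
  data.frame(pos0 = pos[keep], major = a_r[keep], minor = a_d[keep],
             fraction = leakage, stringsAsFactors = FALSE)
}

## distribute sequencing errors of base-reporting reads over the other
## three bases; returns the counts matrix updated in place semantics
add_base_reads <- function(M, idx, base, count, error_rate) {
  err <- stats::rbinom(length(idx), count, error_rate)
  keep <- count - err
  e1 <- stats::rbinom(length(idx), err, 1 / 3)
  e2 <- stats::rbinom(length(idx), err - e1, 1 / 2)
  e3 <- err - e1 - e2
  for (b in BASES) {
    sel <- base == b
    if (!any(sel)) next
    oth <- setdiff(BASES, b)
    M[idx[sel], b] <- M[idx[sel], b] + keep[sel]
    M[idx[sel], oth[1]] <- M[idx[sel], oth[1]] + e1[sel]
    M[idx[sel], oth[2]] <- M[idx[sel], oth[2]] + e2[sel]
    M[idx[sel], oth[3]] <- M[idx[sel], oth[3]] + e3[sel]
  }
  M
}

#' Simulate a deep pileup for one sample
#'
#' Depth per position is Poisson(coverage). Each read reports the sample's
#' allele, or the heteroplasmic minor allele with probability equal to the
#' minor fraction; base-reporting reads are mutated uniformly to another
#' base with probability `error_rate`. Deleted positions yield
#' deletion-supporting reads (plus minor-fraction residual reads where a
#' heteroplasmic record says so); insertion carriers report the inserted
#' sequence on all covering reads.
#'
#' @param genome edit-map genome, or a string of the same length as the
#'   reference (with "-" marking deleted bases).
#' @param reference reference sequence string.
#' @param shp optional data.frame(pos0, minor, fraction) of heteroplasmic
#'   positions for this sample.
#' @param coverage mean depth.
#' @param error_rate per-base error probability.
#' @param seed integer seed (deterministic output).
#' @param positions 0-based positions to emit (default: whole genome).
#' @param sample sample name for the output table.
#' @return data.table allele-count table (see [write_pileup()] for columns).
#' @export
simulate_pileup <- function(genome, reference, shp = NULL, coverage = 2000,
                            error_rate = 0.001, seed = 1L, positions = NULL,
                            sample = "sample") {
  if (coverage < 1) stop("coverage must be >= 1")
  ref_chars <- seqinr::s2c(reference)
  L <- length(ref_chars)
  if (is.character(genome)) {
    gch <- seqinr::s2c(genome)
    if (length(gch) != L)
      stop("string genomes must match the reference length")
    genome <- list(sub = character(0), del = which(gch == "-") - 1L,
                   ins = character(0))
    diffp <- which(gch != ref_chars & gch != "-") - 1L
    genome$sub <- stats::setNames(gch[diffp + 1L], as.character(diffp))
  }
  if (is.null(positions)) positions <- 0:(L - 1L)
  positions <- as.integer(positions)
  set.seed(seed)
  n <- length(positions)
  allele <- genome_allele_at(genome, positions, ref_chars)
  deleted <- allele == "-"

  f <- numeric(n); minor <- character(n)
  if (!is.null(shp) && nrow(shp)) {
    hit <- match(positions, shp$pos0)
    f[!is.na(hit)] <- shp$fraction[hit[!is.na(hit)]]
    minor[!is.na(hit)] <- shp$minor[hit[!is.na(hit)]]
  }

  depth <- stats::rpois(n, coverage)
  minor_n <- stats::rbinom(n, depth, f)
  major_n <- depth - minor_n

  M <- matrix(0L, n, 5, dimnames = list(NULL, c(BASES, "del")))
  M[deleted, "del"] <- major_n[deleted]
  idx <- which(!deleted)
  if (length(idx))
    M <- add_base_reads(M, idx, allele[idx], major_n[idx], error_rate)
  midx <- which(minor_n > 0 & minor %in% BASES)
  if (length(midx))
    M <- add_base_reads(M, midx, minor[midx], minor_n[midx], error_rate)

  ins_col <- rep("", n)
  if (length(genome$ins)) {
    ip <- as.integer(names(genome$ins))
    hit <- match(positions, ip)
    has <- !is.na(hit)
    ins_col[has] <- paste0(unname(genome$ins[hit[has]]), ":", depth[has])
  }

  data.table::data.table(sample = sample, pos0 = positions,
                         A = M[, "A"], C = M[, "C"], G = M[, "G"],
                         T = M[, "T"], del = M[, "del"], ins = ins_col,
                         depth = as.integer(rowSums(M)))
}

#' Simulate a complete dataset: reference, leaf genomes, truth, pileups
#'
#' Runs [generate_reference()], [evolve_genomes()], applies the configured
#' hybridization events, and simulates pileups for every leaf.
#'
#' @param cfg a [sim_config()] with a tree.
#' @param pileups emit pileups (set FALSE to skip the expensive stage).
#' @param positions pileup positions: NULL for the whole genome, or
#'   "variants" to restrict to true variant positions (fast; sufficient for
#'   SNV/heteroplasmy analyses).
#' @return list with `reference`, `tree`, `genomes`, `sequences`, `truth`
#'   (variants, shp, sv, donor, ages) and `pileup` (one table, all samples).
#' @export
simulate_dataset <- function(cfg, pileups = TRUE, positions = NULL) {
  ref <- generate_reference(cfg)
  ev <- evolve_genomes(cfg, ref)
  shp_rows <- list()
  donor_map <- character(0)
  for (h in cfg$hybrid_events) {
    s <- apply_hybridization(ev$genomes[[h$recipient]],
                             ev$genomes[[h$donor]], h$leakage,
                             ref$sequence)
    if (nrow(s)) s$sample <- h$recipient
    shp_rows[[length(shp_rows) + 1L]] <- s
    donor_map[h$recipient] <- h$donor
  }
  true_shp <- if (length(shp_rows)) do.call(rbind, shp_rows) else
    data.frame(pos0 = integer(0), major = character(0), minor = character(0),
               fraction = numeric(0), sample = character(0))

  pk <- NULL
  if (pileups) {
    pos <- positions
    if (identical(positions, "variants")) {
      tv <- ev$true_variants
      del_pos <- unlist(lapply(which(tv$alt == "-"), function(i)
        tv$pos0[i] + 0:(nchar(tv$ref[i]) - 1L)))
      pos <- sort(unique(c(tv$pos0, del_pos, true_shp$pos0)))
    }
    tabs <- lapply(seq_along(ev$genomes), function(i) {
      s <- names(ev$genomes)[i]
      simulate_pileup(ev$genomes[[i]], ref$sequence,
                      shp = true_shp[true_shp$sample == s, , drop = FALSE],
                      coverage = cfg$coverage, error_rate = cfg$error_rate,
                      seed = stage_seed(cfg$seed, 100L + i),
                      positions = pos, sample = s)
    })
    pk <- data.table::rbindlist(tabs)
  }
  list(reference = ref, tree = ev$tree, genomes = ev$genomes,
       sequences = ev$sequences,
       truth = list(variants = ev$true_variants, shp = true_shp,
                    sv = ev$true_sv, donor = donor_map,
                    ages = ev$true_ages),
       pileup = pk)
}
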