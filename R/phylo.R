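# Haplotype phylogenetics: Kimura two-parameter distances, Saitou-Nei
# neighbour joining, and bipartition bootstrap supports. Trees are returned
# as ape "phylo" objects so the usual toolchain (plot, write.tree, ...)
# applies, but the distance and agglomeration arithmetic is implemented
# here: NJ tie-breaking and negative-branch handling are pinned down so
# results are bit-reproducible.

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

# classify aligned site pairs: 0 excluded (gap/N), 1 identical, 2
# transition, 3 transversion
classify_pairs <- function(a, b) {
  out <- integer(length(a))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  same <- ok & a == b
  ts <- ok & !same & TRANSITIONS[a] == b
  out[ok] <- 3L
  out[same] <- 1L
  out[ts] <- 2L
  out
}

#' Kimura two-parameter distance
#'
#' With transition proportion P and transversion proportion Q over the
#' included sites, `D = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`. Sites
#' with a gap or N in either sequence are excluded pairwise.
#'
#' @param seq_a,seq_b aligned nucleotide strings of equal length.
#' @return the distance in substitutions per site.
#' @examples
#' a <- paste(rep("A", 100), collapse = "")
#' k2p(a, a)  # 0
#' @export
k2p <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  cls <- classify_pairs(a, b)
  n <- sum(cls > 0L)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  k2p_from_counts(sum(cls == 2L), sum(cls == 3L), n)
}

k2p_from_counts <- function(n_ts, n_tv, n) {
  P <- n_ts / n; Q <- n_tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance undefined (saturation): 1-2P-Q = ", signif(w1, 4),
         ", 1-2Q = ", signif(w2, 4))
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix
#'
#' @param seqs named character vector of aligned sequences.
#' @return symmetric matrix of K2P distances with zero diagonal.
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  chars <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cls <- classify_pairs(chars[[i]], chars[[j]])
    m <- sum(cls > 0L)
    if (m == 0L) stop("no comparable sites between ", names(seqs)[i],
                      " and ", names(seqs)[j])
    D[i, j] <- D[j, i] <- k2p_from_counts(sum(cls == 2L), sum(cls == 3L), m)
  }
  D
}

#' Neighbour-joining tree
#'
#' Standard Saitou-Nei agglomeration. Ties on the Q criterion are broken by
#' the lexicographically smallest taxon-name pair; negative branch-length
#' estimates are clamped to zero with a warning. Two taxa yield a single
#' edge split evenly.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return an unrooted `ape::phylo` tree.
#' @examples
#' D <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' nj_tree(D)
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (any(is.na(D)) || !isTRUE(all.equal(D, t(D), tolerance = 1e-12)))
    stop("distance matrix must be symmetric with no missing values")
  n <- nrow(D)
  stopifnot(n >= 2L)
  taxa <- rownames(D)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = rep(D[1, 2] / 2, 2L),
               tip.label = taxa, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  # active nodes carry a tree-node id plus a numeric tie-break rank: the
  # lexicographic rank of the smallest taxon name in the node's subtree
  next_node <- n + 1L
  node_id <- seq_len(n)
  rank_ <- rank(taxa)
  edges <- matrix(integer(), 0L, 2L)
  elen <- numeric(0)
  clamped <- FALSE
  while (nrow(D) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    # candidates within numerical tolerance of the minimum; break ties by
    # the lexicographically smallest (sorted) taxon-rank pair
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    r1 <- pmin(rank_[cand[, 1]], rank_[cand[, 2]])
    r2 <- pmax(rank_[cand[, 1]], rank_[cand[, 2]])
    pick <- cand[order(r1, r2)[1L], ]
    i <- pick[1]; j <- pick[2]
    d_ij <- D[i, j]
    li <- 0.5 * d_ij + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- d_ij - li
    if (li < 0 || lj < 0) { clamped <- TRUE; li <- max(li, 0); lj <- max(lj, 0) }
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, node_id[i]), c(u, node_id[j]))
    elen <- c(elen, li, lj)
    d_new <- 0.5 * (D[i, ] + D[j, ] - d_ij)[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, d_new), c(d_new, 0))
    rank_ <- c(rank_[-c(i, j)], min(rank_[c(i, j)]))
    node_id <- c(node_id[-c(i, j)], u)
    dimnames(D) <- NULL
  }
  # terminal star of three nodes
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  if (any(c(l1, l2, l3) < 0)) clamped <- TRUE
  u <- next_node
  edges <- rbind(edges, c(u, node_id[1]), c(u, node_id[2]), c(u, node_id[3]))
  elen <- c(elen, max(l1, 0), max(l2, 0), max(l3, 0))
  if (clamped) warning("negative NJ branch length(s) clamped to zero")
  n_internal <- u - n
  # renumber internal nodes into ape convention (tips 1..n, root n+1, ...)
  # our internal ids were assigned n+1.. in creation order; ape wants the
  # root (last created) first. Map internal id x -> n + 1 + (u - x).
  remap <- function(x) ifelse(x <= n, x, n + 1L + (u - x))
  tr <- list(edge = cbind(remap(edges[, 1]), remap(edges[, 2])),
             edge.length = elen, tip.label = taxa, Nnode = n_internal)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# ---- alignment containers -------------------------------------------------

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param gene_alignments named list of named character vectors
#'   (sample -> aligned sequence), one per gene, identical sample sets.
#' @return list with `sequences` (named character vector) and `partitions`
#'   (data.frame gene, start, end in supermatrix coordinates).
#' @export
concat_alignment <- function(gene_alignments) {
  stopifnot(length(gene_alignments) >= 1L)
  samples <- sort(names(gene_alignments[[1]]))
  parts <- list(); offset <- 0L
  rows <- stats::setNames(rep("", length(samples)), samples)
  for (g in names(gene_alignments)) {
    aln <- gene_alignments[[g]]
    if (!setequal(names(aln), samples))
      stop("gene ", g, " is missing samples present in other genes")
    len <- unique(nchar(aln))
    if (length(len) != 1L)
      stop("gene ", g, ": aligned sequences of unequal length")
    rows[samples] <- paste0(rows[samples], aln[samples])
    parts[[g]] <- data.frame(gene = g, start = offset + 1L,
                             end = offset + len, stringsAsFactors = FALSE)
    offset <- offset + len
  }
  list(sequences = rows, partitions = do.call(rbind, parts))
}

#' Reconstruct sample haplotype alignments from an event table
#'
#' Builds per-sample aligned sequences for one gene directly from
#' reference-anchored events: positions never touched by any event are
#' constant across samples (filled from the reference sequence when given,
#' otherwise with 'A' — the choice cannot affect any pairwise distance),
#' substituted positions carry each sample's allele, and deletion carriers
#' get gap columns at the deleted positions, so no realignment is needed.
#' Insertions are not supported here (none occur in reference-anchored
#' organelle screens of this kind at these divergences).
#'
#' @param events event table for one gene.
#' @param gene a [gene_spec()].
#' @param samples character vector of all samples in the panel (samples
#'   without events get the reference haplotype).
#' @return named character vector of aligned sequences (gap character "-").
#' @export
reconstruct_haplotypes <- function(events, gene, samples) {
  stopifnot(inherits(gene, "gene_spec"))
  if (nrow(events) && any(events$kind == "insertion"))
    stop("insertion events are not supported in haplotype reconstruction")
  base <- if (!is.null(gene$reference_sequence))
    strsplit(gene$reference_sequence, "")[[1]]
  else rep("A", gene$length_bp)
  # place reference alleles of events onto the backbone
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      p <- events$position[i]; r <- events$ref[i]
      if (nchar(r))
        base[p:(p + nchar(r) - 1L)] <- strsplit(r, "")[[1]]
    }
  }
  out <- stats::setNames(vector("list", length(samples)), samples)
  for (s in samples) {
    h <- base
    ev <- events[events$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      p <- ev$position[i]
      if (ev$kind[i] == "substitution") {
        h[p:(p + nchar(ev$ref[i]) - 1L)] <- strsplit(ev$alt[i], "")[[1]]
      } else if (ev$kind[i] == "deletion") {
        h[p:(p + nchar(ev$ref[i]) - 1L)] <- "-"
      }
    }
    out[[s]] <- paste(h, collapse = "")
  }
  unlist(out)
}

# ---- bootstrap ------------------------------------------------------------

# compress an alignment to site patterns; returns list(patterns =
# character matrix [n_seq x n_pat], weights)
site_patterns <- function(seqs) {
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  # canonical pattern identity is computed over taxa sorted by name, so the
  # site -> pattern map does not depend on input order
  ord <- order(rownames(chars) %||% names(seqs))
  pat_key <- apply(chars[ord, , drop = FALSE], 2L, paste, collapse = "")
  first <- which(!duplicated(pat_key))
  pat_of_site <- match(pat_key, pat_key[first])
  list(patterns = chars[, first, drop = FALSE],
       weights = tabulate(pat_of_site, nbins = length(first)),
       pat_of_site = pat_of_site,
       n_sites = length(pat_key))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# K2P distance matrix from site patterns with (possibly resampled) weights;
# pair classification is precomputed once by the caller
pattern_pair_classes <- function(patterns) {
  n <- nrow(patterns)
  pairs <- utils::combn(n, 2L)
  cls <- matrix(0L, ncol(pairs), ncol(patterns))
  for (k in seq_len(ncol(pairs))) {
    cls[k, ] <- classify_pairs(patterns[pairs[1, k], ],
                               patterns[pairs[2, k], ])
  }
  list(pairs = pairs, cls = cls)
}

dist_from_classes <- function(pc, weights, taxa) {
  n <- length(taxa)
  n_inc <- as.numeric((pc$cls > 0L) %*% weights)
  n_ts <- as.numeric((pc$cls == 2L) %*% weights)
  n_tv <- as.numeric((pc$cls == 3L) %*% weights)
  if (any(n_inc == 0)) stop("pair with no comparable sites")
  P <- n_ts / n_inc; Q <- n_tv / n_inc
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (any(w1 <= 0 | w2 <= 0)) stop("K2P distance undefined (saturation)")
  d <- -0.5 * log(w1 * sqrt(w2))
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  D[cbind(pc$pairs[1, ], pc$pairs[2, ])] <- d
  D[cbind(pc$pairs[2, ], pc$pairs[1, ])] <- d
  D
}

# canonical bipartition keys of a phylo tree: for each internal edge, the
# tip-label set on the far side not containing the first tip, sorted
tree_bipartitions <- function(tr) {
  n <- length(tr$tip.label)
  if (tr$Nnode < 2L) return(character(0))
  desc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  # postorder accumulation of descendant tips
  tr2 <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(tr2$edge))) {
    par <- tr2$edge[e, 1]; ch <- tr2$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  keys <- character(0)
  root <- n + 1L
  anchor <- order(tr$tip.label)[1L]   # label-stable canonical side
  for (node in (n + 1L):(n + tr$Nnode)) {
    if (node == root) next
    side <- sort(desc[[node]])
    if (length(side) < 2L || length(side) > n - 2L) next  # trivial split
    if (anchor %in% side) side <- sort(setdiff(seq_len(n), side))
    keys <- c(keys, paste(sort(tr$tip.label[side]), collapse = "|"))
  }
  unique(keys)
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Builds the full-data K2P + NJ tree, then resamples alignment columns
#' with replacement `n_reps` times; the support of each internal
#' bipartition of the full-data tree is the number of replicates whose NJ
#' tree contains it. Replicate r uses the r-th block of the seeded RNG
#' stream, so results do not depend on evaluation order. Site patterns are
#' compressed once and replicates drawn as multinomial pattern weights,
#' which makes large cohorts of near-identical haplotypes cheap.
#'
#' @param seqs named character vector of aligned sequences.
#' @param n_reps number of bootstrap replicates (the conventional screen
#'   uses 1000).
#' @param seed RNG seed.
#' @param display_threshold supports above this count are flagged in the
#'   summary (default 750 of 1000, scaled to `n_reps`).
#' @return list with `tree` (full-data `phylo`), `supports` (data.frame
#'   bipartition, count, n_reps, displayed), `n_reps`.
#' @export
bootstrap_support <- function(seqs, n_reps = 1000L, seed = 1L,
                              display_threshold = NULL) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be >= 1")
  if (is.null(display_threshold)) display_threshold <- 0.75 * n_reps
  sp <- site_patterns(seqs)
  taxa <- names(seqs)
  pc <- pattern_pair_classes(sp$patterns)
  D <- dist_from_classes(pc, sp$weights, taxa)
  full <- nj_tree(D)
  keys <- tree_bipartitions(full)
  counts <- stats::setNames(rep(0L, length(keys)), keys)
  rng <- local_rng(seed)
  for (r in seq_len(n_reps)) {
    u <- rng(sp$n_sites)
    # resample original site indices (taxon-order independent), then count
    # how often each compressed pattern was drawn
    idx <- pmin(floor(u * sp$n_sites) + 1L, sp$n_sites)
    w <- tabulate(sp$pat_of_site[idx], nbins = length(sp$weights))
    Dr <- dist_from_classes(pc, w, taxa)
    tr <- suppressWarnings(nj_tree(Dr))
    hit <- tree_bipartitions(tr)
    seen <- keys %in% hit
    counts[seen] <- counts[seen] + 1L
  }
  supports <- data.frame(bipartition = keys, count = as.integer(counts),
                         n_reps = n_reps,
                         displayed = counts > display_threshold,
                         stringsAsFactors = FALSE)
  list(tree = full, supports = supports, n_reps = n_reps)
}

#' Collapse identical haplotypes
#'
#' Cohorts of this kind contain many byte-identical haplotypes; collapsing
#' them before tree building keeps one representative per haplotype and
#' returns the grouping.
#'
#' @param seqs named character vector of aligned sequences.
#' @return list with `sequences` (representatives) and `groups` (named list
#'   representative -> member samples).
#' @export
collapse_haplotypes <- function(seqs) {
  key <- as.character(seqs)
  reps <- !duplicated(key)
  groups <- split(names(seqs), match(key, key[reps]))
  names(groups) <- names(seqs)[reps]
  list(sequences = seqs[reps], groups = groups)
}

#' Write a tree with bootstrap supports as newick
#'
#' Internal nodes of the full-data tree are labelled with their bipartition
#' support counts before serialisation.
#'
#' @param bs result of [bootstrap_support()].
#' @param path output file.
#' @return the newick string, invisibly.
#' @export
write_support_tree <- function(bs, path) {
  tr <- bs$tree
  n <- length(tr$tip.label)
  lab <- rep("", tr$Nnode)
  desc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  tr2 <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(tr2$edge)))
    desc[[tr2$edge[e, 1]]] <- c(desc[[tr2$edge[e, 1]]], desc[[tr2$edge[e, 2]]])
  anchor <- order(tr$tip.label)[1L]
  for (node in (n + 1L):(n + tr$Nnode)) {
    side <- sort(desc[[node]])
    if (length(side) < 2L || length(side) > n - 2L) next
    if (anchor %in% side) side <- sort(setdiff(seq_len(n), side))
    key <- paste(sort(tr$tip.label[side]), collapse = "|")
    m <- match(key, bs$supports$bipartition)
    if (!is.na(m)) lab[node - n] <- as.character(bs$supports$count[m])
  }
  tr$node.label <- lab
  ape::write.tree(tr, file = path)
  invisible(ape::write.tree(tr))
}
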