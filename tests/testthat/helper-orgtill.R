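# shared generators and oracles

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random event table in normal form on a given reference: isolated SNPs and
# MNPs (never adjacent) plus optionally deletions at leftmost-stable
# placements; positions kept >= 2 apart via a guard base
random_normal_events <- function(ref, n_sub = 3L, n_mnp = 0L, n_del = 0L,
                                 sample_id = "s", gene = "g") {
  rchars <- strsplit(ref, "")[[1]]
  glen <- length(rchars)
  taken <- rep(FALSE, glen)
  mk <- list()
  place <- function(len, need_leftmost_stable = FALSE) {
    for (try in 1:500) {
      p <- sample(glen - len + 1L, 1L)
      guard <- max(1L, p - 1L):min(glen, p + len)
      if (any(taken[guard])) next
      if (need_leftmost_stable && p > 1L &&
          rchars[p - 1L] == rchars[p + len - 1L]) next
      taken[guard] <<- TRUE
      return(p)
    }
    stop("could not place event")
  }
  for (i in seq_len(n_sub)) {
    p <- place(1L)
    mk[[length(mk) + 1L]] <- list(p, "substitution", rchars[p],
      sample(setdiff(c("A", "C", "G", "T"), rchars[p]), 1L))
  }
  for (i in seq_len(n_mnp)) {
    p <- place(2L)
    alt <- vapply(p:(p + 1L), function(q)
      sample(setdiff(c("A", "C", "G", "T"), rchars[q]), 1L), character(1))
    mk[[length(mk) + 1L]] <- list(p, "substitution",
      paste(rchars[p:(p + 1L)], collapse = ""), paste(alt, collapse = ""))
  }
  for (i in seq_len(n_del)) {
    len <- sample(2:6, 1L)
    p <- place(len, need_leftmost_stable = TRUE)
    mk[[length(mk) + 1L]] <- list(p, "deletion",
      paste(rchars[p:(p + len - 1L)], collapse = ""), "")
  }
  if (!length(mk)) return(orgtill::polymorphism_events())
  df <- orgtill::polymorphism_events(
    sample = sample_id, gene = gene,
    position = vapply(mk, function(e) e[[1]], integer(1)),
    kind = vapply(mk, function(e) e[[2]], character(1)),
    ref = vapply(mk, function(e) e[[3]], character(1)),
    alt = vapply(mk, function(e) e[[4]], character(1)))
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# brute-force pairing oracle: enumerate every injective partial matching of
# 700-bands to 800-bands and report the best (max pairs, then min total
# deviation); feasible for <= ~8 bands
brute_force_pairing <- function(s7, s8, L, tol) {
  n7 <- length(s7); n8 <- length(s8)
  best <- list(card = -1L, dev = Inf)
  rec <- function(i, used, pairs, dev) {
    if (i > n7) {
      card <- nrow(pairs)
      if (card > best$card || (card == best$card && dev < best$dev))
        best <<- list(card = card, dev = dev, pairs = pairs)
      return(invisible(NULL))
    }
    for (j in seq_len(n8)) {
      if (!used[j] && abs(s7[i] + s8[j] - L) <= tol) {
        used[j] <- TRUE
        rec(i + 1L, used, rbind(pairs, c(i, j)),
            dev + abs(s7[i] + s8[j] - L))
        used[j] <- FALSE
      }
    }
    rec(i + 1L, used, pairs, dev)
  }
  rec(1L, rep(FALSE, n8), matrix(integer(), 0L, 2L), 0)
  best
}

withr_local_tempdir <- function() {
  d <- tempfile("orgtill-test-")
  dir.create(d)
  d
}

# amplicon covering a whole gene with direct labels
whole_gene_amplicon <- function(gene) {
  orgtill::amplicon_spec(gene, gene$length_bp, forward_start = 1L)
}
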