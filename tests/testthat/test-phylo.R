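seq_of <- function(...) paste(c(...), collapse = "")

test_that("k2p matches the closed form", {
  a100 <- strsplit(random_seq(100), "")[[1]]
  # identical sequences
  expect_equal(k2p(seq_of(a100), seq_of(a100)), 0)
  # 10 transitions + 5 transversions over 100 sites: P=0.1, Q=0.05
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  b <- a100
  b[1:10] <- ts_map[b[1:10]]
  b[11:15] <- tv_map[b[11:15]]
  expect_equal(k2p(seq_of(a100), seq_of(b)),
               -0.5 * log((1 - 0.25) * sqrt(1 - 0.1)), tolerance = 1e-12)
  expect_equal(round(k2p(seq_of(a100), seq_of(b)), 4), 0.1702)
  # transition-only limit: P=0.1, Q=0 -> -(1/2) ln 0.8
  c_ <- a100
  c_[1:10] <- ts_map[c_[1:10]]
  expect_equal(k2p(seq_of(a100), seq_of(c_)), -0.5 * log(0.8),
               tolerance = 1e-12)
  # gap/N sites excluded pairwise: 90 comparable sites, 1 transition
  d <- a100; d[21:30] <- "-"
  e <- a100; e[1] <- ts_map[e[1]]
  expect_equal(k2p(seq_of(d), seq_of(e)), -0.5 * log(1 - 2 / 90),
               tolerance = 1e-12)
  # saturation is an error, not NaN
  sat_a <- paste(rep("A", 10), collapse = "")
  sat_b <- paste(rep("G", 10), collapse = "")
  expect_error(k2p(sat_a, sat_b), "saturation")
  expect_error(k2p("ACGT", "ACG"), "equal length")
})

test_that("k2p is symmetric and zero iff identical over included sites", {
  set.seed(4)
  for (i in 1:25) {
    a <- random_seq(200)
    bc <- strsplit(a, "")[[1]]
    n_mut <- sample(0:6, 1)
    idx <- sample(200, n_mut)
    for (j in idx) bc[j] <- sample(setdiff(c("A", "C", "G", "T"), bc[j]), 1)
    b <- seq_of(bc)
    expect_equal(k2p(a, b), k2p(b, a))
    expect_equal(k2p(a, b) == 0, n_mut == 0L)
  }
})

test_that("nj_tree recovers additive matrices exactly", {
  # two taxa: one edge split evenly
  D2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  t2 <- nj_tree(D2)
  expect_equal(sort(t2$edge.length), c(.2, .2))
  # the classic 4-taxon additive matrix
  D4 <- matrix(c(0, 5, 9, 9,
                 5, 0, 10, 10,
                 9, 10, 0, 8,
                 9, 10, 8, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  t4 <- nj_tree(D4)
  expect_equal(ape::cophenetic.phylo(t4)[letters[1:4], letters[1:4]], D4,
               tolerance = 1e-9)
  # random additive matrices from random trees, path-length metric restored
  set.seed(12)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(tr)
    got <- nj_tree(D)
    expect_equal(ape::cophenetic.phylo(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
  # validation
  Dbad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("nj_tree clamps negative branch lengths with a warning", {
  D <- matrix(c(0, 1, 1, 10,
                1, 0, 1, 10,
                1, 1, 0, 1,
                10, 10, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr <- nj_tree(D), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("concat_alignment concatenates and records partitions", {
  one <- list(g1 = c(s1 = "ACGT", s2 = "ACGA"))
  got1 <- concat_alignment(one)
  expect_equal(got1$sequences, c(s1 = "ACGT", s2 = "ACGA"))
  three <- list(g1 = c(s1 = "AAAA", s2 = "AAAT"),
                g2 = c(s2 = "CC", s1 = "CC"),
                g3 = c(s1 = "GGG", s2 = "GGG"))
  got <- concat_alignment(three)
  expect_equal(unname(nchar(got$sequences)), c(9L, 9L))
  expect_equal(got$sequences[["s2"]], "AAATCCGGG")
  expect_equal(got$partitions$end, c(4L, 6L, 9L))
  bad <- list(g1 = c(s1 = "A"), g2 = c(s2 = "A"))
  expect_error(concat_alignment(bad), "missing samples")
})

test_that("reconstruct_haplotypes is reference-anchored and gap-aware", {
  g <- gene_spec("g", 20)
  ev <- polymorphism_events(c("s2", "s3"), "g", c(5L, 11L),
                            c("substitution", "deletion"),
                            c("A", "AAA"), c("G", ""))
  # note: backbone gets the declared ref alleles at event positions
  h <- reconstruct_haplotypes(ev, g, c("s1", "s2", "s3"))
  expect_equal(nchar(h[["s1"]]), 20L)
  expect_equal(substring(h[["s2"]], 5, 5), "G")
  expect_equal(substring(h[["s1"]], 5, 5), "A")
  expect_equal(substring(h[["s3"]], 11, 13), "---")
  expect_equal(substring(h[["s1"]], 11, 13), "AAA")
  # unaffected positions identical across samples
  expect_equal(substring(h[["s2"]], 14, 20), substring(h[["s3"]], 14, 20))
})

test_that("bootstrap supports a clean bipartition at full strength", {
  # two 10-sample groups differing at 50 fixed sites
  set.seed(3)
  base <- strsplit(random_seq(400), "")[[1]]
  alt <- base
  idx <- sample(400, 50)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  alt[idx] <- ts_map[alt[idx]]
  seqs <- c(stats::setNames(rep(paste(base, collapse = ""), 10),
                            sprintf("g1_%02d", 1:10)),
            stats::setNames(rep(paste(alt, collapse = ""), 10),
                            sprintf("g2_%02d", 1:10)))
  bs <- bootstrap_support(seqs, n_reps = 100, seed = 42)
  key <- paste(sort(sprintf("g2_%02d", 1:10)), collapse = "|")
  expect_equal(bs$supports$count[bs$supports$bipartition == key], 100L)
})

test_that("bootstrap is seed-deterministic and relabeling-invariant", {
  set.seed(6)
  base <- random_seq(300)
  seqs <- vapply(1:8, function(i) {
    bc <- strsplit(base, "")[[1]]
    idx <- sample(300, 6)
    for (j in idx) bc[j] <- sample(setdiff(c("A", "C", "G", "T"), bc[j]), 1)
    paste(bc, collapse = "")
  }, "")
  names(seqs) <- paste0("t", 1:8)
  a <- bootstrap_support(seqs, n_reps = 30, seed = 11)
  b <- bootstrap_support(seqs, n_reps = 30, seed = 11)
  expect_identical(a$supports, b$supports)
  # permuting the input order leaves the supports unchanged (same seed)
  perm <- sample(8)
  c_ <- bootstrap_support(seqs[perm], n_reps = 30, seed = 11)
  m <- match(a$supports$bipartition, c_$supports$bipartition)
  expect_false(any(is.na(m)))
  expect_equal(c_$supports$count[m], a$supports$count)
  expect_error(bootstrap_support(seqs, n_reps = 0), ">= 1")
})

test_that("collapse_haplotypes groups identical sequences", {
  seqs <- c(a = "AAAA", b = "AAAT", c = "AAAA", d = "AAAA")
  got <- collapse_haplotypes(seqs)
  expect_equal(length(got$sequences), 2L)
  expect_equal(sort(got$groups$a), c("a", "c", "d"))
  expect_equal(got$groups$b, "b")
})
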