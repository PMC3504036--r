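make_panel <- function(len = 900L) {
  set.seed(31)
  ref <- random_seq(len)
  g <- gene_spec("g", len, ref)
  list(g = g, ref = ref, amp = whole_gene_amplicon(g))
}

test_that("cleave emits one additive band pair per mismatch", {
  p <- make_panel()
  refs <- c(substring(p$ref, 100, 100), substring(p$ref, 200, 200))
  alts <- vapply(refs, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  E <- polymorphism_events(c("q", "q"), "g", c(100L, 200L),
                           "substitution", refs, alts)
  q <- apply_events(p$ref, E)
  lane <- cleave(p$ref, q, p$amp, sample = "q")
  L <- p$amp$product_length_L
  expect_equal(lane$bands_700, c(100L, 200L))
  expect_equal(lane$bands_800, sort(L - c(100L, 200L)))
  expect_true(lane$full_length_present)
  # additivity across all emitted pairs
  expect_equal(sort(lane$bands_700 + rev(sort(lane$bands_800))),
               rep(L, 2L))
  # homoduplex: no bands, full length still present
  empty <- cleave(p$ref, p$ref, p$amp)
  expect_equal(length(empty$bands_700), 0L)
  expect_equal(length(empty$bands_800), 0L)
  expect_true(empty$full_length_present)
})

test_that("cleave additivity is a loop invariant over random cases", {
  set.seed(77)
  for (i in 1:50) {
    len <- sample(300:900, 1)
    ref <- random_seq(len)
    g <- gene_spec("g", len, ref)
    amp <- whole_gene_amplicon(g)
    E <- random_normal_events(ref, n_sub = sample(1:6, 1),
                              n_mnp = sample(0:1, 1),
                              sample_id = "q")
    lane <- cleave(ref, apply_events(ref, E), amp, sample = "q")
    expect_equal(length(lane$bands_700), length(lane$bands_800))
    expect_true(all(sort(lane$bands_700) + rev(sort(lane$bands_800)) ==
                      amp$product_length_L))
  }
})

test_that("the ideal detection profile is the identity", {
  sites <- data.frame(sample = "q", position = c(5L, 40L, 41L, 42L, 700L),
                      position_g = c(5L, 40L, 41L, 42L, 700L),
                      kind = "substitution", ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  out <- apply_detection_model(sites, ideal_detection(), L = 827L)
  expect_equal(out, sites, ignore_attr = TRUE)
})

test_that("terminal windows suppress sites with the configured probability", {
  # probability 0: every site within 80 bp of either end is lost
  sites <- data.frame(sample = "q",
                      position = c(56L, 63L, 73L, 74L, 81L),
                      position_g = c(56L, 63L, 73L, 74L, 81L),
                      kind = "substitution", ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  m <- detection_model(terminal_window_W = 80L, terminal_detect_prob = 0,
                       cluster_max_detect = Inf)
  out <- apply_detection_model(sites, m, L = 827L)
  expect_equal(out$position, 81L)
  # the far end is symmetric: p >= L - W is terminal too
  sites2 <- sites
  sites2$position <- sites2$position_g <- c(100L, 700L, 750L, 800L, 820L)
  out2 <- apply_detection_model(sites2, m, L = 827L)
  expect_equal(out2$position, c(100L, 700L))
  # probability 1 keeps everything
  m1 <- detection_model(terminal_detect_prob = 1, cluster_max_detect = Inf)
  expect_equal(apply_detection_model(sites, m1, L = 827L)$position,
               sites$position)
})

test_that("dense clusters collapse to the outermost survivors", {
  # 14 sites inside a 27-bp window: only the two outermost remain
  pos <- as.integer(354 + round(seq(0, 26, length.out = 14)))
  pos <- unique(pos)[1:14]
  pos <- sort(as.integer(seq(354, 380, length.out = 14)))
  sites <- data.frame(sample = "q", position = pos, position_g = pos,
                      kind = "substitution", ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  m <- detection_model(terminal_window_W = 0L, terminal_detect_prob = 1,
                       cluster_window_w = 27L, cluster_max_detect = 2L)
  out <- apply_detection_model(sites, m, L = 827L)
  expect_equal(out$position, c(354L, 380L))
  # sparse sites are untouched
  sparse <- data.frame(sample = "q", position = c(100L, 200L, 300L),
                       position_g = c(100L, 200L, 300L),
                       kind = "substitution", ref = "A", alt = "G",
                       stringsAsFactors = FALSE)
  expect_equal(apply_detection_model(sparse, m, L = 827L)$position,
               sparse$position)
})

test_that("detection is deterministic under a fixed seed", {
  set.seed(1234)  # the model must not read the global stream
  sites <- data.frame(sample = "q", position = sort(sample(827L, 30L)),
                      kind = "substitution", ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  sites$position_g <- sites$position
  m <- detection_model(seed = 99L)
  a <- apply_detection_model(sites, m, L = 827L)
  b <- apply_detection_model(sites, m, L = 827L)
  expect_identical(a, b)
  # and does not disturb the global RNG state
  s1 <- .Random.seed
  invisible(apply_detection_model(sites, m, L = 827L))
  expect_identical(s1, .Random.seed)
})

test_that("predict_mixture implements the allele-difference rule", {
  g <- gene_spec("matK", 1575)
  amp <- amplicon_spec(g, 948, forward_start = 628L)  # covers 628..1575
  b76 <- polymorphism_events("B76", "matK", c(822L, 889L, 1132L),
                             "substitution", c("T", "T", "G"),
                             c("A", "G", "T"))
  b26 <- polymorphism_events()   # panel reference: no events
  b60 <- polymorphism_events("B60", "matK", c(822L, 889L, 934L, 1132L),
                             "substitution", c("T", "T", "G", "G"),
                             c("A", "G", "A", "T"))
  # reference-vs-mutated: all three positions reappear
  expect_equal(predict_mixture(b26, b76, amp)$position_g,
               c(822L, 889L, 1132L))
  # shared events vanish; only the private 934 remains
  expect_equal(predict_mixture(b60, b76, amp)$position_g, 934L)
  # symmetry
  expect_equal(predict_mixture(b76, b60, amp),
               predict_mixture(b60, b76, amp))
  # X == Q: silent lane
  expect_equal(nrow(predict_mixture(b76, b76, amp)), 0L)
  # same position, different alt alleles still mismatch (multi-allelic site)
  a65 <- polymorphism_events("A65", "matK", 700L, "substitution", "A", "C")
  a67 <- polymorphism_events("A67", "matK", 700L, "substitution", "A", "T")
  expect_equal(predict_mixture(a65, a67, amp)$position_g, 700L)
  # mixture against an event-free sample equals the sample's own positions
  expect_equal(predict_mixture(b60, polymorphism_events(), amp)$position_g,
               b60$position)
  # different genes refused
  other <- polymorphism_events("x", "rbcL", 66L, "substitution", "G", "A")
  expect_error(predict_mixture(b76, other, amp), "common gene")
})
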