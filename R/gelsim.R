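# Virtual CEL I digestion and LI-COR detection.
#
# CEL I nicks one strand of a heteroduplex 3' of each mismatch, with partial
# efficiency, so every mismatch yields an independent band pair (one
# IRD700-labelled forward fragment, one IRD800-labelled reverse fragment)
# alongside retained full-length product. For a mismatch at amplicon
# position p in a product of length L the labelled fragments are p and
# L - p: the additivity constraint size700 + size800 == L.

#' Detection model for mismatch-cleavage gels
#'
#' Parameters governing which mismatches become visible bands. Defaults are
#' the empirical profile of organelle EcoTILLING on a ~1 kb product: sites
#' in the first/last 80 bp are mostly lost in terminal noise (1/13 observed
#' recovery, ~0.08), and dense clusters (14 sites within 27 bp) collapse so
#' that at most two band positions survive.
#'
#' @param terminal_window_W width of the noisy terminal windows in bp.
#' @param terminal_detect_prob probability a terminal-window site is still
#'   detected.
#' @param cluster_window_w window in bp within which cluster suppression
#'   applies.
#' @param cluster_max_detect maximum sites surviving in any such window
#'   (`Inf` disables suppression).
#' @param size_resolution_r bands in the same channel closer than this merge
#'   (0 = 1-bp gel resolution).
#' @param seed RNG seed for the stochastic terminal rule.
#' @return an object of class `detection_model`.
#' @export
detection_model <- function(terminal_window_W = 80L,
                            terminal_detect_prob = 0.08,
                            cluster_window_w = 27L,
                            cluster_max_detect = 2L,
                            size_resolution_r = 0L,
                            seed = 1L) {
  stopifnot(terminal_window_W >= 0, cluster_window_w >= 0,
            terminal_detect_prob >= 0, terminal_detect_prob <= 1,
            size_resolution_r >= 0, cluster_max_detect >= 0)
  structure(list(terminal_window_W = as.integer(terminal_window_W),
                 terminal_detect_prob = terminal_detect_prob,
                 cluster_window_w = as.integer(cluster_window_w),
                 cluster_max_detect = cluster_max_detect,
                 size_resolution_r = as.integer(size_resolution_r),
                 seed = as.integer(seed)),
            class = "detection_model")
}

#' @rdname detection_model
#' @details `ideal_detection()` is the identity profile: every mismatch is
#'   seen, nothing merges. Under it the simulate -> call round trip is exact.
#' @export
ideal_detection <- function(seed = 1L) {
  detection_model(terminal_window_W = 0L, terminal_detect_prob = 1,
                  cluster_max_detect = Inf, size_resolution_r = 0L,
                  seed = seed)
}

#' Mismatch sites of a reference/query heteroduplex on an amplicon
#'
#' Enumerates polymorphisms between the two templated sequences and maps
#' each event to its amplicon coordinate (the leftmost affected base);
#' events outside the templated span are dropped.
#'
#' @param ref_seq,query_seq templated gene sequences.
#' @param amplicon an [amplicon_spec()].
#' @param sample sample label.
#' @return data.frame with columns sample, position (amplicon coordinate)
#'   and the underlying event columns.
#' @export
mismatch_sites <- function(ref_seq, query_seq, amplicon, sample = "query") {
  ev <- enumerate_polymorphisms(ref_seq, query_seq, amplicon$gene,
                                sample = sample)
  events_to_sites(ev, amplicon)
}

# map gene-coordinate events onto amplicon positions, dropping events whose
# leftmost base lies outside the templated span
events_to_sites <- function(events, amplicon) {
  if (!nrow(events)) {
    return(data.frame(sample = character(), position = integer(),
                      position_g = integer(), kind = character(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  lo <- amplicon$gene_span[1]; hi <- amplicon$gene_span[2]
  keep <- events$position >= lo & events$position <= hi
  events <- events[keep, , drop = FALSE]
  pos_p <- if (nrow(events)) gene_to_amplicon(events$position, amplicon)
           else integer()
  out <- data.frame(sample = events$sample, position = as.integer(pos_p),
                    position_g = events$position, kind = events$kind,
                    ref = events$ref, alt = events$alt,
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Virtual CEL I cleavage of a heteroduplex
#'
#' Ideal detection: each mismatch at amplicon position p emits one band of
#' size p in the IRD700 channel and one of size L - p in the IRD800 channel;
#' the uncleaved full-length product is always retained (partial digestion).
#'
#' @param ref_seq,query_seq templated gene sequences for the amplicon's gene.
#' @param amplicon an [amplicon_spec()].
#' @param sample sample label for the lane.
#' @param model optional [detection_model()]; defaults to ideal detection.
#' @return an object of class `gel_lane` with fields `sample`, `amplicon`,
#'   `bands_700`, `bands_800`, `full_length_present`, `sites`.
#' @export
cleave <- function(ref_seq, query_seq, amplicon, sample = "query",
                   model = NULL) {
  sites <- mismatch_sites(ref_seq, query_seq, amplicon, sample = sample)
  lane_from_sites(sites, amplicon, sample = sample, model = model)
}

#' @rdname cleave
#' @param sites a mismatch-site data.frame (amplicon coordinates).
#' @export
lane_from_sites <- function(sites, amplicon, sample = "query", model = NULL) {
  L <- amplicon$product_length_L
  if (!is.null(model)) sites <- apply_detection_model(sites, model, L)
  p <- sites$position
  b700 <- sort(as.integer(p))
  b800 <- sort(as.integer(L - p))
  if (!is.null(model) && model$size_resolution_r > 0L) {
    b700 <- merge_close_bands(b700, model$size_resolution_r)
    b800 <- merge_close_bands(b800, model$size_resolution_r)
  }
  structure(list(sample = sample, amplicon = amplicon,
                 bands_700 = b700, bands_800 = b800,
                 full_length_present = TRUE, sites = sites),
            class = "gel_lane")
}

#' @export
print.gel_lane <- function(x, ...) {
  cat("<gel_lane>", x$sample, "on", x$amplicon$name,
      sprintf("(L = %d)", x$amplicon$product_length_L), "\n")
  cat("  IRD700:", if (length(x$bands_700)) paste(x$bands_700, collapse = " ")
                   else "-", "\n")
  cat("  IRD800:", if (length(x$bands_800)) paste(x$bands_800, collapse = " ")
                   else "-", "\n")
  invisible(x)
}

# bands closer than r bp collapse; the smaller size wins
merge_close_bands <- function(sizes, r) {
  if (length(sizes) < 2L) return(sizes)
  sizes <- sort(sizes)
  keep <- c(TRUE, diff(sizes) >= r)
  # a run of mutually close bands keeps only its first (smallest) member
  out <- integer(0)
  last <- -Inf
  for (s in sizes) {
    if (s - last >= r) { out <- c(out, s); last <- s }
  }
  out
}

#' Apply a detection model to a set of mismatch sites
#'
#' Three rules, in order: (i) sites inside the terminal windows survive
#' independently with `terminal_detect_prob`; (ii) in any window of
#' `cluster_window_w` bp holding more than `cluster_max_detect` surviving
#' sites, only the outermost `cluster_max_detect` are kept (deterministic);
#' (iii) same-channel bands closer than `size_resolution_r` merge (handled
#' at band level by [lane_from_sites()]). With the ideal profile the output
#' equals the input; the same seed always gives the same subset.
#'
#' @param sites mismatch-site data.frame sorted by position.
#' @param model a [detection_model()].
#' @param L amplicon product length in bp.
#' @return the detected subset of `sites`.
#' @export
apply_detection_model <- function(sites, model, L) {
  stopifnot(inherits(model, "detection_model"))
  if (!nrow(sites)) return(sites)
  sites <- sites[order(sites$position), , drop = FALSE]
  p <- sites$position
  W <- model$terminal_window_W
  keep <- rep(TRUE, length(p))
  terminal <- p <= W | p >= L - W
  if (any(terminal) && model$terminal_detect_prob < 1) {
    rng <- local_rng(model$seed)
    u <- rng(sum(terminal))
    keep[terminal] <- u < model$terminal_detect_prob
  }
  sites <- sites[keep, , drop = FALSE]
  if (is.finite(model$cluster_max_detect) && nrow(sites)) {
    sites <- suppress_clusters(sites, model$cluster_window_w,
                               model$cluster_max_detect)
  }
  rownames(sites) <- NULL
  sites
}

# deterministic cluster suppression: repeatedly find the densest window of
# width w with more than k sites and drop interior sites, keeping the k
# outermost (split evenly, extra to the left end).
suppress_clusters <- function(sites, w, k) {
  repeat {
    p <- sites$position
    n <- length(p)
    if (n <= k) return(sites)
    # number of sites in the window starting at each site
    counts <- vapply(seq_len(n), function(i)
      sum(p >= p[i] & p <= p[i] + w), integer(1))
    imax <- which.max(counts)
    if (counts[imax] <= k) return(sites)
    in_win <- which(p >= p[imax] & p <= p[imax] + w)
    n_lo <- ceiling(k / 2); n_hi <- floor(k / 2)
    keep_idx <- c(utils::head(in_win, n_lo), utils::tail(in_win, n_hi))
    drop_idx <- setdiff(in_win, keep_idx)
    sites <- sites[-drop_idx, , drop = FALSE]
  }
}

# private uniform RNG stream; never touches .Random.seed
local_rng <- function(seed) {
  state <- NULL
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  function(n) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", state, envir = globalenv())
    u <- stats::runif(n)
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    u
  }
}

#' Predict the band positions of a reference-swap mixture
#'
#' When sample X is pooled with sample Q (Q acting as reference), a band
#' appears exactly where their effective alleles differ: a shared
#' polymorphism vanishes, and only allele differences between the two
#' samples form heteroduplex mismatches. The effective allele at a position
#' defaults to the panel-reference allele when a sample carries no event
#' there.
#'
#' @param events_X,events_Q event tables of the two samples, both expressed
#'   against the same panel reference and the same gene.
#' @param amplicon an [amplicon_spec()]; positions outside its templated
#'   span are dropped.
#' @return data.frame with columns position_g and position (amplicon
#'   coordinate), sorted by position.
#' @export
predict_mixture <- function(events_X, events_Q, amplicon) {
  gx <- unique(events_X$gene); gq <- unique(events_Q$gene)
  if (length(gx) > 1L || length(gq) > 1L ||
      (length(gx) == 1L && length(gq) == 1L && gx != gq))
    stop("event lists must reference a single common gene")
  key <- function(df) {
    if (!nrow(df)) return(character())
    paste(df$position, df$kind, df$ref, df$alt, sep = "\r")
  }
  kx <- key(events_X); kq <- key(events_Q)
  pos_x <- events_X$position; pos_q <- events_Q$position
  # a position mismatches iff the allele states at it are not identical
  diff_pos <- sort(unique(c(pos_x[!(kx %in% kq)], pos_q[!(kq %in% kx)])))
  lo <- amplicon$gene_span[1]; hi <- amplicon$gene_span[2]
  diff_pos <- diff_pos[diff_pos >= lo & diff_pos <= hi]
  data.frame(position_g = diff_pos,
             position = if (length(diff_pos))
               as.integer(gene_to_amplicon(diff_pos, amplicon))
             else integer(),
             stringsAsFactors = FALSE)
}
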