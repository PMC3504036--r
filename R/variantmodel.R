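# Domain types and haplotype <-> event conversion.
#
# Coordinate conventions used throughout the package:
#   * gene coordinates are 1-based, counted from the first base of the ATG;
#   * amplicon coordinates are 1-based from the 5' end of the IRD700-labelled
#     forward strand, and include any unlabelled adaptor bases (e.g. the
#     19-bp M13F tail) when the label scheme is two-step;
#   * all intervals are closed.

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Gene specification
#'
#' Describes one organelle gene screened by mismatch cleavage: its name, its
#' length in bp (from the ATG), and optionally its reference sequence.
#'
#' @param name gene identifier, e.g. `"accD"`.
#' @param length_bp gene length in bp counted from the first base of ATG.
#' @param reference_sequence optional nucleotide string of length
#'   `length_bp`; alphabet restricted to A, C, G, T, N.
#' @return an object of class `gene_spec`.
#' @examples
#' gene_spec("accD", 1470)
#' @export
gene_spec <- function(name, length_bp, reference_sequence = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  length_bp <- as.integer(length_bp)
  if (is.na(length_bp) || length_bp <= 0L)
    stop("length_bp must be a positive integer")
  if (!is.null(reference_sequence)) {
    reference_sequence <- toupper(reference_sequence)
    check_nucleotides(reference_sequence)
    if (nchar(reference_sequence) != length_bp)
      stop("reference_sequence length (", nchar(reference_sequence),
           ") != length_bp (", length_bp, ")")
  }
  structure(list(name = name, length_bp = length_bp,
                 reference_sequence = reference_sequence),
            class = "gene_spec")
}

#' @export
print.gene_spec <- function(x, ...) {
  cat("<gene_spec>", x$name, paste0(x$length_bp, " bp"),
      if (is.null(x$reference_sequence)) "(no sequence)" else "(with sequence)",
      "\n")
  invisible(x)
}

#' Amplicon specification
#'
#' Maps gene coordinates onto labelled-amplicon coordinates. The product
#' length includes adaptor bases for the M13 two-step labelling scheme
#' (19 bp M13F forward, 20 bp M13R reverse); direct-labelled primers carry
#' no adaptors.
#'
#' @param gene a [gene_spec()].
#' @param product_length_L amplicon length in bp, adaptors included.
#' @param forward_start gene coordinate of the first templated base of the
#'   forward primer.
#' @param strand `"sense"` or `"antisense"` (the labelled forward primer may
#'   sit on either gene strand).
#' @param adaptor_len_fwd,adaptor_len_rev unlabelled adaptor lengths in bp
#'   (19 and 20 for M13F/M13R, 0 for direct labels).
#' @param label_scheme `"direct"` or `"M13-two-step"`; informational.
#' @param name optional amplicon name.
#' @return an object of class `amplicon_spec`.
#' @examples
#' g <- gene_spec("accD", 1470)
#' amplicon_spec(g, 827, forward_start = 101, adaptor_len_fwd = 19,
#'               adaptor_len_rev = 20, label_scheme = "M13-two-step")
#' @export
amplicon_spec <- function(gene, product_length_L, forward_start,
                          strand = c("sense", "antisense"),
                          adaptor_len_fwd = 0L, adaptor_len_rev = 0L,
                          label_scheme = c("direct", "M13-two-step"),
                          name = NULL) {
  stopifnot(inherits(gene, "gene_spec"))
  strand <- match.arg(strand)
  label_scheme <- match.arg(label_scheme)
  L <- as.integer(product_length_L)
  fs <- as.integer(forward_start)
  af <- as.integer(adaptor_len_fwd)
  ar <- as.integer(adaptor_len_rev)
  if (any(c(af, ar) < 0L)) stop("adaptor lengths must be non-negative")
  if (L < af + ar) stop("product_length_L smaller than combined adaptors")
  span <- L - af - ar               # templated bases
  if (strand == "sense") {
    g_lo <- fs; g_hi <- fs + span - 1L
  } else {
    g_hi <- fs; g_lo <- fs - span + 1L
  }
  if (g_lo < 1L || g_hi > gene$length_bp)
    stop("amplicon [", g_lo, ", ", g_hi, "] not contained in gene ",
         gene$name, " [1, ", gene$length_bp, "]")
  structure(list(gene = gene, product_length_L = L, forward_start = fs,
                 strand = strand, adaptor_len_fwd = af, adaptor_len_rev = ar,
                 label_scheme = label_scheme,
                 gene_span = c(g_lo, g_hi),
                 name = if (is.null(name)) gene$name else name),
            class = "amplicon_spec")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat("<amplicon_spec>", x$name, paste0(x$product_length_L, " bp"),
      x$strand, sprintf("gene span [%d, %d]", x$gene_span[1], x$gene_span[2]),
      "\n")
  invisible(x)
}

check_nucleotides <- function(seq) {
  if (length(seq) != 1L || !is.character(seq) || !nzchar(seq))
    stop("sequence must be a single non-empty string")
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), VALID_BASES)
  if (length(bad))
    stop("non-nucleotide characters in sequence: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Construct a polymorphism event table
#'
#' One row per sample-level difference from the reference gene. The event
#' weight is `max(nchar(ref), nchar(alt))`: a SNP weighs 1, a 2-bp MNP 2,
#' a 6-bp deletion 6. Weights are what the screened-bp mutation-frequency
#' statistics count.
#'
#' @param sample,gene,position,kind,ref,alt vectors, recycled to a common
#'   length. `kind` is one of `"substitution"`, `"deletion"`, `"insertion"`.
#' @return a `data.frame` with columns sample, gene, position, kind, ref,
#'   alt, weight.
#' @export
polymorphism_events <- function(sample = character(), gene = character(),
                                position = integer(), kind = character(),
                                ref = character(), alt = character()) {
  df <- data.frame(sample = as.character(sample), gene = as.character(gene),
                   position = as.integer(position), kind = as.character(kind),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   stringsAsFactors = FALSE)
  validate_events(df)
  df$weight <- pmax(nchar(df$ref), nchar(df$alt))
  df
}

validate_events <- function(df) {
  if (!nrow(df)) return(invisible(df))
  ok_kind <- df$kind %in% c("substitution", "deletion", "insertion")
  if (!all(ok_kind)) stop("unknown event kind: ",
                          paste(unique(df$kind[!ok_kind]), collapse = ", "))
  sub <- df$kind == "substitution"
  if (any(sub & (nchar(df$ref) != nchar(df$alt) | nchar(df$ref) < 1L)))
    stop("substitution events need equal-length, non-empty ref and alt")
  # N marks an unknown allele (e.g. gel-only calls), so N>N is tolerated
  if (any(sub & df$ref == df$alt & !grepl("N", df$ref)))
    stop("substitution with identical ref and alt alleles")
  if (any(df$kind == "deletion" & nchar(df$alt) != 0L))
    stop("deletion events must have empty alt allele")
  if (any(df$kind == "insertion" & nchar(df$ref) != 0L))
    stop("insertion events must have empty ref allele")
  if (any(is.na(df$position) | df$position < 1L))
    stop("event positions must be positive integers")
  invisible(df)
}

empty_events <- function() {
  polymorphism_events()
}

# closed interval of reference bases an event occupies; insertions occupy the
# junction before `position` and get a zero-length footprint.
event_footprint <- function(df) {
  len <- nchar(df$ref)
  cbind(start = df$position,
        end = ifelse(len > 0L, df$position + len - 1L, df$position - 1L))
}

#' Apply polymorphism events to a reference sequence
#'
#' Splices a set of non-overlapping events into `ref_seq`, producing the
#' sample haplotype. The inverse of [enumerate_polymorphisms()]: for events
#' in normal form, `enumerate_polymorphisms(ref, apply_events(ref, E))`
#' returns `E`.
#'
#' @param ref_seq reference nucleotide string.
#' @param events event table as produced by [polymorphism_events()];
#'   insertion events insert `alt` *before* the base at `position`.
#' @return the haplotype nucleotide string.
#' @export
apply_events <- function(ref_seq, events) {
  ref_seq <- toupper(ref_seq)
  check_nucleotides(ref_seq)
  if (!nrow(events)) return(ref_seq)
  validate_events(events)
  events <- events[order(events$position), , drop = FALSE]
  fp <- event_footprint(events)
  n <- nchar(ref_seq)
  ins <- events$kind == "insertion"
  if (any(fp[, "end"] > n) || any(events$position > n + ifelse(ins, 1L, 0L)))
    stop("event position outside sequence of length ", n)
  if (nrow(events) > 1L) {
    prev_end <- fp[-nrow(fp), "end"]
    if (any(fp[-1L, "start"] <= prev_end))
      stop("overlapping events")
  }
  # verify ref alleles match the reference where stated
  has_ref <- nchar(events$ref) > 0L
  if (any(has_ref)) {
    seen <- substring(ref_seq, events$position[has_ref],
                      fp[has_ref, "end"])
    if (any(seen != events$ref[has_ref]))
      stop("event ref allele does not match reference sequence")
  }
  out <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(events))) {
    p <- events$position[i]
    if (p > cursor) out <- c(out, substring(ref_seq, cursor, p - 1L))
    out <- c(out, events$alt[i])
    cursor <- p + nchar(events$ref[i])
  }
  if (cursor <= n) out <- c(out, substring(ref_seq, cursor, n))
  paste(out, collapse = "")
}

#' Enumerate polymorphisms between a reference and a query haplotype
#'
#' Returns the minimal, leftmost-normalized event list whose application to
#' `ref_seq` reproduces `query_seq`. Adjacent substituted bases merge into a
#' single MNP event; a run of deleted or inserted bases forms one event.
#' Equal-length sequence pairs are compared by a direct per-position scan;
#' unequal lengths are aligned globally (unit mismatch cost, affine gaps:
#' open 2, extend 1) and indels are then shifted to their leftmost
#' placement in repeat context.
#'
#' @param ref_seq,query_seq nucleotide strings (A/C/G/T/N).
#' @param gene gene identifier or a [gene_spec()] used to label events.
#' @param sample sample identifier stored on the events.
#' @param max_indel maximum tolerated length difference (default 50 bp);
#'   larger divergence is refused.
#' @return an event table (see [polymorphism_events()]).
#' @examples
#' enumerate_polymorphisms("ACGTACGTAC", "ACGTTCGTAC", "g1")
#' @export
enumerate_polymorphisms <- function(ref_seq, query_seq, gene,
                                    sample = "query", max_indel = 50L) {
  ref_seq <- toupper(ref_seq); query_seq <- toupper(query_seq)
  check_nucleotides(ref_seq); check_nucleotides(query_seq)
  gname <- if (inherits(gene, "gene_spec")) gene$name else as.character(gene)
  if (abs(nchar(ref_seq) - nchar(query_seq)) > max_indel)
    stop("sequence length difference exceeds max_indel (", max_indel, ")")
  if (nchar(ref_seq) == nchar(query_seq)) {
    aln_r <- ref_seq; aln_q <- query_seq
  } else {
    aln <- align_global(ref_seq, query_seq)
    aln_r <- aln$ref; aln_q <- aln$query
  }
  events_from_alignment(aln_r, aln_q, gname, sample, ref_seq)
}

# global alignment via Biostrings; scores chosen so that total penalty is
# (#mismatches) + (2 + length) per gap run, ties left to the aligner and
# resolved afterwards by explicit left-normalization of indels.
align_global <- function(ref_seq, query_seq) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query_seq),
    subject = Biostrings::DNAString(ref_seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  list(ref = as.character(Biostrings::alignedSubject(pa)),
       query = as.character(Biostrings::alignedPattern(pa)))
}

events_from_alignment <- function(aln_r, aln_q, gname, sample, ref_seq) {
  r <- strsplit(aln_r, "")[[1]]
  q <- strsplit(aln_q, "")[[1]]
  stopifnot(length(r) == length(q))
  state <- ifelse(r == "-", "ins", ifelse(q == "-", "del",
           ifelse(r == q, "match", "sub")))
  # reference coordinate of each alignment column (position of the ref base,
  # or of the next ref base for insertion columns)
  ref_pos <- cumsum(r != "-")
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- list()
  for (k in seq_along(runs$values)) {
    s <- runs$values[k]
    if (s == "match") next
    i <- starts[k]; j <- ends[k]
    if (s == "sub") {
      ev[[length(ev) + 1L]] <- list(position = ref_pos[i],
        kind = "substitution",
        ref = paste(r[i:j], collapse = ""),
        alt = paste(q[i:j], collapse = ""))
    } else if (s == "del") {
      ev[[length(ev) + 1L]] <- list(position = ref_pos[i],
        kind = "deletion",
        ref = paste(r[i:j], collapse = ""), alt = "")
    } else { # insertion before the next reference base
      ev[[length(ev) + 1L]] <- list(position = ref_pos[i] + 1L,
        kind = "insertion", ref = "",
        alt = paste(q[i:j], collapse = ""))
    }
  }
  if (!length(ev)) return(empty_events())
  df <- do.call(rbind, lapply(ev, function(e)
    data.frame(sample = sample, gene = gname, position = e$position,
               kind = e$kind, ref = e$ref, alt = e$alt,
               stringsAsFactors = FALSE)))
  df <- left_normalize_indels(df, ref_seq)
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  df$weight <- pmax(nchar(df$ref), nchar(df$alt))
  validate_events(df)
  df
}

# shift indels left through repeat context until blocked; deterministic
# event identity is what makes synthetic round-trips exact.
left_normalize_indels <- function(df, ref_seq) {
  rchars <- strsplit(ref_seq, "")[[1]]
  occupied <- rep(FALSE, nchar(ref_seq))
  fp <- event_footprint(df)
  for (i in which(df$kind == "substitution"))
    occupied[fp[i, "start"]:fp[i, "end"]] <- TRUE
  idx <- which(df$kind %in% c("deletion", "insertion"))
  idx <- idx[order(df$position[idx])]
  for (i in idx) {
    p <- df$position[i]
    if (df$kind[i] == "deletion") {
      k <- nchar(df$ref[i])
      while (p > 1L && !occupied[p - 1L] && rchars[p - 1L] == rchars[p + k - 1L]) {
        p <- p - 1L
      }
      df$position[i] <- p
      df$ref[i] <- paste(rchars[p:(p + k - 1L)], collapse = "")
    } else {
      a <- strsplit(df$alt[i], "")[[1]]
      while (p > 1L && !occupied[p - 1L] && rchars[p - 1L] == a[length(a)]) {
        a <- c(a[length(a)], a[-length(a)])
        p <- p - 1L
      }
      df$position[i] <- p
      df$alt[i] <- paste(a, collapse = "")
    }
  }
  df
}

#' Map a gene coordinate to its labelled-amplicon coordinate
#'
#' On the sense strand `p = position_g - forward_start + 1 + adaptor_len_fwd`;
#' on the antisense strand distances are measured from the 3' templated end.
#' Both directions are bijections on the templated span.
#'
#' @param position_g gene coordinate(s), 1-based from ATG.
#' @param spec an [amplicon_spec()].
#' @return amplicon coordinate(s), 1-based from the 5' end of the
#'   IRD700-labelled forward strand.
#' @export
gene_to_amplicon <- function(position_g, spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  position_g <- as.integer(position_g)
  lo <- spec$gene_span[1]; hi <- spec$gene_span[2]
  if (any(position_g < lo | position_g > hi))
    stop("position outside amplicon templated span [", lo, ", ", hi, "]")
  if (spec$strand == "sense") {
    position_g - spec$forward_start + 1L + spec$adaptor_len_fwd
  } else {
    (spec$forward_start - position_g + 1L) + spec$adaptor_len_fwd
  }
}

#' @rdname gene_to_amplicon
#' @param position_p amplicon coordinate(s).
#' @export
amplicon_to_gene <- function(position_p, spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  position_p <- as.integer(position_p)
  span <- spec$product_length_L - spec$adaptor_len_fwd - spec$adaptor_len_rev
  rel <- position_p - spec$adaptor_len_fwd
  if (any(rel < 1L | rel > span))
    stop("amplicon position outside templated span")
  if (spec$strand == "sense") {
    spec$forward_start + rel - 1L
  } else {
    spec$forward_start - rel + 1L
  }
}

#' Total mutated base pairs in an event table
#'
#' The indel/MNP-weighted count: the sum of event weights over all
#' sample-events. Twelve samples each carrying a 6-bp deletion contribute 72.
#'
#' @param events an event table.
#' @return non-negative integer.
#' @export
mutant_base_count <- function(events) {
  if (!nrow(events)) return(0L)
  if (is.null(events$weight))
    events$weight <- pmax(nchar(events$ref), nchar(events$alt))
  as.integer(sum(events$weight))
}
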