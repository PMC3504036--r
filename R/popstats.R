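# Summary statistics of a mutation-scanning screen: detection rate (gel
# calls vs sequencing truth), screened base pairs, and mutation frequency.
# Two counting conventions coexist and both are exposed:
#   * base-weighted  — every mutated base pair counts (a 6-bp deletion in
#     12 samples contributes 72); this is the unit of the screened-bp /
#     mutation-frequency statistics;
#   * occurrence     — every per-sample polymorphic position counts once,
#     whatever its width; this is the unit of detection-rate bookkeeping.

#' Detection rate A1/A2
#'
#' A1 is the number of per-sample polymorphic positions detected on the gel,
#' A2 the number confirmed by sequencing. Detected positions that were never
#' confirmed (false positives) are excluded from A1 and reported separately.
#'
#' @param detected named list (by sample) of detected position vectors.
#' @param confirmed named list (by sample) of sequencing-confirmed position
#'   vectors; the sample universe is the union of both names.
#' @return object of class `detection_stats`: `A1`, `A2`, `rate`
#'   (fraction), `rate_percent` (rounded to whole percent),
#'   `false_positives`.
#' @examples
#' detection_rate(list(s1 = c(119, 260)), list(s1 = c(119, 260, 365)))
#' @export
detection_rate <- function(detected, confirmed) {
  samples <- union(names(detected), names(confirmed))
  if (is.null(samples) || !length(samples))
    stop("detected/confirmed must be named lists keyed by sample")
  A1 <- 0L; A2 <- 0L; fp <- 0L
  for (s in samples) {
    d <- unique(detected[[s]]); k <- unique(confirmed[[s]])
    A2 <- A2 + length(k)
    A1 <- A1 + sum(d %in% k)
    fp <- fp + sum(!(d %in% k))
  }
  if (A2 == 0L) stop("no sequencing-confirmed events: rate undefined")
  structure(list(A1 = A1, A2 = A2, rate = A1 / A2,
                 rate_percent = round(100 * A1 / A2),
                 false_positives = fp),
            class = "detection_stats")
}

#' @export
print.detection_stats <- function(x, ...) {
  cat(sprintf("<detection_stats> A1 = %d, A2 = %d, rate = %d%%", x$A1,
              x$A2, x$rate_percent))
  if (x$false_positives)
    cat(sprintf(" (+%d unconfirmed detections)", x$false_positives))
  cat("\n")
  invisible(x)
}

#' Total screened base pairs
#'
#' The number of samples times the gene length: 96 samples of a 1470-bp
#' gene screen 141,120 bp.
#'
#' @param n_samples positive sample count.
#' @param gene_length_bp positive gene length in bp.
#' @return integer (or double when the product exceeds integer range).
#' @export
screened_bp <- function(n_samples, gene_length_bp) {
  stopifnot(n_samples > 0, gene_length_bp > 0)
  n_samples * gene_length_bp
}

#' Mutation frequency in screened bp per mutated base
#'
#' Screened bp divided by the total mutated bases; 141,120 bp over 116
#' mutant bases is one mutation per 1.22 kb.
#'
#' @param screened_bp total base pairs screened.
#' @param mutant_bases total mutated base pairs (indel-weighted).
#' @return object of class `frequency_stats` with `bp_per_mutation` and the
#'   display value `kb_per_mutation` (kb, rounded to 2 decimals).
#' @export
mutation_frequency <- function(screened_bp, mutant_bases) {
  if (mutant_bases <= 0)
    stop("mutation frequency undefined with zero mutant bases")
  bp <- screened_bp / mutant_bases
  structure(list(screened_bp = screened_bp, mutant_bases = mutant_bases,
                 bp_per_mutation = bp,
                 kb_per_mutation = round(bp / 1000, 2)),
            class = "frequency_stats")
}

#' @export
print.frequency_stats <- function(x, ...) {
  cat(sprintf("<frequency_stats> 1 mutation per %.2f kb (%s bp / %d mutant bases)\n",
              x$kb_per_mutation, format(x$screened_bp, big.mark = ","),
              as.integer(x$mutant_bases)))
  invisible(x)
}

#' Tabulate an event table by position
#'
#' Per-position counts across samples plus the gene total, in either
#' counting convention.
#'
#' @param events an event table (see [polymorphism_events()]).
#' @param mode `"base"` for base-weighted counts (each event contributes its
#'   weight) or `"occurrence"` for per-sample position occurrences
#'   (weight 1).
#' @return list with `per_position` (data.frame gene, position, count,
#'   n_samples), `total` (sum of counts), `distinct_positions` (per gene),
#'   `samples_with_events` (per gene).
#' @export
tabulate_events <- function(events, mode = c("base", "occurrence")) {
  mode <- match.arg(mode)
  if (!nrow(events)) {
    return(list(per_position = data.frame(gene = character(),
                                          position = integer(),
                                          count = integer(),
                                          n_samples = integer()),
                total = 0L, distinct_positions = integer(0),
                samples_with_events = integer(0)))
  }
  if (is.null(events$weight))
    events$weight <- pmax(nchar(events$ref), nchar(events$alt))
  w <- if (mode == "base") events$weight else rep(1L, nrow(events))
  key <- interaction(events$gene, events$position, drop = TRUE)
  per <- data.frame(
    gene = tapply(events$gene, key, `[`, 1),
    position = as.integer(tapply(events$position, key, `[`, 1)),
    count = as.integer(tapply(w, key, sum)),
    n_samples = as.integer(tapply(events$sample, key,
                                  function(s) length(unique(s)))),
    stringsAsFactors = FALSE)
  per <- per[order(per$gene, per$position), , drop = FALSE]
  rownames(per) <- NULL
  list(per_position = per,
       total = sum(per$count),
       distinct_positions = tapply(per$position, per$gene, length),
       samples_with_events = tapply(events$sample, events$gene,
                                    function(s) length(unique(s))))
}

#' Per-gene screen report
#'
#' Assembles the per-gene statistics table: screened bp, mutant bases,
#' mutation frequency, and (when detected sets are supplied) the A1/A2
#' detection rate.
#'
#' @param events sequencing-confirmed event table.
#' @param genes list of [gene_spec()] (or a data.frame with name,
#'   length_bp).
#' @param n_samples number of samples screened per gene.
#' @param detected optional named list (by sample) of detected gene
#'   positions, or a list of such lists keyed by gene.
#' @return data.frame with one row per gene.
#' @export
screen_report <- function(events, genes, n_samples, detected = NULL) {
  if (is.data.frame(genes))
    genes <- lapply(seq_len(nrow(genes)), function(i)
      gene_spec(genes$name[i], genes$length_bp[i]))
  rows <- lapply(genes, function(g) {
    ev <- events[events$gene == g$name, , drop = FALSE]
    mb <- mutant_base_count(ev)
    sc <- screened_bp(n_samples, g$length_bp)
    tab <- tabulate_events(ev, mode = "base")
    out <- data.frame(gene = g$name, n_samples = n_samples,
                      gene_length_bp = g$length_bp, screened_bp = sc,
                      mutant_bases = mb,
                      n_positions = nrow(tab$per_position),
                      bp_per_mutation_kb =
                        if (mb > 0) mutation_frequency(sc, mb)$kb_per_mutation
                        else NA_real_,
                      A1 = NA_integer_, A2 = NA_integer_,
                      rate_percent = NA_integer_,
                      stringsAsFactors = FALSE)
    if (!is.null(detected)) {
      det <- if (g$name %in% names(detected)) detected[[g$name]] else detected
      confirmed <- split(ev$position, ev$sample)
      dr <- detection_rate(det, confirmed)
      out$A1 <- dr$A1; out$A2 <- dr$A2; out$rate_percent <- dr$rate_percent
    }
    out
  })
  do.call(rbind, rows)
}
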