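# Recovering mutation positions from dual-channel band sizes — the inverse
# of the virtual gel. The physics gives one constraint per cleavage site:
# size700 + size800 == L, with size700 equal to the mutation's amplicon
# position. Calling therefore reduces to pairing the two channels' band
# multisets under that additivity constraint.

#' Pair dual-channel gel bands by fragment additivity
#'
#' Finds the maximum-cardinality pairing of IRD700 with IRD800 band sizes in
#' which every pair sums to `L` within `tol`; among pairings of equal
#' cardinality the one minimising the total |sum - L| deviation is chosen,
#' ties broken by pairing the smallest 700-channel size first. Full-length
#' bands (size within `tol` of `L`) are recognised and excluded. Leftover
#' bands are reported, never dropped silently. The instances are tiny
#' (tens of bands), so the assignment is solved exactly by depth-first
#' search over candidate partners.
#'
#' @param sizes_700,sizes_800 integer band sizes (bp) of the two channels.
#' @param L amplicon product length in bp.
#' @param tol pairing tolerance in bp (default 1).
#' @return an object of class `call_result`: `called` (data.frame with
#'   position, size_700, size_800), `unpaired_700`, `unpaired_800`,
#'   `full_length_700`, `full_length_800`, `L`.
#' @examples
#' pair_bands(c(345, 346), c(481, 482), L = 827)
#' @export
pair_bands <- function(sizes_700, sizes_800, L, tol = 1L) {
  L <- as.integer(L); tol <- as.integer(tol)
  stopifnot(L > 0L, tol >= 0L)
  s7 <- as.integer(sizes_700); s8 <- as.integer(sizes_800)
  if (any(is.na(s7)) || any(is.na(s8)))
    stop("band sizes must be numeric")
  if (any(c(s7, s8) < 0L) || any(c(s7, s8) > L))
    stop("band sizes must lie in [0, L]")
  fl7 <- s7[abs(s7 - L) <= tol]; s7 <- s7[abs(s7 - L) > tol]
  fl8 <- s8[abs(s8 - L) <= tol]; s8 <- s8[abs(s8 - L) > tol]
  s7 <- sort(s7); s8 <- sort(s8)
  best <- assign_bands(s7, s8, L, tol)
  called <- data.frame(position = s7[best$pairs[, 1]],
                       size_700 = s7[best$pairs[, 1]],
                       size_800 = s8[best$pairs[, 2]],
                       stringsAsFactors = FALSE)
  called <- called[order(called$position), , drop = FALSE]
  rownames(called) <- NULL
  structure(list(called = called,
                 unpaired_700 = s7[setdiff(seq_along(s7), best$pairs[, 1])],
                 unpaired_800 = s8[setdiff(seq_along(s8), best$pairs[, 2])],
                 full_length_700 = fl7, full_length_800 = fl8,
                 L = L, tol = tol),
            class = "call_result")
}

#' @export
print.call_result <- function(x, ...) {
  cat("<call_result> L =", x$L, "\n")
  if (nrow(x$called)) {
    cat(sprintf("  %d called position(s): %s\n", nrow(x$called),
                paste(x$called$position, collapse = " ")))
  } else cat("  no called positions\n")
  if (length(x$unpaired_700))
    cat("  unpaired IRD700:", paste(x$unpaired_700, collapse = " "), "\n")
  if (length(x$unpaired_800))
    cat("  unpaired IRD800:", paste(x$unpaired_800, collapse = " "), "\n")
  invisible(x)
}

# exact assignment by DFS with pruning: maximise pairs, then minimise total
# deviation; 700 bands are considered in ascending order so ties fall to
# the smallest-700-first pairing.
assign_bands <- function(s7, s8, L, tol) {
  n7 <- length(s7); n8 <- length(s8)
  cand <- lapply(seq_len(n7), function(i) {
    j <- which(abs(s7[i] + s8 - L) <= tol)
    j[order(abs(s7[i] + s8[j] - L), s8[j])]
  })
  best_pairs <- matrix(integer(), 0L, 2L)
  best_card <- -1L; best_dev <- Inf
  used <- rep(FALSE, n8)
  pairs <- matrix(NA_integer_, n7, 2L)
  npairs <- 0L
  dfs <- function(i, dev) {
    if (i > n7) {
      if (npairs > best_card ||
          (npairs == best_card && dev < best_dev)) {
        best_card <<- npairs; best_dev <<- dev
        best_pairs <<- pairs[seq_len(npairs), , drop = FALSE]
      }
      return(invisible(NULL))
    }
    # bound: even pairing every remaining band cannot beat the incumbent
    if (npairs + (n7 - i + 1L) < best_card) return(invisible(NULL))
    for (j in cand[[i]]) {
      if (!used[j]) {
        used[j] <<- TRUE
        npairs <<- npairs + 1L
        pairs[npairs, ] <<- c(i, j)
        dfs(i + 1L, dev + abs(s7[i] + s8[j] - L))
        npairs <<- npairs - 1L
        used[j] <<- FALSE
      }
    }
    dfs(i + 1L, dev)   # leave band i unpaired
    invisible(NULL)
  }
  dfs(1L, 0)
  list(pairs = best_pairs, deviation = best_dev)
}

#' Call positions from a simulated or observed gel lane
#'
#' Convenience wrapper running [pair_bands()] on a `gel_lane`.
#'
#' @param lane a `gel_lane` from [cleave()].
#' @param tol pairing tolerance in bp.
#' @return a `call_result`.
#' @export
call_lane <- function(lane, tol = 1L) {
  stopifnot(inherits(lane, "gel_lane"))
  pair_bands(lane$bands_700, lane$bands_800,
             L = lane$amplicon$product_length_L, tol = tol)
}

#' Convert a presence matrix into per-sample position sets
#'
#' Presence matrices follow the printed band-table layout: one row per
#' sample, one column per band position, a mark where an intense band was
#' seen.
#'
#' @param presence logical (or 0/1, or "+"-coded) matrix/data.frame, rows
#'   named by sample.
#' @param position_labels strictly increasing numeric band positions, one
#'   per column; defaults to the column names.
#' @return named list of integer position vectors, one per sample.
#' @export
matrix_to_positions <- function(presence, position_labels = NULL) {
  if (is.data.frame(presence)) presence <- as.matrix(presence)
  if (is.character(presence)) {
    presence <- matrix(trimws(presence) %in% c("+", "1", "TRUE"),
                       nrow = nrow(presence), ncol = ncol(presence),
                       dimnames = dimnames(presence))
  }
  if (is.null(position_labels))
    position_labels <- suppressWarnings(as.numeric(colnames(presence)))
  position_labels <- as.numeric(position_labels)
  if (length(position_labels) != ncol(presence))
    stop("need one position label per column")
  if (any(is.na(position_labels)) || is.unsorted(position_labels,
                                                 strictly = TRUE))
    stop("position labels must be strictly increasing numbers")
  mode(presence) <- "logical"
  samples <- rownames(presence)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(presence)))
  out <- lapply(seq_len(nrow(presence)), function(i)
    as.integer(position_labels[presence[i, ]]))
  names(out) <- samples
  out
}
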