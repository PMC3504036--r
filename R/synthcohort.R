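# Seeded synthetic cohorts with the statistical structure of an organelle
# mutation-scanning screen: a handful of reference genes, many samples, a
# few shared haplotypes, per-gene mutation densities in the observed
# ~1 event / 1.2 kb to ~1 event / 7.3 kb range, multi-allelic recurrent
# positions, 2-bp MNPs, short deletions, and optional dense clusters.

#' Cohort configuration
#'
#' Defaults describe the screen the generator emulates: 96 samples over
#' chloroplast-sized genes, a substitution density near one event per
#' 1.2 kb per haplotype (the densest gene observed), a small admixture of
#' 2-bp MNPs and 2-6 bp deletions, and occasional recurrence of an already
#' mutated position with a different alternate allele.
#'
#' @param genes data.frame with columns `name`, `length_bp`.
#' @param n_samples number of samples.
#' @param haplotype_clusters optional data.frame with columns `size`
#'   (samples per cluster) and `n_events` (events per cluster haplotype);
#'   remaining samples draw events independently at `site_rate`. Cluster
#'   members share their event set exactly.
#' @param site_rate per-bp per-haplotype substitution probability for
#'   unclustered samples.
#' @param mnp_prob,deletion_prob probability that an event is a 2-bp MNP or
#'   a deletion (remainder: SNP).
#' @param deletion_length_range inclusive bp range of deletion lengths.
#' @param recurrent_position_prob probability that a new substitution
#'   reuses an existing polymorphic position with a new alternate allele.
#' @param cluster_burst optional `c(n_events, window_bp)`: plant one dense
#'   cluster of that many substitutions within that window on the first
#'   gene, carried by the first unclustered sample.
#' @param seed RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(genes = data.frame(name = c("cpA", "cpB", "cpC"),
                                             length_bp = c(1470L, 1575L, 1440L)),
                          n_samples = 96L,
                          haplotype_clusters = NULL,
                          site_rate = 1 / 1220,
                          mnp_prob = 0.05, deletion_prob = 0.05,
                          deletion_length_range = c(2L, 6L),
                          recurrent_position_prob = 0.1,
                          cluster_burst = NULL,
                          seed = 1L) {
  stopifnot(is.data.frame(genes), all(c("name", "length_bp") %in% names(genes)),
            n_samples >= 1L, site_rate >= 0, mnp_prob >= 0, deletion_prob >= 0,
            mnp_prob + deletion_prob <= 1,
            length(deletion_length_range) == 2L,
            deletion_length_range[1] >= 1L,
            deletion_length_range[1] <= deletion_length_range[2],
            recurrent_position_prob >= 0, recurrent_position_prob <= 1)
  if (!is.null(cluster_burst))
    stopifnot(length(cluster_burst) == 2L, all(cluster_burst >= 1))
  if (!is.null(haplotype_clusters))
    stopifnot(is.data.frame(haplotype_clusters),
              all(c("size", "n_events") %in% names(haplotype_clusters)),
              sum(haplotype_clusters$size) <= n_samples)
  structure(list(genes = genes, n_samples = as.integer(n_samples),
                 haplotype_clusters = haplotype_clusters,
                 site_rate = site_rate, mnp_prob = mnp_prob,
                 deletion_prob = deletion_prob,
                 deletion_length_range = as.integer(deletion_length_range),
                 recurrent_position_prob = recurrent_position_prob,
                 cluster_burst = cluster_burst,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Reference sequences are uniform over A/C/G/T. Haplotypes are built by
#' sampling events and applying them with [apply_events()]; events within a
#' haplotype never overlap (rejection sampling with capped retries), and
#' deletions are only accepted where their leftmost-normalized placement is
#' the sampled one, so the truth table equals
#' [enumerate_polymorphisms()]'s output for every sample by construction.
#' A fixed seed gives byte-identical output.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort`: `references` (named sequences),
#'   `haplotypes` (list gene -> named sample sequences), `truth` (event
#'   table), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  genes <- config$genes
  refs <- stats::setNames(vapply(genes$length_bp, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1)), genes$name)

  samples <- sprintf("S%03d", seq_len(config$n_samples))
  cl <- config$haplotype_clusters
  cluster_of <- rep(0L, config$n_samples)      # 0 = unclustered
  if (!is.null(cl)) {
    k <- 0L
    for (c_i in seq_len(nrow(cl))) {
      cluster_of[(k + 1L):(k + cl$size[c_i])] <- c_i
      k <- k + cl$size[c_i]
    }
  }
  truth <- list()
  haplotypes <- stats::setNames(vector("list", nrow(genes)), genes$name)
  for (gi in seq_len(nrow(genes))) {
    gname <- genes$name[gi]; glen <- genes$length_bp[gi]
    ref <- refs[[gname]]
    known_alts <- list()   # position -> alt alleles already used (recurrence)
    cluster_events <- list()
    if (!is.null(cl)) {
      for (c_i in seq_len(nrow(cl))) {
        # split each cluster's event budget evenly over genes
        n_ev <- distribute_count(cl$n_events[c_i], nrow(genes))[gi]
        cluster_events[[c_i]] <- draw_canonical_events(ref, n_ev, config,
                                                       known_alts)
        known_alts <- attr(cluster_events[[c_i]], "known_alts")
      }
    }
    gene_haps <- stats::setNames(character(config$n_samples), samples)
    first_solo <- match(0L, cluster_of)
    for (si in seq_len(config$n_samples)) {
      s <- samples[si]
      if (cluster_of[si] > 0L) {
        ev <- cluster_events[[cluster_of[si]]]
      } else {
        n_ev <- stats::rbinom(1L, glen, config$site_rate)
        ev <- draw_canonical_events(ref, n_ev, config, known_alts)
        known_alts <- attr(ev, "known_alts")
        if (gi == 1L && !is.na(first_solo) && si == first_solo &&
            !is.null(config$cluster_burst)) {
          for (attempt in 1:25) {
            ev2 <- add_cluster_burst(ref, ev, config$cluster_burst)
            if (events_canonical(ref, ev2)) { ev <- ev2; break }
            if (attempt == 25L)
              stop("could not plant a canonical cluster burst")
          }
        }
      }
      attr(ev, "known_alts") <- NULL
      if (nrow(ev)) { ev$sample <- s; ev$gene <- gname }
      gene_haps[[s]] <- apply_events(ref, ev)
      if (nrow(ev)) truth[[length(truth) + 1L]] <- ev
    }
    haplotypes[[gname]] <- gene_haps
  }
  truth <- if (length(truth)) {
    tt <- do.call(rbind, truth)
    tt <- tt[order(tt$gene, tt$sample, tt$position), , drop = FALSE]
    rownames(tt) <- NULL
    tt
  } else empty_events()
  structure(list(references = refs, haplotypes = haplotypes, truth = truth,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", length(x$references), "gene(s),",
      x$config$n_samples, "samples,", nrow(x$truth), "truth events\n")
  invisible(x)
}

# TRUE when the event set is its own enumeration against ref: guards the
# round-trip guarantee against rare equal-cost alternative alignments
# (a deletion whose content matches nearby context can trade places with a
# neighbouring substitution at identical edit cost)
events_canonical <- function(ref, ev) {
  if (!nrow(ev) || !any(ev$kind != "substitution")) return(TRUE)
  got <- enumerate_polymorphisms(ref, apply_events(ref, ev), "x",
                                 sample = "x")
  cols <- c("position", "kind", "ref", "alt")
  identical(unname(as.list(got[, cols])), unname(as.list(ev[, cols])))
}

# draw events until they are canonical under re-enumeration
draw_canonical_events <- function(ref, n_events, config, known_alts) {
  for (attempt in 1:25) {
    ev <- draw_events(ref, n_events, config, known_alts)
    if (events_canonical(ref, ev)) return(ev)
  }
  stop("could not draw a canonical event set after 25 attempts")
}

# split n as evenly as possible into k parts (first parts get the excess)
distribute_count <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

# draw n non-overlapping events on ref in normal form; returns events with
# a "known_alts" attribute carrying recurrent-position bookkeeping
draw_events <- function(ref, n_events, config, known_alts) {
  rchars <- strsplit(ref, "")[[1]]
  glen <- length(rchars)
  taken <- rep(FALSE, glen)          # footprint + 1bp guard on each side
  ev <- list()
  tries <- 0L; max_tries <- 200L * max(1L, n_events)
  while (length(ev) < n_events) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("cannot place ", n_events, " non-overlapping events on a ",
           glen, "-bp gene (collision overflow)")
    u <- stats::runif(1)
    kind <- if (u < config$deletion_prob) "deletion"
            else if (u < config$deletion_prob + config$mnp_prob) "mnp"
            else "snp"
    if (kind == "snp" && length(known_alts) &&
        stats::runif(1) < config$recurrent_position_prob) {
      # reuse an existing polymorphic position with a fresh alt allele
      pos <- as.integer(sample(names(known_alts), 1L))
      used <- known_alts[[as.character(pos)]]
      avail <- setdiff(setdiff(c("A", "C", "G", "T"), rchars[pos]), used)
      if (!length(avail) || taken[pos]) next
      alt <- sample(avail, 1L)
      ev[[length(ev) + 1L]] <- list(position = pos, kind = "substitution",
                                    ref = rchars[pos], alt = alt)
      known_alts[[as.character(pos)]] <- c(used, alt)
      taken[max(1L, pos - 1L):min(glen, pos + 1L)] <- TRUE
      next
    }
    len <- switch(kind,
      snp = 1L, mnp = 2L,
      deletion = sample(seq(config$deletion_length_range[1],
                            config$deletion_length_range[2]), 1L))
    pos <- sample(glen - len + 1L, 1L)
    span <- pos:(pos + len - 1L)
    guard <- max(1L, pos - 1L):min(glen, pos + len)
    if (any(taken[guard])) next
    if (kind == "deletion") {
      # accept only leftmost-normalized placements so truth == enumeration
      if (pos > 1L && rchars[pos - 1L] == rchars[pos + len - 1L]) next
      ev[[length(ev) + 1L]] <- list(position = pos, kind = "deletion",
        ref = paste(rchars[span], collapse = ""), alt = "")
    } else {
      alt <- vapply(span, function(p)
        sample(setdiff(c("A", "C", "G", "T"), rchars[p]), 1L), character(1))
      ev[[length(ev) + 1L]] <- list(position = pos, kind = "substitution",
        ref = paste(rchars[span], collapse = ""),
        alt = paste(alt, collapse = ""))
      if (len == 1L)
        known_alts[[as.character(pos)]] <-
          c(known_alts[[as.character(pos)]], alt)
    }
    taken[guard] <- TRUE
  }
  df <- if (length(ev)) {
    do.call(rbind, lapply(ev, function(e)
      data.frame(sample = "pending", gene = "pending",
                 position = e$position, kind = e$kind, ref = e$ref,
                 alt = e$alt, stringsAsFactors = FALSE)))
  } else {
    data.frame(sample = character(), gene = character(),
               position = integer(), kind = character(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  }
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  df$weight <- pmax(nchar(df$ref), nchar(df$alt))
  attr(df, "known_alts") <- known_alts
  df
}

# plant a dense run of substitutions within a window, clear of other events
add_cluster_burst <- function(ref, ev, burst) {
  n_b <- as.integer(burst[1]); w <- as.integer(burst[2])
  rchars <- strsplit(ref, "")[[1]]
  glen <- length(rchars)
  if (n_b > w) stop("cluster burst wants ", n_b, " sites in ", w, " bp")
  taken <- rep(FALSE, glen)
  if (nrow(ev)) {
    fp <- event_footprint(ev)
    for (i in seq_len(nrow(ev)))
      taken[max(1L, fp[i, 1] - 1L):min(glen, fp[i, 2] + 1L)] <- TRUE
  }
  if (w < 2L * n_b - 1L)
    stop("cluster burst of ", n_b, " isolated sites cannot fit in ", w,
         " bp (adjacent substitutions would merge into MNPs)")
  for (start in sample(glen - w + 1L)) {
    win <- start:(start + w - 1L)
    if (any(taken[win])) next
    # min-gap-2 combination via the stars-and-bars shift, so dense bursts
    # (e.g. 14 sites in 27 bp) are placed without adjacent pairs
    y <- sort(sample(w - n_b + 1L, n_b))
    pos <- start - 1L + y + (seq_len(n_b) - 1L)
    new <- do.call(rbind, lapply(pos, function(p)
      data.frame(sample = "pending", gene = "pending", position = p,
                 kind = "substitution", ref = rchars[p],
                 alt = sample(setdiff(c("A", "C", "G", "T"), rchars[p]), 1L),
                 weight = 1L, stringsAsFactors = FALSE)))
    out <- rbind(ev, new)
    out <- out[order(out$position), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  stop("no free window for the requested cluster burst")
}

#' Write a cohort to disk
#'
#' Emits reference FASTA, one sample FASTA per gene, the truth event TSV,
#' and a JSON sidecar recording config and seed.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(reference = file.path(dir, "reference.fasta"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  write_fasta(cohort$references, paths[["reference"]])
  write_event_table(cohort$truth, paths[["truth"]])
  for (g in names(cohort$haplotypes)) {
    p <- file.path(dir, paste0("samples_", g, ".fasta"))
    write_fasta(cohort$haplotypes[[g]], p)
    paths[[paste0("samples_", g)]] <- p
  }
  cfg <- cohort$config
  cfg_json <- list(genes = cfg$genes, n_samples = cfg$n_samples,
                   haplotype_clusters = cfg$haplotype_clusters,
                   site_rate = cfg$site_rate, mnp_prob = cfg$mnp_prob,
                   deletion_prob = cfg$deletion_prob,
                   deletion_length_range = cfg$deletion_length_range,
                   recurrent_position_prob = cfg$recurrent_position_prob,
                   cluster_burst = cfg$cluster_burst, seed = cfg$seed)
  jsonlite::write_json(cfg_json, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# ---- packaged fixtures ----------------------------------------------------

#' Packaged screen fixtures
#'
#' Small plain-text tables shipped with the package, transcribing the band
#' and polymorphism matrices of a published organelle screen of Brassica
#' and related crucifers; used by the statistics and acceptance tests.
#'
#' \describe{
#'   \item{`band_table`}{dual-channel band sizes of four highly mutated
#'     samples on an 827-bp chloroplast amplicon (40 band pairs).}
#'   \item{`presence_matrix`}{band presence of 18 samples at 17 positions
#'     of a 733-bp mitochondrial amplicon.}
#'   \item{`panel_positions` / `panel_presence`}{the 96-sample Brassica
#'     panel: 16 polymorphic positions (with alleles) across three
#'     chloroplast genes, and which samples carry them.}
#'   \item{`family_alleles`}{per-sample alleles and gel outcomes at 54
#'     chloroplast and 13 mitochondrial positions across distant genera.}
#' }
#'
#' @param name one of `"band_table"`, `"presence_matrix"`,
#'   `"panel_positions"`, `"panel_presence"`, `"family_alleles"`.
#' @return a data.frame.
#' @export
org_fixture <- function(name = c("band_table", "presence_matrix",
                                 "panel_positions", "panel_presence",
                                 "family_alleles")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "orgtill",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Event table of the 96-sample Brassica panel fixture
#'
#' Joins the fixture position metadata with the presence matrix into a tidy
#' event table (one row per sample-event), ready for [tabulate_events()],
#' [mutant_base_count()] or [reconstruct_haplotypes()].
#'
#' @return an event table.
#' @export
panel_events <- function() {
  pos <- org_fixture("panel_positions")
  pres <- org_fixture("panel_presence")
  rows <- list()
  for (i in seq_len(nrow(pos))) {
    col <- pos$column_id[i]
    carriers <- pres$sample[pres[[col]] == 1]
    if (!length(carriers)) next
    rows[[i]] <- data.frame(sample = carriers, gene = pos$gene[i],
                            position = pos$position[i], kind = pos$kind[i],
                            ref = pos$ref[i], alt = pos$alt[i],
                            stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  ev$weight <- pmax(nchar(ev$ref), nchar(ev$alt))
  rownames(ev) <- NULL
  ev
}
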