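# Seeded synthetic-data generators: motifs, sequences with planted
# sites, hinge-structured activities, and barcode count tables.  The
# default scenario is the reference condition under which the whole
# pipeline is expected to recover the planted structure.

#' Synthetic MPRA scenario specification
#'
#' Bundles every knob of the generators into one seeded, reproducible
#' specification.  The defaults define the package's reference scenario:
#' 5000 constructs of 200 bp, 12 motifs of width 10, two activity
#' clusters separated by the enrichment of the first motif, per-cluster
#' hinge effects, Gaussian noise of SD 0.3, and a barcode count model of
#' 10 barcodes x 3 replicates at depth 200 with 5% irregular constructs.
#'
#' @param n_motifs,motif_length,dominance random PWM set: number of
#'   motifs, motif width, and the frequency of the dominant base per
#'   position (1.0 gives deterministic consensus matrices).
#' @param n_sequences,sequence_length constructs to simulate.
#' @param planting_rates expected planted copies per sequence for each
#'   motif (Poisson; recycled to `n_motifs`).
#' @param cluster_motif,cluster_threshold index of the cluster-defining
#'   motif and the enrichment threshold separating the two clusters.
#'   `NULL` (default) places the boundary at the median enrichment of
#'   the cluster motif, so the planted clusters are balanced whatever
#'   the background hit level of the seed's motif set.
#' @param cluster_offsets baseline activity of cluster 1 (below the
#'   threshold) and cluster 2.
#' @param hinge_terms list of planted response terms, each
#'   `list(cluster =, motif =, knot =, dir = +/-1, coef =)` acting on the
#'   enrichment score of `motif` within `cluster`.
#' @param conditions named numeric vector of condition offsets (one
#'   entry, the default, means a single unnamed condition).
#' @param noise_sd Gaussian activity noise.
#' @param n_barcodes,n_replicates,depth count model: barcodes per
#'   construct, replicates, and mean DNA depth per barcode.
#' @param irregular_fraction,irregular_sd fraction of constructs given
#'   inflated between-replicate variability, and the SD of the
#'   per-replicate activity offsets that inflate it.
#' @param target_fnr false negative rate for the motif cutoffs
#'   (see [calibrate_minfn_cutoff()]).
#' @param seed master seed; all generators derive their streams from it.
#' @return A list of class `mpra_scenario`.
#' @export
mpra_scenario <- function(n_motifs = 12, motif_length = 10, dominance = 0.9,
                          n_sequences = 5000, sequence_length = 200,
                          planting_rates = c(1.5, 1.2, 1.2, 1.2, 1.2,
                                             rep(0.5, 7)),
                          cluster_motif = 1, cluster_threshold = NULL,
                          cluster_offsets = c(0, 3),
                          hinge_terms = list(
                            list(cluster = 1, motif = 2, knot = 1, dir = 1,  coef = 1.5),
                            list(cluster = 1, motif = 3, knot = 2, dir = -1, coef = -1.2),
                            list(cluster = 2, motif = 4, knot = 1, dir = 1,  coef = 2.0),
                            list(cluster = 2, motif = 5, knot = 1, dir = 1,  coef = 1.2)),
                          conditions = c(none = 0),
                          noise_sd = 0.3,
                          n_barcodes = 10, n_replicates = 3, depth = 200,
                          irregular_fraction = 0.05, irregular_sd = 1.5,
                          target_fnr = 0.05, seed = 1) {
  planting_rates <- rep_len(planting_rates, n_motifs)
  stopifnot(n_motifs >= 1, motif_length >= 1, dominance > 0.25,
            dominance <= 1, n_sequences >= 1, sequence_length >= motif_length,
            all(planting_rates >= 0), noise_sd >= 0, n_barcodes >= 1,
            n_replicates >= 1, depth > 0,
            irregular_fraction >= 0, irregular_fraction <= 1)
  structure(as.list(environment()), class = "mpra_scenario")
}

motif_ids <- function(spec) sprintf("M%02d", seq_len(spec$n_motifs))

#' Generate random informative PWMs
#'
#' Each position gets a uniformly chosen dominant base at frequency
#' `dominance` (remaining mass split evenly), and the cutoff is
#' calibrated with [calibrate_minfn_cutoff()] at the scenario's
#' `target_fnr`.  Deterministic per (spec, seed).
#'
#' @param spec an [mpra_scenario()].
#' @param seed defaults to the scenario seed.
#' @return List of [pwm()] objects named `M01`, `M02`, ...
#' @export
make_motifs <- function(spec, seed = spec$seed) {
  ids <- motif_ids(spec)
  pwms <- with_seed(seed * 1000 + 1, {
    lapply(seq_len(spec$n_motifs), function(k) {
      dom <- sample.int(4L, spec$motif_length, replace = TRUE)
      freqs <- matrix((1 - spec$dominance) / 3, spec$motif_length, 4L)
      freqs[cbind(seq_len(spec$motif_length), dom)] <- spec$dominance
      pwm(ids[k], freqs)
    })
  })
  for (k in seq_along(pwms)) {
    pwms[[k]]$cutoff <- calibrate_minfn_cutoff(
      pwms[[k]], target_fnr = spec$target_fnr,
      seed = seed * 1000 + 100 + k)
  }
  names(pwms) <- ids
  pwms
}

#' Generate sequences with planted motif occurrences
#'
#' Uniform background sequence with non-overlapping planted consensus
#' sites; planted copy numbers are Poisson with the scenario's
#' per-motif rates.  Sites are placed on a motif-width slot grid with a
#' random per-sequence phase, which guarantees non-overlap cheaply.
#' A scenario whose expected planted bases exceed the sequence length is
#' rejected upfront; per-sequence copy overflow beyond the available
#' slots is trimmed, and the ledger records what was actually planted.
#'
#' @param spec an [mpra_scenario()].
#' @param motifs list from [make_motifs()].
#' @param seed defaults to the scenario seed.
#' @return `list(sequences = <named character>, ledger = <data frame
#'   sequence_id x matrix_id with planted copy counts>)`.
#' @export
make_sequences <- function(spec, motifs, seed = spec$seed) {
  L <- spec$motif_length
  S <- spec$sequence_length
  consensus <- vapply(motifs, pwm_consensus, character(1L))
  sites <- lapply(consensus, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  seq_ids <- sprintf("construct_%04d", seq_len(spec$n_sequences))
  n_slots <- S %/% L
  if (sum(spec$planting_rates) * L > S)
    stop("infeasible packing: expected planted bases exceed sequence length")
  with_seed(seed * 1000 + 2, {
    copies <- matrix(rpois(spec$n_sequences * spec$n_motifs,
                           rep(spec$planting_rates,
                               each = spec$n_sequences)),
                     spec$n_sequences, spec$n_motifs)
    planted <- matrix(0L, spec$n_sequences, spec$n_motifs,
                      dimnames = list(seq_ids, motif_ids(spec)))
    seqs <- character(spec$n_sequences)
    for (i in seq_len(spec$n_sequences)) {
      chars <- sample(DNA_BASES, S, replace = TRUE)
      want <- copies[i, ]
      while (sum(want) > n_slots) {           # trim overflow, rarest last
        k <- which.max(want)
        want[k] <- want[k] - 1L
      }
      total <- sum(want)
      if (total > 0L) {
        phase <- sample.int(S - n_slots * L + 1L, 1L) - 1L
        slots <- sample.int(n_slots, total)
        motif_of <- rep(seq_len(spec$n_motifs), want)
        for (s in seq_len(total)) {
          at <- phase + (slots[s] - 1L) * L
          chars[(at + 1L):(at + L)] <- sites[[motif_of[s]]]
        }
      }
      planted[i, ] <- want
      seqs[i] <- paste(chars, collapse = "")
    }
    ledger <- data.frame(
      sequence_id = rep(seq_ids, spec$n_motifs),
      matrix_id = rep(motif_ids(spec), each = spec$n_sequences),
      copies = as.integer(planted),
      stringsAsFactors = FALSE)
    list(sequences = stats::setNames(seqs, seq_ids), ledger = ledger)
  })
}

# planted response surface (no noise, no condition offset).  The
# cluster boundary defaults to the median enrichment of the cluster
# motif so the two planted clusters are balanced regardless of the
# seed's background hit level; a numeric cluster_threshold overrides.
true_surface <- function(spec, E) {
  cm <- motif_ids(spec)[spec$cluster_motif]
  thr <- spec$cluster_threshold %||% median(E[, cm])
  cluster <- ifelse(E[, cm] >= thr, 2L, 1L)
  y <- spec$cluster_offsets[cluster]
  for (tm in spec$hinge_terms) {
    col <- motif_ids(spec)[tm$motif]
    h <- hinge_eval(E[, col], tm$knot, tm$dir)
    y <- y + ifelse(cluster == tm$cluster, tm$coef * h, 0)
  }
  list(y = as.numeric(y), cluster = cluster, threshold = thr)
}

#' Generate activities from enrichment scores
#'
#' The planted response surface is exactly the model family the
#' predictor assumes: a cluster baseline (cluster membership set by
#' thresholding the cluster motif's enrichment) plus per-cluster hinge
#' terms, a per-condition offset, and Gaussian noise.
#'
#' @param spec an [mpra_scenario()].
#' @param enrichments matrix from [enrichment_matrix()] over the
#'   generated sequences (rows named by construct).
#' @param seed defaults to the scenario seed.
#' @return `list(activities = <construct_id, condition, activity>,
#'   truth = <list: noiseless surface, cluster assignment, planted
#'   terms>)`.
#' @export
make_activities <- function(spec, enrichments, seed = spec$seed) {
  surf <- true_surface(spec, enrichments)
  conds <- names(spec$conditions)
  with_seed(seed * 1000 + 3, {
    rows <- expand.grid(construct = rownames(enrichments), cond = conds,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- rep(surf$y, times = length(conds)) +
      rep(unname(spec$conditions), each = nrow(enrichments))
    act <- mu + rnorm(length(mu), sd = spec$noise_sd)
    activities <- data.frame(construct_id = rows$construct,
                             condition = rows$cond,
                             activity = act, stringsAsFactors = FALSE)
    list(activities = activities,
         truth = list(surface = mu, cluster = surf$cluster,
                      cluster_motif = motif_ids(spec)[spec$cluster_motif],
                      cluster_threshold = surf$threshold,
                      hinge_terms = spec$hinge_terms,
                      conditions = spec$conditions))
  })
}

#' Generate a barcode count table consistent with given activities
#'
#' DNA counts are Poisson at the scenario depth; mRNA counts are Poisson
#' at `depth * 2^activity` so that the log2 mRNA/DNA ratio recovers the
#' activity.  A seeded `irregular_fraction` of constructs receives
#' per-replicate activity offsets of SD `irregular_sd`, producing the
#' irregular replicate behaviour the preprocessing filter removes.
#'
#' @param activities data frame `construct_id`, `condition`, `activity`.
#' @param spec an [mpra_scenario()].
#' @param seed defaults to the scenario seed.
#' @return `list(counts = <count table>, irregular_ids = <character>)`.
#' @export
make_counts <- function(activities, spec, seed = spec$seed) {
  with_seed(seed * 1000 + 4, {
    constructs <- unique(activities$construct_id)
    n_irr <- round(spec$irregular_fraction * length(constructs))
    irregular <- if (n_irr > 0)
      sample(constructs, n_irr) else character(0)
    nb <- spec$n_barcodes
    nr <- spec$n_replicates
    per <- nb * nr
    idx <- rep(seq_len(nrow(activities)), each = per)
    rep_id <- rep(rep(seq_len(nr), each = nb), times = nrow(activities))
    bc_id <- rep(rep(seq_len(nb), times = nr), times = nrow(activities))
    a <- activities$activity[idx]
    irr <- activities$construct_id[idx] %in% irregular
    # one offset per (construct row, replicate), shared by its barcodes
    key <- (idx - 1L) * nr + rep_id
    off <- rnorm(nrow(activities) * nr, sd = spec$irregular_sd)
    a <- a + ifelse(irr, off[key], 0)
    dna <- rpois(length(a), spec$depth)
    mrna <- rpois(length(a), spec$depth * 2^a)
    counts <- data.frame(
      construct_id = activities$construct_id[idx],
      condition = activities$condition[idx],
      barcode = sprintf("bc%02d", bc_id),
      replicate = rep_id,
      dna_count = dna, mrna_count = mrna,
      stringsAsFactors = FALSE)
    list(counts = counts, irregular_ids = sort(irregular))
  })
}

#' Run every generator of a scenario
#'
#' Motifs, sequences, enrichment scan, activities and counts in one call;
#' everything is deterministic given `spec$seed`.
#'
#' @param spec an [mpra_scenario()].
#' @param counts also generate the barcode count table (default TRUE).
#' @return List with `motifs`, `sequences`, `ledger`, `enrichments`,
#'   `activities`, `truth`, and (if requested) `counts` and
#'   `irregular_ids`.
#' @export
simulate_mpra <- function(spec = mpra_scenario(), counts = TRUE) {
  motifs <- make_motifs(spec)
  sq <- make_sequences(spec, motifs)
  E <- enrichment_matrix(motifs, sq$sequences)
  act <- make_activities(spec, E)
  out <- list(motifs = motifs, sequences = sq$sequences,
              ledger = sq$ledger, enrichments = E,
              activities = act$activities, truth = act$truth)
  if (counts) {
    ct <- make_counts(act$activities, spec)
    out$counts <- ct$counts
    out$irregular_ids <- ct$irregular_ids
  }
  out
}
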