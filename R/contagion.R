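#' Successive time gaps between sorted latencies
#'
#' The latencies of the responding birds within one predator presentation
#' event are sorted ascending; each gap is the latency of a focal bird minus
#' the latency of the immediately preceding bird.
#'
#' @param latencies Numeric vector of latencies (s), at least 2.
#' @return Numeric vector of `length(latencies) - 1` gaps.
#' @export
event_time_gaps <- function(latencies) {
  latencies <- latencies[!is.na(latencies)]
  if (length(latencies) < 2)
    stop("need at least 2 responding individuals to compute time gaps")
  diff(sort(latencies))
}

#' Pair predator events across flocks
#'
#' Events are paired when they share the trial number and the presentation
#' side (North/South) but come from the two different flocks, so that each
#' event enters exactly one pair per side. Unpairable events (one flock
#' missing a side) are reported in the `"unpaired"` attribute.
#'
#' @param events A data.frame with columns `trial`, `side`, `flock` (and any
#'   extra columns, carried along).
#' @return A data.frame of pairs with columns `trial`, `side`, `flock_a`,
#'   `flock_b`.
#' @export
pair_events <- function(events) {
  stopifnot(all(c("trial", "side", "flock") %in% names(events)))
  key <- interaction(events$trial, events$side, drop = TRUE)
  pairs <- data.frame(trial = character(0), side = character(0),
                      flock_a = character(0), flock_b = character(0),
                      stringsAsFactors = FALSE)
  unpaired <- events[0, ]
  for (k in levels(key)) {
    g <- events[key == k, , drop = FALSE]
    if (length(unique(g$flock)) < nrow(g))
      stop("events within a trial x side group must come from different flocks")
    if (nrow(g) < 2) { unpaired <- rbind(unpaired, g); next }
    if (nrow(g) > 2)
      stop("more than two flocks per trial x side group is not supported")
    pairs[nrow(pairs) + 1, ] <- list(as.character(g$trial[1]),
                                     as.character(g$side[1]),
                                     as.character(g$flock[1]),
                                     as.character(g$flock[2]))
  }
  attr(pairs, "unpaired") <- unpaired
  pairs
}

#' Restrict a pair of events to the overlapping distance range
#'
#' Controls for the flocks' distance from the monitor: computes the overlap of
#' the two flocks' \[min, max\] distance ranges and keeps only individuals
#' whose distance lies inside it (inclusive). An empty overlap drops the pair.
#'
#' @param pair List with elements `a`, `b` (latencies) and `dist_a`, `dist_b`
#'   (matching distances to the active monitor, m).
#' @return The filtered pair (same shape), or NULL when the overlap is empty.
#' @export
distance_overlap_filter <- function(pair) {
  stopifnot(length(pair$a) == length(pair$dist_a),
            length(pair$b) == length(pair$dist_b))
  lo <- max(min(pair$dist_a), min(pair$dist_b))
  hi <- min(max(pair$dist_a), max(pair$dist_b))
  if (lo > hi) return(NULL)
  ka <- pair$dist_a >= lo - 1e-9 & pair$dist_a <= hi + 1e-9
  kb <- pair$dist_b >= lo - 1e-9 & pair$dist_b <= hi + 1e-9
  list(a = pair$a[ka], b = pair$b[kb],
       dist_a = pair$dist_a[ka], dist_b = pair$dist_b[kb])
}

# core permutation machinery for one event pair: returns the observed summed
# gap, the gap count, and per-permutation summed gaps under random
# reassignment of the pooled latencies (group sizes preserved). The mean gap
# of sorted latencies is (max - min) / (n - 1), so only group extremes are
# needed.
perm_pair_gaps <- function(a, b, n_perm) {
  na <- length(a); nb <- length(b); n <- na + nb
  z <- c(a, b)
  obs <- (max(a) - min(a)) + (max(b) - min(b))
  ord <- apply(matrix(stats::runif(n * n_perm), n, n_perm), 2, order)
  zp <- matrix(z[ord], n, n_perm)
  za <- zp[seq_len(na), , drop = FALSE]
  zb <- zp[na + seq_len(nb), , drop = FALSE]
  cmax <- function(m) Reduce(pmax, asplit(m, 1))
  cmin <- function(m) Reduce(pmin, asplit(m, 1))
  null <- (cmax(za) - cmin(za)) + (cmax(zb) - cmin(zb))
  list(obs = obs, n_gaps = n - 2, null = null)
}

#' Permutation test for latency clustering in one event pair
#'
#' Pools the latencies of the two matched events, reassigns them at random
#' between the events `n_perm` times (preserving group sizes), and compares
#' the observed mean time gap (averaged over the two events, weighted by gap
#' count) with the permutation distribution. The p-value is the proportion of
#' permuted mean gaps less than or equal to the observed one (ties counted as
#' extreme); small p indicates that responses are more clustered in time than
#' expected by chance.
#'
#' @param a,b Latency vectors (s) of the two events; each needs >= 2 values.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional RNG seed for reproducibility.
#' @param smoothing If TRUE use the (+1)-smoothed estimator
#'   `(1 + #\{null <= obs\}) / (1 + n_perm)`.
#' @return Object of class `contagion_test`: `observed_mean_gap`, `null_gaps`,
#'   `p_value`, `n_perm`, `seed`, `n_pairs`.
#' @export
permutation_test <- function(a, b, n_perm = 10000, seed = NULL,
                             smoothing = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both events need at least 2 responding individuals")
  if (!is.null(seed)) set.seed(seed)
  if (stats::sd(c(a, b)) < 1e-12) {
    warning("all pooled latencies identical; permutation test degenerate")
    return(structure(list(observed_mean_gap = 0,
                          null_gaps = rep(0, n_perm), p_value = 1,
                          n_perm = n_perm, seed = seed, n_pairs = 1L),
                     class = "contagion_test"))
  }
  pp <- perm_pair_gaps(a, b, n_perm)
  obs <- pp$obs / pp$n_gaps
  null <- pp$null / pp$n_gaps
  hits <- sum(null <= obs + 1e-12)
  p <- if (smoothing) (1 + hits) / (1 + n_perm) else hits / n_perm
  structure(list(observed_mean_gap = obs, null_gaps = null, p_value = p,
                 n_perm = n_perm, seed = seed, n_pairs = 1L),
            class = "contagion_test")
}

#' Aggregate contagion test over all event pairs
#'
#' The observed statistic is the mean time gap pooled over all pairs (total
#' summed gap / total gap count); the null distribution is built by permuting
#' latencies within each pair independently and pooling per permutation.
#' Optionally restricts each pair to the overlapping monitor-distance range
#' first ([distance_overlap_filter()]); pairs left with fewer than 2
#' responders per event (or an empty overlap) are dropped and counted.
#'
#' @param pairs List of pairs, each a list with latency vectors `a`, `b` and
#'   (when `control_distance`) `dist_a`, `dist_b`.
#' @param control_distance Apply the distance-overlap control (default FALSE).
#' @inheritParams permutation_test
#' @return Object of class `contagion_test` (as [permutation_test()], plus
#'   `n_pairs` used and `n_dropped`).
#' @export
aggregate_contagion <- function(pairs, n_perm = 10000, seed = NULL,
                                control_distance = FALSE, smoothing = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  dropped <- 0L
  num_obs <- 0; den <- 0
  null_num <- rep(0, n_perm)
  used <- 0L
  for (pair in pairs) {
    pair$a <- pair$a[!is.na(pair$a)]; pair$b <- pair$b[!is.na(pair$b)]
    if (control_distance) {
      pair <- distance_overlap_filter(pair)
      if (is.null(pair)) { dropped <- dropped + 1L; next }
    }
    if (length(pair$a) < 2 || length(pair$b) < 2) {
      dropped <- dropped + 1L; next
    }
    pp <- perm_pair_gaps(pair$a, pair$b, n_perm)
    num_obs <- num_obs + pp$obs
    den <- den + pp$n_gaps
    null_num <- null_num + pp$null
    used <- used + 1L
  }
  if (used == 0L) stop("no valid event pairs")
  obs <- num_obs / den
  null <- null_num / den
  hits <- sum(null <= obs + 1e-12)
  p <- if (smoothing) (1 + hits) / (1 + n_perm) else hits / n_perm
  structure(list(observed_mean_gap = obs, null_gaps = null, p_value = p,
                 n_perm = n_perm, seed = seed, n_pairs = used,
                 n_dropped = dropped,
                 control_distance = control_distance),
            class = "contagion_test")
}

#' Build event pairs from a latency table
#'
#' Converts the tidy per-bird latency table emitted by the pipeline into the
#' pair list consumed by [aggregate_contagion()]. The escape latency is the
#' earliest of the run and fly latencies; birds with no response are excluded
#' from the event's latency set.
#'
#' @param latency_table Data.frame with columns `trial`, `side`, `flock`,
#'   `t_run`, `t_fly`, `dist_monitor`.
#' @param response `"escape"` (min of run/fly) or `"fly"`.
#' @return List of pairs (`a`, `b`, `dist_a`, `dist_b`).
#' @export
contagion_pairs <- function(latency_table, response = c("escape", "fly")) {
  response <- match.arg(response)
  lat <- if (response == "fly") latency_table$t_fly
  else suppressWarnings(pmin(latency_table$t_run, latency_table$t_fly,
                             na.rm = TRUE))
  lat[is.infinite(lat)] <- NA_real_
  events <- unique(latency_table[, c("trial", "side", "flock")])
  prs <- pair_events(events)
  out <- list()
  for (r in seq_len(nrow(prs))) {
    sel_a <- latency_table$trial == prs$trial[r] &
      latency_table$side == prs$side[r] &
      latency_table$flock == prs$flock_a[r]
    sel_b <- latency_table$trial == prs$trial[r] &
      latency_table$side == prs$side[r] &
      latency_table$flock == prs$flock_b[r]
    ok_a <- sel_a & !is.na(lat)
    ok_b <- sel_b & !is.na(lat)
    out[[length(out) + 1]] <-
      list(trial = prs$trial[r], side = prs$side[r],
           a = lat[ok_a], b = lat[ok_b],
           dist_a = latency_table$dist_monitor[ok_a],
           dist_b = latency_table$dist_monitor[ok_b])
  }
  out
}

#' @export
print.contagion_test <- function(x, ...) {
  cat("Permutation test for clustering of escape latencies\n")
  cat(sprintf("  event pairs: %d%s, permutations: %d\n", x$n_pairs,
              if (!is.null(x$n_dropped) && x$n_dropped > 0)
                sprintf(" (%d dropped)", x$n_dropped) else "",
              x$n_perm))
  cat(sprintf("  observed mean gap: %.3f s\n", x$observed_mean_gap))
  cat(sprintf("  null mean gap:     %.3f s\n", mean(x$null_gaps)))
  cat(sprintf("  p (null <= observed): %.4g\n", x$p_value))
  invisible(x)
}

#' @export
plot.contagion_test <- function(x, main = "Permutation null distribution",
                                ...) {
  graphics::hist(x$null_gaps, breaks = 40, main = main,
                 xlab = "Mean time gap (s)", col = "grey85", border = "white",
                 ...)
  graphics::abline(v = x$observed_mean_gap, lty = 2, lwd = 2)
  graphics::mtext(sprintf("observed = %.3f s, p = %.4g",
                          x$observed_mean_gap, x$p_value), side = 3, line = 0,
                  cex = 0.8)
  invisible(x)
}
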