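# Independent brute-force oracles and fixture builders shared across tests.

# --- per-millisecond ethogram oracle --------------------------------------
# Discretizes the span into 1-ms ticks (tick centers) and counts ticks
# covered by any interval of the behavior; independent of the interval
# arithmetic in the package.
msDuration <- function(log, behavior, span) {
  if (behavior == "All Sniff") {
    subs <- c("Face Sniff", "Body Sniff", "Anogenital Sniff", "Tail Sniff")
    return(sum(vapply(subs, msDuration, 0, log = log, span = span)))
  }
  ev <- events(log)
  ev <- ev[ev$behavior == behavior & ev$event_type == "state", , drop = FALSE]
  nticks <- round((span[2] - span[1]) * 1000)
  if (nticks == 0L || nrow(ev) == 0L) return(0)
  ticks <- span[1] + (seq_len(nticks) - 0.5) / 1000
  active <- logical(nticks)
  for (k in seq_len(nrow(ev)))
    active <- active | (ticks >= ev$onset[k] & ticks <= ev$offset[k])
  sum(active) / 1000
}

msPointCount <- function(log, behavior, span) {
  ev <- events(log)
  n <- 0L
  for (k in seq_len(nrow(ev)))
    if (ev$behavior[k] == behavior && ev$event_type[k] == "point" &&
        ev$onset[k] >= span[1] && ev$onset[k] < span[2])
      n <- n + 1L
  n
}

# Random event log over the default session timeline. Intervals of the same
# behavior never overlap (a bout cannot restart before it ends), matching
# how scored logs and the simulator behave.
randomEventLog <- function(seed, span = c(180, 780), nState = 25,
                           nPoint = 15) {
  set.seed(seed)
  reg <- behaviorRegistry()
  states <- reg$behavior[reg$type == "state"]
  points <- reg$behavior[reg$type == "point"]
  bs <- sample(states, nState, replace = TRUE)
  on <- runif(nState, span[1], span[2])
  off <- on + rexp(nState, 1 / 3)
  for (b in unique(bs)) {         # de-overlap within each behavior
    i <- which(bs == b)[order(on[bs == b])]
    if (length(i) > 1L)
      for (k in seq_len(length(i) - 1L))
        off[i[k]] <- min(off[i[k]], on[i[k + 1L]] - 1e-6)
    off[i] <- pmax(off[i], on[i])
  }
  bp <- sample(points, nPoint, replace = TRUE)
  po <- runif(nPoint, span[1], span[2])
  EventLog(data.frame(
    behavior = c(bs, bp),
    actor = reg$actor[match(c(bs, bp), reg$behavior)],
    event_type = c(rep("state", nState), rep("point", nPoint)),
    onset = c(on, po),
    offset = c(off, rep(NA_real_, nPoint)),
    stringsAsFactors = FALSE))
}

# --- steepest-ascent watershed oracle -------------------------------------
# Walks each cell uphill to its peak, one cell at a time, with the same
# neighbor rules as the package (strictly greater, ties toward the lower
# linear index); peaks ranked by descending density then lower index.
hillClimbOracle <- function(density) {
  n <- nrow(density); m <- ncol(density)
  peakOf <- integer(n * m)
  for (start in seq_len(n * m)) {
    cur <- start
    repeat {
      r <- ((cur - 1L) %% n) + 1L
      cc <- ((cur - 1L) %/% n) + 1L
      best <- density[cur]; nxt <- 0L
      for (dc in c(-1L, 0L, 1L)) for (dr in c(-1L, 0L, 1L)) {
        if (dc == 0L && dr == 0L) next
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > n || c2 < 1L || c2 > m) next
        v <- density[rr, c2]
        if (v > best) { best <- v; nxt <- (c2 - 1L) * n + rr }
      }
      if (nxt == 0L) break
      cur <- nxt
    }
    peakOf[start] <- cur
  }
  peaks <- sort(unique(peakOf))
  ord <- order(-density[peaks], peaks)
  rank <- integer(length(peaks)); rank[ord] <- seq_along(peaks)
  matrix(rank[match(peakOf, peaks)], n, m)
}

# --- small trajectory fixtures --------------------------------------------
# A trajectory with both animals' full skeletons planted at fixed centers.
plantedTrajectory <- function(nframes, centerA = c(15, 15),
                              centerB = c(60, 15), fps = 30) {
  offs <- cbind(c(2.5, 1.5, 1.2, 1.2, 0, -0.8, -0.8, -2.4),
                c(0, 0, 0.6, -0.6, 0, 0.7, -0.7, 0))
  co <- array(NA_real_, c(nframes, 2, 8, 2))
  for (nd in 1:8) {
    co[, 1, nd, 1] <- centerA[1] + offs[nd, 1]
    co[, 1, nd, 2] <- centerA[2] + offs[nd, 2]
    co[, 2, nd, 1] <- centerB[1] + offs[nd, 1]
    co[, 2, nd, 2] <- centerB[2] + offs[nd, 2]
  }
  KeypointTrajectory(co, fps = fps)
}

quickConfig <- function(...) {
  generatorConfig(baselineS = 30, testS = 90, ...)
}

# Occupancy profiles shaped like real cohort data: a shared mean profile,
# multiplicative per-subject noise, and one region's occupancy doubled in
# the second (SI) group before renormalization.
plantedProfiles <- function(seed, planted = 3L, nPerGroup = 18L,
                            nRegions = 8L, noiseSd = 0.3) {
  set.seed(seed)
  p0 <- rev(sort(rexp(nRegions) + 0.3))
  n <- 2L * nPerGroup
  base <- matrix(rep(p0, each = n), n, nRegions) *
    exp(matrix(rnorm(n * nRegions, 0, noiseSd), n, nRegions))
  base[(nPerGroup + 1):n, planted] <- base[(nPerGroup + 1):n, planted] * 2
  prof <- base / rowSums(base)
  colnames(prof) <- paste0("region_", seq_len(nRegions))
  rownames(prof) <- sprintf("m%02d", seq_len(n))
  prof
}
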