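#' @include AllClasses.R utils-geometry.R
NULL

#' Condition parameter presets for the session simulator
#'
#' Per-condition behavioral parameters. Magnitudes are the package's own
#' defaults, chosen so that the isolated (SI) preset reproduces the expected
#' direction of every group contrast relative to group-housed (GH) animals:
#' more social freezing and reactivity to being sniffed, longer first tunnel
#' sheltering, more reversing, fewer prosocial initiations, more aggression,
#' and unchanged social chamber preference. CNTL/Shock presets model a
#' stress cohort with increased hesitancy and reduced motivation but
#' unchanged sniff-evoked fear.
#'
#' @return named list of per-condition parameter lists.
#' @export
conditionPresets <- function() {
  gh <- list(
    pFreeze = 0.05,        # P(social freeze | being sniffed)
    pReact = 0.10,         # P(social reactivity | being sniffed)
    shelterMeanS = 5,      # mean duration of one pre-entry shelter bout
    reverseProb = 0.10,    # P(reverse | tunnel crossing before first entry)
    initRate = 2.0,        # prosocial initiations / min in social chamber
    sniffRate = 3.0,       # spontaneous sniff bouts / min
    consSniffRate = 3.0,   # conspecific sniff bouts / min
    aggressionRate = 0.02, # aggression bouts / min
    groomRate = 0.3,       # grooming bouts / min
    jumpRate = 0.1,        # escape jumps / min
    nsFreezeRateBase = 0.4, nsFreezeRateTest = 0.05, # bouts / min
    homeReturnRate = 1.2,  # home visits / min while in social chamber
    homeDwellMeanS = 15, preTunnelMeanS = 8,
    freezeMeanS = 3, sniffMeanS = 2, reverseMeanS = 1.5,
    groomMeanS = 4, nsFreezeMeanS = 3, aggMeanS = 2,
    walkSpeed = 8)
  si <- gh
  si$pFreeze <- 0.50       # x10
  si$pReact <- 0.30        # x3
  si$shelterMeanS <- 20    # x4
  si$reverseProb <- 0.30   # x3
  si$initRate <- 1.0       # x0.5
  si$aggressionRate <- 0.10 # x5
  shock <- gh
  shock$shelterMeanS <- 10
  shock$reverseProb <- 0.35
  shock$initRate <- 1.0
  shock$homeReturnRate <- 2.4
  list(GH = gh, SI = si, CNTL = gh, Shock = shock)
}

#' Generator configuration
#'
#' Session structure (30 fps, 180 s solo baseline, 600 s dyadic test by
#' default), arena geometry, per-condition behavioral parameters and noise
#' parameters (keypoint jitter sd in cm, missing-point rate, identity-swap
#' rate). Any field can be overridden by name.
#'
#' @param ... overrides, e.g. \code{jitterSd = 0}, \code{testS = 120}, or
#'   \code{conditions = ...}.
#' @return configuration list.
#' @export
generatorConfig <- function(...) {
  cfg <- list(fps = 30, baselineS = 180, testS = 600,
              arena = defaultArena(),
              jitterSd = 0.15, missingRate = 0.01, swapRate = 0,
              conditions = conditionPresets())
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(cfg$fps > 0, cfg$baselineS >= 0, cfg$testS > 0,
            cfg$jitterSd >= 0, cfg$missingRate >= 0, cfg$missingRate <= 1,
            cfg$swapRate >= 0, cfg$swapRate <= 1)
  cfg
}

# growable segment buffer -------------------------------------------------
newBuf <- function(n = 2048L) {
  e <- new.env(parent = emptyenv())
  e$t0 <- numeric(n); e$t1 <- numeric(n)
  e$x0 <- numeric(n); e$y0 <- numeric(n)
  e$x1 <- numeric(n); e$y1 <- numeric(n)
  e$state <- character(n); e$n <- 0L
  e
}
bufGrow <- function(e) {
  for (f in c("t0", "t1", "x0", "y0", "x1", "y1"))
    e[[f]] <- c(e[[f]], numeric(length(e[[f]])))
  e$state <- c(e$state, character(length(e$state)))
}
bufAsList <- function(e) {
  i <- seq_len(e$n)
  list(t0 = e$t0[i], t1 = e$t1[i], x0 = e$x0[i], y0 = e$y0[i],
       x1 = e$x1[i], y1 = e$y1[i], state = e$state[i])
}

postureTable <- function() {
  # yaw, bend, spread (rad), oscillation amplitude (rad) and frequency (Hz)
  rbind(
    idle            = c(0.00, 0.12, 0.85, 0.06, 0.5),
    locomote        = c(0.00, 0.00, 0.75, 0.25, 3.0),
    dart            = c(0.00, 0.00, 0.70, 0.30, 5.0),
    sniff_face      = c(0.45, 0.15, 0.75, 0.12, 1.5),
    sniff_body      = c(0.30, 0.20, 0.75, 0.12, 1.5),
    sniff_anogenital= c(0.15, 0.35, 0.80, 0.12, 1.5),
    sniff_tail      = c(0.05, 0.30, 0.70, 0.12, 1.5),
    social_freeze   = c(0.00, 0.55, 1.15, 0.01, 0.2),
    nonsocial_freeze= c(0.00, 0.50, 1.10, 0.01, 0.2),
    tunnel_shelter  = c(0.00, 0.80, 1.30, 0.02, 0.3),
    groom           = c(0.95, 0.95, 1.00, 0.15, 2.0),
    aggress         = c(0.20, 0.25, 0.80, 0.45, 5.0),
    jump            = c(0.00, 0.30, 0.60, 0.10, 2.0),
    absent          = c(0, 0, 0, 0, 0))
}

#' Simulate one assay session
#'
#' Continuous-time simulation of the dyad: a solo baseline in the home
#' chamber, then a hesitancy phase (home dwell, tunnel sheltering bouts with
#' possible reversing, first social-chamber entry) followed by a dyadic
#' interaction phase in which competing exponential clocks drive sniffing
#' (with subtype mix), prosocial initiations, conspecific sniff bouts (each
#' resolving into social freezing, reactivity, or no response), aggression,
#' grooming, jumps, and home-chamber visits. Body centers move along
#' piecewise-linear goal-directed segments; the eight skeleton nodes are
#' placed on fixed-length limbs around a smoothed heading with
#' state-dependent posture (head yaw, spine bend, hip spread plus
#' state-specific oscillation), then Gaussian jitter is added and random
#' cells are marked missing. The emitted event log is the realized state
#' sequence in the scoring vocabulary, and the ground truth carries
#' summaries recomputed from the realized frames and events by the
#' generator's own code. Identical (config, condition, seed) gives
#' bit-identical output.
#'
#' @param config see \code{\link{generatorConfig}}.
#' @param condition a label present in \code{config$conditions}.
#' @param seed integer seed.
#' @param subjectId,sex identifiers for the session record.
#' @return list(session = \linkS4class{SessionRecord},
#'   truth = \linkS4class{GroundTruth}).
#' @export
simulateSession <- function(config = generatorConfig(), condition = "GH",
                            seed = 1L, subjectId = NULL, sex = "F") {
  if (!condition %in% names(config$conditions))
    stop("unknown condition label: ", condition)
  par <- config$conditions[[condition]]
  if (is.null(subjectId)) subjectId <- paste0(condition, "_s", seed)
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(seed)

  fps <- config$fps
  T0 <- config$baselineS
  T1 <- config$baselineS + config$testS
  nfr <- round(T1 * fps)
  speed <- par$walkSpeed
  # internal layout constants (match defaultArena-style rectangles)
  hx <- range(config$arena@home[, 1]); hy <- range(config$arena@home[, 2])
  tx <- range(config$arena@tunnel[, 1]); ty <- range(config$arena@tunnel[, 2])
  sx <- range(config$arena@social[, 1]); sy <- range(config$arena@social[, 2])
  tmy <- mean(ty)
  homeGate <- c(hx[2] - 1, tmy); tunnelIn <- c(tx[1] + 1, tmy)
  tunnelMid <- c(mean(tx), tmy); tunnelOut <- c(tx[2] - 1, tmy)
  socialGate <- c(sx[1] + 1, tmy)

  ev <- list(behavior = character(), actor = character(),
             type = character(), onset = numeric(), offset = numeric())
  addEvent <- function(behavior, onset, offset = NA_real_,
                       actor = "experimental") {
    ev$behavior[[length(ev$behavior) + 1L]] <<- behavior
    ev$actor[[length(ev$actor) + 1L]] <<- actor
    ev$type[[length(ev$type) + 1L]] <<-
      if (is.na(offset)) "point" else "state"
    ev$onset[[length(ev$onset) + 1L]] <<- onset
    ev$offset[[length(ev$offset) + 1L]] <<- min(offset, T1)
  }

  mkAnimal <- function(x, y, t) {
    a <- new.env(parent = emptyenv())
    a$pos <- c(x, y); a$t <- t; a$buf <- newBuf()
    a
  }
  addSeg <- function(a, t1, x1, y1, state) {
    b <- a$buf
    if (b$n + 1L > length(b$t0)) bufGrow(b)
    i <- b$n + 1L
    b$t0[i] <- a$t; b$t1[i] <- t1
    b$x0[i] <- a$pos[1]; b$y0[i] <- a$pos[2]
    b$x1[i] <- x1; b$y1[i] <- y1
    b$state[i] <- state
    b$n <- i
    a$t <- t1; a$pos <- c(x1, y1)
  }
  hold <- function(a, dur, state) {
    tEnd <- min(a$t + dur, T1)
    if (tEnd > a$t) addSeg(a, tEnd, a$pos[1], a$pos[2], state)
    tEnd
  }
  walkTo <- function(a, target, state = "locomote", spd = speed,
                     tCap = T1) {
    d <- sqrt(sum((target - a$pos)^2))
    if (d < 1e-9) return(TRUE)
    dur <- d / spd
    if (a$t + dur > tCap) {
      frac <- max(0, (tCap - a$t) / dur)
      target <- a$pos + frac * (target - a$pos)
      addSeg(a, tCap, target[1], target[2], state)
      return(FALSE)
    }
    addSeg(a, a$t + dur, target[1], target[2], state)
    TRUE
  }
  randIn <- function(xr, yr, margin = 2) {
    c(stats::runif(1, xr[1] + margin, xr[2] - margin),
      stats::runif(1, yr[1] + margin, yr[2] - margin))
  }
  wallPoint <- function(xr, yr, margin = 1) {
    side <- sample.int(4L, 1L)
    switch(side,
      c(stats::runif(1, xr[1] + margin, xr[2] - margin), yr[1] + margin),
      c(stats::runif(1, xr[1] + margin, xr[2] - margin), yr[2] - margin),
      c(xr[1] + margin, stats::runif(1, yr[1] + margin, yr[2] - margin)),
      c(xr[2] - margin, stats::runif(1, yr[1] + margin, yr[2] - margin)))
  }
  wander <- function(a, tEnd, xr, yr, thigmo = FALSE) {
    while (a$t < tEnd - 1e-9) {
      if (stats::runif(1) < 0.45) {
        hold(a, min(stats::rexp(1, 1 / 1.5), tEnd - a$t), "idle")
      } else {
        target <- if (thigmo && stats::runif(1) < 0.7)
          wallPoint(xr, yr) else randIn(xr, yr)
        walkTo(a, target, "locomote", speed, tCap = tEnd)
      }
    }
  }

  exp <- mkAnimal(mean(hx), mean(hy), 0)
  # -- baseline: experimental alone in the home chamber ---------------------
  t <- 0
  while (t < T0 - 1e-9) {
    tg <- stats::rexp(1, par$groomRate / 60)
    tf <- stats::rexp(1, par$nsFreezeRateBase / 60)
    tn <- min(tg, tf, T0 - t)
    wander(exp, t + tn, hx, hy, thigmo = TRUE)
    t <- t + tn
    if (t >= T0 - 1e-9) break
    if (tg < tf) {
      dur <- stats::rexp(1, 1 / par$groomMeanS)
      end <- hold(exp, min(dur, T0 - t), "groom")
      addEvent("Groom", t, end)
    } else {
      dur <- stats::rexp(1, 1 / par$nsFreezeMeanS)
      end <- hold(exp, min(dur, T0 - t), "nonsocial_freeze")
      addEvent("Non-social Freeze", t, end)
    }
    t <- exp$t
  }

  con <- mkAnimal(stats::runif(1, sx[1] + 5, sx[2] - 5),
                  stats::runif(1, sy[1] + 5, sy[2] - 5), T0)
  syncCon <- function(tEnd) if (con$t < tEnd - 1e-9)
    wander(con, tEnd, sx, sy)

  # -- hesitancy: home dwell, tunnel sheltering, reversing, first entry -----
  wander(exp, min(T0 + stats::rexp(1, 1 / par$preTunnelMeanS), T1), hx, hy)
  entered <- FALSE
  while (!entered && exp$t < T1 - 1e-9) {
    if (!walkTo(exp, homeGate) || !walkTo(exp, tunnelIn) ||
        !walkTo(exp, tunnelMid)) break
    sh0 <- exp$t
    shEnd <- hold(exp, stats::rexp(1, 1 / par$shelterMeanS),
                  "tunnel_shelter")
    addEvent("First Tunnel Sheltering", sh0, shEnd)
    if (exp$t >= T1 - 1e-9) break
    if (stats::runif(1) < par$reverseProb) {
      rv0 <- exp$t
      ok <- walkTo(exp, tunnelIn, "reverse", speed / 2)
      addEvent("Reverse in Tunnel", rv0, exp$t)
      if (!ok || !walkTo(exp, homeGate)) break
      wander(exp, min(exp$t + stats::rexp(1, 1 / 5), T1), hx, hy)
    } else {
      if (walkTo(exp, tunnelOut) && walkTo(exp, socialGate))
        entered <- TRUE
    }
  }

  # -- dyadic interaction loop ---------------------------------------------
  if (entered) {
    zone <- "social"
    while (exp$t < T1 - 1e-9) {
      if (zone == "social") {
        rates <- c(init = par$initRate, sniff = par$sniffRate,
                   cons = par$consSniffRate, agg = par$aggressionRate,
                   groom = par$groomRate, jump = par$jumpRate,
                   nsf = par$nsFreezeRateTest, home = par$homeReturnRate) / 60
        dt <- stats::rexp(1, sum(rates))
        tEvt <- exp$t + dt
        if (tEvt >= T1) { wander(exp, T1, sx, sy); break }
        wander(exp, tEvt, sx, sy)
        syncCon(tEvt)
        what <- sample(names(rates), 1L, prob = rates)
        t <- exp$t
        if (what %in% c("init", "sniff")) {
          if (what == "init") {
            gap <- sqrt(sum((exp$pos - con$pos)^2))
            if (gap < 8) {  # reposition so the approach closes a real gap
              away <- exp$pos + (exp$pos - con$pos) /
                max(gap, 1e-6) * (10 - gap)
              away[1] <- min(max(away[1], sx[1] + 2), sx[2] - 2)
              away[2] <- min(max(away[2], sy[1] + 2), sy[2] - 2)
              walkTo(exp, away)
            }
            addEvent("Social Initiation", exp$t)
          }
          tgt <- con$pos + (exp$pos - con$pos) /
            max(sqrt(sum((exp$pos - con$pos)^2)), 1e-6) * 1.8
          walkTo(exp, tgt, "locomote", 10)
          if (exp$t < T1 - 1e-9) {
            sub <- sample(c("sniff_face", "sniff_body", "sniff_anogenital",
                            "sniff_tail"), 1L,
                          prob = c(0.4, 0.3, 0.2, 0.1))
            lab <- c(sniff_face = "Face Sniff", sniff_body = "Body Sniff",
                     sniff_anogenital = "Anogenital Sniff",
                     sniff_tail = "Tail Sniff")[[sub]]
            s0 <- exp$t
            sEnd <- hold(exp, stats::rexp(1, 1 / par$sniffMeanS), sub)
            hold(con, sEnd - con$t, "idle")  # stays put while being sniffed
            addEvent(lab, s0, sEnd)
          }
        } else if (what == "cons") {
          syncCon(exp$t)
          tgt <- exp$pos + (con$pos - exp$pos) /
            max(sqrt(sum((con$pos - exp$pos)^2)), 1e-6) * 1.8
          walkTo(con, tgt, "locomote", 10)
          tA <- con$t
          if (tA < T1 - 1e-9) {
            addEvent("Conspecific Sniff", tA, actor = "conspecific")
            bEnd <- hold(con, stats::rexp(1, 1 / 1.5), "sniff_body")
            hold(exp, bEnd - exp$t, "idle")
            u <- stats::runif(1)
            if (u < par$pFreeze) {
              f0 <- exp$t
              fEnd <- hold(exp, stats::rexp(1, 1 / par$freezeMeanS),
                           "social_freeze")
              addEvent("Social Freeze", f0, fEnd)
            } else if (u < par$pFreeze + par$pReact) {
              addEvent("Social Reactivity", exp$t)
              ang <- stats::runif(1, 0, 2 * pi)
              tgt <- exp$pos + 6 * c(cos(ang), sin(ang))
              tgt[1] <- min(max(tgt[1], sx[1] + 2), sx[2] - 2)
              tgt[2] <- min(max(tgt[2], sy[1] + 2), sy[2] - 2)
              walkTo(exp, tgt, "dart", 18)
            }
          }
        } else if (what == "agg") {
          syncCon(exp$t)
          tgt <- con$pos + (exp$pos - con$pos) /
            max(sqrt(sum((exp$pos - con$pos)^2)), 1e-6) * 1.5
          walkTo(exp, tgt, "locomote", 12)
          if (exp$t < T1 - 1e-9) {
            a0 <- exp$t
            aEnd <- hold(exp, stats::rexp(1, 1 / par$aggMeanS), "aggress")
            hold(con, aEnd - con$t, "locomote")
            addEvent("Aggression", a0, aEnd)
          }
        } else if (what == "groom") {
          g0 <- exp$t
          gEnd <- hold(exp, stats::rexp(1, 1 / par$groomMeanS), "groom")
          addEvent("Groom", g0, gEnd)
        } else if (what == "jump") {
          addEvent("Jump", exp$t)
          hold(exp, 0.3, "jump")
        } else if (what == "nsf") {
          f0 <- exp$t
          fEnd <- hold(exp, stats::rexp(1, 1 / par$nsFreezeMeanS),
                       "nonsocial_freeze")
          addEvent("Non-social Freeze", f0, fEnd)
        } else { # home visit
          if (walkTo(exp, socialGate) && walkTo(exp, tunnelOut) &&
              walkTo(exp, tunnelIn) && walkTo(exp, homeGate)) {
            zone <- "home"
            wander(exp, min(exp$t + stats::rexp(1, 1 / par$homeDwellMeanS),
                            T1), hx, hy)
          }
        }
      } else { # back from a home visit
        if (walkTo(exp, homeGate) && walkTo(exp, tunnelIn) &&
            walkTo(exp, tunnelOut) && walkTo(exp, socialGate))
          zone <- "social"
        else break
      }
    }
  }
  if (exp$t < T1 - 1e-9) {
    if (exp$pos[1] >= sx[1]) wander(exp, T1, sx, sy)
    else if (exp$pos[1] <= hx[2]) wander(exp, T1, hx, hy)
    else hold(exp, T1 - exp$t, "idle")  # truncated mid-tunnel
  }
  syncCon(T1)
  if (con$t < T1 - 1e-9) hold(con, T1 - con$t, "idle")

  # -- rasterize ------------------------------------------------------------
  tfr <- frameTimes(nfr, fps)
  rasterize <- function(a, tStart) {
    s <- bufAsList(a$buf)
    use <- tfr >= tStart
    idx <- findInterval(tfr[use], s$t0)
    idx <- pmin(pmax(idx, 1L), length(s$t0))
    len <- s$t1[idx] - s$t0[idx]
    frac <- ifelse(len > 0, (tfr[use] - s$t0[idx]) / len, 0)
    frac <- pmin(pmax(frac, 0), 1)
    list(use = use, idx = idx,
         px = s$x0[idx] + frac * (s$x1[idx] - s$x0[idx]),
         py = s$y0[idx] + frac * (s$y1[idx] - s$y0[idx]),
         state = s$state[idx])
  }
  expR <- rasterize(exp, 0)
  conR <- rasterize(con, T0)

  placeNodes <- function(r, nframesTotal) {
    n <- nframesTotal
    px <- rep(NA_real_, n); py <- rep(NA_real_, n)
    st <- rep("absent", n)
    px[r$use] <- r$px; py[r$use] <- r$py; st[r$use] <- r$state
    # heading from segment direction, carried over stationary segments
    dx <- c(0, diff(px)); dy <- c(0, diff(py))
    mov <- which(is.finite(dx) & (abs(dx) + abs(dy)) > 1e-6)
    th <- rep(NA_real_, n)
    th[mov] <- atan2(dy[mov], dx[mov])
    # forward-fill, then default
    known <- !is.na(th)
    if (any(known)) {
      last <- cummax(ifelse(known, seq_len(n), 0L))
      has <- last > 0L
      th[has] <- th[last[has]]
    }
    th[is.na(th)] <- 0
    # smooth heading over ~5 frames via unit vectors
    k <- rep(1 / 5, 5)
    cs <- stats::filter(cos(th), k, sides = 2)
    sn <- stats::filter(sin(th), k, sides = 2)
    ok <- !is.na(cs)
    th[ok] <- atan2(sn[ok], cs[ok])
    pt <- postureTable()
    si <- match(st, rownames(pt))
    si[is.na(si)] <- match("idle", rownames(pt))
    # per-segment oscillation phase and lateral signs
    fidx <- integer(n)
    fidx[r$use] <- r$idx
    segChange <- c(TRUE, (st[-1] != st[-n]) | (diff(fidx) != 0L))
    segId <- cumsum(segChange)
    nseg <- max(segId)
    phase <- stats::runif(nseg, 0, 2 * pi)[segId]
    ysign <- sample(c(-1, 1), nseg, replace = TRUE)[segId]
    osc <- pt[si, 4] * sin(2 * pi * pt[si, 5] * tfr + phase)
    yaw <- ysign * pt[si, 1] + osc
    bend <- ysign * pt[si, 2] + pt[si, 4] *
      sin(2 * pi * pt[si, 5] * tfr + phase + 1.3)
    spread <- pt[si, 3]
    co <- array(NA_real_, c(n, 8, 2))
    u <- function(a) cbind(cos(a), sin(a))
    trunk <- cbind(px, py)
    headDir <- th + 0.5 * yaw
    noseDir <- th + yaw
    head <- trunk + 1.5 * u(headDir)
    rear <- th + pi + bend
    co[, 1, ] <- head + 1.0 * u(noseDir)            # nose
    co[, 2, ] <- head                               # head
    co[, 3, ] <- head + 0.6 * u(noseDir + 1.92)     # left_ear
    co[, 4, ] <- head + 0.6 * u(noseDir - 1.92)     # right_ear
    co[, 5, ] <- trunk                              # trunk
    co[, 6, ] <- trunk + 0.9 * u(rear + spread)     # left_hip
    co[, 7, ] <- trunk + 0.9 * u(rear - spread)     # right_hip
    co[, 8, ] <- trunk + 1.6 * u(rear)              # tail_base
    list(co = co, state = st, present = r$use)
  }
  pe <- placeNodes(expR, nfr)
  pc <- placeNodes(conR, nfr)
  co <- array(NA_real_, c(nfr, 2, 8, 2))
  co[, 1, , ] <- pe$co
  co[, 2, , ] <- pc$co
  if (config$jitterSd > 0)
    co <- co + stats::rnorm(length(co), 0, config$jitterSd)
  valid <- array(TRUE, c(nfr, 2, 8))
  valid[, 1, ] <- pe$present
  valid[, 2, ] <- pc$present
  if (config$missingRate > 0)
    valid <- valid & (array(stats::runif(length(valid)), dim(valid)) >=
                        config$missingRate)
  traj <- KeypointTrajectory(co, valid = valid & !is.na(co[, , , 1]),
                             fps = fps)
  if (config$swapRate > 0) {
    traj <- injectArtifacts(traj, missingRate = 0,
                            swapRate = config$swapRate,
                            seed = seed + 1L)$trajectory
  }

  evdf <- data.frame(behavior = ev$behavior, actor = ev$actor,
                     event_type = ev$type, onset = ev$onset,
                     offset = ev$offset, stringsAsFactors = FALSE)
  log <- EventLog(evdf)
  session <- SessionRecord(subjectId, condition, traj, log, sex = sex,
                           baselineSpan = c(0, T0), testSpan = c(T0, T1))

  # -- ground-truth summaries from realized frames + emitted events ---------
  truth <- makeGroundTruth(session, cbind(pe$state, pc$state), evdf,
                           hx, hy, tx, ty, sx, sy, condition)
  list(session = session, truth = truth)
}

# Summaries recomputed by the generator's own (rectangle-based) code, kept
# independent of classifyZones/scoreSession.
makeGroundTruth <- function(session, states, evdf, hx, hy, tx, ty, sx, sy,
                            condition) {
  traj <- session@trajectory
  fps <- traj@fps
  nfr <- nFrames(traj)
  T0 <- session@testSpan[1]; T1 <- session@testSpan[2]
  tfr <- frameTimes(nfr, fps)
  x <- traj@coords[, 1, 5, 1]; y <- traj@coords[, 1, 5, 2]
  vok <- traj@valid[, 1, 5]
  zone <- rep("unknown", nfr)
  i <- which(vok)
  zone[i][x[i] >= hx[1] & x[i] <= hx[2] & y[i] >= hy[1] & y[i] <= hy[2]] <- "home"
  zone[i][x[i] > tx[1] & x[i] < tx[2] & y[i] >= ty[1] & y[i] <= ty[2]] <- "tunnel"
  zone[i][x[i] >= sx[1] & x[i] <= sx[2] & y[i] >= sy[1] & y[i] <= sy[2]] <- "social"
  test <- tfr >= T0 & tfr < T1
  base <- tfr < T0
  socialFrames <- which(test & zone == "social")
  firstEntry <- if (length(socialFrames)) tfr[socialFrames[1]] else NA_real_
  dur <- function(b, lo, hi) {
    r <- evdf$behavior == b & evdf$event_type == "state"
    sum(pmax(0, pmin(evdf$offset[r], hi) - pmax(evdf$onset[r], lo)))
  }
  cnt <- function(b, lo, hi)
    sum(evdf$behavior == b & evdf$onset >= lo & evdf$onset < hi)
  cutoff <- if (is.na(firstEntry)) T1 else firstEntry
  shr <- evdf$behavior == "First Tunnel Sheltering" & evdf$onset < cutoff
  firstShelter <- sum(pmax(0, pmin(evdf$offset[shr], cutoff) -
                             pmax(evdf$onset[shr], T0)))
  cons <- cnt("Conspecific Sniff", T0, T1)
  react <- cnt("Social Reactivity", T0, T1)
  bi <- which(base & vok)
  thig <- if (length(bi)) {
    wall <- pmin(x[bi] - hx[1], hx[2] - x[bi], y[bi] - hy[1], hy[2] - y[bi])
    100 * mean(wall <= 2)
  } else NA_real_
  summ <- c(
    face_sniff_s = dur("Face Sniff", T0, T1),
    body_sniff_s = dur("Body Sniff", T0, T1),
    anogenital_sniff_s = dur("Anogenital Sniff", T0, T1),
    tail_sniff_s = dur("Tail Sniff", T0, T1),
    all_sniff_s = dur("Face Sniff", T0, T1) + dur("Body Sniff", T0, T1) +
      dur("Anogenital Sniff", T0, T1) + dur("Tail Sniff", T0, T1),
    conspecific_sniff_bouts = cons,
    social_reactivity_pct = if (cons == 0) NA_real_ else 100 * react / cons,
    social_freeze_s = dur("Social Freeze", T0, T1),
    first_tunnel_shelter_s = firstShelter,
    reverse_count = cnt("Reverse in Tunnel", T0, T1),
    reverse_s = dur("Reverse in Tunnel", T0, T1),
    latency_to_social_s = if (is.na(firstEntry)) NA_real_ else
      firstEntry - T0,
    prosocial_initiations = cnt("Social Initiation", T0, T1),
    chamber_preference_pct = 100 * mean(zone[test] == "social"),
    groom_s = dur("Groom", T0, T1),
    nonsocial_freeze_baseline_s = dur("Non-social Freeze", 0, T0),
    nonsocial_freeze_test_s = dur("Non-social Freeze", T0, T1),
    aggression_s = dur("Aggression", T0, T1),
    jump_count = cnt("Jump", T0, T1),
    thigmotaxis_pct = thig)
  new("GroundTruth", states = states, condition = condition,
      summaries = summ)
}

#' Simulate a balanced two-condition cohort
#'
#' \code{2 * nPerGroup} sessions with per-session seeds derived from the
#' master seed by a splittable counter scheme, so cohorts are reproducible
#' and sessions independent.
#'
#' @param config see \code{\link{generatorConfig}}.
#' @param nPerGroup sessions per condition (>= 1).
#' @param conditions pair of labels present in \code{config$conditions}.
#' @param seed master seed.
#' @return list of list(session=, truth=), conditions interleaved
#'   group-by-group with ids "<condition>_<k>".
#' @export
simulateCohort <- function(config = generatorConfig(), nPerGroup = 18L,
                           conditions = c("GH", "SI"), seed = 1L) {
  stopifnot(nPerGroup >= 1L, length(conditions) == 2L)
  labels <- rep(conditions, each = nPerGroup)
  lapply(seq_along(labels), function(i) {
    simulateSession(config, labels[i], seed = deriveSeed(seed, i),
                    subjectId = sprintf("%s_%02d", labels[i],
                                        ((i - 1L) %% nPerGroup) + 1L))
  })
}
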