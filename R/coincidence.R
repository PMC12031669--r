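#' Triple-coincidence grouping configuration
#'
#' Time and energy gates for grouping a singles stream into prompt triple
#' coincidences. Each energy-gated 511-keV single is taken in turn as the
#' reference event; a forward window of width `pair_window` collects the
#' second 511-keV photon, and prompt-gamma candidates are collected in
#' `[reference - pg_window_before, reference + pg_window_after]`. The
#' prompt-gamma window must be wide enough to contain every lifetime
#' measurement the reconstruction and correction windows require.
#'
#' @param pair_window Max time difference between the two 511-keV singles, ns.
#' @param pg_window_before,pg_window_after Prompt-gamma window extent before
#'   and after the reference 511-keV event, ns.
#' @param e511_low,e511_high 511-keV energy window, keV.
#' @param pg_threshold Lower prompt-gamma energy threshold, keV.
#' @param pg_high Upper prompt-gamma energy bound, keV (`Inf` = unbounded).
#' @param windows Optional [time_windows()]; when given, the prompt-gamma
#'   window is checked to cover both of its intervals.
#' @return An object of class `grouping_config`.
#' @export
grouping_config <- function(pair_window = 1,
                            pg_window_before = 25, pg_window_after = 25,
                            e511_low = 430, e511_high = 650,
                            pg_threshold = 700, pg_high = Inf,
                            windows = NULL) {
  if (pair_window <= 0) stop("`pair_window` must be positive (ns)")
  if (pg_window_before < 0 || pg_window_after < 0)
    stop("prompt-gamma window extents must be nonnegative")
  if (!is.null(windows)) {
    need <- range(windows$t_r1, windows$t_r2, windows$t_c1, windows$t_c2)
    # tau ~= t_ref - t_pg, so the PG window must reach [-need2, -need1]
    if (-pg_window_after > need[1] || pg_window_before < need[2])
      stop("prompt-gamma window too narrow for the requested time windows")
  }
  structure(list(pair_window = pair_window,
                 pg_window_before = pg_window_before,
                 pg_window_after = pg_window_after,
                 e511_low = e511_low, e511_high = e511_high,
                 pg_threshold = pg_threshold, pg_high = pg_high),
            class = "grouping_config")
}

#' Group a singles stream into prompt triple coincidences
#'
#' Take-all-good grouping: every eligible (pair, prompt gamma) combination
#' is emitted. The earlier 511-keV single of each pair is the reference; a
#' forward window of width `pair_window` forms the pair and all energy-gated
#' prompt gammas within the prompt-gamma window of the reference join it.
#' Window boundaries are closed (ties kept).
#'
#' @param singles A time-sorted data.frame with columns `time`, `crystal`,
#'   `energy` (and optionally `decay_id`), as from [simulate_singles()].
#' @param cfg A [grouping_config()].
#' @param dedup Drop duplicate triples that share the same three singles
#'   (can arise when both 511s act as reference for symmetric windows);
#'   default `FALSE` (keep all).
#' @return A data.frame of triple precursors with columns `c1`, `c2`, `cpg`
#'   (crystal ids; `c1` is the reference/earlier 511), `t1`, `t2`, `tpg`
#'   (detection times, ns), `e1`, `e2`, `epg` (keV) and, when `decay_id` is
#'   present, `id1`, `id2`, `idpg`.
#' @export
group_triples <- function(singles, cfg = grouping_config(), dedup = FALSE) {
  if (nrow(singles) == 0L)
    return(data.frame(c1 = integer(0), c2 = integer(0), cpg = integer(0),
                      t1 = numeric(0), t2 = numeric(0), tpg = numeric(0),
                      e1 = numeric(0), e2 = numeric(0), epg = numeric(0)))
  if (is.unsorted(singles$time)) stop("singles stream must be time-sorted")
  has_id <- "decay_id" %in% names(singles)
  is511 <- singles$energy >= cfg$e511_low & singles$energy <= cfg$e511_high
  ispg <- singles$energy >= cfg$pg_threshold & singles$energy <= cfg$pg_high
  i511 <- which(is511)
  ipg <- which(ispg)
  if (length(i511) < 2L || length(ipg) == 0L)
    return(group_triples(singles[0, , drop = FALSE], cfg))
  t511 <- singles$time[i511]
  tpg <- singles$time[ipg]
  # for each reference r: partner 511s in (t_r, t_r + pair_window]
  # (strictly later so a pair is formed once, by its earlier member)
  p_hi <- findInterval(t511 + cfg$pair_window, t511)
  # pg candidates in [t_r - before, t_r + after]
  g_lo <- findInterval(t511 - cfg$pg_window_before, tpg, left.open = TRUE) + 1L
  g_hi <- findInterval(t511 + cfg$pg_window_after, tpg)
  out <- vector("list", length(i511))
  for (r in seq_along(i511)) {
    np <- p_hi[r] - r
    ng <- g_hi[r] - g_lo[r] + 1L
    if (np < 1L || ng < 1L) next
    partners <- i511[(r + 1L):p_hi[r]]
    pgs <- ipg[g_lo[r]:g_hi[r]]
    cmb <- expand.grid(p = partners, g = pgs)
    ref <- i511[r]
    out[[r]] <- data.frame(
      c1 = singles$crystal[ref], c2 = singles$crystal[cmb$p],
      cpg = singles$crystal[cmb$g],
      t1 = singles$time[ref], t2 = singles$time[cmb$p],
      tpg = singles$time[cmb$g],
      e1 = singles$energy[ref], e2 = singles$energy[cmb$p],
      epg = singles$energy[cmb$g],
      id1 = if (has_id) singles$decay_id[ref] else NA_integer_,
      id2 = if (has_id) singles$decay_id[cmb$p] else NA_integer_,
      idpg = if (has_id) singles$decay_id[cmb$g] else NA_integer_
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(group_triples(singles[0, , drop = FALSE], cfg))
  if (!has_id) out$id1 <- out$id2 <- out$idpg <- NULL
  if (dedup) out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Rebuild a singles stream from recorded double coincidences
#'
#' Flattens a list of double-coincidence records (two singles each),
#' discards exact repeats of `(time, crystal, energy)` — the same single can
#' appear in several doubles under a take-all-good pairing — and time-sorts.
#'
#' @param doubles A data.frame with columns `t1`, `t2`, `c1`, `c2`,
#'   `e1`, `e2` (one row per double coincidence).
#' @return A time-sorted singles data.frame (`time`, `crystal`, `energy`).
#' @export
rebuild_singles <- function(doubles) {
  s <- rbind(
    data.frame(time = doubles$t1, crystal = doubles$c1, energy = doubles$e1),
    data.frame(time = doubles$t2, crystal = doubles$c2, energy = doubles$e2)
  )
  s <- unique(s)
  s <- s[order(s$time), ]
  rownames(s) <- NULL
  s
}

#' Travel-time-corrected lifetime measurement
#'
#' Corrects the detection times of a triple coincidence for photon flight:
#' the pair emission time is `t_511 = (t1 + t2 - d_lor/c) / 2` and the
#' prompt-gamma emission time is its detection time minus `pg_path / c`,
#' giving `tau = t_511 - t_pg_emission`.
#'
#' @param t1,t2 Detection times of the two 511-keV photons, ns.
#' @param t_pg Detection time of the prompt gamma, ns.
#' @param d_lor Distance between the two 511-keV detectors, mm.
#' @param pg_path Distance from the (TOF-inferred) annihilation point to the
#'   prompt-gamma detector, mm.
#' @return Lifetime measurement `tau`, ns (vectorised).
#' @export
travel_time_correct <- function(t1, t2, t_pg, d_lor, pg_path) {
  if (any(d_lor <= 0)) stop("`d_lor` must be positive (mm)")
  t511 <- (t1 + t2 - d_lor / .c_mm_ns) / 2
  t511 - (t_pg - pg_path / .c_mm_ns)
}

#' Lifetime measurement from a crystal triple
#'
#' Infers the annihilation point as the most likely TOF position along the
#' LOR (the Gaussian-mean/centroid reading of the pair time difference),
#' computes the prompt-gamma path from that point, and applies
#' [travel_time_correct()].
#'
#' @param geom A [ring_geometry()].
#' @param c1,c2 Crystal ids of the 511-keV photons (1-based, vectorised).
#' @param cpg Crystal id of the prompt gamma.
#' @param t1,t2,tpg Detection times, ns.
#' @return Lifetime measurements, ns.
#' @export
lifetime_from_triple <- function(geom, c1, c2, cpg, t1, t2, tpg) {
  x1 <- geom$crystal_x[c1]; y1 <- geom$crystal_y[c1]
  x2 <- geom$crystal_x[c2]; y2 <- geom$crystal_y[c2]
  L <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  # distance of the inferred annihilation point from crystal c1
  d1 <- (L + .c_mm_ns * (t1 - t2)) / 2
  f <- d1 / L
  qx <- x1 + f * (x2 - x1); qy <- y1 + f * (y2 - y1)
  pg_path <- sqrt((qx - geom$crystal_x[cpg])^2 + (qy - geom$crystal_y[cpg])^2)
  travel_time_correct(t1, t2, tpg, L, pg_path)
}

#' Convert grouped triple precursors to binned PLI events
#'
#' Computes the travel-time-corrected lifetime measurement and the
#' `(LOR, TOF bin)` address of each grouped triple. Triples whose crystal
#' pair is not an enumerated LOR or whose TOF bin falls outside the sinogram
#' are dropped.
#'
#' @param precursors Output of [group_triples()].
#' @param geom A [ring_geometry()].
#' @return A data.frame with columns `lor`, `tof_bin`, `tau` (and
#'   provenance ids when present in `precursors`).
#' @export
triples_to_events <- function(precursors, geom) {
  if (nrow(precursors) == 0L)
    return(data.frame(lor = integer(0), tof_bin = integer(0),
                      tau = numeric(0)))
  tau <- lifetime_from_triple(geom, precursors$c1, precursors$c2,
                              precursors$cpg, precursors$t1, precursors$t2,
                              precursors$tpg)
  a <- pmin(precursors$c1, precursors$c2)
  b <- pmax(precursors$c1, precursors$c2)
  ta <- ifelse(precursors$c1 <= precursors$c2, precursors$t1, precursors$t2)
  tb <- ifelse(precursors$c1 <= precursors$c2, precursors$t2, precursors$t1)
  lor <- geom$lor_lookup[cbind(a, b)]
  k <- as.integer(round((ta - tb) / geom$tof_bin_width))
  k0 <- (geom$n_tof_bins - 1L) %/% 2L
  ok <- !is.na(lor) & abs(k) <= k0 & a != b
  ev <- data.frame(lor = lor[ok], tof_bin = k[ok], tau = tau[ok])
  if ("id1" %in% names(precursors)) {
    ev$id1 <- precursors$id1[ok]
    ev$id2 <- precursors$id2[ok]
    ev$idpg <- precursors$idpg[ok]
  }
  ev
}

#' Gate events into reconstruction and correction windows
#'
#' Events with `tau` in the reconstruction window are kept for
#' reconstruction; events in the correction window are only counted (they
#' estimate the type I randoms level); all others are dropped. Both windows
#' are closed intervals.
#'
#' @param events A data.frame with at least columns `lor`, `tof_bin`, `tau`.
#' @param windows A [time_windows()].
#' @return List with `recon_events` (gated data.frame) and
#'   `correction_count` (integer).
#' @export
gate_and_bin <- function(events, windows) {
  stopifnot(inherits(windows, "time_windows"))
  in_rec <- events$tau >= windows$t_r1 & events$tau <= windows$t_r2
  in_cor <- events$tau >= windows$t_c1 & events$tau <= windows$t_c2
  list(recon_events = events[in_rec, , drop = FALSE],
       correction_count = sum(in_cor))
}
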