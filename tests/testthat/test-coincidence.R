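mk_stream <- function(time, energy, crystal = seq_along(time)) {
  o <- order(time)
  data.frame(time = time[o], crystal = crystal[o], energy = energy[o])
}

test_that("grouping hand cases follow the take-all-good policy", {
  cfg <- grouping_config(pair_window = 1, pg_window_before = 25,
                         pg_window_after = 25)
  s <- mk_stream(c(0.0, 0.3, -0.5), c(511, 511, 1157))
  tr <- group_triples(s, cfg)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$t1, 0.0)   # earlier 511 is the reference
  expect_equal(tr$t2, 0.3)
  expect_equal(tr$tpg, -0.5)

  # two prompt gammas in the window -> two triples from the same pair
  s2 <- mk_stream(c(0.0, 0.3, -0.5, 2.0), c(511, 511, 1157, 1200))
  expect_equal(nrow(group_triples(s2, cfg)), 2L)

  # empty stream and no-PG stream
  expect_equal(nrow(group_triples(s[0, ], cfg)), 0L)
  s3 <- mk_stream(c(0, 0.3), c(511, 511))
  expect_equal(nrow(group_triples(s3, cfg)), 0L)

  expect_error(group_triples(data.frame(time = c(1, 0), crystal = 1:2,
                                        energy = c(511, 511)), cfg),
               "sorted")
})

test_that("grouping equals the brute-force triple-loop oracle", {
  brute_force <- function(s, cfg) {
    is5 <- s$energy >= cfg$e511_low & s$energy <= cfg$e511_high
    ispg <- s$energy >= cfg$pg_threshold & s$energy <= cfg$pg_high
    out <- list()
    for (i in seq_len(nrow(s))) for (j in seq_len(nrow(s))) {
      if (!is5[i] || !is5[j]) next
      if (!(s$time[j] > s$time[i] &&
            s$time[j] <= s$time[i] + cfg$pair_window)) next
      for (g in which(ispg)) {
        if (s$time[g] >= s$time[i] - cfg$pg_window_before &&
            s$time[g] <= s$time[i] + cfg$pg_window_after)
          out[[length(out) + 1L]] <- c(i, j, g)
      }
    }
    if (!length(out)) return(matrix(integer(0), 0, 3))
    do.call(rbind, out)
  }
  cfg <- grouping_config(pair_window = 1, pg_window_before = 20,
                         pg_window_after = 5)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:100, 1)
    s <- mk_stream(runif(n, 0, 50),
                   sample(c(450, 511, 600, 800, 1157, 300), n,
                          replace = TRUE),
                   crystal = sample.int(64, n, replace = TRUE))
    got <- group_triples(s, cfg)
    want <- brute_force(s, cfg)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      key <- function(t1, t2, tg) paste(t1, t2, tg)
      expect_setequal(key(got$t1, got$t2, got$tpg),
                      key(s$time[want[, 1]], s$time[want[, 2]],
                          s$time[want[, 3]]))
    }
  }
})

test_that("singles are rebuilt from doubles with exact deduplication", {
  d <- data.frame(t1 = c(0, 0), t2 = c(1, 2), c1 = c(5, 5), c2 = c(9, 11),
                  e1 = c(511, 511), e2 = c(511, 520))
  s <- rebuild_singles(d)
  expect_equal(nrow(s), 3L)       # shared reference single deduplicated
  expect_false(is.unsorted(s$time))
  d2 <- data.frame(t1 = c(0, 5), t2 = c(1, 6), c1 = c(1, 2), c2 = c(3, 4),
                   e1 = c(511, 511), e2 = c(511, 511))
  expect_equal(nrow(rebuild_singles(d2)), 4L)
})

test_that("travel-time correction follows the printed formula", {
  c_l <- speed_of_light()
  # symmetric source at the centre
  expect_equal(travel_time_correct(0.5, 0.5, 100 / c_l, c_l, 100), 0)
  # hand arithmetic: t511 = (0.6 + 0.6 - 1)/2 = 0.1, corrected t_PG = 0
  expect_equal(travel_time_correct(0.6, 0.6, 50 / c_l, c_l * 1.0, 50), 0.1)
  # time-origin invariance
  t0 <- travel_time_correct(0.6, 0.8, 0.1, 400, 180)
  t5 <- travel_time_correct(5.6, 5.8, 5.1, 400, 180)
  expect_equal(t0, t5, tolerance = 1e-12)
  expect_error(travel_time_correct(0, 0, 0, -1, 10), "positive")
})

test_that("noiseless grouped triples recover the generated lifetime exactly", {
  phan <- mid_phantom()
  geom <- mid_geom()
  # short duration keeps absolute times small so the 1e-9 ns check is not
  # limited by double-precision cancellation in t1 + t2
  s <- simulate_singles(phan, geom, duration = 1e6, activity_bq = 3e6,
                        energy_res = 0, efficiency = 1, single_sigma = 0,
                        seed = 6)
  truth <- attr(s, "decays")
  cfg <- grouping_config(pair_window = 1, pg_window_before = 25,
                         pg_window_after = 25)
  tr <- group_triples(s, cfg)
  # keep triples whose three singles share one decay (true triples)
  own <- tr$id1 == tr$id2 & tr$id1 == tr$idpg
  tau <- lifetime_from_triple(geom, tr$c1[own], tr$c2[own], tr$cpg[own],
                              tr$t1[own], tr$t2[own], tr$tpg[own])
  want <- truth$tau[match(tr$id1[own], truth$decay_id)]
  expect_gt(sum(own), 0.9 * nrow(truth))
  expect_lt(max(abs(tau - want)), 1e-9)
})

test_that("grouping recovers nearly all generated true triples", {
  phan <- mid_phantom()
  geom <- mid_geom()
  s <- simulate_singles(phan, geom, duration = 1e9, activity_bq = 5e3,
                        energy_res = 0.13, efficiency = 1,
                        seed = 16)
  truth <- attr(s, "decays")
  cfg <- grouping_config()
  tr <- group_triples(s, cfg)
  own <- tr$id1 == tr$id2 & tr$id1 == tr$idpg
  # loss only from energy-blur tails of the gates
  expect_gt(sum(own) / nrow(truth), 0.9)
  ev <- triples_to_events(tr, geom)
  expect_true(all(c("lor", "tof_bin", "tau") %in% names(ev)))
})

test_that("events are gated into reconstruction and correction windows", {
  wins <- time_windows(c(-1, 15), c(-20, -5))
  ev <- data.frame(lor = 1:5, tof_bin = 0L,
                   tau = c(16, -10, 7, -1, 15))
  g <- gate_and_bin(ev, wins)
  expect_equal(g$correction_count, 1L)
  expect_equal(sort(g$recon_events$tau), c(-1, 7, 15))  # closed bounds kept
  all_in <- data.frame(lor = 1:3, tof_bin = 0L, tau = c(0, 5, 10))
  expect_equal(gate_and_bin(all_in, wins)$correction_count, 0L)
})
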