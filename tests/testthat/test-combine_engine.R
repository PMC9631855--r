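track <- function(b, e, id = "r", N = 10000, phen = "trembling", trig = "FOG_Target") {
  if (length(b) == 0L) return(fog_track(NULL, id, "t", N))
  fog_track(data.frame(begin_ms = b, end_ms = e,
                       phenotype = rep_len(phen, length(b)),
                       trigger = rep_len(trig, length(b))), id, "t", N)
}

test_that("partition_timeline separates black, white and gray correctly", {
  # identical annotations: no gray at all
  p <- partition_timeline(track(1000, 4000), track(1000, 4000, "r2"))
  expect_equal(p$segments$color, c("white", "black", "white"))
  expect_equal(p$segments$begin_ms, c(0, 1000, 4000))

  # late-starting second rater: gray head classified 'preceding'
  p2 <- partition_timeline(track(1000, 4000), track(1500, 4000, "r2"))
  expect_equal(p2$segments$color, c("white", "gray", "black", "white"))
  expect_equal(p2$segments$gray_class[2], "preceding")
  expect_equal(p2$segments[2, c("begin_ms", "end_ms")],
               data.frame(begin_ms = 1000, end_ms = 1500, row.names = 2L))

  # an episode only one rater saw is an isolated gray
  p3 <- partition_timeline(track(1000, 2000), track(numeric(0), numeric(0), "r2"))
  expect_equal(p3$segments$color, c("white", "gray", "white"))
  expect_equal(p3$segments$gray_class[2], "isolated")

  # metadata mismatches are refused
  expect_error(partition_timeline(track(0, 1000),
                                  fog_track(NULL, "r2", "other", 10000)),
               "trial_id")
  expect_error(partition_timeline(track(0, 1000),
                                  fog_track(NULL, "r2", "t", 9000)),
               "trial_duration_ms")
})

test_that("gray classification covers all four neighbourhood cases", {
  a <- track(c(1000, 6000), c(3000, 8000))
  b <- track(c(1000, 3500, 6000), c(3000, 4000, 8000), "r2")
  # gray [3500,4000) is surrounded by white -> isolated
  p <- partition_timeline(a, b)
  g <- p$segments[p$segments$color == "gray", ]
  expect_equal(g$gray_class, "isolated")
  # enclosed: one rater bridges the other's two episodes
  a2 <- track(1000, 8000)
  b2 <- track(c(1000, 5000), c(4000, 8000), "r2")
  p2 <- partition_timeline(a2, b2)
  expect_equal(p2$segments$gray_class[p2$segments$color == "gray"], "enclosed")
  # following: gray tail after a black
  p3 <- partition_timeline(track(1000, 5000), track(1000, 4000, "r2"))
  expect_equal(p3$segments$gray_class[p3$segments$color == "gray"], "following")
})

test_that("resolve applies tolerance, correction and the isolation rule", {
  res_for <- function(a, b, tol, corr) {
    resolve_partition(partition_timeline(a, b), combine_config(tol, corr))
  }
  gray_out <- function(res) res$outcome[grepl("gray", res$provenance)]

  # short preceding gray: include -> FOG, exclude -> no_FOG
  a <- track(1000, 4000); b <- track(1500, 4000, "r2")   # 500 ms gray
  expect_equal(gray_out(res_for(a, b, 2000, "include")), "FOG")
  expect_equal(gray_out(res_for(a, b, 2000, "exclude")), "no_FOG")

  # 3 s preceding gray: substantial disagreement under either correction
  b3 <- track(4000, 7000, "r2"); a3 <- track(1000, 7000)
  expect_equal(gray_out(res_for(a3, b3, 2000, "include")), "discussion")
  expect_equal(gray_out(res_for(a3, b3, 2000, "exclude")), "discussion")

  # isolated grays are always discussed, however short
  ai <- track(5000, 5100); bi <- track(numeric(0), numeric(0), "r2")
  expect_equal(gray_out(res_for(ai, bi, 2000, "include")), "discussion")

  # tolerance 0 sends every non-isolated gray to discussion
  expect_equal(gray_out(res_for(a, b, 0, "include")), "discussion")
})

test_that("tolerance boundary: exactly 2000 ms resolvable, 2001 ms discussed", {
  a <- track(1000, 6000)
  res_eq <- resolve_partition(partition_timeline(a, track(3000, 6000, "r2")),
                              combine_config(2000, "include"))
  expect_equal(res_eq$outcome[res_eq$provenance == "gray-included"], "FOG")
  res_gt <- resolve_partition(partition_timeline(a, track(3001, 6000, "r2")),
                              combine_config(2000, "include"))
  expect_true(any(res_gt$provenance == "gray-long→discussion"))
})

test_that("merge_episodes fuses across included enclosed grays", {
  a <- track(0, 5000, N = 6000)
  b <- track(c(0, 2500), c(2000, 5000), "r2", N = 6000)  # enclosed gray [2000,2500)
  p <- partition_timeline(a, b)
  inc <- merge_episodes(resolve_partition(p, combine_config(2000, "include")))
  exc <- merge_episodes(resolve_partition(p, combine_config(2000, "exclude")))
  expect_equal(inc[, c("begin_ms", "end_ms")],
               data.frame(begin_ms = 0, end_ms = 5000))
  expect_equal(exc$begin_ms, c(0, 2500))
  expect_equal(exc$end_ms, c(2000, 5000))
  # no FOG at all -> empty episode list
  w <- resolve_partition(partition_timeline(track(numeric(0), numeric(0)),
                                            track(numeric(0), numeric(0), "r2")),
                         combine_config())
  expect_equal(nrow(merge_episodes(w)), 0L)
})

test_that("label disagreements are flagged; agreed labels are carried", {
  combo <- function(pa, pb, ta = "FOG_Target", tb = "FOG_Target") {
    combine_tracks(track(1000, 4000, phen = pa, trig = ta),
                   track(1000, 4000, "r2", phen = pb, trig = tb))
  }
  same <- combo("trembling", "trembling")$episodes
  expect_false(same$check_type)
  expect_equal(same$phenotype, "trembling")
  expect_equal(same$trigger, "FOG_Target")

  diff_type <- combo("trembling", "akinesia")$episodes
  expect_true(diff_type$check_type)
  expect_false(diff_type$check_trigger)

  diff_trig <- combo("trembling", "trembling", "FOG_Doorway", "FOG_Target")$episodes
  expect_true(diff_trig$check_trigger)
  expect_false(diff_trig$check_type)
})

test_that("included grays inherit labels from the bordering agreed episode", {
  a <- track(1000, 4000, phen = "akinesia", trig = "FOG_Doorway")
  b <- track(1500, 4000, "r2", phen = "akinesia", trig = "FOG_Doorway")
  res <- resolve_partition(partition_timeline(a, b), combine_config(2000, "include"))
  inc <- res[res$provenance == "gray-included", ]
  expect_equal(inc$phenotype, "akinesia")
  expect_equal(inc$trigger, "FOG_Doorway")
})

test_that("partition properties hold on randomized fixtures", {
  for (seed in 1:40) {
    pair <- random_pair(seed)
    p <- partition_timeline(pair$a, pair$b)
    seg <- p$segments
    # conservation: segments tile [0, N) exactly
    expect_equal(sum(seg$end_ms - seg$begin_ms), pair$N)
    expect_equal(seg$begin_ms[1], 0)
    expect_equal(seg$end_ms[nrow(seg)], pair$N)
    if (nrow(seg) > 1L) {
      expect_equal(seg$begin_ms[-1], seg$end_ms[-nrow(seg)])
      # maximality: adjacent segments differ in colour
      expect_true(all(seg$color[-1] != seg$color[-nrow(seg)]))
    }
    # rater symmetry: swapping raters leaves geometry and outcomes unchanged
    q <- partition_timeline(pair$b, pair$a)
    expect_equal(q$segments[, c("begin_ms", "end_ms", "color", "gray_class")],
                 seg[, c("begin_ms", "end_ms", "color", "gray_class")])
    cfg <- combine_config(sample(c(0, 500, 2000, 5000), 1), sample(c("include", "exclude"), 1))
    expect_equal(resolve_partition(q, cfg)$outcome, resolve_partition(p, cfg)$outcome)
  }
})

test_that("identical tracks give zero gray, zero discussion, identity episodes", {
  for (seed in 1:10) {
    pair <- random_pair(seed)
    a2 <- pair$a; a2$rater_id <- "r2"
    cmb <- combine_tracks(pair$a, a2)
    expect_false(any(cmb$partition$segments$color == "gray"))
    expect_equal(sum(cmb$resolved$outcome == "discussion"), 0L)
    expect_equal(cmb$episodes$begin_ms, pair$a$episodes$begin_ms)
    expect_equal(cmb$episodes$end_ms, pair$a$episodes$end_ms)
  }
})

test_that("percent_time_frozen reflects correction monotonicity", {
  pair <- fig2_tracks()
  inc <- combine_tracks(pair$a, pair$b, combine_config(2000, "include"))
  exc <- combine_tracks(pair$a, pair$b, combine_config(2000, "exclude"))
  expect_gte(percent_time_frozen(inc), percent_time_frozen(exc))
  expect_equal(percent_time_frozen(inc),
               100 * (4000 + 4000 + 3000) / 30000)
})
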