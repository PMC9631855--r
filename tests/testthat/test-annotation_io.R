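test_that("time dialects parse and format as exact millisecond inverses", {
  # the same instants in all three dialects parse to identical integers
  cases <- data.frame(
    ms = c("0", "1500", "4000", "2500", "3250", "3661234"),
    sms = c("0.000", "1.500", "4.000", "2.5", "3.25", "3661.234"),
    hms = c("00:00:00.000", "00:00:01.500", "00:00:04.000", "00:00:02.500",
            "00:00:03.250", "01:01:01.234"),
    want = c(0, 1500, 4000, 2500, 3250, 3661234)
  )
  expect_equal(parse_elan_time(cases$ms, "ms"), cases$want)
  expect_equal(parse_elan_time(cases$sms, "s.ms"), cases$want)
  expect_equal(parse_elan_time(cases$hms, "hh:mm:ss.ms"), cases$want)
  # auto sniffing: ":" -> hh:mm:ss.ms, "." -> s.ms, else ms
  expect_equal(parse_elan_time(c("00:00:02.500", "2.5", "2500"), "auto"),
               c(2500, 2500, 2500))
  for (d in c("ms", "s.ms", "hh:mm:ss.ms")) {
    set.seed(42)
    t <- sample.int(7200000L, 200L) - 1L
    expect_equal(parse_elan_time(format_elan_time(t, d), d), as.numeric(t),
                 info = d)
  }
})

test_that("read_elan_export parses rows, dialects and tier maps", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("FOG\t00:00:01.500\t00:00:04.000\ttrembling",
               "FOG\t00:00:10.000\t00:00:12.000\tShuffling"), path)
  tr <- read_elan_export(path, "hh:mm:ss.ms", rater_id = "r1")
  expect_equal(tr$episodes$begin_ms, c(1500, 10000))
  expect_equal(tr$episodes$end_ms, c(4000, 12000))
  expect_equal(tr$episodes$phenotype, c("trembling", "shuffling"))  # case-insensitive
  expect_equal(tr$trial_duration_ms, 12000)

  # s.ms dialect, header row detected and skipped, Duration column tolerated
  writeLines(c("Tier\tBegin Time\tEnd Time\tDuration\tAnnotation",
               "FOG\t2.5\t4.0\t1.5\takinesia",
               "FOG\t3.25\t5.0\t1.75\ttrembling"), path)
  tr2 <- read_elan_export(path, "s.ms")
  expect_equal(tr2$episodes$begin_ms, c(2500, 3250))
  tr2auto <- read_elan_export(path, "auto")
  expect_equal(tr2auto$episodes$begin_ms, tr2$episodes$begin_ms)

  # empty table: a rater may legitimately see no FOG
  writeLines("Tier\tBegin Time\tEnd Time\tDuration\tAnnotation", path)
  expect_equal(nrow(read_elan_export(path)$episodes), 0L)

  # unknown tiers ignored by default, an error in strict mode
  writeLines(c("FOG\t1000\t2000\ttrembling",
               "gait_task\t0\t5000\twalk"), path)
  expect_equal(nrow(read_elan_export(path, "ms")$episodes), 1L)
  expect_error(read_elan_export(path, "ms", strict = TRUE), "unknown tier")
})

test_that("read_elan_export reports malformed rows by number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("FOG\t1000\t2000\ttrembling", "FOG\tabc\t3000\ttrembling"), path)
  expect_error(read_elan_export(path, "ms"), "row 2.*abc")
  writeLines(c("FOG\t2000\t2000\ttrembling"), path)
  expect_error(read_elan_export(path, "ms"), "row 1.*not before")
})

test_that("triggers attach by majority overlap of the episode", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("FOG\t1000\t5000\ttrembling",
               "FOG\t10000\t14000\takinesia",
               "Trigger\t900\t4000\tFOG_Doorway",     # 3000/4000 overlap -> attach
               "Trigger\t13500\t16000\tFOG_Target"),  # 500/4000 overlap -> no
             path)
  tr <- read_elan_export(path, "ms", tier_map = list(fog = "FOG", trigger = "Trigger"))
  expect_equal(tr$episodes$trigger, c("FOG_Doorway", fog_unspecified))
})

test_that("normalize_track merges overlapping and abutting episodes", {
  mk <- function(b, e, p = "trembling") {
    fog_track(data.frame(begin_ms = b, end_ms = e, phenotype = p), "r", "t", 10000)
  }
  # abutting, same label -> single episode, label kept
  tr <- normalize_track(mk(c(0, 1000), c(1000, 2000)))
  expect_equal(tr$episodes$begin_ms, 0)
  expect_equal(tr$episodes$end_ms, 2000)
  expect_equal(tr$episodes$phenotype, "trembling")
  # overlapping, conflicting labels -> unspecified with a warning
  expect_warning(
    tr2 <- normalize_track(mk(c(0, 1000), c(1500, 2000), c("trembling", "shuffling"))),
    "phenotype")
  expect_equal(tr2$episodes$end_ms, 2000)
  expect_equal(tr2$episodes$phenotype, fog_unspecified)
  # disjoint episodes unchanged
  tr3 <- normalize_track(mk(c(0, 3000), c(1000, 4000)))
  expect_equal(nrow(tr3$episodes), 2L)
})

test_that("fog_track rejects invalid episodes", {
  expect_error(fog_track(data.frame(begin_ms = 0, end_ms = 0)), "zero-length")
  expect_error(fog_track(data.frame(begin_ms = -5, end_ms = 10)), ">= 0")
  expect_error(fog_track(data.frame(begin_ms = 0, end_ms = 10),
                         trial_duration_ms = 5), "trial_duration_ms")
})

test_that("write_resolved_table carries flags and survives a round trip", {
  pair <- fig2_tracks()
  cmb <- combine_tracks(pair$a, pair$b, combine_config(2000, "include"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_resolved_table(cmb, path, "hh:mm:ss.ms")
  back <- read_elan_export(path, "hh:mm:ss.ms",
                           tier_map = list(fog = "FOG_agreed", trigger = "FOG_trigger"))
  expect_equal(back$episodes$begin_ms, cmb$episodes$begin_ms)
  expect_equal(back$episodes$end_ms, cmb$episodes$end_ms)
  # flagged episodes announce their flags in the annotation value
  lines <- readLines(path)
  flagged <- cmb$episodes[cmb$episodes$check_type, , drop = FALSE]
  expect_gt(nrow(flagged), 0L)
  expect_true(any(grepl("check_type", lines)))
  # discussion rows present on their own tier
  disc <- read_elan_export(path, "hh:mm:ss.ms", tier_map = list(fog = "discussion"))
  want <- cmb$resolved[cmb$resolved$outcome == "discussion", ]
  expect_equal(disc$episodes$begin_ms, want$begin_ms)
  expect_equal(disc$episodes$end_ms, want$end_ms)
})

test_that("an empty resolution writes a header-only file", {
  empty <- data.frame(begin_ms = numeric(0), end_ms = numeric(0),
                      outcome = character(0), provenance = character(0),
                      phenotype = character(0), trigger = character(0),
                      check_type = logical(0), check_trigger = logical(0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_resolved_table(empty, path)
  expect_equal(length(readLines(path)), 1L)
})
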