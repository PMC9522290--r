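test_that("a minimal tabular file parses into a clipped scored recording", {
  path <- write_rows(c("lights-off,0,0", "lm-left,100,2", "lights-on,3600,0"))
  rec <- read_annotation_file(path, "tabular")
  expect_s3_class(rec, "scored_recording")
  expect_equal(rec$lights_off, 0)
  expect_equal(rec$lights_on, 3600)
  expect_equal(tib_seconds(rec), 3600)
  expect_equal(nrow(rec$annotations), 1L)
  expect_equal(rec$annotations$onset, 100)
  expect_equal(rec$annotations$duration, 2)
})

test_that("events straddling lights-on are clipped to the TIB", {
  path <- write_rows(c("lights-off,0,0", "lm-left,3590,30", "lights-on,3600,0"))
  rec <- read_annotation_file(path, "tabular")
  expect_equal(rec$annotations$onset, 3590)
  expect_equal(rec$annotations$duration, 10)
  # an event entirely outside TIB disappears
  path2 <- write_rows(c("lights-off,60,0", "lm-left,10,5", "lm-left,100,2",
                        "lights-on,3600,0"))
  rec2 <- read_annotation_file(path2, "tabular")
  expect_equal(nrow(rec2$annotations), 1L)
  expect_equal(rec2$annotations$onset, 100)
})

test_that("clipping preserves total in-TIB event time", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    onset <- runif(n, -100, 4000)
    duration <- runif(n, 0.6, 60)
    ann <- annotations(rep("arousal", n), pmax(onset, 0), duration)
    lo <- 200; hi <- 3500
    clipped <- clip_annotations(ann, lo, hi)
    expected <- sum(pmax(0, pmin(ann$onset + ann$duration, hi) -
                           pmax(ann$onset, lo)))
    expect_equal(sum(clipped$duration), expected, tolerance = 1e-12)
  }
})

test_that("read/write round-trips in both dialects on random recordings", {
  for (seed in c(1, 7, 23)) {
    for (dialect in c("tabular", "edfplus")) {
      rec <- random_recording(seed, task = "respiratory")
      path <- tempfile()
      write_annotation_file(rec, path, dialect)
      back <- read_annotation_file(path, dialect,
                                   recording_id = rec$recording_id,
                                   scorer_id = rec$scorer_id,
                                   task = rec$task)
      expect_equal(back$annotations, rec$annotations, tolerance = 1e-9)
      expect_equal(back$lights_off, rec$lights_off)
      expect_equal(back$lights_on, rec$lights_on)
    }
  }
})

test_that("a staging recording round-trips through stage records", {
  rec <- scored_recording(
    "r1", "s1", task = "staging", lights_off = 120, lights_on = 120 + 90,
    annotations = annotations(c("stage-W", "stage-N1", "stage-N2"),
                              120 + c(0, 30, 60), rep(30, 3)))
  expect_equal(rec$context_hypnogram$stages, c("W", "N1", "N2"))
  for (dialect in c("tabular", "edfplus")) {
    path <- tempfile()
    write_annotation_file(rec, path, dialect)
    if (dialect == "tabular") {
      lines <- readLines(path)
      expect_true(any(grepl("^stage-W,120,30$", lines)))
      expect_true(any(grepl("^stage-N2,180,30$", lines)))
    }
    back <- read_annotation_file(path, dialect, task = "staging")
    expect_equal(back$context_hypnogram$stages, c("W", "N1", "N2"))
    expect_equal(back$context_hypnogram$lights_off, 120)
  }
})

test_that("writing is byte-stable across repeated writes", {
  rec <- random_recording(99, task = "respiratory", tib = 20000,
                          n_events = 1000)
  for (dialect in c("tabular", "edfplus")) {
    p1 <- tempfile(); p2 <- tempfile()
    write_annotation_file(rec, p1, dialect)
    write_annotation_file(rec, p2, dialect)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("an empty event list writes a file with only lights markers", {
  rec <- scored_recording("r1", "s1", task = "arousals",
                          lights_off = 0, lights_on = 600)
  path <- tempfile()
  write_annotation_file(rec, path, "tabular")
  expect_equal(length(readLines(path)), 3L)  # header + two markers
  back <- read_annotation_file(path, "tabular", task = "arousals")
  expect_equal(nrow(back$annotations), 0L)
})

test_that("malformed input produces named, informative errors", {
  bad_ts <- write_rows(c("lights-off,0,0", "lm-left,abc,2",
                         "lights-on,3600,0"))
  expect_error(read_annotation_file(bad_ts, "tabular"),
               "malformed timestamp at line 3")
  unknown <- write_rows(c("lights-off,0,0", "zzz-event,5,2",
                          "lights-on,3600,0"))
  expect_error(read_annotation_file(unknown, "tabular"), "zzz-event")
  no_lights <- write_rows("lm-left,5,2")
  expect_error(read_annotation_file(no_lights, "tabular"), "lights")
  expect_error(read_annotation_file(tempfile(), "tabular"), "no such file")
  # zero-duration events are invalid; lights markers are exempt
  expect_error(annotations("arousal", 10, 0), "zero-duration")
  expect_silent(annotations("lights-off", 0, 0))
})

test_that("the alias map normalizes free-text labels and is extensible", {
  path <- write_rows(c("Lights off,0,0", "Limb movement LEFT,10,2",
                       "LIGHTS ON,600,0"))
  rec <- read_annotation_file(path, "tabular")
  expect_equal(rec$annotations$label, "lm-left")
  path2 <- write_rows(c("lights-off,0,0", "PLM li,10,2", "lights-on,600,0"))
  expect_error(read_annotation_file(path2, "tabular"), "PLM li")
  map <- register_aliases(default_alias_map(), "PLM li" = "lm-left")
  rec2 <- read_annotation_file(path2, "tabular", alias_map = map)
  expect_equal(rec2$annotations$label, "lm-left")
  expect_error(register_aliases(default_alias_map(), "x" = "not-a-token"),
               "unknown canonical token")
})

test_that("TAL records carry onset, duration and text with EDF+ separators", {
  rec <- scored_recording(
    "r1", "s1", task = "arousals", lights_off = 0, lights_on = 100,
    annotations = annotations("arousal", 12.5, 7.25))
  path <- tempfile()
  write_annotation_file(rec, path, "edfplus")
  bytes <- readBin(path, "raw", file.size(path))
  expect_true(as.raw(0x14) %in% bytes)
  expect_true(as.raw(0x15) %in% bytes)
  txt <- rawToChar(bytes[bytes > 0x1f])
  expect_match(txt, "\\+12\\.5")
  # missing +/- prefix is a parse error
  bad <- tempfile()
  writeBin(c(charToRaw("12.5"), as.raw(0x14), charToRaw("arousal"),
             as.raw(c(0x14, 0x00))), bad)
  expect_error(read_annotation_file(bad, "edfplus"), "TAL record 1")
})
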