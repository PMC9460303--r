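test_that("default grid enumerates 18 sizes from 180 to 10 by -10", {
  g <- window_grid()
  expect_equal(window_sizes(g), seq(180, 10, by = -10))
  expect_length(window_sizes(g), 18L)
  expect_equal(g$step_s, 1)
  expect_equal(window_sizes(window_grid(seq(60, 10, by = -10))),
               c(60, 50, 40, 30, 20, 10))
  expect_error(window_grid(c(60, 0)), "> 0")
  expect_error(window_grid(step_s = 0), "step_s")
})

test_that("placement counts and centres follow the hop formula", {
  s <- const_series(800, 200)          # exactly 200 s
  seg <- segment_series(s, 180, 1)
  expect_length(seg$centers_s, floor((200 - 180) / 1) + 1)   # 21
  expect_equal(seg$centers_s, 90:110)
  seg60 <- segment_series(s, 60, 1)
  expect_length(seg60$centers_s, 141L)
  expect_equal(range(seg60$centers_s), c(30, 170))
  # every placement's intervals fit wholly inside [start, start + w)
  for (k in c(1, 60, 141)) {
    i1 <- seg60$first[k]; i2 <- seg60$last[k]
    start <- seg60$centers_s[k] - 30
    expect_gte(s$t_beats_s[i1], start - 1e-9)
    expect_lt(s$t_beats_s[i2 + 1], start + 60)
  }
})

test_that("runs shorter than the window yield a warned empty segmentation", {
  s <- const_series(900, 9)
  expect_warning(seg <- segment_series(s, 10, 1), "shorter")
  expect_length(seg$centers_s, 0L)
})

test_that("smaller windows never yield fewer measurements", {
  run <- generate_rr(gen_config(gen_segment(205), seed = 21))
  counts <- vapply(window_sizes(window_grid()), function(w)
    length(segment_series(run, w, 1)$centers_s), numeric(1))
  expect_true(all(diff(counts) >= 0))   # sizes ordered 180 -> 10
})

test_that("alignment restricts the short vector to the reference instants", {
  # 200-s run: ref (180 s) centres 90..110, short (60 s) centres 30..170
  ref <- feature_tbl("S1", "R1", "mNN", 180, values = rnorm(21))
  short <- feature_tbl("S1", "R1", "mNN", 60, values = seq(30, 170) * 2,
                       centers = seq(30, 170))
  al <- align_to_reference(short, ref)
  expect_equal(nrow(al), nrow(ref))
  expect_equal(al$center_s, 90:110)
  # set-intersection oracle: centres common to both vectors
  expect_equal(al$center_s, intersect(short$center_s, ref$center_s))
  expect_equal(al$short, (90:110) * 2)

  # identity alignment: every pair equal
  ali <- align_to_reference(ref, ref)
  expect_equal(ali$short, ali$ref)

  # disjoint centre ranges fail
  far <- feature_tbl("S2", "RB", "mNN", 60, values = 1:5,
                     centers = 400 + 0:4)
  expect_error(align_to_reference(far, ref), "overlap")
})

test_that("half-step parity offsets snap to the earlier nearest centre", {
  ref <- feature_tbl("S1", "R1", "f", 181, values = c(1, 2, 3),
                     centers = c(90.5, 91.5, 92.5))
  short <- feature_tbl("S1", "R1", "f", 60, values = 10 * (1:6),
                       centers = 88:93)
  al <- align_to_reference(short, ref)
  # ties at exactly half a step resolve toward the earlier short centre
  expect_equal(al$short, c(30, 40, 50))
})

test_that("extraction yields one vector per feature-window pair", {
  run <- generate_rr(gen_config(gen_segment(201, noise_sd_ms = 10), seed = 2))
  f <- extract_all(run, window_grid(c(180, 90, 30)),
                   feature_registry("time"))
  vec <- dplyr::distinct(f, feature_id, window_s)
  expect_equal(nrow(vec), 6 * 3)
  # vector lengths grow as the window shrinks
  n_by_w <- dplyr::count(dplyr::filter(f, feature_id == "mNN"), window_s)
  expect_true(all(diff(n_by_w$n[order(-n_by_w$window_s)]) >= 0))
  # first/last centre bookkeeping
  m <- dplyr::filter(f, feature_id == "mNN", window_s == 90)
  expect_equal(m$center_s[1], 45)
  expect_lte(max(m$center_s), duration_s(run) - 45)
})
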