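test_that("localization CSVs parse under the default and variant dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(data.frame(frame = 0:2, x = c(100, 200, 300),
                               y = c(10, 20, 30)), path)
  tab <- read_localizations(path)
  expect_s3_class(tab, "loc_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$x, c(100, 200, 300))
  expect_false("z" %in% names(tab))

  # header-only file parses to an empty table, no error
  writeLines('"frame","x [nm]","y [nm]"', path)
  expect_equal(nrow(read_localizations(path)), 0)

  # micrometre dialect converts to nm
  write_fixture_csv(data.frame(frame = 0, x = 0.1, y = 0.25), path)
  tab <- read_localizations(path, loc_dialect(unit = "um"))
  expect_equal(tab$x, 100)
  expect_equal(tab$y, 250)

  # alternating-frame parity channel assignment
  write_fixture_csv(data.frame(frame = 0:3, x = 1:4, y = 1:4), path)
  tab <- read_localizations(path, loc_dialect(channel_from = "frame_parity"))
  expect_equal(tab$channel, c(1L, 2L, 1L, 2L))

  # errors name the offending column / row
  writeLines(c('"frame","y [nm]"', "0,1"), path)
  expect_error(read_localizations(path), "x \\[nm\\]")
  writeLines(c('"frame","x [nm]","y [nm]"', "0,1,2", "1,oops,4"), path)
  expect_error(read_localizations(path), "row 2")
})

test_that("write_localizations round-trips through read_localizations", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- loc_table(data.frame(frame = c(0L, 5L), x = c(1.5, 2.5),
                              y = c(3, 4), z = c(-10, 10),
                              channel = c(1L, 2L)))
  write_localizations(tab, path)
  back <- read_localizations(path, loc_dialect(channel_from = "column"))
  expect_equal(back$x, tab$x)
  expect_equal(back$z, tab$z)
  expect_equal(back$channel, tab$channel)
})

test_that("ROI cropping is half-open and replaces the window", {
  set.seed(42)
  tab <- loc_table(data.frame(frame = 0, x = runif(10, 0, 1000),
                              y = runif(10, 0, 1000)),
                   window = roi(0, 1000, 0, 1000))
  r <- roi(200, 600, 200, 600)
  inside <- sum(tab$x >= 200 & tab$x < 600 & tab$y >= 200 & tab$y < 600)
  cropped <- crop_roi(tab, r)
  expect_equal(nrow(cropped), inside)
  expect_identical(attr(cropped, "window"), r)

  # ROI equal to window keeps every record
  expect_equal(nrow(crop_roi(tab, roi(0, 1000, 0, 1000))), nrow(tab))

  # boundary: point exactly on x_max is excluded, on x_min included
  edge <- loc_table(data.frame(frame = 0, x = c(200, 600), y = c(300, 300)))
  expect_equal(crop_roi(edge, r)$x, 200)

  # disjoint ROI gives an empty table, not an error
  expect_equal(nrow(crop_roi(tab, roi(5000, 6000, 5000, 6000))), 0)
})

test_that("blinking merge collapses linked localizations at weighted means", {
  # two localizations 10 nm apart in consecutive frames merge to one
  # molecule at the midpoint under the standard 20 nm / 50 ms settings
  tab <- loc_table(data.frame(frame = c(0L, 1L), x = c(0, 10), y = c(0, 0)),
                   frame_rate = 13.4)
  m <- merge_localizations(tab, 20, 50)
  expect_equal(nrow(m), 1)
  expect_equal(m$x, 5)
  expect_equal(m$frame, 0)
  expect_equal(m$n_merged, 2L)

  # 25 nm apart exceeds the radius: two molecules remain
  tab2 <- loc_table(data.frame(frame = c(0L, 1L), x = c(0, 25), y = c(0, 0)))
  expect_equal(nrow(merge_localizations(tab2, 20, 50)), 2)

  # intensity-weighted position
  tab3 <- loc_table(data.frame(frame = c(0L, 1L), x = c(0, 10), y = c(0, 0),
                               intensity = c(3, 1)))
  expect_equal(merge_localizations(tab3, 20, 50)$x, 2.5)

  # the temporal gap bounds linking: same distance, frames too far apart
  tab4 <- loc_table(data.frame(frame = c(0L, 10L), x = c(0, 10), y = c(0, 0)))
  expect_equal(nrow(merge_localizations(tab4, 20, 50)), 2)

  # mixed channels and negative thresholds are rejected
  mixed <- loc_table(data.frame(frame = 0:1, x = 1:2, y = 1:2,
                                channel = 1:2))
  expect_error(merge_localizations(mixed), "single channel")
  expect_error(merge_localizations(tab, -1, 50), "non-negative")
})

test_that("merge is contractive, identity at zero thresholds, and matches the
           spatiotemporal connected-components oracle", {
  set.seed(101)
  mols <- simulate_csr(8, fixture_window()) # well-separated molecules
  tab <- emulate_blinking(mols, mean_emissions = 4, localization_sigma = 8.5,
                          n_frames = 500, frame_rate = 13.4)
  m <- merge_localizations(tab, 20, 50)
  expect_lte(nrow(m), nrow(tab))

  # zero thresholds leave the table untouched (even coincident points)
  dup <- loc_table(data.frame(frame = c(0L, 1L), x = c(5, 5), y = c(5, 5)))
  expect_equal(nrow(merge_localizations(dup, 0, 0)), 2)

  # exact agreement with the brute-force oracle on <= 200 localizations
  sub <- as.data.frame(tab)[seq_len(min(200, nrow(tab))), ]
  sub <- sub[order(sub$frame), ]
  gap_frames <- ceiling(50 / 1000 * 13.4)
  comp <- oracle_merge_components(sub$x, sub$y, sub$frame, 20,
                                  gap_frames + 1)
  m_sub <- merge_localizations(loc_table(sub, frame_rate = 13.4), 20, 50)
  expect_equal(nrow(m_sub), length(unique(comp)))
  expect_equal(sort(m_sub$n_merged), sort(as.integer(table(comp))))

  # re-application with the same thresholds is stable on a well-separated
  # low-error fixture (fragment centroids can re-link on noisier data)
  set.seed(102)
  tight <- emulate_blinking(simulate_csr(3, fixture_window()),
                            mean_emissions = 4, localization_sigma = 5,
                            n_frames = 500, frame_rate = 13.4)
  m1 <- merge_localizations(tight, 20, 50)
  m2 <- merge_localizations(m1, 20, 50)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(sort(m2$x), sort(m1$x))
})

test_that("crop and merge commute when merge groups avoid the ROI boundary", {
  set.seed(7)
  mols <- simulate_csr(8, fixture_window())
  tab <- emulate_blinking(mols, mean_emissions = 3, localization_sigma = 5,
                          n_frames = 500)
  # ROI edges placed far (>100 nm) from every localization
  r <- roi(1000, 3000, 1000, 3000)
  near_edge <- abs(tab$x - 1000) < 100 | abs(tab$x - 3000) < 100 |
    abs(tab$y - 1000) < 100 | abs(tab$y - 3000) < 100
  tab <- loc_table(as.data.frame(tab)[!near_edge, ], frame_rate = 13.4)
  a <- merge_localizations(crop_roi(tab, r), 20, 50)
  b <- crop_roi(merge_localizations(tab, 20, 50), r)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$x), sort(b$x))
})

test_that("live-frame accumulation partitions the movie and conserves counts", {
  set.seed(3)
  n <- 600
  movie <- loc_table(data.frame(frame = c(0L, 499L,
                                          sample(0:499, n - 2, replace = TRUE)),
                                x = runif(n, 0, 4000), y = runif(n, 0, 4000)),
                     frame_rate = 50)
  blocks <- accumulate_live_frames(movie, 50)
  expect_length(blocks, 10)
  expect_equal(sum(vapply(blocks, nrow, integer(1))), n)
  # block timestamps are the first participating frame's time (1 s apart)
  expect_equal(vapply(blocks, attr, numeric(1), "timestamp"), 0:9 * 1)
  expect_false(any(vapply(blocks, attr, logical(1), "partial")))

  # a movie no longer than one block accumulates to a single image
  short <- loc_table(data.frame(frame = sample(0:49, 30, replace = TRUE),
                                x = runif(30), y = runif(30)),
                     frame_rate = 50)
  expect_length(accumulate_live_frames(short, 50), 1)

  # trailing partial block is kept and flagged
  odd <- loc_table(data.frame(frame = c(0L, 60L), x = 1:2, y = 1:2),
                   frame_rate = 50)
  blocks <- accumulate_live_frames(odd, 50)
  expect_length(blocks, 2)
  expect_true(attr(blocks[[2]], "partial"))

  # alternating flag maps frame parity to channels
  four <- loc_table(data.frame(frame = 0:3, x = 1:4, y = 1:4),
                    frame_rate = 50)
  got <- accumulate_live_frames(four, 4, alternating_channels = TRUE)[[1]]
  expect_equal(got$channel, c(1L, 2L, 1L, 2L))
})
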