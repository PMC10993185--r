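raw5 <- function() {
  data.frame(time_ms = c(0, 25, 50, 75, 100),
             gaze_target = c("A", "A", "B", "wall", "C"),
             stringsAsFactors = FALSE)
}

test_that("placeholder-coded rows are dropped and columns reduced", {
  df <- data.frame(time_ms = c(0, 25, 50, 75),
                   gaze_target = c("A", "A", "B", "B"),
                   pupil_left_mm = c(3.1, -1, 3.2, 3.3),
                   pupil_right_mm = c(3.0, 3.0, -1, 3.2),
                   head_x = 0)
  res <- clean_samples(df)
  expect_equal(res$n_dropped, 2L)
  expect_equal(res$samples$time_ms, c(0, 75))
  expect_equal(names(res$samples), c("time_ms", "gaze_target"))
  # passthrough keeps requested extras
  res2 <- clean_samples(df, keep = "head_x")
  expect_true("head_x" %in% names(res2$samples))
})

test_that("cleaning is a no-op on valid data and on empty input", {
  df <- data.frame(time_ms = c(0, 25), gaze_target = c("A", "B"),
                   pupil_left_mm = c(3, 3), pupil_right_mm = c(3, 3))
  res <- clean_samples(df)
  expect_equal(res$n_dropped, 0L)
  expect_equal(res$samples$gaze_target, c("A", "B"))
  empty <- clean_samples(df[0, ])
  expect_equal(nrow(empty$samples), 0L)
  expect_equal(empty$n_dropped, 0L)
})

test_that("unsorted or duplicated timestamps are rejected with the offending row", {
  bad <- data.frame(time_ms = c(0, 50, 25), gaze_target = c("A", "B", "C"),
                    pupil_left_mm = 3, pupil_right_mm = 3)
  expect_error(clean_samples(bad), "row 3")
  dup <- data.frame(time_ms = c(0, 25, 25), gaze_target = c("A", "B", "C"),
                    pupil_left_mm = 3, pupil_right_mm = 3)
  expect_error(clean_samples(dup), "row 3")
})

test_that("the five-sample hand trace yields the two expected transitions", {
  tab <- extract_transitions(raw5(), c("A", "B", "C"), max_duration_ms = 60)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$t_start_ms, c(25, 50))
  expect_equal(tab$duration_ms, c(25, 50))
  expect_equal(tab$source, c("A", "B"))
  expect_equal(tab$target, c("B", "C"))
  expect_equal(attr(tab, "n_excluded_duration"), 0L)
})

test_that("the duration threshold excludes indirect transitions and counts them", {
  tab <- extract_transitions(raw5(), c("A", "B", "C"), max_duration_ms = 30)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$duration_ms, 25)
  expect_equal(tab$source, "A"); expect_equal(tab$target, "B")
  expect_equal(attr(tab, "n_excluded_duration"), 1L)
})

test_that("dwelling on one OOI produces no transitions; alternation gives constant durations", {
  one <- data.frame(time_ms = seq(0, 100, 25), gaze_target = "A")
  expect_equal(nrow(extract_transitions(one, c("A", "B"), 1000)), 0L)
  alt <- data.frame(time_ms = seq(0, by = 25, length.out = 20),
                    gaze_target = rep(c("A", "B"), 10))
  tab <- extract_transitions(alt, c("A", "B"), 1000)
  expect_equal(nrow(tab), 19L)
  expect_true(all(tab$duration_ms == 25))
  expect_true(all(tab$source != tab$target))
})

test_that("transition accounting conserves the number of target changes", {
  set.seed(301)
  for (i in 1:30) {
    n <- sample(20:120, 1)
    df <- data.frame(time_ms = cumsum(runif(n, 10, 200)),
                     gaze_target = sample(c("A", "B", "C", "wall", "none"), n,
                                          replace = TRUE))
    maxd <- runif(1, 50, 400)
    tab <- extract_transitions(df, c("A", "B", "C"), maxd)
    sub <- df$gaze_target[df$gaze_target %in% c("A", "B", "C")]
    changes <- if (length(sub) > 1) sum(sub[-1] != sub[-length(sub)]) else 0L
    expect_equal(nrow(tab) + attr(tab, "n_excluded_duration"), changes)
    expect_true(all(tab$source != tab$target))
    expect_true(all(tab$duration_ms > 0 & tab$duration_ms <= maxd))
  }
})

test_that("extraction ignores interleaved non-OOI rows that stay under the threshold", {
  ooi_only <- data.frame(time_ms = c(0, 100, 200, 300),
                         gaze_target = c("A", "B", "A", "C"))
  interleaved <- data.frame(time_ms = c(0, 40, 100, 150, 200, 300),
                            gaze_target = c("A", "wall", "B", "none", "A", "C"))
  t1 <- extract_transitions(ooi_only, c("A", "B", "C"), 1000)
  t2 <- extract_transitions(interleaved, c("A", "B", "C"), 1000)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("transitions are invariant to uniform time shifts", {
  tab0 <- extract_transitions(raw5(), c("A", "B", "C"), 60)
  shifted <- raw5(); shifted$time_ms <- shifted$time_ms + 12345
  tab1 <- extract_transitions(shifted, c("A", "B", "C"), 60)
  expect_equal(tab1$duration_ms, tab0$duration_ms)
  expect_equal(tab1$t_start_ms, tab0$t_start_ms + 12345)
  expect_equal(tab1$source, tab0$source)
})

test_that("invalid extraction parameters are rejected", {
  expect_error(extract_transitions(raw5(), character(0), 60), "non-empty")
  expect_error(extract_transitions(raw5(), "A", 0), "positive")
  expect_error(extract_transitions(raw5(), "A", -10), "positive")
})

test_that("transition tables round trip through CSV", {
  tab <- extract_transitions(raw5(), c("A", "B", "C"), 60, participant_id = "p7")
  path <- tempfile(fileext = ".csv")
  write_transitions(tab, path)
  rt <- read_transitions(path)
  expect_equal(as.data.frame(rt), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(rt$participant, rep("p7", 2))
})
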