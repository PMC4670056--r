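test_that("threshold assignment labels each side, boundary goes above", {
  expect_equal(assign_by_threshold(c(0.1, 0.9), 0.5, "low", "high"),
               c("low", "high"))
  expect_equal(assign_by_threshold(0.5, 0.5, "low", "high"), "high")
  # masked-out seconds keep their previous label
  out <- assign_by_threshold(c(0.1, 0.9, 0.1), 0.5, "low", "high",
                             mask = c(TRUE, FALSE, TRUE),
                             labels = c("unassigned", "keep", "unassigned"))
  expect_equal(out, c("low", "keep", "low"))
  # non-finite metric at an eligible second stays unassigned
  expect_message(
    out2 <- assign_by_threshold(c(0.1, NA), 0.5, "low", "high"),
    "non-finite")
  expect_equal(out2, c("low", "unassigned"))
})

test_that("bout segments cover all non-anchor seconds, edges included", {
  segs <- bout_segments(c("F", "F", "N", "N", "N", "F", "N", "N"), "F")
  expect_equal(segs$start, c(3L, 7L))
  expect_equal(segs$end, c(5L, 8L))

  segs2 <- bout_segments(rep("N", 5), "F")
  expect_equal(segs2$start, 1L)
  expect_equal(segs2$end, 5L)

  # anchor runs below the minimum duration merge into their neighbours
  segs3 <- bout_segments(c("N", "F", "N", "F", "F", "N"), "F",
                         min_bout_seconds = 2)
  expect_equal(segs3$start, c(1L, 6L))
  expect_equal(segs3$end, c(3L, 6L))
})

test_that("segment structure matches a brute-force scan on enumerated labels", {
  brute <- function(lab) {
    segs <- list()
    i <- 1
    while (i <= length(lab)) {
      if (lab[i] != "F") {
        j <- i
        while (j < length(lab) && lab[j + 1] != "F") j <- j + 1
        segs[[length(segs) + 1]] <- c(i, j)
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    segs
  }
  for (len in 1:10) {
    for (code in 0:(2^len - 1)) {
      lab <- ifelse(bitwAnd(code, 2^(0:(len - 1))) > 0, "F", "N")
      got <- bout_segments(lab, "F")
      want <- brute(lab)
      expect_equal(nrow(got), length(want))
      if (length(want) > 0) {
        expect_equal(got$start, vapply(want, function(w) as.integer(w[1]), integer(1)))
        expect_equal(got$end, vapply(want, function(w) as.integer(w[2]), integer(1)))
      }
    }
  }
})

test_that("segment averaging is piecewise constant at the segment mean", {
  segs <- tibble::tibble(start = 1L, end = 2L)
  expect_equal(average_within_segments(c(10, 30), segs), c(20, 20))
  segs1 <- tibble::tibble(start = 2L, end = 2L)
  expect_equal(average_within_segments(c(10, 30, 50), segs1), c(10, 30, 50))

  set.seed(21)
  x <- rnorm(50)
  segs2 <- tibble::tibble(start = c(3L, 20L, 41L), end = c(10L, 31L, 50L))
  out <- average_within_segments(x, segs2)
  for (i in seq_len(nrow(segs2))) {
    idx <- segs2$start[i]:segs2$end[i]
    expect_equal(out[idx], rep(mean(x[idx]), length(idx)))
  }
  outside <- setdiff(seq_along(x), unlist(Map(`:`, segs2$start, segs2$end)))
  expect_equal(out[outside], x[outside])
})

test_that("averaging preserves a segment's side when all seconds agree", {
  set.seed(22)
  for (i in 1:20) {
    thr <- runif(1, -1, 1)
    x <- thr + abs(rnorm(30))        # all at or above the threshold
    segs <- tibble::tibble(start = 1L, end = 30L)
    expect_true(all(average_within_segments(x, segs) >= thr))
  }
})

test_that("a zero-step plan leaves everything unassigned", {
  sim <- generate_accel(default_human_spec(5))
  m <- compute_metrics(sim$accel)
  plan0 <- classification_plan(character(0), list())
  res <- run_plan(m, plan0)
  expect_true(all(tidy(res)$label == "unassigned"))
})

test_that("the kittiwake plan recovers the simulated behaviors", {
  sim <- generate_accel(default_kittiwake_spec(2))
  m <- compute_metrics(sim$accel)
  res <- run_plan(m, kittiwake_plan())
  lab <- tidy(res)$label
  expect_setequal(unique(lab), c("flight", "on_land", "on_water"))
  for (b in c("flight", "on_land", "on_water")) {
    expect_gte(accuracy(lab, sim$truth$label, scope = b), 95)
  }
  expect_gte(accuracy(lab, sim$truth$label), 95)
  # audit trail carries one threshold per step
  expect_length(res$thresholds, 2)
  expect_equal(glance(res)$metric, c("sd_heave", "pitch"))
})

test_that("the human plan separates sitting, walking and running", {
  sim <- generate_accel(default_human_spec(2))
  m <- compute_metrics(sim$accel)
  res <- run_plan(m, human_plan())
  lab <- tidy(res)$label
  expect_setequal(unique(lab), c("sitting", "walking", "running"))
  expect_gte(accuracy(lab, sim$truth$label), 95)
  # the two thresholds bracket the walking mode
  thr <- glance(res)$threshold
  expect_lt(thr[1], thr[2])
})

test_that("classification is deterministic for identical inputs", {
  sim <- generate_accel(default_kittiwake_spec(4))
  m <- compute_metrics(sim$accel)
  r1 <- run_plan(m, kittiwake_plan())
  r2 <- run_plan(m, kittiwake_plan())
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(glance(r1), glance(r2))
})

test_that("every second ends labeled or explicitly unassigned", {
  sim <- generate_accel(default_kittiwake_spec(6))
  m <- compute_metrics(sim$accel)
  res <- run_plan(m, kittiwake_plan())
  lab <- tidy(res)$label
  expect_equal(length(lab), nrow(m))
  expect_true(all(lab %in% c(kittiwake_plan()$vocabulary, "unassigned")))
})

test_that("land and water never touch without a flight bout between", {
  sim <- generate_accel(default_kittiwake_spec(7))
  m <- compute_metrics(sim$accel)
  res <- run_plan(m, kittiwake_plan())
  expect_false(violates_transition_rule(tidy(res)$label))
})

test_that("the audit trail JSON reproduces every threshold decision", {
  sim <- generate_accel(default_human_spec(3))
  m <- compute_metrics(sim$accel)
  res <- run_plan(m, human_plan())
  path <- withr::local_tempfile(fileext = ".json")
  write_threshold_audit(res, path)
  audit <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(audit), 2)
  expect_equal(audit$threshold, glance(res)$threshold)
  expect_equal(audit$bin_width, c(0.02, 0.02))
})

test_that("plans referencing unassigned anchors or labels are rejected", {
  expect_error(
    classification_plan(
      c("a", "b"),
      list(classification_step("pitch", 2, 1, "a", "b",
                               bout_constraint = bout_constraint("flight")))),
    class = "ethopeak_validation_error")
  expect_error(
    classification_plan(
      c("a", "b", "ghost"),
      list(classification_step("pitch", 2, 1, "a", "b"))),
    class = "ethopeak_validation_error")
})
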