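test_that("the default grid enumerates the stated 1200 candidates", {
  g <- param_grid()
  expect_equal(g$nt_values, seq(2L, 24L, 2L))
  expect_length(g$cl_values, 100L)
  expect_equal(g$cl_values[1], 0.01)
  expect_equal(g$cl_values[100], 1)
  cand <- enumerate_grid(g)
  expect_equal(nrow(cand), 1200L)
  # nt-major, cl-minor order
  expect_equal(cand$nt[1:100], rep(2L, 100L))
  expect_equal(cand$cl[1:2], c(0.01, 0.02))

  single <- enumerate_grid(param_grid(2L, 0.5))
  expect_equal(nrow(single), 1L)
  expect_equal(single$cl, 0.5)
  expect_identical(enumerate_grid(g), enumerate_grid(param_grid()))
  expect_error(param_grid(integer(0)), "non-empty")
  expect_error(param_grid(c(4L, 2L)), "increasing")
})

test_that("candidate evaluation scores every variant plus the baseline", {
  img <- random_image(16, seed = 1)
  grid <- param_grid(c(1L, 2L), c(0.5, 1))
  tab <- evaluate_candidates(img, grid, stub_mean_scorer(), image_id = "a")
  expect_equal(nrow(tab), 5L)
  expect_equal(sum(tab$baseline), 1L)
  for (i in 1:4)
    expect_equal(tab$score[i], mean(as.numeric(
      apply_clahe(img, clahe_params(tab$nt[i], tab$cl[i])))))
  expect_equal(tab$score[5], mean(as.numeric(img)))

  # constant input: every enhanced variant is constant (255 when cl = 1)
  const <- gray_image(matrix(7L, 16, 16))
  tabc <- evaluate_candidates(const, grid, stub_mean_scorer())
  expect_true(all(tabc$score[!tabc$baseline & tabc$cl == 1] == 255))
  expect_true(all(tabc$score[!tabc$baseline] ==
                    round(tabc$score[!tabc$baseline])))

  boom <- scorer_spec("stub", fun = function(img) stop("nope"))
  expect_error(evaluate_candidates(img, grid, boom), "nt=1")
})

test_that("selection is the first argmin, flagging baseline wins", {
  tab <- structure(
    data.frame(nt = c(2L, 4L, 6L), cl = c(0.1, 0.2, 0.3),
               score = c(5.0, 3.2, 4.1), baseline = FALSE),
    image_id = "x", class = c("candidate_table", "data.frame"))
  sel <- select_best(tab)
  expect_equal(sel$index, 2L)
  expect_equal(sel$nt, 4L)
  expect_equal(sel$cl, 0.2)
  expect_false(sel$no_enhancement)

  tab$score <- c(1, 1, 1)
  expect_equal(select_best(tab)$index, 1L)

  tab2 <- rbind(tab, data.frame(nt = NA, cl = NA, score = 0.5,
                                baseline = TRUE))
  class(tab2) <- class(tab)
  expect_true(select_best(tab2)$no_enhancement)
})

test_that("select_best matches an exhaustive brute-force argmin", {
  grid <- param_grid(c(2L, 4L, 8L), c(0.1, 0.5, 1.0))
  stub <- stub_mean_scorer()
  set.seed(2)
  for (rep in 1:20) {
    img <- random_image(sample(16:24, 1))
    tab <- evaluate_candidates(img, grid, stub)
    sel <- select_best(tab)
    # independent oracle: nested loops, no table machinery
    best <- Inf; best_params <- NULL
    for (nt in grid$nt_values) for (cl in grid$cl_values) {
      s <- mean(as.numeric(apply_clahe(img, clahe_params(nt, cl))))
      if (s < best) { best <- s; best_params <- c(nt, cl) }
    }
    raw <- mean(as.numeric(img))
    if (raw < best) {
      expect_true(sel$no_enhancement)
    } else {
      expect_equal(sel$nt, best_params[1])
      expect_equal(sel$cl, best_params[2])
      expect_equal(sel$score, best)
    }
  }
})

make_selection <- function(nt, cl, id = NA_character_) {
  structure(list(image_id = id, index = 1L, nt = nt, cl = cl,
                 score = 0, no_enhancement = is.na(nt)),
            class = "per_image_selection")
}

test_that("aggregation takes the modal pair with the stated tie-break", {
  sels <- mapply(make_selection, c(2L, 2L, 2L, 4L), c(0.02, 0.03, 0.02, 0.01),
                 SIMPLIFY = FALSE)
  agg <- aggregate_common(sels)
  expect_equal(agg$nt, 2L)
  expect_equal(agg$cl, 0.02)
  expect_equal(agg$count, 2L)
  expect_equal(nrow(agg$table), 4L)

  # all-distinct rows: tie among singletons resolves to smallest (nt, cl)
  sels <- mapply(make_selection, c(2L, 2L, 4L, 6L), c(0.02, 0.03, 0.01, 0.04),
                 SIMPLIFY = FALSE)
  agg <- aggregate_common(sels)
  expect_equal(agg$nt, 2L)
  expect_equal(agg$cl, 0.02)
  expect_equal(agg$count, 1L)

  one <- aggregate_common(list(make_selection(6L, 0.9)))
  expect_equal(one$nt, 6L); expect_equal(one$cl, 0.9)
  expect_equal(one$count, 1L)
  expect_error(aggregate_common(list()), "no selections")
})

test_that("aggregation equals an independent frequency-count oracle", {
  set.seed(3)
  for (rep in 1:100) {
    n <- sample(1:12, 1)
    nts <- sample(c(2L, 4L, 6L), n, replace = TRUE)
    cls <- sample(c(0.01, 0.02, 0.05), n, replace = TRUE)
    sels <- mapply(make_selection, nts, cls, SIMPLIFY = FALSE)
    agg <- aggregate_common(sels)
    # oracle: tabulate pairs, pick max count, break ties by nt then cl
    key <- sprintf("%02d|%.6f", nts, cls)
    tb <- table(key)
    winners <- sort(names(tb)[tb == max(tb)])[1]
    expect_equal(sprintf("%02d|%.6f", agg$nt, agg$cl), winners)
    expect_equal(agg$count, as.integer(max(tb)))
  }
})

test_that("dataset enhancement composes per mode and never regresses", {
  # bright phantoms: equalization lowers the mean, so the stub (mean
  # intensity) scorer prefers enhancement and aggregation has material
  imgs <- lapply(1:6, function(i) {
    sp <- phantom_preset("default"); sp$background <- 170; sp$seed <- 100L + i
    generate_phantom(sp)$image
  })
  stub <- stub_mean_scorer()
  grid <- param_grid(c(1L, 2L), c(0.5, 1))

  common <- aggregate_common(lapply(seq_along(imgs), function(i)
    select_best(evaluate_candidates(imgs[[i]], grid, stub, image_id = i))))
  enh <- enhance_dataset(imgs, common, stub, mode = "common")
  for (i in seq_along(imgs))
    expect_identical(as.integer(enh$images[[i]]), as.integer(
      apply_clahe(imgs[[i]], clahe_params(common$nt, common$cl))))

  sels <- lapply(seq_along(imgs), function(i)
    select_best(evaluate_candidates(imgs[[i]], grid, stub, image_id = i)))
  per <- enhance_dataset(imgs, sels, stub, mode = "per-image")
  # argmin over candidates including the baseline cannot exceed baseline
  expect_true(all(per$report$score_after <= per$report$score_before + 1e-12))
  expect_lte(attr(per$report, "mean_after"), attr(per$report, "mean_before"))
  for (i in seq_along(imgs))
    if (sels[[i]]$no_enhancement)
      expect_identical(as.integer(per$images[[i]]), as.integer(imgs[[i]]))
})

test_that("candidate and selection tables export in the documented shapes", {
  img <- random_image(16, seed = 5)
  tab <- evaluate_candidates(img, param_grid(2L, c(0.5, 1)),
                             stub_mean_scorer(), image_id = "img0")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_candidate_csv(tab, p1)
  df <- read.csv(p1)
  expect_equal(names(df), c("NL", "CL", "BRISQUE"))
  expect_equal(nrow(df), 3L)

  p2 <- withr::local_tempfile(fileext = ".csv")
  write_selection_csv(list(select_best(tab)), p2)
  df2 <- read.csv(p2)
  expect_equal(names(df2), c("Image", "NL", "CL"))
  expect_equal(df2$Image, "img0")
})
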