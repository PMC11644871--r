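#' Parameter grid for CLAHE optimization
#'
#' The default grid is the one searched by the enhancement procedure:
#' tiles-per-axis `nt` from 2 to 24 in steps of 2 (12 values) and contrast
#' limit `cl` from 0.01 to 1.00 in steps of 0.01 (100 values), 1200
#' combinations in all. `cl = 0` is excluded because the clip mapping
#' `T = max(1, ceiling(cl * tile_pixels))` makes it indistinguishable from
#' the smallest positive limit.
#'
#' @param nt_values Strictly increasing integer tile counts.
#' @param cl_values Strictly increasing contrast limits in `(0, 1]`.
#' @return A list of class `param_grid`.
#' @export
param_grid <- function(nt_values = seq(2L, 24L, by = 2L),
                       cl_values = seq(0.01, 1, by = 0.01)) {
  if (length(nt_values) < 1L || length(cl_values) < 1L)
    stop("grid must be non-empty")
  if (is.unsorted(nt_values, strictly = TRUE) ||
      is.unsorted(cl_values, strictly = TRUE))
    stop("grid values must be strictly increasing")
  if (any(cl_values <= 0) || any(cl_values > 1))
    stop("cl values must lie in (0, 1]")
  structure(list(nt_values = as.integer(nt_values),
                 cl_values = as.numeric(cl_values)),
            class = "param_grid")
}

#' Enumerate all grid candidates
#'
#' @param grid A [param_grid()].
#' @return Data frame with columns `nt`, `cl`, in nt-major / cl-minor
#'   order; one row per candidate.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "param_grid"))
  data.frame(nt = rep(grid$nt_values, each = length(grid$cl_values)),
             cl = rep(grid$cl_values, times = length(grid$nt_values)))
}

#' Score every CLAHE candidate for one image
#'
#' Applies [apply_clahe()] at every grid point and scores each enhanced
#' variant with the given scorer; a baseline record holding the raw image's
#' score is appended so that "no enhancement" is always a candidate.
#'
#' @param img A [gray_image()].
#' @param grid A [param_grid()].
#' @param spec A [scorer_spec()].
#' @param image_id Optional identifier stored in the table.
#' @return Data frame of class `candidate_table` with columns `nt`, `cl`,
#'   `score`, `baseline` (logical); `nrow = grid size + 1`.
#' @export
evaluate_candidates <- function(img, grid, spec = scorer_spec("fallback"),
                                image_id = NA_character_) {
  img <- as_gray_image(img)
  cand <- enumerate_grid(grid)
  scores <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    enhanced <- apply_clahe(img, clahe_params(cand$nt[i], cand$cl[i]))
    s <- tryCatch(quality_score(enhanced, spec), error = function(e)
      stop("scorer failed on candidate (nt=", cand$nt[i], ", cl=",
           cand$cl[i], "): ", conditionMessage(e)))
    scores[i] <- s
  }
  out <- rbind(
    data.frame(nt = cand$nt, cl = cand$cl, score = scores, baseline = FALSE),
    data.frame(nt = NA_integer_, cl = NA_real_,
               score = quality_score(img, spec), baseline = TRUE))
  attr(out, "image_id") <- image_id
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Select the best candidate of a table
#'
#' Returns the record at the first index attaining the minimum score
#' (argmin with first-index tie-break). If the raw-image baseline wins,
#' the selection is flagged `no_enhancement` and carries no parameters.
#'
#' @param table A `candidate_table` from [evaluate_candidates()].
#' @return List of class `per_image_selection` with `image_id`, `index`,
#'   `nt`, `cl`, `score`, `no_enhancement`.
#' @export
select_best <- function(table) {
  if (nrow(table) < 1L) stop("empty candidate table")
  if (any(!is.finite(table$score))) stop("non-finite candidate scores")
  m <- which.min(table$score)  # first index on ties
  structure(list(image_id = attr(table, "image_id"),
                 index = m,
                 nt = table$nt[m], cl = table$cl[m],
                 score = table$score[m],
                 no_enhancement = isTRUE(table$baseline[m])),
            class = "per_image_selection")
}

#' Aggregate per-image selections into dataset-level parameters
#'
#' Takes the most frequent joint `(nt, cl)` pair over the per-image
#' selections (selections flagged "no enhancement" are excluded from the
#' frequency count but kept in the table). Ties are broken by smallest
#' `nt`, then smallest `cl`.
#'
#' @param selections List of `per_image_selection` objects.
#' @return List of class `dataset_params` with `nt`, `cl`, `count`, and
#'   `table` (one row per image: `image`, `nt`, `cl`).
#' @export
aggregate_common <- function(selections) {
  if (length(selections) < 1L) stop("no selections to aggregate")
  tab <- data.frame(
    image = vapply(selections, function(s)
      if (is.null(s$image_id) || is.na(s$image_id)) NA_character_
      else as.character(s$image_id), character(1)),
    nt = vapply(selections, function(s) as.integer(s$nt %||% NA), integer(1)),
    cl = vapply(selections, function(s) as.numeric(s$cl %||% NA), numeric(1)))
  enh <- tab[!is.na(tab$nt), , drop = FALSE]
  if (nrow(enh) == 0L)
    stop("every selection was 'no enhancement'; nothing to aggregate")
  key <- paste(enh$nt, format(enh$cl, digits = 15))
  freq <- table(key)
  best <- names(freq)[freq == max(freq)]
  rows <- enh[key %in% best, , drop = FALSE]
  rows <- unique(rows[c("nt", "cl")])
  rows <- rows[order(rows$nt, rows$cl), , drop = FALSE]
  structure(list(nt = rows$nt[1L], cl = rows$cl[1L],
                 count = as.integer(max(freq)), table = tab),
            class = "dataset_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enhance a set of images with selected CLAHE parameters
#'
#' In `"common"` mode every image is enhanced with the dataset-level
#' `(nt, cl)` pair. In `"per-image"` mode each image uses its own
#' selection; images whose baseline won pass through unchanged. A quality
#' report compares before/after scores.
#'
#' @param images List of [gray_image()]s.
#' @param params A `dataset_params` (common mode) or list of
#'   `per_image_selection` (per-image mode).
#' @param spec A [scorer_spec()] used for the report.
#' @param mode `"common"` or `"per-image"`.
#' @return List with `images` (enhanced) and `report` (data frame with
#'   `image`, `score_before`, `score_after`, plus means as attributes).
#' @export
enhance_dataset <- function(images, params, spec = scorer_spec("fallback"),
                            mode = c("common", "per-image")) {
  mode <- match.arg(mode)
  n <- length(images)
  out <- vector("list", n)
  before <- after <- numeric(n)
  for (i in seq_len(n)) {
    img <- as_gray_image(images[[i]])
    before[i] <- quality_score(img, spec)
    if (mode == "common") {
      stopifnot(inherits(params, "dataset_params"))
      out[[i]] <- apply_clahe(img, clahe_params(params$nt, params$cl))
    } else {
      sel <- params[[i]]
      stopifnot(inherits(sel, "per_image_selection"))
      out[[i]] <- if (sel$no_enhancement) img
                  else apply_clahe(img, clahe_params(sel$nt, sel$cl))
    }
    after[i] <- quality_score(out[[i]], spec)
  }
  report <- data.frame(image = seq_len(n), score_before = before,
                       score_after = after)
  attr(report, "mean_before") <- mean(before)
  attr(report, "mean_after") <- mean(after)
  list(images = out, report = report)
}

#' Write a candidate table as CSV (columns `NL,CL,BRISQUE`)
#' @param table A `candidate_table`.
#' @param path Output path.
#' @export
write_candidate_csv <- function(table, path) {
  df <- data.frame(NL = table$nt, CL = table$cl, BRISQUE = table$score)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-image selections as CSV (columns `Image,NL,CL`)
#' @param selections List of `per_image_selection`.
#' @param path Output path.
#' @export
write_selection_csv <- function(selections, path) {
  df <- data.frame(
    Image = vapply(seq_along(selections), function(i) {
      id <- selections[[i]]$image_id
      if (is.null(id) || is.na(id)) as.character(i - 1L) else as.character(id)
    }, character(1)),
    NL = vapply(selections, function(s) as.integer(s$nt %||% NA), integer(1)),
    CL = vapply(selections, function(s) as.numeric(s$cl %||% NA), numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
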