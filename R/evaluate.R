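#' Dice overlap of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks score 1 by convention.
#'
#' @param a,b Logical matrices of identical shape.
#' @return A scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("dice: mask shapes differ", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

# interior-most TRUE pixel of a region: argmax of the Euclidean distance to
# the nearest FALSE pixel (image border is not background, matching the
# distance-transform convention); ties -> lowest row, then lowest column
interior_most_point <- function(region) {
  dm <- EBImage::distmap(region * 1, metric = "euclidean")
  dm[!region] <- -Inf
  best <- max(dm)
  cand <- which(dm == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  cand[1L, ]
}

#' Simulate the next user click from the current error
#'
#' Labels the false-negative region (`truth & !pred`) and false-positive
#' region (`pred & !truth`) into 8-connected components and targets the
#' largest one: a positive click if it is missing mask, a negative click if
#' it is spurious mask.  The click lands on the component's interior-most
#' pixel (distance-transform argmax; ties broken by lowest row then
#' column), which is fully deterministic.  Optional uniform jitter inside
#' the component is available for stress testing.
#'
#' @param pred Logical matrix (current prediction; may be all-`FALSE`).
#' @param truth Logical matrix (ground truth), non-empty.
#' @param jitter If `TRUE`, pick a uniform random pixel of the component
#'   instead of the interior-most one.
#' @return A [click()], or `NULL` when `pred` equals `truth` (session done).
#' @export
simulate_next_click <- function(pred, truth, jitter = FALSE) {
  if (!identical(dim(pred), dim(truth)))
    stop("simulate_next_click: shapes differ", call. = FALSE)
  if (!any(truth))
    stop("simulate_next_click: truth mask is empty", call. = FALSE)
  fn <- truth & !pred
  fp <- pred & !truth
  if (!any(fn) && !any(fp)) return(NULL)

  largest <- function(err) {
    if (!any(err)) return(list(size = 0L))
    lab <- label8(err)
    sizes <- tabulate(lab[lab > 0L])
    id <- which.max(sizes)
    list(size = sizes[id], region = lab == id)
  }
  cfn <- largest(fn); cfp <- largest(fp)
  positive <- cfn$size >= cfp$size      # prefer growth on equal error sizes
  region <- if (positive) cfn$region else cfp$region
  pt <- if (jitter) {
    cand <- which(region, arr.ind = TRUE)
    cand[sample.int(nrow(cand), 1L), ]
  } else interior_most_point(region)
  click(pt[1L], pt[2L], positive = positive)
}

#' Run a full simulated interactive session
#'
#' Implements the best-Dice-per-click protocol: the first simulated click
#' is positive and seeds the initial segmentation; each further simulated
#' click refines the mask ([apply_positive_click()] /
#' [apply_negative_click()]).  The Dice score against the ground truth is
#' recorded after every click, along with its running maximum
#' (`best_dice_per_click`, non-decreasing by construction).
#'
#' @param image Numeric H x W matrix in `[0, 1]`.
#' @param truth Logical H x W matrix, non-empty.
#' @param weights An [ae_weights()] object.
#' @param max_clicks Maximum number of simulated clicks (>= 1).
#' @param seed Integer seed (only consumed when `jitter = TRUE`).
#' @param config A [run_config()].
#' @param jitter Passed to [simulate_next_click()].
#' @param keep_masks Store the per-click masks in the record.
#' @return An object of class `"session_record"`: `clicks`,
#'   `dice_per_click`, `best_dice_per_click`, `seed`, optionally `masks`.
#' @export
interactive_session <- function(image, truth, weights, max_clicks = 5L,
                                seed = 0L, config = run_config(),
                                jitter = FALSE, keep_masks = FALSE) {
  check_intensity_image(image)
  if (!any(truth)) stop("interactive_session: truth mask is empty", call. = FALSE)
  if (max_clicks < 1L) stop("interactive_session: max_clicks must be >= 1", call. = FALSE)
  set.seed(seed)

  clicks <- list()
  dices <- numeric(0)
  masks <- if (keep_masks) list() else NULL
  pos_clicks <- list()
  pred <- matrix(FALSE, nrow(truth), ncol(truth))

  for (k in seq_len(max_clicks)) {
    ck <- simulate_next_click(pred, truth, jitter = jitter)
    if (is.null(ck)) break
    clicks[[k]] <- ck
    if (k == 1L) {
      pos_clicks[[1L]] <- ck
      st <- run_initial_segmentation(image, ck, weights, config)
      pred <- st$current_mask
    } else if (ck$positive) {
      pos_clicks[[length(pos_clicks) + 1L]] <- ck
      pred <- apply_positive_click(image, pred, ck, weights, config)
    } else {
      pred <- apply_negative_click(pred, pos_clicks, ck)
      pred <- matrix(as.logical(pred), nrow(pred), ncol(pred))
    }
    dices <- c(dices, dice(pred, truth))
    if (keep_masks) masks[[k]] <- pred
    if (!any(pred)) break   # carved to nothing; next click would reseed FN anyway
  }
  structure(list(clicks = clicks, dice_per_click = dices,
                 best_dice_per_click = cummax(dices),
                 masks = masks, seed = seed),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record: %d click(s), final dice %.3f, best %.3f>\n",
              length(x$clicks),
              if (length(x$dice_per_click)) utils::tail(x$dice_per_click, 1) else NA,
              if (length(x$best_dice_per_click)) max(x$best_dice_per_click) else NA))
  invisible(x)
}

#' Serialize a session record to JSON
#'
#' Stores clicks (row, col, polarity), per-click and best Dice, and the
#' seed; masks are not serialized (replay recomputes them).
#'
#' @param record A `"session_record"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  obj <- list(
    clicks = lapply(record$clicks, function(ck)
      list(row = ck$row, col = ck$col,
           polarity = if (ck$positive) "positive" else "negative")),
    dice_per_click = record$dice_per_click,
    best_dice_per_click = record$best_dice_per_click,
    seed = record$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session record written by [write_session()]
#' @param path Path to the JSON file.
#' @return A `"session_record"` (without masks).
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    clicks = lapply(obj$clicks, function(ck)
      click(ck$row, ck$col, positive = identical(ck$polarity, "positive"))),
    dice_per_click = as.numeric(unlist(obj$dice_per_click)),
    best_dice_per_click = as.numeric(unlist(obj$best_dice_per_click)),
    masks = NULL, seed = obj$seed), class = "session_record")
}

#' Replay a recorded session's clicks
#'
#' Re-applies the stored click sequence (initial segmentation from the
#' first click, then refinement) and recomputes the Dice after each click.
#' With the same image, truth, and weights this reproduces the recorded
#' Dice values exactly, since every stage of the pipeline is deterministic.
#'
#' @param record A `"session_record"`.
#' @param image,truth,weights As in [interactive_session()].
#' @param config A [run_config()].
#' @return A new `"session_record"` with recomputed Dice values.
#' @export
replay_session <- function(record, image, truth, weights,
                           config = run_config()) {
  pred <- matrix(FALSE, nrow(truth), ncol(truth))
  pos_clicks <- list()
  dices <- numeric(0)
  for (k in seq_along(record$clicks)) {
    ck <- record$clicks[[k]]
    if (k == 1L) {
      pos_clicks[[1L]] <- ck
      pred <- run_initial_segmentation(image, ck, weights, config)$current_mask
    } else if (ck$positive) {
      pos_clicks[[length(pos_clicks) + 1L]] <- ck
      pred <- apply_positive_click(image, pred, ck, weights, config)
    } else {
      pred <- apply_negative_click(pred, pos_clicks, ck)
      pred <- matrix(as.logical(pred), nrow(pred), ncol(pred))
    }
    dices <- c(dices, dice(pred, truth))
  }
  structure(list(clicks = record$clicks, dice_per_click = dices,
                 best_dice_per_click = cummax(dices),
                 masks = NULL, seed = record$seed),
            class = "session_record")
}
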