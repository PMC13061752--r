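# Spatial matching of predicted vs true centers at a physical radius,
# and the counting / detection metrics computed from it.

#' Match predicted and true centers within a physical radius
#'
#' Builds the bipartite graph of (pred, true) pairs whose distance is
#' at most `radius_mm` and finds a maximum-cardinality one-to-one
#' matching; among maximum-cardinality matchings the one with minimum
#' total distance is chosen. Matched pairs are the true positives,
#' unmatched predictions false positives, unmatched truths false
#' negatives. A `"greedy"` mode (repeatedly take the closest remaining
#' admissible pair) is available for comparison.
#'
#' @param pred,true Data frames with columns `x`, `y` in pixels (0-based).
#' @param radius_mm Matching radius in millimetres (default 2).
#' @param scale A [scale_calibration()] converting pixels to mm.
#' @param method `"assignment"` (default) or `"greedy"`.
#' @return An object of class `match_result`: list with `tp_pairs`
#'   (data frame `true_idx`, `pred_idx`, `dist_mm`), `fp` (unmatched
#'   pred indices), `fn` (unmatched true indices), `radius_mm`.
#' @export
match_centers <- function(pred, true, radius_mm = 2, scale,
                          method = c("assignment", "greedy")) {
  method <- match.arg(method)
  if (radius_mm <= 0) stop("`radius_mm` must be > 0", call. = FALSE)
  scale <- as_scale(scale)
  np <- nrow(pred); nt <- nrow(true)
  empty <- data.frame(true_idx = integer(0), pred_idx = integer(0),
                      dist_mm = numeric(0))
  if (np == 0L || nt == 0L) {
    return(structure(list(tp_pairs = empty, fp = seq_len(np), fn = seq_len(nt),
                          radius_mm = radius_mm), class = "match_result"))
  }
  dx <- outer(true$x, pred$x, `-`)
  dy <- outer(true$y, pred$y, `-`)
  dmm <- px_to_mm(sqrt(dx^2 + dy^2), scale) # nt x np
  adm <- which(dmm <= radius_mm, arr.ind = TRUE)
  if (nrow(adm) == 0L) {
    return(structure(list(tp_pairs = empty, fp = seq_len(np), fn = seq_len(nt),
                          radius_mm = radius_mm), class = "match_result"))
  }
  if (method == "greedy") {
    ord <- order(dmm[adm])
    used_t <- logical(nt); used_p <- logical(np)
    ti <- integer(0); pi <- integer(0)
    for (k in ord) {
      t1 <- adm[k, 1L]; p1 <- adm[k, 2L]
      if (!used_t[t1] && !used_p[p1]) {
        used_t[t1] <- TRUE; used_p[p1] <- TRUE
        ti <- c(ti, t1); pi <- c(pi, p1)
      }
    }
  } else {
    # weight M - d makes cardinality dominate, then minimizes total
    # distance among maximum matchings
    M <- radius_mm * (min(np, nt) + 1) + 1
    types <- c(rep(FALSE, nt), rep(TRUE, np))
    edges <- as.vector(t(cbind(adm[, 1L], nt + adm[, 2L])))
    g <- igraph::make_bipartite_graph(types, edges)
    igraph::E(g)$weight <- M - dmm[adm]
    mm <- igraph::max_bipartite_match(g)$matching
    ti <- which(!is.na(mm[seq_len(nt)]))
    pi <- mm[ti] - nt
  }
  ord2 <- order(ti)
  ti <- ti[ord2]; pi <- as.integer(pi[ord2])
  tp <- data.frame(true_idx = as.integer(ti), pred_idx = pi,
                   dist_mm = dmm[cbind(ti, pi)])
  structure(list(tp_pairs = tp,
                 fp = setdiff(seq_len(np), pi),
                 fn = setdiff(seq_len(nt), ti),
                 radius_mm = radius_mm),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d (radius %g mm)\n",
              nrow(x$tp_pairs), length(x$fp), length(x$fn), x$radius_mm))
  invisible(x)
}

f1_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else if (fn > 0) 0 else 1
  r <- if (tp + fn > 0) tp / (tp + fn) else if (fp > 0) 0 else 1
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

#' Precision, recall and F1 from a match result
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Zero
#' denominators follow the standard conventions: with no predictions
#' and no truths all three are 1; with `TP = 0` and either errors
#' present the affected metrics are 0.
#'
#' @param match A [match_centers()] result, or a list with elements
#'   `tp`, `fp`, `fn` giving pooled counts.
#' @return An object of class `detection_metrics`: list with
#'   `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
detection_metrics <- function(match) {
  if (inherits(match, "match_result")) {
    tp <- nrow(match$tp_pairs); fp <- length(match$fp); fn <- length(match$fn)
  } else {
    tp <- match$tp; fp <- match$fp; fn <- match$fn
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else if (fn > 0) 0 else 1
  r <- if (tp + fn > 0) tp / (tp + fn) else if (fp > 0) 0 else 1
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> P %.4f  R %.4f  F1 %.4f (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Per-image counting errors (MAE / MAPE)
#'
#' `MAE = mean |t_i - p_i|` and `MAPE = 100 * mean(|t_i - p_i| / t_i)`
#' over images, where `t_i` is the manual ground-truth count and `p_i`
#' the predicted count. Images with `t_i = 0` cannot enter the MAPE
#' (division by zero) and are excluded from it with a warning; they
#' still count toward the MAE.
#'
#' @param pairs Data frame (or 2-column matrix) with columns `t`
#'   (true counts) and `p` (predicted counts).
#' @return An object of class `count_metrics`: list with `mae`, `mape`
#'   (percent), `n`.
#' @export
count_error_metrics <- function(pairs) {
  if (is.matrix(pairs)) pairs <- data.frame(t = pairs[, 1L], p = pairs[, 2L])
  if (is.null(pairs$t) || is.null(pairs$p)) {
    stop("`pairs` must have columns `t` and `p`", call. = FALSE)
  }
  n <- nrow(pairs)
  if (n < 1L) stop("need at least one (t, p) pair", call. = FALSE)
  if (any(pairs$t < 0)) stop("true counts must be >= 0", call. = FALSE)
  err <- abs(pairs$t - pairs$p)
  mae <- mean(err)
  pos <- pairs$t > 0
  if (!all(pos)) {
    warning(sprintf("%d image(s) with a true count of 0 excluded from MAPE",
                    sum(!pos)))
  }
  mape <- if (any(pos)) 100 * mean(err[pos] / pairs$t[pos]) else NA_real_
  structure(list(mae = mae, mape = mape, n = n), class = "count_metrics")
}

#' @export
print.count_metrics <- function(x, ...) {
  cat(sprintf("<count_metrics> MAE %.4f  MAPE %.2f%%  (n = %d)\n",
              x$mae, x$mape, x$n))
  invisible(x)
}

#' Evaluate a set of per-image predictions against annotations
#'
#' Matches each image's predicted centers to its annotated centers,
#' then reports per-image results, the aggregate detection metrics
#' from pooled TP/FP/FN counts (micro-averaging — the headline number),
#' the mean of per-image F1 (macro, for transparency), and the
#' counting metrics over all images.
#'
#' @param predictions Named list (by image id) of data frames with
#'   `x`, `y`.
#' @param annotations Named list (by image id) of
#'   [point_annotation_set()]s.
#' @param radius_mm Matching radius in millimetres.
#' @param scale Optional [scale_calibration()] overriding each
#'   annotation set's own.
#' @param method Matching method, see [match_centers()].
#' @return An object of class `evaluation_report`: list with
#'   `per_image` (data frame), `detection` (micro
#'   [detection_metrics()]), `macro_f1`, `counts`
#'   ([count_error_metrics()]).
#' @export
evaluate_run <- function(predictions, annotations, radius_mm = 2,
                         scale = NULL, method = "assignment") {
  pid <- names(predictions); aid <- names(annotations)
  if (is.null(pid) || is.null(aid)) {
    stop("`predictions` and `annotations` must be named by image id", call. = FALSE)
  }
  extra <- setdiff(pid, aid); missing <- setdiff(aid, pid)
  if (length(extra) || length(missing)) {
    stop(sprintf(
      "image id mismatch: %s%s",
      if (length(extra)) paste0("no annotations for [", paste(extra, collapse = ", "), "] ") else "",
      if (length(missing)) paste0("no predictions for [", paste(missing, collapse = ", "), "]") else ""
    ), call. = FALSE)
  }
  rows <- vector("list", length(aid))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(aid)) {
    id <- aid[i]
    ann <- annotations[[id]]
    sc <- if (is.null(scale)) ann$scale else as_scale(scale)
    mr <- match_centers(predictions[[id]], ann$points, radius_mm, sc, method)
    dm <- detection_metrics(mr)
    rows[[i]] <- data.frame(
      image_id = id, n_true = nrow(ann$points), n_pred = nrow(predictions[[id]]),
      tp = dm$tp, fp = dm$fp, fn = dm$fn,
      precision = dm$precision, recall = dm$recall, f1 = dm$f1
    )
    tp <- tp + dm$tp; fp <- fp + dm$fp; fn <- fn + dm$fn
  }
  per_image <- do.call(rbind, rows)
  micro <- detection_metrics(list(tp = tp, fp = fp, fn = fn))
  counts <- suppressWarnings(
    count_error_metrics(data.frame(t = per_image$n_true, p = per_image$n_pred)))
  structure(list(per_image = per_image, detection = micro,
                 macro_f1 = mean(per_image$f1), counts = counts,
                 radius_mm = radius_mm),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %d image(s), radius %g mm\n  MAE %.3f  MAPE %.2f%%  P %.4f  R %.4f  F1 %.4f (micro; macro F1 %.4f)\n",
    nrow(x$per_image), x$radius_mm, x$counts$mae, x$counts$mape,
    x$detection$precision, x$detection$recall, x$detection$f1, x$macro_f1))
  invisible(x)
}

#' Write an evaluation report to JSON (+ CSV summary)
#'
#' @param report An [evaluate_run()] result.
#' @param json_path Output JSON path (per-image and aggregate blocks).
#' @param csv_path Optional CSV path for the per-image table.
#' @return Invisibly, `json_path`.
#' @export
write_evaluation_report <- function(report, json_path, csv_path = NULL) {
  out <- list(
    radius_mm = report$radius_mm,
    aggregate = list(
      mae = report$counts$mae, mape = report$counts$mape,
      precision = report$detection$precision, recall = report$detection$recall,
      f1 = report$detection$f1, macro_f1 = report$macro_f1,
      tp = report$detection$tp, fp = report$detection$fp, fn = report$detection$fn,
      n_images = report$counts$n
    ),
    per_image = report$per_image
  )
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  invisible(json_path)
}
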