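# EMA diary ingestion and pain-rhythmicity phenotyping.
#
# The classifier follows the published rules: diary entries within +/-1 h of
# the 08:00/14:00/20:00 prompts form a 7-day x 3-slot grid; participants are
# split at the cohort median of daily (within-day) pain-score SD; the
# low-variability half is split at the median of mean intensity into
# constant-low/high; the high-variability half is rhythmic increasing
# (decreasing) when the 08:00 -> 20:00 relative change is >= 30% (<= -30%)
# on at least 4 of the 7 scheduled days, and mixed otherwise.

# Element-wise ISO-8601 parsing: rows that match no format become NA
# instead of aborting the whole read.
parse_timestamps <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in formats) {
    idx <- is.na(ts)
    if (!any(idx)) break
    ts[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"), tz = "UTC")
  }
  ts
}

#' Read a long-format EMA diary CSV
#'
#' Required columns: `participant_id`, `timestamp` (ISO-8601),
#' `scale`, `score`. Rows with unparseable timestamps or scores outside the
#' integer 0-10 numeric rating scale are rejected; rejected row numbers and
#' reasons are attached as attribute `"rejected"` and reported via a
#' message.
#'
#' @param path CSV file path.
#' @return data.frame of valid entries with POSIXct `timestamp`.
#' @export
read_diary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "timestamp", "scale", "score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("diary file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("diary file '", path, "' contains no entries", call. = FALSE)
    df$timestamp <- as.POSIXct(character(0), tz = "UTC")
    attr(df, "rejected") <- data.frame(row = integer(0),
                                       reason = character(0))
    return(df)
  }
  ts <- parse_timestamps(df$timestamp)
  score <- suppressWarnings(as.numeric(df$score))
  bad_ts <- is.na(ts)
  bad_score <- is.na(score) | score < 0 | score > 10 | score != floor(score)
  bad <- bad_ts | bad_score
  rejected <- data.frame(
    row = which(bad),
    reason = ifelse(bad_ts[bad], "unparseable timestamp",
                    "score outside integer 0-10 scale"))
  if (nrow(rejected)) {
    message("read_diary: rejected ", nrow(rejected), " row(s): ",
            paste(utils::head(rejected$row, 10), collapse = ", "),
            if (nrow(rejected) > 10) ", ..." else "")
  }
  out <- df[!bad, , drop = FALSE]
  out$timestamp <- ts[!bad]
  out$score <- score[!bad]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Assign diary entries to scheduled slots and build per-participant grids
#'
#' Each entry is assigned to the nearest of the scheduled slots on its
#' calendar day; entries further than `tolerance_min` minutes from every
#' slot are discarded (the published +/-1 h window). When several entries
#' map to one slot the entry closest to the slot time wins, ties going to
#' the earliest. Day 1 is a participant's first diary date; entries beyond
#' `n_days` days are dropped.
#'
#' @param entries diary data.frame (one scale; see `scale` to subset).
#' @param scale scale to keep when `entries` holds several.
#' @param slot_hours scheduled prompt hours.
#' @param tolerance_min half-width of the retention window in minutes.
#' @param n_days number of scheduled diary days.
#' @return named list (by participant) of `n_days` x 3 score matrices with
#'   NA for empty slots; class `ema_grid_set`.
#' @export
window_filter <- function(entries, scale = NULL, slot_hours = c(8, 14, 20),
                          tolerance_min = 60, n_days = 7) {
  if (!is.null(scale)) entries <- entries[entries$scale == scale, ]
  if (!inherits(entries$timestamp, "POSIXct")) {
    entries$timestamp <- parse_timestamps(entries$timestamp)
  }
  slot_labels <- sprintf("%02d:00", slot_hours)
  out <- list()
  for (pid in sort(unique(entries$participant_id))) {
    e <- entries[entries$participant_id == pid, ]
    day0 <- min(as.Date(e$timestamp, tz = "UTC"))
    day <- as.integer(as.Date(e$timestamp, tz = "UTC") - day0) + 1L
    minute_of_day <- as.numeric(difftime(
      e$timestamp, as.POSIXct(as.Date(e$timestamp, tz = "UTC"), tz = "UTC"),
      units = "mins"))
    delta <- abs(outer(minute_of_day, slot_hours * 60, "-"))
    slot <- apply(delta, 1, which.min)
    dist <- delta[cbind(seq_len(nrow(e)), slot)]
    keep <- dist <= tolerance_min & day >= 1 & day <= n_days
    grid <- matrix(NA_real_, n_days, length(slot_hours),
                   dimnames = list(paste0("day", seq_len(n_days)),
                                   slot_labels))
    best_dist <- matrix(Inf, n_days, length(slot_hours))
    best_time <- matrix(Inf, n_days, length(slot_hours))
    for (i in which(keep)) {
      d <- day[i]; s <- slot[i]
      better <- dist[i] < best_dist[d, s] ||
        (dist[i] == best_dist[d, s] &&
           as.numeric(e$timestamp[i]) < best_time[d, s])
      if (better) {
        grid[d, s] <- e$score[i]
        best_dist[d, s] <- dist[i]
        best_time[d, s] <- as.numeric(e$timestamp[i])
      }
    }
    out[[pid]] <- grid
  }
  structure(out, class = "ema_grid_set")
}

#' Per-participant variability metrics from an EMA grid
#'
#' A day is SD-evaluable when at least 2 of its 3 slots are present; the
#' within-day SD uses the sample (n-1) denominator. The participant
#' variability metric is, by default, the unweighted mean of the evaluable
#' days' SDs; `method = "pooled_sd"` instead takes one SD over all available
#' scores. Mean intensity averages all available scores.
#'
#' @param grid a days x slots score matrix (one participant).
#' @param method variability summary: `"mean_daily_sd"` (default) or
#'   `"pooled_sd"`.
#' @return list: `day_mean`, `day_sd`, `variability`, `mean_intensity`,
#'   `n_evaluable_days`, `classifiable`.
#' @export
daily_stats <- function(grid, method = c("mean_daily_sd", "pooled_sd")) {
  method <- match.arg(method)
  stopifnot(is.matrix(grid), nrow(grid) >= 1)
  n_obs <- rowSums(!is.na(grid))
  day_mean <- ifelse(n_obs >= 1, rowMeans(grid, na.rm = TRUE), NA_real_)
  day_sd <- rep(NA_real_, nrow(grid))
  ok <- n_obs >= 2
  day_sd[ok] <- apply(grid[ok, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
  n_eval <- sum(ok)
  variability <- if (n_eval == 0) NA_real_ else if (method == "mean_daily_sd") {
    mean(day_sd[ok])
  } else {
    stats::sd(grid[!is.na(grid)])
  }
  list(day_mean = day_mean, day_sd = day_sd, variability = variability,
       mean_intensity = if (any(n_obs >= 1)) mean(grid, na.rm = TRUE)
                        else NA_real_,
       n_evaluable_days = n_eval,
       classifiable = n_eval >= 1)
}

#' Split a cohort at the median of the variability metric
#'
#' The percentile is computed with linear interpolation; participants at or
#' below it are low-variability (ties go to the low group).
#'
#' @param variability numeric vector (one value per classifiable
#'   participant).
#' @param percentile split percentile (default 50).
#' @return logical vector, `TRUE` = high variability.
#' @export
split_variability <- function(variability, percentile = 50) {
  if (length(variability) < 2) {
    stop("need at least 2 classifiable participants to split", call. = FALSE)
  }
  cut <- unname(stats::quantile(variability, percentile / 100, type = 7))
  if (all(variability == variability[1])) {
    warning("all variability values identical; everyone assigned low",
            call. = FALSE)
    return(rep(FALSE, length(variability)))
  }
  variability > cut
}

#' Split low-variability participants into constant-low/high
#'
#' Median split (within the low-variability subset) of mean pain intensity;
#' at or below the median is constant-low.
#'
#' @param mean_intensity numeric vector for the low-variability subset.
#' @param percentile split percentile (default 50).
#' @return character vector of labels.
#' @export
classify_constant <- function(mean_intensity, percentile = 50) {
  stopifnot(length(mean_intensity) >= 1)
  cut <- unname(stats::quantile(mean_intensity, percentile / 100, type = 7))
  ifelse(mean_intensity <= cut, "constant_low", "constant_high")
}

#' Detect the rhythmic increasing/decreasing pattern in one grid
#'
#' A day qualifies as increasing when both the 08:00 and 20:00 scores are
#' present and `(s20 - s08)/s08 >= rel_threshold` (a morning score of 0 with
#' a positive evening score counts as increasing; 0 -> 0 is no change), and
#' as decreasing when `(s20 - s08)/s08 <= -rel_threshold`. The participant
#' is rhythmic when at least `min_days` of the 7 scheduled days qualify in
#' one direction; days missing either anchor slot cannot qualify but still
#' count in the 7-day denominator.
#'
#' @param grid days x slots score matrix; first and last columns are the
#'   08:00 and 20:00 anchors.
#' @param rel_threshold relative change threshold (default 0.30).
#' @param min_days minimum qualifying days (default 4).
#' @param inclusive whether the threshold itself qualifies (default TRUE,
#'   matching the ">= 30%" reading).
#' @return list: `label` ("rhythmic_up", "rhythmic_down" or "none"),
#'   `n_increase_days`, `n_decrease_days`.
#' @export
detect_rhythmic <- function(grid, rel_threshold = 0.30, min_days = 4,
                            inclusive = TRUE) {
  s08 <- grid[, 1]
  s20 <- grid[, ncol(grid)]
  complete <- !is.na(s08) & !is.na(s20)
  cmp_up <- if (inclusive) `>=` else `>`
  cmp_dn <- if (inclusive) `<=` else `<`
  rel <- (s20 - s08) / s08
  inc <- complete & ((s08 > 0 & cmp_up(rel, rel_threshold)) |
                       (s08 == 0 & s20 > 0))
  dec <- complete & s08 > 0 & cmp_dn(rel, -rel_threshold)
  n_inc <- sum(inc)
  n_dec <- sum(dec)
  label <- if (n_inc >= min_days) "rhythmic_up"
           else if (n_dec >= min_days) "rhythmic_down"
           else "none"
  list(label = label, n_increase_days = n_inc, n_decrease_days = n_dec)
}

#' Phenotype a diary cohort
#'
#' Full composition of the classification rules. Participants without any
#' SD-evaluable day are labelled `unclassifiable` and excluded from the
#' variability split. Rhythmic decreasing participants are flagged in
#' `excluded` when `exclude_rhythmic_down = TRUE` (the study excluded its 2
#' such participants from downstream analyses); their label is preserved.
#' The same rules apply unchanged to the mood and fatigue scales via
#' `scale`.
#'
#' @param diary long diary data.frame (as from [read_diary()] or
#'   [gen_diaries()]).
#' @param scale which scale to phenotype (default "pain").
#' @param tolerance_min retention window half-width (minutes).
#' @param rel_threshold,min_days,inclusive rhythm rule knobs, see
#'   [detect_rhythmic()].
#' @param variability_method see [daily_stats()].
#' @param exclude_rhythmic_down flag rhythmic decreasing participants for
#'   downstream exclusion.
#' @return data.frame, one row per participant: `participant_id`, `label`,
#'   `variability`, `mean_intensity`, `n_evaluable_days`,
#'   `n_increase_days`, `n_decrease_days`, `high_variability`, `excluded`.
#' @export
phenotype_cohort <- function(diary, scale = "pain", tolerance_min = 60,
                             rel_threshold = 0.30, min_days = 4,
                             inclusive = TRUE,
                             variability_method = "mean_daily_sd",
                             exclude_rhythmic_down = TRUE) {
  grids <- window_filter(diary, scale = scale, tolerance_min = tolerance_min)
  if (length(grids) < 2) {
    stop("need at least 2 participants to phenotype", call. = FALSE)
  }
  ids <- names(grids)
  stats_list <- lapply(grids, daily_stats, method = variability_method)
  out <- data.frame(
    participant_id = ids,
    label = NA_character_,
    variability = vapply(stats_list, `[[`, numeric(1), "variability"),
    mean_intensity = vapply(stats_list, `[[`, numeric(1), "mean_intensity"),
    n_evaluable_days = vapply(stats_list, `[[`, integer(1),
                              "n_evaluable_days"),
    n_increase_days = NA_integer_,
    n_decrease_days = NA_integer_,
    high_variability = NA,
    excluded = FALSE,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  classifiable <- vapply(stats_list, `[[`, logical(1), "classifiable")
  out$label[!classifiable] <- "unclassifiable"
  idx <- which(classifiable)
  if (length(idx) < 2) {
    stop("need at least 2 classifiable participants", call. = FALSE)
  }
  high <- split_variability(out$variability[idx])
  out$high_variability[idx] <- high
  low_idx <- idx[!high]
  if (length(low_idx)) {
    out$label[low_idx] <- classify_constant(out$mean_intensity[low_idx])
  }
  for (i in idx[high]) {
    r <- detect_rhythmic(grids[[out$participant_id[i]]],
                         rel_threshold = rel_threshold, min_days = min_days,
                         inclusive = inclusive)
    out$label[i] <- if (r$label == "none") "mixed" else r$label
    out$n_increase_days[i] <- r$n_increase_days
    out$n_decrease_days[i] <- r$n_decrease_days
  }
  if (exclude_rhythmic_down) {
    out$excluded <- out$label == "rhythmic_down"
  }
  out
}
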