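#' Fixation-duration measures from scan-path records
#'
#' Derive the three reading measures from a scan path (the time-ordered
#' sequence of fixations to word regions):
#'
#' * **scan path duration** -- time from entering a word region (from either
#'   direction) until entering a different word region (in either direction);
#'   consecutive fixations on the same region merge into one visit; the final
#'   visit runs until the end of the record.
#' * **first-pass duration** -- as scan path, but only for visits whose entry
#'   came from a lower-indexed region (or the start of the record) and whose
#'   region had not been visited before.
#' * **go-past duration** -- for each region first entered from the left:
#'   time from that entry until the first entry of any higher-indexed region,
#'   including all intervening regressive fixation time. Regions whose
#'   rightward exit never occurs before the record ends are unresolved and
#'   excluded (reported in the `"unresolved"` attribute).
#'
#' Region indices are word positions in text order. "From the left" means
#' the previously fixated region had a strictly lower index; the first
#' fixation of a record counts as a leftward entry. Durations are
#' entry-to-entry, so inter-fixation gaps (saccade time) inside a visit are
#' included.
#'
#' @param path data.frame with columns `region_index` (integer >= 0),
#'   `start`, `end` (seconds); fixations must be time-ordered and
#'   non-overlapping.
#' @return data.frame with columns `region_index` and `duration_ms`, one row
#'   per qualifying visit, in visit order. For `go_past_durations` the
#'   attribute `"unresolved"` lists regions without a rightward exit.
#' @examples
#' path <- data.frame(region_index = c(1, 2, 1, 3),
#'                    start = c(0, .2, .35, .45),
#'                    end   = c(.2, .35, .45, .6))
#' scan_path_durations(path)
#' go_past_durations(path)   # go-past of region 2 spans the regression
#' @export
scan_path_durations <- function(path) {
  v <- path_visits(path)
  if (!nrow(v)) return(empty_measure())
  data.frame(region_index = v$region, duration_ms = v$duration_ms)
}

#' @rdname scan_path_durations
#' @export
first_pass_durations <- function(path) {
  v <- path_visits(path)
  if (!nrow(v)) return(empty_measure())
  keep <- v$from_left & !v$seen_before
  data.frame(region_index = v$region[keep], duration_ms = v$duration_ms[keep])
}

#' @rdname scan_path_durations
#' @export
go_past_durations <- function(path) {
  v <- path_visits(path)
  if (!nrow(v)) {
    out <- empty_measure()
    attr(out, "unresolved") <- integer(0)
    return(out)
  }
  first_left <- v$from_left & !v$seen_before
  res <- list()
  unresolved <- integer(0)
  for (i in which(first_left)) {
    r <- v$region[i]
    later <- which(seq_len(nrow(v)) > i & v$region > r)
    if (length(later)) {
      res[[length(res) + 1L]] <- data.frame(
        region_index = r,
        duration_ms = (v$entry[min(later)] - v$entry[i]) * 1000)
    } else {
      unresolved <- c(unresolved, r)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty_measure()
  attr(out, "unresolved") <- unresolved
  out
}

empty_measure <- function() {
  data.frame(region_index = integer(0), duration_ms = numeric(0))
}

# Collapse a fixation sequence into visits: maximal runs of consecutive
# same-region fixations, with entry time, duration (entry-to-entry; last
# visit until record end), entry direction, and whether the region was
# visited before.
path_visits <- function(path) {
  stopifnot(all(c("region_index", "start", "end") %in% names(path)))
  if (!nrow(path)) {
    return(data.frame(region = integer(0), entry = numeric(0),
                      duration_ms = numeric(0), from_left = logical(0),
                      seen_before = logical(0)))
  }
  if (any(path$end <= path$start))
    stop("each fixation must have end > start")
  if (is.unsorted(path$start) ||
      any(path$start[-1] < path$end[-nrow(path)] - 1e-9))
    stop("fixations must be time-ordered and non-overlapping")
  r <- rle(path$region_index)
  n_runs <- length(r$lengths)
  last_of_run <- cumsum(r$lengths)
  first_of_run <- c(1L, last_of_run[-n_runs] + 1L)
  entry <- path$start[first_of_run]
  exit_next <- c(entry[-1], path$end[nrow(path)])
  region <- r$values
  prev_region <- c(NA_integer_, region[-n_runs])
  from_left <- is.na(prev_region) | prev_region < region
  seen_before <- logical(n_runs)
  seen <- integer(0)
  for (i in seq_len(n_runs)) {
    seen_before[i] <- region[i] %in% seen
    seen <- c(seen, region[i])
  }
  data.frame(region = region, entry = entry,
             duration_ms = (exit_next - entry) * 1000,
             from_left = from_left, seen_before = seen_before)
}

#' Grouped reading-measure computation
#'
#' Applies one of the scan-path measures per record (participant x text) of
#' a fixation table.
#'
#' @param fixations data.frame with columns `participant_id`, `text_id`,
#'   `region_index`, `start_s`, `end_s`.
#' @param measure one of `"scanpath"`, `"firstpass"`, `"gopast"`.
#' @return data.frame with `participant_id`, `text_id`, `region_index`,
#'   `duration_ms`.
#' @export
reading_measures <- function(fixations,
                             measure = c("scanpath", "firstpass", "gopast")) {
  measure <- match.arg(measure)
  fn <- switch(measure,
               scanpath = scan_path_durations,
               firstpass = first_pass_durations,
               gopast = go_past_durations)
  grp <- interaction(fixations$participant_id, fixations$text_id, drop = TRUE)
  out <- lapply(split(seq_len(nrow(fixations)), grp), function(idx) {
    sub <- fixations[idx, ]
    m <- fn(data.frame(region_index = sub$region_index,
                       start = sub$start_s, end = sub$end_s))
    if (!nrow(m)) return(NULL)
    data.frame(participant_id = sub$participant_id[1],
               text_id = sub$text_id[1], m)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(0), text_id = character(0),
                      region_index = integer(0), duration_ms = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Filter configuration for response exclusion
#'
#' Encodes the per-dataset response-filtering protocols. Rules set to `NULL`
#' are disabled. Filtering applies only to the response vector; event
#' (predictor) tables are never filtered.
#'
#' @param rt_min,rt_max reaction-time bounds in ms (responses outside are
#'   excluded).
#' @param max_saccade_len exclude responses following a saccade longer than
#'   this many words (in either direction).
#' @param exclude_sentence_boundary,exclude_screen_boundary,exclude_line_boundary
#'   logical; exclude responses at the corresponding boundary.
#' @param exclude_blinks logical; exclude fixations interrupted by blinks.
#' @param min_accuracy exclude all responses of participants whose
#'   comprehension/task accuracy is below this proportion.
#' @param correct_only logical; keep only correct-response trials.
#' @param min_rts_per_participant exclude participants left with fewer than
#'   this many responses after the preceding rules.
#' @return object of class `filter_config`.
#' @seealso [filter_preset()] for the published per-dataset protocols.
#' @export
filter_config <- function(rt_min = NULL, rt_max = NULL,
                          max_saccade_len = NULL,
                          exclude_sentence_boundary = FALSE,
                          exclude_screen_boundary = FALSE,
                          exclude_line_boundary = FALSE,
                          exclude_blinks = FALSE,
                          min_accuracy = NULL,
                          correct_only = FALSE,
                          min_rts_per_participant = NULL) {
  if (!is.null(rt_min) && !is.null(rt_max) && rt_min >= rt_max)
    stop("rt_min must be less than rt_max")
  if (!is.null(max_saccade_len) && max_saccade_len <= 0)
    stop("max_saccade_len must be positive")
  structure(list(rt_min = rt_min, rt_max = rt_max,
                 max_saccade_len = max_saccade_len,
                 exclude_sentence_boundary = exclude_sentence_boundary,
                 exclude_screen_boundary = exclude_screen_boundary,
                 exclude_line_boundary = exclude_line_boundary,
                 exclude_blinks = exclude_blinks,
                 min_accuracy = min_accuracy,
                 correct_only = correct_only,
                 min_rts_per_participant = min_rts_per_participant),
            class = "filter_config")
}

#' Published per-dataset filter protocols
#'
#' Ready-made [filter_config()]s matching the filtering described for each
#' public reading dataset: Brown SPR (RT bounds 100-3000 ms, sentence
#' boundaries), Dundee ET (outlier saccades > 20 words, sentence/screen/line
#' boundaries, blinks), GECO ET (saccades, sentence boundaries), Natural
#' Stories SPR (RT bounds 100-3000 ms, sentence boundaries, < 5/8
#' comprehension accuracy, participants with fewer than 100 RTs), Natural
#' Stories Maze (RT bounds 100-5000 ms, sentence boundaries, incorrect
#' responses, < 80% accuracy), and Provo ET (saccades, sentence boundaries,
#' blinks).
#'
#' @param dataset one of `"brown"`, `"dundee"`, `"geco"`,
#'   `"natural_stories_spr"`, `"natural_stories_maze"`, `"provo"`.
#' @return a [filter_config()].
#' @export
filter_preset <- function(dataset = c("brown", "dundee", "geco",
                                      "natural_stories_spr",
                                      "natural_stories_maze", "provo")) {
  dataset <- match.arg(dataset)
  switch(dataset,
    brown = filter_config(rt_min = 100, rt_max = 3000,
                          exclude_sentence_boundary = TRUE),
    dundee = filter_config(max_saccade_len = 20,
                           exclude_sentence_boundary = TRUE,
                           exclude_screen_boundary = TRUE,
                           exclude_line_boundary = TRUE,
                           exclude_blinks = TRUE),
    geco = filter_config(max_saccade_len = 20,
                         exclude_sentence_boundary = TRUE),
    natural_stories_spr = filter_config(rt_min = 100, rt_max = 3000,
                                        exclude_sentence_boundary = TRUE,
                                        min_accuracy = 5 / 8,
                                        min_rts_per_participant = 100),
    natural_stories_maze = filter_config(rt_min = 100, rt_max = 5000,
                                         exclude_sentence_boundary = TRUE,
                                         correct_only = TRUE,
                                         min_accuracy = 0.8),
    provo = filter_config(max_saccade_len = 20,
                          exclude_sentence_boundary = TRUE,
                          exclude_blinks = TRUE)
  )
}

#' Apply a filter protocol to a response table
#'
#' Rules are applied in a fixed order -- track quality (blinks, outlier
#' saccades), boundary exclusions, RT bounds, accuracy/correctness, and
#' finally the per-participant minimum-response rule (which therefore sees
#' post-item-filter counts). Every excluded response is attributed to the
#' first rule that matches it, and per-rule counts are reported.
#'
#' @param responses data.frame with at least `duration_ms` and
#'   `participant_id`; rules additionally require metadata columns
#'   `blink` (logical), `saccade_len` (words, signed or absolute),
#'   `sentence_boundary`/`screen_boundary`/`line_boundary` (logical),
#'   `accuracy` (per-participant proportion) and `correct` (logical) where
#'   the corresponding rule is enabled. A rule whose metadata column is
#'   missing raises an error naming the rule.
#' @param cfg a [filter_config()].
#' @return list with `kept` (the retained responses) and `log`
#'   (data.frame of `rule`, `n_excluded`).
#' @export
apply_filters <- function(responses, cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  n <- nrow(responses)
  excluded_by <- rep(NA_character_, n)
  need <- function(col, rule) {
    if (!col %in% names(responses))
      stop(sprintf("rule '%s' requires missing metadata column '%s'",
                   rule, col))
    responses[[col]]
  }
  mark <- function(idx, rule) {
    idx <- idx & is.na(excluded_by)
    excluded_by[idx] <<- rule
  }

  # 1. track quality
  if (isTRUE(cfg$exclude_blinks))
    mark(need("blink", "blinks") %in% TRUE, "blink")
  if (!is.null(cfg$max_saccade_len))
    mark(abs(need("saccade_len", "max_saccade_len")) > cfg$max_saccade_len,
         "outlier_saccade")
  # 2. boundaries
  if (isTRUE(cfg$exclude_sentence_boundary))
    mark(need("sentence_boundary", "sentence_boundary") %in% TRUE,
         "sentence_boundary")
  if (isTRUE(cfg$exclude_screen_boundary))
    mark(need("screen_boundary", "screen_boundary") %in% TRUE,
         "screen_boundary")
  if (isTRUE(cfg$exclude_line_boundary))
    mark(need("line_boundary", "line_boundary") %in% TRUE, "line_boundary")
  # 3. RT bounds
  if (!is.null(cfg$rt_min))
    mark(responses$duration_ms < cfg$rt_min, "rt_too_short")
  if (!is.null(cfg$rt_max))
    mark(responses$duration_ms > cfg$rt_max, "rt_too_long")
  # 4. accuracy / correctness
  if (!is.null(cfg$min_accuracy))
    mark(need("accuracy", "min_accuracy") < cfg$min_accuracy, "low_accuracy")
  if (isTRUE(cfg$correct_only))
    mark(!(need("correct", "correct_only") %in% TRUE), "incorrect_response")
  # 5. per-participant minimum, on post-filter counts
  if (!is.null(cfg$min_rts_per_participant)) {
    alive <- is.na(excluded_by)
    counts <- table(responses$participant_id[alive])
    low <- names(counts)[counts < cfg$min_rts_per_participant]
    mark(responses$participant_id %in% low, "too_few_responses")
  }

  rules <- c("blink", "outlier_saccade", "sentence_boundary",
             "screen_boundary", "line_boundary", "rt_too_short",
             "rt_too_long", "low_accuracy", "incorrect_response",
             "too_few_responses")
  log <- data.frame(rule = rules,
                    n_excluded = vapply(rules, function(r)
                      sum(excluded_by %in% r), integer(1)))
  list(kept = responses[is.na(excluded_by), , drop = FALSE], log = log)
}

#' Deterministic train/validation/test partition
#'
#' Assigns each (participant, sentence) cell to a split using modular
#' arithmetic on `i = (s + p) mod 4`: train for `i` in `{0, 1}`, validation
#' for `i = 2`, test for `i = 3`. Over a complete participant x sentence
#' grid with both dimensions multiples of 4 the split fractions are exactly
#' 1/2, 1/4, 1/4.
#'
#' @param p participant index (integer >= 0), vectorized.
#' @param s sentence index (integer >= 0), vectorized.
#' @return character vector in `{"train", "validation", "test"}`.
#' @examples
#' assign_partition(0, 0)  # "train"
#' assign_partition(1, 1)  # "validation"
#' assign_partition(3, 0)  # "test"
#' @export
assign_partition <- function(p, s) {
  if (any(p < 0) || any(s < 0)) stop("participant and sentence indices must be >= 0")
  i <- (as.integer(s) + as.integer(p)) %% 4L
  c("train", "train", "validation", "test")[i + 1L]
}
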