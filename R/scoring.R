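#' Total the 4-sign observational neurological score
#'
#' The score counts four abnormal signs on one body side — hands/feet
#' slipping off poles, hands dangling below perch level, an arms-across-
#' midline posture, and uncoordinated arm movement/hand waving — one point
#' each, 0–4 total. Higher = worse.
#'
#' @param record A one-row data frame (or list) with logical/0-1 fields
#'   `slip`, `dangle`, `midline`, `uncoordinated`.
#' @return Integer score 0–4.
#' @export
total_score <- function(record) {
  signs <- c("slip", "dangle", "midline", "uncoordinated")
  if (!all(signs %in% names(record)))
    stop("total_score: record must carry fields ",
         paste(signs, collapse = ", "), call. = FALSE)
  v <- vapply(signs, function(s) {
    x <- record[[s]]
    if (length(x) != 1 || is.na(x) || !(x %in% c(0, 1, TRUE, FALSE)))
      stop("total_score: sign '", s, "' must be a single 0/1 flag",
           call. = FALSE)
    as.integer(x)
  }, integer(1))
  sum(v)
}

#' Daily neurological-score time course for the affected side
#'
#' Totals the sign flags per animal-day on the chosen side and returns a
#' complete day-indexed series per animal: every day between the first and
#' last recorded day appears, with missing days reported as `NA`, never
#' imputed.
#'
#' @param records Data frame with columns
#'   `animal, day, side, slip, dangle, midline, uncoordinated`.
#' @param affected_side Side whose score enters the analysis; the affected
#'   side is contralateral to the lesion (right, for a left-hemisphere
#'   stroke).
#' @return Data frame of class `score_series`: `animal, day, score`.
#' @export
score_timecourse <- function(records, affected_side = "right") {
  need <- c("animal", "day", "side", "slip", "dangle", "midline",
            "uncoordinated")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("score_timecourse: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec <- records[records$side == affected_side, , drop = FALSE]
  if (!nrow(rec))
    stop("score_timecourse: no records for side '", affected_side, "'",
         call. = FALSE)
  key <- paste(rec$animal, rec$day, sep = "#")
  if (anyDuplicated(key))
    stop("score_timecourse: duplicate animal-day-side records: ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  rec$score <- vapply(seq_len(nrow(rec)),
                      function(i) total_score(rec[i, ]), integer(1))
  out <- do.call(rbind, lapply(split(rec, rec$animal), function(a) {
    days <- seq(min(a$day), max(a$day))
    data.frame(animal = a$animal[1], day = days,
               score = a$score[match(days, a$day)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("score_series", "data.frame")
  out
}
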