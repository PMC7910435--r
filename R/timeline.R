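#' Posting timeline for one user
#'
#' An ordered record of one user's posts: event times (hours since an
#' arbitrary epoch), likes received per post, and the derived inter-post
#' latencies. The latency attached to post `t` (`t >= 2`) is
#' `tau[t] = timestamps[t] - timestamps[t - 1]` in hours; the first post has
#' no latency.
#'
#' @param user_id Identifier (coerced to character).
#' @param timestamps Strictly increasing numeric event times in hours, or a
#'   `POSIXct` vector (converted to hours).
#' @param likes Non-negative integer likes per post, same length as
#'   `timestamps`.
#' @return An object of class `post_timeline` with elements `user_id`,
#'   `timestamps`, `likes` and `latencies` (length `n - 1`, aligned with
#'   posts `2..n`).
#' @examples
#' tl <- post_timeline("u1", cumsum(c(0, 10, 20, 30)), c(2, 5, 1, 0))
#' tl$latencies
#' @export
post_timeline <- function(user_id, timestamps, likes) {
  if (inherits(timestamps, "POSIXct"))
    timestamps <- as.numeric(timestamps) / 3600
  timestamps <- as.numeric(timestamps)
  likes <- as.numeric(likes)
  if (length(likes) != length(timestamps))
    stop("likes and timestamps must have the same length", call. = FALSE)
  if (length(timestamps) >= 2 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(!is.finite(likes)) || any(likes < 0) || any(likes != round(likes)))
    stop("likes must be non-negative integers", call. = FALSE)
  structure(list(user_id = as.character(user_id)[1],
                 timestamps = timestamps,
                 likes = likes,
                 latencies = diff(timestamps)),
            class = "post_timeline")
}

#' @export
print.post_timeline <- function(x, ...) {
  n <- length(x$timestamps)
  cat(sprintf("Posting timeline for user '%s': %d posts", x$user_id, n))
  if (n >= 2)
    cat(sprintf(", median latency %.3g h, mean likes %.3g",
                median(x$latencies), mean(x$likes)))
  cat("\n")
  invisible(x)
}

#' @export
length.post_timeline <- function(x) length(x$timestamps)

#' @export
as.data.frame.post_timeline <- function(x, ...) {
  data.frame(user_id = x$user_id,
             t = seq_along(x$timestamps),
             timestamp = x$timestamps,
             likes = x$likes,
             tau = c(NA_real_, x$latencies),
             stringsAsFactors = FALSE)
}

#' Read posting timelines from CSV or JSON Lines
#'
#' The CSV format has a required header with columns `user_id`, `timestamp`
#' and `likes`; `timestamp` is either numeric hours or an ISO 8601 datetime.
#' The JSON Lines format has one object per line with the same fields.
#'
#' @param path File path.
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (by file extension).
#' @return A named list of [post_timeline] objects, one per user, posts
#'   sorted by timestamp.
#' @export
read_timelines <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    jsonlite::stream_in(file(path), verbose = FALSE)
  }
  req <- c("user_id", "timestamp", "likes")
  if (!all(req %in% names(df)))
    stop("timeline file must have columns user_id, timestamp, likes",
         call. = FALSE)
  ts <- df$timestamp
  if (!is.numeric(ts)) {
    parsed <- as.POSIXct(ts, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                        "%Y-%m-%dT%H:%M", "%Y-%m-%d"))
    if (any(is.na(parsed)))
      stop("could not parse timestamps as ISO 8601", call. = FALSE)
    ts <- as.numeric(parsed) / 3600
  }
  df$.hours <- ts
  split_df <- split(df, df$user_id)
  out <- lapply(split_df, function(d) {
    d <- d[order(d$.hours), , drop = FALSE]
    post_timeline(d$user_id[1], d$.hours, d$likes)
  })
  out[order(names(out))]
}

#' Write posting timelines to CSV
#'
#' Writes the long format read back by [read_timelines()]: columns
#' `user_id`, `timestamp` (hours), `likes`.
#'
#' @param timelines A list of [post_timeline] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timelines <- function(timelines, path) {
  rows <- lapply(timelines, function(tl)
    data.frame(user_id = tl$user_id, timestamp = tl$timestamps,
               likes = tl$likes, stringsAsFactors = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Stack timelines into a long data frame
#'
#' @param timelines A list of [post_timeline] objects.
#' @return A data frame with one row per post: `user_id`, `t` (post index),
#'   `timestamp`, `likes`, `tau` (NA for the first post of each user).
#' @export
timelines_to_df <- function(timelines) {
  do.call(rbind, c(lapply(timelines, as.data.frame),
                   list(make.row.names = FALSE)))
}
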