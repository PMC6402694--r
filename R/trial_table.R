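#' Trial tables of delay-period firing rates
#'
#' A trial table is the package's tabular data model: one row per trial,
#' holding task metadata and the binned multiunit firing rate of every
#' channel during the delay window (spikes/s). It is a plain `data.frame`
#' with class `"trial_table"`, so all usual data-frame idioms apply.
#'
#' Required metadata columns: `trial_id` (integer), `session_id`
#' (character), `task` (one of `"ring"`, `"horizontal"`, `"vertical"`,
#' `"rings3"`), `condition_id` (integer), `target_x`, `target_y` (cm),
#' `delay` (ms, > 0), `max_speed` (cm/s), `max_speed_x`, `max_speed_y`
#' (cm, hand position at maximum speed). Rate columns are named
#' `rate_000`, `rate_001`, ... and must be finite.
#'
#' @param df a data.frame with the columns above.
#' @return `trial_table()` returns a validated `trial_table`.
#' @examples
#' tt <- simulate_trials(make_target_layout("ring", "J"),
#'                       n_per_condition = 2, seed = 1)
#' n_channels(tt)
#' dim(rate_matrix(tt))
#' @export
trial_table <- function(df) {
  validate_trial_table(df)
  class(df) <- unique(c("trial_table", class(df)))
  df
}

TASKS <- c("ring", "horizontal", "vertical", "rings3")

META_COLS <- c("trial_id", "session_id", "task", "condition_id",
               "target_x", "target_y", "delay", "max_speed",
               "max_speed_x", "max_speed_y")

#' @rdname trial_table
#' @export
validate_trial_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(META_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  rc <- rate_cols(df)
  if (length(rc) == 0) stop("missing required column(s): rate_000, ...")
  if (!all(df$task %in% TASKS))
    stop("unknown task value(s): ",
         paste(unique(setdiff(df$task, TASKS)), collapse = ", "))
  if (any(df$delay <= 0))
    stop("delay must be > 0 for all retained trials (trial_id ",
         df$trial_id[which(df$delay <= 0)[1]], ")")
  rates <- as.matrix(df[rc])
  if (!all(is.finite(rates))) {
    bad <- which(!apply(is.finite(rates), 1, all))[1]
    stop("non-finite rate value (trial_id ", df$trial_id[bad], ")")
  }
  # each condition_id maps to one target position within a task
  key <- paste(df$task, df$condition_id)
  pos <- paste(signif(df$target_x, 12), signif(df$target_y, 12))
  if (any(tapply(pos, key, function(p) length(unique(p))) > 1))
    stop("a condition_id maps to more than one target position within a task")
  invisible(df)
}

#' @rdname trial_table
#' @param table a `trial_table`.
#' @export
rate_cols <- function(table) grep("^rate_[0-9]+$", names(table), value = TRUE)

#' @rdname trial_table
#' @return `rate_matrix()` returns the trials x channels numeric matrix.
#' @export
rate_matrix <- function(table) {
  m <- as.matrix(table[rate_cols(table)])
  rownames(m) <- NULL
  m
}

#' @rdname trial_table
#' @return `n_channels()` returns the channel count.
#' @export
n_channels <- function(table) length(rate_cols(table))

#' Combine trial tables
#'
#' Row-binds trial tables (e.g. the horizontal and vertical line tasks,
#' which the subspace fit pools because a single line leaves one target
#' coordinate constant), re-numbering `trial_id` so it stays unique.
#'
#' @param ... trial tables with identical columns.
#' @return a [trial_table()].
#' @export
pool_trials <- function(...) {
  parts <- lapply(list(...), as.data.frame)
  out <- do.call(rbind, parts)
  out$trial_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  trial_table(out)
}

#' Read and write trial tables
#'
#' CSV is the canonical interchange format: one row per trial, rates in
#' columns `rate_000..rate_NNN`, full `double` precision preserved on
#' round-trip. Row order is preserved.
#'
#' @param path file path.
#' @param format only `"csv"` is supported.
#' @return `read_trials()` returns a validated [trial_table()];
#'   `write_trials()` invisibly returns `path`.
#' @examples
#' tt <- simulate_trials(make_target_layout("ring", "J"),
#'                       n_per_condition = 1, seed = 1)
#' p <- tempfile(fileext = ".csv")
#' write_trials(tt, p)
#' identical(dim(read_trials(p)), dim(tt))
#' @export
read_trials <- function(path, format = "csv") {
  if (!identical(format, "csv"))
    stop("unsupported format '", format, "': only 'csv' is implemented")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(session_id = "character"))
  df$trial_id <- as.integer(df$trial_id)
  df$condition_id <- as.integer(df$condition_id)
  trial_table(df)
}

#' @rdname read_trials
#' @param table a [trial_table()].
#' @export
write_trials <- function(table, path, format = "csv") {
  if (!identical(format, "csv"))
    stop("unsupported format '", format, "': only 'csv' is implemented")
  validate_trial_table(table)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to missing directory: ", dir)
  df <- as.data.frame(table)
  # 17 significant digits round-trips IEEE doubles exactly through text
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = which(names(df) == "session_id"))
  invisible(path)
}
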