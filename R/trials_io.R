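#' @keywords internal
TRIAL_SCHEMA_VERSION <- "huememory-trials v1"

# Column order and types of the trial table; one row per 2AFC trial.
trial_columns <- function() {
  c(condition = "character",
    background_symmetry = "character",
    delay = "character",
    distractors = "character",
    reference_hue = "numeric",
    test_hue = "numeric",
    reference_background = "character",
    reference_side = "character",
    phase = "character",
    staircase_id = "integer",
    response_test_bluer = "logical",
    trial_index = "integer",
    seed = "integer")
}

#' An empty trial table
#'
#' @return A zero-row data frame with the trial-table schema: one row
#'   per 2AFC trial, carrying the condition, reference and test hues
#'   (radians), the reference background and side, the collection phase
#'   (`"staircase"` or `"mocs"`), the staircase id where applicable,
#'   the binary response, and the seed of the generating block.
#' @export
empty_trials <- function() {
  cols <- trial_columns()
  out <- lapply(names(cols), function(nm) vector(cols[[nm]], 0L))
  names(out) <- names(cols)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @keywords internal
validate_trials <- function(trials, context = "trial table") {
  cols <- trial_columns()
  missing <- setdiff(names(cols), names(trials))
  if (length(missing) > 0)
    stop(context, ": missing column(s): ", paste(missing, collapse = ", "))
  trials
}

#' Write / read a trial table
#'
#' Trial tables are plain comma-separated text with a header line,
#' preceded by a `#`-prefixed comment naming the schema version. The
#' round trip through disk is lossless. `read_trials()` validates the
#' schema and reports malformed rows by line number.
#'
#' @param trials A trial table (see [empty_trials()] for the schema).
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the trial table.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", TRIAL_SCHEMA_VERSION), con)
  utils::write.csv(trials[, names(trial_columns())], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such trial table: ", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = NA)
  validate_trials(raw, context = path)
  cols <- trial_columns()
  # Header comment occupies line 1, column header line 2; data start at 3.
  for (nm in names(cols)) {
    coerced <- switch(cols[[nm]],
                      numeric = suppressWarnings(as.numeric(raw[[nm]])),
                      integer = suppressWarnings(as.integer(raw[[nm]])),
                      logical = as.logical(raw[[nm]]),
                      as.character(raw[[nm]]))
    bad <- which(is.na(coerced) & !is.na(raw[[nm]]))
    no_na <- nm %in% c("reference_hue", "test_hue", "response_test_bluer",
                       "trial_index")
    if (no_na) bad <- union(bad, which(is.na(coerced)))
    if (length(bad) > 0)
      stop(path, ": malformed value in column '", nm, "' at line ",
           bad[1] + 2L)
    raw[[nm]] <- coerced
  }
  raw[, names(cols)]
}

# Assemble trial rows from parallel vectors; fills schema defaults.
build_trials <- function(condition_name, cond, reference_hue, test_hue,
                         reference_background, reference_side, phase,
                         staircase_id = NA_integer_, response, seed) {
  n <- length(reference_hue)
  data.frame(
    condition = rep_len(condition_name, n),
    background_symmetry = rep_len(cond$background_symmetry, n),
    delay = rep_len(cond$delay, n),
    distractors = rep_len(cond$distractors, n),
    reference_hue = reference_hue,
    test_hue = test_hue,
    reference_background = reference_background,
    reference_side = reference_side,
    phase = rep_len(phase, n),
    staircase_id = rep_len(as.integer(staircase_id), n),
    response_test_bluer = response,
    trial_index = seq_len(n),
    seed = rep_len(as.integer(seed), n),
    stringsAsFactors = FALSE
  )
}
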