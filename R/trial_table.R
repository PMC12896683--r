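# Trial tables: one row per trial, presentation order, with condition labels
# and derived previous-trial (N-1) labels.

.tt_required_cols <- c(
  "session", "block", "trial", "distractor_present",
  "distractor_hemifield", "distractor_position",
  "target_hemifield", "target_position", "high_prob_hemifield"
)
.tt_prev_cols <- c("prev_distractor_hemifield", "prev_target_hemifield")

#' Validate a trial table
#'
#' Checks the contract for trial tables: required columns, strict ordering by
#' (session, block, trial), and the consistency rule that
#' `distractor_hemifield == "absent"` exactly on distractor-absent trials.
#'
#' @param table a data.frame, one row per trial in presentation order.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_trial_table <- function(table) {
  .assert(is.data.frame(table), "trial table must be a data.frame")
  missing <- setdiff(.tt_required_cols, names(table))
  .assert(length(missing) == 0,
          paste("trial table lacks columns:", paste(missing, collapse = ", ")))
  key <- order(table$session, table$block, table$trial)
  .assert(all(key == seq_len(nrow(table))),
          "trial table rows must be ordered by (session, block, trial)")
  kid <- paste(table$session, table$block, table$trial)
  .assert(!anyDuplicated(kid), "duplicated (session, block, trial) keys")
  .assert(all((table$distractor_hemifield == "absent") ==
                !table$distractor_present),
          "distractor_hemifield must be 'absent' exactly when distractor_present is FALSE")
  .assert(all(table$distractor_hemifield %in% c("left", "right", "absent")),
          "distractor_hemifield must be left/right/absent")
  .assert(all(table$target_hemifield %in% c("left", "right")),
          "target_hemifield must be left/right")
  invisible(table)
}

#' Attach previous-trial (N-1) labels
#'
#' Fills `prev_distractor_hemifield` and `prev_target_hemifield` with the
#' values of the immediately preceding trial within the same block. The first
#' trial of each block gets NA (previous-trial history does not cross block
#' breaks). Idempotent: the derived columns are recomputed from the current
#' labels on every call.
#'
#' @param table a valid trial table (see [validate_trial_table()]).
#' @return the table with the two `prev_*` columns (re)filled.
#' @export
attach_previous_labels <- function(table) {
  validate_trial_table(table)
  grp <- paste(table$session, table$block)
  shift1 <- function(x) c(NA, x[-length(x)])
  prev_d <- unlist(lapply(split(table$distractor_hemifield, factor(grp, unique(grp))), shift1),
                   use.names = FALSE)
  prev_t <- unlist(lapply(split(table$target_hemifield, factor(grp, unique(grp))), shift1),
                   use.names = FALSE)
  table$prev_distractor_hemifield <- prev_d
  table$prev_target_hemifield <- prev_t
  table
}

#' Write / read a trial table as CSV
#'
#' Plain-CSV serialization with the exact trial-table column names and the
#' string "NA" for missing values.
#'
#' @param table a trial table.
#' @param path file path.
#' @return `read_trial_table` returns the table; `write_trial_table` returns
#'   the path invisibly.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(table)
  utils::write.csv(table, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  .assert(file.exists(path), paste("no such file:", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  tab$distractor_present <- as.logical(tab$distractor_present)
  validate_trial_table(tab)
  tab
}
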