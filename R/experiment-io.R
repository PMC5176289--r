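# Reading and writing trial-record tables. External raw files (e.g. the
# experiments' deposited TXT) are mapped onto the canonical schema through a
# small, data-driven dialect so that unknown column names or role/treatment
# codes never get silently coerced.

# Canonical schema. `wins`/`points` are optional: no analysis needs them.
.TRIAL_COLUMNS <- c("session", "group", "design", "information", "role",
                    "subject", "block", "trial", "concordant", "urn_chosen",
                    "demo_optimal_urn", "social_optimal_urn")
.TRIAL_COLUMNS_OPT <- c("wins", "points")

#' Dialect describing an external raw-data layout
#'
#' A dialect maps an external file's columns and codes onto the canonical
#' trial-record schema. The default is a best guess for a tab-separated file
#' already using canonical names; real deposited files should be inspected and
#' given an explicit mapping — the reader validates totality and never guesses.
#'
#' @param delimiter Field delimiter.
#' @param columns Named character vector mapping canonical field names to the
#'   source file's column names. Must cover every canonical field (wins and
#'   points are optional).
#' @param role_codes Named character vector mapping the source file's role
#'   codes to `"demonstrator"` and `"social_learner"`; names are the source
#'   codes.
#' @param urn_codes Named character vector mapping source urn codes to `"L"`
#'   and `"R"`; names are the source codes.
#' @param true_codes Character vector of source values read as `TRUE` for the
#'   concordance field.
#' @return An object of class `raw_dialect`.
#' @export
#' @examples
#' raw_dialect(delimiter = "\t")
raw_dialect <- function(delimiter = "\t",
                        columns = stats::setNames(.TRIAL_COLUMNS, .TRIAL_COLUMNS),
                        role_codes = c(demonstrator = "demonstrator",
                                       social_learner = "social_learner"),
                        urn_codes = c(L = "L", R = "R"),
                        true_codes = c("TRUE", "1", "yes")) {
  stopifnot(is.character(delimiter), nchar(delimiter) >= 1,
            is.character(columns), !is.null(names(columns)))
  missing_fields <- setdiff(.TRIAL_COLUMNS, names(columns))
  if (length(missing_fields) > 0) {
    stop("dialect does not map required fields: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  structure(list(delimiter = delimiter, columns = columns,
                 role_codes = role_codes, urn_codes = urn_codes,
                 true_codes = true_codes),
            class = "raw_dialect")
}

#' Validate a trial-record table
#'
#' Checks the canonical schema and the design invariants: allowed role and
#' urn codes, blocks with exactly `demonstrators_per_group` demonstrator rows
#' per trial and one row per social learner, a constant urn assignment within
#' each group-block, and (for within-subjects sessions) social learners with
#' exactly `n_blocks` block rows. Errors name the offending rows.
#'
#' @param table A trial-record data frame.
#' @param demonstrators_per_group Expected demonstrators per group.
#' @param n_blocks Expected blocks per within-subjects learner, or `NULL` to
#'   accept any count.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_trial_records <- function(table, demonstrators_per_group = 5L,
                                   n_blocks = 20L) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(.TRIAL_COLUMNS, names(table))
  if (length(missing_cols) > 0) {
    stop("trial-record table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_role <- !table$role %in% c("demonstrator", "social_learner")
  if (any(bad_role)) {
    stop("unknown role code at row ", which(bad_role)[1], ": ",
         table$role[which(bad_role)[1]], call. = FALSE)
  }
  for (col in c("urn_chosen", "demo_optimal_urn", "social_optimal_urn")) {
    bad <- !table[[col]] %in% c("L", "R")
    if (any(bad)) {
      stop("unknown urn code in column ", col, " at row ", which(bad)[1],
           call. = FALSE)
    }
  }
  if (!is.logical(table$concordant) || anyNA(table$concordant)) {
    stop("column `concordant` must be logical and complete", call. = FALSE)
  }

  key <- interaction(table$session, table$group, table$block, drop = TRUE)
  # urn assignment constant within a group-block
  n_opt <- tapply(table$demo_optimal_urn, key, function(u) length(unique(u)))
  if (any(n_opt > 1)) {
    stop("demo_optimal_urn varies within group-block ",
         names(n_opt)[which(n_opt > 1)[1]], call. = FALSE)
  }
  # demonstrator rows: demonstrators_per_group per trial per group-block
  demo <- table[table$role == "demonstrator", ]
  if (nrow(demo) > 0) {
    dkey <- interaction(demo$session, demo$group, demo$block, demo$trial,
                        drop = TRUE)
    counts <- table(dkey)
    if (any(counts != demonstrators_per_group)) {
      bad <- names(counts)[which(counts != demonstrators_per_group)[1]]
      stop("group-block-trial ", bad, " has ",
           counts[which(counts != demonstrators_per_group)[1]],
           " demonstrator rows, expected ", demonstrators_per_group,
           call. = FALSE)
    }
  }
  # social learners: one row per learner-block; within design: n_blocks rows
  soc <- table[table$role == "social_learner", ]
  if (nrow(soc) > 0) {
    skey <- interaction(soc$subject, soc$block, drop = TRUE)
    dup <- table(skey)
    if (any(dup > 1)) {
      stop("social learner has multiple rows in a block: ",
           names(dup)[which(dup > 1)[1]], call. = FALSE)
    }
    if (!is.null(n_blocks)) {
      within <- soc[soc$design == "within", ]
      if (nrow(within) > 0) {
        per <- table(within$subject)
        if (any(per != n_blocks)) {
          bad <- names(per)[which(per != n_blocks)[1]]
          stop("within-subjects social learner ", bad, " has ",
               per[[which(per != n_blocks)[1]]], " block rows, expected ",
               n_blocks, call. = FALSE)
        }
      }
    }
  }
  invisible(table)
}

#' Read a raw data file into the canonical trial-record schema
#'
#' @param path Path to a delimited text file.
#' @param dialect A [raw_dialect()] describing the file's layout.
#' @param validate Validate the resulting table (recommended).
#' @param ... Passed to [validate_trial_records()].
#' @return A validated trial-record data frame.
#' @export
read_trial_records <- function(path, dialect = raw_dialect(), validate = TRUE,
                               ...) {
  stopifnot(inherits(dialect, "raw_dialect"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_src <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing_src) > 0) {
    stop("file ", path, " lacks columns required by the dialect: ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  tab <- raw[unname(dialect$columns)]
  names(tab) <- names(dialect$columns)
  for (opt in .TRIAL_COLUMNS_OPT) {
    if (opt %in% names(raw) && !opt %in% names(tab)) tab[[opt]] <- raw[[opt]]
  }

  # decode roles
  src_role <- as.character(tab$role)
  unknown <- !src_role %in% names(dialect$role_codes)
  if (any(unknown)) {
    stop("unmappable role code at row ", which(unknown)[1], ": ",
         src_role[which(unknown)[1]], call. = FALSE)
  }
  tab$role <- unname(dialect$role_codes[src_role])
  # decode urns
  for (col in c("urn_chosen", "demo_optimal_urn", "social_optimal_urn")) {
    src <- as.character(tab[[col]])
    unknown <- !src %in% names(dialect$urn_codes)
    if (any(unknown)) {
      stop("unmappable urn code in ", col, " at row ", which(unknown)[1],
           ": ", src[which(unknown)[1]], call. = FALSE)
    }
    tab[[col]] <- unname(dialect$urn_codes[src])
  }
  if (!is.logical(tab$concordant)) {
    tab$concordant <- as.character(tab$concordant) %in% dialect$true_codes
  }
  tab$block <- as.integer(tab$block)
  tab$trial <- suppressWarnings(as.integer(tab$trial))
  if (validate) validate_trial_records(tab, ...)
  tab
}

#' Write a trial-record table as tidy delimited text
#'
#' @param table A trial-record data frame.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab, matching [raw_dialect()]).
#' @return `path`, invisibly.
#' @export
write_trial_records <- function(table, path, delimiter = "\t") {
  validate_trial_records(table, n_blocks = NULL)
  utils::write.table(table, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
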