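# Canonical column names of a household-level cost-effectiveness table.
# The analysis triplet (treated, cost, effect) is mandatory for any fit;
# covariates are optional and may contain missing values.
CEA_COLUMNS <- c("household_id", "treated", "cost", "effect",
                 "education", "place", "asset_quintile", "age_head")
CEA_CORE <- c("household_id", "treated", "cost", "effect")

#' Construct a household-level cost-effectiveness dataset
#'
#' A `cea_dataset` is a data frame with one row per household (or patient)
#' holding the arm indicator, total cost, effect, and optional covariates,
#' plus metadata describing currency and effect labels. The constructor
#' normalises column types; it does not reject invalid values — use
#' [validate_cea_dataset()] to obtain a list of invariant violations.
#'
#' @param data data frame with at least the columns `household_id`,
#'   `treated` (0/1 arm indicator, 1 = intervention), `cost` (non-negative,
#'   in `currency` units) and `effect` (binary utilisation indicator by
#'   default). Optional covariate columns: `education` (0/1), `place`
#'   (0/1, 1 = town), `asset_quintile` (1..5, 1 = most poor), `age_head`
#'   (years).
#' @param currency currency label for reporting (default `"XOF"`).
#' @param effect_label label of the effect measure.
#' @param effect_binary whether the effect is declared binary (the reference
#'   analysis); continuous non-negative effects are admitted when `FALSE`.
#' @param covariates character vector naming the covariate columns carried
#'   by the dataset; defaults to those of the canonical schema present in
#'   `data`.
#' @return an object of class `cea_dataset` (a data frame).
#' @seealso [read_cea_dataset()], [write_cea_dataset()],
#'   [validate_cea_dataset()]
#' @export
#' @examples
#' d <- cea_dataset(data.frame(household_id = c("a", "b"),
#'                             treated = c(1, 0),
#'                             cost = c(70253, 9630),
#'                             effect = c(1, 0)))
#' d
cea_dataset <- function(data, currency = "XOF",
                        effect_label = "use of health services",
                        effect_binary = TRUE,
                        covariates = NULL) {
  data <- as.data.frame(data)
  missing_core <- setdiff(CEA_CORE, names(data))
  if (length(missing_core))
    stop("missing required column(s): ", paste(missing_core, collapse = ", "),
         call. = FALSE)
  data$household_id <- as.character(data$household_id)
  for (col in setdiff(intersect(CEA_COLUMNS, names(data)), "household_id"))
    data[[col]] <- as.numeric(data[[col]])
  if (is.null(covariates))
    covariates <- intersect(c("education", "place", "asset_quintile",
                              "age_head"), names(data))
  structure(data,
            currency = currency,
            effect_label = effect_label,
            effect_binary = effect_binary,
            covariates = covariates,
            class = c("cea_dataset", "data.frame"))
}

#' @export
print.cea_dataset <- function(x, ...) {
  n1 <- sum(x$treated == 1, na.rm = TRUE)
  n0 <- sum(x$treated == 0, na.rm = TRUE)
  cat(sprintf("<cea_dataset> %d records (%d intervention, %d comparison)\n",
              nrow(x), n1, n0))
  cat(sprintf("  cost in %s; effect: %s (%s)\n", attr(x, "currency"),
              attr(x, "effect_label"),
              if (isTRUE(attr(x, "effect_binary"))) "binary" else "continuous"))
  if (length(attr(x, "covariates")))
    cat("  covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a cost-effectiveness dataset from a delimited text file
#'
#' Reads a comma-separated file with a header row into a [cea_dataset].
#' Column names can be remapped through `schema`; unmapped columns are
#' ignored. Missing values are empty cells. Row order is preserved.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping canonical names
#'   (`household_id`, `treated`, `cost`, `effect`, `education`, `place`,
#'   `asset_quintile`, `age_head`) to the column names used in the file;
#'   canonical names absent from `schema` are looked up verbatim.
#' @inheritParams cea_dataset
#' @return a [cea_dataset].
#' @export
read_cea_dataset <- function(path, schema = NULL, currency = "XOF",
                             effect_label = "use of health services",
                             effect_binary = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  mapping <- stats::setNames(CEA_COLUMNS, CEA_COLUMNS)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), CEA_COLUMNS)
    if (length(bad))
      stop("unknown canonical column(s) in schema: ",
           paste(bad, collapse = ", "), call. = FALSE)
    mapping[names(schema)] <- schema
  }
  present <- mapping[mapping %in% names(raw)]
  missing_core <- setdiff(CEA_CORE, names(present))
  if (length(missing_core))
    stop("mapped column(s) not found in file header: ",
         paste(mapping[missing_core], collapse = ", "), call. = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(present)) {
    col <- raw[[present[[canon]]]]
    if (canon == "household_id") {
      out[[canon]] <- col
    } else {
      parsed <- suppressWarnings(as.numeric(col))
      bad_rows <- which(!is.na(col) & is.na(parsed))
      if (length(bad_rows))
        stop(sprintf("unparseable value '%s' in column '%s' at data row %d",
                     col[bad_rows[1]], present[[canon]], bad_rows[1]),
             call. = FALSE)
      out[[canon]] <- parsed
    }
  }
  cea_dataset(out, currency = currency, effect_label = effect_label,
              effect_binary = effect_binary)
}

#' Write a cost-effectiveness dataset to a delimited text file
#'
#' Writes a [cea_dataset] as comma-separated text with a header row and
#' empty cells for missing values, such that [read_cea_dataset()] on the
#' result reproduces the dataset field by field.
#'
#' @param dataset a [cea_dataset].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cea_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "cea_dataset"))
  cols <- intersect(CEA_COLUMNS, names(dataset))
  utils::write.csv(as.data.frame(dataset)[, cols, drop = FALSE], path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Validate a cost-effectiveness dataset against its type invariants
#'
#' Checks every record against the schema invariants: `treated` in {0, 1},
#' `effect` in {0, 1} when the effect is declared binary (non-negative
#' otherwise), `cost` non-negative, `asset_quintile` in 1..5 or missing,
#' the analysis triplet non-missing, and unique `household_id`. Violations
#' are returned as data, not raised as errors.
#'
#' @param dataset a [cea_dataset].
#' @return data frame with columns `household_id`, `field`, `rule`; zero
#'   rows iff the dataset satisfies every invariant.
#' @export
validate_cea_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "cea_dataset"))
  v <- list()
  flag <- function(idx, field, rule) {
    if (any(idx)) v[[length(v) + 1L]] <<- data.frame(
      household_id = dataset$household_id[idx], field = field, rule = rule,
      stringsAsFactors = FALSE)
  }
  flag(is.na(dataset$treated), "treated", "missing arm indicator")
  flag(!is.na(dataset$treated) & !dataset$treated %in% c(0, 1),
       "treated", "arm indicator must be 0 or 1")
  flag(is.na(dataset$cost), "cost", "missing cost")
  flag(!is.na(dataset$cost) & dataset$cost < 0, "cost", "negative cost")
  flag(is.na(dataset$effect), "effect", "missing effect")
  if (isTRUE(attr(dataset, "effect_binary"))) {
    flag(!is.na(dataset$effect) & !dataset$effect %in% c(0, 1),
         "effect", "binary effect must be 0 or 1")
  } else {
    flag(!is.na(dataset$effect) & dataset$effect < 0,
         "effect", "negative effect")
  }
  if ("asset_quintile" %in% names(dataset))
    flag(!is.na(dataset$asset_quintile) &
           !dataset$asset_quintile %in% 1:5,
         "asset_quintile", "asset quintile must be in 1..5")
  dup <- duplicated(dataset$household_id)
  flag(dup, "household_id", "duplicate household id")
  if (!length(v))
    return(data.frame(household_id = character(), field = character(),
                      rule = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

# Internal: complete-case subset on the analysis triplet plus `vars`,
# reporting how many records were dropped.
complete_cases_on <- function(dataset, vars = character()) {
  need <- c("treated", "cost", "effect", vars)
  keep <- stats::complete.cases(as.data.frame(dataset)[, need, drop = FALSE])
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("dropping %d record(s) with missing values in: %s",
                    dropped, paste(need, collapse = ", ")))
  list(data = dataset[keep, , drop = FALSE], n_dropped = dropped)
}

# Internal: both-arms precondition used by two-arm operations.
check_two_arms <- function(data, context = "dataset") {
  n1 <- sum(data$treated == 1)
  n0 <- sum(data$treated == 0)
  if (n1 == 0 || n0 == 0)
    stop(sprintf("%s must contain records from both arms (found %d intervention, %d comparison)",
                 context, n1, n0), call. = FALSE)
  invisible(c(n1 = n1, n0 = n0))
}
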