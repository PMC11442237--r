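CORE_COLS <- c("item_id", "unit_id", "model", "a", "b", "steps", "subpool")

#' Construct a unit-nested item pool
#'
#' Items are nested in units that share a stimulus; selecting any item of a
#' unit implies "selecting" its stimulus during assembly. The item table is
#' long/flat with `unit_id` as foreign key; the unit table is derived from
#' it (an explicit one may be supplied to fix unit ordering or carry extra
#' unit metadata).
#'
#' @param items Data frame with mandatory columns `item_id`, `unit_id`,
#'   `model` ("2PL" or "GPCM"), `a`, `b`, `steps` (list-column of numeric
#'   step parameters, or a character column of semicolon-joined reals).
#'   An optional `subpool` column ("A"/"B"/NA) carries the item-position
#'   partition label. Every remaining column is a categorical blueprint
#'   attribute (e.g. `cognitive_process`, `coding`).
#' @param units Optional data frame with column `unit_id` (ordering is
#'   respected); derived from `items` when omitted.
#' @param domain Domain label for the pool (e.g. "READ").
#' @return An object of class `hat_pool` with elements `items`, `units`,
#'   `domain`.
#' @export
hat_pool <- function(items, units = NULL, domain = "GEN") {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  miss <- setdiff(c("item_id", "unit_id", "model", "a", "b"), names(items))
  if (length(miss))
    stop_hat(paste0("item table lacks mandatory column(s): ",
                    paste(miss, collapse = ", ")), "hatcat_schema_error")
  if (!"steps" %in% names(items)) items$steps <- replicate(nrow(items),
                                                           numeric(0),
                                                           simplify = FALSE)
  if (is.character(items$steps)) items$steps <- parse_steps(items$steps)
  if (!"subpool" %in% names(items)) items$subpool <- NA_character_
  if (anyDuplicated(items$item_id))
    stop_hat("duplicate item_id in pool", "hatcat_integrity_error")
  if (!all(items$model %in% c("2PL", "GPCM")))
    stop_hat("model must be '2PL' or 'GPCM'", "hatcat_schema_error")
  if (any(items$a <= 0))
    stop_hat("all discriminations must be positive", "hatcat_integrity_error")
  nst <- lengths(items$steps)
  if (any(items$model == "2PL" & nst > 0))
    stop_hat("dichotomous items must have empty steps",
             "hatcat_integrity_error")
  if (any(items$model == "GPCM" & nst < 1))
    stop_hat("polytomous items need at least one step parameter",
             "hatcat_integrity_error")
  if (is.null(units)) {
    units <- data.frame(unit_id = unique(items$unit_id),
                        stringsAsFactors = FALSE)
  } else {
    units <- as.data.frame(units, stringsAsFactors = FALSE)
    if (!"unit_id" %in% names(units))
      stop_hat("unit table lacks mandatory column(s): unit_id",
               "hatcat_schema_error")
    unknown <- setdiff(items$unit_id, units$unit_id)
    if (length(unknown))
      stop_hat(paste0("item(s) reference unknown unit(s): ",
                      paste(unique(unknown), collapse = ", ")),
               "hatcat_integrity_error")
  }
  units$n_items <- as.integer(table(factor(items$unit_id,
                                           levels = units$unit_id)))
  if (any(units$n_items == 0))
    units <- units[units$n_items > 0, , drop = FALSE]
  rownames(items) <- rownames(units) <- NULL
  structure(list(items = items, units = units, domain = domain),
            class = "hat_pool")
}

parse_steps <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

format_steps <- function(steps) {
  vapply(steps, function(s) paste(format(s, digits = 15, trim = TRUE),
                                  collapse = ";"),
         character(1))
}

#' Names of the categorical attribute columns of a pool
#' @param pool A [hat_pool()].
#' @return Character vector of attribute column names.
#' @export
pool_attributes <- function(pool) {
  setdiff(names(pool$items), CORE_COLS)
}

#' @export
print.hat_pool <- function(x, ...) {
  cat(sprintf("<hat_pool> domain %s: %d items in %d units (%d polytomous)\n",
              x$domain, nrow(x$items), nrow(x$units),
              sum(x$items$model == "GPCM")))
  att <- pool_attributes(x)
  if (length(att)) cat("attributes:", paste(att, collapse = ", "), "\n")
  invisible(x)
}

#' Read an item pool from disk
#'
#' CSV schema: columns `item_id`, `unit_id`, `model`, `a`, `b`, `steps`
#' (semicolon-joined reals, empty for dichotomous items), optional
#' `subpool`, plus one column per attribute; UTF-8 with a header row.
#' JSON mirror: an object with fields `domain`, `units`, `items`.
#'
#' @param path File path.
#' @param format "csv" or "json" (guessed from the extension by default).
#' @return A validated [hat_pool()].
#' @export
load_pool <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path))
    stop_hat(paste0("no such file: ", path), "hatcat_io_error")
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(item_id = "character",
                                         unit_id = "character"))
    miss <- setdiff(c("item_id", "unit_id", "model", "a", "b"), names(df))
    if (length(miss))
      stop_hat(paste0("pool file lacks mandatory column(s): ",
                      paste(miss, collapse = ", ")), "hatcat_schema_error")
    if ("steps" %in% names(df)) df$steps <- as.character(df$steps)
    dom <- attr(df, "domain") %||% "GEN"
    hat_pool(df, domain = dom)
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    items <- as.data.frame(j$items, stringsAsFactors = FALSE)
    if (!is.null(items$steps) && is.character(items$steps))
      items$steps <- parse_steps(items$steps)
    units <- if (!is.null(j$units)) as.data.frame(j$units) else NULL
    if (!is.null(units)) units$n_items <- NULL
    hat_pool(items, units = units, domain = j$domain %||% "GEN")
  }
}

#' Write an item pool to disk
#'
#' Output is reloadable by [load_pool()] with identical semantic content
#' (step parameters keep their order; empty attribute values round-trip as
#' empty strings).
#'
#' @param pool A [hat_pool()].
#' @param path File path.
#' @param format "csv" or "json".
#' @export
save_pool <- function(pool, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- pool$items
  df$steps <- format_steps(df$steps)
  if (format == "csv") {
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                       fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop_hat(paste0("cannot write: ", path), "hatcat_io_error")
  } else {
    obj <- list(domain = pool$domain,
                units = pool$units[setdiff(names(pool$units), "n_items")],
                items = df)
    ok <- tryCatch({
      jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop_hat(paste0("cannot write: ", path), "hatcat_io_error")
  }
  invisible(NULL)
}

#' Necessary-condition feasibility check of a pool against a blueprint
#'
#' For each blueprint rule, counts the pool's qualifying items (or units)
#' and flags whether the count reaches the rule's lower bound. This is a
#' necessary condition for a compliant shadow test to exist, not a full
#' mixed-integer feasibility proof: attribute interactions can still render
#' a pool that passes this check unassemblable.
#'
#' @param pool A [hat_pool()].
#' @param constraints A [hat_blueprint()] (data frame of rules).
#' @return A data frame (class `hat_feasibility`) with one row per rule and
#'   attribute `feasible` giving the conjunction.
#' @export
validate_feasibility <- function(pool, constraints) {
  constraints <- as_blueprint(constraints)
  check_blueprint_attributes(pool, constraints)
  items <- pool$items
  rows <- lapply(seq_len(nrow(constraints)), function(k) {
    cs <- constraints[k, ]
    if (cs$level == "item_count") {
      cnt <- sum(constraint_matches(cs, items))
    } else if (cs$level == "unit_count") {
      cnt <- nrow(pool$units)
    } else {  # per_unit_count: units able to donate at least lb items
      cnt <- sum(pool$units$n_items >= cs$lb)
      unit_lb <- constraints$lb[constraints$level == "unit_count"]
      need <- if (length(unit_lb)) max(unit_lb) else 1L
      return(data.frame(constraint_id = cs$constraint_id, level = cs$level,
                        count = cnt, lb = need,
                        satisfied = cnt >= need))
    }
    data.frame(constraint_id = cs$constraint_id, level = cs$level,
               count = cnt, lb = cs$lb, satisfied = cnt >= cs$lb)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "feasible") <- all(rep$satisfied)
  class(rep) <- c("hat_feasibility", "data.frame")
  rep
}

#' @export
print.hat_feasibility <- function(x, ...) {
  cat(sprintf("pool feasibility (necessary conditions): %s\n",
              if (attr(x, "feasible")) "PASS" else "FAIL"))
  print.data.frame(x)
  invisible(x)
}
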