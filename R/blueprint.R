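#' Blueprint constraint sets
#'
#' A blueprint is a data frame of count-type assembly rules with columns
#' `constraint_id`, `description`, `level` ("item_count", "unit_count" or
#' "per_unit_count"), `attribute`, `value`, `lb`, `ub`. An empty
#' `attribute` means the rule applies to all items (the test-length rule)
#' or all units. `value` may list several categories joined by `|`
#' (logical OR within the attribute). The constraint sets of the PISA 2018
#' reading, mathematics and science designs ship as package fixtures.
#'
#' @param x Data frame of rules.
#' @return A validated object of class `hat_blueprint`.
#' @export
hat_blueprint <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("constraint_id", "level", "attribute", "value", "lb", "ub")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_hat(paste0("blueprint lacks column(s): ",
                    paste(miss, collapse = ", ")), "hatcat_schema_error")
  if (!"description" %in% names(x)) x$description <- ""
  x$attribute[is.na(x$attribute)] <- ""
  x$value[is.na(x$value)] <- ""
  if (!all(x$level %in% c("item_count", "unit_count", "per_unit_count")))
    stop_hat("level must be item_count, unit_count or per_unit_count",
             "hatcat_schema_error")
  if (any(x$lb < 0) || any(x$lb > x$ub))
    stop_hat("bounds must satisfy 0 <= lb <= ub", "hatcat_definition_error")
  rownames(x) <- NULL
  class(x) <- c("hat_blueprint", "data.frame")
  x
}

as_blueprint <- function(x) {
  if (inherits(x, "hat_blueprint")) x else hat_blueprint(x)
}

# logical index of pool items matched by one rule's predicate
constraint_matches <- function(cs, items) {
  if (!nzchar(cs$attribute)) return(rep(TRUE, nrow(items)))
  vals <- strsplit(cs$value, "|", fixed = TRUE)[[1]]
  items[[cs$attribute]] %in% vals
}

check_blueprint_attributes <- function(pool, constraints) {
  att <- unique(constraints$attribute[nzchar(constraints$attribute)])
  unknown <- setdiff(att, pool_attributes(pool))
  if (length(unknown))
    stop_hat(paste0("constraint references attribute(s) absent from the ",
                    "pool schema: ", paste(unknown, collapse = ", ")),
             "hatcat_definition_error")
  invisible(TRUE)
}

#' Read / write a blueprint CSV
#'
#' @param path CSV file with the [hat_blueprint()] columns.
#' @return A `hat_blueprint`.
#' @export
read_blueprint <- function(path) {
  if (!file.exists(path))
    stop_hat(paste0("no such file: ", path), "hatcat_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = character(0))
  hat_blueprint(df)
}

#' @rdname read_blueprint
#' @param blueprint A `hat_blueprint` to serialize.
#' @export
write_blueprint <- function(blueprint, path) {
  utils::write.csv(as.data.frame(blueprint), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Shipped blueprint fixtures (PISA 2018 designs)
#'
#' Loads the packaged constraint set for one domain: reading (36 items,
#' 12 units of exactly 3 items, eight cognitive-process windows, coding /
#' text-type / trend windows), mathematics (24 items from 10 units of 1-4
#' items) or science (36 items from 12 units of 1-5 items).
#'
#' @param domain "reading", "mathematics" or "science".
#' @return A `hat_blueprint`.
#' @examples
#' bp <- hat_blueprint_fixture("reading")
#' subset(bp, level == "item_count" & attribute == "")$lb  # test length 36
#' @export
hat_blueprint_fixture <- function(domain = c("reading", "mathematics",
                                             "science")) {
  domain <- match.arg(domain)
  path <- system.file("extdata", paste0("blueprint_", domain, ".csv"),
                      package = "hatcat", mustWork = TRUE)
  read_blueprint(path)
}

# the blueprint's fixed test length (empty-predicate item_count equality)
blueprint_test_length <- function(constraints) {
  i <- which(constraints$level == "item_count" &
               !nzchar(constraints$attribute))
  if (!length(i))
    stop_hat("blueprint has no test-length rule", "hatcat_definition_error")
  as.integer(constraints$lb[i[1]])
}
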