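#' HEI-NVS component vocabulary
#'
#' The ten food-group components of the Healthy Eating Index-NVS. Diary rows
#' may additionally carry the label `"other"` for foods that belong to no
#' component (they still count towards energy intake and energy density).
#'
#' @return Character vector of the ten component labels.
#' @export
hei_components <- function() {
  c("vegetables", "fruits", "grains", "dairy", "fish",
    "beverages", "meat", "eggs", "spreadable_fats", "alcohol")
}

#' Trial timepoint vocabulary
#'
#' @return Character vector `c("t0","t1","t2","t3")`: baseline, end of the
#'   12-week intervention, and the 6- and 12-month follow-ups.
#' @export
hei_timepoints <- function() {
  c("t0", "t1", "t2", "t3")
}

#' Default HEI-NVS scoring standards
#'
#' One row per component: the direction of scoring (`adequacy` components earn
#' points up to the reference amount, `moderation` components keep full points
#' at or below the reference and lose points linearly above it), the daily
#' reference amount in grams, the maximum points (15 for vegetables and
#' fruits, 10 for the remaining eight; total 110), and for moderation
#' components the multiple of the reference at which the score reaches zero.
#'
#' The vegetable (400 g/day) and fruit (250 g/day) references are the DGE
#' recommendations the index is built on. The remaining reference amounts are
#' DGE-plausible defaults and are deliberately editable: the whole table can
#' be serialised to YAML ([write_reference_table()]), adjusted, and read back,
#' so a different published standard can be dropped in without code changes.
#'
#' @return A tibble with columns `component`, `direction`, `reference_amount`
#'   (g/day), `max_points`, `zero_point_multiple`.
#' @examples
#' default_reference_table()
#' @export
default_reference_table <- function() {
  refs <- tibble::tribble(
    ~component,        ~direction,   ~reference_amount, ~max_points, ~zero_point_multiple,
    "vegetables",      "adequacy",   400,               15,          NA_real_,
    "fruits",          "adequacy",   250,               15,          NA_real_,
    "grains",          "adequacy",   300,               10,          NA_real_,
    "dairy",           "adequacy",   250,               10,          NA_real_,
    "fish",            "adequacy",   30,                10,          NA_real_,
    "beverages",       "adequacy",   1500,              10,          NA_real_,
    "meat",            "moderation", 85,                10,          2,
    "eggs",            "moderation", 30,                10,          2,
    "spreadable_fats", "moderation", 30,                10,          2,
    "alcohol",         "moderation", 10,                10,          2
  )
  validate_reference_table(refs)
}

#' Validate a reference table
#'
#' Checks the structural invariants of a scoring-standard table: exactly one
#' row per component, positive reference amounts, maxima of 15 for vegetables
#' and fruits and 10 elsewhere summing to 110, and a zero-point multiple
#' greater than 1 for every moderation component.
#'
#' @param refs A data frame as returned by [default_reference_table()].
#' @return The validated table, invisibly coerced to a tibble.
#' @export
validate_reference_table <- function(refs) {
  refs <- tibble::as_tibble(refs)
  needed <- c("component", "direction", "reference_amount", "max_points",
              "zero_point_multiple")
  missing_cols <- setdiff(needed, names(refs))
  if (length(missing_cols) > 0) {
    stop("reference table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!setequal(refs$component, hei_components()) ||
      nrow(refs) != length(hei_components())) {
    stop("reference table must contain exactly one row per HEI-NVS component",
         call. = FALSE)
  }
  if (!all(refs$direction %in% c("adequacy", "moderation"))) {
    stop("direction must be 'adequacy' or 'moderation'", call. = FALSE)
  }
  if (!all(refs$reference_amount > 0)) {
    stop("reference amounts must be positive", call. = FALSE)
  }
  if (!all(refs$max_points %in% c(10, 15))) {
    stop("max_points must be 10 or 15", call. = FALSE)
  }
  if (sum(refs$max_points) != 110) {
    stop("component maxima must sum to 110 points", call. = FALSE)
  }
  if (sum(refs$max_points == 15) != 2) {
    stop("exactly two components (vegetables, fruits) carry 15 points",
         call. = FALSE)
  }
  mod <- refs$direction == "moderation"
  if (any(is.na(refs$zero_point_multiple[mod])) ||
      any(refs$zero_point_multiple[mod] <= 1)) {
    stop("zero_point_multiple must exceed 1 for moderation components",
         call. = FALSE)
  }
  refs
}

#' Read or write a reference table as YAML
#'
#' The interchange format is a YAML list with one entry per component carrying
#' the same fields as [default_reference_table()].
#'
#' @param path File path to a YAML reference table.
#' @return `read_reference_table()` returns a validated tibble;
#'   `write_reference_table()` returns `path` invisibly.
#' @export
read_reference_table <- function(path) {
  raw <- yaml::read_yaml(path)
  refs <- purrr::map_dfr(raw, function(entry) {
    tibble::tibble(
      component = entry$component,
      direction = entry$direction,
      reference_amount = as.numeric(entry$reference_amount),
      max_points = as.numeric(entry$max_points),
      zero_point_multiple = if (is.null(entry$zero_point_multiple)) {
        NA_real_
      } else {
        as.numeric(entry$zero_point_multiple)
      }
    )
  })
  validate_reference_table(refs)
}

#' @rdname read_reference_table
#' @param refs Reference table to serialise.
#' @export
write_reference_table <- function(refs, path) {
  refs <- validate_reference_table(refs)
  entries <- purrr::pmap(refs, function(component, direction, reference_amount,
                                        max_points, zero_point_multiple) {
    out <- list(component = component, direction = direction,
                reference_amount = reference_amount, max_points = max_points)
    if (!is.na(zero_point_multiple)) {
      out$zero_point_multiple <- zero_point_multiple
    }
    out
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
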