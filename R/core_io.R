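# Shared domain vocabulary, delimited-text IO with schema validation, and the
# stocking-rate arithmetic used throughout.

#' Walker eight-point greenness classes
#'
#' The ordinal scale of percent green material scored in each quadrat. Range
#' labels use ASCII hyphens so files are bit-stable across locales.
#'
#' @return Character vector of the eight class labels, in increasing greenness.
#' @export
walker_classes <- function() {
  c("0", "1-10", "11-25", "26-50", "51-75", "76-90", "91-99", "100")
}

#' Four-bin greenness categories
#'
#' The collapsed greenness categories used for diet and availability analyses,
#' from brownest to greenest.
#'
#' @return Character vector of the four bin labels.
#' @export
greenness_bins <- function() {
  c("very brown", "mainly brown", "mainly green", "very green")
}

#' Herbivore and season level sets
#' @return Character vector of admissible labels.
#' @keywords internal
herbivore_levels <- function() c("oribi", "cattle")

#' @rdname herbivore_levels
#' @keywords internal
season_levels <- function() c("wet", "dry")

#' Cattle stocking rate in hectares per animal unit
#'
#' One adult cow counts as 1 animal unit (AU) and one heifer as 0.7 AU; the
#' stocking rate is land area divided by total animal units, so lower values
#' mean denser stocking.
#'
#' @param area_ha Camp area in hectares (> 0). Vectorised.
#' @param n_cows Number of adult cows (non-negative integer).
#' @param n_heifers Number of heifers (non-negative integer).
#' @return Stocking rate in ha per AU.
#' @examples
#' stocking_rate(100, 100, 0)   # 1 ha/AU
#' stocking_rate(0.95, 1, 0)    # the "high" stocking rate
#' @export
stocking_rate <- function(area_ha, n_cows = 0, n_heifers = 0) {
  stopifnot(is.numeric(area_ha), is.numeric(n_cows), is.numeric(n_heifers))
  if (any(area_ha <= 0)) {
    stop("`area_ha` must be positive", call. = FALSE)
  }
  if (any(n_cows < 0) || any(n_heifers < 0) ||
      any(n_cows != round(n_cows)) || any(n_heifers != round(n_heifers))) {
    stop("animal counts must be non-negative integers", call. = FALSE)
  }
  au <- n_cows * 1.0 + n_heifers * 0.7
  if (any(au <= 0)) {
    stop("stocking rate undefined: zero animal units in camp", call. = FALSE)
  }
  area_ha / au
}

# ---- schemas ----------------------------------------------------------------

# A column spec is a list(type =, domain = NULL, min = NULL, min_open = TRUE/FALSE).
col_num <- function(min = NULL, min_open = FALSE, max = NULL) {
  list(type = "double", domain = NULL, min = min, min_open = min_open, max = max)
}
col_int <- function(min = NULL, min_open = FALSE, max = NULL) {
  list(type = "integer", domain = NULL, min = min, min_open = min_open, max = max)
}
col_chr <- function(domain = NULL) {
  list(type = "character", domain = domain, min = NULL, min_open = FALSE, max = NULL)
}

#' Table schemas for the record types handled by the pipeline
#'
#' Every table exchanged between pipeline stages is delimited text (CSV, UTF-8,
#' header row) conforming to one of these schemas. Units are part of column
#' names (cm, g, min, ha) to prevent silent mismatch.
#'
#' @return Named list of schemas; each schema is a named list of column specs.
#' @export
grazekit_schemas <- function() {
  list(
    camps = list(
      camp_id = col_chr(),
      stocking_label = col_chr(),
      area_ha = col_num(min = 0, min_open = TRUE),
      n_cows = col_int(min = 0),
      n_heifers = col_int(min = 0),
      season = col_chr(domain = season_levels())
    ),
    quadrats = list(
      camp_id = col_chr(),
      season = col_chr(domain = season_levels()),
      month = col_chr(),
      transect_id = col_chr(),
      position_m = col_num(min = 0),
      sward_height_cm = col_num(min = 0, min_open = TRUE),
      greenness_pct_class = col_chr(domain = walker_classes())
    ),
    observations = list(
      observation_id = col_chr(),
      camp_id = col_chr(),
      herbivore = col_chr(domain = herbivore_levels()),
      season = col_chr(domain = season_levels()),
      total_bites = col_int(min = 0, min_open = TRUE),
      elapsed_min = col_num(min = 0, min_open = TRUE)
    ),
    bites = list(
      observation_id = col_chr(),
      station_index = col_int(min = 1, max = 5),
      species = col_chr(),
      greenness4 = col_chr(domain = greenness_bins()),
      sward_height_cm = col_num(min = 0, min_open = TRUE),
      bite_mass_g = col_num(min = 0)
    ),
    sward_heights = list(
      sward_id = col_chr(),
      group_id = col_chr(),
      mode = col_chr(domain = c("grazed", "clipped")),
      day = col_num(min = 0),
      height_cm = col_num(min = 0, min_open = TRUE)
    ),
    defoliations = list(
      sward_id = col_chr(),
      day = col_num(min = 0)
    ),
    nutrients = list(
      species = col_chr(),
      greenness4 = col_chr(domain = greenness_bins()),
      cp_pct = col_num(min = 0, max = 100),
      omd_pct = col_num(min = 0, max = 100)
    )
  )
}

get_schema <- function(schema) {
  if (is.character(schema)) {
    all <- grazekit_schemas()
    if (!schema %in% names(all)) {
      stop("unknown schema: '", schema, "'", call. = FALSE)
    }
    return(all[[schema]])
  }
  stopifnot(is.list(schema))
  schema
}

fmt_rows <- function(rows, limit = 5) {
  shown <- utils::head(rows, limit)
  txt <- paste(shown, collapse = ", ")
  if (length(rows) > limit) txt <- paste0(txt, ", ... (", length(rows), " rows)")
  txt
}

#' Validate a table against a schema
#'
#' Checks column presence, types, closed label domains, and numeric range
#' invariants. Violations are reported with the offending column and row
#' numbers.
#'
#' @param df A data frame.
#' @param schema A schema name from [grazekit_schemas()] or a schema list.
#' @return The validated table as a tibble, columns coerced to schema types
#'   and ordered as in the schema.
#' @export
validate_table <- function(df, schema) {
  sch <- get_schema(schema)
  missing <- setdiff(names(sch), names(df))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)[names(sch)]
  for (col in names(sch)) {
    spec <- sch[[col]]
    x <- df[[col]]
    if (spec$type %in% c("double", "integer")) {
      if (!is.numeric(x)) {
        stop("schema error: column '", col, "' must be numeric", call. = FALSE)
      }
      bad <- which(!is.finite(x))
      if (length(bad) > 0) {
        stop("schema error: column '", col, "' has missing/non-finite values at row(s) ",
             fmt_rows(bad), call. = FALSE)
      }
      if (spec$type == "integer" && any(x != round(x))) {
        bad <- which(x != round(x))
        stop("schema error: column '", col, "' must be integer-valued at row(s) ",
             fmt_rows(bad), call. = FALSE)
      }
      if (!is.null(spec$min)) {
        bad <- if (spec$min_open) which(x <= spec$min) else which(x < spec$min)
        if (length(bad) > 0) {
          cmp <- if (spec$min_open) "> " else ">= "
          stop("schema error: column '", col, "' must be ", cmp, spec$min,
               " at row(s) ", fmt_rows(bad), call. = FALSE)
        }
      }
      if (!is.null(spec$max)) {
        bad <- which(x > spec$max)
        if (length(bad) > 0) {
          stop("schema error: column '", col, "' must be <= ", spec$max,
               " at row(s) ", fmt_rows(bad), call. = FALSE)
        }
      }
      if (spec$type == "integer") df[[col]] <- as.integer(round(x))
    } else {
      x <- as.character(x)
      bad <- which(is.na(x))
      if (length(bad) > 0) {
        stop("schema error: column '", col, "' has missing values at row(s) ",
             fmt_rows(bad), call. = FALSE)
      }
      if (!is.null(spec$domain)) {
        bad <- which(!x %in% spec$domain)
        if (length(bad) > 0) {
          stop("schema error: column '", col, "' has out-of-domain label(s) ",
               paste(unique(utils::head(x[bad], 3)), collapse = ", "),
               " at row(s) ", fmt_rows(bad),
               "; allowed: ", paste(spec$domain, collapse = ", "), call. = FALSE)
        }
      }
      df[[col]] <- x
    }
  }
  df
}

#' Read a schema-validated CSV table
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Schema name or schema list (see [grazekit_schemas()]).
#' @return Validated tibble.
#' @export
read_table <- function(path, schema) {
  sch <- get_schema(schema)
  # base parser: correctly-rounded doubles, so write -> read is lossless
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  missing <- setdiff(names(sch), names(df))
  if (length(missing) > 0) {
    stop("schema error reading '", path, "': missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in names(sch)) {
    if (sch[[col]]$type == "character") df[[col]] <- as.character(df[[col]])
  }
  validate_table(df, sch)
}

#' Write a schema-validated CSV table
#'
#' Doubles are written in shortest round-trip representation, so
#' write-then-read is lossless.
#'
#' @param df Table to write; validated first.
#' @param path Output path.
#' @param schema Schema name or schema list.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema) {
  df <- validate_table(df, schema)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
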