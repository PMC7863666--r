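#' @details
#' The central data objects are two plain data frames:
#'
#' * a *lake table* (class `lake_table`): one row per water body, columns
#'   `lake_id`, `name`, `lat`, `lon`, `area_ha`, `perimeter_km`,
#'   `shape_index`, `max_depth`, `secchi`, `ph`, `trophic_code`, `suitable`;
#' * a *visit table* (class `visit_table`): one row per observation of a
#'   marked juvenile on a non-natal lake, columns `juvenile_id`,
#'   `natal_lake_id`, `destination_lake_id`, `date`.
#'
#' @keywords internal
"_PACKAGE"

# Five quantitative lake traits used throughout the analysis.
BASIC_TRAITS <- c("area_ha", "max_depth", "shape_index", "secchi", "ph")

LAKE_COLUMNS <- c("lake_id", "name", "lat", "lon", "area_ha", "perimeter_km",
                  "shape_index", "max_depth", "secchi", "ph", "trophic_code",
                  "suitable")

#' Quantitative lake traits used by the similarity tests
#'
#' Surface area (ha), maximum depth, shape index, Secchi clarity and pH.
#' @return Character vector of lake-table column names.
#' @export
basic_traits <- function() BASIC_TRAITS

#' Read a lake attribute table
#'
#' Loads a UTF-8 CSV with header columns `lake_id, name, lat, lon, area_ha,
#' perimeter_km, shape_index, max_depth, secchi, ph, trophic_code, suitable`.
#' Rows with missing trait values are loaded with those fields `NA`, never
#' dropped; a load report (attribute `"report"`) counts complete versus
#' incomplete records, where "complete" means all five basic traits present.
#'
#' @param path Path to the CSV file.
#' @return A `lake_table` data frame, one row per lake.
#' @export
read_lake_table <- function(path) {
  if (!file.exists(path)) stop("lake table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(lake_id = "character"),
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(LAKE_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("lake table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as_lake_table(raw[LAKE_COLUMNS])
}

#' Construct a lake table from a data frame
#'
#' Validates identifiers, coordinates and trait ranges and attaches the
#' completeness report. Used by [read_lake_table()] and the landscape
#' generator.
#'
#' @param df Data frame with the lake-table columns.
#' @return A validated `lake_table`.
#' @export
as_lake_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$lake_id <- as.character(df$lake_id)
  dup <- unique(df$lake_id[duplicated(df$lake_id)])
  if (length(dup)) {
    stop("duplicate lake_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  for (col in c("lat", "lon", "area_ha", "perimeter_km", "shape_index",
                "max_depth", "secchi", "ph")) {
    v <- df[[col]]
    if (is.character(v)) {
      bad <- which(!is.na(v) & v != "" & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad)) {
        stop("unparseable value in column '", col, "' at row ",
             bad[1], ": '", v[bad[1]], "'", call. = FALSE)
      }
      v[v == ""] <- NA
      df[[col]] <- as.numeric(v)
    }
  }
  bad_coord <- which(is.na(df$lat) | is.na(df$lon))
  if (length(bad_coord)) {
    stop("missing or unparseable coordinates at row ",
         paste(bad_coord, collapse = ", "), call. = FALSE)
  }
  check_coords(df$lat, df$lon)
  if (any(!is.na(df$area_ha) & df$area_ha <= 0)) {
    stop("area_ha must be positive", call. = FALSE)
  }
  if (any(!is.na(df$ph) & (df$ph <= 0 | df$ph >= 14))) {
    stop("ph must lie in (0, 14)", call. = FALSE)
  }
  if (any(!is.na(df$shape_index) & df$shape_index <= 0)) {
    stop("shape_index must be positive", call. = FALSE)
  }
  df$suitable <- as.logical(df$suitable)
  df$trophic_code <- as.character(df$trophic_code)
  df$trophic_code[df$trophic_code %in% c("", "NA")] <- NA_character_
  complete <- stats::complete.cases(df[BASIC_TRAITS])
  attr(df, "report") <- list(n = nrow(df), n_complete = sum(complete),
                             n_incomplete = sum(!complete))
  class(df) <- c("lake_table", "data.frame")
  df
}

#' @export
print.lake_table <- function(x, ...) {
  rep <- attr(x, "report")
  cat("Lake table: ", nrow(x), " lakes (",
      rep$n_complete, " complete, ", rep$n_incomplete,
      " with missing basic traits)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Write a lake table to CSV
#'
#' Full double precision is preserved so that a write/read round trip
#' reproduces every numeric field exactly.
#'
#' @param lakes A `lake_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lake_table <- function(lakes, path) {
  df <- as.data.frame(lakes)[LAKE_COLUMNS]
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf_num(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

sprintf_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE,
                                            trim = TRUE)
  }, character(1))
  out
}

#' Read a visit table
#'
#' Loads a CSV with columns `juvenile_id, natal_lake_id, destination_lake_id,
#' date` (ISO 8601 dates) and resolves every visit against a lake table.
#' Visits that reference an unknown lake raise an error naming the offending
#' id. Visits whose natal and destination lake coincide are dropped with a
#' warning and recorded in the report. With `require_complete_traits = TRUE`
#' only visits whose natal and destination lakes both carry all five basic
#' traits are kept; the report records counts before and after.
#'
#' @param path Path to the visit CSV.
#' @param lakes A `lake_table` the visits must refer to.
#' @param require_complete_traits Apply the five-trait completeness filter?
#' @return A `visit_table` data frame with a `"report"` attribute
#'   (`n_read`, `n_after_filter`, `rejected`).
#' @export
read_visit_table <- function(path, lakes, require_complete_traits = FALSE) {
  if (!file.exists(path)) stop("visit table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  need <- c("juvenile_id", "natal_lake_id", "destination_lake_id", "date")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("visit table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_visit_table(raw[need], lakes,
                 require_complete_traits = require_complete_traits)
}

#' Construct a visit table from a data frame
#'
#' @inheritParams read_visit_table
#' @param df Data frame with visit columns.
#' @return A validated `visit_table`.
#' @export
as_visit_table <- function(df, lakes, require_complete_traits = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("juvenile_id", "natal_lake_id", "destination_lake_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$date <- as.Date(df$date)
  unknown <- setdiff(c(df$natal_lake_id, df$destination_lake_id),
                     lakes$lake_id)
  if (length(unknown)) {
    stop("visit references unknown lake(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_read <- nrow(df)
  self_visit <- df$natal_lake_id == df$destination_lake_id
  rejected <- NULL
  if (any(self_visit)) {
    rejected <- data.frame(row = which(self_visit),
                           reason = "natal equals destination")
    warning(sum(self_visit),
            " visit(s) dropped: natal equals destination lake",
            call. = FALSE)
    df <- df[!self_visit, , drop = FALSE]
  }
  if (require_complete_traits) {
    complete_ids <- lakes$lake_id[stats::complete.cases(
      as.data.frame(lakes)[BASIC_TRAITS])]
    keep <- df$natal_lake_id %in% complete_ids &
      df$destination_lake_id %in% complete_ids
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "report") <- list(n_read = n_read, n_after_filter = nrow(df),
                             rejected = rejected)
  class(df) <- c("visit_table", "data.frame")
  df
}

#' @export
print.visit_table <- function(x, ...) {
  rep <- attr(x, "report")
  cat("Visit table: ", rep$n_read, " read -> ", rep$n_after_filter,
      " retained\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Write a visit table to CSV
#'
#' @param visits A `visit_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_visit_table <- function(visits, path) {
  df <- as.data.frame(visits)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Shoreline development (shape) index
#'
#' Shoreline perimeter in km divided by the square root of the surface area
#' in ha. Under this unit convention a perfect circle of 100 ha has index
#' 2*sqrt(pi)/10 = 0.354, the analytic minimum over all shapes of that area
#' scale; the index is invariant under uniform linear rescaling of the
#' outline.
#'
#' @param perimeter_km Shoreline length, km. Must be positive.
#' @param area_ha Surface area, hectares. Must be positive.
#' @return Dimensionless shape index, vectorized over inputs.
#' @examples
#' compute_shape_index(2 * sqrt(pi), 100) # circular lake, ~0.3545
#' @export
compute_shape_index <- function(perimeter_km, area_ha) {
  if (any(!is.finite(perimeter_km)) || any(perimeter_km <= 0)) {
    stop("perimeter_km must be positive", call. = FALSE)
  }
  if (any(!is.finite(area_ha)) || any(area_ha <= 0)) {
    stop("area_ha must be positive", call. = FALSE)
  }
  perimeter_km / sqrt(area_ha)
}

# Closed set of trophic-class codes the classifier can emit. Letters are
# complexity (C/S), temperature (C/W), clarity (C/D); stratified lakes
# collapse to the single two-story label.
TROPHIC_CODES <- c("CCC", "CCD", "CWC", "CWD",
                   "SCC", "SCD", "SWC", "SWD", "TS")

#' The closed set of trophic-class codes
#'
#' @return Character vector of the codes [classify_trophic()] can emit.
#' @export
trophic_codes <- function() TROPHIC_CODES

#' Classify a lake into a trophic class
#'
#' Discrete lake categories combining sportfish richness (Complex when the
#' sportfish species count reaches `complex_threshold`, Simple below it),
#' water temperature regime (Warm/Cool), clarity (Clear/Dark) and thermal
#' stratification: two-story lakes — stratified such that both warm- and
#' cold-water fish communities coexist — take the `TS` code regardless of the
#' other axes. A count exactly at the threshold is Complex.
#'
#' @param sportfish_species_count Non-negative integer count(s) of sportfish
#'   species present.
#' @param temperature `"Warm"` or `"Cool"`.
#' @param clarity `"Clear"` or `"Dark"`.
#' @param two_story Logical; thermally stratified two-story lake?
#' @param complex_threshold Species count at and above which a lake is
#'   Complex. Default 4.
#' @return Character vector of codes from [trophic_codes()].
#' @examples
#' classify_trophic(6, "Cool", "Clear", FALSE) # "CCC"
#' classify_trophic(2, "Warm", "Dark", FALSE)  # "SWD"
#' classify_trophic(5, "Cool", "Clear", TRUE)  # "TS"
#' @export
classify_trophic <- function(sportfish_species_count, temperature, clarity,
                             two_story, complex_threshold = 4) {
  if (any(sportfish_species_count < 0)) {
    stop("sportfish_species_count must be non-negative", call. = FALSE)
  }
  temperature <- match_arg_vec(temperature, c("Warm", "Cool"))
  clarity <- match_arg_vec(clarity, c("Clear", "Dark"))
  n <- max(length(sportfish_species_count), length(temperature),
           length(clarity), length(two_story))
  cnt <- rep_len(sportfish_species_count, n)
  tmp <- rep_len(temperature, n)
  clr <- rep_len(clarity, n)
  ts <- rep_len(as.logical(two_story), n)
  code <- paste0(ifelse(cnt >= complex_threshold, "C", "S"),
                 ifelse(tmp == "Warm", "W", "C"),
                 ifelse(clr == "Clear", "C", "D"))
  code[ts] <- "TS"
  code
}

match_arg_vec <- function(x, choices) {
  x <- as.character(x)
  bad <- setdiff(unique(x), choices)
  if (length(bad)) {
    stop("invalid value(s) ", paste(sQuote(bad), collapse = ", "),
         "; expected one of ", paste(choices, collapse = ", "), call. = FALSE)
  }
  x
}

#' Filter a lake table to loon-suitable water bodies
#'
#' Drops lakes below a minimum surface area and lakes of excluded classes
#' (e.g. trout ponds), and lakes explicitly flagged unsuitable. Removal
#' counts per reason are attached as attribute `"removals"`.
#'
#' @param lakes A `lake_table`.
#' @param min_area_ha Minimum surface area in hectares; default 10.
#' @param excluded_classes Character vector of trophic codes / labels to
#'   exclude, e.g. `"trout pond"`. Default none.
#' @param use_flag Also drop lakes whose `suitable` flag is `FALSE`?
#' @return The filtered `lake_table`.
#' @export
filter_loon_suitable <- function(lakes, min_area_ha = 10,
                                 excluded_classes = character(),
                                 use_flag = TRUE) {
  too_small <- !is.na(lakes$area_ha) & lakes$area_ha < min_area_ha
  bad_class <- !is.na(lakes$trophic_code) &
    lakes$trophic_code %in% excluded_classes
  flagged <- if (use_flag) !is.na(lakes$suitable) & !lakes$suitable else
    rep(FALSE, nrow(lakes))
  keep <- !(too_small | bad_class | flagged)
  out <- lakes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removals") <- list(below_min_area = sum(too_small),
                                excluded_class = sum(bad_class),
                                flagged_unsuitable = sum(flagged))
  attr(out, "report") <- list(
    n = nrow(out),
    n_complete = sum(stats::complete.cases(as.data.frame(out)[BASIC_TRAITS])),
    n_incomplete = sum(!stats::complete.cases(
      as.data.frame(out)[BASIC_TRAITS])))
  class(out) <- c("lake_table", "data.frame")
  out
}
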