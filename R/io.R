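# Pinned CSV dialect: UTF-8, comma, ".", ISO-8601 dates, header row.

table_schemas <- list(
  temperature = c(date = "Date", temp_c = "numeric"),
  fish = c(fish_id = "character", year = "integer", month = "integer",
           class = "character", site = "integer", haul = "integer",
           sl_mm = "numeric", mass_g = "numeric", liver_g = "numeric"),
  otolith = c(fish_id = "character", increment_index = "integer",
              radius_um = "numeric", radius_at_capture_um = "numeric"),
  stomach = c(fish_id = "character", prey_taxon = "character",
              count = "integer", weight_mg = "numeric",
              stomach_total_g = "numeric", fish_total_g = "numeric")
)

#' Read a pipeline table with schema validation
#'
#' @param path CSV path.
#' @param table one of `"temperature"`, `"fish"`, `"otolith"`,
#'   `"stomach"`.
#' @return validated data.frame.
#' @export
read_table_csv <- function(path, table = names(table_schemas)) {
  table <- match.arg(table)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  rep <- check_table(df, table, path)
  bad <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(bad))
    stop("schema violations in ", path, ":\n",
         paste(bad$message, collapse = "\n"))
  if (table == "temperature") df$date <- as.Date(df$date)
  df
}

#' Write a pipeline table
#'
#' @param df data.frame.
#' @param path destination CSV.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

check_table <- function(df, table, path = "<in-memory>") {
  schema <- table_schemas[[table]]
  msgs <- list()
  add <- function(severity, message)
    msgs[[length(msgs) + 1]] <<- data.frame(table = table, path = path,
                                            severity = severity,
                                            message = message)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    add("error", paste0("missing column(s): ",
                        paste(missing, collapse = ", ")))
    return(do.call(rbind, msgs))
  }
  row_of <- function(i) paste0("row ", i)
  if (table == "temperature") {
    d <- as.Date(df$date)
    if (anyNA(d)) add("error", paste0("unparseable date at ",
                                      row_of(which(is.na(d))[1])))
    else if (is.unsorted(d, strictly = TRUE))
      add("error", "dates not strictly increasing")
  }
  if (table == "fish") {
    for (col in c("sl_mm", "mass_g")) {
      bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
      if (length(bad))
        add("error", paste0("non-positive ", col, " at ", row_of(bad[1]),
                            ", column ", col))
    }
    bad <- which(df$liver_g < 0 | df$liver_g >= df$mass_g)
    if (length(bad))
      add("error", paste0("liver_g out of range at ", row_of(bad[1]),
                          ", column liver_g"))
  }
  if (table == "otolith") {
    for (id in unique(df$fish_id)) {
      sub <- df[df$fish_id == id, ]
      sub <- sub[order(sub$increment_index), ]
      if (any(diff(sub$radius_um) <= 0))
        add("error", paste0("non-monotone radii for fish ", id, " at ",
                            row_of(which(df$fish_id == id)[1]),
                            ", column radius_um"))
      if (any(sub$radius_um > sub$radius_at_capture_um + 1e-9))
        add("error", paste0("radius exceeds capture radius for fish ", id))
    }
  }
  if (table == "stomach") {
    bad <- which(df$weight_mg < 0 | df$count < 0)
    if (length(bad))
      add("error", paste0("negative count/weight at ", row_of(bad[1]),
                          ", column weight_mg"))
  }
  if (length(msgs)) do.call(rbind, msgs)
  else data.frame(table = character(), path = character(),
                  severity = character(), message = character())
}

#' Validate the four pipeline tables
#'
#' Runs per-table column, type and invariant checks (monotone radii,
#' positive weights, increasing dates) without stopping, returning a
#' report of every violation found.
#'
#' @param paths named list/vector of CSV paths; names among
#'   `temperature`, `fish`, `otolith`, `stomach`.
#' @return data.frame report: `table`, `path`, `severity`, `message`;
#'   zero rows when everything checks out.
#' @export
validate_tables <- function(paths) {
  reports <- lapply(names(paths), function(nm) {
    df <- utils::read.csv(paths[[nm]], stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    check_table(df, nm, paths[[nm]])
  })
  do.call(rbind, reports)
}
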