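#' Crest height normalized to sarcomere length
#'
#' The standard normalization for surface-crest height: dividing by the
#' sarcomere length of the first myofibril layer below the crest
#' compensates for the unknown diastolic/systolic state of the fixed
#' tissue (crest height co-varies with sarcomere length). Vectorized.
#'
#' @param crest_height_um crest height(s), um (> 0).
#' @param sarcomere_length_um sarcomere length(s), um (> 0).
#' @return dimensionless ratio(s).
#' @examples
#' normalized_crest_height(0.5, 2.0)  # 0.25
#' @export
normalized_crest_height <- function(crest_height_um, sarcomere_length_um) {
  if (!is.numeric(crest_height_um) || !is.numeric(sarcomere_length_um)) {
    stop_validation("lengths must be numeric")
  }
  if (any(!is.finite(sarcomere_length_um)) || any(sarcomere_length_um <= 0)) {
    stop_validation("sarcomere_length_um must be finite and > 0")
  }
  if (any(!is.finite(crest_height_um)) || any(crest_height_um <= 0)) {
    stop_validation("crest_height_um must be finite and > 0")
  }
  crest_height_um / sarcomere_length_um
}

#' Derive per-crest crest/sarcomere ratio rows
#'
#' Pairs each crest's `crest_height_um` row with the `sarcomere_length_um`
#' row sharing the same `structure_id` and returns new rows with metric
#' `crest_ratio` (dimensionless), ready to append to or summarize like any
#' other metric.
#'
#' @param table a morphometry table (see [simulate_morphometry()]).
#' @return a data.frame in the same schema with metric `crest_ratio`.
#' @export
crest_ratios <- function(table) {
  check_morpho_table(table)
  ch <- table[table$metric == "crest_height_um", ]
  sl <- table[table$metric == "sarcomere_length_um", ]
  m <- match(ch$structure_id, sl$structure_id)
  if (anyNA(m)) {
    stop_validation("crest_height_um rows without matching ",
                    "sarcomere_length_um rows")
  }
  data.frame(
    group = ch$group, animal_id = ch$animal_id, cell_id = ch$cell_id,
    structure_id = ch$structure_id, metric = "crest_ratio",
    value = normalized_crest_height(ch$value, sl$value[m]),
    unit = "ratio", stringsAsFactors = FALSE
  )
}

check_morpho_table <- function(table) {
  needed <- c("group", "animal_id", "cell_id", "structure_id",
              "metric", "value", "unit")
  if (!is.data.frame(table) || !all(needed %in% names(table))) {
    stop_validation(
      "morphometry table must have columns ", paste(needed, collapse = ", ")
    )
  }
  invisible(table)
}

#' Summarize a morphometry metric per group at a chosen nesting level
#'
#' Computes mean and SD per group for one metric at the requested unit of
#' analysis. `"structure"` treats every measured structure as a unit;
#' `"cell"` first averages within each cell; `"animal"` (the default, and
#' the level matching legends that report n = animals) first averages
#' within each animal — the group mean is then the mean of per-animal
#' means and the SD is taken across animals.
#'
#' @param table a morphometry table.
#' @param metric metric name present in the table (e.g. `"crest_ratio"`
#'   after [crest_ratios()]).
#' @param nesting `"animal"`, `"cell"` or `"structure"`.
#' @return a data.frame with columns `group`, `metric`, `nesting`,
#'   `n_units`, `mean`, `sd`, `unit`.
#' @export
summarize_morphometry <- function(table, metric,
                                  nesting = c("animal", "cell",
                                              "structure")) {
  check_morpho_table(table)
  nesting <- match.arg(nesting)
  sub <- table[table$metric == metric, ]
  if (nrow(sub) == 0L) {
    stop_validation("metric '", metric, "' not present in table")
  }
  unit <- sub$unit[1]
  units <- switch(nesting,
    structure = sub,
    cell = aggregate(value ~ group + animal_id + cell_id, data = sub,
                     FUN = mean),
    animal = aggregate(value ~ group + animal_id, data = sub, FUN = mean)
  )
  out <- do.call(rbind, lapply(split(units, units$group), function(d) {
    data.frame(
      group = d$group[1], metric = metric, nesting = nesting,
      n_units = nrow(d), mean = mean(d$value),
      sd = if (nrow(d) > 1) sd(d$value) else 0,
      unit = unit, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Validate a morphometry table
#'
#' Checks the schema and measurement rules without mutating the data:
#' required columns, missing identifiers, nonpositive lengths/areas,
#' negative interspaces, non-integer or negative counts, and agreement
#' between each crest's recorded `ssm_count` and the number of
#' `ssm_area_um2` rows attached to it.
#'
#' @param table a morphometry table.
#' @return a data.frame report with columns `rule`, `structure_id`,
#'   `message`; zero rows when the table is clean.
#' @export
validate_morphometry <- function(table) {
  report <- list()
  flag <- function(rule, sid, msg) {
    report[[length(report) + 1L]] <<- data.frame(
      rule = rule, structure_id = sid, message = msg,
      stringsAsFactors = FALSE
    )
  }
  needed <- c("group", "animal_id", "cell_id", "structure_id",
              "metric", "value", "unit")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    flag("schema", NA_character_,
         paste("missing columns:", paste(missing_cols, collapse = ", ")))
    return(do.call(rbind, report))
  }
  id_bad <- !complete.cases(table[c("group", "animal_id", "cell_id",
                                    "structure_id")]) |
    table$group == "" | table$animal_id == "" | table$structure_id == ""
  for (i in which(id_bad)) {
    flag("missing_id", table$structure_id[i],
         sprintf("row %d has missing identifiers", i))
  }
  length_metrics <- c("crest_height_um", "sarcomere_length_um",
                      "sarcomere_height_um", "ssm_area_um2", "crest_ratio")
  bad_len <- table$metric %in% length_metrics &
    (!is.finite(table$value) | table$value <= 0)
  for (i in which(bad_len)) {
    flag("nonpositive_length", table$structure_id[i],
         sprintf("%s = %g must be > 0", table$metric[i], table$value[i]))
  }
  bad_gap <- table$metric == "lateral_interspace_nm" &
    (!is.finite(table$value) | table$value <= 0)
  for (i in which(bad_gap)) {
    flag("nonpositive_interspace", table$structure_id[i],
         sprintf("lateral_interspace_nm = %g must be > 0", table$value[i]))
  }
  bad_count <- table$metric %in% c("ssm_count", "myofibril_count") &
    (!is.finite(table$value) | table$value < 0 |
       abs(table$value - round(table$value)) > 1e-8)
  for (i in which(bad_count)) {
    flag("invalid_count", table$structure_id[i],
         sprintf("%s = %g must be a nonnegative integer",
                 table$metric[i], table$value[i]))
  }
  # ssm_count must equal the number of ssm_area rows under the crest
  counts <- table[table$metric == "ssm_count" & !bad_count, ]
  areas <- table[table$metric == "ssm_area_um2", ]
  if (nrow(counts)) {
    # area ids look like <crest_id>_ssm<j>
    parent <- sub("_ssm[0-9]+$", "", areas$structure_id)
    n_area <- table(parent)
    for (i in seq_len(nrow(counts))) {
      sid <- counts$structure_id[i]
      found <- if (sid %in% names(n_area)) as.integer(n_area[[sid]]) else 0L
      if (found != counts$value[i]) {
        flag("ssm_mismatch", sid,
             sprintf("ssm_count = %d but %d ssm_area_um2 rows found",
                     as.integer(counts$value[i]), found))
      }
    }
  }
  if (length(report)) do.call(rbind, report) else data.frame(
    rule = character(), structure_id = character(), message = character(),
    stringsAsFactors = FALSE
  )
}

#' Write / read a morphometry table as CSV
#'
#' Plain CSV in the long schema (`group, animal_id, cell_id, structure_id,
#' metric, value, unit`); values round-trip exactly to 15 significant
#' digits.
#'
#' @param table a morphometry table.
#' @param path CSV path.
#' @return `write_morphometry`: `path` invisibly; `read_morphometry`: the
#'   table.
#' @export
write_morphometry <- function(table, path) {
  check_morpho_table(table)
  write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_morphometry
#' @export
read_morphometry <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(
                    group = "character", animal_id = "character",
                    cell_id = "character", structure_id = "character",
                    metric = "character", value = "numeric",
                    unit = "character"
                  ))
  check_morpho_table(tab)
  tab
}
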