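# Readers for the pipeline's CSV dialect (header row, UTF-8, '.' decimal)
# and a thin column-mapping adapter for externally deposited tables.

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(basename(path), " lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' Read pipeline tables from CSV
#'
#' Each reader checks for its required columns and returns a plain
#' data.frame: trajectories (`individual_id, day, phase, t_s, x_cm, y_cm`),
#' daily behavior (`individual_id, day, activity_cm_s, feeding_min`), weekly
#' sizes (`individual_id, age_days, length_cm`), broods (`individual_id,
#' mother_id, brood_id, age_at_parturition_days, brood_size`), and the
#' offspring long table (`individual_id, brood_id, length_cm`).
#'
#' @param path Path to the CSV file.
#' @return A data.frame.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_trajectory_csv <- function(path)
  read_checked_csv(path, c("individual_id", "day", "phase", "t_s", "x_cm", "y_cm"))

#' @rdname pipeline_io
#' @export
read_behavior_csv <- function(path)
  read_checked_csv(path, c("individual_id", "day", "activity_cm_s", "feeding_min"))

#' @rdname pipeline_io
#' @export
read_sizes_csv <- function(path)
  read_checked_csv(path, c("individual_id", "age_days", "length_cm"))

#' @rdname pipeline_io
#' @export
read_broods_csv <- function(path)
  read_checked_csv(path, c("individual_id", "mother_id", "brood_id",
                           "age_at_parturition_days", "brood_size"))

#' @rdname pipeline_io
#' @export
read_offspring_csv <- function(path)
  read_checked_csv(path, c("individual_id", "brood_id", "length_cm"))

#' Read an external table through a column mapping
#'
#' Adapter for deposited datasets whose headers differ from the internal
#' schema: `mapping` is a named character vector `c(internal = "external",
#' ...)`. Columns not in the mapping are dropped. A ready-to-edit mapping
#' template ships as `system.file("extdata", "deposit_mapping_template.csv",
#' package = "indilife")`.
#'
#' @param path CSV file to read.
#' @param mapping Named character vector mapping internal names to the
#'   file's column names.
#' @return A data.frame with internal column names.
#' @export
read_mapped_table <- function(path, mapping) {
  if (is.null(names(mapping)) || any(names(mapping) == ""))
    stop("mapping must be a fully named character vector", call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unname(mapping), names(d))
  if (length(miss))
    stop(basename(path), " lacks mapped columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- d[unname(mapping)]
  names(out) <- names(mapping)
  out
}
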