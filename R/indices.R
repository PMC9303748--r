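#' Culture indices
#'
#' The three summary indices of a myogenic culture, each expressed as a
#' percentage:
#' * proliferation index = 100 x (Pax7+MyoD+ double-positive nuclei) /
#'   (Pax7-positive nuclei);
#' * differentiation index = 100 x (MyoD+MyoG+ double-positive nuclei) /
#'   (MyoD-positive nuclei);
#' * fusion index = 100 x (nuclei inside myotubes) / (total nuclei).
#'
#' An index is undefined (`NA`) when its denominator is zero; a numerator
#' exceeding its denominator is a consistency error.
#'
#' @param n_double number of double-positive nuclei.
#' @param n_pax7 number of Pax7-positive nuclei.
#' @param n_myod number of MyoD-positive nuclei.
#' @param n_in_myotubes number of nuclei inside myotubes.
#' @param n_total total number of nuclei.
#' @return percentage in `[0, 100]`, or `NA` when undefined.
#' @examples
#' proliferation_index(77, 250)   # 30.8
#' differentiation_index(401, 1000)  # 40.1
#' fusion_index(269, 1000)        # 26.9
#' @export
proliferation_index <- function(n_double, n_pax7) {
  index_pct(n_double, n_pax7, "double-positive", "Pax7-positive")
}

#' @rdname proliferation_index
#' @export
differentiation_index <- function(n_double, n_myod) {
  index_pct(n_double, n_myod, "double-positive", "MyoD-positive")
}

#' @rdname proliferation_index
#' @export
fusion_index <- function(n_in_myotubes, n_total) {
  index_pct(n_in_myotubes, n_total, "nuclei-in-myotubes", "total nucleus")
}

index_pct <- function(num, den, num_name, den_name) {
  if (!is_count(num) || !is_count(den))
    stop_param("counts must be single non-negative integers")
  if (num > den)
    stop_param(num_name, " count (", num, ") exceeds ", den_name,
               " count (", den, ")")
  if (den == 0) return(NA_real_)
  100 * num / den
}

#' Pool a well's fields into one index record
#'
#' Counts are summed across the well's fields and the index formulas are
#' applied once to the pooled counts (pooling, not averaging of per-field
#' ratios: with sparse fields the pooled ratio is the better-behaved
#' estimator, and it equals the per-field ratio whenever the fields agree).
#' All fields must come from the same coating, day and well.
#'
#' @param fields data frame of per-field quantifications as returned by
#'   [quantify_field()] (rows may be `rbind`-ed).
#' @param mode which indices to compute from the pooled counts:
#'   `"pax7-myod"` yields the proliferation index (double / green),
#'   `"myog-myod"` the differentiation index (double / red),
#'   `"myhc"` the fusion index and myotube count; `"auto"` computes whatever
#'   the counts support.
#' @return one-row data frame: provenance, pooled counts, and
#'   `proliferation_index_pct`, `differentiation_index_pct`,
#'   `fusion_index_pct`, `myotube_count` (`NA` where undefined or not
#'   requested).
#' @export
aggregate_well <- function(fields, mode = c("auto", "pax7-myod", "myog-myod",
                                            "myhc")) {
  mode <- match.arg(mode)
  if (!is.data.frame(fields) || nrow(fields) == 0)
    stop_param("fields must be a non-empty data frame of field counts")
  for (lab in c("coating", "day", "well")) {
    if (lab %in% names(fields) && length(unique(fields[[lab]])) > 1)
      stop_param("mixed provenance: fields span several values of '", lab, "'")
  }
  tot <- function(col) {
    if (!col %in% names(fields) || all(is.na(fields[[col]]))) NA_integer_
    else as.integer(sum(fields[[col]], na.rm = TRUE))
  }
  n_nuclei <- tot("n_nuclei")
  n_green <- tot("n_green")
  n_red <- tot("n_red")
  n_double <- tot("n_double")
  n_tubes <- tot("n_myotubes")
  n_in <- tot("n_nuclei_in_myotubes")
  want <- function(what) mode == "auto" || mode == what
  prol <- if (want("pax7-myod") && !is.na(n_double) && !is.na(n_green) &&
              n_green > 0) proliferation_index(n_double, n_green) else NA_real_
  diff <- if (want("myog-myod") && !is.na(n_double) && !is.na(n_red) &&
              n_red > 0) differentiation_index(n_double, n_red) else NA_real_
  fus <- if (want("myhc") && !is.na(n_in) && n_nuclei > 0)
    fusion_index(n_in, n_nuclei) else NA_real_
  tubes <- if (want("myhc")) n_tubes else NA_integer_
  data.frame(coating = if ("coating" %in% names(fields)) fields$coating[1] else NA,
             day = if ("day" %in% names(fields)) fields$day[1] else NA,
             well = if ("well" %in% names(fields)) fields$well[1] else NA,
             n_fields = nrow(fields),
             n_nuclei = n_nuclei, n_green = n_green, n_red = n_red,
             n_double = n_double, n_myotubes = n_tubes,
             n_nuclei_in_myotubes = n_in,
             proliferation_index_pct = prol,
             differentiation_index_pct = diff,
             fusion_index_pct = fus,
             myotube_count = tubes)
}

#' Build the tidy analysis table from per-field counts
#'
#' Pools each coating x day x well group with [aggregate_well()] and
#' reshapes the result into the long table consumed by the statistics layer:
#' one row per well x day x coating x outcome. Undefined indices propagate
#' as missing values, not zeros.
#'
#' @param field_counts data frame of per-field quantifications with
#'   `coating`, `day`, `well` columns.
#' @param mode passed to [aggregate_well()].
#' @return data frame with columns `coating`, `day`, `well`, `outcome`
#'   (`proliferation`, `differentiation`, `fusion`, `myotubes`), `value`.
#' @export
build_analysis_table <- function(field_counts, mode = "auto") {
  groups <- split(field_counts,
                  interaction(field_counts$coating, field_counts$day,
                              field_counts$well, drop = TRUE))
  wells <- do.call(rbind, lapply(groups, aggregate_well, mode = mode))
  long <- do.call(rbind, lapply(c(proliferation = "proliferation_index_pct",
                                  differentiation = "differentiation_index_pct",
                                  fusion = "fusion_index_pct",
                                  myotubes = "myotube_count"),
                                function(col) {
    data.frame(coating = wells$coating, day = wells$day, well = wells$well,
               value = wells[[col]])
  }))
  long$outcome <- rep(c("proliferation", "differentiation", "fusion",
                        "myotubes"), each = nrow(wells))
  rownames(long) <- NULL
  long[!is.na(long$value), c("coating", "day", "well", "outcome", "value")]
}
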