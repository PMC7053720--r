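# Sampled time series are plain tibbles: the first column is `time_min`
# (strictly increasing) and the second carries the values, named after
# the quantity (conc_mg_l, c3_mg_l, D, taps_per_min, ...).

new_series <- function(time_min, values, name = "value") {
  validate_series_vectors(time_min, values)
  out <- tibble::tibble(time_min = as.numeric(time_min),
                        value = as.numeric(values))
  names(out)[2] <- name
  out
}

validate_series_vectors <- function(time_min, values) {
  if (length(time_min) == 0)
    abort("input error: empty series", class = "levotap_input_error")
  if (length(time_min) != length(values))
    abort("input error: times and values must have equal length",
          class = "levotap_input_error")
  if (anyNA(time_min) || any(!is.finite(time_min)))
    abort("input error: series times must be finite", class = "levotap_input_error")
  if (any(diff(time_min) <= 0))
    abort("input error: series times must be strictly increasing",
          class = "levotap_input_error")
  if (anyNA(values) || any(!is.finite(values)))
    abort("input error: series values must be finite", class = "levotap_input_error")
  invisible(TRUE)
}

series_times <- function(x) {
  if (!is.data.frame(x) || !"time_min" %in% names(x))
    abort("input error: expected a data frame with a `time_min` column",
          class = "levotap_input_error")
  x[["time_min"]]
}

series_values <- function(x) {
  vcol <- setdiff(names(x), "time_min")[1]
  if (is.na(vcol))
    abort("input error: series has no value column", class = "levotap_input_error")
  x[[vcol]]
}

check_series <- function(x) {
  validate_series_vectors(series_times(x), series_values(x))
  x
}
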