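#' Construct a right-censored survival dataset
#'
#' Bundles follow-up times (months) and event indicators, with optional
#' patient identifiers, after validating the usual constraints of
#' right-censored survival data.
#'
#' @param time Positive numeric vector of follow-up times in months.
#' @param event Integer/logical vector of event indicators (1 = event
#'   observed, 0 = censored), same length as `time`.
#' @param patient_id Optional character vector of identifiers.
#' @return An object of class `surv_data`: a data frame with columns
#'   `patient_id`, `time`, `event`.
#' @examples
#' surv_data(c(5, 12, 30), c(1, 0, 1))
#' @export
surv_data <- function(time, event, patient_id = NULL) {
  if (length(time) != length(event)) {
    stop("`time` and `event` must have equal length")
  }
  if (length(time) == 0L) stop("empty survival data")
  if (!all(is.finite(time)) || any(time <= 0)) {
    stop("all times must be finite and > 0")
  }
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("`event` must be 0/1")
  if (is.null(patient_id)) {
    patient_id <- sprintf("P%04d", seq_along(time))
  }
  if (anyDuplicated(patient_id)) stop("duplicate patient ids")
  out <- data.frame(patient_id = as.character(patient_id),
                    time = as.numeric(time), event = event,
                    stringsAsFactors = FALSE)
  class(out) <- c("surv_data", "data.frame")
  out
}

as_surv_data <- function(x) {
  if (inherits(x, "surv_data")) return(x)
  if (is.data.frame(x) && all(c("time", "event") %in% names(x))) {
    return(surv_data(x$time, x$event,
                     if ("patient_id" %in% names(x)) x$patient_id else NULL))
  }
  stop("cannot interpret input as survival data")
}
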