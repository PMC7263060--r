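#' @importFrom rlang %||% abort warn .data
#' @importFrom stats dnorm pnorm qnorm pchisq qchisq pt sd var median
#'   rnorm rbinom aov t.test integrate uniroot setNames
NULL

# error helpers: every condition carries a ctbayes_* class so callers can
# distinguish configuration errors from data problems programmatically
stop_config <- function(msg) abort(msg, class = "ctbayes_config_error")
stop_data <- function(msg) abort(msg, class = "ctbayes_data_error")
stop_solve <- function(msg) abort(msg, class = "ctbayes_solve_error")

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

assert_prob <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) stop_config(sprintf("`%s` must lie in [0, 1].", name))
  invisible(x)
}

#' Assays expected in a raw Ct table
#'
#' @return Character vector of the four assay names used throughout the
#'   package: the two candidate marker microRNAs, miR21-5p, and the RNU6B
#'   (U6) endogenous normalizer.
#' @export
ct_assays <- function() c("miR375", "miR205", "miR21", "U6")

# canonical column set of a raw Ct table
ct_table_columns <- function() {
  c("sample_id", "subtype", "class", "stage", "assay", "replicate", "ct")
}

validate_ct_table <- function(table, ct_range = c(5, 40), check_range = FALSE) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_data("Ct table is empty or not a data frame.")
  }
  missing <- setdiff(setdiff(ct_table_columns(), "stage"), names(table))
  if (length(missing) > 0L) {
    stop_data(sprintf("Ct table lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(table$ct))) stop_data("Ct table contains non-finite Ct values.")
  if (check_range && (any(table$ct < ct_range[1]) || any(table$ct > ct_range[2]))) {
    warn(sprintf(
      "Some Ct values fall outside the plausible range [%g, %g] cycles.",
      ct_range[1], ct_range[2]
    ))
  }
  invisible(table)
}
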