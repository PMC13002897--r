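#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an SR matrix into a long tibble
#'
#' @param x an [sr_matrix()] result.
#' @param ... unused.
#' @return tibble: one row per electrode-emitter cell with powers and SR.
#' @method tidy sr_matrix
#' @export
tidy.sr_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$pattern_id <- attr(x, "pattern_id") %||% NA_integer_
  out
}

#' One-row summary of an SR matrix
#'
#' @param x an [sr_matrix()] result.
#' @param ... unused.
#' @return tibble: `pattern_id`, `n_cells` (non-missing), `mean_sr_percent`,
#'   `median_sr_percent`, `fpsr_percent`.
#' @method glance sr_matrix
#' @export
glance.sr_matrix <- function(x, ...) {
  srs <- x$sr_percent[!is.na(x$sr_percent)]
  f <- fpsr(x)
  tibble::tibble(
    pattern_id = f$pattern_id,
    n_cells = f$n_cells,
    mean_sr_percent = mean(srs),
    median_sr_percent = median(srs),
    fpsr_percent = f$fpsr_percent
  )
}

#' Tidy a pre/during/post test result
#'
#' @param x a [pre_dur_post_test()] result.
#' @param ... unused.
#' @return the underlying tibble.
#' @method tidy power_test_result
#' @export
tidy.power_test_result <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a pipeline report
#'
#' @param x a [run_pipeline()] report.
#' @param ... unused.
#' @return tibble with seed, config hash, stage kind and output count.
#' @method glance probeseize_report
#' @export
glance.probeseize_report <- function(x, ...) {
  tibble::tibble(
    seed = x$provenance$seed,
    config_hash = x$provenance$config_hash,
    analysis = x$stages$analysis$kind,
    n_outputs = length(x$manifest)
  )
}
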