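#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training run
#'
#' @param x A `vldet_fit` from [train_toy()].
#' @param ... Unused.
#' @return The per-step loss trace as a tibble (`step`, per-term columns,
#'   `total`).
#' @export
tidy.vldet_fit <- function(x, ...) x$trace

#' @rdname tidy.vldet_fit
#' @return `glance()`: a one-row tibble with `steps`, `initial_loss`,
#'   `final_loss`, `loss_ratio`, `n_params`, `lr`.
#' @export
glance.vldet_fit <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    steps = nrow(tr),
    initial_loss = if (nrow(tr)) tr$total[1] else NA_real_,
    final_loss = if (nrow(tr)) tr$total[nrow(tr)] else NA_real_,
    loss_ratio = if (nrow(tr)) tr$total[nrow(tr)] / tr$total[1]
                 else NA_real_,
    n_params = n_params(x$model),
    lr = x$lr
  )
}

#' Tidy a metric report
#'
#' @param x A `metric_report` from [evaluate_dataset()].
#' @param ... Unused.
#' @return A long tibble with columns `metric`, `value`.
#' @export
tidy.metric_report <- function(x, ...) {
  tibble::tibble(metric = names(x), value = as.numeric(x[1, ]))
}

#' Tidy a match result
#'
#' @param x A `match_result` from [hungarian_match()].
#' @param ... Unused.
#' @return The pair table (`pred`, `gt`, `cost`).
#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @rdname tidy.match_result
#' @return `glance()`: one row with `n_pairs`, `total_cost`,
#'   `n_unmatched_pred`.
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), total_cost = x$total_cost,
                 n_unmatched_pred = length(x$unmatched_pred))
}

#' Tidy a validation report
#'
#' @param x Output of [validate_spine_annotation()] (already tidy); returns
#'   it unchanged for pipe symmetry.
#' @param ... Unused.
#' @keywords internal
#' @noRd
NULL
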