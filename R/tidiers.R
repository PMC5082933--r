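# broom-style tidiers and plots for sync reports.

#' Tidy a sync report
#'
#' One row per planned path with its action, outcome, fetch attempts
#' and resulting repository version.
#'
#' @param x A `tv_sync_report` from [run_sync()].
#' @param ... Unused.
#' @return A tibble of per-path outcomes.
#' @method tidy tv_sync_report
#' @export
tidy.tv_sync_report <- function(x, ...) {
  x$outcomes
}

#' One-row summary of a sync report
#'
#' @param x A `tv_sync_report` from [run_sync()].
#' @param ... Unused.
#' @return A one-row tibble: run id, timestamps, planned changes,
#'   download attempts, ingested/deleted/refreshed/failed counts,
#'   messages and events emitted.
#' @method glance tv_sync_report
#' @export
glance.tv_sync_report <- function(x, ...) {
  tibble::tibble(
    run_id = x$run_id, started = x$started, finished = x$finished,
    n_planned = x$n_planned, downloads = x$downloads,
    n_ingested = sum(x$outcomes$outcome == "ingested"),
    n_deleted = sum(x$outcomes$outcome == "deleted"),
    n_refreshed = sum(x$outcomes$outcome == "refreshed"),
    n_failed = length(x$failed),
    n_messages = x$n_messages, n_events = x$n_events)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot sync outcomes
#'
#' Bar chart of per-path outcomes by planned action.
#'
#' @param object A `tv_sync_report` from [run_sync()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tv_sync_report
#' @export
autoplot.tv_sync_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$action, fill = .data$outcome)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "planned action", y = "files",
                  title = paste("Sync", object$run_id)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
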