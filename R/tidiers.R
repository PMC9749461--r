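## broom-style tidiers for the result objects.

#' @exportS3Method generics::tidy
tidy.hvcpg_result <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.hvcpg_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_hvcpgs = sum(x$is_hvcpg),
    n_background = length(attr(x, "array_background")),
    n_datasets = p$n_datasets,
    min_fraction_pct = p$min_fraction_pct,
    min_datasets = p$min_datasets,
    n_unreliable_removed = attr(x, "n_unreliable_removed") %||% 0L
  )
}

#' @exportS3Method generics::tidy
tidy.control_match <- function(x, ...) {
  x$matches
}

#' @exportS3Method generics::glance
glance.control_match <- function(x, ...) {
  tibble(n_matched = nrow(x$matches), n_unmatched = length(x$unmatched))
}

#' @exportS3Method generics::tidy
tidy.cluster_set <- function(x, ...) {
  x$membership
}

#' @exportS3Method generics::glance
glance.cluster_set <- function(x, ...) {
  tibble(n_clusters = length(x$clusters),
         n_clustered_cpgs = sum(lengths(x$clusters)),
         n_singletons = length(x$singletons),
         gap_bp = x$gap)
}

#' @exportS3Method generics::tidy
tidy.siv_power <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.siv_power <- function(x, ...) {
  q <- quantile(x$power, c(0.25, 0.75), names = FALSE)
  p <- attr(x, "params")
  tibble(mean_power = mean(x$power), median_power = stats::median(x$power),
         iqr_low = q[1], iqr_high = q[2],
         n_cpgs = nrow(x), n_reps = p$n_reps, n_individuals = p$n_individuals)
}

#' @exportS3Method generics::tidy
tidy.hvcpg_grid <- function(x, ...) {
  as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    setNames(c("i", "j", "n_hvcpgs")) |>
    mutate(i = as.numeric(.data$i), j = as.numeric(.data$j))
}
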