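#' Co-methylation correlation decay with genomic distance
#'
#' For every same-chromosome pair of the given CpGs with distance at most
#' `max_dist`, computes the Spearman correlation of their Beta vectors in each
#' qualifying dataset (at least `min_samples` samples), assigns the pair to a
#' `bin_bp`-wide distance bin, and averages. By default every pair-by-dataset
#' value gets equal weight (`average = "pair_dataset"`); `average = "dataset"`
#' first averages within dataset and then across datasets.
#'
#' @param datasets List of [meth_dataset()] objects.
#' @param cpgs Character vector of CpG ids to profile.
#' @param annotation Probe annotation tibble (`cpg`, `chrom`, `pos`).
#' @param bin_bp Distance bin width in bp (default 100).
#' @param max_dist Maximum pair distance in bp (default 10000).
#' @param min_samples Minimum dataset sample size (default 100).
#' @param average `"pair_dataset"` (default) or `"dataset"`.
#' @return A tibble of class `decay_profile` with columns `bin_start`,
#'   `bin_end`, `mean_rho`, `n_pairs`.
#' @export
correlation_decay_profile <- function(datasets, cpgs, annotation,
                                      bin_bp = 100, max_dist = 10000,
                                      min_samples = 100,
                                      average = c("pair_dataset", "dataset")) {
  average <- match.arg(average)
  use <- Filter(function(d) ncol(d$beta) >= min_samples, datasets)
  if (!length(use)) abort(sprintf("No dataset has >= %d samples.", min_samples))
  ann <- annotation |> filter(.data$cpg %in% cpgs) |> arrange(.data$chrom, .data$pos)

  pairs <- ann |>
    group_by(.data$chrom) |>
    summarise(pair = {
      p <- list()
      for (a in seq_len(n())) {
        b <- a + 1L
        while (b <= n() && pos[b] - pos[a] <= max_dist) {
          p[[length(p) + 1L]] <- tibble(cpg1 = cpg[a], cpg2 = cpg[b],
                                        dist = pos[b] - pos[a])
          b <- b + 1L
        }
      }
      list(bind_rows(p))
    }, .groups = "drop") |>
    (\(x) bind_rows(x$pair))()
  if (!nrow(pairs)) abort("No same-chromosome CpG pair within `max_dist`.")

  per_dataset <- map(use, function(d) {
    beta <- d$beta
    ok <- pairs$cpg1 %in% rownames(beta) & pairs$cpg2 %in% rownames(beta)
    pp <- pairs[ok, , drop = FALSE]
    if (!nrow(pp)) return(NULL)
    rho <- vapply(seq_len(nrow(pp)), function(i) {
      x <- beta[pp$cpg1[i], ]; y <- beta[pp$cpg2[i], ]
      keep <- !is.na(x) & !is.na(y)
      if (sum(keep) < 3) return(NA_real_)
      suppressWarnings(cor(x[keep], y[keep], method = "spearman"))
    }, numeric(1))
    mutate(pp, rho = rho, dataset_id = d$dataset_id)
  })
  values <- bind_rows(per_dataset) |> filter(!is.na(.data$rho))
  if (!nrow(values)) abort("No pair had enough complete observations.")
  values <- values |> mutate(bin_start = (.data$dist %/% bin_bp) * bin_bp)

  prof <- if (average == "pair_dataset") {
    values |>
      group_by(.data$bin_start) |>
      summarise(mean_rho = mean(.data$rho), n_pairs = n(), .groups = "drop")
  } else {
    values |>
      group_by(.data$dataset_id, .data$bin_start) |>
      summarise(rho = mean(.data$rho), n_pairs = n(), .groups = "drop") |>
      group_by(.data$bin_start) |>
      summarise(mean_rho = mean(.data$rho), n_pairs = sum(.data$n_pairs),
                .groups = "drop")
  }
  prof <- prof |>
    mutate(bin_end = .data$bin_start + bin_bp) |>
    select("bin_start", "bin_end", "mean_rho", "n_pairs") |>
    arrange(.data$bin_start)
  structure(prof, class = c("decay_profile", class(prof)))
}

#' Fit an exponential decay length to a correlation-decay profile
#'
#' Fits `mean_rho ~ A * exp(-d / L)` to the binned profile (bin midpoints,
#' weighted by pair counts) with Levenberg-Marquardt least squares and returns
#' the amplitude `A` and the decay length `L` in bp.
#'
#' @param profile A `decay_profile` from [correlation_decay_profile()].
#' @param start_length Starting value for `L` (default 1000 bp).
#' @return A one-row tibble `(amplitude, decay_length_bp)`.
#' @export
fit_decay_length <- function(profile, start_length = 1000) {
  stopifnot(inherits(profile, "decay_profile"))
  d <- (profile$bin_start + profile$bin_end) / 2
  fit <- minpack.lm::nlsLM(
    mean_rho ~ A * exp(-d / L),
    data = data.frame(mean_rho = profile$mean_rho, d = d),
    start = list(A = max(profile$mean_rho), L = start_length),
    weights = profile$n_pairs,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  tibble(amplitude = unname(est["A"]), decay_length_bp = unname(est["L"]))
}

#' Single-linkage genomic clustering of CpGs
#'
#' Sorts the CpGs by position within each chromosome and chains consecutive
#' CpGs at most `gap` bp apart (inclusive boundary). Maximal chains with at
#' least two members are clusters; the rest are singletons. The output is
#' invariant to the input order.
#'
#' @param cpgs Character vector of CpG ids; all must be annotated.
#' @param annotation Probe annotation tibble (`cpg`, `chrom`, `pos`).
#' @param gap Maximum within-cluster gap in bp (default 4000).
#' @return A list of class `cluster_set`: `clusters` (list of id vectors,
#'   position-sorted), `singletons` (id vector) and a `membership` tibble.
#' @export
build_clusters <- function(cpgs, annotation, gap = 4000) {
  cpgs <- unique(cpgs)
  ann <- annotation[match(cpgs, annotation$cpg), ]
  if (anyNA(ann$cpg)) {
    abort(paste0("Unannotated CpGs: ",
                 paste(head(setdiff(cpgs, annotation$cpg), 5), collapse = ", ")))
  }
  ann <- ann |> arrange(.data$chrom, .data$pos)
  new_chain <- c(TRUE, diff(ann$pos) > gap | ann$chrom[-1] != ann$chrom[-nrow(ann)])
  chain_id <- cumsum(new_chain)
  chains <- split(ann$cpg, chain_id)
  sizes <- lengths(chains)
  clusters <- unname(chains[sizes >= 2])
  singletons <- unlist(chains[sizes == 1], use.names = FALSE) %||% character(0)
  membership <- tibble(
    cpg = unlist(chains, use.names = FALSE),
    cluster = rep(ifelse(sizes >= 2, cumsum(sizes >= 2), NA_integer_), sizes)
  )
  structure(list(clusters = clusters, singletons = singletons,
                 membership = membership, gap = gap),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters (%d CpGs) + %d singletons, gap <= %d bp\n",
              length(x$clusters), sum(lengths(x$clusters)),
              length(x$singletons), x$gap))
  invisible(x)
}

#' De-cluster a CpG set
#'
#' Picks one uniformly random member from each cluster and keeps every
#' singleton, so the result contains `n_clusters + n_singletons` CpGs and no
#' two retained CpGs on one chromosome lie within the clustering gap of each
#' other. Deterministic given the seed.
#'
#' @param clusterset A `cluster_set` from [build_clusters()].
#' @param seed Integer seed.
#' @return Sorted character vector of retained CpG ids.
#' @export
decluster <- function(clusterset, seed = 1L) {
  stopifnot(inherits(clusterset, "cluster_set"))
  set.seed(seed)
  picked <- vapply(clusterset$clusters,
                   function(cl) cl[sample.int(length(cl), 1L)], character(1))
  sort(c(picked, clusterset$singletons))
}
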