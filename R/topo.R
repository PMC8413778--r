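#' Subject-level MMN scalp map
#'
#' One value per scalp electrode (mastoids and any excluded channels
#' dropped): the mean of the difference wave over the subject's individual
#' 50-ms MMN window (default), or the value at the peak sample.
#'
#' @param dw A `difference_wave`.
#' @param measure The subject's measures row from [measure_mmn()] (supplies
#'   the individual window / peak latency).
#' @param mode `"window"` (mean over `[window_start_ms, window_end_ms]`) or
#'   `"peak"` (single sample at the peak latency).
#' @param exclude Channels excluded from the map.
#' @return Tibble with columns `electrode`, `value` and attributes
#'   `subject_id`, `window`.
#' @export
subject_topomap <- function(dw, measure, mode = c("window", "peak"),
                            exclude = c("A1", "A2")) {
  mode <- match.arg(mode)
  t_ms <- times_ms(dw)
  idx <- if (mode == "window") {
    window_sample_idx(t_ms, measure$window_start_ms, measure$window_end_ms)
  } else {
    window_sample_idx(t_ms, measure$peak_latency_ms, measure$peak_latency_ms)
  }
  keep <- !(dw$montage$name %in% exclude)
  vals <- rowMeans(dw$diff[keep, idx, drop = FALSE])
  out <- tibble::tibble(electrode = dw$montage$name[keep], value = unname(vals))
  attr(out, "subject_id") <- dw$subject_id
  attr(out, "window") <- c(measure$window_start_ms, measure$window_end_ms)
  out
}

map_values <- function(map) {
  if (is.data.frame(map)) {
    v <- map$value
    names(v) <- map$electrode
    v
  } else if (is.numeric(map)) {
    map
  } else {
    abort("A scalp map must be a numeric vector or a tibble with `electrode`, `value`.")
  }
}

#' Global field power of a scalp map
#'
#' The spatial root-mean-square of the average-referenced map:
#' `sqrt(mean((v - mean(v))^2))`. A reference-free measure of map strength.
#'
#' @param map Numeric vector of electrode values, or a topomap tibble.
#' @return Non-negative scalar.
#' @examples
#' gfp(c(1, -1))  # 1
#' @export
gfp <- function(map) {
  v <- map_values(map)
  if (length(v) < 2) abort("GFP needs at least 2 electrodes.")
  sqrt(mean((v - mean(v))^2))
}

# Average-reference then scale to unit GFP. Errors on flat maps.
gfp_normalize <- function(v) {
  g <- sqrt(mean((v - mean(v))^2))
  if (g == 0) abort("Cannot GFP-normalize a spatially uniform map (GFP = 0).")
  (v - mean(v)) / g
}

#' Global dissimilarity (DISS) between two scalp maps
#'
#' Both maps are average-referenced and divided by their global field
#' power; DISS is the root mean square of the electrode-wise differences of
#' the normalized maps. It ranges from 0 (identical topographies) to 2
#' (polarity-reversed topographies), and satisfies
#' `DISS^2 = 2 * (1 - r)` with `r` the spatial Pearson correlation.
#'
#' @param u,v Scalp maps (numeric vectors or topomap tibbles) over the same
#'   electrode set. Named inputs are aligned by electrode.
#' @return DISS in `[0, 2]`.
#' @examples
#' m <- c(Fz = 2, Cz = 1, Pz = -1, Oz = -2)
#' diss(m, m)    # 0
#' diss(m, -m)   # 2
#' @export
diss <- function(u, v) {
  uu <- map_values(u)
  vv <- map_values(v)
  if (length(uu) != length(vv)) abort("Maps must share the electrode set.")
  if (!is.null(names(uu)) && !is.null(names(vv))) {
    if (!setequal(names(uu), names(vv))) {
      abort("Maps must share the electrode set.")
    }
    vv <- vv[names(uu)]
  }
  un <- gfp_normalize(uu)
  vn <- gfp_normalize(vv)
  sqrt(mean((un - vn)^2))
}

# Vectorized DISS between paired columns of two electrode x k matrices.
diss_cols <- function(A, B) {
  An <- sweep(A, 2, colMeans(A))
  Bn <- sweep(B, 2, colMeans(B))
  ga <- sqrt(colMeans(An^2))
  gb <- sqrt(colMeans(Bn^2))
  if (any(ga == 0) || any(gb == 0)) abort("Zero-GFP map in permutation set.")
  An <- sweep(An, 2, ga, "/")
  Bn <- sweep(Bn, 2, gb, "/")
  sqrt(colMeans((An - Bn)^2))
}

#' Randomization test for topographic differences between two groups
#'
#' Computes the DISS between the two groups' average maps, then builds a
#' null distribution by repeatedly reassigning the pooled individual maps
#' to two groups of the original sizes uniformly at random, re-averaging,
#' and recomputing DISS. The p-value is the plain proportion of permuted
#' DISS values greater than or equal to the observed one (ties count as
#' greater or equal); `add_one = TRUE` uses the (b+1)/(m+1) variant.
#'
#' @param maps Long tibble of individual maps: columns `subject_id`,
#'   `group`, `electrode`, `value` (exactly two groups).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param add_one Use the add-one p-value variant. Default `FALSE`.
#' @return An object of class `diss_test` with elements `diss_observed`,
#'   `p_value`, `n_permutations`, `null_distribution`, `seed`,
#'   `group_sizes`.
#' @export
diss_permutation_test <- function(maps, n_perm = 10000, seed = 1L,
                                  add_one = FALSE) {
  stopifnot(all(c("subject_id", "group", "electrode", "value") %in% names(maps)))
  groups <- unique(maps$group)
  if (length(groups) != 2) abort("Need exactly two groups.")
  wide <- tidyr::pivot_wider(maps, id_cols = "electrode",
                             names_from = "subject_id", values_from = "value")
  electrodes <- wide$electrode
  M <- as.matrix(wide[, -1, drop = FALSE])          # electrodes x subjects
  sub_group <- maps$group[match(colnames(M), maps$subject_id)]
  nA <- sum(sub_group == groups[1])
  nB <- sum(sub_group == groups[2])
  if (nA < 2 || nB < 2) abort("Each group needs at least 2 subjects.")
  if (n_perm < 100) warn("Fewer than 100 permutations: p-value resolution is coarse.")

  mean_map <- function(idx) rowMeans(M[, idx, drop = FALSE])
  obs <- diss(mean_map(sub_group == groups[1]), mean_map(sub_group == groups[2]))

  null <- with_seed(seed, {
    n <- ncol(M)
    A <- matrix(0, nrow(M), n_perm)
    B <- matrix(0, nrow(M), n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, nA)
      A[, b] <- rowMeans(M[, idx, drop = FALSE])
      B[, b] <- rowMeans(M[, -idx, drop = FALSE])
    }
    diss_cols(A, B)
  })
  b_ge <- sum(null >= obs - 1e-12)
  p <- if (add_one) (b_ge + 1) / (n_perm + 1) else b_ge / n_perm

  structure(
    list(diss_observed = obs, p_value = p, n_permutations = n_perm,
         null_distribution = null, seed = seed,
         group_sizes = setNames(c(nA, nB), as.character(groups)),
         electrodes = electrodes, add_one = add_one),
    class = "diss_test"
  )
}

#' @export
print.diss_test <- function(x, ...) {
  cat(sprintf("Topographic dissimilarity randomization test\n"))
  cat(sprintf("  groups: %s (n = %d) vs %s (n = %d), %d electrodes\n",
              names(x$group_sizes)[1], x$group_sizes[1],
              names(x$group_sizes)[2], x$group_sizes[2],
              length(x$electrodes)))
  cat(sprintf("  DISS = %.3f, p = %.4g (%d permutations)\n",
              x$diss_observed, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
tidy.diss_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$diss_observed,
    p.value = x$p_value,
    n_permutations = x$n_permutations,
    null_mean = mean(x$null_distribution),
    null_q95 = unname(stats::quantile(x$null_distribution, 0.95))
  )
}

#' @export
glance.diss_test <- function(x, ...) tidy(x)

#' @export
autoplot.diss_test <- function(object, ...) {
  df <- tibble::tibble(diss = object$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diss)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$diss_observed,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "DISS under random group reassignment",
      y = "count",
      title = sprintf("Observed DISS = %.3f, p = %.3g",
                      object$diss_observed, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
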