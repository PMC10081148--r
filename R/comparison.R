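#' Full reconstruction comparison on the synthetic phantom
#'
#' Reproduces the whole evaluation protocol on simulated data: for each seed
#' (one "dataset", analogous to one patient study) the phantom is acquired
#' with 72 radial views per frame plus complex k-space noise, undersampled to
#' `72 / keep_every` views with a frame-interleaved angular pattern (frame
#' `t` keeps views congruent to `t` modulo `keep_every`, so neighbouring
#' frames measure complementary angles — the regime in which a temporal
#' constraint can recover a frame's missing views from its neighbours, at the
#' price of temporal bias), and reconstructed by
#' * the fully sampled FBP gold standard (V4),
#' * raw sparse FBP (`beta_raw`; V3 when 0, V2 otherwise),
#' * deformation-extended FBP (V1, `beta_ext`), and
#' * the iterative Bayesian method, once per value of `alpha1`.
#'
#' All magnitude images are median filtered before RMSE and SSIM are measured
#' against the gold standard.
#'
#' @param spec A [phantom_spec()].
#' @param seeds Integer vector; one dataset per seed (acquisition noise).
#' @param n_views Fully sampled view count (default 72).
#' @param keep_every Undersampling factor (default 3: 72 -> 24 views).
#' @param beta_raw Regularisation for the raw sparse FBP column.
#' @param beta_ext Regularisation for the view-extended FBP column.
#' @param alpha1 Temporal weights for the iterative method (vectorised).
#' @param alpha2,n_iter Remaining iterative parameters (see [bayes_config()]).
#' @param median_size Median filter window (default 3).
#' @return A `recon_comparison`: tibble with one row per dataset x method and
#'   columns `dataset`, `method`, `beta`, `alpha1`, `rmse`, `ssim`.
#' @export
run_comparison <- function(spec = phantom_spec(), seeds = 1L,
                           n_views = 72L, keep_every = 3L,
                           beta_raw = 0, beta_ext = 1,
                           alpha1 = 0.04, alpha2 = 0.006, n_iter = 1000L,
                           median_size = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  phantom <- generate_phantom(spec)
  sampling <- radial_sampling(n_views, spec$grid_size)
  rows <- list()
  for (seed in seeds) {
    fr72 <- acquire_series(phantom, sampling, spec$noise_sigma, seed)
    # interleaved undersampling: frame t keeps views t mod keep_every, so
    # consecutive frames jointly cover the full angular set
    fr24 <- lapply(seq_along(fr72), function(t)
      undersample(fr72[[t]], keep_every, offset = (t - 1L) %% keep_every))
    stack <- function(frames, f) {
      out <- array(0, c(spec$grid_size, spec$grid_size, length(frames)))
      for (t in seq_along(frames)) out[, , t] <- f(frames[[t]])
      median_filter_series(out, median_size)
    }
    gold <- stack(fr72, function(f) run_version(frame72 = f, version = "V4"))
    raw <- stack(fr24, function(f) fbp_reconstruct(f, beta = beta_raw))
    ext <- stack(fr24, function(f) fbp_reconstruct(f, beta = beta_ext,
                                                   extend = TRUE))
    add <- function(method, beta, a1, img)
      tibble::tibble(dataset = seed, method = method,
                     beta = beta, alpha1 = a1,
                     rmse = rmse(img, gold), ssim = ssim(img, gold))
    rows[[length(rows) + 1L]] <- add("gold", 0, NA_real_, gold)
    rows[[length(rows) + 1L]] <- add("raw", beta_raw, NA_real_, raw)
    rows[[length(rows) + 1L]] <- add("extended", beta_ext, NA_real_, ext)
    grids <- lapply(fr24, grid_radial)
    for (a1 in alpha1) {
      rec <- reconstruct(grids, bayes_config(alpha1 = a1, alpha2 = alpha2,
                                             n_iter = n_iter))
      mag <- median_filter_series(combine_norm(rec), median_size)
      rows[[length(rows) + 1L]] <- add("bayes", NA_real_, a1, mag)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recon_comparison", class(out))
  attr(out, "spec") <- spec
  out
}

method_label <- function(method, beta, alpha1) {
  ifelse(method == "bayes",
         sprintf("%s (alpha1=%g)", method, alpha1),
         ifelse(is.na(beta), method, sprintf("%s (beta=%g)", method, beta)))
}

#' Metrics table in the wide per-dataset layout
#'
#' One row per dataset, one column per reconstruction method, values of the
#' chosen metric. The gold-standard column is exactly 0 (RMSE) / 1 (SSIM).
#'
#' @param x A `recon_comparison` from [run_comparison()].
#' @param metric `"rmse"` or `"ssim"`.
#' @return A tibble.
#' @export
metrics_table <- function(x, metric = c("rmse", "ssim")) {
  metric <- match.arg(metric)
  long <- tibble::as_tibble(x)
  long$label <- method_label(long$method, long$beta, long$alpha1)
  tidyr::pivot_wider(long[, c("dataset", "label", metric)],
                     names_from = "label",
                     values_from = tidyr::all_of(metric))
}

#' Write both metrics tables to CSV
#'
#' @param x A `recon_comparison`.
#' @param rmse_path,ssim_path Output file paths.
#' @return Invisibly, the list of the two tables.
#' @export
write_metrics_csv <- function(x, rmse_path, ssim_path) {
  tr <- metrics_table(x, "rmse")
  ts <- metrics_table(x, "ssim")
  utils::write.csv(tr, rmse_path, row.names = FALSE)
  utils::write.csv(ts, ssim_path, row.names = FALSE)
  invisible(list(rmse = tr, ssim = ts))
}

#' @export
tidy.recon_comparison <- function(x, ...) {
  long <- tibble::as_tibble(x)
  long$label <- method_label(long$method, long$beta, long$alpha1)
  tidyr::pivot_longer(long, cols = tidyr::all_of(c("rmse", "ssim")),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.recon_comparison <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  sparse <- tb[tb$method != "gold", ]
  lab <- method_label(sparse$method, sparse$beta, sparse$alpha1)
  agg <- tapply(sparse$rmse, lab, mean)
  tibble::tibble(n_datasets = length(unique(tb$dataset)),
                 n_methods = length(unique(method_label(tb$method, tb$beta, tb$alpha1))),
                 best_sparse_method = names(agg)[which.min(agg)],
                 best_sparse_rmse = min(agg))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of the comparison metrics
#'
#' @param object A `recon_comparison`.
#' @param metric `"rmse"` or `"ssim"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recon_comparison <- function(object, metric = c("rmse", "ssim"), ...) {
  metric <- match.arg(metric)
  long <- tibble::as_tibble(object)
  long$label <- method_label(long$method, long$beta, long$alpha1)
  long <- long[long$method != "gold", ]
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$label, y = .data[[metric]],
                               fill = factor(.data$dataset))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = toupper(metric), fill = "dataset") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 25, hjust = 1))
}

#' Raster montage of selected frames of a series
#'
#' @param object A `dynamic_series` (complex series are shown as magnitude).
#' @param frames Frame indices to display (default up to 4, evenly spaced).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dynamic_series <- function(object, frames = NULL, ...) {
  mag <- combine_norm(object)
  Tn <- n_frames(mag)
  if (is.null(frames))
    frames <- unique(round(seq(1, Tn, length.out = min(4, Tn))))
  df <- do.call(rbind, lapply(frames, function(t) {
    data.frame(x = rep(seq_len(dim(mag)[1]), times = dim(mag)[2]),
               y = rep(seq_len(dim(mag)[2]), each = dim(mag)[1]),
               value = as.vector(mag[, , t]),
               frame = paste0("frame ", t))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$x,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~frame) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
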