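#' Add Gaussian white noise at a target SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise to every non-ground electrode with
#' variance `P_signal * 10^(-snr_db/10)`, where `P_signal` is the mean
#' squared ground-referenced potential over the non-ground electrodes, so
#' that the nominal SNR `10 log10(P_signal / P_noise)` equals `snr_db` in
#' expectation. The ground entry stays exactly 0; `snr_db = Inf` returns the
#' input unchanged.
#'
#' @param phi a `scalp_potentials` vector.
#' @param snr_db signal-to-noise ratio in dB (may be `Inf`).
#' @param seed optional integer seed fixing the noise draw.
#' @return A `scalp_potentials` vector.
#' @export
add_noise <- function(phi, snr_db, seed = NULL) {
  if (is.infinite(snr_db)) return(phi)
  g <- attr(phi, "ground")
  live <- setdiff(seq_along(phi), g)
  p_sig <- mean(phi[live]^2)
  if (p_sig == 0) stop("zero signal power; cannot set a finite SNR")
  if (!is.null(seed)) set.seed(seed)
  out <- unclass(phi)
  out[live] <- out[live] + stats::rnorm(length(live),
                                        sd = sqrt(p_sig * 10^(-snr_db / 10)))
  structure(out, ground = g, class = "scalp_potentials")
}

#' Source depth
#'
#' Euclidean distance from the brain center (for a sphere phantom, its
#' centroid; anatomically, the intersection of the lines under Cz, T7 and
#' T8). Smaller values mean deeper sources.
#'
#' @param location n x 3 matrix (or length-3 vector) of mm positions.
#' @param center length-3 mm position of the brain center.
#' @return numeric vector of depths in mm.
#' @export
source_depth <- function(location, center) {
  location <- rbind(location)
  as.numeric(sqrt(rowSums(sweep(location, 2, center, `-`)^2)))
}

#' Monte-Carlo localization experiment
#'
#' Reproduces the evaluation protocol: for each trial a gray-matter voxel,
#' a coordinate axis and a polarity are drawn at random, the forward problem
#' is solved in `forward_model`, Gaussian noise is added at each requested
#' SNR, and matching pursuit localizes the source with each supplied lead
#' field. The localization error is the Euclidean distance between the true
#' and estimated source locations. Supplying lead fields from head models
#' other than `forward_model` (but on the same grid) runs the model-mismatch
#' protocol; potentials then stay fixed at the forward model's values. Noise
#' draws are shared across lead fields with the same montage, so model
#' comparisons are paired.
#'
#' @param forward_model `conductivity_volume` used to generate the potentials.
#' @param lfms a `leadfield` or named list of `leadfield`s (possibly from
#'   different conductivity models and/or montages, same grid and gray-matter
#'   index).
#' @param n_trials number of random test dipoles (paper-scale default 500).
#' @param snr_db SNR levels in dB (default `c(Inf, 20, 10, 5, 0)`).
#' @param seed RNG seed; fixes dipole draws and noise, making the report
#'   bit-reproducible.
#' @param config a [solver_config()].
#' @param mode matching-pursuit mode, see [mp_localize()].
#' @param current dipole current (A).
#' @param hier optional prebuilt [mg_hierarchy()] of `forward_model`.
#' @param center brain center for depth; default: head centroid of the first
#'   montage.
#' @param verbose print per-trial progress.
#' @return An `eval_report`: `trials` data.frame (one row per trial x lead
#'   field x SNR) and metadata.
#' @export
run_experiment <- function(forward_model, lfms, n_trials = 500L,
                           snr_db = c(Inf, 20, 10, 5, 0), seed = 1L,
                           config = solver_config(), mode = "abs",
                           current = 1e-3, hier = NULL, center = NULL,
                           verbose = FALSE) {
  if (inherits(lfms, "leadfield")) lfms <- list(model = lfms)
  stopifnot(length(lfms) >= 1, !is.null(names(lfms)))
  gm <- lfms[[1]]$gm
  for (L in lfms) stopifnot(L$gm$n == gm$n, same_grid(L$grid, forward_model$grid))
  if (is.null(hier)) hier <- mg_hierarchy(forward_model, config)
  if (is.null(center)) center <- lfms[[1]]$montage$center

  # one montage entry per distinct electrode layout (noise shared within)
  mkey <- vapply(lfms, function(L)
    paste(L$montage$system, paste(L$montage$node_index, collapse = ","),
          sep = "|"), "")
  montages <- lapply(lfms[!duplicated(mkey)], function(L) L$montage)
  names(montages) <- mkey[!duplicated(mkey)]

  set.seed(seed)
  vox <- sample.int(gm$n, n_trials, replace = n_trials > gm$n)
  axs <- sample.int(3L, n_trials, replace = TRUE)
  sgn <- sample(c(1L, -1L), n_trials, replace = TRUE)
  noise_seeds <- sample.int(.Machine$integer.max, n_trials)

  rows <- vector("list", n_trials)
  ax_chr <- c("x", "y", "z")
  for (t in seq_len(n_trials)) {
    v <- gm$voxel_list[vox[t], ]
    true_loc <- drop(voxel_center(gm$grid, v))
    src <- voxel_dipole_term(forward_model$grid, v,
                             axis = paste0(if (sgn[t] > 0) "+" else "-",
                                           ax_chr[axs[t]]),
                             current = current, gm = gm)
    sol <- solve_multigrid(hier, src, config)
    if (verbose && t %% 10L == 0L)
      message(sprintf("  trial %d / %d", t, n_trials))
    phi0 <- lapply(montages, function(mo) reference_potentials(sol, mo))
    depth <- source_depth(true_loc, center)

    out <- list()
    for (s in seq_along(snr_db)) {
      phin <- lapply(seq_along(montages), function(im)
        add_noise(phi0[[im]], snr_db[s],
                  seed = (as.numeric(noise_seeds[t]) + im * 131 + s) %%
                         .Machine$integer.max))
      names(phin) <- names(montages)
      for (ln in names(lfms)) {
        fit <- mp_localize(lfms[[ln]], phin[[mkey[ln]]], mode = mode)
        out[[length(out) + 1L]] <- data.frame(
          trial = t, model = ln, montage = lfms[[ln]]$montage$system,
          snr_db = snr_db[s],
          true_voxel = vox[t],
          true_x = true_loc[1], true_y = true_loc[2], true_z = true_loc[3],
          axis = ax_chr[axs[t]], sign = sgn[t],
          est_voxel = fit$est_voxel,
          est_x = fit$est_location_mm[1], est_y = fit$est_location_mm[2],
          est_z = fit$est_location_mm[3],
          est_axis = fit$est_axis, corr = fit$corr,
          error_mm = sqrt(sum((fit$est_location_mm - true_loc)^2)),
          depth_mm = depth,
          stringsAsFactors = FALSE)
      }
    }
    rows[[t]] <- do.call(rbind, out)
  }
  structure(list(trials = do.call(rbind, rows),
                 n_trials = n_trials, snr_db = snr_db, seed = seed,
                 mode = mode, center = center),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d trials x %d condition rows (models: %s)\n",
              x$n_trials, nrow(x$trials),
              paste(unique(x$trials$model), collapse = ", ")))
  invisible(x)
}

#' Summary statistics of an evaluation report
#'
#' Per (model, montage, SNR): mean and SD of the localization error, its
#' maximum, the fraction of errors below 10 mm, the Pearson correlation
#' between source depth and error, and the cumulative error distribution in
#' 0.5 mm bins.
#'
#' @param report an `eval_report`.
#' @param bin_mm cumulative-distribution bin width (default 0.5 mm).
#' @return An `eval_summary` list: `summary` data.frame and `cumulative`
#'   data.frame.
#' @export
summarize_report <- function(report, bin_mm = 0.5) {
  tr <- report$trials
  stopifnot(nrow(tr) >= 2)
  key <- interaction(tr$model, tr$montage, tr$snr_db, drop = TRUE)
  groups <- split(tr, key)
  summ <- do.call(rbind, lapply(groups, function(g) data.frame(
    model = g$model[1], montage = g$montage[1], snr_db = g$snr_db[1],
    n = nrow(g),
    mean_error_mm = mean(g$error_mm),
    sd_error_mm = stats::sd(g$error_mm),
    max_error_mm = max(g$error_mm),
    frac_below_10mm = mean(g$error_mm < 10),
    depth_error_corr = if (stats::sd(g$error_mm) > 0 && stats::sd(g$depth_mm) > 0)
      stats::cor(g$depth_mm, g$error_mm) else NA_real_,
    stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  summ <- summ[order(summ$model, summ$montage, -summ$snr_db), ]

  cum <- do.call(rbind, lapply(groups, function(g) {
    brk <- seq(0, max(g$error_mm) + bin_mm, by = bin_mm)
    data.frame(model = g$model[1], montage = g$montage[1], snr_db = g$snr_db[1],
               bin_upper_mm = brk[-1],
               cum_fraction = stats::ecdf(g$error_mm)(brk[-1]),
               stringsAsFactors = FALSE)
  }))
  rownames(cum) <- NULL
  structure(list(summary = summ, cumulative = cum), class = "eval_summary")
}

#' @export
summary.eval_report <- function(object, ...) summarize_report(object, ...)

#' @export
print.eval_summary <- function(x, ...) {
  cat("Localization error by model / montage / SNR:\n")
  df <- x$summary
  df$mean_sd <- sprintf("%.2f +/- %.2f", df$mean_error_mm, df$sd_error_mm)
  print(df[, c("model", "montage", "snr_db", "n", "mean_sd",
               "max_error_mm", "frac_below_10mm", "depth_error_corr")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Two-sample t-test between the pooled errors of two reports
#'
#' Pools each report's localization errors across its SNR levels and runs a
#' two-sample two-tailed t-test (pooled variance by default, Welch with
#' `var_equal = FALSE`). Degenerate zero-variance pools return p = 1 when
#' the means are equal and p = 0 otherwise, with a warning.
#'
#' @param report_a,report_b `eval_report`s (or bare numeric error vectors).
#' @param var_equal pooled-variance t-test when `TRUE` (default).
#' @return A `model_comparison` list: `p_value`, `statistic`, `df`, `means`,
#'   `n`.
#' @export
compare_models <- function(report_a, report_b, var_equal = TRUE) {
  pull <- function(x) if (inherits(x, "eval_report")) x$trials$error_mm
                      else as.numeric(x)
  a <- pull(report_a); b <- pull(report_b)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    warning("zero-variance samples; p-value defined by mean equality")
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(structure(list(p_value = p, statistic = NA_real_, df = NA_real_,
                          means = c(mean(a), mean(b)),
                          n = c(length(a), length(b))),
                     class = "model_comparison"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(p_value = unname(tt$p.value),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 means = unname(tt$estimate),
                 n = c(length(a), length(b))),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> mean %.3f vs %.3f mm, t = %.3f (df %.1f), p = %.4g\n",
              x$means[1], x$means[2], x$statistic, x$df, x$p_value))
  invisible(x)
}
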