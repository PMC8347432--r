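# broom-style tidiers, plots and printers for the three fit classes.

#' @describeIn fit_isodesmic Per-proton parameter table.
#' @param x,object An `isodesmic_fit`.
#' @param ... Unused.
#' @export
tidy.isodesmic_fit <- function(x, ...) x$per_proton

#' @describeIn fit_isodesmic One-row summary (`Ka_mean`, `Ka_sd`, `mode`,
#'   numbers of protons and points).
#' @export
glance.isodesmic_fit <- function(x, ...) {
  tibble::tibble(
    Ka_mean = x$Ka_mean, Ka_sd = x$Ka_sd, mode = x$mode,
    n_protons = nrow(x$per_proton),
    n_excluded = sum(x$per_proton$excluded),
    n_points = nrow(x$data)
  )
}

#' @export
print.isodesmic_fit <- function(x, ...) {
  cat("Isodesmic self-association fit (", x$mode, ")\n", sep = "")
  cat(sprintf("  Ka = %.3f +/- %.3f mM^-1  (%d protons, %d excluded)\n",
              x$Ka_mean, x$Ka_sd, nrow(x$per_proton), sum(x$per_proton$excluded)))
  print(x$per_proton)
  invisible(x)
}

#' @describeIn fit_isodesmic Observed shifts and fitted isotherms versus
#'   concentration (log scale), one facet per proton.
#' @export
autoplot.isodesmic_fit <- function(object, ...) {
  pp <- object$per_proton
  grid <- purrr::map_dfr(seq_len(nrow(pp)), function(i) {
    cc <- exp(seq(log(min(object$data$conc_mM)), log(max(object$data$conc_mM)),
                  length.out = 100))
    tibble::tibble(
      proton = pp$proton[i], conc_mM = cc,
      shift_ppm = pp$delta_mon[i] -
        predict_dilution_shift(pp$Ka[i], cc, pp$delta_max[i])
    )
  })
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc_mM, y = .data$shift_ppm)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~proton, scales = "free_y") +
    ggplot2::labs(x = "total ligand (mM)", y = "observed shift (ppm)",
                  title = sprintf("Isodesmic fit: Ka = %.2f +/- %.2f mM^-1",
                                  object$Ka_mean, object$Ka_sd))
}

#' @describeIn fit_binding_titration Per-proton parameter table.
#' @param x,object A `binding_fit`.
#' @param ... Unused.
#' @export
tidy.binding_fit <- function(x, ...) x$per_proton

#' @describeIn fit_binding_titration One-row summary.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(
    Ka_mean = x$Ka_mean, Ka_sd = x$Ka_sd,
    dna_mode = x$dna_mode, baseline_mode = x$baseline_mode,
    n_protons = nrow(x$per_proton),
    n_excluded = sum(x$per_proton$excluded)
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("1:1 binding fit from shift titration (", x$dna_mode, ")\n", sep = "")
  cat(sprintf("  Ka = %.3f +/- %.3f mM^-1  (%d protons, %d excluded)\n",
              x$Ka_mean, x$Ka_sd, nrow(x$per_proton), sum(x$per_proton$excluded)))
  print(x$per_proton)
  invisible(x)
}

#' @describeIn fit_binding_titration Shift change versus duplex
#'   concentration with fitted isotherms, one facet per proton.
#' @export
autoplot.binding_fit <- function(object, ...) {
  dat <- object$data
  base <- dat |>
    dplyr::filter(.data$C_DNA_mM == 0) |>
    dplyr::group_by(.data$proton) |>
    dplyr::summarise(delta_L = mean(.data$shift_ppm), .groups = "drop")
  dat <- dplyr::left_join(dat, base, by = "proton")
  dat$dd <- dat$shift_ppm - dat$delta_L
  pp <- object$per_proton
  grid <- purrr::map_dfr(seq_len(nrow(pp)), function(i) {
    cd <- seq(0, max(dat$C_DNA_mM), length.out = 100)
    tibble::tibble(
      proton = pp$proton[i], C_DNA_mM = cd,
      dd = predict_titration_shift(pp$Ka[i], cd, max(dat$C_L_mM),
                                   pp$delta_complex[i], object$dna_mode)
    )
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$C_DNA_mM, y = .data$dd)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::facet_wrap(~proton, scales = "free_y") +
    ggplot2::labs(x = "total duplex (mM)", y = "shift change (ppm)",
                  title = sprintf("1:1 binding fit: Ka = %.2f +/- %.2f mM^-1",
                                  object$Ka_mean, object$Ka_sd))
}

#' @describeIn fit_decay One-row parameter table (`k`, `t_half`, `A0`, `rss`).
#' @param x,object A `decay_fit`.
#' @param ... Unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(k_per_day = x$k, t_half_days = x$t_half, A0 = x$A0, rss = x$rss)
}

#' @describeIn fit_decay One-row summary including the model settings.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    k_per_day = x$k, t_half_days = x$t_half, A0 = x$A0, rss = x$rss,
    order = x$order, normalization = x$normalization, n_points = nrow(x$data)
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Degradation fit (order %d, %s): k = %.4g /day, t1/2 = %.1f days\n",
              x$order, x$normalization, x$k, x$t_half))
  invisible(x)
}

#' @describeIn fit_decay Intact fraction versus time with the fitted decay
#'   curve.
#' @export
autoplot.decay_fit <- function(object, ...) {
  tt <- seq(0, max(object$data$time_days), length.out = 200)
  curve <- tibble::tibble(
    time_days = tt,
    intact_fraction = predict_remaining_fraction(object$k, tt, object$A0, object$order)
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_days, y = .data$intact_fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "time (days)", y = "intact fraction",
                  title = sprintf("t1/2 = %.1f days", object$t_half))
}
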