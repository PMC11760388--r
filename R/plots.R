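#' Plot a synthetic or WFDB ECG record
#'
#' Shows both leads over a time window with R-peak markers when available.
#'
#' @param record An `af_synth_record` or [ecg_record()].
#' @param t_lim Optional length-2 time window in seconds.
#' @return A ggplot object.
#' @export
plot_record <- function(record, t_lim = NULL) {
  if (inherits(record, "af_synth_record")) {
    sigs <- record$signals
    fs <- record$fs
    rpk <- record$r_peaks
  } else {
    sigs <- stats::setNames(record$signals,
                            ifelse(nzchar(record$lead_names),
                                   record$lead_names,
                                   paste0("ch", seq_along(record$signals))))
    fs <- record$fs
    rpk <- NULL
  }
  df <- do.call(rbind, lapply(names(sigs), function(nm) {
    tibble::tibble(time = (seq_along(sigs[[nm]]) - 1) / fs,
                   value = sigs[[nm]], lead = nm)
  }))
  if (!is.null(t_lim)) df <- df[df$time >= t_lim[1] & df$time <= t_lim[2], ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)")
  if (!is.null(rpk)) {
    rdf <- tibble::tibble(time = (rpk - 1) / fs)
    if (!is.null(t_lim)) rdf <- rdf[rdf$time >= t_lim[1] & rdf$time <= t_lim[2], ]
    p <- p + ggplot2::geom_vline(data = rdf,
                                 ggplot2::aes(xintercept = .data$time),
                                 linetype = 3, colour = "red",
                                 linewidth = 0.2)
  }
  p
}

#' Plot the pre-training loss trajectory
#'
#' Per-step total and per-term contrastive losses from a checkpoint's
#' training log.
#'
#' @param checkpoint An `af_checkpoint` from [pretrain()].
#' @return A ggplot object.
#' @export
plot_training_log <- function(checkpoint) {
  stopifnot(inherits(checkpoint, "af_checkpoint"))
  log <- checkpoint$log
  if (is.null(log) || nrow(log) == 0) stop_af("checkpoint has no training log")
  log$global_step <- seq_len(nrow(log))
  long <- do.call(rbind, lapply(
    c("loss_total", "loss_temporal", "loss_channel", "loss_label"),
    function(cn) tibble::tibble(global_step = log$global_step,
                                loss = log[[cn]],
                                term = sub("loss_", "", cn),
                                source = log$source)
  ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$global_step, y = .data$loss,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$source), size = 1) +
    ggplot2::labs(x = "pre-training step", y = "loss", colour = "term",
                  shape = "batch source")
}
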