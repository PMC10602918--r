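# ggplot2 views of the result types.

#' Plot a per-position mapping profile
#'
#' 5'-end counts along the reference, coloured by read length, (+) strand
#' up and (-) strand down.
#'
#' @param object An `amir_profile` from [map_exact()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amir_profile
#' @export
autoplot.amir_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(signed = ifelse(.data$strand == "+", .data$count, -.data$count))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$signed, fill = factor(.data$length)
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = sprintf("position on %s (nt)", attr(object, "reference_name") %||% "reference"),
      y = "5'-end read count (+ up / - down)", fill = "read length"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a phasing-register table
#'
#' Proportion of 21-nt (+) reads per register; register 1 (reads initiating
#' at the cleavage site and every 21 nt thereafter) is highlighted, and the
#' 1/21 uniform expectation is drawn as a reference line.
#'
#' @param object A `phasing_table` from [phasing_registers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phasing_table
#' @export
autoplot.phasing_table <- function(object, ...) {
  df <- as_tibble(object) |> mutate(in_phase = .data$register == 1)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$register), y = .data$proportion, fill = .data$in_phase
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1 / 21, linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#c0392b")) +
    ggplot2::labs(x = "phasing register", y = "proportion of 21-nt (+) reads") +
    ggplot2::theme_minimal()
}

#' Plot the window breakdown of a processing report
#'
#' Counts by 5'-end offset from the guide start, coloured by read length;
#' the authentic amiRNA is the 21-nt stack at offset 0.
#'
#' @param object A `processing_report` from [processing_accuracy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot processing_report
#' @export
autoplot.processing_report <- function(object, ...) {
  ggplot2::ggplot(object$size_by_offset, ggplot2::aes(
    x = .data$offset, y = .data$count, fill = factor(.data$length)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "5'-end offset from guide start (nt)", y = "read count",
      fill = "read length",
      title = sprintf(
        "%s: %s accurately processed", object$precursor,
        if (object$undefined) "undefined" else sprintf("%.1f%%", 100 * object$accuracy)
      )
    ) +
    ggplot2::theme_minimal()
}
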