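# broom-style accessors and ggplot2 autoplot methods for result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an error report into its event table
#' @param x An `mhc_error_report`.
#' @param ... Unused.
#' @return The events tibble.
#' @method tidy mhc_error_report
#' @export
tidy.mhc_error_report <- function(x, ...) x$events

#' One-row summary of an error report
#' @param x An `mhc_error_report`.
#' @param ... Unused.
#' @return One-row tibble of assembled length and error percentages.
#' @method glance mhc_error_report
#' @export
glance.mhc_error_report <- function(x, ...) {
  tibble::tibble(
    assembly_len = x$assembly_len,
    base_call_error_pct = x$base_call_error_pct,
    nonrepeat_sv_error_pct = x$nonrepeat_sv_error_pct,
    repeat_sv_error_pct = x$repeat_sv_error_pct,
    total_error_pct = x$total_error_pct)
}

#' @export
print.mhc_error_report <- function(x, ...) {
  cat("<mhc_error_report> over", x$assembly_len, "assembled bp\n")
  cat(sprintf("  base call error:      %.4f%%\n", x$base_call_error_pct))
  cat(sprintf("  non-repeat SV error:  %.4f%%\n", x$nonrepeat_sv_error_pct))
  cat(sprintf("  repeat SV error:      %.4f%%\n", x$repeat_sv_error_pct))
  cat(sprintf("  total error:          %.4f%%\n", x$total_error_pct))
  invisible(x)
}

#' Plot an error report as a category bar chart
#' @param object An `mhc_error_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mhc_error_report
#' @export
autoplot.mhc_error_report <- function(object, ...) {
  df <- tibble::tibble(
    category = factor(c("base call", "non-repeat SV", "repeat SV"),
                      levels = c("base call", "non-repeat SV", "repeat SV")),
    pct = c(object$base_call_error_pct, object$nonrepeat_sv_error_pct,
            object$repeat_sv_error_pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "error (% of assembled bp)") +
    ggplot2::theme_minimal()
}

#' Tidy an anchor alignment into its anchor table
#' @param x An `mhc_anchor_alignment`.
#' @param ... Unused.
#' @return Tibble of chained anchors (`apos`, `tpos`, `len`).
#' @method tidy mhc_anchor_alignment
#' @export
tidy.mhc_anchor_alignment <- function(x, ...) x$anchors

#' One-row summary of an anchor alignment
#' @param x An `mhc_anchor_alignment`.
#' @param ... Unused.
#' @return One-row tibble (orientation, anchor count, aligned bp, largest
#'   break).
#' @method glance mhc_anchor_alignment
#' @export
glance.mhc_anchor_alignment <- function(x, ...) {
  br <- alignment_breaks(x)
  tibble::tibble(
    orientation = x$orientation,
    n_anchors = nrow(x$anchors),
    aligned_bp = x$aligned_bp,
    assembly_len = x$assembly_len,
    max_break = if (nrow(br)) max(br$break_size) else 0L)
}

#' Dotplot of an anchor alignment
#'
#' The classic assembly-vs-reference dotplot: each chained anchor is a
#' diagonal segment; breaks in the diagonal mark structural discontinuities
#' (for example a mismatched class II cassette).
#'
#' @param object An `mhc_anchor_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mhc_anchor_alignment
#' @export
autoplot.mhc_anchor_alignment <- function(object, ...) {
  anc <- object$anchors
  ggplot2::ggplot(anc) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$tpos, xend = .data$tpos + .data$len,
      y = .data$apos, yend = .data$apos + .data$len),
      linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "truth / guide (bp)", y = "assembly (bp)") +
    ggplot2::theme_minimal()
}

#' Tidy an oriented assembly into its placement table
#' @param x An `mhc_assembly`.
#' @param ... Unused.
#' @return The placements tibble.
#' @method tidy mhc_assembly
#' @export
tidy.mhc_assembly <- function(x, ...) x$placements

#' One-row summary of an oriented assembly
#' @param x An `mhc_assembly`.
#' @param ... Unused.
#' @return One-row tibble (consensus length, non-N bp, scaffold counts).
#' @method glance mhc_assembly
#' @export
glance.mhc_assembly <- function(x, ...) {
  tibble::tibble(
    consensus_len = nchar(x$consensus),
    assembled_bp = nonN_length(x$consensus),
    n_placed = nrow(x$placements),
    n_unplaced = nrow(x$unplaced))
}
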