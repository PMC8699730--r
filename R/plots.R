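map_raster_df <- function(m) {
  tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 value = as.vector(m))
}

#' Plot an OPD map
#'
#' @param object an [opd_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.opd_map <- function(object, ...) {
  ggplot2::ggplot(map_raster_df(unclass(object)),
                  ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "OPD (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = "OPD map")
}

#' Plot a temporal standard-deviation map
#'
#' @param object a [temporal_std_map()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.temporal_std_map <- function(object, ...) {
  ggplot2::ggplot(map_raster_df(unclass(object)),
                  ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "std (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = "Temporal std of OPD")
}
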