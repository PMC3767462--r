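#' Plot the stars distribution of one or more libraries
#'
#' @param ... Named profiles tibbles (e.g. `total = profiles,
#'   drug_like = profiles[drug, ]`); a single unnamed library is labelled
#'   `"library"`.
#' @param panel Range panel used for scoring.
#' @return A ggplot object: stars on the x axis, compound counts on y, one
#'   coloured line per library.
#' @export
plot_stars_distribution <- function(..., panel = drugs95_panel()) {
  libs <- list(...)
  if (length(libs) == 1 && is.null(names(libs))) names(libs) <- "library"
  dat <- imap(libs, function(p, nm) {
    stars_distribution(p, panel) %>% mutate(library = nm)
  }) %>% bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stars, y = .data$count,
                                    colour = .data$library)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "# descriptors outside the 95%-of-drugs range",
                  y = "compounds", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Binned distribution of one descriptor across libraries
#'
#' Bars are labelled by the lower edge of each bin (left-closed binning).
#'
#' @param profiles Profiles tibble.
#' @param descriptor Canonical descriptor name.
#' @param width,origin Binning parameters, see [histogram_counts()].
#' @return A ggplot object.
#' @export
plot_descriptor_histogram <- function(profiles, descriptor, width = 0.5,
                                      origin = 0) {
  v <- profiles[[descriptor]]
  if (is.null(v)) abort(paste0("descriptor not present: ", descriptor))
  h <- histogram_counts(v[!is.na(v)], width = width, origin = origin)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$lower_edge, y = .data$count)) +
    ggplot2::geom_col(width = width * 0.9, just = 0) +
    ggplot2::labs(x = paste0(descriptor, " (bin lower edge)"),
                  y = "compounds") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a compliance result as its stars distribution
#' @param object An `admet_compliance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.admet_compliance <- function(object, ...) {
  dat <- object$stars %>% count(.data$stars, name = "count")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stars, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "# descriptors outside the 95%-of-drugs range",
                  y = "compounds") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
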