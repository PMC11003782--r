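#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_tile
#'   facet_wrap labs scale_fill_viridis_c theme_minimal
NULL

#' Tidy a fitted polynomial chaos expansion
#'
#' One row per basis term and QoI: the multi-index (as a compact string),
#' its total degree, and the regression coefficient.
#'
#' @param x a [fit_pce()] model
#' @param ... unused
#' @return a tibble
#' @export
tidy.pce_model <- function(x, ...) {
  mi <- x$multi_index
  term <- apply(mi, 1, function(a) {
    nz <- which(a > 0)
    if (!length(nz)) return("1")
    paste0(x$input_names[nz], "^", a[nz], collapse = " ")
  })
  out <- tibble(term = rep(term, ncol(x$coef)),
                degree = rep(rowSums(mi), ncol(x$coef)),
                qoi = rep(x$qoi_names, each = nrow(mi)),
                estimate = as.vector(x$coef))
  out
}

#' One-row summary of a fitted polynomial chaos expansion
#'
#' @param x a [fit_pce()] model
#' @param ... unused
#' @return a tibble with degree, basis size, sample count, residual and
#'   design condition number
#' @export
glance.pce_model <- function(x, ...) {
  tibble(degree = x$degree, n_inputs = x$n_inputs, basis_size = x$basis_size,
         n_samples = x$n_samples, rms_residual = max(x$rms_residual),
         condition = x$condition)
}

#' Tidy Sobol' indices
#'
#' Long format over QoIs and inputs with first-order, total and
#' second-order indices.
#'
#' @param x a [sobol_from_pce()] result
#' @param ... unused
#' @return a tibble with columns `qoi`, `index`, `input` (and `input2` for
#'   second-order rows), `value`
#' @export
tidy.sobol_indices <- function(x, ...) {
  long <- function(m, label) {
    tibble(qoi = rep(colnames(m), each = nrow(m)),
           index = label,
           input = rep(rownames(m), ncol(m)),
           input2 = NA_character_,
           value = as.vector(m))
  }
  dplyr::bind_rows(
    long(x$first, "first"),
    long(x$total, "total"),
    tibble(qoi = x$second$qoi, index = "second", input = x$second$i,
           input2 = x$second$j, value = x$second$value)
  )
}

#' Bar chart of first-order and total Sobol' indices
#'
#' @param object a [sobol_from_pce()] result
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.sobol_indices <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$index %in% c("first", "total"), ]
  ggplot(d, aes(x = .data$input, y = .data$value, fill = .data$index)) +
    geom_col(position = "dodge") +
    facet_wrap(~qoi) +
    labs(x = NULL, y = "Sobol' index", fill = NULL) +
    theme_minimal()
}

#' Coefficient spectrum of a polynomial chaos expansion
#'
#' Squared coefficient magnitude (variance contribution) against total
#' degree, per QoI — a quick convergence diagnostic.
#'
#' @param object a [fit_pce()] model
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pce_model <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$degree > 0, ]
  ggplot(d, aes(x = .data$degree, y = .data$estimate^2)) +
    geom_point(alpha = 0.6) +
    facet_wrap(~qoi, scales = "free_y") +
    ggplot2::scale_y_log10() +
    labs(x = "total degree", y = "squared coefficient") +
    theme_minimal()
}

#' Unrolled wall map of a risk factor field
#'
#' Plots a wall-element field (e.g. TAWSS) against axial position and
#' azimuthal angle about the vessel axis — an unrolled analogue of the
#' usual 3-d wall maps.
#'
#' @param field tibble from [risk_factor_field()] built with a domain (so
#'   that element coordinates are present)
#' @param domain the `voxel_domain`
#' @param variable column to map
#' @return a ggplot
#' @export
plot_wall_map <- function(field, domain, variable = "tawss") {
  ctr <- domain$meta$centre %||% c(mean(field$x), mean(field$y))
  d <- dplyr::mutate(field,
                     angle = atan2(.data$y - ctr[2], .data$x - ctr[1]))
  ggplot(d, aes(x = .data$z, y = .data$angle, colour = .data[[variable]])) +
    geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c() +
    labs(x = "axial position (m)", y = "azimuth (rad)") +
    theme_minimal()
}
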