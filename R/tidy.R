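#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ADM mixture fit
#'
#' One row per mixture component with its mixing weight, consensus and
#' length; `signal_fraction` is the weight renormalized over non-background
#' components (reporting only, the weights themselves are untouched).
#'
#' @param x An `adm_fit` from [run_em()], or a `mixture_model`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `kind`, `k1`, `k2`,
#'   `orientation`, `d`, `lambda`, `signal_fraction`, `length`,
#'   `consensus`.
#' @export
tidy.adm_fit <- function(x, ...) tidy(x$model, ...)

#' @rdname tidy.adm_fit
#' @export
tidy.mixture_model <- function(x, ...) {
  comps <- flatten_model(x)
  out <- dplyr::bind_rows(lapply(comps, function(c) {
    tibble::tibble(
      component = c$key, kind = c$kind,
      k1 = if (c$kind == "dimer") c$k1 else c$k,
      k2 = if (c$kind == "dimer") c$k2 else NA_integer_,
      orientation = if (c$kind == "dimer") c$o else NA_character_,
      d = if (c$kind == "dimer") c$d else NA_integer_,
      lambda = c$lambda, length = c$len, consensus = consensus(c$tau)
    )
  }))
  out <- dplyr::bind_rows(
    tibble::tibble(component = "background", kind = "background",
                   lambda = x$lambda0),
    out
  )
  sig <- sum(out$lambda[out$kind != "background"])
  out$signal_fraction <- ifelse(out$kind == "background", NA_real_,
                                if (sig > 0) out$lambda / sig else NA_real_)
  dplyr::relocate(out, "signal_fraction", .after = "lambda")
}

#' One-row summary of an ADM mixture fit
#'
#' @param x An `adm_fit`.
#' @param ... Unused.
#' @return Tibble with `iterations`, `converged`, `loglik`, `distance`,
#'   `n_monomers`, `n_dimers`, `n_pruned`, `lambda0`.
#' @export
glance.adm_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    loglik = utils::tail(x$trace$loglik, 1),
    distance = utils::tail(x$trace$distance, 1),
    n_monomers = length(x$model$monomers),
    n_dimers = nrow(x$model$dimers),
    n_pruned = nrow(x$model$pruned),
    lambda0 = x$model$lambda0
  )
}

#' Plot the EM trace of a fit
#'
#' Log-likelihood and consecutive-model distance per iteration.
#'
#' @param object An `adm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adm_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              c("loglik", "distance"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "EM iteration", y = NULL)
}

#' Heat map of a co-operative binding table
#'
#' Spacing on the horizontal axis, orientation rows, cell shade by mixing
#' weight (displayed in integer multiples of 0.001); pruned cells are
#' blank.
#'
#' @param object A `cob_table` (see [assemble_cob()], [cob_tables()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cob_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$d), .data$orientation,
                               fill = .data$lambda)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$display), "", .data$display)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey95") +
    ggplot2::labs(x = "spacing d", y = NULL, fill = "lambda")
}

#' @rdname autoplot.cob_table
#' @export
plot_cob <- function(object, ...) autoplot.cob_table(object, ...)

#' Per-position marginal profile of an ADM
#'
#' A quick base-probability profile (the order-zero shadow of the model);
#' dinucleotide dependency structure is exported by [export_logo_data()].
#'
#' @param object An `adm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adm <- function(object, ...) {
  m <- marginals(object)
  df <- tibble::tibble(
    position = rep(seq_len(ncol(m)), each = 4),
    base = rep(DNA_BASES, ncol(m)),
    probability = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$position),
                                   .data$probability,
                                   fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "position", y = "marginal probability")
}
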