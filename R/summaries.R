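#' Summarise a prior sample set
#'
#' Per-node posterior-style summaries of a prior sample set: mean, standard
#' deviation, equal-tail 95% credibility interval, 95% highest-density
#' (HPD) interval and effective sample size.  Deterministic given the
#' samples.
#'
#' @param samples A `prior_samples` object.
#' @param prob Interval probability (default 0.95).
#' @return A tibble with one row per interior node.
#' @export
summarize_prior <- function(samples, prob = 0.95) {
  stopifnot(inherits(samples, "prior_samples"))
  x <- samples$draws
  a <- (1 - prob) / 2
  purrr::map_dfr(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    hpd <- hpd_interval(v, prob)
    tibble::tibble(
      node = as.integer(colnames(x)[j]),
      mean = mean(v),
      sd = stats::sd(v),
      lower = unname(stats::quantile(v, a)),
      upper = unname(stats::quantile(v, 1 - a)),
      hpd_lower = hpd[1],
      hpd_upper = hpd[2],
      ess = unname(samples$ess[j])
    )
  })
}

# shortest interval containing `prob` of the sample
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

# effective sample size by Geyer's initial monotone positive sequence
ess_geyer <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  lag_max <- min(n - 1L, 1000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  # pair sums Gamma_m = rho(2m) + rho(2m+1), m = 0, 1, ...
  n_pairs <- (lag_max + 1L) %/% 2L
  gam <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  keep <- which(gam <= 0)
  cut <- if (length(keep) > 0) keep[1] - 1L else n_pairs
  if (cut == 0L) return(n)
  gam <- cummin(gam[seq_len(cut)]) # enforce monotone decrease
  tau <- max(2 * sum(gam) - 1, 1e-8)
  min(n, n / tau)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a prior sample set into long format
#'
#' @param x A `prior_samples` object.
#' @param ... Unused.
#' @return A tibble with columns `chain`, `draw`, `node`, `age`.
#' @export
tidy.prior_samples <- function(x, ...) {
  tibble::as_tibble(x$draws) |>
    dplyr::mutate(chain = x$chain, draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-c("chain", "draw"),
      names_to = "node", values_to = "age",
      names_transform = as.integer
    )
}

#' One-row overview of a prior sample set
#'
#' @param x A `prior_samples` object.
#' @param ... Unused.
#' @export
glance.prior_samples <- function(x, ...) {
  tibble::tibble(
    sampler = x$settings$sampler,
    construction = x$construction,
    n_draws = nrow(x$draws),
    n_chains = length(unique(x$chain)),
    n_nodes = ncol(x$draws),
    min_ess = min(x$ess),
    mean_accept = if (is.null(x$accept)) NA_real_ else mean(x$accept, na.rm = TRUE)
  )
}

#' @export
print.prior_samples <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<prior_samples> %d draws x %d nodes (%s, %s; min ESS %.0f)\n",
    g$n_draws, g$n_nodes, g$sampler, g$construction, g$min_ess
  ))
  invisible(x)
}

#' Plot marginal effective priors against calibration densities
#'
#' One panel per calibrated node: the sampled effective-prior marginal
#' (histogram density) overlaid with the user-specified calibration density
#' curve -- the standard visual check of truncation impact.
#'
#' @param object A `prior_samples` object.
#' @param nodes Optional subset of node ids to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prior_samples <- function(object, nodes = NULL, ...) {
  calibs <- object$calibs
  long <- tidy(object)
  if (is.null(nodes)) nodes <- calibs$node
  long <- dplyr::filter(long, .data$node %in% nodes)
  cal_curves <- purrr::map_dfr(seq_along(calibs$node), function(i) {
    nd <- calibs$node[i]
    if (!nd %in% nodes) return(NULL)
    v <- long$age[long$node == nd]
    grid <- seq(min(v), max(v), length.out = 200)
    tibble::tibble(
      node = nd, t = grid,
      density = cal_pdf(calibs$density[[i]], grid)
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = 60, fill = "grey70"
    ) +
    ggplot2::geom_line(
      data = cal_curves,
      ggplot2::aes(x = .data$t, y = .data$density),
      colour = "firebrick", linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~node, scales = "free") +
    ggplot2::labs(
      x = "node age (time units)", y = "density",
      title = "Effective time prior vs user-specified calibrations"
    )
}
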