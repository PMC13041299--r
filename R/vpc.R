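# Visual predictive check: observed percentiles per nominal time bin against
# the simulation band of the same percentiles under the (fitted) model.

#' Visual predictive check percentile bands
#'
#' Simulates `n_sim` replicates of the dataset under `params` (new random
#' effects and residual errors at the observed design, see
#' [simulate.qtcfit()]) and contrasts, per nominal time bin, the observed
#' 5th/50th/95th QTcF percentiles with the 95% simulation band of those
#' percentiles.
#'
#' @param data trial dataset, or pass a [qtcfit()] object as `data` to use
#'   its data and estimates.
#' @param params [qtc_params()] to simulate under (ignored when `data` is a
#'   fit).
#' @param n_sim number of simulation replicates (>= 100).
#' @param seed optional integer seed.
#' @param probs percentiles to track.
#' @param bins optional numeric vector of bin breaks on `TIME_H`; default
#'   one bin per distinct nominal time.
#' @return object of class `qtc_vpc`: a data.frame with one row per bin and
#'   percentile: `time`, `n`, `prob`, `obs`, `sim_lo`, `sim_med`, `sim_hi`.
#' @export
qtc_vpc <- function(data, params = qtc_params(), n_sim = 200, seed = NULL,
                    probs = c(0.05, 0.5, 0.95), bins = NULL) {
  if (inherits(data, "qtcfit")) {
    params <- coef(data)
    data <- data$data
  }
  if (n_sim < 100) stop("n_sim must be at least 100")
  data <- prepare_qtc_data(data)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bins)) {
    bin <- factor(data$TIME_H)
    btime <- as.numeric(levels(bin))
  } else {
    bin <- cut(data$TIME_H, breaks = bins, include.lowest = TRUE)
    if (any(is.na(bin))) {
      warning("records outside bin breaks dropped")
      keep <- !is.na(bin)
      data <- data[keep, , drop = FALSE]
      bin <- droplevels(bin[keep])
    }
    btime <- as.numeric(tapply(data$TIME_H, bin, median))
  }
  empty <- table(bin) == 0
  if (any(empty)) {
    warning("empty time bins dropped: ",
            paste(names(which(empty)), collapse = ", "))
    bin <- droplevels(bin)
    btime <- btime[!empty]
  }
  sims <- simulate_qtcf_replicates(data, params, n_sim)
  ix <- split(seq_len(nrow(data)), bin)
  out <- list()
  for (b in seq_along(ix)) {
    o <- quantile(data$QTCF_MS[ix[[b]]], probs, names = FALSE)
    sq <- apply(sims[ix[[b]], , drop = FALSE], 2, quantile, probs = probs,
                names = FALSE)
    if (is.null(dim(sq))) sq <- matrix(sq, nrow = length(probs))
    band <- apply(sq, 1, quantile, probs = c(0.025, 0.5, 0.975),
                  names = FALSE)
    out[[b]] <- data.frame(time = btime[b], n = length(ix[[b]]),
                           prob = probs, obs = o,
                           sim_lo = band[1, ], sim_med = band[2, ],
                           sim_hi = band[3, ])
  }
  structure(do.call(rbind, out), class = c("qtc_vpc", "data.frame"),
            n_sim = n_sim)
}

#' @export
plot.qtc_vpc <- function(x, ...) {
  d <- as.data.frame(x)
  plot(range(d$time) / 24, range(c(d$obs, d$sim_lo, d$sim_hi)),
       type = "n", xlab = "Time since first dose (days)",
       ylab = "QTcF (ms)", ...)
  for (p in unique(d$prob)) {
    dp <- d[d$prob == p, ]
    dp <- dp[order(dp$time), ]
    polygon(c(dp$time, rev(dp$time)) / 24, c(dp$sim_lo, rev(dp$sim_hi)),
            col = adjustcolor("steelblue", 0.3), border = NA)
    lines(dp$time / 24, dp$obs, lwd = 2)
  }
  legend("topleft", legend = c("observed percentile", "95% simulation band"),
         lwd = c(2, 8), col = c("black", adjustcolor("steelblue", 0.3)),
         bty = "n", cex = 0.8)
  invisible(x)
}
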