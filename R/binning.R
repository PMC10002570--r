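# Spatial and temporal binning of TCSPC stacks. The published analysis bins
# 20 x 20 pixels / 2 time channels before fitting and 10 x 10 pixels before
# phasor analysis; sliding-window (shape-preserving) binning is the default
# because the published parametric images retain full resolution.

# sliding-window sum along rows with edge truncation
row_window_sum <- function(M, w) {
  n <- nrow(M)
  if (w == 1L) return(M)
  r0 <- (w - 1L) %/% 2L
  r1 <- w - 1L - r0
  C <- rbind(0, apply(M, 2, cumsum))
  hi <- pmin(n, seq_len(n) + r1) + 1L
  lo <- pmax(1L, seq_len(n) - r0)
  C[hi, , drop = FALSE] - C[lo, , drop = FALSE]
}

box_sum <- function(M, w) {
  t(row_window_sum(t(row_window_sum(M, w)), w))
}

block_sum <- function(M, w) {
  n1 <- (nrow(M) %/% w) * w
  n2 <- (ncol(M) %/% w) * w
  M <- M[seq_len(n1), seq_len(n2), drop = FALSE]
  g1 <- rep(seq_len(n1 %/% w), each = w)
  A <- rowsum(M, g1)
  t(rowsum(t(A), rep(seq_len(n2 %/% w), each = w)))
}

#' Binning policy
#'
#' @param spatial Square spatial window size in pixels (>= 1).
#' @param temporal Time-channel merge factor (>= 1); an odd trailing channel
#'   (e.g. 783 channels at factor 2 -> 391 pairs) is dropped with a message.
#' @param mode `"sliding"` (shape-preserving, window centered on each output
#'   pixel and truncated at image edges) or `"block"` (non-overlapping
#'   windows; output shape shrinks, trailing rows/cols are dropped).
#' @return An object of class `binning_policy`.
#' @export
binning_policy <- function(spatial = 1L, temporal = 1L,
                           mode = c("sliding", "block")) {
  spatial <- as.integer(spatial); temporal <- as.integer(temporal)
  stopifnot(spatial >= 1L, temporal >= 1L)
  structure(list(spatial = spatial, temporal = temporal,
                 mode = match.arg(mode)),
            class = "binning_policy")
}

#' Bin a TCSPC image spatially and temporally
#'
#' Spatial binning sums photon counts over the window (sliding or block mode);
#' temporal binning sums groups of consecutive channels and widens the channel
#' accordingly. Acquisition metadata is updated to match.
#'
#' @param image A [tcspc_image()].
#' @param policy A [binning_policy()].
#' @return A [tcspc_image()] of binned counts.
#' @export
bin_image <- function(image, policy) {
  stopifnot(inherits(image, "tcspc_image"), inherits(policy, "binning_policy"))
  counts <- image$counts
  d <- dim(counts)
  if (policy$spatial > min(d[1:2]))
    stop("spatial window (", policy$spatial,
         ") larger than image (", d[1], " x ", d[2], ")")
  nchan_out <- d[3] %/% policy$temporal
  dropped <- d[3] - nchan_out * policy$temporal
  if (dropped > 0L)
    message("bin_image: dropping ", dropped,
            " trailing time channel(s) (", d[3], " -> ", nchan_out,
            " merged channels)")
  # temporal first (cheap dimension reduction)
  if (policy$temporal > 1L) {
    M <- matrix(counts, d[1] * d[2], d[3])
    M <- M[, seq_len(nchan_out * policy$temporal), drop = FALSE]
    grp <- rep(seq_len(nchan_out), each = policy$temporal)
    M <- t(rowsum(t(M), grp))
    counts <- array(M, c(d[1], d[2], nchan_out))
  }
  shape_out <- if (policy$mode == "sliding") d[1:2]
    else (d[1:2] %/% policy$spatial)
  if (policy$spatial > 1L) {
    out <- array(0, c(shape_out, nchan_out))
    for (k in seq_len(nchan_out)) {
      out[, , k] <- if (policy$mode == "sliding")
        box_sum(counts[, , k], policy$spatial)
      else block_sum(counts[, , k], policy$spatial)
    }
    counts <- out
  }
  acq <- image$acq
  acq2 <- acquisition_params(acq$rep_rate, nchan_out,
                             acq$channel_width * policy$temporal,
                             shape_out, acq$harmonic)
  prov <- image$provenance
  prov$binning <- list(spatial = policy$spatial, temporal = policy$temporal,
                       mode = policy$mode, dropped_channels = dropped)
  tcspc_image(counts, acq2, provenance = prov)
}
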