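# Synthetic TCSPC FLIM data with the statistical structure the downstream
# analysis assumes: Poisson photon counting of IRF-convolved bi-exponential
# decays, homogeneous regions, and bright short-lifetime aggregates.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' TCSPC image container
#'
#' A 3-D photon-count histogram stack indexed `(row, col, channel)` plus its
#' acquisition metadata; the raw input of the analysis pipeline.
#'
#' @param counts Non-negative integer array `rows x cols x channels`.
#' @param acq An [acquisition_params()]; `dim(counts)[3]` must equal
#'   `acq$n_channels` and `dim(counts)[1:2]` must equal `acq$image_shape`.
#' @param provenance Free-form list recording how the stack was produced
#'   (seed, preset name, ...).
#' @return An object of class `tcspc_image`.
#' @export
tcspc_image <- function(counts, acq, provenance = list()) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L,
            inherits(acq, "acquisition_params"))
  if (dim(counts)[3] != acq$n_channels)
    stop("channel axis length (", dim(counts)[3],
         ") does not equal acq$n_channels (", acq$n_channels, ")")
  if (!all(dim(counts)[1:2] == acq$image_shape))
    stop("image shape mismatch with acquisition metadata")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, acq = acq, provenance = provenance),
            class = "tcspc_image")
}

#' @export
print.tcspc_image <- function(x, ...) {
  cat(sprintf("TCSPC image: %d x %d x %d channels, %.3g photons total\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              sum(x$counts)))
  invisible(x)
}

#' Simulate one pixel's TCSPC count histogram
#'
#' Draws per-channel counts as independent Poisson variates with expectation
#' proportional to [expected_decay()], scaled so the expected total equals
#' `n_photons`.
#'
#' @param model A [decay_model()].
#' @param irf An [irf_model()].
#' @param acq An [acquisition_params()].
#' @param n_photons Expected total photon count (>= 0).
#' @param seed Optional integer seed; identical seeds give identical
#'   histograms (the caller's RNG state is preserved).
#' @return Integer vector of length `acq$n_channels`.
#' @export
simulate_decay_histogram <- function(model, irf, acq, n_photons, seed = NULL) {
  stopifnot(is.numeric(n_photons), length(n_photons) == 1L,
            is.finite(n_photons))
  if (n_photons < 0) stop("n_photons must be >= 0")
  if (n_photons == 0) return(integer(acq$n_channels))
  mu <- expected_decay(model, irf, acq)
  lambda <- n_photons * mu / sum(mu)
  with_seed(seed, as.integer(stats::rpois(length(lambda), lambda)))
}

#' Phantom layout for synthetic TCSPC images
#'
#' A phantom is a set of regions (pixel masks with a decay model and a mean
#' photon budget per pixel) optionally overlaid with disk-shaped aggregates
#' that substitute their own decay model and multiply the photon budget —
#' emulating the bright, short-lifetime aggregates seen in melanin
#' suspensions.
#'
#' @param regions List of regions, each `list(mask =, model =, photons =)`
#'   with `mask` a logical matrix over the image, `model` a [decay_model()],
#'   and `photons` the mean photons per pixel.
#' @param aggregates Optional list of aggregates, each
#'   `list(center = c(row, col), radius =, intensity =, model =)`; `intensity`
#'   multiplies the underlying region's photon budget. Overlapping aggregates
#'   are applied in order (last wins).
#' @return An object of class `phantom_layout`.
#' @export
phantom_layout <- function(regions, aggregates = list()) {
  stopifnot(is.list(regions), length(regions) >= 1L)
  for (r in regions) {
    stopifnot(is.logical(r$mask), inherits(r$model, "decay_model"),
              is.numeric(r$photons), r$photons >= 0)
  }
  for (a in aggregates) {
    stopifnot(length(a$center) == 2L, a$radius > 0, a$intensity > 0,
              inherits(a$model, "decay_model"))
  }
  structure(list(regions = regions, aggregates = aggregates),
            class = "phantom_layout")
}

#' Uniform single-region layout helper
#'
#' @param acq An [acquisition_params()] providing the image shape.
#' @param model A [decay_model()].
#' @param photons Mean photons per pixel.
#' @param aggregates Passed to [phantom_layout()].
#' @return A [phantom_layout()] with one region covering the whole image.
#' @export
uniform_layout <- function(acq, model, photons, aggregates = list()) {
  mask <- matrix(TRUE, acq$image_shape[1], acq$image_shape[2])
  phantom_layout(list(list(mask = mask, model = model, photons = photons)),
                 aggregates = aggregates)
}

disk_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Render a phantom into a TCSPC image
#'
#' Per-pixel histograms are drawn independently (Poisson per channel) from the
#' expected decay of the pixel's region — or aggregate, where one overlaps.
#'
#' @param layout A [phantom_layout()].
#' @param irf An [irf_model()].
#' @param acq An [acquisition_params()].
#' @param seed Optional integer seed; identical `(layout, seed)` give a
#'   bit-identical image.
#' @return A [tcspc_image()].
#' @export
render_phantom <- function(layout, irf, acq, seed = NULL) {
  stopifnot(inherits(layout, "phantom_layout"))
  shape <- acq$image_shape
  nchan <- acq$n_channels
  # resolve per-pixel model id and budget
  model_id <- matrix(NA_integer_, shape[1], shape[2])
  budget <- matrix(0, shape[1], shape[2])
  models <- list()
  for (r in layout$regions) {
    if (!all(dim(r$mask) == shape)) stop("region mask does not match image shape")
    models[[length(models) + 1L]] <- r$model
    model_id[r$mask] <- length(models)
    budget[r$mask] <- r$photons
  }
  overlap <- 0L
  agg_seen <- matrix(FALSE, shape[1], shape[2])
  for (a in layout$aggregates) {
    m <- disk_mask(shape, a$center, a$radius) & !is.na(model_id)
    if (any(m & agg_seen)) overlap <- overlap + 1L
    agg_seen <- agg_seen | m
    models[[length(models) + 1L]] <- a$model
    model_id[m] <- length(models)
    budget[m] <- budget[m] * a$intensity
  }
  if (overlap > 0L)
    message("render_phantom: ", overlap,
            " overlapping aggregate(s); last wins")
  counts <- array(0L, c(shape[1], shape[2], nchan))
  with_seed(seed, {
    for (mid in seq_along(models)) {
      sel <- which(model_id == mid)       # column-major pixel indices
      if (!length(sel)) next
      mu <- expected_decay(models[[mid]], irf, acq)
      p <- mu / sum(mu)
      lam <- outer(p, budget[sel])        # nchan x npix
      draws <- stats::rpois(length(lam), lam)
      # scatter channel-major draws into the (pixel, channel) slab
      npix <- length(sel)
      idx <- rep(sel, each = nchan) +
        prod(shape) * rep(seq_len(nchan) - 1L, npix)
      counts[idx] <- as.integer(draws)
    }
  })
  tcspc_image(counts, acq,
              provenance = list(seed = seed,
                                n_regions = length(layout$regions),
                                n_aggregates = length(layout$aggregates)))
}
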