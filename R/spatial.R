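#' PFT class vocabulary
#'
#' Fixed vocabulary of plant functional type labels used by grids and
#' biomass models.  `"other"` marks non-vegetated pixels and is masked in
#' anomaly maps; `"urban"` pixels carry a vegetated model (by default the
#' agriculture model, reflecting urban green space adjacent to
#' agricultural land).
#'
#' @return character vector of class labels.
#' @export
pft_classes <- function() {
  c("forest", "agriculture", "grassland", "urban", "other")
}

#' Categorical PFT grid
#'
#' @param classes character matrix of class labels from [pft_classes()].
#' @param pixel_size pixel edge length, metres (> 0).
#' @param origin numeric `(x, y)` of the lower-left corner, metres.
#' @return an object of class `pft_grid`.
#' @export
pft_grid <- function(classes, pixel_size = 500, origin = c(0, 0)) {
  if (!is.matrix(classes)) stop("classes must be a matrix")
  bad <- setdiff(unique(as.vector(classes)), c(pft_classes(), NA))
  if (length(bad))
    stop("unknown PFT class(es): ", paste(bad, collapse = ", "))
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(classes = classes, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "pft_grid")
}

#' @export
print.pft_grid <- function(x, ...) {
  tab <- table(x$classes)
  cat(sprintf("<pft_grid> %dx%d @ %gm: %s\n", nrow(x$classes),
              ncol(x$classes), x$pixel_size,
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Gridded anomaly field
#'
#' @param values numeric matrix of fractional anomalies; `NA` marks masked
#'   pixels.
#' @param pixel_size pixel edge length, metres.
#' @param origin `(x, y)` lower-left corner.
#' @param units units tag, default `"fraction"`.
#' @return an object of class `grid_field`.
#' @export
grid_field <- function(values, pixel_size = 500, origin = c(0, 0),
                       units = "fraction") {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(values = values, pixel_size = pixel_size,
                 origin = as.numeric(origin), units = units),
            class = "grid_field")
}

#' Per-pixel emission anomaly map
#'
#' Evaluates the attribution pipeline pixel by pixel: each pixel's biomass
#' contribution comes from its own NDVI series through its class's
#' regression model, while the environmental drivers (temperature, CO2,
#' soil moisture) are spatially uniform series shared by all pixels.
#' Pixels of class `"other"` are masked; `"urban"` pixels use the model
#' named by `urban_model_class`.
#'
#' @param ndvi a `gridded_series` from [generate_gridded_ndvi()] (or of
#'   the same shape), co-registered with `pft`.
#' @param pft a [pft_grid()].
#' @param env list with spatially uniform [factor_series()] elements
#'   `temperature`, `co2`, `soil_moisture`.
#' @param model a [biomass_model()].
#' @param params a [response_params()].
#' @param reference_year anomaly origin.
#' @param target_year year of the mapped anomaly; default the last year.
#' @param include_interaction include the interaction term?
#' @param urban_model_class biomass model used for urban pixels.
#' @return a [grid_field()] of fractional anomalies.
#' @export
pixel_anomaly <- function(ndvi, pft, env, model = default_biomass_model(),
                          params = response_params(),
                          reference_year = 1978, target_year = NULL,
                          include_interaction = TRUE,
                          urban_model_class = "agriculture") {
  stopifnot(inherits(ndvi, "gridded_series"), inherits(pft, "pft_grid"))
  nr <- nrow(pft$classes); nc <- ncol(pft$classes)
  if (!all(dim(ndvi$values)[1:2] == c(nr, nc)))
    stop("NDVI stack geometry does not match the PFT grid")
  if (!is.null(ndvi$grid) &&
      !isTRUE(all.equal(ndvi$grid$pixel_size, pft$pixel_size)))
    stop("NDVI stack geometry does not match the PFT grid")

  yrs <- floor(ndvi$timestamps)
  if (is.null(target_year)) target_year <- max(yrs)
  if (!reference_year %in% yrs || !target_year %in% yrs)
    stop("NDVI stack must cover both the reference and target years")

  ## per-pixel annual-mean NDVI at the two years
  mean_at <- function(year) {
    sel <- which(yrs == year)
    apply(ndvi$values[, , sel, drop = FALSE], c(1, 2), mean)
  }
  nd_ref <- mean_at(reference_year)
  nd_tgt <- mean_at(target_year)

  ## scalar environmental contributions at the target year
  tm <- annual_or_stop(env$temperature, c(reference_year, target_year),
                       "temperature")
  co <- annual_or_stop(env$co2, c(reference_year, target_year), "co2")
  sm <- annual_or_stop(env$soil_moisture, c(reference_year, target_year),
                       "soil_moisture")
  e_t <- temperature_activity(tm[2] - tm[1], params$beta_t)
  e_c <- isoprene_to_total(co2_activity(co[2] / co[1], params$beta_co2),
                           params$isoprene_share)
  e_s <- soil_moisture_contribution(sm[2], sm[1])
  env_c <- e_t + e_c + e_s

  out <- matrix(NA_real_, nr, nc)
  for (cls in setdiff(unique(as.vector(pft$classes)), c("other", NA))) {
    model_cls <- if (cls == "urban") urban_model_class else cls
    idx <- which(pft$classes == cls)
    b_ref <- ndvi_to_biomass(nd_ref[idx], model_cls, model)
    b_tgt <- ndvi_to_biomass(nd_tgt[idx], model_cls, model)
    bio <- b_tgt / b_ref - 1
    net <- bio + env_c
    if (include_interaction) net <- net + bio * env_c
    out[idx] <- net
  }
  grid_field(out, pixel_size = pft$pixel_size, origin = pft$origin)
}

#' Mixing-length smoothing of an anomaly field
#'
#' Smooths a field with an isotropic kernel whose radius represents the
#' average atmospheric transfer-and-mixing distance of BVOCs (default
#' interpretation: a uniform disc; a Gaussian with `sigma = radius / 2`
#' is selectable).  Masked (`NA`) pixels are excluded from both numerator
#' and denominator; at the domain boundary the truncated kernel is
#' renormalised (or wrapped periodically with `wrap = TRUE`).
#'
#' @param field a [grid_field()].
#' @param radius_km kernel radius in km (>= 0); 0 returns the field
#'   unchanged.
#' @param kernel `"disc"` (default) or `"gaussian"`.
#' @param wrap treat the domain as periodic (no boundary truncation)?
#' @return a smoothed [grid_field()].
#' @export
smooth_field <- function(field, radius_km, kernel = c("disc", "gaussian"),
                         wrap = FALSE) {
  stopifnot(inherits(field, "grid_field"))
  kernel <- match.arg(kernel)
  if (radius_km < 0) stop("radius must be non-negative")
  if (radius_km == 0) return(field)
  r_px <- radius_km * 1000 / field$pixel_size
  ext <- if (kernel == "disc") floor(r_px) else ceiling(3 * r_px / 2)
  offs <- expand.grid(dy = -ext:ext, dx = -ext:ext)
  d2 <- offs$dy^2 + offs$dx^2
  if (kernel == "disc") {
    keep <- d2 <= r_px^2
    offs <- offs[keep, ]
    w <- rep(1, nrow(offs))
  } else {
    sigma <- r_px / 2
    keep <- d2 <= (3 * sigma)^2
    offs <- offs[keep, ]
    w <- exp(-d2[keep] / (2 * sigma^2))
  }

  v <- field$values
  nr <- nrow(v); nc <- ncol(v)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  vz <- ifelse(is.na(v), 0, v)
  ok <- !is.na(v)
  for (k in seq_len(nrow(offs))) {
    sv <- shift_matrix(vz, offs$dy[k], offs$dx[k], wrap)
    so <- shift_matrix(ok * 1, offs$dy[k], offs$dx[k], wrap)
    num <- num + w[k] * sv
    den <- den + w[k] * so
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  out[is.na(v)] <- NA_real_
  grid_field(out, pixel_size = field$pixel_size, origin = field$origin,
             units = field$units)
}

## Shift a matrix by (dy, dx), filling with 0 (or wrapping periodically).
## out[i, j] = m[i + dy, j + dx] where in range.
shift_matrix <- function(m, dy, dx, wrap = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  if (wrap) {
    ri <- ((seq_len(nr) - 1 + dy) %% nr) + 1
    ci <- ((seq_len(nc) - 1 + dx) %% nc) + 1
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(0, nr, nc)
  ri <- seq_len(nr) + dy
  ci <- seq_len(nc) + dx
  rok <- ri >= 1 & ri <= nr
  cok <- ci >= 1 & ci <= nc
  if (any(rok) && any(cok))
    out[which(rok), which(cok)] <- m[ri[rok], ci[cok], drop = FALSE]
  out
}
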