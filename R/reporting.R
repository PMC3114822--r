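## Publication-style outputs: smoothed concentration surface maps and
## side-by-side coefficient tables.

#' Smoothed concentration surface map
#'
#' Fits log concentration on a bivariate spatial smooth (optionally plus
#' sampling-shift dummies, to remove diurnal background before mapping),
#' predicts on a regular lattice over the observation bounding box and
#' exponentiates back to original units. Lattice cells farther than
#' `mask_radius` from every observation are masked (`NA`).
#'
#' @param observations Data frame with `easting`, `northing`, a pollutant
#'   column and (if `adjust_by_shift`) `shift_id`.
#' @param pollutant Column name (`"ufp"`, `"pm25"`, `"pah"`).
#' @param adjust_by_shift Remove per-shift offsets before mapping (the
#'   shift-adjusted surface used for background-dominated pollutants).
#' @param k Spatial basis dimension for the descriptive map (default 60,
#'   richer than the model's adjustment surface).
#' @param cell Lattice resolution in metres (default 10).
#' @param mask_radius Metres from the nearest observation beyond which cells
#'   are masked (default 100).
#' @return A `surface_map`: data frame `easting`, `northing`, `value`
#'   (original units; NA where masked), `masked`; attributes `pollutant`,
#'   `adjustment`.
#' @export
surface_map <- function(observations, pollutant = "ufp",
                        adjust_by_shift = FALSE, k = 60, cell = 10,
                        mask_radius = 100) {
  if (nrow(observations) < 100)
    stop("surface_map needs at least 100 observations")
  yl <- log(observations[[pollutant]])
  coords <- cbind(observations$easting, observations$northing)
  sm <- build_spatial_basis(coords, k = k, name = "f_map")
  if (adjust_by_shift) {
    sh <- droplevels(factor(observations$shift_id))
    Xp <- stats::model.matrix(~sh, data.frame(sh = sh))
    colnames(Xp) <- c("(Intercept)", paste0("shift_", levels(sh)[-1]))
  } else {
    Xp <- matrix(1, nrow(observations), 1,
                 dimnames = list(NULL, "(Intercept)"))
  }
  pf <- fit_penalized(yl, Xp, list(sm))

  gx <- seq(min(coords[, 1]), max(coords[, 1]), by = cell)
  gy <- seq(min(coords[, 2]), max(coords[, 2]), by = cell)
  grid <- as.matrix(expand.grid(easting = gx, northing = gy))
  B <- sm$evalmat(grid)
  idx <- pf$blocks[["f_map"]]
  eta <- pf$beta[1] + as.numeric(B %*% pf$beta[idx])

  ## mask cells with no observation within reach (block over grid chunks)
  masked <- rep(TRUE, nrow(grid))
  r2max <- mask_radius^2
  chunk <- 2000L
  for (i0 in seq(1, nrow(grid), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nrow(grid))
    d2 <- outer(grid[ii, 1], coords[, 1], "-")^2 +
      outer(grid[ii, 2], coords[, 2], "-")^2
    masked[ii] <- apply(d2, 1, min) > r2max
  }
  value <- exp(eta)
  value[masked] <- NA_real_
  structure(data.frame(easting = grid[, 1], northing = grid[, 2],
                       value = value, masked = masked),
            pollutant = pollutant,
            adjustment = if (adjust_by_shift) "shift-adjusted" else "none",
            class = c("surface_map", "data.frame"))
}

#' Side-by-side coefficient table for a set of fits
#'
#' One row per covariate or smooth term, one column block per model
#' (estimate / lower 95% CI / upper 95% CI / p), mirroring the layout of
#' published model-comparison tables; smooth terms carry `NA` in the
#' estimate and CI columns and a final `R^2` row closes each block. Row
#' order follows the first fit's covariate order.
#'
#' @param fits Named list of `mg_fit`s sharing a pollutant.
#' @param digits Numbers are rounded to this many decimals (default 3).
#' @return Data frame.
#' @export
results_tables <- function(fits, digits = 3) {
  if (!length(fits)) stop("no fits supplied")
  pols <- unique(vapply(fits, `[[`, "", "pollutant"))
  if (length(pols) > 1)
    stop("fits mix pollutants: ", paste(pols, collapse = ", "))
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, `[[`, "", "model_kind")
  terms <- unique(unlist(lapply(fits, function(f) f$table$term)))
  out <- data.frame(term = c(terms, "R^2"), stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    tb <- fits[[nm]]$table
    m <- match(terms, tb$term)
    block <- data.frame(estimate = round(tb$estimate[m], digits),
                        lo95 = round(tb$lo95[m], digits),
                        hi95 = round(tb$hi95[m], digits),
                        p = round(tb$p[m], digits))
    block <- rbind(block, data.frame(estimate = round(fits[[nm]]$r2, digits),
                                     lo95 = NA, hi95 = NA, p = NA))
    names(block) <- paste(nm, names(block), sep = ".")
    out <- cbind(out, block)
  }
  out
}
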